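test_that("valency enumeration matches the combinatorics", {
  expect_length(enumerate_valencies(2, FALSE), 1)
  expect_length(enumerate_valencies(4, FALSE), 3)
  expect_length(enumerate_valencies(4, TRUE), 4)
  expect_length(enumerate_valencies(6, FALSE), 15)
  expect_length(enumerate_valencies(6, TRUE), 30)
  mv <- vapply(enumerate_valencies(6, TRUE), attr, logical(1), "multivalent")
  expect_equal(sum(mv), 15)
  # gamete states: 2 per bivalent, 10 per quadrivalent
  expect_length(gamete_states(enumerate_valencies(4, FALSE)[[1]]), 4)
  quad <- Filter(function(v) isTRUE(attr(v, "multivalent")),
                 enumerate_valencies(4, TRUE))[[1]]
  expect_length(gamete_states(quad), 10)
  doubled <- vapply(gamete_states(quad), attr, logical(1), "doubled")
  expect_equal(sum(doubled), 4)
})

test_that("transition matrices are stochastic and Haldane-consistent", {
  for (v in enumerate_valencies(4, TRUE)) {
    for (r in c(0, 0.1, 0.5)) {
      Tm <- transition_matrix(v, r)
      expect_equal(rowSums(Tm), rep(1, nrow(Tm)), tolerance = 1e-12)
      expect_true(all(Tm >= 0))
    }
    expect_equal(transition_matrix(v, 0),
                 diag(nrow(transition_matrix(v, 0))))
  }
  expect_equal(haldane(0), 0)
  expect_equal(haldane(Inf), 0.5)
  expect_equal(haldane(50), (1 - exp(-1)) / 2)
})

test_that("HMM matches the exhaustive oracle on small instances", {
  map <- toy_tetra_map()
  dos <- toy_tetra_dosages()
  for (mv in c(FALSE, TRUE)) {
    bf <- brute_force_ibd(map, dos, 0.05, mv)
    hm <- estimate_ibd_hmm(map, dos, 0.05, allow_multivalents = mv)
    expect_lt(max(abs(bf$X - hm$lg[["1"]]$X)), 1e-10)
    if (mv) expect_lt(max(abs(bf$dr - hm$lg[["1"]]$dr)), 1e-10)
  }
})

test_that("HMM matches the oracle on 1- and 2-marker subsets and with missing data", {
  full <- toy_tetra_map()
  for (nmk in 1:2) {
    keep <- seq_len(nmk)
    map <- phased_map(full$marker[keep], rep(1, nmk), full$position[keep],
                      full$phase[keep, , drop = FALSE], 4, 4)
    v <- matrix(c(1, NA, 2, 3)[seq_len(2 * nmk)], 2, nmk,
                dimnames = list(c("i1", "i2"), full$marker[keep]))
    dos <- dosage_data(v, 4)
    bf <- brute_force_ibd(map, dos, 0.02)
    hm <- estimate_ibd_hmm(map, dos, 0.02)
    expect_lt(max(abs(bf$X - hm$lg[["1"]]$X)), 1e-10)
  }
})

test_that("HMM matches the oracle on probabilistic dosages", {
  map <- toy_tetra_map()
  v <- array(0, dim = c(2, 3, 5),
             dimnames = list(c("i1", "i2"), c("a", "b", "c"), NULL))
  v[1, 1, ] <- c(0.1, 0.8, 0.1, 0, 0)
  v[1, 2, ] <- c(0, 0.2, 0.7, 0.1, 0)
  v[1, 3, ] <- c(0, 0, 1, 0, 0)
  v[2, 1, ] <- c(0.9, 0.1, 0, 0, 0)
  v[2, 2, ] <- c(0, 0, 0, 0.5, 0.5)
  v[2, 3, ] <- c(0, 0.6, 0.4, 0, 0)
  dos <- dosage_data(v, 4, type = "prob")
  bf <- brute_force_ibd(map, dos, 0.05)
  hm <- estimate_ibd_hmm(map, dos, 0.05)
  expect_lt(max(abs(bf$X - hm$lg[["1"]]$X)), 1e-10)
})

test_that("HMM matches the oracle on a triploid (4x2) cross", {
  ph <- rbind(c(1, 0, 0, 0, 1, 0),
              c(0, 1, 1, 0, 0, 1),
              c(1, 1, 0, 1, 0, 0))
  map <- phased_map(c("a", "b", "c"), c(1, 1, 1), c(0, 15, 40), ph, 4, 2)
  dos <- dosage_data(matrix(c(2, 1, 2, 0, 1, 1), 2, 3, byrow = TRUE,
                            dimnames = list(c("i1", "i2"),
                                            c("a", "b", "c"))), 3)
  bf <- brute_force_ibd(map, dos, 0.03)
  hm <- estimate_ibd_hmm(map, dos, 0.03)
  expect_lt(max(abs(bf$X - hm$lg[["1"]]$X)), 1e-10)
})

test_that("HMM output satisfies invariants and handles edge cases", {
  map <- toy_tetra_map()
  dos <- toy_tetra_dosages()
  ibd <- estimate_ibd_hmm(map, dos, 0.05)
  expect_true(validate_ibd(ibd))
  expect_true(all(is.finite(ibd$lg[["1"]]$loglik)))
  expect_null(ibd$lg[["1"]]$dr)  # bivalent-only: no DR track
  # valency posteriors sum to 1 per individual
  expect_equal(unname(rowSums(ibd$lg[["1"]]$val_post$p1)), c(1, 1),
               tolerance = 1e-9)

  # an all-missing individual gets uniform probabilities and is flagged
  v <- rbind(dos$values, i3 = c(NA, NA, NA))
  ibd2 <- estimate_ibd_hmm(map, dosage_data(v, 4), 0.05)
  expect_equal(ibd2$lg[["1"]]$all_missing, "i3")
  expect_equal(unname(ibd2$lg[["1"]]$X[, 3, ]),
               matrix(0.5, 3, 8), tolerance = 1e-9)

  # invalid inputs
  expect_error(estimate_ibd_hmm(map, dos, 0), "error_prior")
  expect_error(estimate_ibd_hmm(map, dosage_data(dos$values, 5), 0.01),
               "ploidy")
})

test_that("tied map positions (0 cM apart) are handled via the floor", {
  ph <- rbind(c(1, 0, 0, 0, 0, 0, 0, 0),
              c(0, 1, 0, 0, 1, 0, 0, 0),
              c(0, 0, 1, 1, 0, 0, 1, 1))
  map <- phased_map(c("a", "b", "c"), c(1, 1, 1), c(0, 10, 10), ph, 4, 4)
  dos <- dosage_data(matrix(c(1, 1, 2), 1, 3,
                            dimnames = list("i1", c("a", "b", "c"))), 4)
  ibd <- estimate_ibd_hmm(map, dos, 0.05)
  expect_true(validate_ibd(ibd))
  expect_true(all(is.finite(ibd$lg[["1"]]$X)))
})

test_that("HMM recovers simulated truth on a small multivalent cross", {
  cfg <- sim_config(n_offspring = 60, n_chromosomes = 1, n_markers = 50,
                    multivalent_prob = 0.3, seed = 101)
  sim <- simulate_cross(cfg)
  ibd <- estimate_ibd_hmm(sim$map, sim$dosages, 0.01,
                          allow_multivalents = TRUE,
                          multivalent_prior = 0.3)
  expect_lt(true_ibd_error(ibd, sim$truth), 0.1)
  # DR probabilities populated and within [0, 1]
  expect_true(!is.null(ibd$lg[["1"]]$dr))
  expect_true(all(ibd$lg[["1"]]$dr >= -1e-9 & ibd$lg[["1"]]$dr <= 1 + 1e-9))
})

test_that("HMM handles a hexaploid cross on a small instance", {
  cfg <- sim_config(ploidy1 = 6, ploidy2 = 6, n_offspring = 40,
                    n_chromosomes = 1, n_markers = 40, seed = 77)
  sim <- simulate_cross(cfg)
  ibd <- estimate_ibd_hmm(sim$map, sim$dosages, 0.01)
  expect_true(validate_ibd(ibd))
  expect_lt(true_ibd_error(ibd, sim$truth), 0.12)
})
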