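# Shared small multivalent simulation + HMM estimate for diagnostics.
mei_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(n_offspring = 60, n_chromosomes = 1, n_markers = 50,
                      multivalent_prob = 0.3, seed = 301)
    sim <- simulate_cross(cfg)
    ibd <- estimate_ibd_hmm(sim$map, sim$dosages, 0.01,
                            allow_multivalents = TRUE,
                            multivalent_prior = 0.3)
    cache <<- list(sim = sim, ibd = ibd)
    cache
  }
})

test_that("count_valencies assigns plausible pairings and counts multivalents", {
  s <- mei_sim()
  vc <- count_valencies(s$ibd, plausibility = 0.4)
  expect_s3_class(vc, "valency_assignment")
  a <- vc$assignments
  expect_equal(nrow(a), 60 * 2)  # one row per individual x parent
  expect_true(all(a$posterior >= 0.4 | !a$plausible))
  expect_true(all(a$label[!a$plausible] == "ambiguous"))
  # predicted multivalent fraction in the right ballpark of the simulated 0.3
  mv_frac <- sum(vc$multivalent_counts$n_multivalent) /
    sum(vc$multivalent_counts$n_assigned)
  expect_gt(mv_frac, 0.1)
  expect_lt(mv_frac, 0.5)
  # assignments agree with the simulated valency for most confident meioses
  truth <- s$sim$truth$meioses
  merged <- merge(a[a$plausible, ], truth,
                  by = c("individual", "parent"))
  expect_gt(mean(merged$multivalent.x == merged$multivalent.y), 0.7)

  # heuristic IBDs carry no valency posteriors
  heur <- estimate_ibd_heuristic(s$sim$map, s$sim$dosages)
  expect_error(count_valencies(heur), "HMM")
})

test_that("double_reduction_rate tracks the simulated terminal DR landscape", {
  s <- mei_sim()
  dr <- double_reduction_rate(s$ibd)
  expect_true(all(dr$rate >= 0 & dr$rate <= 1))
  # terminal mechanism: more DR at the telomere than at the centromere
  expect_gt(dr$rate[nrow(dr)], dr$rate[1])
  # combined rate is the union of the per-parent rates
  l <- s$ibd$lg[["1"]]
  comb <- rowMeans(1 - (1 - l$dr[, , 1]) * (1 - l$dr[, , 2]))
  expect_equal(dr$rate, comb, tolerance = 1e-12)

  # bivalent-only IBDs: identically zero, with a warning
  ibd0 <- estimate_ibd_hmm(toy_tetra_map(), toy_tetra_dosages(), 0.05)
  expect_warning(dr0 <- double_reduction_rate(ibd0), "multivalent")
  expect_true(all(dr0$rate == 0))
})

test_that("preferential-pairing chi-square matches hand-computed statistics", {
  # uniform pairing: every one of the 15 hexaploid matchings equally often
  vc_unif <- fabricated_assignment(setNames(rep(4L, 15), 1:15), ploidy = 6)
  pr <- test_preferential_pairing(vc_unif)
  expect_s3_class(pr, "pairing_report")
  expect_equal(pr$homologue_tests$statistic, rep(0, 12))
  expect_equal(pr$homologue_tests$p_value, rep(1, 12))
  expect_equal(pr$homologue_tests$df, rep(4L, 12))
  expect_equal(unique(pr$pair_counts$deviation), 0)

  # partner counts (100, 0, 0, 0, 0): statistic 400 on df = 4
  vals <- enumerate_valencies(6, FALSE)
  ab <- which(vapply(vals, function(v)
    any(vapply(v, function(u) all(u == c(1, 2)), logical(1))), logical(1)))
  cnt <- integer(0)
  cnt[as.character(ab[1])] <- 100L
  vc_ab <- fabricated_assignment(cnt, ploidy = 6)
  pr2 <- test_preferential_pairing(vc_ab)
  ta <- pr2$homologue_tests
  a_row <- ta[ta$parent == 1 & ta$homologue == "A", ]
  expect_equal(a_row$statistic, 400)
  expect_equal(a_row$df, 4L)
  expect_lt(a_row$p_value, 1e-10)

  # too few meioses warns
  vc_small <- fabricated_assignment(setNames(1L, 1), ploidy = 6)
  w <- capture_warnings(test_preferential_pairing(vc_small))
  expect_length(w, 2L)  # one per parent
  expect_match(w, "meioses", all = TRUE)
})

test_that("pairing test is calibrated on random-pairing simulations", {
  cfg <- sim_config(ploidy1 = 6, ploidy2 = 6, n_offspring = 400,
                    n_chromosomes = 1, n_markers = 5, seed = 411)
  sim <- simulate_cross(cfg)
  truth <- sim$truth$meioses
  vals <- enumerate_valencies(6, FALSE)
  labs <- vapply(vals, valency_label, character(1))
  counts <- table(factor(truth$valency[truth$parent == 1], levels = labs))
  vc <- fabricated_assignment(
    setNames(as.integer(counts), seq_along(vals)), ploidy = 6)
  pr <- test_preferential_pairing(vc)
  p1 <- pr$homologue_tests$p_value[pr$homologue_tests$parent == 1]
  # random pairing: no homologue strongly significant
  expect_gt(min(p1), 0.001)
})

test_that("recombination detection follows the sign-change midpoint rule", {
  # constructed track: +0.9 up to 30 cM, -0.9 after, grid points at 30/31
  pos <- c(0, 10, 20, 30, 31, 40, 50)
  X <- array(0.5, dim = c(7, 1, 8))
  X[, 1, 1] <- c(0.95, 0.95, 0.95, 0.95, 0.05, 0.05, 0.05)
  X[, 1, 2] <- 1 - X[, 1, 1]
  vp <- list(p1 = concentrated_val_post(4, 1L),  # (AB)(CD)
             p2 = concentrated_val_post(4, 1L))
  ibd <- manual_ibd(X, pos, val_post = vp, method = "hmm")
  rec <- count_recombinations(ibd)
  evAB <- rec$events[rec$events$pair == "AB", ]
  expect_equal(nrow(evAB), 1)
  expect_equal(evAB$position, 30.5)
  # all other tracks are constant: no further events
  expect_equal(nrow(rec$events), 1)
  expect_equal(rec$counts$recombinations, 1L)

  # constant IBD: zero events
  Xc <- array(0.5, dim = c(7, 1, 8))
  ibd0 <- manual_ibd(Xc, pos, val_post = vp, method = "hmm")
  rec0 <- count_recombinations(ibd0)
  expect_equal(nrow(rec0$events), 0)

  # a zero plateau between sign changes counts once, at its midpoint
  Xp <- array(0.5, dim = c(7, 1, 8))
  Xp[, 1, 1] <- c(0.9, 0.9, 0.5, 0.5, 0.5, 0.1, 0.1)
  Xp[, 1, 2] <- 1 - Xp[, 1, 1]
  ibdp <- manual_ibd(Xp, pos, val_post = vp, method = "hmm")
  recp <- count_recombinations(ibdp)
  evp <- recp$events[recp$events$pair == "AB", ]
  expect_equal(nrow(evp), 1)
  expect_equal(evp$position, (10 + 40) / 2)
})

test_that("recombination counts on simulation are close to the truth", {
  cfg <- sim_config(n_offspring = 60, n_chromosomes = 1, n_markers = 200,
                    seed = 421)
  sim <- simulate_cross(cfg)
  ibd <- estimate_ibd_hmm(sim$map, sim$dosages, 0.01)
  rec <- count_recombinations(ibd)
  truth <- stats::aggregate(crossovers ~ individual,
                            data = sim$truth$meioses, FUN = sum)
  est <- rec$counts$recombinations[match(truth$individual,
                                         rec$counts$individual)]
  expect_lt(mean(abs(est - truth$crossovers)), 0.5)
  # expected reference: offspring ploidy x number of LGs
  expect_equal(rec$expected, 4 * 1)
})

test_that("screen_outliers flags excessive recombination counts", {
  rec <- list(counts = data.frame(individual = c("i1", "i2", "i3"),
                                  recombinations = c(4L, 4L, 13L)),
              expected = 4)
  out <- screen_outliers(rec, multiplier = 2)
  expect_equal(out$individual, "i3")
  expect_equal(out$expected, 4)
  expect_true(is.na(out$missing_fraction))
  # with dosage data, the missing fraction is reported
  v <- matrix(c(1, 2, NA, 0, 1, 2), 3, 2,
              dimnames = list(c("i1", "i2", "i3"), c("a", "b")))
  out2 <- screen_outliers(rec, multiplier = 2, dosages = dosage_data(v, 4))
  expect_equal(out2$missing_fraction, 0.5)
  # all at expectation: nothing flagged
  rec0 <- list(counts = data.frame(individual = c("i1", "i2"),
                                   recombinations = c(4L, 4L)),
               expected = 4)
  expect_equal(nrow(screen_outliers(rec0)), 0)
})

test_that("GIC evaluates its closed forms and stays within [0, 1]", {
  # all P in {0, 1}: GIC = 1
  X1 <- array(0, dim = c(2, 4, 8))
  X1[, , c(1, 3, 5, 7)] <- 1
  g1 <- gic(manual_ibd(X1, c(0, 10), method = "heuristic"))
  expect_equal(unique(g1$GIC), 1)
  # all P = 0.5: GIC = 0
  g0 <- gic(manual_ibd(array(0.5, dim = c(2, 4, 8)), c(0, 10),
                       method = "heuristic"))
  expect_equal(unique(g0$GIC), 0)
  # all P = 0.25: GIC = 1 - 4 * 0.25 * 0.75 = 0.25
  g25 <- gic(manual_ibd(array(0.25, dim = c(2, 4, 8)), c(0, 10),
                        method = "heuristic"))
  expect_equal(unique(g25$GIC), 0.25)
  # estimated IBDs: bounds hold everywhere
  s <- mei_sim()
  gg <- gic(s$ibd)
  expect_true(all(gg$GIC >= -1e-9 & gg$GIC <= 1 + 1e-9))
  expect_true(all(gg$n <= 60))
})

test_that("impute_dosages applies the product-sum and rounding rules", {
  # one-hot X on homologues {1, 3}, phase (1,0,0,0 | 0,0,1,0): d-hat = 2
  ph <- rbind(c(1, 0, 0, 0, 0, 0, 1, 0),
              c(1, 0, 0, 0, 0, 0, 1, 0))
  map <- phased_map(c("a", "b"), c(1, 1), c(0, 10), ph, 4, 4)
  X <- array(0, dim = c(2, 1, 8))
  X[, 1, c(1, 3)] <- 1          # maternal: homologues 1 and 3
  X[, 1, c(6, 7)] <- 1          # paternal: homologues 6 and 7
  ibd <- manual_ibd(X, c(0, 10), markers = c("a", "b"), method = "hmm")
  imp <- impute_dosages(ibd, map)
  expect_equal(unname(imp$values["i1", ]), c(2, 2))

  # half-half mass over a carrier and a non-carrier: fractional 0.5, missing
  X2 <- X
  X2[1, 1, c(1, 3)] <- 0
  X2[1, 1, c(1, 2)] <- c(0.5, 0.5)
  X2[1, 1, 3] <- 1
  ibd2 <- manual_ibd(X2, c(0, 10), markers = c("a", "b"), method = "hmm")
  imp2 <- impute_dosages(ibd2, map)
  expect_true(is.na(imp2$values["i1", "a"]))
  expect_equal(unname(imp2$values["i1", "b"]), 2)

  # grid-interpolated IBDs (no marker names) are rejected
  ibd_grid <- manual_ibd(X, c(0, 10), method = "hmm")
  expect_error(impute_dosages(ibd_grid, map), "marker")
})

test_that("imputation is idempotent on consistent data", {
  cfg <- sim_config(n_offspring = 40, n_chromosomes = 1, n_markers = 30,
                    seed = 431)
  sim <- simulate_cross(cfg)
  imp <- impute_dosages(as_ibd(sim$truth), sim$map)
  expect_equal(unname(imp$values[, sim$dosages$markers]),
               unname(sim$dosages$values))
})
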