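# Shared simulated cross with one strong QTL, scanned on the true IBDs so
# QTL-machinery tests are isolated from IBD-estimation error.
qtl_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(n_offspring = 150, n_chromosomes = 2, n_markers = 40,
                      seed = 1001)
    sim <- simulate_cross(cfg)
    qtl <- data.frame(linkage_group = 1, position = 30, effect = 1.2)
    qtl$homologues <- list(c(2L, 7L))
    set.seed(2001)
    pheno <- simulate_phenotypes(sim$truth, qtl, resid_sd = 1)
    cache <<- list(sim = sim, ibd = as_ibd(sim$truth), pheno = pheno,
                   qtl = qtl)
    cache
  }
})

test_that("block_correct handles single-block, residuals and BLUE modes", {
  ph <- data.frame(individual = c("a", "b", "c", "d"),
                   trait = c(1, 2, 3, 6))
  bc <- block_correct(ph)
  expect_equal(bc$value, c(1, 2, 3, 6) - 3)

  # two blocks with a pure additive block effect: corrected values centred,
  # block shift removed
  ph2 <- rbind(data.frame(individual = c("a", "b", "c", "d"),
                          trait = c(1, 2, 3, 4), block = "B1"),
               data.frame(individual = c("a", "b", "c", "d"),
                          trait = c(11, 12, 13, 14), block = "B2"))
  bc2 <- block_correct(ph2)
  expect_equal(bc2$value, c(-1.5, -0.5, 0.5, 1.5))
  blue <- block_correct(ph2, mode = "blue")
  expect_equal(sort(blue$value), c(-1.5, -0.5, 0.5, 1.5))

  # missing-value imputation only with >= 50% of blocks observed
  ph3 <- rbind(data.frame(individual = c("a", "b"), trait = c(1, 2),
                          block = "B1"),
               data.frame(individual = c("a", "b"), trait = c(NA, 12),
                          block = "B2"),
               data.frame(individual = c("a", "b"), trait = c(3, 4),
                          block = "B3"))
  bc3 <- block_correct(ph3)
  expect_equal(attr(bc3, "n_imputed"), 1L)
  ph4 <- rbind(data.frame(individual = c("a", "b"), trait = c(1, 2),
                          block = "B1"),
               data.frame(individual = c("a", "b"), trait = c(NA, 12),
                          block = "B2"),
               data.frame(individual = c("a", "b"), trait = c(NA, 4),
                          block = "B3"))
  bc4 <- block_correct(ph4)  # 'a' observed in 1/3 blocks: no imputation
  expect_equal(attr(bc4, "n_imputed"), 0L)
})

test_that("scan_qtl finds the simulated QTL and satisfies the PVE identity", {
  s <- qtl_sim()
  scan <- scan_qtl(s$ibd, s$pheno)
  expect_s3_class(scan, "qtl_scan")
  # design matrix: tetraploid x tetraploid drops one homologue per parent
  expect_equal(ncol(attr(scan, "coef")), 6)
  peak <- scan[which.max(scan$LOD), ]
  expect_equal(peak$linkage_group, "1")
  expect_lt(abs(peak$position - 30), 10)
  expect_gt(peak$LOD, 10)
  # PVE identity: 100(1 - 10^(-2 LOD / N)) == 100(1 - RSS1/RSS0)
  N <- attr(scan, "N")
  expect_equal(scan$PVE, 100 * (1 - 10^(-2 * scan$LOD / N)),
               tolerance = 1e-10)
})

test_that("co-factors absorb a QTL's signal into the null model", {
  s <- qtl_sim()
  scan0 <- scan_qtl(s$ibd, s$pheno)
  cof <- data.frame(linkage_group = "1", position = 30)
  scan1 <- scan_qtl(s$ibd, s$pheno, cofactors = cof)
  on1 <- scan1$linkage_group == "1" & abs(scan1$position - 30) < 10
  expect_lt(max(scan1$LOD[on1]), max(scan0$LOD) / 2)
  expect_match(attr(scan1, "null_model"), "co-factor")
})

test_that("single_marker_scan ranks markers near the QTL highest", {
  s <- qtl_sim()
  sms <- single_marker_scan(s$sim$dosages, s$pheno, map = s$sim$map)
  top <- sms[which.max(sms$LOD), ]
  expect_equal(top$linkage_group, 1)
  expect_lt(abs(top$position - 30), 15)
})

test_that("permutation_threshold uses the ceiling-percentile convention", {
  s <- qtl_sim()
  thr <- permutation_threshold(s$ibd, s$pheno, n_perm = 50, alpha = 0.05,
                               seed = 5)
  ml <- attr(thr, "max_lods")
  expect_length(ml, 50)
  expect_equal(as.numeric(thr), sort(ml)[ceiling(0.95 * 50)])
  # reproducible under the same seed
  thr2 <- permutation_threshold(s$ibd, s$pheno, n_perm = 50, alpha = 0.05,
                                seed = 5)
  expect_equal(as.numeric(thr), as.numeric(thr2))
  # the true QTL clears its own permutation threshold
  scan <- scan_qtl(s$ibd, s$pheno)
  expect_gt(max(scan$LOD), thr)
  expect_error(permutation_threshold(s$ibd, s$pheno, n_perm = 5), "10")
  expect_error(permutation_threshold(s$ibd, s$pheno, n_perm = 50,
                                     alpha = 1.5), "alpha")
})

test_that("cofactor_search evaluates 2^n - 1 models per pass and refines peaks", {
  cfg <- sim_config(n_offspring = 150, n_chromosomes = 3, n_markers = 40,
                    seed = 1101)
  sim <- simulate_cross(cfg)
  qtl <- data.frame(linkage_group = c(1, 2), position = c(40, 70),
                    effect = c(1.2, 1))
  qtl$homologues <- list(c(1L, 6L), c(3L))
  set.seed(2101)
  pheno <- simulate_phenotypes(sim$truth, qtl, resid_sd = 1)
  ibd <- as_ibd(sim$truth)
  # min_dist = 50 keeps shoulder positions of the strong peaks out of the
  # initial peak list so the model count of the worked example is clean
  res <- cofactor_search(ibd, pheno, threshold = 5, min_dist = 50)
  # both QTL found near their true positions
  expect_equal(nrow(res$qtl), 2)
  for (k in 1:2) {
    hit <- res$qtl$linkage_group == as.character(qtl$linkage_group[k]) &
      abs(res$qtl$position - qtl$position[k]) < 15
    expect_true(any(hit))
  }
  # 2 QTL enter each refinement pass: 2^2 - 1 = 3 co-factor models per pass
  expect_equal(res$n_models, c(3L, 3L))
  # joint-model PVE is sane and at least the single-QTL PVE of the scan
  expect_gt(res$pve, max(res$scan$PVE))
  expect_lt(res$pve, 100)
  # no significant peaks: empty result
  set.seed(99)
  null_ph <- data.frame(individual = sim$truth$individuals,
                        trait = rnorm(150))
  res0 <- cofactor_search(ibd, null_ph, threshold = 1e6)
  expect_equal(nrow(res0$qtl), 0)
  expect_equal(res0$n_models, integer(0))
})

test_that("configuration enumeration and labels match the combinatorics", {
  expect_length(enumerate_configurations(4, 4), 224)
  expect_length(enumerate_configurations(2, 2), 8)
  expect_length(enumerate_configurations(6, 6), 3968)
  cfgs <- enumerate_configurations(4, 4)
  labs <- vapply(cfgs, configuration_label, character(1), 4, 4)
  expect_false(any(duplicated(labs)))
  expect_true("oooQ x oQoo" %in% labs)
  expect_false("QQQQ x oooo" %in% labs)  # full parental sets excluded
  expect_false("oooo x oooo" %in% labs)  # all-nulliplex excluded
})

test_that("fit_configuration rejects excluded configurations and scores BIC", {
  s <- qtl_sim()
  expect_error(fit_configuration(s$ibd, s$pheno, "1", 30,
                                 list(S1 = integer(0), S2 = integer(0),
                                      action = "additive")), "null")
  expect_error(fit_configuration(s$ibd, s$pheno, "1", 30,
                                 list(S1 = 1:4, S2 = integer(0),
                                      action = "additive")), "full")
  f <- fit_configuration(s$ibd, s$pheno, "1", 30,
                         list(S1 = 2L, S2 = 3L, action = "additive"))
  expect_true(is.finite(f$BIC))
  expect_equal(f$BIC, f$N * log(f$RSS / f$N) + 2 * log(f$N))
  expect_equal(f$label, "oQoo x ooQo")
})

test_that("explore_configurations recovers the simulated QTL configuration", {
  s <- qtl_sim()
  scan <- scan_qtl(s$ibd, s$pheno)
  peak <- scan[which.max(scan$LOD), ]
  tab <- explore_configurations(s$ibd, s$pheno, peak$linkage_group,
                                peak$position)
  expect_equal(nrow(tab), 224)
  expect_equal(tab$deltaBIC[1], 0)
  fin <- is.finite(tab$BIC)
  expect_true(all(diff(round(tab$BIC[fin], 6)) >= 0))
  # truth: Q on maternal homologue 2 and paternal homologue 3 (index 7)
  expect_equal(tab$label[1], "oQoo x ooQo")
})

test_that("homologue_effects profiles each homologue and flags the Q carriers", {
  s <- qtl_sim()
  he <- homologue_effects(s$ibd, s$pheno, "1")
  expect_equal(sort(unique(he$homologue)), LETTERS[1:8])
  pos <- unique(he$position)
  m <- pos[which.min(abs(pos - 30))]
  at <- he[he$position == m, ]
  top2 <- at$homologue[order(-abs(at$effect))][1:2]
  expect_setequal(top2, c("B", "G"))
  expect_error(homologue_effects(s$ibd, s$pheno, "nope"), "unknown")
})
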