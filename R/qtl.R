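# IBD-based QTL interval mapping. At every position the phenotype is
# regressed on the parental homologue probabilities with the first
# homologue of each parent dropped (their probabilities sum to ploidy/2 per
# parent, so full designs are collinear). LOD = (N/2) log10(RSS0/RSS1);
# experimental blocks and genetic co-factors are absorbed into the null
# model by scanning residuals. The scan engine evaluates many response
# vectors at once (QR decomposition per position, shared across responses),
# which makes permutation tests cheap.

.lod_cap <- 1e6

# Reduced homologue predictor columns: drop the first homologue per parent.
.reduced_cols <- function(ploidy1, ploidy2) {
  c(seq_len(ploidy1)[-1], (ploidy1 + seq_len(ploidy2))[-1])
}

# Flatten an ibd_probs into per-position predictor matrices for a set of
# individuals. Returns list(pos = data.frame(linkage_group, position, idx),
# get = function(row) n_ind x k matrix).
.predictor_index <- function(ibd, ind_idx) {
  cols <- .reduced_cols(ibd$ploidy1, ibd$ploidy2)
  tabs <- lapply(names(ibd$lg), function(nm) {
    data.frame(linkage_group = nm, position = ibd$lg[[nm]]$positions,
               idx = seq_along(ibd$lg[[nm]]$positions),
               stringsAsFactors = FALSE)
  })
  pos <- do.call(rbind, tabs)
  get <- function(row) {
    l <- ibd$lg[[pos$linkage_group[row]]]
    l$X[pos$idx[row], ind_idx, cols, drop = TRUE]
  }
  list(pos = pos, get = get, cols = cols)
}

# RSS of Y (n x m matrix) under the linear model with design X (with
# intercept added), rank-deficiency tolerated via the QR rank.
.rss_fit <- function(X, Y) {
  qrd <- qr(cbind(`(Intercept)` = 1, X))
  Q <- qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]
  proj <- crossprod(Q, Y)
  pmax(colSums(Y^2) - colSums(proj^2), 0)
}

# LOD scores for all positions x all response columns.
# Y must already be null-model residuals (mean zero per column).
.scan_engine <- function(pred, Y, rss0, N) {
  n_pos <- nrow(pred$pos)
  m <- ncol(Y)
  LOD <- matrix(0, n_pos, m)
  for (rix in seq_len(n_pos)) {
    rss1 <- .rss_fit(pred$get(rix), Y)
    lod <- (N / 2) * log10(rss0 / pmax(rss1, .Machine$double.xmin))
    LOD[rix, ] <- pmin(pmax(lod, 0), .lod_cap)
  }
  LOD
}

#' Correct phenotypes for experimental blocks
#'
#' Fits the fixed-effect block model and returns one corrected value per
#' individual. In \code{"residuals"} mode the per-individual mean of the
#' block-model residuals is returned; a missing observation is first
#' imputed from the fitted block effect plus the individual's mean
#' deviation in its non-missing blocks, provided at least
#' \code{min_prop_observed} of its block observations are non-missing
#' (individuals below that remain missing in the affected blocks and
#' contribute only their observed residuals). In \code{"blue"} mode, best
#' linear unbiased estimates per genotype are computed from a fixed-effect
#' genotype + block model.
#'
#' @param pheno data.frame with columns individual, trait and optionally
#'   block.
#' @param mode \code{"residuals"} (default) or \code{"blue"}.
#' @param min_prop_observed minimum fraction of non-missing block
#'   observations required before missing ones are imputed (default 0.5).
#' @return data.frame with columns individual and value (one row per
#'   individual with at least one observation), with attribute
#'   \code{"n_imputed"}.
#' @export
block_correct <- function(pheno, mode = c("residuals", "blue"),
                          min_prop_observed = 0.5) {
  mode <- match.arg(mode)
  if (!"block" %in% names(pheno) || length(unique(pheno$block)) < 2L) {
    v <- tapply(pheno$trait, pheno$individual, mean, na.rm = TRUE)
    v <- v - mean(v, na.rm = TRUE)
    out <- data.frame(individual = names(v), value = as.numeric(v))
    out <- out[is.finite(out$value), , drop = FALSE]
    attr(out, "n_imputed") <- 0L
    return(out)
  }
  pheno$block <- factor(pheno$block)
  bl <- levels(pheno$block)
  if (any(tapply(!is.na(pheno$trait), pheno$block, sum) == 0)) {
    stop("a block has no non-missing observations")
  }
  if (mode == "blue") {
    d <- pheno[!is.na(pheno$trait), ]
    fit <- stats::lm(trait ~ individual + block, data = d)
    grid <- expand.grid(individual = unique(d$individual), block = bl,
                        stringsAsFactors = FALSE)
    pr <- stats::predict(fit, newdata = grid)
    v <- tapply(pr, grid$individual, mean)
    out <- data.frame(individual = names(v),
                      value = as.numeric(v - mean(v)))
    attr(out, "n_imputed") <- 0L
    return(out)
  }
  fit <- stats::lm(trait ~ block, data = pheno, na.action = stats::na.omit)
  beff <- stats::predict(fit, newdata = data.frame(block = factor(bl, bl)))
  names(beff) <- bl
  inds <- unique(pheno$individual)
  n_imputed <- 0L
  value <- vapply(inds, function(id) {
    rows <- pheno$individual == id
    y <- pheno$trait[rows]
    b <- as.character(pheno$block[rows])
    res <- y - beff[b]
    obs <- !is.na(y)
    if (!any(obs)) return(NA_real_)
    if (any(!obs) && mean(obs) >= min_prop_observed) {
      res[!obs] <- mean(res[obs])  # impute: block effect + own deviation
      n_imputed <<- n_imputed + sum(!obs)
    }
    mean(res, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(individual = inds, value = value)
  out <- out[!is.na(out$value), , drop = FALSE]
  attr(out, "n_imputed") <- n_imputed
  out
}

# Shared preparation: block-correct, intersect individuals with the IBD
# object, optionally residualize on co-factor predictors.
.prepare_scan <- function(ibd, pheno, cofactors = NULL,
                          block_mode = "residuals") {
  corr <- block_correct(pheno, mode = block_mode)
  keep <- intersect(ibd$individuals, corr$individual)
  if (length(keep) < 4L) stop("fewer than 4 phenotyped individuals in common")
  ind_idx <- match(keep, ibd$individuals)
  y <- corr$value[match(keep, corr$individual)]
  y <- y - mean(y)
  pred <- .predictor_index(ibd, ind_idx)
  null_desc <- if ("block" %in% names(pheno)) "blocks" else "mean"
  C <- NULL
  if (!is.null(cofactors) && nrow(cofactors) > 0L) {
    C <- do.call(cbind, lapply(seq_len(nrow(cofactors)), function(k) {
      rows <- pred$pos$linkage_group == as.character(cofactors$linkage_group[k])
      if (!any(rows)) stop("co-factor linkage group not in the IBD object")
      sub <- pred$pos[rows, ]
      row <- which(rows)[which.min(abs(sub$position - cofactors$position[k]))]
      pred$get(row)
    }))
    qrd <- qr(cbind(1, C))
    y <- qr.resid(qrd, y)
    null_desc <- paste0(null_desc, " + ", nrow(cofactors), " co-factor(s)")
  }
  rss0 <- sum(y^2)
  list(pred = pred, y = y, rss0 = rss0, N = length(y), keep = keep,
       ind_idx = ind_idx, null_desc = null_desc)
}

#' Genome-wide IBD-based QTL scan
#'
#' At every IBD position, fits the additive homologue-probability model
#' (first homologue of each parent dropped; a tetraploid x tetraploid scan
#' has 6 homologue predictors, a hexaploid x hexaploid scan 10) and returns
#' LOD = (N/2) log10(RSS0/RSS1) and the percentage of variance explained
#' PVE = 100 (1 - 10^(-2 LOD / N)). Blocks, when present in \code{pheno},
#' and genetic co-factors are fitted first and included in the null model:
#' the scan runs on their residuals.
#'
#' @param ibd an \code{\link{ibd_probs}} (typically grid-interpolated).
#' @param pheno data.frame with columns individual, trait, optional block.
#' @param cofactors optional data.frame with columns linkage_group and
#'   position; the homologue predictors at the nearest IBD position on each
#'   listed linkage group are absorbed into the null model.
#' @param block_mode how to correct for blocks ("residuals" or "blue"); see
#'   \code{\link{block_correct}}.
#' @return Object of class \code{qtl_scan}: a data.frame with columns
#'   linkage_group, position, LOD, PVE, plus attributes \code{coef}
#'   (adjusted homologue coefficients per position), \code{N},
#'   \code{null_model}, \code{rss0} and \code{individuals}.
#' @export
scan_qtl <- function(ibd, pheno, cofactors = NULL,
                     block_mode = "residuals") {
  prep <- .prepare_scan(ibd, pheno, cofactors, block_mode)
  Y <- matrix(prep$y, ncol = 1)
  LOD <- .scan_engine(prep$pred, Y, prep$rss0, prep$N)[, 1]
  coefs <- t(vapply(seq_len(nrow(prep$pred$pos)), function(rix) {
    X <- prep$pred$get(rix)
    cf <- stats::lm.fit(cbind(1, X), prep$y)$coefficients[-1]
    cf[is.na(cf)] <- 0
    cf
  }, numeric(length(prep$pred$cols))))
  colnames(coefs) <- homologue_names(ibd$ploidy1,
                                     ibd$ploidy2)[prep$pred$cols]
  out <- data.frame(prep$pred$pos[, c("linkage_group", "position")],
                    LOD = LOD, PVE = 100 * (1 - 10^(-2 * LOD / prep$N)))
  attr(out, "coef") <- coefs
  attr(out, "N") <- prep$N
  attr(out, "null_model") <- prep$null_desc
  attr(out, "rss0") <- prep$rss0
  attr(out, "individuals") <- prep$keep
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Single-marker QTL scan
#'
#' Regresses the (block-corrected) phenotype on the marker dosage at every
#' marker: Y = mean + alpha D + e. Probabilistic dosages enter as their
#' expected value. Monomorphic markers get LOD 0 with a warning; a perfect
#' fit is capped at LOD 1e6.
#'
#' @param dosages a \code{\link{dosage_data}}.
#' @param pheno phenotype data.frame (individual, trait, optional block).
#' @param map optional \code{\link{phased_map}} to attach positions.
#' @return data.frame marker, (linkage_group, position if map given), LOD,
#'   PVE, effect.
#' @export
single_marker_scan <- function(dosages, pheno, map = NULL) {
  corr <- block_correct(pheno)
  keep <- intersect(dosages$individuals, corr$individual)
  ii <- match(keep, dosages$individuals)
  y <- corr$value[match(keep, corr$individual)]
  y <- y - mean(y)
  N <- length(y)
  rss0 <- sum(y^2)
  D <- if (dosages$type == "discrete") dosages$values[ii, , drop = FALSE] else
    apply(dosages$values[ii, , , drop = FALSE], c(1, 2), function(q) {
      sum(q * (seq_along(q) - 1))
    })
  res <- t(vapply(seq_len(ncol(D)), function(m) {
    d <- D[, m]
    ok <- !is.na(d)
    if (sum(ok) < 3L || stats::var(d[ok]) == 0) {
      return(c(0, 0))
    }
    fit <- stats::lm.fit(cbind(1, d[ok]), y[ok])
    rss1 <- sum(fit$residuals^2)
    r0 <- sum((y[ok] - mean(y[ok]))^2)
    lod <- (sum(ok) / 2) * log10(r0 / max(rss1, .Machine$double.xmin))
    c(min(max(lod, 0), .lod_cap), fit$coefficients[2])
  }, numeric(2)))
  mono <- apply(D, 2, function(d) stats::var(d, na.rm = TRUE) == 0)
  if (any(mono, na.rm = TRUE)) {
    warning(sum(mono, na.rm = TRUE), " monomorphic marker(s) scored LOD 0")
  }
  out <- data.frame(marker = dosages$markers, LOD = res[, 1],
                    PVE = 100 * (1 - 10^(-2 * res[, 1] / N)),
                    effect = res[, 2])
  if (!is.null(map)) {
    mi <- match(out$marker, map$marker)
    out$linkage_group <- map$linkage_group[mi]
    out$position <- map$position[mi]
  }
  out
}

#' Permutation significance threshold for the IBD scan
#'
#' Permutes the (block-corrected) trait values over individuals
#' \code{n_perm} times, records the maximum LOD of each permuted genome-wide
#' scan (optionally restricted to a subset of chromosomes), and returns the
#' empirical 100 (1 - alpha) percentile using the conservative "higher"
#' (ceiling-index) convention: with 10 permutations and alpha = 0.05 the
#' threshold is the largest of the 10 maxima.
#'
#' @param ibd an \code{\link{ibd_probs}}.
#' @param pheno phenotype data.frame.
#' @param n_perm number of permutations (default 1000, minimum 10).
#' @param alpha type I error rate in (0, 1) (default 0.05).
#' @param chromosomes optional character vector of linkage groups for a
#'   chromosome-specific threshold.
#' @param cofactors optional co-factor data.frame, absorbed into the null
#'   model before permuting.
#' @param seed optional integer seed for reproducible permutations.
#' @return The LOD threshold, with attribute \code{"max_lods"} (the n_perm
#'   permutation maxima).
#' @export
permutation_threshold <- function(ibd, pheno, n_perm = 1000, alpha = 0.05,
                                  chromosomes = NULL, cofactors = NULL,
                                  seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_perm < 10) stop("at least 10 permutations required")
  if (!is.null(seed)) set.seed(seed)
  prep <- .prepare_scan(ibd, pheno, cofactors)
  pred <- prep$pred
  if (!is.null(chromosomes)) {
    rows <- pred$pos$linkage_group %in% as.character(chromosomes)
    if (!any(rows)) stop("no positions on the requested chromosome(s)")
    pos_sub <- pred$pos[rows, , drop = FALSE]
    get_orig <- pred$get
    row_map <- which(rows)
    pred <- list(pos = pos_sub, get = function(r) get_orig(row_map[r]),
                 cols = pred$cols)
  }
  Y <- vapply(seq_len(n_perm), function(k) sample(prep$y),
              numeric(prep$N))
  LOD <- .scan_engine(pred, Y, prep$rss0, prep$N)
  max_lods <- apply(LOD, 2, max)
  k <- ceiling((1 - alpha) * n_perm)
  thr <- sort(max_lods)[k]
  attr(thr, "max_lods") <- max_lods
  thr
}

# Collapse a scan into distinct significant peaks at least min_dist apart.
.find_peaks <- function(scan, threshold, min_dist = 20) {
  peaks <- list()
  for (nm in unique(scan$linkage_group)) {
    sub <- scan[scan$linkage_group == nm, ]
    avail <- sub$LOD > threshold
    while (any(avail)) {
      i <- which(avail)[which.max(sub$LOD[avail])]
      peaks[[length(peaks) + 1L]] <- data.frame(
        linkage_group = nm, position = sub$position[i], LOD = sub$LOD[i])
      avail <- avail & abs(sub$position - sub$position[i]) >= min_dist
    }
  }
  if (!length(peaks)) {
    return(data.frame(linkage_group = character(0), position = numeric(0),
                      LOD = numeric(0)))
  }
  out <- do.call(rbind, peaks)
  # lowest-cM tie-break, stable order by LG then position
  out[order(out$linkage_group, out$position), , drop = FALSE]
}

#' Automatic genetic co-factor search for multi-QTL models
#'
#' Starting from the peaks of a plain genome-wide scan that exceed the
#' significance threshold, evaluates every nonempty combination of the
#' detected QTL as genetic co-factors (2^n - 1 models). For each QTL, only
#' models whose co-factor set contains no locus within \code{min_dist} cM of
#' that QTL on the same linkage group are considered, and the position
#' maximizing the threshold-adjusted LOD (LOD - threshold) within
#' \code{min_dist} cM of the current estimate is retained; the plain scan
#' serves as fallback when every model conflicts. The refreshed positions
#' are fed through the same procedure once more. The multi-QTL percentage
#' of variance explained is 100 (1 - RSS1/RSS0) from the joint fit of all
#' final QTL predictors.
#'
#' @param ibd an \code{\link{ibd_probs}}.
#' @param pheno phenotype data.frame.
#' @param threshold LOD significance threshold (e.g. from
#'   \code{\link{permutation_threshold}}).
#' @param min_dist minimum resolution between independent QTL in cM
#'   (default 20).
#' @param max_qtl guard against combinatorial blow-up (default 10).
#' @return List with \code{qtl} (data.frame linkage_group, position, LOD,
#'   adj_LOD, cofactors used), \code{pve} (joint multi-QTL PVE),
#'   \code{n_models} evaluated per refinement pass (integer vector; 2^n - 1
#'   for n QTL entering the pass), and the initial \code{scan}.
#' @export
cofactor_search <- function(ibd, pheno, threshold, min_dist = 20,
                            max_qtl = 10) {
  scan0 <- scan_qtl(ibd, pheno)
  qtl <- .find_peaks(scan0, threshold, min_dist)
  if (nrow(qtl) == 0L) {
    return(list(qtl = cbind(qtl, adj_LOD = numeric(0),
                            cofactors = character(0)),
                pve = 0, n_models = integer(0), scan = scan0))
  }
  if (nrow(qtl) > max_qtl) {
    stop("more than ", max_qtl, " initial QTL; raise max_qtl to override")
  }
  n_models <- integer(0)
  refine <- function(qtl) {
    n_models <<- c(n_models, 0L)
    n <- nrow(qtl)
    best <- data.frame(qtl,
                       adj_LOD = qtl$LOD - threshold,
                       cofactors = "none", stringsAsFactors = FALSE)
    subsets <- unlist(lapply(seq_len(n), function(k) {
      utils::combn(n, k, simplify = FALSE)
    }), recursive = FALSE)
    for (S in subsets) {
      cof <- qtl[S, , drop = FALSE]
      sc <- scan_qtl(ibd, pheno, cofactors = cof)
      n_models[length(n_models)] <<- n_models[length(n_models)] + 1L
      for (i in seq_len(n)) {
        conflict <- any(cof$linkage_group == qtl$linkage_group[i] &
                          abs(cof$position - qtl$position[i]) < min_dist)
        if (conflict) next
        reg <- sc$linkage_group == qtl$linkage_group[i] &
          abs(sc$position - qtl$position[i]) < min_dist
        if (!any(reg)) next
        sub <- sc[reg, ]
        j <- which.max(sub$LOD)
        adj <- sub$LOD[j] - threshold
        if (adj > best$adj_LOD[i]) {
          best$position[i] <- sub$position[j]
          best$LOD[i] <- sub$LOD[j]
          best$adj_LOD[i] <- adj
          best$cofactors[i] <- paste(paste0(cof$linkage_group, "@",
                                            round(cof$position, 1)),
                                     collapse = ";")
        }
      }
    }
    best
  }
  dedup <- function(q) {
    keep <- rep(TRUE, nrow(q))
    for (i in seq_len(nrow(q))) {
      if (!keep[i]) next
      dup <- keep & q$linkage_group == q$linkage_group[i] &
        abs(q$position - q$position[i]) < min_dist
      if (sum(dup) > 1L) {
        best_i <- which(dup)[which.max(q$LOD[dup])]
        keep[dup] <- FALSE
        keep[best_i] <- TRUE
      }
    }
    q[keep, , drop = FALSE]
  }
  r1 <- dedup(refine(qtl))
  r2 <- dedup(refine(r1[, c("linkage_group", "position", "LOD")]))
  # joint multi-QTL fit
  prep <- .prepare_scan(ibd, pheno)
  Xj <- do.call(cbind, lapply(seq_len(nrow(r2)), function(i) {
    rows <- prep$pred$pos$linkage_group == r2$linkage_group[i]
    sub <- prep$pred$pos[rows, ]
    row <- which(rows)[which.min(abs(sub$position - r2$position[i]))]
    prep$pred$get(row)
  }))
  rss1 <- .rss_fit(Xj, matrix(prep$y, ncol = 1))
  pve <- 100 * (1 - rss1 / prep$rss0)
  list(qtl = r2, pve = as.numeric(pve), n_models = n_models, scan = scan0)
}

#' Enumerate candidate QTL allele configurations
#'
#' A configuration assigns the QTL allele Q to a subset S1 of maternal and a
#' subset S2 of paternal homologues. Per parent the full set is excluded
#' (a parent homozygous for Q does not segregate), and the configuration
#' with no Q in either parent is excluded: (2^p1 - 1)(2^p2 - 1) - 1 models,
#' e.g. 224 for a tetraploid x tetraploid cross.
#'
#' @param ploidy1,ploidy2 parental ploidies.
#' @param action \code{"additive"} or \code{"dominant"}.
#' @return List of configurations: each a list with integer vectors
#'   \code{S1}, \code{S2} (possibly empty) and \code{action}.
#' @examples
#' length(enumerate_configurations(4, 4)) # 224
#' @export
enumerate_configurations <- function(ploidy1, ploidy2,
                                     action = c("additive", "dominant")) {
  action <- match.arg(action)
  subs <- function(p) {
    s <- lapply(0:(2^p - 1), function(b) which(bitwAnd(b, 2^(0:(p - 1))) > 0))
    s[lengths(s) < p]  # exclude the full set
  }
  s1 <- subs(ploidy1)
  s2 <- subs(ploidy2)
  out <- list()
  for (a in s1) {
    for (b in s2) {
      if (length(a) == 0L && length(b) == 0L) next
      out[[length(out) + 1L]] <- list(S1 = a, S2 = b, action = action)
    }
  }
  out
}

#' Label for a QTL configuration
#' @param config a configuration from
#'   \code{\link{enumerate_configurations}}.
#' @param ploidy1,ploidy2 parental ploidies.
#' @return String such as \code{"oooQ x oQoo"}.
#' @export
configuration_label <- function(config, ploidy1, ploidy2) {
  g <- function(S, p) {
    v <- rep("o", p)
    v[S] <- "Q"
    paste(v, collapse = "")
  }
  paste(g(config$S1, ploidy1), "x", g(config$S2, ploidy2))
}

#' Fit one QTL allele configuration at a position
#'
#' Builds the configuration predictor from the IBD probabilities at the
#' position nearest the requested one -- additive: the summed inheritance
#' of Q-bearing homologues; dominant: the probability that at least one
#' Q-bearing homologue was inherited (independence approximation) -- and
#' returns the Gaussian BIC = N ln(RSS/N) + k ln(N) (k = fitted regression
#' parameters including the intercept) together with the effect estimate.
#'
#' @param ibd an \code{\link{ibd_probs}}.
#' @param pheno phenotype data.frame.
#' @param linkage_group,position QTL peak location.
#' @param config a configuration (list with S1, S2, action).
#' @return List with BIC, effect, se, RSS, N, label. A configuration whose
#'   predictor has zero variance at the position gets BIC = +Inf.
#' @export
fit_configuration <- function(ibd, pheno, linkage_group, position, config) {
  if (length(config$S1) == 0L && length(config$S2) == 0L) {
    stop("the null configuration (no Q allele in either parent) cannot be fitted")
  }
  if (length(config$S1) == ibd$ploidy1 || length(config$S2) == ibd$ploidy2) {
    stop("per-parent full-Q configurations are excluded from the enumeration")
  }
  prep <- .prepare_scan(ibd, pheno)
  l <- ibd$lg[[as.character(linkage_group)]]
  if (is.null(l)) stop("unknown linkage group: ", linkage_group)
  m <- which.min(abs(l$positions - position))
  hs <- c(config$S1, ibd$ploidy1 + config$S2)
  Xh <- l$X[m, prep$ind_idx, hs, drop = FALSE]
  Xh <- matrix(Xh, nrow = length(prep$ind_idx))
  x <- if (identical(config$action, "dominant")) {
    1 - apply(1 - pmin(Xh, 1), 1, prod)
  } else {
    rowSums(Xh)
  }
  N <- prep$N
  lab <- configuration_label(config, ibd$ploidy1, ibd$ploidy2)
  if (stats::var(x) < 1e-12) {
    return(list(BIC = Inf, effect = NA_real_, se = NA_real_, RSS = NA_real_,
                N = N, label = lab))
  }
  fit <- stats::lm(prep$y ~ x)
  rss <- sum(fit$residuals^2)
  sm <- summary(fit)$coefficients
  list(BIC = N * log(rss / N) + 2 * log(N), effect = sm["x", 1],
       se = sm["x", 2], RSS = rss, N = N, label = lab)
}

#' Rank all QTL configurations at a peak by BIC
#'
#' @param ibd an \code{\link{ibd_probs}}.
#' @param pheno phenotype data.frame.
#' @param linkage_group,position QTL peak location.
#' @param action \code{"additive"}, \code{"dominant"} or both.
#' @return data.frame (one row per configuration, sorted by BIC) with
#'   columns label, action, n_alleles, BIC, deltaBIC, effect, se.
#' @export
explore_configurations <- function(ibd, pheno, linkage_group, position,
                                   action = "additive") {
  rows <- list()
  for (act in action) {
    cfgs <- enumerate_configurations(ibd$ploidy1, ibd$ploidy2, act)
    for (cf in cfgs) {
      f <- fit_configuration(ibd, pheno, linkage_group, position, cf)
      rows[[length(rows) + 1L]] <- data.frame(
        label = f$label, action = act,
        n_alleles = length(cf$S1) + length(cf$S2),
        BIC = f$BIC, effect = f$effect, se = f$se)
    }
  }
  out <- do.call(rbind, rows)
  # complement configurations give collinear predictors and tie in BIC;
  # prefer the more parsimonious (fewer Q alleles) among numerical ties
  out <- out[order(round(out$BIC, 6), out$n_alleles), ]
  out$deltaBIC <- out$BIC - out$BIC[1]
  rownames(out) <- NULL
  out
}

#' Per-homologue effect tracks along a linkage group
#'
#' At every position of the linkage group, regresses the (block-corrected)
#' phenotype on each homologue's inheritance probability separately and
#' records the coefficient and its standard error -- the homologue-effects
#' view used to interpret a QTL's allelic configuration.
#'
#' @param ibd an \code{\link{ibd_probs}}.
#' @param pheno phenotype data.frame.
#' @param linkage_group which linkage group to profile.
#' @return Tidy data.frame: position, homologue (letter), effect, se,
#'   zero_variance flag.
#' @export
homologue_effects <- function(ibd, pheno, linkage_group) {
  prep <- .prepare_scan(ibd, pheno)
  l <- ibd$lg[[as.character(linkage_group)]]
  if (is.null(l)) stop("unknown linkage group: ", linkage_group)
  hn <- homologue_names(ibd$ploidy1, ibd$ploidy2)
  rows <- list()
  for (m in seq_along(l$positions)) {
    for (h in seq_along(hn)) {
      x <- l$X[m, prep$ind_idx, h]
      if (stats::var(x) < 1e-12) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = l$positions[m], homologue = hn[h], effect = 0,
          se = NA_real_, zero_variance = TRUE)
        next
      }
      fit <- stats::lm.fit(cbind(1, x), prep$y)
      rss <- sum(fit$residuals^2)
      se <- sqrt(rss / (prep$N - 2) / sum((x - mean(x))^2))
      rows[[length(rows) + 1L]] <- data.frame(
        position = l$positions[m], homologue = hn[h],
        effect = fit$coefficients[2], se = se, zero_variance = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
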