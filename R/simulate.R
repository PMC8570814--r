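# Forward simulator of polysomic meiosis in a single F1 cross. Generates a
# phased parental map, true inheritance (which parental homologues each
# offspring carries at every marker, with the pairing configuration and
# cross-over count of every meiosis) and error-perturbed offspring dosages.
# Cross-overs follow a Poisson process at 1 event per 100 cM per chromatid
# lineage (no interference), so marginal recombination fractions follow
# Haldane's map function -- the same model the HMM assumes.

#' Simulation configuration
#'
#' @param ploidy1,ploidy2 parental ploidies (2, 4 or 6); offspring ploidy
#'   (ploidy1 + ploidy2)/2 must be an integer.
#' @param n_offspring number of F1 offspring.
#' @param n_chromosomes number of chromosomes (linkage groups).
#' @param chrom_length chromosome length in cM.
#' @param n_markers markers per chromosome, uniformly spaced.
#' @param prop_simplex_nulliplex fraction of markers segregating 1x0 or 0x1
#'   (half each); the rest are drawn uniformly from all other segregating
#'   phase patterns.
#' @param multivalent_prob per-parent, per-chromosome probability of a
#'   quadrivalent pairing (0 = bivalents only).
#' @param pairing_preference optional list with symmetric nonnegative
#'   weight matrices \code{p1} (ploidy1 x ploidy1) and \code{p2}; a bivalent
#'   configuration is drawn with probability proportional to the product of
#'   its pair weights. NULL = random (polysomic) pairing.
#' @param genotyping_error_rate probability that an offspring dosage call is
#'   replaced by a different, uniformly drawn class.
#' @param seed integer seed (applied by \code{\link{simulate_cross}}).
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(ploidy1 = 4, ploidy2 = 4, n_offspring = 200,
                       n_chromosomes = 5, chrom_length = 100,
                       n_markers = 100, prop_simplex_nulliplex = 0.5,
                       multivalent_prob = 0, pairing_preference = NULL,
                       genotyping_error_rate = 0, seed = NULL) {
  if (!ploidy1 %in% c(2, 4, 6) || !ploidy2 %in% c(2, 4, 6)) {
    stop("parental ploidies must be 2, 4 or 6")
  }
  if ((ploidy1 + ploidy2) %% 2 != 0) stop("offspring ploidy must be integer")
  fr <- c(prop_simplex_nulliplex, multivalent_prob, genotyping_error_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (!is.null(pairing_preference)) {
    for (nm in c("p1", "p2")) {
      M <- pairing_preference[[nm]]
      p <- if (nm == "p1") ploidy1 else ploidy2
      if (is.null(M)) next
      if (!isSymmetric(unname(M)) || any(M < 0) || nrow(M) != p) {
        stop("pairing preference matrix '", nm,
             "' must be a symmetric nonnegative ", p, "x", p, " matrix")
      }
    }
  }
  cfg <- list(ploidy1 = as.integer(ploidy1), ploidy2 = as.integer(ploidy2),
              n_offspring = as.integer(n_offspring),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length, n_markers = as.integer(n_markers),
              prop_simplex_nulliplex = prop_simplex_nulliplex,
              multivalent_prob = multivalent_prob,
              pairing_preference = pairing_preference,
              genotyping_error_rate = genotyping_error_rate, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a phased parental linkage map
#'
#' Markers are uniformly spaced along each chromosome. A fraction
#' \code{prop_simplex_nulliplex} of them are simplex x nulliplex (half 1x0,
#' half 0x1, the carrier homologue drawn at random); the remainder are drawn
#' uniformly from all other segregating phase patterns (patterns where both
#' parents are homozygous, and 1x0/0x1 patterns, are excluded).
#'
#' @param config a \code{\link{sim_config}}.
#' @return A \code{\link{phased_map}}.
#' @export
simulate_parent_phase <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p1 <- config$ploidy1
  p2 <- config$ploidy2
  n_m <- config$n_markers
  n_c <- config$n_chromosomes
  marker <- character(0)
  lgv <- integer(0)
  posv <- numeric(0)
  phase <- matrix(0, 0, p1 + p2)
  for (lg in seq_len(n_c)) {
    pos <- if (n_m == 1L) 0 else
      seq(0, config$chrom_length, length.out = n_m)
    n_sn <- round(config$prop_simplex_nulliplex * n_m)
    n_10 <- floor(n_sn / 2)
    n_01 <- n_sn - n_10
    type <- sample(c(rep("10", n_10), rep("01", n_01),
                     rep("other", n_m - n_sn)))
    ph <- t(vapply(type, function(tp) {
      if (tp == "10") {
        v <- rep(0, p1 + p2)
        v[sample.int(p1, 1L)] <- 1
        v
      } else if (tp == "01") {
        v <- rep(0, p1 + p2)
        v[p1 + sample.int(p2, 1L)] <- 1
        v
      } else {
        repeat {
          v <- stats::rbinom(p1 + p2, 1, 0.5)
          d1 <- sum(v[seq_len(p1)])
          d2 <- sum(v[p1 + seq_len(p2)])
          seg1 <- d1 > 0 && d1 < p1
          seg2 <- d2 > 0 && d2 < p2
          if (!(seg1 || seg2)) next                 # both parents homozygous
          if ((d1 == 1 && d2 == 0) || (d1 == 0 && d2 == 1)) next
          return(v)
        }
      }
    }, numeric(p1 + p2)))
    marker <- c(marker, sprintf("mk%d_%03d", lg, seq_len(n_m)))
    lgv <- c(lgv, rep(lg, n_m))
    posv <- c(posv, pos)
    phase <- rbind(phase, ph)
  }
  phased_map(marker, lgv, posv, phase, p1, p2)
}

# One chromatid lineage through a bivalent {a, b}: Poisson cross-overs,
# alternating homologue. Returns list(hom = homologue at each position,
# n_co = cross-over count).
.bivalent_lineage <- function(pair, positions, L) {
  n_bp <- stats::rpois(1L, L / 100)
  bp <- sort(stats::runif(n_bp, 0, L))
  seg <- findInterval(positions, bp)
  start <- sample(pair, 1L)
  other <- setdiff(pair, start)
  list(hom = ifelse(seg %% 2 == 0, start, other), n_co = n_bp)
}

# One chromatid lineage through a quadrivalent: Poisson events, each a jump
# to a uniformly chosen different homologue of the unit. The two lineages a
# gamete draws start on distinct homologues at the centromere (position 0):
# double reduction -- both lineages on the same homologue -- can only arise
# distal to a cross-over, so its rate rises away from the centromere.
.quadrivalent_lineage <- function(unit, positions, L, start) {
  n_bp <- stats::rpois(1L, L / 100)
  bp <- sort(stats::runif(n_bp, 0, L))
  labs <- integer(n_bp + 1L)
  labs[1L] <- start
  if (n_bp > 0) {
    for (k in seq_len(n_bp)) {
      labs[k + 1L] <- sample(setdiff(unit, labs[k]), 1L)
    }
  }
  list(hom = labs[findInterval(positions, bp) + 1L], n_co = n_bp)
}

# Sample one parent's pairing configuration for a chromosome.
.sample_valency <- function(p, mv_prob, pref) {
  if (stats::runif(1) < mv_prob) {
    if (p == 4L) {
      v <- list(1:4)
    } else if (p == 6L) {
      q <- sort(sample.int(6L, 4L))
      v <- list(q, setdiff(1:6, q))
    } else {
      v <- list(c(1L, 2L))  # diploid: no multivalent possible
    }
    attr(v, "multivalent") <- p >= 4L
    return(v)
  }
  matchings <- .perfect_matchings(seq_len(p))
  w <- vapply(matchings, function(m) {
    prod(vapply(m, function(u) pref[u[1], u[2]], numeric(1)))
  }, numeric(1))
  if (sum(w) <= 0) stop("pairing preference weights exclude all pairings")
  v <- matchings[[sample.int(length(matchings), 1L, prob = w)]]
  attr(v, "multivalent") <- FALSE
  v
}

#' Simulate meiosis and offspring genotypes
#'
#' For every offspring, chromosome and parent: a pairing configuration is
#' drawn (quadrivalent with probability \code{multivalent_prob}, otherwise a
#' bivalent pairing weighted by the pairing preference); each bivalent
#' contributes one recombinant chromatid and a quadrivalent contributes two
#' chromatid lineages that may coincide on the same homologue (double
#' reduction). Offspring dosages are the phase sums over inherited
#' homologue copies, then perturbed by the genotyping error rate.
#'
#' @param map a \code{\link{phased_map}} (e.g. from
#'   \code{\link{simulate_parent_phase}}).
#' @param config a \code{\link{sim_config}} consistent with the map.
#' @return List with elements \code{truth} (class \code{true_inheritance}:
#'   \code{X} true copy-count array markers x individuals x homologues per
#'   LG, \code{meioses} data.frame of per-meiosis valency, multivalent flag
#'   and cross-over count, \code{dr} per-LG logical array markers x
#'   individuals x 2 of realized double reduction) and \code{dosages}
#'   (a discrete \code{\link{dosage_data}}).
#' @export
simulate_meiosis <- function(map, config) {
  stopifnot(inherits(map, "phased_map"), inherits(config, "sim_config"))
  p1 <- config$ploidy1
  p2 <- config$ploidy2
  if (map$ploidy1 != p1 || map$ploidy2 != p2) {
    stop("map ploidies do not match the configuration")
  }
  ploidy_off <- (p1 + p2) %/% 2L
  n_i <- config$n_offspring
  prefs <- list(
    p1 = if (!is.null(config$pairing_preference$p1))
      config$pairing_preference$p1 else matrix(1, p1, p1),
    p2 = if (!is.null(config$pairing_preference$p2))
      config$pairing_preference$p2 else matrix(1, p2, p2))
  inds <- sprintf("F1_%03d", seq_len(n_i))
  lgs <- unique(map$linkage_group)
  Xlg <- list()
  drlg <- list()
  mei <- list()
  dose_all <- NULL
  for (lg in lgs) {
    sel <- which(map$linkage_group == lg)
    pos <- map$position[sel]
    phase <- map$phase[sel, , drop = FALSE]
    n_m <- length(sel)
    L <- max(pos)
    X <- array(0, dim = c(n_m, n_i, p1 + p2))
    dr <- array(FALSE, dim = c(n_m, n_i, 2))
    dose <- matrix(0, n_i, n_m)
    for (i in seq_len(n_i)) {
      copies <- matrix(0, n_m, p1 + p2)
      for (parent in 1:2) {
        p <- if (parent == 1L) p1 else p2
        off <- if (parent == 1L) 0L else p1
        v <- .sample_valency(p, config$multivalent_prob, prefs[[parent]])
        n_co <- 0L
        quad_homs <- NULL
        for (u in v) {
          if (length(u) == 2L) {
            lin <- .bivalent_lineage(u, pos, L)
            copies[cbind(seq_len(n_m), off + lin$hom)] <-
              copies[cbind(seq_len(n_m), off + lin$hom)] + 1
            n_co <- n_co + lin$n_co
          } else {
            starts <- sample(u, 2L)
            lin1 <- .quadrivalent_lineage(u, pos, L, starts[1L])
            lin2 <- .quadrivalent_lineage(u, pos, L, starts[2L])
            for (lin in list(lin1, lin2)) {
              copies[cbind(seq_len(n_m), off + lin$hom)] <-
                copies[cbind(seq_len(n_m), off + lin$hom)] + 1
              n_co <- n_co + lin$n_co
            }
            quad_homs <- cbind(lin1$hom, lin2$hom)
          }
        }
        if (!is.null(quad_homs)) {
          dr[, i, parent] <- quad_homs[, 1] == quad_homs[, 2]
        }
        mei[[length(mei) + 1L]] <- data.frame(
          individual = inds[i], linkage_group = lg, parent = parent,
          valency = valency_label(v, offset = off),
          multivalent = isTRUE(attr(v, "multivalent")), crossovers = n_co)
      }
      X[, i, ] <- copies
      dose[i, ] <- as.numeric(rowSums(copies * phase))
    }
    # genotyping errors: flip to a different uniformly drawn class
    if (config$genotyping_error_rate > 0) {
      flip <- matrix(stats::runif(n_i * n_m) < config$genotyping_error_rate,
                     n_i, n_m)
      if (any(flip)) {
        idx <- which(flip)
        dose[idx] <- (dose[idx] +
                        sample.int(ploidy_off, length(idx),
                                   replace = TRUE)) %% (ploidy_off + 1L)
      }
    }
    colnames(dose) <- map$marker[sel]
    rownames(dose) <- inds
    dose_all <- cbind(dose_all, dose)
    Xlg[[as.character(lg)]] <- X
    drlg[[as.character(lg)]] <- dr
  }
  truth <- list(X = Xlg, dr = drlg, meioses = do.call(rbind, mei),
                individuals = inds, ploidy1 = p1, ploidy2 = p2,
                map = list(marker = map$marker, linkage_group =
                             map$linkage_group, position = map$position))
  class(truth) <- "true_inheritance"
  list(truth = truth,
       dosages = dosage_data(dose_all, ploidy_off, type = "discrete"))
}

#' Simulate a full cross (map + meiosis) from one configuration
#'
#' @param config a \code{\link{sim_config}}; \code{config$seed}, when set,
#'   makes the run reproducible.
#' @return List with \code{map}, \code{dosages}, \code{truth}.
#' @export
simulate_cross <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  map <- simulate_parent_phase(config)
  sim <- simulate_meiosis(map, config)
  list(map = map, dosages = sim$dosages, truth = sim$truth)
}

#' True inheritance as an IBD object
#'
#' Wraps the simulator's true homologue copy counts in an
#' \code{\link{ibd_probs}} container (method \code{"truth"}), so that QTL
#' scans and diagnostics can run directly on noiseless ground truth.
#'
#' @param truth a \code{true_inheritance}.
#' @return An \code{ibd_probs} at the marker positions.
#' @export
as_ibd <- function(truth) {
  stopifnot(inherits(truth, "true_inheritance"))
  lg <- lapply(names(truth$X), function(nm) {
    sel <- truth$map$linkage_group == as.integer(nm)
    list(positions = truth$map$position[sel], marker = truth$map$marker[sel],
         X = truth$X[[nm]], dr = NULL, val_post = NULL)
  })
  names(lg) <- names(truth$X)
  ibd_probs(lg, truth$individuals, truth$ploidy1, truth$ploidy2,
            method = "truth",
            multivalents = any(vapply(truth$dr, any, logical(1))))
}

#' Mean absolute error of estimated IBD probabilities
#'
#' Average absolute deviation between estimated and true parental homologue
#' inheritance values over all positions, individuals and homologues.
#' The estimate must be on the marker positions (not an interpolated grid)
#' and cover the same individuals.
#'
#' @param estimate an \code{\link{ibd_probs}}.
#' @param truth a \code{true_inheritance}.
#' @return Mean absolute error (a single number in [0, 2]).
#' @export
true_ibd_error <- function(estimate, truth) {
  stopifnot(inherits(estimate, "ibd_probs"),
            inherits(truth, "true_inheritance"))
  tot <- 0
  n <- 0
  for (nm in names(estimate$lg)) {
    Xe <- estimate$lg[[nm]]$X
    Xt <- truth$X[[nm]]
    if (is.null(Xt) || !identical(dim(Xe), dim(Xt))) {
      stop("estimate and truth have mismatching shapes on LG ", nm)
    }
    tot <- tot + sum(abs(Xe - Xt))
    n <- n + length(Xe)
  }
  tot / n
}

#' Simulate phenotypes with QTL effects from true inheritance
#'
#' The genetic value of an individual is the sum over QTL of
#' \code{effect} times the number of Q-bearing homologue copies it carries
#' at the marker nearest the QTL position (from the true inheritance);
#' Gaussian noise with \code{resid_sd} is added. With \code{blocks > 1},
#' one observation per block is produced, each with its own additive block
#' effect (drawn once from N(0, block_sd)) and noise draw.
#'
#' @param truth a \code{true_inheritance}.
#' @param qtl data.frame with columns \code{linkage_group}, \code{position},
#'   \code{homologues} (list-column of integer vectors: Q-carrying
#'   homologues, full 1..(ploidy1+ploidy2) indexing), \code{effect}.
#' @param resid_sd residual standard deviation.
#' @param blocks number of blocks (1 = no block structure).
#' @param block_sd standard deviation of block effects.
#' @return data.frame with columns individual, trait and (when
#'   \code{blocks > 1}) block.
#' @export
simulate_phenotypes <- function(truth, qtl, resid_sd = 1, blocks = 1L,
                                block_sd = 1) {
  stopifnot(inherits(truth, "true_inheritance"))
  n_i <- length(truth$individuals)
  g <- numeric(n_i)
  for (k in seq_len(nrow(qtl))) {
    nm <- as.character(qtl$linkage_group[k])
    sel <- truth$map$linkage_group == qtl$linkage_group[k]
    pos <- truth$map$position[sel]
    m <- which.min(abs(pos - qtl$position[k]))
    hs <- qtl$homologues[[k]]
    xs <- truth$X[[nm]][m, , hs, drop = FALSE]  # 1 x n_i x |hs|
    g <- g + qtl$effect[k] * apply(xs, 2, sum)
  }
  if (blocks <= 1L) {
    return(data.frame(individual = truth$individuals,
                      trait = g + stats::rnorm(n_i, 0, resid_sd)))
  }
  be <- stats::rnorm(blocks, 0, block_sd)
  do.call(rbind, lapply(seq_len(blocks), function(b) {
    data.frame(individual = truth$individuals,
               trait = g + be[b] + stats::rnorm(n_i, 0, resid_sd),
               block = factor(paste0("B", b)))
  }))
}
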