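# Meiotic diagnostics computed from HMM IBD output: predicted pairing
# configurations, double-reduction landscape, preferential-pairing tests,
# recombination detection and outlier screening, plus the genotypic
# information coefficient (GIC) and IBD-informed dosage imputation.

#' Assign pairing configurations and count multivalents
#'
#' Per individual, linkage group and parent, assigns the
#' maximum-posterior valency when its posterior reaches the plausibility
#' threshold (default 0.4) and labels the meiosis "ambiguous" otherwise;
#' tabulates predicted multivalent counts per linkage group and parent.
#'
#' @param ibd an \code{\link{ibd_probs}} from the HMM (valency posteriors
#'   required; heuristic output is rejected).
#' @param plausibility minimum posterior probability for an assignment.
#' @return List of class \code{valency_assignment}: \code{assignments}
#'   (data.frame individual, linkage_group, parent, valency, label,
#'   multivalent, posterior, plausible), \code{multivalent_counts}
#'   (data.frame linkage_group, parent, n_multivalent, n_assigned),
#'   \code{ploidy1}, \code{ploidy2}, and the valency lists per parent.
#' @export
count_valencies <- function(ibd, plausibility = 0.4) {
  stopifnot(inherits(ibd, "ibd_probs"))
  if (ibd$method != "hmm" ||
      is.null(ibd$lg[[1]]$val_post)) {
    stop("valency posteriors are only available from HMM-estimated IBDs")
  }
  rows <- list()
  for (nm in names(ibd$lg)) {
    vp <- ibd$lg[[nm]]$val_post
    for (parent in 1:2) {
      M <- vp[[parent]]
      vals <- attr(M, "valencies")
      off <- if (parent == 1L) 0L else ibd$ploidy1
      best <- max.col(M, ties.method = "first")
      post <- M[cbind(seq_len(nrow(M)), best)]
      plausible <- post >= plausibility
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ibd$individuals, linkage_group = nm, parent = parent,
        valency = ifelse(plausible, best, NA_integer_),
        label = ifelse(plausible,
                       vapply(vals[best], valency_label, character(1),
                              offset = off), "ambiguous"),
        multivalent = ifelse(plausible,
                             vapply(vals[best], function(v)
                               isTRUE(attr(v, "multivalent")), logical(1)),
                             NA),
        posterior = post, plausible = plausible)
    }
  }
  assignments <- do.call(rbind, rows)
  mv <- stats::aggregate(cbind(n_multivalent = multivalent,
                               n_assigned = plausible) ~
                           linkage_group + parent,
                         data = assignments, FUN = sum, na.action = NULL,
                         na.rm = TRUE)
  out <- list(assignments = assignments, multivalent_counts = mv,
              ploidy1 = ibd$ploidy1, ploidy2 = ibd$ploidy2,
              valencies = list(p1 = attr(ibd$lg[[1]]$val_post$p1, "valencies"),
                               p2 = attr(ibd$lg[[1]]$val_post$p2, "valencies")),
              plausibility = plausibility)
  class(out) <- "valency_assignment"
  out
}

#' Double-reduction rate along the genome
#'
#' Per position, the mean over offspring of the posterior probability that
#' a gamete carried two copies of one homologue: reported per parent and
#' combined (probability that the maternal or the paternal gamete was
#' doubled, assuming independence between parents).
#'
#' @param ibd an \code{\link{ibd_probs}} from the HMM.
#' @return data.frame linkage_group, position, rate_p1, rate_p2, rate.
#'   All-zero with a warning when the IBDs were estimated bivalent-only.
#' @export
double_reduction_rate <- function(ibd) {
  stopifnot(inherits(ibd, "ibd_probs"))
  out <- lapply(names(ibd$lg), function(nm) {
    l <- ibd$lg[[nm]]
    if (is.null(l$dr)) {
      warning("IBDs were estimated without multivalents; ",
              "double-reduction rate is identically zero")
      return(data.frame(linkage_group = nm, position = l$positions,
                        rate_p1 = 0, rate_p2 = 0, rate = 0))
    }
    r1 <- rowMeans(l$dr[, , 1, drop = FALSE], dims = 1)
    r2 <- rowMeans(l$dr[, , 2, drop = FALSE], dims = 1)
    comb <- rowMeans(1 - (1 - l$dr[, , 1]) * (1 - l$dr[, , 2]))
    data.frame(linkage_group = nm, position = l$positions,
               rate_p1 = as.numeric(r1), rate_p2 = as.numeric(r2),
               rate = comb)
  })
  do.call(rbind, out)
}

#' Chi-square test of preferential chromosome pairing
#'
#' Counts how often each pair of a parent's homologues was predicted to
#' form a bivalent across the plausibly assigned bivalent-only meioses of a
#' linkage group, and tests each homologue's partner counts against the
#' uniform (random pairing, polysomic) expectation with a chi-square
#' goodness-of-fit test on ploidy - 2 degrees of freedom. Deviations
#' (observed - expected) per pair are reported for plotting.
#'
#' @param vc a \code{valency_assignment} from \code{\link{count_valencies}}.
#' @param min_meioses warn when fewer plausibly assigned bivalent-only
#'   meioses are available for a parent and linkage group (default 20).
#' @return List of class \code{pairing_report}: \code{pair_counts}
#'   (linkage_group, parent, pair, observed, expected, deviation) and
#'   \code{homologue_tests} (linkage_group, parent, homologue, statistic,
#'   df, p_value, p_bonferroni, n_meioses).
#' @export
test_preferential_pairing <- function(vc, min_meioses = 20L) {
  stopifnot(inherits(vc, "valency_assignment"))
  pair_rows <- list()
  test_rows <- list()
  for (nm in unique(vc$assignments$linkage_group)) {
    for (parent in 1:2) {
      p <- if (parent == 1L) vc$ploidy1 else vc$ploidy2
      if (p < 4L) next  # a diploid parent has a single possible pairing
      off <- if (parent == 1L) 0L else vc$ploidy1
      vals <- vc$valencies[[parent]]
      a <- vc$assignments
      a <- a[a$linkage_group == nm & a$parent == parent & a$plausible &
               !a$multivalent, , drop = FALSE]
      n_mei <- nrow(a)
      if (n_mei == 0L) stop("no plausibly assigned bivalent-only meioses ",
                            "for parent ", parent, " on LG ", nm)
      if (n_mei < min_meioses) {
        warning("only ", n_mei, " assigned bivalent-only meioses for parent ",
                parent, " on LG ", nm)
      }
      cnt <- matrix(0, p, p)
      for (vi in unique(a$valency)) {
        nrep <- sum(a$valency == vi)
        for (u in vals[[vi]]) {
          cnt[u[1], u[2]] <- cnt[u[1], u[2]] + nrep
          cnt[u[2], u[1]] <- cnt[u[2], u[1]] + nrep
        }
      }
      for (h1 in seq_len(p - 1L)) {
        for (h2 in (h1 + 1L):p) {
          pair_rows[[length(pair_rows) + 1L]] <- data.frame(
            linkage_group = nm, parent = parent,
            pair = paste0(LETTERS[h1 + off], LETTERS[h2 + off]),
            observed = cnt[h1, h2],
            expected = n_mei / (p - 1),
            deviation = cnt[h1, h2] - n_mei / (p - 1))
        }
      }
      for (h in seq_len(p)) {
        obs <- cnt[h, -h]
        e <- n_mei / (p - 1)
        stat <- sum((obs - e)^2 / e)
        df <- p - 2L
        test_rows[[length(test_rows) + 1L]] <- data.frame(
          linkage_group = nm, parent = parent, homologue = LETTERS[h + off],
          statistic = stat, df = df,
          p_value = stats::pchisq(stat, df, lower.tail = FALSE),
          n_meioses = n_mei)
      }
    }
  }
  tests <- do.call(rbind, test_rows)
  tests$p_bonferroni <- pmin(tests$p_value * nrow(tests), 1)
  out <- list(pair_counts = do.call(rbind, pair_rows),
              homologue_tests = tests)
  class(out) <- "pairing_report"
  out
}

# Sign-change breakpoints of one difference track. Zero plateaus count
# once, at the midpoint between the flanking non-zero positions.
.sign_change_midpoints <- function(d, pos) {
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(numeric(0))
  ch <- which(s[nz[-1]] != s[nz[-length(nz)]])
  if (!length(ch)) return(numeric(0))
  (pos[nz[ch]] + pos[nz[ch + 1L]]) / 2
}

#' Detect recombination break-points from IBD probabilities
#'
#' Within every plausibly predicted bivalent of every meiosis, tracks the
#' difference between the two pairing homologues' inheritance
#' probabilities along the chromosome; each sign change marks one
#' cross-over recombination, placed at the midpoint between the flanking
#' positions. Ambiguous or multivalent meioses are skipped.
#'
#' @param ibd an \code{\link{ibd_probs}} from the HMM.
#' @param plausibility assignment threshold passed to
#'   \code{\link{count_valencies}}.
#' @return List: \code{events} (data.frame individual, linkage_group,
#'   parent, pair, position), \code{counts} (per-individual genome-wide
#'   totals), and \code{expected} -- the reference count
#'   offspring ploidy x number of linkage groups (one cross-over per
#'   homologue).
#' @export
count_recombinations <- function(ibd, plausibility = 0.4) {
  vc <- count_valencies(ibd, plausibility)
  ev <- list()
  for (nm in names(ibd$lg)) {
    l <- ibd$lg[[nm]]
    for (parent in 1:2) {
      off <- if (parent == 1L) 0L else ibd$ploidy1
      vals <- vc$valencies[[parent]]
      a <- vc$assignments
      a <- a[a$linkage_group == nm & a$parent == parent & a$plausible &
               !a$multivalent, , drop = FALSE]
      for (k in seq_len(nrow(a))) {
        i <- match(a$individual[k], ibd$individuals)
        for (u in vals[[a$valency[k]]]) {
          d <- l$X[, i, off + u[1]] - l$X[, i, off + u[2]]
          bp <- .sign_change_midpoints(d, l$positions)
          for (b in bp) {
            ev[[length(ev) + 1L]] <- data.frame(
              individual = a$individual[k], linkage_group = nm,
              parent = parent,
              pair = paste0(LETTERS[u[1] + off], LETTERS[u[2] + off]),
              position = b)
          }
        }
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(individual = character(0), linkage_group = character(0),
               parent = integer(0), pair = character(0),
               position = numeric(0))
  counts <- table(factor(events$individual, levels = ibd$individuals))
  counts <- data.frame(individual = names(counts),
                       recombinations = as.integer(counts))
  expected <- (ibd$ploidy1 + ibd$ploidy2) / 2 * length(ibd$lg)
  list(events = events, counts = counts, expected = expected)
}

#' Flag individuals with implausibly many recombinations
#'
#' @param recomb result of \code{\link{count_recombinations}}.
#' @param multiplier flag individuals whose genome-wide count exceeds
#'   \code{multiplier} times the expected reference (default 2).
#' @param dosages optional \code{\link{dosage_data}}; when given, the
#'   fraction of missing genotypes of each flagged individual is reported
#'   (outliers often carry excess missing or erroneous data).
#' @return data.frame individual, recombinations, expected, missing_fraction
#'   (NA without dosages), restricted to flagged individuals.
#' @export
screen_outliers <- function(recomb, multiplier = 2, dosages = NULL) {
  cts <- recomb$counts
  flag <- cts$recombinations > multiplier * recomb$expected
  out <- cts[flag, , drop = FALSE]
  out$expected <- rep(recomb$expected, nrow(out))
  out$missing_fraction <- rep(NA_real_, nrow(out))
  if (!is.null(dosages) && nrow(out)) {
    mf <- if (dosages$type == "discrete") {
      rowMeans(is.na(dosages$values))
    } else {
      apply(dosages$values, 1, function(v) mean(is.na(v))) # nocov
    }
    out$missing_fraction <- mf[match(out$individual, dosages$individuals)]
  }
  rownames(out) <- NULL
  out
}

#' Genotypic information coefficient (GIC)
#'
#' GIC of homologue j at a position is 1 - (4/N) sum_n P_nj (1 - P_nj),
#' where P_nj is the probability that offspring n inherited homologue j:
#' 1 when inheritance is known with certainty for all offspring, 0 when
#' maximally uncertain (all P = 0.5). When multivalents were modelled, only
#' offspring whose meiosis for that parent and linkage group is predicted
#' bivalent-only (maximum-posterior valency) are included, so that P stays
#' a probability in [0, 1].
#'
#' @param ibd an \code{\link{ibd_probs}}.
#' @return data.frame linkage_group, position, homologue, GIC, n (offspring
#'   included).
#' @export
gic <- function(ibd) {
  stopifnot(inherits(ibd, "ibd_probs"))
  hn <- homologue_names(ibd$ploidy1, ibd$ploidy2)
  rows <- list()
  for (nm in names(ibd$lg)) {
    l <- ibd$lg[[nm]]
    for (parent in 1:2) {
      hidx <- if (parent == 1L) .mat_idx(ibd) else .pat_idx(ibd)
      inc <- seq_along(ibd$individuals)
      if (ibd$multivalents) {
        if (is.null(l$val_post)) stop("multivalent IBDs without posteriors")
        M <- l$val_post[[parent]]
        vals <- attr(M, "valencies")
        best <- max.col(M, ties.method = "first")
        biv <- !vapply(vals[best], function(v)
          isTRUE(attr(v, "multivalent")), logical(1))
        inc <- which(biv)
        if (!length(inc)) {
          stop("no bivalent-predicted offspring for parent ", parent,
               " on LG ", nm)
        }
      }
      N <- length(inc)
      P <- l$X[, inc, hidx, drop = FALSE]
      P <- pmin(pmax(P, 0), 1)
      g <- 1 - (4 / N) * apply(P * (1 - P), c(1, 3), sum)
      for (j in seq_along(hidx)) {
        rows[[length(rows) + 1L]] <- data.frame(
          linkage_group = nm, position = l$positions,
          homologue = hn[hidx[j]], GIC = g[, j], n = N)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Impute marker dosages from IBD probabilities
#'
#' The imputed dosage of an individual at a marker is the element-wise
#' product of its homologue probabilities with the parental phase, summed
#' over homologues, rounded to the nearest integer. If the exact value
#' deviates from the rounded one by more than \code{rounding_threshold},
#' the call is set missing. Estimating the IBDs with a high error prior
#' (e.g. 0.2) first suppresses spurious recombinations caused by
#' genotyping errors, so the imputation corrects them.
#'
#' @param ibd an \code{\link{ibd_probs}} estimated at the marker positions
#'   (not an interpolated grid).
#' @param map the \code{\link{phased_map}} providing the phase.
#' @param rounding_threshold maximum allowed |exact - rounded| (default
#'   0.05).
#' @return A discrete \code{\link{dosage_data}} of imputed calls.
#' @export
impute_dosages <- function(ibd, map, rounding_threshold = 0.05) {
  stopifnot(inherits(ibd, "ibd_probs"), inherits(map, "phased_map"))
  n_i <- length(ibd$individuals)
  cols <- list()
  for (nm in names(ibd$lg)) {
    l <- ibd$lg[[nm]]
    if (is.null(l$marker)) {
      stop("IBDs must be at marker positions for imputation, not on a grid")
    }
    mi <- match(l$marker, map$marker)
    if (anyNA(mi)) stop("IBD markers not found on the map (LG ", nm, ")")
    phase <- map$phase[mi, , drop = FALSE]
    for (m in seq_along(l$marker)) {
      dhat <- as.numeric(l$X[m, , ] %*% phase[m, ])
      drounded <- round(dhat)
      drounded[abs(dhat - drounded) > rounding_threshold] <- NA
      cols[[l$marker[m]]] <- drounded
    }
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- ibd$individuals
  ploidy_off <- (ibd$ploidy1 + ibd$ploidy2) %/% 2L
  vals[!is.na(vals) & (vals < 0 | vals > ploidy_off)] <- NA
  dosage_data(vals, ploidy_off, type = "discrete")
}
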