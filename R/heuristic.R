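# Heuristic (non-HMM) IBD estimation. Works for any parental ploidy
# combination because it never builds a joint state space: each marker
# contributes per-homologue evidence for each parent independently, and
# evidence is pooled along the chromosome with a distance-decay kernel.
# Faster but less accurate than the HMM, especially for markers that are
# not simplex x nulliplex.

# Unnormalized evidence tables for one marker and one parent.
# Gametes are the uniform (p/2)-subsets of the parent's homologues; the
# other parent's dosage contribution is marginalized over its own uniform
# gametes. Returns list(U = (ploidy_off+1) x p matrix of
# sum_{g: h in g} P(obs = d | g), tot = row totals sum_g P(obs = d | g)).
.evidence_table <- function(phase_row, parent, ploidy1, ploidy2) {
  p <- if (parent == 1L) ploidy1 else ploidy2
  q <- if (parent == 1L) ploidy2 else ploidy1
  own_phase <- if (parent == 1L) phase_row[seq_len(ploidy1)] else
    phase_row[ploidy1 + seq_len(ploidy2)]
  oth_phase <- if (parent == 1L) phase_row[ploidy1 + seq_len(ploidy2)] else
    phase_row[seq_len(ploidy1)]
  ploidy_off <- (ploidy1 + ploidy2) / 2
  gam <- utils::combn(p, p / 2, simplify = FALSE)
  gdose <- vapply(gam, function(g) sum(own_phase[g]), numeric(1))
  # distribution of the other parent's dosage contribution
  ogam <- utils::combn(q, q / 2, simplify = FALSE)
  od <- vapply(ogam, function(g) sum(oth_phase[g]), numeric(1))
  Pd2 <- tabulate(od + 1L, nbins = ploidy_off + 1L) / length(ogam)
  U <- matrix(0, ploidy_off + 1L, p)
  tot <- numeric(ploidy_off + 1L)
  for (obs in 0:ploidy_off) {
    pg <- vapply(gdose, function(dg) {
      d2 <- obs - dg
      if (d2 < 0 || d2 > ploidy_off) 0 else Pd2[d2 + 1L]
    }, numeric(1))
    tot[obs + 1L] <- sum(pg)
    for (i in seq_along(gam)) U[obs + 1L, gam[[i]]] <-
        U[obs + 1L, gam[[i]]] + pg[i]
  }
  list(U = U, tot = tot)
}

#' Per-homologue evidence of a single marker observation
#'
#' For one parent, computes the probability that each of its homologues was
#' transmitted to the offspring, given the observed offspring dosage at a
#' marker, assuming the parent's gamete is a uniform draw of half its
#' homologues and marginalizing the other parent's contribution over its
#' own uniform gametes. The weights sum to the gamete size (ploidy/2).
#'
#' @param phase_row phase vector of the marker (length ploidy1 + ploidy2).
#' @param obs observed offspring dosage (single value, NA for missing) or a
#'   simplex over dosage classes.
#' @param parent 1 (maternal) or 2 (paternal).
#' @param ploidy1,ploidy2 parental ploidies.
#' @return Numeric vector of length ploidy_parent with attribute
#'   \code{"informative"}: FALSE when the marker does not segregate for
#'   this parent (all weights equal) or the observation is impossible.
#' @examples
#' # simplex x nulliplex marker, offspring dosage 1: the simplex homologue
#' # was certainly transmitted, the rest are equally likely companions
#' marker_homologue_evidence(c(1, 0, 0, 0, 0, 0, 0, 0), 1, 1, 4, 4)
#' @export
marker_homologue_evidence <- function(phase_row, obs, parent, ploidy1,
                                      ploidy2) {
  tabs <- .evidence_table(phase_row, parent, ploidy1, ploidy2)
  p <- if (parent == 1L) ploidy1 else ploidy2
  ploidy_off <- (ploidy1 + ploidy2) / 2
  uniform <- rep(0.5, p)
  if (length(obs) == 1L && is.na(obs)) {
    attr(uniform, "informative") <- FALSE
    return(uniform)
  }
  if (length(obs) == 1L) {
    q <- rep(0, ploidy_off + 1L)
    q[obs + 1L] <- 1
  } else {
    q <- obs
  }
  num <- as.numeric(q %*% tabs$U)
  den <- sum(q * tabs$tot)
  if (den <= 0) {
    attr(uniform, "informative") <- FALSE
    return(uniform)
  }
  w <- num / den
  attr(w, "informative") <- max(w) - min(w) > 1e-12
  w
}

# Scale a nonnegative vector so it sums to `target` with every entry <= 1
# (water-filling: capped entries stay at 1, the rest share the remainder
# proportionally). Requires length(v) >= target.
.cap_renorm <- function(v, target) {
  capped <- rep(FALSE, length(v))
  for (it in seq_along(v)) {
    free <- !capped
    rem <- target - sum(capped)
    if (rem <= 0 || !any(free)) break
    s <- sum(v[free])
    if (s <= 0) {
      v[free] <- rem / sum(free)
      break
    }
    v[free] <- v[free] * rem / s
    over <- free & v > 1
    if (!any(over)) break
    v[over] <- 1
    capped <- capped | over
  }
  v
}

#' Estimate IBD probabilities with the heuristic method
#'
#' At every marker position, per-marker homologue evidence
#' (\code{\link{marker_homologue_evidence}}) from all informative markers
#' within \code{window} cM is pooled geometrically: log-evidence is averaged
#' with distance-decay weights \code{1 - 2 r(d)} (Haldane), exponentiated,
#' capped at 1 (no double reduction is modelled) and renormalized so each
#' parent's homologue probabilities sum to half its ploidy. Any parental
#' ploidy in 2, 4, 6, 8, 10 is supported.
#'
#' @param map a \code{\link{phased_map}}.
#' @param dosages a \code{\link{dosage_data}}.
#' @param window half-width (cM) of the evidence window (default 20).
#' @param min_informative minimum number of informative markers in the
#'   window before a position is considered well supported; positions below
#'   this are recorded per linkage group in \code{low_confidence}.
#' @return An \code{\link{ibd_probs}} (method \code{"heuristic"}, no
#'   valency posteriors or double-reduction tracks).
#' @export
estimate_ibd_heuristic <- function(map, dosages, window = 20,
                                   min_informative = 2L) {
  stopifnot(inherits(map, "phased_map"), inherits(dosages, "dosage_data"))
  if (window <= 0) stop("window must be > 0")
  p1 <- map$ploidy1
  p2 <- map$ploidy2
  ploidy_off <- (p1 + p2) / 2
  if (dosages$ploidy != ploidy_off) {
    stop("dosage ploidy does not match the parents")
  }
  dosages <- align_dosages(dosages, map)
  n_i <- length(dosages$individuals)
  floor_ev <- 1e-10
  out <- list()
  for (lg in unique(map$linkage_group)) {
    sel <- which(map$linkage_group == lg)
    pos <- map$position[sel]
    phase <- map$phase[sel, , drop = FALSE]
    n_m <- length(sel)
    X <- array(0.5, dim = c(n_m, n_i, p1 + p2))
    low_conf <- rep(FALSE, n_m)
    for (parent in 1:2) {
      p <- if (parent == 1L) p1 else p2
      cols <- if (parent == 1L) seq_len(p1) else p1 + seq_len(p2)
      # per-marker evidence tables (shared across individuals)
      tabs <- lapply(seq_len(n_m), function(m) {
        .evidence_table(phase[m, ], parent, p1, p2)
      })
      informative <- vapply(seq_len(n_m), function(m) {
        U <- tabs[[m]]$U
        tot <- tabs[[m]]$tot
        any(apply(U[tot > 0, , drop = FALSE] / tot[tot > 0], 1,
                  function(w) max(w) - min(w) > 1e-12))
      }, logical(1))
      if (!any(informative)) {
        warning("no informative markers for parent ", parent,
                " on linkage group ", lg, "; returning uniform probabilities")
        X[, , cols] <- 0.5
        low_conf <- rep(TRUE, n_m)
        next
      }
      # distance-decay weight matrix restricted to the window
      D <- abs(outer(pos, pos, "-"))
      Wt <- (1 - 2 * haldane(D)) * (D <= window)
      Wt[, !informative] <- 0
      n_inf <- rowSums(Wt > 0)
      low_conf <- low_conf | n_inf < min_informative
      rs <- rowSums(Wt)
      rs[rs <= 0] <- 1
      Wt <- Wt / rs
      # per-individual log evidence and pooling
      logEv <- array(log(0.5), dim = c(n_m, p, n_i))
      for (m in which(informative)) {
        U <- tabs[[m]]$U
        tot <- tabs[[m]]$tot
        if (dosages$type == "discrete") {
          obs <- dosages$values[, sel[m]]
          ev <- matrix(0.5, n_i, p)
          ok <- !is.na(obs) & tot[obs + 1L] > 0
          if (any(ok)) {
            ev[ok, ] <- U[obs[ok] + 1L, , drop = FALSE] / tot[obs[ok] + 1L]
          }
        } else {
          q <- dosages$values[, sel[m], ]
          q[is.na(q)] <- 0
          num <- q %*% U
          den <- as.numeric(q %*% tot)
          ev <- matrix(0.5, n_i, p)
          ok <- den > 0
          ev[ok, ] <- num[ok, , drop = FALSE] / den[ok]
        }
        logEv[m, , ] <- t(log(pmax(ev, floor_ev)))
      }
      for (i in seq_len(n_i)) {
        Xi <- exp(Wt %*% logEv[, , i])       # n_m x p pooled evidence
        Xi <- Xi * (p / 2) / pmax(rowSums(Xi), 1e-300)
        bad <- which(apply(Xi, 1, max) > 1)
        for (m in bad) Xi[m, ] <- .cap_renorm(Xi[m, ], p / 2)
        X[, i, cols] <- Xi
      }
    }
    out[[as.character(lg)]] <- list(positions = pos, marker = map$marker[sel],
                                    X = X, dr = NULL, val_post = NULL,
                                    low_confidence = low_conf)
  }
  ibd_probs(out, dosages$individuals, p1, p2, method = "heuristic")
}
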