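# Pairing configurations (valencies) of a parent's homologues during
# meiosis, the gamete states they can produce, and the Markov transition
# model between gamete states along a chromosome.
#
# A valency partitions the parent's homologues into bivalents (pairs) and,
# when multivalents are allowed, one quadrivalent (four homologues). Each
# bivalent contributes one chromatid to the gamete; a quadrivalent
# contributes two chromatid lineages, which may end up as sister copies of
# the same homologue (double reduction).

# All perfect matchings of the integer vector v (even length).
.perfect_matchings <- function(v) {
  if (length(v) == 0L) return(list(list()))
  a <- v[1L]
  out <- list()
  for (j in seq_along(v)[-1L]) {
    rest <- .perfect_matchings(v[-c(1L, j)])
    for (m in rest) out[[length(out) + 1L]] <- c(list(c(a, v[j])), m)
  }
  out
}

#' Enumerate pairing configurations (valencies) of one parent
#'
#' Bivalent-only valencies are all perfect matchings of the parent's
#' homologues (1 for a diploid, 3 for a tetraploid, 15 for a hexaploid).
#' When multivalents are allowed, quadrivalent configurations are added:
#' for a tetraploid the single quadrivalent of all four homologues; for a
#' hexaploid every 4-subset as a quadrivalent with the remaining pair as a
#' bivalent (15 configurations). Hexavalents are not modelled.
#'
#' @param ploidy_parent parental ploidy: 2, 4 or 6.
#' @param allow_multivalents logical.
#' @return List of valencies; each valency is a list of units (integer
#'   vectors of homologue indices), bivalents of size 2 and at most one
#'   quadrivalent of size 4, with attribute \code{"multivalent"}.
#' @examples
#' length(enumerate_valencies(6, FALSE)) # 15 bivalent pairings
#' @export
enumerate_valencies <- function(ploidy_parent, allow_multivalents = FALSE) {
  if (!ploidy_parent %in% c(2L, 4L, 6L)) {
    stop("unsupported parental ploidy: ", ploidy_parent)
  }
  vals <- .perfect_matchings(seq_len(ploidy_parent))
  vals <- lapply(vals, function(v) {
    attr(v, "multivalent") <- FALSE
    v
  })
  if (allow_multivalents && ploidy_parent >= 4L) {
    if (ploidy_parent == 4L) {
      q <- list(list(1:4))
    } else {
      subs <- utils::combn(6L, 4L, simplify = FALSE)
      q <- lapply(subs, function(s) list(s, setdiff(1:6, s)))
    }
    q <- lapply(q, function(v) {
      attr(v, "multivalent") <- TRUE
      v
    })
    vals <- c(vals, q)
  }
  vals
}

#' Human-readable label for a valency
#' @param v a valency from \code{\link{enumerate_valencies}}.
#' @param offset integer added to homologue indices before lettering (use
#'   ploidy1 for paternal valencies).
#' @return A string such as \code{"(AB)(CD)"} or \code{"(ABCD)"}.
#' @export
valency_label <- function(v, offset = 0L) {
  paste0(vapply(v, function(u) {
    paste0("(", paste(LETTERS[u + offset], collapse = ""), ")")
  }, character(1)), collapse = "")
}

#' Enumerate gamete states of a valency
#'
#' The gamete receives one homologue from each bivalent and two (possibly
#' identical, i.e. double reduction) from a quadrivalent: all multisets of
#' size 2 of its four homologues, 10 in total.
#'
#' @param v a valency.
#' @return List of gamete states; each state is an integer vector (sorted,
#'   possibly with a repeated label) of length ploidy_parent/2 with
#'   attribute \code{"doubled"} (TRUE if some homologue appears twice).
#' @export
gamete_states <- function(v) {
  unit_choices <- lapply(v, function(u) {
    if (length(u) == 2L) {
      lapply(u, function(h) h)
    } else {
      ch <- utils::combn(u, 2L, simplify = FALSE)
      c(ch, lapply(u, function(h) c(h, h)))
    }
  })
  grid <- do.call(expand.grid, c(lapply(unit_choices, seq_along),
                                 KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(grid)), function(i) {
    s <- sort(unlist(lapply(seq_along(unit_choices), function(k) {
      unit_choices[[k]][[grid[i, k]]]
    })))
    attr(s, "doubled") <- anyDuplicated(s) > 0L
    s
  })
}

# Per-unit gamete-state transition matrix at recombination fraction r.
# Bivalent: stay 1-r / switch r. Quadrivalent: two independent chromatid
# lineages, each staying with 1-r or moving to each of the other three
# homologues with r/3; the 16 ordered lineage pairs are aggregated to the
# 10 unordered multiset states.
.unit_transition <- function(unit, r) {
  if (length(unit) == 2L) {
    return(matrix(c(1 - r, r, r, 1 - r), 2L, 2L))
  }
  T4 <- matrix(r / 3, 4L, 4L)
  diag(T4) <- 1 - r
  T16 <- T4 %x% T4  # ordered pairs (a, b): index (a-1)*4 + b
  ch <- utils::combn(4L, 2L, simplify = FALSE)
  states <- c(ch, lapply(1:4, function(h) c(h, h)))  # 10 multisets
  ord_of <- function(s) {
    if (s[1] == s[2]) (s[1] - 1L) * 4L + s[2]
    else c((s[1] - 1L) * 4L + s[2], (s[2] - 1L) * 4L + s[1])
  }
  T10 <- matrix(0, 10L, 10L)
  for (i in 1:10) {
    row <- T16[ord_of(states[[i]])[1], ]
    for (j in 1:10) T10[i, j] <- sum(row[ord_of(states[[j]])])
  }
  T10
}

#' Gamete-state transition matrix along a chromosome
#'
#' Transition probabilities between the gamete states of a valency across
#' an interval with recombination fraction \code{r}, assuming independence
#' across units (one cross-over process per bivalent; two independent
#' chromatid lineages within a quadrivalent).
#'
#' @param v a valency.
#' @param r recombination fraction in [0, 0.5]; map distances are converted
#'   via Haldane's function r = (1 - exp(-2d/100))/2 upstream.
#' @return Row-stochastic matrix over the states of
#'   \code{\link{gamete_states}(v)}, in the same order.
#' @export
transition_matrix <- function(v, r) {
  if (r < 0 || r > 0.5) stop("recombination fraction out of [0, 0.5]")
  unitTs <- lapply(v, .unit_transition, r = r)
  Reduce(function(A, B) B %x% A, unitTs)
}

#' Haldane map function
#' @param d distance in cM.
#' @return Recombination fraction \code{(1 - exp(-2 d / 100)) / 2}.
#' @export
haldane <- function(d) (1 - exp(-2 * d / 100)) / 2

# Copy-count matrix: n_states x ploidy_parent, entry = copies of homologue
# h carried by the gamete in that state.
.state_copies <- function(states, ploidy_parent) {
  C <- matrix(0, length(states), ploidy_parent)
  for (i in seq_along(states)) {
    for (h in states[[i]]) C[i, h] <- C[i, h] + 1
  }
  C
}

#' Emission probability of an observed dosage given gamete states
#'
#' Given the maternal and paternal gamete states and the marker phase, the
#' predicted offspring dosage is the sum of phase entries over all inherited
#' homologue copies. A discrete observation then has probability
#' \code{1 - eps} if it equals the prediction and \code{eps/ploidy}
#' otherwise; a missing observation has probability 1; a probabilistic
#' observation \code{q} has probability
#' \code{(1-eps) q[d*] + eps (1 - q[d*]) / ploidy}.
#'
#' @param state_m maternal gamete state (integer vector of maternal
#'   homologue indices 1..ploidy1, repeats meaning double reduction).
#' @param state_p paternal gamete state (indices 1..ploidy2).
#' @param phase phase vector of length ploidy1 + ploidy2.
#' @param obs either a single dosage (NA for missing) or a numeric simplex
#'   of length offspring_ploidy + 1.
#' @param eps genotyping error prior in (0, 0.5).
#' @param ploidy1,ploidy2 parental ploidies.
#' @return Emission probability.
#' @export
emission_prob <- function(state_m, state_p, phase, obs, eps, ploidy1,
                          ploidy2) {
  ploidy_off <- (ploidy1 + ploidy2) / 2
  dstar <- sum(phase[state_m]) + sum(phase[ploidy1 + state_p])
  if (length(obs) == 1L) {
    if (is.na(obs)) return(1)
    if (obs < 0 || obs > ploidy_off) stop("observed dosage out of range")
    return(if (obs == dstar) 1 - eps else eps / ploidy_off)
  }
  q <- obs
  if (length(q) != ploidy_off + 1) stop("simplex of wrong length")
  (1 - eps) * q[dstar + 1] + eps * (1 - q[dstar + 1]) / ploidy_off
}
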