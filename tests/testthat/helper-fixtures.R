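# Small in-code fixtures shared across test files.

# 3-marker tetraploid x tetraploid toy map with mixed segregation types.
toy_tetra_map <- function() {
  ph <- rbind(c(1, 0, 0, 0, 0, 0, 0, 0),
              c(0, 1, 1, 0, 0, 0, 1, 1),
              c(1, 1, 0, 0, 0, 1, 0, 1))
  phased_map(c("a", "b", "c"), c(1, 1, 1), c(0, 12, 30), ph, 4, 4)
}

toy_tetra_dosages <- function() {
  dosage_data(matrix(c(1, 2, 2, 0, 3, 1), 2, 3, byrow = TRUE,
                     dimnames = list(c("i1", "i2"), c("a", "b", "c"))), 4)
}

# Hand-built IBD object (bivalent-style probabilities) for diagnostics
# tests: X is positions x individuals x homologues.
manual_ibd <- function(X, positions, ploidy1 = 4, ploidy2 = 4,
                       markers = NULL, val_post = NULL, dr = NULL,
                       method = "hmm", multivalents = FALSE,
                       lg_name = "1") {
  individuals <- if (is.null(dimnames(X)[[2]]))
    paste0("i", seq_len(dim(X)[2])) else dimnames(X)[[2]]
  lg <- list(list(positions = positions, marker = markers, X = X, dr = dr,
                  val_post = val_post))
  names(lg) <- lg_name
  ibd_probs(lg, individuals, ploidy1, ploidy2, method = method,
            multivalents = multivalents)
}

# Valency posterior matrices concentrated on given valency indices.
concentrated_val_post <- function(ploidy, idx, multivalents = FALSE,
                                  conf = 0.99) {
  vals <- enumerate_valencies(ploidy, multivalents)
  M <- matrix((1 - conf) / (length(vals) - 1), length(idx), length(vals))
  M[cbind(seq_along(idx), idx)] <- conf
  attr(M, "valencies") <- vals
  M
}

# A fabricated valency_assignment with prescribed bivalent counts: 'counts'
# is a named integer vector of valency indices -> number of meioses, for
# one hexaploid parent on one LG (the other parent mirrors it).
fabricated_assignment <- function(counts, ploidy = 6) {
  vals <- enumerate_valencies(ploidy, FALSE)
  vidx <- rep(as.integer(names(counts)), counts)
  n <- length(vidx)
  assignments <- do.call(rbind, lapply(1:2, function(parent) {
    data.frame(individual = paste0("i", seq_len(n)), linkage_group = "1",
               parent = parent, valency = vidx,
               label = vapply(vals[vidx], valency_label, character(1),
                              offset = if (parent == 2) ploidy else 0L),
               multivalent = FALSE, posterior = 1, plausible = TRUE)
  }))
  out <- list(assignments = assignments,
              multivalent_counts = data.frame(linkage_group = "1",
                                              parent = 1:2,
                                              n_multivalent = 0,
                                              n_assigned = n),
              ploidy1 = ploidy, ploidy2 = ploidy,
              valencies = list(p1 = vals, p2 = vals), plausibility = 0.4)
  class(out) <- "valency_assignment"
  out
}
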