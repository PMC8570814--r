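# Exhaustive-enumeration oracle for the HMM: builds the full joint
# probability array over all state paths (feasible for <= 3 markers) and
# computes the exact posterior expected homologue copy counts and
# double-reduction probabilities, independently of the forward-backward
# implementation.
brute_force_ibd <- function(map, dosages, eps, mv = FALSE, mv_prior = 0.1) {
  p1 <- map$ploidy1
  p2 <- map$ploidy2
  valM <- enumerate_valencies(p1, mv)
  valP <- enumerate_valencies(p2, mv)
  prM <- polyseg:::.valency_prior(valM, mv, mv_prior)
  prP <- polyseg:::.valency_prior(valP, mv, mv_prior)
  n_m <- length(map$marker)
  n_i <- length(dosages$individuals)
  stopifnot(n_m <= 3)
  X <- array(0, dim = c(n_m, n_i, p1 + p2))
  dr <- array(0, dim = c(n_m, n_i, 2))
  rv <- polyseg:::haldane(pmax(diff(map$position), 1e-4))
  for (i in seq_len(n_i)) {
    tot <- 0
    Xi <- array(0, dim = c(n_m, p1 + p2))
    dri <- matrix(0, n_m, 2)
    for (a in seq_along(valM)) {
      for (b in seq_along(valP)) {
        sm <- gamete_states(valM[[a]])
        sp <- gamete_states(valP[[b]])
        idx <- expand.grid(p = seq_along(sp),
                           m = seq_along(sm))[, c("m", "p")]
        S <- nrow(idx)
        Tj <- lapply(rv, function(r) {
          transition_matrix(valM[[a]], r) %x% transition_matrix(valP[[b]], r)
        })
        Emat <- sapply(seq_len(n_m), function(t) {
          obs <- if (dosages$type == "discrete") dosages$values[i, t] else
            dosages$values[i, t, ]
          vapply(seq_len(S), function(s) {
            emission_prob(sm[[idx$m[s]]], sp[[idx$p[s]]], map$phase[t, ],
                          obs, eps, p1, p2)
          }, numeric(1))
        })
        if (n_m == 1) {
          J <- array(Emat[, 1] / S, dim = S)
          margins <- list(J)
        } else if (n_m == 2) {
          J <- (Emat[, 1] / S) * Tj[[1]] * rep(Emat[, 2], each = S)
          margins <- list(rowSums(matrix(J, S, S)),
                          colSums(matrix(J, S, S)))
        } else {
          J <- array(0, dim = c(S, S, S))
          for (s3 in seq_len(S)) {
            J[, , s3] <- (Emat[, 1] / S) * Tj[[1]] *
              rep(Emat[, 2] * Tj[[2]][, s3], each = S) * Emat[s3, 3]
          }
          margins <- list(apply(J, 1, sum), apply(J, 2, sum),
                          apply(J, 3, sum))
        }
        w <- prM[a] * prP[b]
        tot <- tot + w * sum(J)
        Cm <- polyseg:::.state_copies(sm, p1)
        Cp <- polyseg:::.state_copies(sp, p2)
        Cj <- cbind(Cm[idx$m, , drop = FALSE], Cp[idx$p, , drop = FALSE])
        dm <- vapply(sm, attr, logical(1), "doubled")[idx$m]
        dp <- vapply(sp, attr, logical(1), "doubled")[idx$p]
        for (t in seq_len(n_m)) {
          Xi[t, ] <- Xi[t, ] + w * as.numeric(margins[[t]] %*% Cj)
          dri[t, 1] <- dri[t, 1] + w * sum(margins[[t]] * dm)
          dri[t, 2] <- dri[t, 2] + w * sum(margins[[t]] * dp)
        }
      }
    }
    X[, i, ] <- Xi / tot
    dr[, i, ] <- dri / tot
  }
  list(X = X, dr = dr)
}
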