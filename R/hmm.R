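# HMM estimation of offspring IBD probabilities.
#
# Per offspring and linkage group, each parent makes one pairing decision
# (valency) for the whole chromosome. Conditional on the maternal and
# paternal valencies, the gamete states of the two parents evolve as
# independent Markov chains along the chromosome (transition_matrix), and
# the observed offspring dosages are noisy emissions of the joint state
# (emission_prob). Forward-backward over the joint chain gives per-position
# state posteriors; averaging over valency pairs weighted by their
# posterior probabilities gives the expected inheritance count of every
# parental homologue. The forward recursion is run for all individuals
# simultaneously (individuals x states matrices), with per-step scaling;
# log-likelihoods accumulate from the scaling factors.

# Emission lookup: n_ind x (ploidy_off+1) x n_markers array of
# P(observation | predicted dosage d), for every d.
.emission_lookup <- function(dosages, marker_idx, eps) {
  p <- dosages$ploidy
  n_i <- length(dosages$individuals)
  n_m <- length(marker_idx)
  P <- array(1, dim = c(n_i, p + 1L, n_m))
  if (dosages$type == "discrete") {
    obs <- dosages$values[, marker_idx, drop = FALSE]
    for (d in 0:p) {
      slab <- ifelse(is.na(obs), 1, ifelse(obs == d, 1 - eps, eps / p))
      P[, d + 1L, ] <- slab
    }
  } else {
    q <- dosages$values[, marker_idx, , drop = FALSE]
    for (d in 0:p) {
      qd <- q[, , d + 1L, drop = TRUE]
      if (is.null(dim(qd))) qd <- matrix(qd, nrow = n_i)
      slab <- (1 - eps) * qd + eps * (1 - qd) / p
      slab[is.na(slab)] <- 1
      P[, d + 1L, ] <- slab
    }
  }
  P
}

# Precompute, for one valency pair, everything the chain needs.
.pair_model <- function(vm, vp, ploidy1, ploidy2, phase, rvec) {
  sm <- gamete_states(vm)
  sp <- gamete_states(vp)
  nm <- length(sm)
  np <- length(sp)
  Cm <- .state_copies(sm, ploidy1)
  Cp <- .state_copies(sp, ploidy2)
  # predicted dosage per joint state per marker; joint index (im-1)*np + ip
  dM <- Cm %*% t(phase[, seq_len(ploidy1), drop = FALSE])        # nm x n_mk
  dP <- Cp %*% t(phase[, ploidy1 + seq_len(ploidy2), drop = FALSE])
  dstar <- dM[rep(seq_len(nm), each = np), , drop = FALSE] +
    dP[rep(seq_len(np), times = nm), , drop = FALSE]
  Tlist <- lapply(rvec, function(r) {
    transition_matrix(vm, r) %x% transition_matrix(vp, r)
  })
  Cjoint <- cbind(Cm[rep(seq_len(nm), each = np), , drop = FALSE],
                  Cp[rep(seq_len(np), times = nm), , drop = FALSE])
  dbl_m <- vapply(sm, attr, logical(1), "doubled")
  dbl_p <- vapply(sp, attr, logical(1), "doubled")
  list(n_states = nm * np, dstar = dstar, Tlist = Tlist, Cjoint = Cjoint,
       dr = cbind(m = dbl_m[rep(seq_len(nm), each = np)],
                  p = dbl_p[rep(seq_len(np), times = nm)]))
}

# Scaled forward pass for all individuals at once.
# Returns list(loglik = n_ind vector, alpha = list of scaled n_ind x S).
.forward <- function(model, E, keep_alpha = FALSE) {
  n_m <- dim(E)[3]
  n_i <- dim(E)[1]
  S <- model$n_states
  loglik <- numeric(n_i)
  alpha <- if (keep_alpha) vector("list", n_m) else NULL
  A <- matrix(1 / S, n_i, S) * E[, model$dstar[, 1] + 1L, 1]
  sc <- rowSums(A)
  sc[sc <= 0] <- .Machine$double.xmin
  A <- A / sc
  loglik <- loglik + log(sc)
  if (keep_alpha) alpha[[1]] <- A
  if (n_m > 1L) {
    for (t in 2:n_m) {
      A <- (A %*% model$Tlist[[t - 1L]]) * E[, model$dstar[, t] + 1L, t]
      sc <- rowSums(A)
      sc[sc <= 0] <- .Machine$double.xmin
      A <- A / sc
      loglik <- loglik + log(sc)
      if (keep_alpha) alpha[[t]] <- A
    }
  }
  list(loglik = loglik, alpha = alpha)
}

# Backward pass returning per-position state posteriors gamma (list of
# n_ind x S matrices, rows summing to 1).
.state_posteriors <- function(model, E) {
  fw <- .forward(model, E, keep_alpha = TRUE)
  n_m <- dim(E)[3]
  S <- model$n_states
  n_i <- dim(E)[1]
  gamma <- vector("list", n_m)
  B <- matrix(1, n_i, S)
  g <- fw$alpha[[n_m]] * B
  gamma[[n_m]] <- g / rowSums(g)
  if (n_m > 1L) {
    for (t in (n_m - 1L):1L) {
      B <- (B * E[, model$dstar[, t + 1L] + 1L, t + 1L]) %*%
        t(model$Tlist[[t]])
      bs <- rowSums(B)
      bs[bs <= 0] <- .Machine$double.xmin
      B <- B / bs
      g <- fw$alpha[[t]] * B
      gamma[[t]] <- g / rowSums(g)
    }
  }
  list(gamma = gamma, loglik = fw$loglik)
}

#' Estimate IBD probabilities with the hidden Markov model
#'
#' Runs forward-backward over the joint maternal x paternal gamete-state
#' chain for every valency pair and every offspring, per linkage group.
#' Valency posteriors are proportional to prior times marginal likelihood;
#' the prior places \code{multivalent_prior} total mass on multivalent
#' configurations (split evenly) and the remainder evenly over the
#' bivalent-only pairings. IBD probabilities are posterior-weighted expected
#' homologue copy counts; when multivalents are allowed, the posterior mass
#' on doubled (double-reduction) gamete states is recorded per position and
#' parent.
#'
#' @param map a \code{\link{phased_map}}.
#' @param dosages a \code{\link{dosage_data}} (discrete or probabilistic);
#'   markers are aligned to the map by name.
#' @param error_prior genotyping error prior in (0, 0.5); 0.01-0.05 for
#'   high-quality data, up to 0.2 for noisy data.
#' @param allow_multivalents include quadrivalent pairings in the model?
#' @param multivalent_prior prior probability that a parent forms a
#'   multivalent on a given chromosome (used only when
#'   \code{allow_multivalents}).
#' @return An \code{\link{ibd_probs}} at the marker positions, with valency
#'   posteriors, per-individual log-likelihoods and (if multivalents were
#'   allowed) double-reduction tracks. Individuals with no non-missing
#'   genotype on a linkage group receive uniform probabilities and are
#'   listed in that group's \code{all_missing} element.
#' @export
estimate_ibd_hmm <- function(map, dosages, error_prior = 0.01,
                             allow_multivalents = FALSE,
                             multivalent_prior = 0.1) {
  stopifnot(inherits(map, "phased_map"), inherits(dosages, "dosage_data"))
  p1 <- map$ploidy1
  p2 <- map$ploidy2
  ploidy_off <- (p1 + p2) / 2
  if (!ploidy_off %in% c(2, 3, 4, 6)) {
    stop("HMM supports offspring ploidies 2, 3, 4 and 6 (got ",
         ploidy_off, "); use the heuristic for other ploidies")
  }
  if (dosages$ploidy != ploidy_off) {
    stop("dosage ploidy ", dosages$ploidy, " does not match offspring ploidy ",
         ploidy_off, " implied by the parents")
  }
  if (error_prior <= 0 || error_prior >= 0.5) {
    stop("error_prior must lie in (0, 0.5)")
  }
  dosages <- align_dosages(dosages, map)
  valM <- enumerate_valencies(p1, allow_multivalents)
  valP <- enumerate_valencies(p2, allow_multivalents)
  priorM <- .valency_prior(valM, allow_multivalents, multivalent_prior)
  priorP <- .valency_prior(valP, allow_multivalents, multivalent_prior)
  n_i <- length(dosages$individuals)
  lgs <- unique(map$linkage_group)
  out <- list()
  for (lg in lgs) {
    sel <- which(map$linkage_group == lg)
    pos <- map$position[sel]
    phase <- map$phase[sel, , drop = FALSE]
    n_m <- length(sel)
    d <- diff(pos)
    rvec <- haldane(pmax(d, 1e-4))  # 0 cM ties floored to keep chains mixing
    E <- .emission_lookup(dosages, sel, error_prior)
    n_pairs <- length(valM) * length(valP)
    models <- vector("list", n_pairs)
    lprior <- numeric(n_pairs)
    k <- 0L
    for (a in seq_along(valM)) {
      for (b in seq_along(valP)) {
        k <- k + 1L
        models[[k]] <- .pair_model(valM[[a]], valP[[b]], p1, p2, phase, rvec)
        lprior[k] <- log(priorM[a]) + log(priorP[b])
        models[[k]]$vm <- a
        models[[k]]$vp <- b
      }
    }
    # pass 1: marginal log-likelihood of every valency pair
    LL <- matrix(0, n_pairs, n_i)
    for (k in seq_len(n_pairs)) {
      LL[k, ] <- .forward(models[[k]], E)$loglik
    }
    LP <- LL + lprior
    mx <- apply(LP, 2, max)
    W <- exp(sweep(LP, 2, mx, "-"))
    W <- sweep(W, 2, colSums(W), "/")  # n_pairs x n_ind posterior weights
    # pass 2: accumulate posterior-weighted expected copy counts
    X <- array(0, dim = c(n_m, n_i, p1 + p2))
    dr <- array(0, dim = c(n_m, n_i, 2))
    for (k in seq_len(n_pairs)) {
      if (max(W[k, ]) < 1e-12) next
      sp <- .state_posteriors(models[[k]], E)
      wk <- W[k, ]
      for (t in seq_len(n_m)) {
        gw <- sp$gamma[[t]] * wk
        X[t, , ] <- X[t, , ] + gw %*% models[[k]]$Cjoint
        dr[t, , 1] <- dr[t, , 1] + gw %*% models[[k]]$dr[, "m"]
        dr[t, , 2] <- dr[t, , 2] + gw %*% models[[k]]$dr[, "p"]
      }
    }
    # per-parent valency posteriors
    vpostM <- matrix(0, n_i, length(valM))
    vpostP <- matrix(0, n_i, length(valP))
    for (k in seq_len(n_pairs)) {
      vpostM[, models[[k]]$vm] <- vpostM[, models[[k]]$vm] + W[k, ]
      vpostP[, models[[k]]$vp] <- vpostP[, models[[k]]$vp] + W[k, ]
    }
    attr(vpostM, "valencies") <- valM
    attr(vpostP, "valencies") <- valP
    rownames(vpostM) <- rownames(vpostP) <- dosages$individuals
    all_missing <- .all_missing_individuals(dosages, sel)
    # total marginal log-likelihood per individual (mixture over pairs)
    llind <- mx + log(colSums(exp(sweep(LP, 2, mx, "-"))))
    out[[as.character(lg)]] <- list(
      positions = pos, marker = map$marker[sel], X = X,
      dr = if (allow_multivalents) dr else NULL,
      val_post = list(p1 = vpostM, p2 = vpostP),
      loglik = stats::setNames(llind, dosages$individuals),
      all_missing = dosages$individuals[all_missing])
  }
  ibd_probs(out, dosages$individuals, p1, p2, method = "hmm",
            error_prior = error_prior, multivalents = allow_multivalents)
}

.valency_prior <- function(vals, allow_multivalents, multivalent_prior) {
  mv <- vapply(vals, attr, logical(1), "multivalent")
  if (!allow_multivalents || !any(mv)) {
    return(rep(1 / length(vals), length(vals)))
  }
  pr <- numeric(length(vals))
  pr[mv] <- multivalent_prior / sum(mv)
  pr[!mv] <- (1 - multivalent_prior) / sum(!mv)
  pr
}

.all_missing_individuals <- function(dosages, marker_idx) {
  if (dosages$type == "discrete") {
    rowSums(!is.na(dosages$values[, marker_idx, drop = FALSE])) == 0L
  } else {
    apply(dosages$values[, marker_idx, , drop = FALSE], 1,
          function(v) all(is.na(v)))
  }
}
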