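# Readers and writers for the package's tabular formats (comma or tab
# separated, header mandatory, missing values as empty cells or "NA"),
# plus cubic-spline interpolation of IBD probabilities onto a cM grid.

.read_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("no markers: file '", path, "' is empty")
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = FALSE,
                    comment.char = "")
}

#' Read a phased linkage map from file
#'
#' Expects a header row with columns \code{marker}, \code{LG},
#' \code{position} and one column per parental homologue (\code{h1} ..
#' \code{h(ploidy1+ploidy2)}), comma or tab separated. The split between
#' maternal and paternal homologue columns is given by \code{ploidy1}.
#'
#' @param path file path.
#' @param ploidy1,ploidy2 parental ploidies; columns h1..h(ploidy1) are
#'   maternal, the remainder paternal.
#' @return A \code{\link{phased_map}}.
#' @export
read_phased_map <- function(path, ploidy1, ploidy2) {
  tab <- .read_table(path)
  need <- c("marker", "LG", "position")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  hcols <- paste0("h", seq_len(ploidy1 + ploidy2))
  miss <- setdiff(hcols, names(tab))
  if (length(miss)) {
    stop("missing phase column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop("no markers in '", path, "'")
  phase <- as.matrix(tab[, hcols])
  bad <- which(!(phase %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad))) {
    stop("non-binary phase entry in row ", bad[1, 1], " (marker '",
         tab$marker[bad[1, 1]], "', data line ", bad[1, 1] + 1L, ")")
  }
  phased_map(tab$marker, tab$LG, tab$position, phase, ploidy1, ploidy2)
}

#' Write a phased linkage map
#'
#' @param map a \code{phased_map}.
#' @param path output path; tab separated with header.
#' @return \code{path}, invisibly.
#' @export
write_phased_map <- function(map, path) {
  stopifnot(inherits(map, "phased_map"))
  ph <- map$phase
  colnames(ph) <- paste0("h", seq_len(ncol(ph)))
  tab <- data.frame(marker = map$marker, LG = map$linkage_group,
                    position = map$position, ph, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read offspring dosages from file
#'
#' Discrete dosages: a wide table, individuals as rows (first column
#' \code{individual}), markers as columns; empty cells or "NA" are missing.
#' Probabilistic dosages: a long table with columns \code{individual},
#' \code{marker}, \code{p0} .. \code{p<ploidy>}.
#'
#' @param path file path.
#' @param ploidy offspring ploidy.
#' @param probabilistic logical; read the long probabilistic format?
#' @return A \code{\link{dosage_data}}.
#' @export
read_dosages <- function(path, ploidy, probabilistic = FALSE) {
  tab <- .read_table(path)
  if (!probabilistic) {
    if (names(tab)[1] != "individual") {
      stop("first column of a discrete dosage table must be 'individual'")
    }
    vals <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- tab$individual
    over <- which(vals > ploidy | vals < 0, arr.ind = TRUE)
    if (nrow(over)) {
      stop("dosage ", vals[over[1, 1], over[1, 2]], " outside 0..", ploidy,
           " for individual '", tab$individual[over[1, 1]], "', marker '",
           colnames(vals)[over[1, 2]], "'")
    }
    return(dosage_data(vals, ploidy, type = "discrete"))
  }
  need <- c("individual", "marker", paste0("p", 0:ploidy))
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  P <- as.matrix(tab[, paste0("p", 0:ploidy)])
  s <- rowSums(P)
  if (any(abs(s - 1) > 1e-6)) {
    i <- which(abs(s - 1) > 1e-6)[1]
    stop("probabilities sum to ", format(s[i]), " (not 1) for individual '",
         tab$individual[i], "', marker '", tab$marker[i], "'")
  }
  inds <- unique(tab$individual)
  mks <- unique(tab$marker)
  arr <- array(NA_real_, dim = c(length(inds), length(mks), ploidy + 1L),
               dimnames = list(inds, mks, NULL))
  ii <- match(tab$individual, inds)
  mi <- match(tab$marker, mks)
  for (d in 0:ploidy) {
    arr[cbind(ii, mi, d + 1L)] <- P[, d + 1L]
  }
  dosage_data(arr, ploidy, type = "prob")
}

#' Write offspring dosages
#'
#' Writes the wide format for discrete data and the long \code{p0..p<k>}
#' format for probabilistic data (see \code{\link{read_dosages}}).
#'
#' @param dosages a \code{dosage_data}.
#' @param path output path; tab separated.
#' @return \code{path}, invisibly.
#' @export
write_dosages <- function(dosages, path) {
  stopifnot(inherits(dosages, "dosage_data"))
  if (dosages$type == "discrete") {
    tab <- data.frame(individual = dosages$individuals, dosages$values,
                      check.names = FALSE)
  } else {
    n_i <- length(dosages$individuals)
    n_m <- length(dosages$markers)
    P <- matrix(aperm(dosages$values, c(1, 2, 3)),
                nrow = n_i * n_m, ncol = dosages$ploidy + 1L)
    colnames(P) <- paste0("p", 0:dosages$ploidy)
    tab <- data.frame(individual = rep(dosages$individuals, times = n_m),
                      marker = rep(dosages$markers, each = n_i),
                      P, check.names = FALSE)
    tab <- tab[stats::complete.cases(P), , drop = FALSE]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phenotypes from file
#'
#' Expects columns \code{individual}, \code{trait} and optionally
#' \code{block}. Multiple rows per individual are allowed (one per block).
#'
#' @param path file path.
#' @return A data.frame with columns individual, trait and (if present)
#'   block (as factor).
#' @export
read_phenotypes <- function(path) {
  tab <- .read_table(path)
  miss <- setdiff(c("individual", "trait"), names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  tab$individual <- as.character(tab$individual)
  tab$trait <- as.numeric(tab$trait)
  if ("block" %in% names(tab)) tab$block <- factor(tab$block)
  ok <- !is.na(tab$trait)
  if (sum(ok) < 2L) stop("fewer than 2 non-missing phenotype values")
  tab
}

#' Export IBD probabilities as a tidy table
#'
#' @param ibd an \code{ibd_probs}.
#' @return data.frame with columns linkage_group, position, marker,
#'   individual and one column per homologue.
#' @export
ibd_table <- function(ibd) {
  stopifnot(inherits(ibd, "ibd_probs"))
  hn <- homologue_names(ibd$ploidy1, ibd$ploidy2)
  out <- lapply(names(ibd$lg), function(nm) {
    l <- ibd$lg[[nm]]
    np <- length(l$positions)
    ni <- length(ibd$individuals)
    Xf <- matrix(aperm(l$X, c(2, 1, 3)), nrow = np * ni)
    colnames(Xf) <- hn
    data.frame(linkage_group = nm,
               position = rep(l$positions, each = ni),
               marker = rep(if (is.null(l$marker)) NA_character_ else l$marker,
                            each = ni),
               individual = rep(ibd$individuals, times = np),
               Xf, check.names = FALSE)
  })
  do.call(rbind, out)
}

#' Write IBD probabilities to a directory
#'
#' One tab-separated table per linkage group plus, when available, valency
#' posterior tables, and a JSON metadata sidecar recording ploidies, method
#' and error prior.
#'
#' @param ibd an \code{ibd_probs}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_ibd <- function(ibd, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- ibd_table(ibd)
  for (nm in unique(tab$linkage_group)) {
    utils::write.table(tab[tab$linkage_group == nm, , drop = FALSE],
                       file.path(dir, paste0("ibd_LG", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(ibd$lg)) {
    l <- ibd$lg[[nm]]
    ni <- length(ibd$individuals)
    if (!is.null(l$dr)) {
      np <- length(l$positions)
      dtab <- data.frame(position = rep(l$positions, each = ni),
                         individual = rep(ibd$individuals, times = np),
                         dr_p1 = as.vector(t(l$dr[, , 1])),
                         dr_p2 = as.vector(t(l$dr[, , 2])))
      utils::write.table(dtab, file.path(dir, paste0("dr_LG", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(l$val_post)) {
      vt <- do.call(rbind, lapply(1:2, function(parent) {
        M <- l$val_post[[parent]]
        data.frame(individual = rep(ibd$individuals, times = ncol(M)),
                   parent = parent,
                   valency = rep(seq_len(ncol(M)), each = nrow(M)),
                   posterior = as.vector(M))
      }))
      utils::write.table(vt, file.path(dir, paste0("valency_posterior_LG",
                                                   nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  meta <- list(ploidy1 = ibd$ploidy1, ploidy2 = ibd$ploidy2,
               method = ibd$method, error_prior = ibd$error_prior,
               multivalents = ibd$multivalents,
               individuals = ibd$individuals,
               linkage_groups = names(ibd$lg))
  jsonlite::write_json(meta, file.path(dir, "ibd_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read IBD probabilities from a directory written by \code{write_ibd}
#'
#' Restores the per-position homologue probabilities, and (when present)
#' double-reduction tracks and valency posteriors, using the metadata
#' sidecar. Valency posteriors are re-attached to the deterministic valency
#' enumeration order of \code{\link{enumerate_valencies}}.
#'
#' @param dir directory produced by \code{\link{write_ibd}}.
#' @return An \code{\link{ibd_probs}}.
#' @export
read_ibd <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "ibd_metadata.json"),
                              simplifyVector = TRUE)
  hn <- homologue_names(meta$ploidy1, meta$ploidy2)
  inds <- meta$individuals
  lg <- list()
  for (nm in meta$linkage_groups) {
    tab <- .read_table(file.path(dir, paste0("ibd_LG", nm, ".tsv")))
    pos <- sort(unique(tab$position))
    np <- length(pos)
    ni <- length(inds)
    X <- array(0, dim = c(np, ni, length(hn)))
    pi_ <- match(tab$position, pos)
    ii <- match(tab$individual, inds)
    for (h in seq_along(hn)) X[cbind(pi_, ii, h)] <- tab[[hn[h]]]
    mk <- tab$marker[match(pos, tab$position)]
    if (all(is.na(mk))) mk <- NULL
    l <- list(positions = pos, marker = mk, X = X, dr = NULL,
              val_post = NULL)
    drf <- file.path(dir, paste0("dr_LG", nm, ".tsv"))
    if (file.exists(drf)) {
      dtab <- .read_table(drf)
      dr <- array(0, dim = c(np, ni, 2))
      pi2 <- match(dtab$position, pos)
      ii2 <- match(dtab$individual, inds)
      dr[cbind(pi2, ii2, 1L)] <- dtab$dr_p1
      dr[cbind(pi2, ii2, 2L)] <- dtab$dr_p2
      l$dr <- dr
    }
    vpf <- file.path(dir, paste0("valency_posterior_LG", nm, ".tsv"))
    if (file.exists(vpf)) {
      vtab <- .read_table(vpf)
      vp <- list()
      for (parent in 1:2) {
        p <- if (parent == 1L) meta$ploidy1 else meta$ploidy2
        vals <- enumerate_valencies(p, isTRUE(meta$multivalents))
        sub <- vtab[vtab$parent == parent, ]
        M <- matrix(0, ni, length(vals))
        M[cbind(match(sub$individual, inds), sub$valency)] <- sub$posterior
        attr(M, "valencies") <- vals
        rownames(M) <- inds
        vp[[c("p1", "p2")[parent]]] <- M
      }
      l$val_post <- vp
    }
    lg[[as.character(nm)]] <- l
  }
  ibd_probs(lg, inds, meta$ploidy1, meta$ploidy2, method = meta$method,
            error_prior = if (is.null(meta$error_prior)) NA_real_ else
              meta$error_prior,
            multivalents = isTRUE(meta$multivalents))
}

#' Interpolate IBD probabilities onto a regular cM grid
#'
#' Each homologue track of each individual is interpolated by a natural
#' cubic spline through the per-marker estimates, evaluated on the grid
#' \code{0, spacing, 2*spacing, ..., LG length}. Spline overshoot is clipped
#' to the valid range and each parent's block is renormalised so the
#' expected inheritance counts again sum to half that parent's ploidy.
#' Linkage groups with fewer than two estimated positions are copied
#' through unchanged.
#'
#' @param ibd an \code{ibd_probs}.
#' @param spacing grid spacing in cM (default 1).
#' @return An \code{ibd_probs} on the grid (double-reduction tracks and
#'   valency posteriors, which are positionless or per-LG, are carried
#'   over; DR tracks are interpolated the same way and clipped to [0, 1]).
#' @export
interpolate_ibd <- function(ibd, spacing = 1) {
  stopifnot(inherits(ibd, "ibd_probs"))
  if (spacing <= 0) stop("spacing must be > 0")
  xmax <- if (ibd$multivalents) 2 else 1
  for (nm in names(ibd$lg)) {
    l <- ibd$lg[[nm]]
    np <- length(l$positions)
    if (np < 2L) next
    grid <- seq(0, max(l$positions), by = spacing)
    ni <- dim(l$X)[2]
    nh <- dim(l$X)[3]
    Xg <- array(0, dim = c(length(grid), ni, nh))
    for (i in seq_len(ni)) {
      for (h in seq_len(nh)) {
        y <- l$X[, i, h]
        if (all(y == y[1])) {
          Xg[, i, h] <- y[1]
        } else {
          Xg[, i, h] <- stats::spline(l$positions, y, xout = grid,
                                      method = "natural", ties = mean)$y
        }
      }
    }
    Xg[Xg < 0] <- 0
    Xg[Xg > xmax] <- xmax
    Xg <- .renorm_parents(Xg, ibd$ploidy1, ibd$ploidy2)
    l$X <- Xg
    if (!is.null(l$dr)) {
      drg <- array(0, dim = c(length(grid), ni, 2))
      for (i in seq_len(ni)) {
        for (k in 1:2) {
          y <- l$dr[, i, k]
          drg[, i, k] <- if (all(y == y[1])) y[1] else {
            stats::spline(l$positions, y, xout = grid,
                          method = "natural", ties = mean)$y
          }
        }
      }
      drg[drg < 0] <- 0
      drg[drg > 1] <- 1
      l$dr <- drg
    }
    l$positions <- grid
    l$marker <- NULL
    ibd$lg[[nm]] <- l
  }
  ibd
}

# Rescale each parent's homologue block so rows sum to ploidy/2.
.renorm_parents <- function(X, ploidy1, ploidy2) {
  m_idx <- seq_len(ploidy1)
  p_idx <- ploidy1 + seq_len(ploidy2)
  sm <- apply(X[, , m_idx, drop = FALSE], c(1, 2), sum)
  sp <- apply(X[, , p_idx, drop = FALSE], c(1, 2), sum)
  sm[sm <= 0] <- 1
  sp[sp <= 0] <- 1
  for (h in m_idx) X[, , h] <- X[, , h] * (ploidy1 / 2) / sm
  for (h in p_idx) X[, , h] <- X[, , h] * (ploidy2 / 2) / sp
  X
}
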