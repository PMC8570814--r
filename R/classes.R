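#' Construct a phased linkage map
#'
#' A phased linkage map assigns every marker to a linkage group and cM
#' position, and records the parental phase: which parental homologues carry
#' the alternative (dosage-counted) allele. Homologues \code{1..ploidy1}
#' belong to parent 1 (maternal), homologues
#' \code{ploidy1+1..ploidy1+ploidy2} to parent 2 (paternal). For display,
#' homologues are labelled with consecutive letters (A, B, ... for parent 1,
#' continuing for parent 2).
#'
#' @param marker character vector of unique marker names.
#' @param linkage_group integer vector (>= 1) of linkage-group assignments.
#' @param position numeric vector of cM positions (>= 0).
#' @param phase binary matrix with one row per marker and
#'   \code{ploidy1 + ploidy2} columns; entry \code{[m, h]} is 1 if homologue
#'   \code{h} carries the alternative allele at marker \code{m}.
#' @param ploidy1,ploidy2 parental ploidies.
#' @return An object of class \code{phased_map}: a list with elements
#'   \code{marker}, \code{linkage_group}, \code{position}, \code{phase},
#'   \code{ploidy1}, \code{ploidy2}. Rows are sorted by
#'   (linkage group, position), ties kept in input order.
#' @examples
#' ph <- rbind(c(1, 0, 0, 0, 0, 0, 0, 0), c(0, 1, 1, 0, 0, 0, 1, 1))
#' phased_map(c("m1", "m2"), c(1, 1), c(0, 10), ph, 4, 4)
#' @export
phased_map <- function(marker, linkage_group, position, phase,
                       ploidy1, ploidy2) {
  marker <- as.character(marker)
  linkage_group <- as.integer(linkage_group)
  position <- as.numeric(position)
  phase <- as.matrix(phase)
  n <- length(marker)
  if (n == 0L) stop("no markers")
  if (length(linkage_group) != n || length(position) != n ||
      nrow(phase) != n) {
    stop("marker, linkage_group, position and phase must agree in length")
  }
  if (anyDuplicated(marker)) {
    stop("duplicate marker name(s): ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  }
  if (ncol(phase) != ploidy1 + ploidy2) {
    stop("phase must have ploidy1 + ploidy2 = ", ploidy1 + ploidy2,
         " columns, found ", ncol(phase))
  }
  bad <- which(!(phase %in% c(0, 1)), arr.ind = TRUE)
  if (length(bad)) {
    stop("non-binary phase entry at marker '", marker[bad[1L]], "'")
  }
  if (any(linkage_group < 1L) || any(position < 0)) {
    stop("linkage groups must be >= 1 and positions >= 0")
  }
  ord <- order(linkage_group, position)
  storage.mode(phase) <- "double"
  colnames(phase) <- homologue_names(ploidy1, ploidy2)
  obj <- list(marker = marker[ord], linkage_group = linkage_group[ord],
              position = position[ord], phase = phase[ord, , drop = FALSE],
              ploidy1 = as.integer(ploidy1), ploidy2 = as.integer(ploidy2))
  class(obj) <- "phased_map"
  obj
}

#' Display labels for parental homologues
#'
#' @param ploidy1,ploidy2 parental ploidies.
#' @return Character vector of length \code{ploidy1 + ploidy2}: letters
#'   A.. for parent 1 continuing for parent 2 (e.g. A-F maternal, G-L
#'   paternal for a hexaploid cross).
#' @export
homologue_names <- function(ploidy1, ploidy2) {
  LETTERS[seq_len(ploidy1 + ploidy2)]
}

#' @export
print.phased_map <- function(x, ...) {
  cat("Phased linkage map:", length(x$marker), "markers,",
      length(unique(x$linkage_group)), "linkage group(s), parental ploidies",
      x$ploidy1, "x", x$ploidy2, "\n")
  invisible(x)
}

#' Parental dosages implied by the phase
#'
#' @param map a \code{phased_map}.
#' @return Two-column matrix (parent 1, parent 2) of marker dosages.
#' @export
parental_dosage <- function(map) {
  stopifnot(inherits(map, "phased_map"))
  cbind(p1 = rowSums(map$phase[, seq_len(map$ploidy1), drop = FALSE]),
        p2 = rowSums(map$phase[, map$ploidy1 + seq_len(map$ploidy2),
                               drop = FALSE]))
}

#' Construct offspring dosage data
#'
#' Holds SNP dosages of an F1 population, either as discrete allele counts
#' (0..ploidy, NA for missing) or as probabilistic calls: a simplex over the
#' dosage classes 0..ploidy per individual and marker.
#'
#' @param values for \code{type = "discrete"}, an individuals x markers
#'   matrix of integer dosages (NA allowed); for \code{type = "prob"}, a
#'   3-d array individuals x markers x (ploidy + 1) of class probabilities.
#' @param ploidy offspring ploidy.
#' @param type \code{"discrete"} or \code{"prob"}.
#' @return Object of class \code{dosage_data} with elements
#'   \code{individuals}, \code{markers}, \code{values}, \code{ploidy},
#'   \code{type}.
#' @export
dosage_data <- function(values, ploidy, type = c("discrete", "prob")) {
  type <- match.arg(type)
  ploidy <- as.integer(ploidy)
  if (type == "discrete") {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    rng <- range(values, na.rm = TRUE)
    if (!all(is.na(values)) && (rng[1] < 0 || rng[2] > ploidy)) {
      stop("dosage outside 0..", ploidy)
    }
    if (any(values[!is.na(values)] != round(values[!is.na(values)]))) {
      stop("discrete dosages must be integers")
    }
    individuals <- rownames(values)
    markers <- colnames(values)
  } else {
    if (length(dim(values)) != 3L || dim(values)[3] != ploidy + 1L) {
      stop("probabilistic values must be individuals x markers x (ploidy+1)")
    }
    s <- apply(values, c(1, 2), sum)
    if (any(abs(s - 1) > 1e-6, na.rm = TRUE)) {
      stop("dosage-class probabilities must sum to 1 (tolerance 1e-6)")
    }
    individuals <- dimnames(values)[[1]]
    markers <- dimnames(values)[[2]]
  }
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(dim(values)[1]))
  if (is.null(markers)) markers <- paste0("mk", seq_len(dim(values)[2]))
  obj <- list(individuals = individuals, markers = markers, values = values,
              ploidy = ploidy, type = type)
  class(obj) <- "dosage_data"
  obj
}

#' @export
print.dosage_data <- function(x, ...) {
  cat("Dosage data (", x$type, "): ", length(x$individuals),
      " individuals x ", length(x$markers), " markers, offspring ploidy ",
      x$ploidy, "\n", sep = "")
  invisible(x)
}

#' Align dosage data to a phased map
#'
#' Subsets and reorders markers of a \code{dosage_data} object to match the
#' marker order of a map. Markers on the map but absent from the dosage data
#' are an error.
#'
#' @param dosages a \code{dosage_data}.
#' @param map a \code{phased_map}.
#' @return A \code{dosage_data} whose marker order equals \code{map$marker}.
#' @export
align_dosages <- function(dosages, map) {
  stopifnot(inherits(dosages, "dosage_data"), inherits(map, "phased_map"))
  idx <- match(map$marker, dosages$markers)
  if (anyNA(idx)) {
    stop("markers on the map but missing from the dosage data: ",
         paste(utils::head(map$marker[is.na(idx)], 5L), collapse = ", "))
  }
  if (dosages$type == "discrete") {
    dosages$values <- dosages$values[, idx, drop = FALSE]
  } else {
    dosages$values <- dosages$values[, idx, , drop = FALSE]
  }
  dosages$markers <- map$marker
  dosages
}

#' Convert discrete dosage calls to one-hot probabilistic calls
#'
#' @param dosages a discrete \code{dosage_data}.
#' @return The same data as a probabilistic \code{dosage_data}, with each
#'   observed call given probability 1 and missing calls all-NA (treated as
#'   uninformative downstream).
#' @export
as_probabilistic <- function(dosages) {
  stopifnot(inherits(dosages, "dosage_data"))
  if (dosages$type == "prob") return(dosages)
  p <- dosages$ploidy
  n_i <- length(dosages$individuals)
  n_m <- length(dosages$markers)
  arr <- array(NA_real_, dim = c(n_i, n_m, p + 1L),
               dimnames = list(dosages$individuals, dosages$markers, NULL))
  for (d in 0:p) {
    slice <- ifelse(is.na(dosages$values), NA_real_,
                    as.numeric(dosages$values == d))
    arr[, , d + 1L] <- slice
  }
  out <- dosage_data(arr, p, type = "prob")
  out
}

#' Construct an IBD probability object
#'
#' Container for estimated identity-by-descent probabilities: for each
#' linkage group, an array of expected inheritance counts of every parental
#' homologue per position and individual, optionally with valency posteriors
#' and per-position double-reduction probabilities (HMM method only).
#'
#' @param lg named list, one element per linkage group, each a list with
#'   \code{positions} (cM), \code{marker} (marker names or NA on a grid),
#'   \code{X} (array positions x individuals x homologues),
#'   \code{dr} (optional array positions x individuals x 2: per-parent
#'   double-reduction posterior), \code{val_post} (optional list with
#'   matrices \code{p1}, \code{p2}: individuals x valencies, with the
#'   valency list stored as attribute \code{"valencies"}).
#' @param individuals individual IDs.
#' @param ploidy1,ploidy2 parental ploidies.
#' @param method \code{"hmm"} or \code{"heuristic"}.
#' @param error_prior genotyping error prior used in estimation.
#' @param multivalents logical; were multivalent pairings modelled?
#' @return Object of class \code{ibd_probs}.
#' @export
ibd_probs <- function(lg, individuals, ploidy1, ploidy2, method,
                      error_prior = NA_real_, multivalents = FALSE) {
  stopifnot(is.list(lg), length(lg) > 0L)
  obj <- list(lg = lg, individuals = individuals,
              ploidy1 = as.integer(ploidy1), ploidy2 = as.integer(ploidy2),
              method = method, error_prior = error_prior,
              multivalents = multivalents)
  class(obj) <- "ibd_probs"
  obj
}

#' @export
print.ibd_probs <- function(x, ...) {
  np <- vapply(x$lg, function(l) length(l$positions), integer(1))
  cat("IBD probabilities (", x$method, "): ", length(x$individuals),
      " individuals, ", length(x$lg), " linkage group(s), ",
      sum(np), " positions total, ploidies ", x$ploidy1, "x", x$ploidy2,
      if (x$multivalents) ", multivalents modelled" else "", "\n", sep = "")
  invisible(x)
}

# Indices of maternal / paternal homologue columns in X
.mat_idx <- function(ibd) seq_len(ibd$ploidy1)
.pat_idx <- function(ibd) ibd$ploidy1 + seq_len(ibd$ploidy2)

#' Validate IBD sum invariants
#'
#' At every position and for every individual the expected maternal
#' inheritance counts must sum to ploidy1/2 and the paternal counts to
#' ploidy2/2 (each parent contributes half its chromosomes to a gamete).
#'
#' @param ibd an \code{ibd_probs}.
#' @param tol numeric tolerance.
#' @return TRUE invisibly, or an error describing the violated invariant.
#' @export
validate_ibd <- function(ibd, tol = 1e-6) {
  stopifnot(inherits(ibd, "ibd_probs"))
  for (nm in names(ibd$lg)) {
    X <- ibd$lg[[nm]]$X
    if (min(X) < -tol || max(X) > 2 + tol) {
      stop("X outside [0, 2] on linkage group ", nm)
    }
    sm <- apply(X[, , .mat_idx(ibd), drop = FALSE], c(1, 2), sum)
    sp <- apply(X[, , .pat_idx(ibd), drop = FALSE], c(1, 2), sum)
    if (max(abs(sm - ibd$ploidy1 / 2)) > tol) {
      stop("maternal IBD sums deviate from ploidy1/2 on LG ", nm)
    }
    if (max(abs(sp - ibd$ploidy2 / 2)) > tol) {
      stop("paternal IBD sums deviate from ploidy2/2 on LG ", nm)
    }
  }
  invisible(TRUE)
}
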