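#' Conformer ensemble
#'
#' A set of conformers with per-conformer populations summing to 1.
#' Each conformer is a list with fields `xyz` (n_atoms x 3 matrix, Angstrom),
#' `atom` (atom names, e.g. "N","CA","C","O"), `resno` (construct residue
#' numbers per atom) and optionally `sequence` and `anchor_id`.
#'
#' @param conformers List of conformer lists.
#' @param populations Nonnegative weights; default uniform. Normalized to
#'   unit sum.
#' @param provenance Optional list of run metadata (seed, restraint set id,
#'   fit diagnostics).
#' @return Object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(conformers, populations = NULL,
                               provenance = list()) {
  if (length(conformers) == 0L) stop("ensemble must contain conformers")
  if (is.null(populations)) {
    populations <- rep(1 / length(conformers), length(conformers))
  }
  if (length(populations) != length(conformers)) {
    stop("populations and conformers lengths differ")
  }
  if (any(populations < 0)) stop("populations must be nonnegative")
  s <- sum(populations)
  if (s <= 0) stop("populations sum to zero")
  structure(list(conformers = conformers, populations = populations / s,
                 provenance = provenance),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  n <- length(x$conformers)
  cat(sprintf("<conformer_ensemble> %d conformers, %d atoms each\n",
              n, nrow(x$conformers[[1]]$xyz)))
  cat(sprintf("  max population %.4f, effective size %.1f\n",
              max(x$populations), 1 / sum(x$populations^2)))
  invisible(x)
}

#' Number of conformers in an ensemble
#' @param ensemble A `conformer_ensemble`.
#' @return Integer count.
#' @export
n_conformers <- function(ensemble) length(ensemble$conformers)

#' CA coordinates of an ensemble as an array
#'
#' @param ensemble A `conformer_ensemble`.
#' @param residue_range Optional integer vector of construct residue numbers
#'   to retain (e.g. `188:320`).
#' @return Array of dimension `n_conf x n_res x 3`.
#' @export
ca_array <- function(ensemble, residue_range = NULL) {
  c1 <- ensemble$conformers[[1]]
  sel <- which(c1$atom == "CA")
  if (!is.null(residue_range)) {
    sel <- sel[c1$resno[sel] %in% residue_range]
  }
  if (length(sel) == 0L) stop("no CA atoms in the requested range")
  n_conf <- n_conformers(ensemble)
  out <- array(NA_real_, c(n_conf, length(sel), 3))
  for (i in seq_len(n_conf)) {
    out[i, , ] <- ensemble$conformers[[i]]$xyz[sel, , drop = FALSE]
  }
  attr(out, "resno") <- c1$resno[sel]
  out
}

#' Subset an ensemble by conformer index
#'
#' @param ensemble A `conformer_ensemble`.
#' @param idx Integer indices of conformers to keep.
#' @param renormalize Rescale retained populations to unit sum (default).
#' @return A `conformer_ensemble`.
#' @export
subset_ensemble <- function(ensemble, idx, renormalize = TRUE) {
  if (length(idx) == 0L) stop("cannot create an empty ensemble")
  p <- ensemble$populations[idx]
  if (renormalize) p <- p / sum(p)
  conformer_ensemble(ensemble$conformers[idx], p, ensemble$provenance)
}
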