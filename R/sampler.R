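#' Gaussian distance restraint between two labeled sites
#'
#' @param site_i,site_j Residue indices (1-based construct numbering).
#' @param mean Mean label-label distance (Angstrom).
#' @param sigma Standard deviation of the Gaussian restraint (Angstrom).
#' @param dist Optional full experimental `distance_distribution` used in
#'   ensemble fitting (sampling uses only the Gaussian summary).
#' @return Object of class `gaussian_restraint`.
#' @export
gaussian_restraint <- function(site_i, site_j, mean, sigma, dist = NULL) {
  if (site_i == site_j) stop("restraint sites must differ")
  if (sigma <= 0) stop("sigma must be positive")
  if (!is.null(dist)) stopifnot(inherits(dist, "distance_distribution"))
  structure(list(site_i = as.integer(site_i), site_j = as.integer(site_j),
                 mean = unname(mean), sigma = unname(sigma), dist = dist),
            class = "gaussian_restraint")
}

#' Consistency score of a distance with a Gaussian restraint
#'
#' Max-normalized Gaussian score `p = exp(-(d - <r>)^2 / (2 s^2))` with
#' softened width `s = sqrt(2) sigma_r`, equal to 1 at the restraint mean.
#' During chain growth the running product of these scores over all
#' evaluated restraints must stay at or above the acceptance threshold
#' (default 0.75) or the conformer is discarded.
#'
#' @param distance Label-label distance (Angstrom), nonnegative.
#' @param restraint A `gaussian_restraint`.
#' @return Score in (0, 1].
#' @export
restraint_probability <- function(distance, restraint) {
  stopifnot(inherits(restraint, "gaussian_restraint"))
  s <- sqrt(2) * restraint$sigma
  exp(-(distance - restraint$mean)^2 / (2 * s^2))
}

.restraint_matrix <- function(restraints) {
  if (length(restraints) == 0L) {
    return(matrix(numeric(0), 0, 4))
  }
  t(vapply(restraints, function(r) {
    c(r$site_i, r$site_j, r$mean, sqrt(2) * r$sigma)
  }, numeric(4)))
}

.anchor_prep <- function(anchor, restraints, label_params) {
  if (is.null(anchor)) {
    return(list(frame = matrix(numeric(0), 0, 3),
                ca = matrix(numeric(0), 0, 3),
                labels = matrix(numeric(0), 0, 4), offset = 0L))
  }
  resno_ca <- anchor$resno[anchor$atom == "CA"]
  offset <- max(resno_ca)
  last <- which(anchor$resno == offset & anchor$atom %in% c("N", "CA", "C"))
  frame <- anchor$xyz[last[match(c("N", "CA", "C"), anchor$atom[last])], ,
                      drop = FALSE]
  if (nrow(frame) != 3 || any(is.na(frame))) {
    stop("anchor is missing N/CA/C of its last residue")
  }
  ca <- anchor$xyz[anchor$atom == "CA", , drop = FALSE]
  sites <- unique(unlist(lapply(restraints, function(r) c(r$site_i, r$site_j))))
  sites <- sites[sites <= offset]
  labels <- matrix(numeric(0), 0, 4)
  for (s in sites) {
    pos <- predict_label_position(anchor, s, params = label_params)
    labels <- rbind(labels, c(s, pos))
  }
  list(frame = frame, ca = ca, labels = labels, offset = as.integer(offset))
}

.assemble_conformers <- function(res, sequence, anchor, offset, anchor_id) {
  n_res <- nchar(sequence)
  aa <- strsplit(sequence, "")[[1]]
  atom <- rep(c("N", "CA", "C", "O"), n_res)
  resno <- rep(offset + seq_len(n_res), each = 4)
  resid <- rep(aa, each = 4)
  out <- list()
  for (i in which(res$success)) {
    xyz <- t(res$coords[, , i])
    if (!is.null(anchor)) {
      xyz <- rbind(anchor$xyz, xyz)
      conf <- list(xyz = xyz, atom = c(anchor$atom, atom),
                   resno = c(anchor$resno, resno),
                   resid = c(anchor$resid %||% rep("ALA", nrow(anchor$xyz)),
                             resid),
                   anchor_id = anchor_id)
    } else {
      conf <- list(xyz = xyz, atom = atom, resno = resno, resid = resid,
                   anchor_id = anchor_id)
    }
    conf$sequence <- sequence
    out[[length(out) + 1L]] <- conf
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a single restrained backbone conformer
#'
#' Grows the chain residue by residue, sampling (phi, psi) from the coil
#' library with ideal bond geometry and trans peptide bonds. After each
#' placement, any restraint whose two sites both have coordinates is scored
#' at surrogate label positions; the running product of scores must stay at
#' or above `threshold`. CA clashes (closer than `clash_ca` for sequence
#' separation >= 3, or `clash_anchor` against anchor CA atoms) also abort
#' the attempt.
#'
#' @param sequence One-letter amino-acid string for the flexible segment.
#' @param library A `ramachandran_library`.
#' @param restraints List of `gaussian_restraint` objects (construct
#'   numbering), or `NULL`.
#' @param anchor Optional folded-domain model: list with `xyz`, `atom`,
#'   `resno` (the chain is grown from the C terminus of its last residue).
#' @param threshold Acceptance threshold on the score product (default 0.75).
#' @param label_params `label_surrogate_params` used for restraint scoring.
#' @param clash_ca,clash_anchor Clash cutoffs (Angstrom).
#' @param max_attempts Restart budget before reporting failure.
#' @return A conformer list, or an object of class `sampling_failure` with
#'   the attempt count.
#' @export
sample_chain <- function(sequence, library = ramachandran_library(),
                         restraints = NULL, anchor = NULL, threshold = 0.75,
                         label_params = label_surrogate_params(),
                         clash_ca = 4.0, clash_anchor = 3.5,
                         max_attempts = 500) {
  ens <- .sample_block(1L, sequence, library, restraints, anchor, threshold,
                       label_params, clash_ca, clash_anchor, max_attempts,
                       anchor_id = 1L)
  if (length(ens$conformers) == 0L) {
    return(structure(list(attempts = ens$attempts,
                          message = "no conformer within the restart budget"),
                     class = "sampling_failure"))
  }
  ens$conformers[[1]]
}

.sample_block <- function(n_conf, sequence, library, restraints, anchor,
                          threshold, label_params, clash_ca, clash_anchor,
                          max_attempts, anchor_id) {
  stopifnot(inherits(library, "ramachandran_library"))
  cls <- match(.residue_class(sequence), library$classes) - 1L
  rmat <- .restraint_matrix(restraints)
  ap <- .anchor_prep(anchor, restraints, label_params)
  n_res <- nchar(sequence)
  if (nrow(rmat) > 0) {
    flex_max <- ap$offset + n_res
    bad <- rmat[, 1] > flex_max | rmat[, 2] > flex_max |
      rmat[, 1] < 1 | rmat[, 2] < 1
    if (any(bad)) stop("restraint sites outside the modeled construct")
  }
  res <- cpp_build_conformers(
    n_conf = as.integer(n_conf), n_res = n_res, cls = cls,
    cdf = library$cdf, n_bins = library$n_bins,
    bin_width = library$bin_width, restraints = rmat,
    threshold = threshold, label_offset = label_params$radial_offset,
    anchor_frame = ap$frame, anchor_ca = ap$ca, anchor_labels = ap$labels,
    res_offset = ap$offset, clash_ca = clash_ca,
    clash_anchor = clash_anchor, max_attempts = as.integer(max_attempts))
  list(conformers = .assemble_conformers(res, sequence, anchor, ap$offset,
                                         anchor_id),
       attempts = sum(res$attempts), n_failed = sum(!res$success))
}

#' Build a raw conformer ensemble
#'
#' Generates `n_target` conformers with uniform initial populations,
#' distributing them round-robin across the supplied anchor models (e.g.
#' the models of an NMR structure). Acceptance statistics are recorded in
#' the ensemble provenance.
#'
#' @inheritParams sample_chain
#' @param anchor_models List of anchor models (each with `xyz`, `atom`,
#'   `resno`), or `NULL` for free chains.
#' @param n_target Number of conformers to generate (> 0).
#' @param rng_seed Seed for the Monte-Carlo stream; the same seed and inputs
#'   reproduce the ensemble exactly.
#' @return A `conformer_ensemble` with uniform populations. If some
#'   conformers could not be generated within the budget, the ensemble is
#'   smaller than `n_target` and provenance records the failures.
#' @export
build_raw_ensemble <- function(sequence, library = ramachandran_library(),
                               restraints = NULL, anchor_models = NULL,
                               n_target = 100, rng_seed = 1,
                               threshold = 0.75,
                               label_params = label_surrogate_params(),
                               clash_ca = 4.0, clash_anchor = 3.5,
                               max_attempts = 500) {
  if (n_target < 1) stop("n_target must be positive")
  set.seed(rng_seed)
  if (is.null(anchor_models)) anchor_models <- list(NULL)
  n_anchor <- length(anchor_models)
  per_anchor <- diff(round(seq(0, n_target, length.out = n_anchor + 1)))
  conformers <- list()
  attempts <- 0L
  failed <- 0L
  for (a in seq_len(n_anchor)) {
    if (per_anchor[a] == 0) next
    blk <- .sample_block(per_anchor[a], sequence, library, restraints,
                         anchor_models[[a]], threshold, label_params,
                         clash_ca, clash_anchor, max_attempts, anchor_id = a)
    conformers <- c(conformers, blk$conformers)
    attempts <- attempts + blk$attempts
    failed <- failed + blk$n_failed
  }
  if (length(conformers) == 0L) {
    stop("sampling failure: no conformer satisfied the restraints within ",
         "the restart budget (", attempts, " attempts)")
  }
  if (failed > 0) {
    warning(failed, " of ", n_target, " conformers could not be generated ",
            "within the restart budget")
  }
  conformer_ensemble(
    conformers,
    provenance = list(seed = rng_seed, n_target = n_target,
                      attempts = attempts, n_failed = failed,
                      acceptance_rate = length(conformers) / attempts,
                      threshold = threshold))
}
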