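#' Segment-wise RMS CA-CA distances
#'
#' For every residue pair (i, j) with i < j in the analyzed range, the
#' population-weighted RMS distance `sqrt(sum_c p_c d_c^2)` over conformers,
#' with the pair assigned to segment length `k = j - i`.
#'
#' @param ensemble A `conformer_ensemble` with normalized populations.
#' @param residue_range Integer vector of construct residue numbers
#'   (default: all modeled residues).
#' @return Object of class `segment_rms`: list with `rms_matrix`
#'   (n_res x n_res, Angstrom), `resno`, and a data frame `pairs` with
#'   columns `i`, `j`, `k`, `rms`.
#' @export
segment_rms <- function(ensemble, residue_range = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  ca <- ca_array(ensemble, residue_range)
  resno <- attr(ca, "resno")
  n_res <- dim(ca)[2]
  if (n_res < 2) stop("residue range must span at least 2 residues")
  p <- ensemble$populations
  acc <- matrix(0, n_res, n_res)
  for (c in seq_len(dim(ca)[1])) {
    xyz <- ca[c, , ]
    sq <- rowSums(xyz^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(xyz)
    acc <- acc + p[c] * pmax(d2, 0)
  }
  rms <- sqrt(acc)
  iu <- which(upper.tri(rms), arr.ind = TRUE)
  pairs <- data.frame(i = resno[iu[, 1]], j = resno[iu[, 2]],
                      k = iu[, 2] - iu[, 1], rms = rms[iu])
  structure(list(rms_matrix = rms, resno = resno, pairs = pairs),
            class = "segment_rms")
}

#' Power-law fit of segment RMS distances
#'
#' Least-squares fit of `R_k = b * k^nu` to all (k, RMS) pairs (every pair
#' enters as one point, in linear space). A log-log regression provides the
#' starting values.
#'
#' @param sr A `segment_rms` object.
#' @param weighting `"pairs"` (default; every pair one point) or `"k_means"`
#'   (fit to per-k mean RMS values).
#' @return Object of class `scaling_fit` with `b` (Angstrom), `nu`,
#'   `k_means` (per-k mean RMS), `residuals` and `rmsd`.
#' @export
fit_scaling_law <- function(sr, weighting = c("pairs", "k_means")) {
  stopifnot(inherits(sr, "segment_rms"))
  weighting <- match.arg(weighting)
  pr <- sr$pairs
  if (length(unique(pr$k)) < 3) stop("need at least 3 distinct segment lengths")
  if (stats::sd(pr$rms) < 1e-12) {
    stop("degenerate input: all segment distances equal; nu is undefined")
  }
  if (weighting == "k_means") {
    agg <- stats::aggregate(rms ~ k, pr, mean)
    kk <- agg$k; rr <- agg$rms
  } else {
    kk <- pr$k; rr <- pr$rms
  }
  lf <- stats::lm(log(rr) ~ log(kk))
  start <- c(b = exp(unname(stats::coef(lf)[1])),
             nu = unname(stats::coef(lf)[2]))
  fit <- minpack.lm::nlsLM(rr ~ b * kk^nu, start = as.list(start),
                           lower = c(1e-3, 0.01), upper = c(100, 2),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  res <- rr - cf["b"] * kk^cf["nu"]
  k_means <- stats::aggregate(rms ~ k, pr, mean)
  structure(list(b = unname(cf["b"]), nu = unname(cf["nu"]),
                 k_means = k_means, residuals = res,
                 rmsd = sqrt(mean(res^2)), weighting = weighting),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> R_k = %.3f * k^%.3f A (rmsd %.2f A)\n",
              x$b, x$nu, x$rmsd))
  invisible(x)
}

#' Segment-length deviation matrix
#'
#' `DeltaL_ij = RMS(i, j) - mean over all pairs with the same k = j - i`.
#' Negative entries mark segments more compact than average at their length
#' (conventionally drawn blue), positive entries more extended (red). By
#' construction the entries at each k sum to zero. With
#' `normalized = TRUE` each entry is divided by the per-k mean, giving the
#' relative (proximity-matrix-style) variant.
#'
#' @inheritParams segment_rms
#' @param normalized Divide deviations by the per-k mean RMS (default off).
#' @return Object of class `deviation_matrix`: `delta` (symmetric matrix
#'   with zero diagonal, Angstrom), `resno`, `k_means`.
#' @export
deviation_matrix <- function(ensemble, residue_range = NULL,
                             normalized = FALSE) {
  sr <- segment_rms(ensemble, residue_range)
  pr <- sr$pairs
  mk <- tapply(pr$rms, pr$k, mean)
  dev <- pr$rms - mk[as.character(pr$k)]
  if (normalized) dev <- dev / mk[as.character(pr$k)]
  n <- length(sr$resno)
  delta <- matrix(0, n, n)
  iu <- which(upper.tri(delta), arr.ind = TRUE)
  delta[iu] <- dev
  delta[cbind(iu[, 2], iu[, 1])] <- dev
  structure(list(delta = delta, resno = sr$resno,
                 k_means = data.frame(k = as.integer(names(mk)),
                                      rms = as.numeric(mk)),
                 normalized = normalized),
            class = "deviation_matrix")
}

# Kabsch superposition: minimum RMSD of y onto x (both n x 3)
.kabsch_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((xc - yc %*% R)^2)))
}

#' Ensemble width
#'
#' `Gamma = sqrt( sum_{i<j} p_i p_j D_ij^2 / sum_{i<j} p_i p_j )` where
#' `D_ij` is the CA RMSD between conformers i and j after optimal rigid
#' superposition (Kabsch). Invariant under rigid motion of any conformer.
#'
#' @param ensemble A `conformer_ensemble` (>= 2 conformers).
#' @param residue_range Optional residue subset.
#' @return Width in Angstrom; 0 (with a message) for a single conformer.
#' @export
ensemble_width <- function(ensemble, residue_range = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  n <- n_conformers(ensemble)
  if (n < 2) {
    message("single conformer: ensemble width is 0 by convention")
    return(0)
  }
  ca <- ca_array(ensemble, residue_range)
  p <- ensemble$populations
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    xi <- ca[i, , ]
    for (j in (i + 1):n) {
      w <- p[i] * p[j]
      if (w == 0) next
      num <- num + w * .kabsch_rmsd(xi, ca[j, , ])^2
      den <- den + w
    }
  }
  if (den == 0) return(0)
  sqrt(num / den)
}

#' Ensemble radius of gyration
#'
#' Population-weighted RMS of per-conformer CA radii of gyration,
#' `sqrt(sum_i p_i R_g,i^2)` (default), or their arithmetic mean.
#'
#' @inheritParams ensemble_width
#' @param combine `"rms"` (default) or `"mean"`.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(ensemble, residue_range = NULL,
                               combine = c("rms", "mean")) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  combine <- match.arg(combine)
  ca <- ca_array(ensemble, residue_range)
  p <- ensemble$populations
  rg <- vapply(seq_len(dim(ca)[1]), function(i) {
    xyz <- ca[i, , , drop = FALSE]
    dim(xyz) <- dim(ca)[2:3]
    ctr <- colMeans(xyz)
    sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
  }, numeric(1))
  if (combine == "rms") sqrt(sum(p * rg^2)) else sum(p * rg)
}
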