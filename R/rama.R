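# Residue classes used by the coil library. Exact residue-specific tables
# can be plugged in via ramachandran_library(densities = ...).
.rama_classes <- c("generic", "gly", "pro", "prepro", "branched")

.residue_class <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (!all(aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])) {
    stop("sequence contains non-standard residue codes")
  }
  n <- length(aa)
  cls <- rep("generic", n)
  cls[aa %in% c("I", "V", "T")] <- "branched"
  cls[aa == "G"] <- "gly"
  cls[aa == "P"] <- "pro"
  pre_pro <- which(aa == "P") - 1L
  pre_pro <- pre_pro[pre_pro >= 1L]
  cls[pre_pro[cls[pre_pro] %in% c("generic", "branched")]] <- "prepro"
  cls
}

# wrapped 2D Gaussian basin on a periodic (phi, psi) grid (degrees)
.basin_density <- function(phi_grid, psi_grid, mu, sd) {
  wrap <- function(x) (x + 180) %% 360 - 180
  dphi <- wrap(outer(phi_grid, rep(1, length(psi_grid))) - mu[1])
  dpsi <- wrap(outer(rep(1, length(phi_grid)), psi_grid) - mu[2])
  exp(-0.5 * ((dphi / sd[1])^2 + (dpsi / sd[2])^2))
}

# Coil (loop-region) basin parameterization per residue class: mixtures of
# wrapped Gaussians over the beta/PPII, alpha_R, alpha_L and bridge regions,
# with weights chosen to reproduce random-coil scaling of segment RMS
# end-to-end distances (nu ~ 0.57, b ~ 5.2 A) for low-complexity sequences.
.rama_basins <- function() {
  list(
    generic = list(
      list(w = 0.20, mu = c(-65, 145), sd = c(15, 20)),   # PPII
      list(w = 0.17, mu = c(-120, 135), sd = c(25, 25)),  # beta
      list(w = 0.50, mu = c(-63, -40), sd = c(12, 14)),   # alpha_R
      list(w = 0.08, mu = c(60, 45), sd = c(12, 14)),     # alpha_L
      list(w = 0.05, mu = c(-90, 0), sd = c(20, 20))      # bridge
    ),
    gly = list(
      list(w = 0.09, mu = c(-80, 165), sd = c(25, 25)),
      list(w = 0.09, mu = c(80, -165), sd = c(25, 25)),
      list(w = 0.28, mu = c(-63, -40), sd = c(14, 16)),
      list(w = 0.28, mu = c(63, 40), sd = c(14, 16)),
      list(w = 0.13, mu = c(-90, 0), sd = c(25, 25)),
      list(w = 0.13, mu = c(90, 0), sd = c(25, 25))
    ),
    pro = list(
      list(w = 0.60, mu = c(-63, 150), sd = c(10, 18)),   # PPII
      list(w = 0.40, mu = c(-63, -25), sd = c(10, 15))    # alpha-like
    ),
    prepro = list(
      list(w = 0.35, mu = c(-65, 140), sd = c(15, 20)),
      list(w = 0.30, mu = c(-120, 130), sd = c(25, 25)),
      list(w = 0.30, mu = c(-63, -35), sd = c(12, 14)),
      list(w = 0.05, mu = c(-90, 0), sd = c(20, 20))
    ),
    branched = list(
      list(w = 0.25, mu = c(-65, 140), sd = c(14, 20)),
      list(w = 0.30, mu = c(-115, 130), sd = c(22, 22)),
      list(w = 0.40, mu = c(-63, -40), sd = c(12, 14)),
      list(w = 0.05, mu = c(60, 45), sd = c(12, 14))
    )
  )
}

#' Ramachandran coil library
#'
#' Discretized joint (phi, psi) densities for loop/coil regions, binned at
#' `bin_width` degrees, for the residue classes generic, glycine, proline,
#' pre-proline and beta-branched (Ile/Val/Thr). Densities are built from
#' class-specific mixtures of wrapped Gaussian basins; a residue-specific
#' library can be substituted by passing `densities` (a named list of
#' matrices on the same grid).
#'
#' @param bin_width Bin width in degrees (default 10).
#' @param densities Optional plug-in named list of unnormalized density
#'   matrices (`n_bins x n_bins`, phi by psi), overriding the built-in
#'   basins for the named classes.
#' @return Object of class `ramachandran_library` with per-class normalized
#'   densities and sampling CDFs.
#' @export
ramachandran_library <- function(bin_width = 10, densities = NULL) {
  n_bins <- as.integer(360 / bin_width)
  centers <- -180 + (seq_len(n_bins) - 0.5) * bin_width
  basins <- .rama_basins()
  dens <- lapply(basins, function(bs) {
    d <- Reduce(`+`, lapply(bs, function(b) {
      b$w * .basin_density(centers, centers, b$mu, b$sd)
    }))
    d / sum(d)
  })
  if (!is.null(densities)) {
    for (nm in names(densities)) {
      m <- densities[[nm]]
      if (!all(dim(m) == n_bins)) stop("plug-in density has wrong bin count")
      if (any(m < 0)) stop("plug-in density has negative entries")
      dens[[nm]] <- m / sum(m)
    }
  }
  cdf <- t(vapply(dens, function(d) cumsum(as.numeric(t(d))),
                  numeric(n_bins * n_bins)))
  structure(list(densities = dens, cdf = cdf, classes = names(dens),
                 n_bins = n_bins, bin_width = bin_width),
            class = "ramachandran_library")
}

#' @export
print.ramachandran_library <- function(x, ...) {
  cat(sprintf("<ramachandran_library> %d classes, %d-degree bins\n",
              length(x$classes), x$bin_width))
  invisible(x)
}
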