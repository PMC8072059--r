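# Euclidean projection onto the probability simplex
.project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# per-conformer predicted densities for one restraint, as unit-sum columns
# on the restraint's experimental grid
.restraint_columns <- function(distances, r_axis, sigma_conv) {
  A <- vapply(distances, function(d) {
    col <- stats::dnorm(r_axis, d, sigma_conv)
    s <- sum(col)
    if (s <= 0) rep(0, length(r_axis)) else col / s
  }, numeric(length(r_axis)))
  matrix(A, nrow = length(r_axis))
}

#' Forward-modelled distribution of a restraint for an ensemble
#'
#' `P_pred = sum_i p_i P_i`, where `P_i` is conformer i's label-label
#' distribution for the restraint's site pair (unit-sum, broadened by the
#' label surrogate).
#'
#' @param ensemble A `conformer_ensemble`.
#' @param restraint A `gaussian_restraint`; its experimental grid is used
#'   when a full distribution is attached, otherwise `r_axis`.
#' @param r_axis Fallback distance grid (Angstrom).
#' @param label_params `label_surrogate_params`.
#' @return A `distance_distribution`.
#' @export
predict_restraint_distribution <- function(ensemble, restraint,
                                           r_axis = default_r_axis(),
                                           label_params =
                                             label_surrogate_params()) {
  stopifnot(inherits(ensemble, "conformer_ensemble"),
            inherits(restraint, "gaussian_restraint"))
  grid <- if (!is.null(restraint$dist)) restraint$dist$r_axis else r_axis
  d <- label_distances(ensemble, restraint$site_i, restraint$site_j,
                       label_params)
  A <- .restraint_columns(d, grid, sqrt(2) * label_params$sigma_label)
  distance_distribution(grid, as.numeric(A %*% ensemble$populations),
                        normalize = TRUE)
}

# exact objective: per-restraint overlaps and their geometric mean, with the
# log-domain floor applied inside the objective only
.fit_objective <- function(p, mats, floor = 1e-6) {
  o <- vapply(mats, function(m) sum(pmin(as.numeric(m$A %*% p), m$b)),
              numeric(1))
  list(overlaps = o, f = sum(log(pmax(o, floor))),
       gbar = if (any(o == 0)) 0 else exp(mean(log(o))))
}

.fit_gradient <- function(p, mats, floor = 1e-6) {
  g <- numeric(length(p))
  for (m in mats) {
    pred <- as.numeric(m$A %*% p)
    o <- max(sum(pmin(pred, m$b)), floor)
    active <- pred < m$b
    if (any(active)) {
      g <- g + colSums(m$A[active, , drop = FALSE]) / o
    }
  }
  g
}

# entropy of a population vector (0 log 0 = 0)
.pop_entropy <- function(p) -sum(ifelse(p > 0, p * log(p), 0))

# projected (super)gradient ascent with monotone line search on the exact
# objective f(p) = sum_m log o_m + entropy_weight * H(p)
.ascend <- function(p, mats, entropy_weight = 0, max_iter = 600,
                    tol = 1e-10) {
  # entropy_weight is relative to the mean log overlap, so its effect is
  # comparable across restraint counts
  w <- entropy_weight * length(mats)
  fval <- function(p) {
    .fit_objective(p, mats)$f + w * .pop_entropy(p)
  }
  gval <- function(p) {
    g <- .fit_gradient(p, mats)
    if (w > 0) {
      g <- g - w * (log(pmax(p, 1e-300)) + 1)
    }
    g
  }
  fcur <- fval(p)
  step <- 0.1
  stall <- 0L
  for (it in seq_len(max_iter)) {
    fprev <- fcur
    g <- gval(p)
    improved <- FALSE
    s <- step
    for (bt in 1:30) {
      cand <- .project_simplex(p + s * g / max(sqrt(sum(g^2)), 1e-12))
      fc <- fval(cand)
      if (fc > fcur + 1e-14) {
        p <- cand; fcur <- fc; step <- s * 1.3; improved <- TRUE
        break
      }
      s <- s / 2
    }
    if (!improved) {
      stall <- stall + 1L
      step <- max(step / 4, 1e-9)
      if (stall >= 4L) break
    } else {
      stall <- 0L
      if (it > 50 && fcur - fprev < tol) break
    }
  }
  p
}

# maximize sum_m log o_m over the simplex: nonnegative-least-squares
# initializer, projected supergradient ascent; with entropy_weight > 0 the
# pure optimum is refined toward the maximum-entropy solution in its
# near-optimal neighborhood (resolves population degeneracy toward the
# representative, densest reweighting)
.solve_populations <- function(mats, p0 = NULL, max_iter = 600,
                               tol = 1e-10, entropy_weight = 0) {
  n <- ncol(mats[[1]]$A)
  if (n == 1L) return(1)
  if (is.null(p0)) {
    A_all <- do.call(rbind, lapply(mats, function(m) m$A))
    b_all <- unlist(lapply(mats, function(m) m$b))
    p0 <- try(pracma::lsqnonneg(A_all, b_all)$x, silent = TRUE)
    if (inherits(p0, "try-error") || sum(p0) <= 0) p0 <- rep(1, n)
    p0 <- p0 / sum(p0)
    # mix with uniform so no conformer starts exactly at zero
    p0 <- 0.95 * p0 + 0.05 / n
  }
  p <- .ascend(p0, mats, entropy_weight = 0, max_iter = max_iter, tol = tol)
  if (entropy_weight > 0) {
    # the sparse pure optimum is a nonsmooth stall point for the combined
    # objective; restart the entropy phase from interior points and keep
    # the best candidate under the combined objective
    u <- rep(1 / n, n)
    starts <- list(p, u, 0.5 * p + 0.5 * u)
    fcomb <- function(q) {
      .fit_objective(q, mats)$f +
        entropy_weight * length(mats) * .pop_entropy(q)
    }
    cands <- lapply(starts, function(s) {
      .ascend(s, mats, entropy_weight = entropy_weight,
              max_iter = max_iter, tol = tol)
    })
    p <- cands[[which.max(vapply(cands, fcomb, numeric(1)))]]
  }
  p
}

#' Fit conformer populations to distance-distribution restraints
#'
#' Maximizes the geometric mean of per-restraint overlaps between predicted
#' and experimental distance distributions over the population simplex.
#' Conformers are processed in blocks (generation order): fit the current
#' block, discard conformers below `prune_frac` of the most populated one,
#' admit the next block, refit. When fewer than 10% of the block size are
#' free for admission, the block size grows by 50%; when the retained count
#' later drops, it resets to the specified value. Populations among
#' conformers with identical predicted distributions are non-identifiable;
#' only their sum is meaningful.
#'
#' @param raw A `conformer_ensemble` (uniform or prior populations ignored;
#'   fitting starts from scratch).
#' @param restraints List of `gaussian_restraint` objects, each carrying a
#'   full experimental `distance_distribution` (`dist` field).
#' @param block_size Initial block size (default 100).
#' @param prune_frac Pruning threshold relative to the maximum population
#'   (default 0.01).
#' @param label_params `label_surrogate_params` for the forward model.
#' @param entropy_weight Weight of a population-entropy term added to the
#'   mean log overlap. The default 0 maximizes overlap alone; a small
#'   positive value (e.g. 0.02) pulls the solution toward the densest,
#'   maximum-entropy reweighting compatible with near-optimal overlap.
#'   Useful when the fitted ensemble is used to predict distributions it
#'   was not fitted to. With a nonzero weight the recorded `gbar_history`
#'   tracks the penalized objective and need not be monotone in overlap
#'   alone.
#' @return A `conformer_ensemble` of the retained conformers with fitted
#'   populations; provenance carries `gbar` (geometric mean overlap),
#'   `overlaps`, `gbar_history` (per block iteration, non-decreasing), and
#'   the retained conformer indices. If all overlaps are zero a
#'   `fit_failure` object is returned instead.
#' @export
fit_populations <- function(raw, restraints, block_size = 100,
                            prune_frac = 0.01,
                            label_params = label_surrogate_params(),
                            entropy_weight = 0) {
  stopifnot(inherits(raw, "conformer_ensemble"))
  if (length(restraints) < 1) stop("need at least one restraint")
  has_dist <- vapply(restraints, function(r) !is.null(r$dist), logical(1))
  if (!all(has_dist)) {
    stop("every restraint must carry a full experimental distribution")
  }
  n_all <- n_conformers(raw)
  sigma_conv <- sqrt(2) * label_params$sigma_label

  # precompute label distances and unit-sum experimental vectors
  mats_full <- lapply(restraints, function(r) {
    d <- label_distances(raw, r$site_i, r$site_j, label_params)
    list(dist = d, grid = r$dist$r_axis, b = r$dist$p / sum(r$dist$p))
  })

  cols_for <- function(idx) {
    lapply(mats_full, function(m) {
      list(A = .restraint_columns(m$dist[idx], m$grid, sigma_conv), b = m$b)
    })
  }

  bs <- block_size
  active <- integer(0)
  queue <- seq_len(n_all)
  gbar_history <- numeric(0)
  pops <- numeric(0)
  prev_retained <- 0L
  repeat {
    free <- bs - length(active)
    if (free < 0.1 * bs && length(queue) > 0) {
      bs <- ceiling(bs * 1.5)
      free <- bs - length(active)
    }
    take <- head(queue, max(free, 0))
    queue <- setdiff(queue, take)
    active <- c(active, take)
    mats <- cols_for(active)
    p0 <- NULL
    if (length(pops) > 0 && length(take) > 0) {
      p0 <- c(pops, rep(1e-3, length(take)))
      p0 <- p0 / sum(p0)
    }
    p <- .solve_populations(mats, p0 = p0, entropy_weight = entropy_weight)
    ob <- .fit_objective(p, mats)
    gbar_history <- c(gbar_history, ob$gbar)
    keep <- p >= prune_frac * max(p)
    if (sum(keep) < prev_retained) bs <- block_size
    prev_retained <- sum(keep)
    active <- active[keep]
    pops <- p[keep] / sum(p[keep])
    if (length(queue) == 0) break
  }

  mats <- cols_for(active)
  p <- .solve_populations(mats, p0 = pops, entropy_weight = entropy_weight)
  keep <- p >= prune_frac * max(p)
  active <- active[keep]
  p <- p[keep] / sum(p[keep])
  ob <- .fit_objective(p, cols_for(active))
  gbar_history <- c(gbar_history, ob$gbar)
  if (all(ob$overlaps <= 0)) {
    return(structure(list(message = "all overlaps are zero (disjoint supports)",
                          overlaps = ob$overlaps), class = "fit_failure"))
  }
  out <- subset_ensemble(raw, active, renormalize = FALSE)
  out$populations <- p
  out$provenance <- c(raw$provenance,
                      list(gbar = ob$gbar, overlaps = ob$overlaps,
                           gbar_history = gbar_history,
                           retained = active, block_size = block_size,
                           prune_frac = prune_frac,
                           entropy_weight = entropy_weight))
  out
}
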