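# Dipolar frequency constant: nu_dd = 52.04 MHz at r = 1 nm, scaling as r^-3.
.nu_dd_const <- 52.04

#' Dipolar evolution trace
#'
#' Time-domain DEER signal, assumed phase- and zero-time corrected upstream.
#'
#' @param t_axis Time axis in microseconds (may start at or below zero).
#' @param v Real signal values.
#' @param noise_estimate Optional noise standard deviation; if `NULL`, it is
#'   estimated from second differences of the signal.
#' @param normalize Rescale so the value at the time point nearest zero is 1.
#' @return Object of class `deer_trace`.
#' @export
deer_trace <- function(t_axis, v, noise_estimate = NULL, normalize = TRUE) {
  if (length(t_axis) != length(v)) stop("t_axis and v lengths differ")
  if (any(diff(t_axis) <= 0)) stop("time axis must be increasing")
  if (any(!is.finite(v))) stop("signal contains non-finite values")
  if (normalize) {
    i0 <- which.min(abs(t_axis))
    if (abs(v[i0]) < .Machine$double.eps) stop("zero-time amplitude is zero")
    v <- v / v[i0]
  }
  if (is.null(noise_estimate)) {
    noise_estimate <- stats::sd(diff(v, differences = 2)) / sqrt(6)
  }
  structure(list(t_axis = as.numeric(t_axis), v = as.numeric(v),
                 noise_estimate = noise_estimate),
            class = "deer_trace")
}

#' @export
print.deer_trace <- function(x, ...) {
  cat(sprintf("<deer_trace> %d points, t = %.3f..%.3f us, noise ~ %.2e\n",
              length(x$t_axis), min(x$t_axis), max(x$t_axis),
              x$noise_estimate))
  invisible(x)
}

#' Multi-pathway kernel parameters
#'
#' Amplitudes of the unmodulated (`lambda0`) and the two modulated dipolar
#' pathways (`lambda1`, `lambda2`), the refocusing time of the second
#' modulated pathway (`t02`, microseconds), and the exponential background
#' decay rate `k_bg` (1/us) of homogeneously distributed remote labels.
#'
#' @param lambda0,lambda1,lambda2 Nonnegative pathway amplitudes.
#' @param t02 Refocusing time of the second modulated pathway (us).
#' @param k_bg Background decay rate (1/us).
#' @return Object of class `pathway_model`.
#' @export
pathway_model <- function(lambda0 = 0.7, lambda1 = 0.3, lambda2 = 0,
                          t02 = 0, k_bg = 0) {
  if (any(c(lambda0, lambda1, lambda2) < 0)) {
    stop("pathway amplitudes must be nonnegative")
  }
  # small tolerance: amplitudes fitted to noisy normalized traces can
  # land marginally above unit sum
  if (lambda0 + lambda1 + lambda2 > 1.05) {
    stop("pathway amplitudes sum above 1")
  }
  if (k_bg < 0) stop("background rate must be nonnegative")
  structure(list(lambda0 = lambda0, lambda1 = lambda1, lambda2 = lambda2,
                 t02 = t02, k_bg = k_bg), class = "pathway_model")
}

#' Elementary dipolar kernel
#'
#' Powder-averaged dipolar trace
#' `K0(t, r) = int_0^1 cos[(1 - 3 z^2) w_dd(r) t] dz` with dipolar frequency
#' `w_dd/2pi = 52.04 MHz (r / 1 nm)^-3`. Evaluated by the Fresnel-integral
#' closed form; `K0(0, r) = 1` for all r.
#'
#' @param t_axis Times (us).
#' @param r_axis Distances (Angstrom).
#' @return Matrix of dimension `length(t_axis) x length(r_axis)`.
#' @export
elementary_kernel <- function(t_axis, r_axis) {
  if (any(r_axis <= 0)) stop("distances must be positive")
  r_nm <- r_axis / 10
  w_dd <- 2 * pi * .nu_dd_const / r_nm^3      # rad/us
  phi <- abs(outer(t_axis, w_dd))             # dipolar phase, >= 0
  K <- matrix(0, nrow(phi), ncol(phi))
  small <- phi < 1e-3
  # series: K0 = 1 - (2/5) phi^2 + O(phi^4)
  K[small] <- 1 - 0.4 * phi[small]^2
  if (any(!small)) {
    ph <- phi[!small]
    q <- sqrt(6 * ph / pi)
    K[!small] <- sqrt(pi / (6 * ph)) *
      (cos(ph) * pracma::fresnelC(q) + sin(ph) * pracma::fresnelS(q))
  }
  K
}

.kernel_matrix <- function(t_axis, r_axis, model) {
  K0 <- elementary_kernel(t_axis, r_axis)
  mod <- model$lambda0 + model$lambda1 * K0
  if (model$lambda2 > 0) {
    mod <- mod + model$lambda2 * elementary_kernel(t_axis - model$t02, r_axis)
  }
  bg <- exp(-model$k_bg * (model$lambda1 * abs(t_axis) +
                             model$lambda2 * abs(t_axis - model$t02)))
  mod * bg
}

#' Forward multi-pathway DEER signal
#'
#' `V(t) = sum_r P(r) K(t, r)` with
#' `K(t,r) = [L0 + l1 K0(t,r) + l2 K0(t - T02, r)] exp(-k(l1|t| + l2|t-T02|))`.
#'
#' @param dist Normalized `distance_distribution`.
#' @param model A `pathway_model`.
#' @param t_axis Times (us).
#' @return A `deer_trace` (not renormalized).
#' @export
multipathway_signal <- function(dist, model, t_axis) {
  stopifnot(inherits(dist, "distance_distribution"),
            inherits(model, "pathway_model"))
  p <- dist$p / sum(dist$p)
  v <- as.numeric(.kernel_matrix(t_axis, dist$r_axis, model) %*% p)
  deer_trace(t_axis, v, normalize = FALSE)
}

# --- parametric inversion ----------------------------------------------------

.model_dist <- function(family, th, r_axis) {
  if (family == "gaussian") {
    gaussian_pdf(r_axis, gaussian_params(mean = th[1], sigma = th[2]))
  } else if (family == "saw_nu") {
    saw_nu_pdf(r_axis, saw_nu_params(R = th[1], nu = th[2]))
  } else {
    n <- (length(th)) / 3
    means <- th[seq_len(n)]
    sigmas <- th[n + seq_len(n)]
    w <- th[2 * n + seq_len(n)]
    w <- w / sum(w)
    p <- rep(0, length(r_axis))
    for (i in seq_len(n)) {
      p <- p + w[i] * stats::dnorm(r_axis, means[i], sigmas[i])
    }
    distance_distribution(r_axis, p, normalize = TRUE)
  }
}

.forward_v <- function(dist_p, K0, th_path, t_axis) {
  lambda0 <- th_path[1]; lambda1 <- th_path[2]; k_bg <- th_path[3]
  bg <- exp(-k_bg * lambda1 * abs(t_axis))
  (lambda0 + lambda1 * as.numeric(K0 %*% dist_p)) * bg
}

#' Fit a parametric distance distribution to a dipolar trace
#'
#' Joint bounded nonlinear least squares of the distribution parameters and
#' the pathway/background parameters (`lambda0`, `lambda1`, `k_bg`; single
#' modulated pathway, exponential background). For `multi_gaussian`, the
#' number of components is selected over `1..n_max` by AIC or BIC computed
#' from the residual sum of squares.
#'
#' @param trace A `deer_trace`.
#' @param model_family `"gaussian"`, `"saw_nu"` or `"multi_gaussian"`.
#' @param r_axis Distance grid for the recovered distribution (Angstrom).
#' @param n_max Maximum number of Gaussian components (multi_gaussian only).
#' @param criterion `"bic"` or `"aic"` for component-count selection.
#' @param n_starts Number of multi-start initializations.
#' @return List with `dist` (fitted `distance_distribution`), `params`
#'   (distribution parameters), `pathway` (`pathway_model`), `residuals`,
#'   `rss`, `converged`, and for multi_gaussian `n_components` and the
#'   per-count criterion table.
#' @export
fit_parametric <- function(trace, model_family = c("gaussian", "saw_nu",
                                                   "multi_gaussian"),
                           r_axis = default_r_axis(), n_max = 3,
                           criterion = c("bic", "aic"), n_starts = 5) {
  stopifnot(inherits(trace, "deer_trace"))
  model_family <- match.arg(model_family)
  criterion <- match.arg(criterion)
  t_axis <- trace$t_axis
  v <- trace$v
  K0 <- elementary_kernel(t_axis, r_axis)

  fit_one <- function(n_comp) {
    # crude first guess of the mean from the dipolar frequency of the
    # initial decay: use several spread starts instead of a transform
    mean_grid <- seq(0.3, 0.7, length.out = n_starts) * diff(range(r_axis)) +
      min(r_axis)
    if (model_family == "multi_gaussian") {
      n_dist_par <- 3 * n_comp
      lower <- c(rep(min(r_axis), n_comp), rep(0.5, n_comp),
                 rep(1e-3, n_comp), 0, 0, 0)
      upper <- c(rep(max(r_axis), n_comp), rep(60, n_comp),
                 rep(1, n_comp), 1.2, 1.2, 2)
    } else {
      n_dist_par <- 2
      lower <- c(min(r_axis), if (model_family == "gaussian") 0.5 else 0.2,
                 0, 0, 0)
      upper <- c(max(r_axis), if (model_family == "gaussian") 60 else 0.95,
                 1.2, 1.2, 2)
    }
    obj <- function(th) {
      thd <- th[seq_len(n_dist_par)]
      thp <- th[n_dist_par + 1:3]
      d <- try(.model_dist(model_family, thd, r_axis), silent = TRUE)
      if (inherits(d, "try-error")) return(rep(1e3, length(v)))
      .forward_v(d$p, K0, c(thp[1], thp[2], thp[3]), t_axis) - v
    }
    best <- NULL
    for (s in seq_len(n_starts)) {
      if (model_family == "multi_gaussian") {
        # tile the most DEER-sensitive part of the range (short-to-middle
        # distances), spreading the tiling across starts
        lo <- 0.08 + 0.10 * (s - 1) / max(n_starts - 1, 1)
        hi <- 0.35 + 0.20 * (s - 1) / max(n_starts - 1, 1)
        mus <- min(r_axis) +
          seq(lo, hi, length.out = n_comp) * diff(range(r_axis))
        th0 <- c(mus, rep(5, n_comp), rep(1 / n_comp, n_comp),
                 0.6, 0.4, 0.05)
      } else if (model_family == "gaussian") {
        th0 <- c(mean_grid[s], 8, 0.6, 0.4, 0.05)
      } else {
        th0 <- c(mean_grid[s], 0.57, 0.6, 0.4, 0.05)
      }
      th0 <- pmin(pmax(th0, lower + 1e-6), upper - 1e-6)
      fit <- try(minpack.lm::nls.lm(
        par = th0, lower = lower, upper = upper, fn = obj,
        control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      rss <- sum(obj(fit$par)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(par = fit$par, rss = rss,
                     converged = fit$info %in% 1:4)
      }
    }
    if (is.null(best)) return(NULL)
    best$n_par <- n_dist_par + 3
    best
  }

  n_obs <- length(v)
  crit_value <- function(rss, k) {
    n_obs * log(rss / n_obs) + if (criterion == "bic") k * log(n_obs) else 2 * k
  }

  if (model_family == "multi_gaussian") {
    fits <- lapply(seq_len(n_max), fit_one)
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) stop("multi-Gaussian fit failed for all component counts")
    crit <- vapply(seq_len(n_max), function(i) {
      if (!ok[i]) return(Inf)
      # weights are sum-constrained: one weight is redundant
      crit_value(fits[[i]]$rss, fits[[i]]$n_par - 1)
    }, numeric(1))
    n_sel <- which.min(crit)
    best <- fits[[n_sel]]
  } else {
    best <- fit_one(1)
    if (is.null(best)) stop("parametric fit failed from all starts")
    n_sel <- 1
    crit <- crit_value(best$rss, best$n_par)
  }

  n_dist_par <- best$n_par - 3
  thd <- best$par[seq_len(n_dist_par)]
  thp <- best$par[n_dist_par + 1:3]
  dist <- .model_dist(model_family, thd, r_axis)
  params <- switch(model_family,
    gaussian = gaussian_params(mean = thd[1], sigma = thd[2]),
    saw_nu = saw_nu_params(R = thd[1], nu = thd[2]),
    multi_gaussian = {
      n <- n_sel
      w <- thd[2 * n + seq_len(n)]
      list(means = thd[seq_len(n)], sigmas = thd[n + seq_len(n)],
           weights = w / sum(w))
    })
  res <- .forward_v(dist$p, K0, thp, t_axis) - v
  out <- list(dist = dist, params = params,
              pathway = pathway_model(lambda0 = thp[1], lambda1 = thp[2],
                                      k_bg = thp[3]),
              residuals = res, rss = best$rss, converged = best$converged,
              family = model_family)
  if (model_family == "multi_gaussian") {
    out$n_components <- n_sel
    out$criterion_table <- data.frame(n = seq_along(crit), criterion = crit)
  }
  if (!best$converged) {
    warning("parametric fit did not formally converge; result flagged")
  }
  out
}

# --- Tikhonov regularization -------------------------------------------------

.second_difference <- function(n) {
  L <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) L[i, i + 0:2] <- c(1, -2, 1)
  L
}

#' Tikhonov inversion of a dipolar trace
#'
#' Solves `P = argmin ||K P - V||^2 + alpha^2 ||L P||^2` subject to `P >= 0`,
#' with `L` the second-difference operator, by nonnegative least squares on
#' the stacked system. The pathway/background model is either supplied or
#' pre-fitted with a single-Gaussian parametric fit. When `alpha` is a
#' criterion name, it is selected over a log-spaced grid; the effective
#' number of degrees of freedom entering AIC/BIC is the trace of the
#' (unconstrained) influence matrix. Absolute `alpha` values are
#' convention-dependent; here `alpha` multiplies the plain second-difference
#' seminorm on the unit-sum density over the 0.5-Angstrom default grid.
#'
#' @param trace A `deer_trace`.
#' @param alpha Positive number, or one of `"aic"`, `"bic"`, `"residual"`
#'   (discrepancy principle against the trace's noise estimate).
#' @param model A `pathway_model`, or `"fit"` to pre-fit pathway parameters.
#' @param r_axis Distance grid (Angstrom).
#' @param alpha_grid Candidate grid for criterion-based selection.
#' @return List with `dist`, `alpha_used`, `diagnostics` (per-alpha table),
#'   and `pathway`.
#' @export
tikhonov <- function(trace, alpha = "bic", model = "fit",
                     r_axis = default_r_axis(),
                     alpha_grid = 10^seq(-2, 3, length.out = 24)) {
  stopifnot(inherits(trace, "deer_trace"))
  if (identical(model, "fit")) {
    pre <- fit_parametric(trace, "gaussian", r_axis = r_axis)
    model <- pre$pathway
  }
  stopifnot(inherits(model, "pathway_model"))
  t_axis <- trace$t_axis
  v <- trace$v
  K <- .kernel_matrix(t_axis, r_axis, model)
  n_r <- length(r_axis)
  L <- .second_difference(n_r)

  solve_alpha <- function(a) {
    A <- rbind(K, a * L)
    b <- c(v, rep(0, nrow(L)))
    p <- pracma::lsqnonneg(A, b)$x
    p
  }
  edf <- function(a) {
    H <- K %*% solve(crossprod(K) + a^2 * crossprod(L), t(K))
    sum(diag(H))
  }

  if (is.character(alpha)) {
    alpha <- match.arg(alpha, c("aic", "bic", "residual"))
    n_obs <- length(v)
    tab <- lapply(alpha_grid, function(a) {
      p <- solve_alpha(a)
      rss <- sum((as.numeric(K %*% p) - v)^2)
      df <- edf(a)
      data.frame(alpha = a, rss = rss, edf = df,
                 aic = n_obs * log(rss / n_obs) + 2 * df,
                 bic = n_obs * log(rss / n_obs) + df * log(n_obs))
    })
    tab <- do.call(rbind, tab)
    if (alpha %in% c("aic", "bic")) {
      a_used <- tab$alpha[which.min(tab[[alpha]])]
    } else {
      # discrepancy principle: smallest alpha with rss per point <= noise^2
      target <- length(v) * trace$noise_estimate^2
      ok <- tab$rss <= target
      a_used <- if (any(ok)) max(tab$alpha[ok]) else
        tab$alpha[which.min(abs(tab$rss - target))]
    }
    p <- solve_alpha(a_used)
    diagnostics <- tab
  } else {
    if (alpha <= 0) stop("alpha must be positive")
    a_used <- alpha
    p <- solve_alpha(a_used)
    diagnostics <- data.frame(alpha = a_used,
                              rss = sum((as.numeric(K %*% p) - v)^2))
  }
  if (sum(p) <= 0) stop("Tikhonov solution is identically zero")
  # ill-conditioning warning: max observation time below one dipolar period
  # at the recovered distribution mode cannot constrain the width there
  mode_r <- r_axis[which.max(p)]
  if (max(t_axis) < (mode_r / 10)^3 / .nu_dd_const) {
    warning("max observation time is below one dipolar period at the ",
            "distribution mode; inversion is strongly ill-conditioned")
  }
  list(dist = distance_distribution(r_axis, p, normalize = TRUE),
       alpha_used = a_used, diagnostics = diagnostics, pathway = model)
}
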