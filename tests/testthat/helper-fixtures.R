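# Shared fixtures, built once per test run. The FUS NTD 1-100 sequence is the
# glycine/serine/glutamine/tyrosine-rich low-complexity reference sequence
# used for random-coil calibration checks.
fus_1_100 <- paste0(
  "MASNDYTQQATQSYGAYPTQPGQGYSQQSSQPYGQQSYSGYSQSTDTSGY",
  "GQSSYSSYGQSQNTGYGTQSTPQGYGSTGGYGSSQSSQSSYGQQSSYPGY")

seq_60 <- substr(fus_1_100, 1, 60)

# small unrestrained backbone ensemble reused across tests
local_fus_ensemble <- local({
  cache <- NULL
  function(n = 400, seed = 11) {
    key <- paste(n, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- build_raw_ensemble(fus_1_100, n_target = n,
                                          rng_seed = seed)
    }
    cache[[key]]
  }
})

# One compact, seeded leave-one-out study reused across test files: a
# 60-residue low-complexity segment, ground truth from unrestrained coil
# sampling, and restraints simulated from that ground truth so the set is
# self-consistent by construction.
jk_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ax <- default_r_axis(2, 100, 0.5)
      gt <- build_raw_ensemble(seq_60, n_target = 400, rng_seed = 7)
      pairs <- rbind(c(5, 30), c(20, 45), c(35, 60), c(10, 50), c(15, 55))
      restr <- simulate_restraints(gt, pairs, noise = 0, seed = 4,
                                   r_axis = ax)
      jk <- suppressWarnings(
        run_jackknife(seq_60, restraints = restr, n_target = 150,
                      master_seed = 17))
      cache <<- list(gt = gt, restr = restr, jk = jk, ax = ax)
    }
    cache
  }
})

# brute-force total variation distance of two unit-sum vectors
tv_distance <- function(a, b) 0.5 * sum(abs(a / sum(a) - b / sum(b)))

# Monte-Carlo powder average of the dipolar trace at one (t, r)
mc_kernel <- function(t_us, r_A, n = 2e5) {
  z <- stats::runif(n)                    # cos(theta) uniform on a sphere
  w <- 2 * pi * 52.04 / (r_A / 10)^3
  mean(cos((1 - 3 * z^2) * w * t_us))
}

# exhaustive simplex grid search for the geometric-mean-overlap optimum
grid_search_gbar <- function(mats, step = 0.005) {
  n <- ncol(mats[[1]]$A)
  stopifnot(n <= 4)
  gbar_of <- function(p) {
    o <- vapply(mats, function(m) sum(pmin(as.numeric(m$A %*% p), m$b)),
                numeric(1))
    if (any(o == 0)) 0 else exp(mean(log(o)))
  }
  best <- -Inf
  gr <- seq(0, 1, by = step)
  if (n == 2) {
    for (p1 in gr) best <- max(best, gbar_of(c(p1, 1 - p1)))
  } else if (n == 3) {
    for (p1 in gr) for (p2 in seq(0, 1 - p1, by = step)) {
      best <- max(best, gbar_of(c(p1, p2, 1 - p1 - p2)))
    }
  } else {
    gr <- seq(0, 1, by = max(step, 0.02))
    for (p1 in gr) for (p2 in seq(0, 1 - p1, by = max(step, 0.02))) {
      for (p3 in seq(0, 1 - p1 - p2, by = max(step, 0.02))) {
        best <- max(best, gbar_of(c(p1, p2, p3, 1 - p1 - p2 - p3)))
      }
    }
  }
  best
}

# restraint-matrix view used by the solver, built from scratch for oracles
oracle_mats <- function(ensemble, restraints,
                        lp = label_surrogate_params()) {
  lapply(restraints, function(r) {
    d <- label_distances(ensemble, r$site_i, r$site_j, lp)
    list(A = ddrensemble:::.restraint_columns(d, r$dist$r_axis,
                                              sqrt(2) * lp$sigma_label),
         b = r$dist$p / sum(r$dist$p))
  })
}
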