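make_recovery_problem <- function(seed = 5) {
  scen <- synthetic_scenario(n_res = 60, motif = "none")
  gt <- make_weakly_ordered_ensemble(scen, n_conf = 3, seed = seed)
  gt$populations <- c(0.5, 0.3, 0.2)
  pairs <- rbind(c(5, 25), c(10, 40), c(20, 55), c(5, 55), c(30, 50))
  restr <- simulate_restraints(gt, pairs, noise = 0, seed = 2,
                               r_axis = default_r_axis(2, 100, 0.5))
  raw <- gt
  raw$populations <- rep(1 / 3, 3)
  list(gt = gt, raw = raw, restr = restr)
}

test_that("predicted restraint distribution is the population-weighted mix", {
  prob <- make_recovery_problem()
  # single conformer: equals that conformer's label distribution
  one <- subset_ensemble(prob$raw, 1)
  pred1 <- predict_restraint_distribution(one, prob$restr[[1]])
  lp <- label_surrogate_params()
  direct <- label_distance_distribution(one, 5, 25,
                                        prob$restr[[1]]$dist$r_axis, lp)
  expect_equal(pred1$p, direct$p, tolerance = 1e-12)
  # weighted mix equals brute-force per-conformer summation
  pred <- predict_restraint_distribution(prob$gt, prob$restr[[2]])
  brute <- 0
  for (i in 1:3) {
    pi <- predict_restraint_distribution(subset_ensemble(prob$gt, i),
                                         prob$restr[[2]])
    brute <- brute + prob$gt$populations[i] * pi$p
  }
  expect_equal(pred$p, brute / sum(brute), tolerance = 1e-12)
  # 50/50 mix of two well-separated conformers is bimodal with equal mass
  two <- subset_ensemble(prob$raw, c(1, 2))
  two$populations <- c(0.5, 0.5)
  d <- label_distances(two, 5, 55)
  if (abs(d[1] - d[2]) > 15) {
    pr <- predict_restraint_distribution(two, prob$restr[[4]])
    mid <- mean(d)
    expect_equal(sum(pr$p[pr$r_axis < mid]), 0.5, tolerance = 0.05)
  }
})

test_that("populations of a synthetic 3-conformer ensemble are recovered", {
  prob <- make_recovery_problem()
  fit <- fit_populations(prob$raw, prob$restr)
  recovered <- numeric(3)
  recovered[match(fit$provenance$retained, 1:3)] <- fit$populations
  expect_equal(recovered, c(0.5, 0.3, 0.2), tolerance = 0.05)
  expect_gte(fit$provenance$gbar, 0.99)
})

test_that("the solver matches an exhaustive simplex grid search", {
  prob <- make_recovery_problem()
  mats <- oracle_mats(prob$raw, prob$restr)
  p <- ddrensemble:::.solve_populations(mats)
  gbar_solver <- ddrensemble:::.fit_objective(p, mats)$gbar
  gbar_grid <- grid_search_gbar(mats, step = 0.005)
  expect_gte(gbar_solver, gbar_grid - 1e-3)
  expect_lte(abs(gbar_solver - gbar_grid), 1e-3)
  # 4-conformer variant at coarser grid resolution
  scen <- synthetic_scenario(n_res = 40, motif = "none")
  gt4 <- make_weakly_ordered_ensemble(scen, 4, seed = 11)
  gt4$populations <- c(0.4, 0.3, 0.2, 0.1)
  restr4 <- simulate_restraints(gt4, rbind(c(3, 20), c(10, 35), c(5, 38)),
                                noise = 0, seed = 3,
                                r_axis = default_r_axis(2, 80, 0.5))
  raw4 <- gt4
  raw4$populations <- rep(0.25, 4)
  mats4 <- oracle_mats(raw4, restr4)
  p4 <- ddrensemble:::.solve_populations(mats4)
  expect_gte(ddrensemble:::.fit_objective(p4, mats4)$gbar,
             grid_search_gbar(mats4, step = 0.02) - 1e-3)
})

test_that("duplicated conformers constrain only the population sum", {
  prob <- make_recovery_problem()
  raw_dup <- conformer_ensemble(c(prob$raw$conformers,
                                  prob$raw$conformers[1]))
  fit <- fit_populations(raw_dup, prob$restr)
  pop_of <- function(i) {
    j <- match(i, fit$provenance$retained)
    if (is.na(j)) 0 else fit$populations[j]
  }
  expect_equal(pop_of(1) + pop_of(4), 0.5, tolerance = 0.05)
  expect_equal(pop_of(2), 0.3, tolerance = 0.05)
})

test_that("objective history is monotone and populations stay normalized", {
  seq40 <- substr(fus_1_100, 1, 40)
  gt <- build_raw_ensemble(seq40, n_target = 200, rng_seed = 21)
  restr <- simulate_restraints(gt, rbind(c(5, 25), c(10, 35), c(15, 40)),
                               noise = 0, seed = 1,
                               r_axis = default_r_axis(2, 90, 0.5))
  raw <- build_raw_ensemble(seq40, restraints = restr, n_target = 220,
                            rng_seed = 8, max_attempts = 2000)
  fit <- fit_populations(raw, restr, block_size = 60)
  hist <- fit$provenance$gbar_history
  expect_gte(length(hist), 2)
  expect_true(all(diff(hist) > -1e-6))
  expect_equal(sum(fit$populations), 1, tolerance = 1e-9)
  expect_true(all(fit$populations >= 0))
  # pruning contract: no retained conformer below the threshold
  expect_true(all(fit$populations >=
                    0.01 * max(fit$populations) - 1e-12))
  expect_lte(n_conformers(fit), n_conformers(raw))
})

test_that("entropy regularization densifies the fit at bounded overlap cost", {
  seq40 <- substr(fus_1_100, 1, 40)
  gt <- build_raw_ensemble(seq40, n_target = 300, rng_seed = 33)
  restr <- simulate_restraints(gt, rbind(c(5, 25), c(10, 35), c(15, 40)),
                               noise = 0, seed = 1,
                               r_axis = default_r_axis(2, 90, 0.5))
  raw <- build_raw_ensemble(seq40, restraints = restr, n_target = 200,
                            rng_seed = 9, max_attempts = 2000)
  f0 <- fit_populations(raw, restr, entropy_weight = 0)
  f1 <- fit_populations(raw, restr, entropy_weight = 0.05)
  expect_gt(n_conformers(f1), n_conformers(f0))
  expect_gte(f1$provenance$gbar, f0$provenance$gbar - 0.06)
})

test_that("restraints without full distributions are rejected", {
  prob <- make_recovery_problem()
  bare <- list(gaussian_restraint(5, 25, mean = 25, sigma = 5))
  expect_error(fit_populations(prob$raw, bare), "full experimental")
})
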