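test_that("unrestrained chains have ideal virtual bonds and no clashes", {
  ens <- build_raw_ensemble(paste(rep("A", 50), collapse = ""),
                            n_target = 100, rng_seed = 2)
  expect_equal(n_conformers(ens), 100)
  ca <- ca_array(ens)
  for (i in seq_len(20)) {
    xyz <- ca[i, , ]
    bonds <- sqrt(rowSums((xyz[-1, ] - xyz[-50, ])^2))
    expect_true(all(abs(bonds - 3.8) < 0.1))
    d <- as.matrix(dist(xyz))
    sep <- abs(outer(1:50, 1:50, "-"))
    expect_true(all(d[sep >= 3] >= 4.0))
  }
})

test_that("residue classes are assigned by identity and context", {
  cls <- ddrensemble:::.residue_class("AGPIVTAPA")
  expect_equal(cls, c("generic", "gly", "pro", "branched", "branched",
                      "branched", "prepro", "pro", "generic"))
  expect_error(ddrensemble:::.residue_class("AXZ"), "non-standard")
})

test_that("restraint probability has the max-normalized Gaussian form", {
  r <- gaussian_restraint(10, 29, mean = 25, sigma = 5)
  s <- sqrt(2) * 5
  expect_equal(restraint_probability(25, r), 1)
  expect_equal(restraint_probability(25 + s * sqrt(2 * log(2)), r), 0.5)
  # product arithmetic against the 0.75 acceptance threshold
  expect_gte(0.91^3, 0.75)
  expect_lt(0.90^3, 0.75)
  d_91 <- 25 + s * sqrt(-2 * log(0.91))
  expect_equal(restraint_probability(d_91, r), 0.91, tolerance = 1e-12)
})

test_that("a single restraint biases accepted conformers toward its mean", {
  r <- gaussian_restraint(10, 29, mean = 25, sigma = 5)
  ens <- build_raw_ensemble(paste(rep("A", 50), collapse = ""),
                            restraints = list(r), n_target = 500,
                            rng_seed = 3)
  d <- label_distances(ens, 10, 29)
  expect_lt(abs(mean(d) - 25), 3)
  # every accepted conformer satisfies the product threshold
  expect_true(all(restraint_probability(d, r) >= 0.75 - 1e-9))
})

test_that("geometrically impossible restraints produce an explicit failure", {
  r <- gaussian_restraint(10, 29, mean = 95, sigma = 2)  # > 3.8 * 19 A
  sf <- sample_chain(paste(rep("A", 50), collapse = ""),
                     restraints = list(r), max_attempts = 50)
  expect_s3_class(sf, "sampling_failure")
  expect_error(
    suppressWarnings(build_raw_ensemble(paste(rep("A", 50), collapse = ""),
                                        restraints = list(r), n_target = 3,
                                        rng_seed = 1, max_attempts = 30)),
    "sampling failure")
})

test_that("sampling is deterministic under a fixed seed", {
  s <- substr(fus_1_100, 1, 30)
  e1 <- build_raw_ensemble(s, n_target = 10, rng_seed = 42)
  e2 <- build_raw_ensemble(s, n_target = 10, rng_seed = 42)
  expect_identical(lapply(e1$conformers, `[[`, "xyz"),
                   lapply(e2$conformers, `[[`, "xyz"))
  e3 <- build_raw_ensemble(s, n_target = 10, rng_seed = 43)
  expect_false(identical(e1$conformers[[1]]$xyz, e3$conformers[[1]]$xyz))
})

test_that("conformers are distributed round-robin across anchor models", {
  # toy two-model anchor: short ideal strand ending in a complete residue
  mk_anchor <- function(shift) {
    ens <- build_raw_ensemble("AAAA", n_target = 1, rng_seed = shift)
    cf <- ens$conformers[[1]]
    cf$xyz <- cf$xyz + shift
    cf
  }
  anchors <- list(mk_anchor(1), mk_anchor(2))
  ens <- build_raw_ensemble(paste(rep("A", 20), collapse = ""),
                            anchor_models = anchors, n_target = 10,
                            rng_seed = 5)
  ids <- vapply(ens$conformers, `[[`, integer(1), "anchor_id")
  expect_equal(as.numeric(table(ids)), c(5, 5))
  # flexible residues continue the anchor numbering
  expect_equal(max(ens$conformers[[1]]$resno), 4 + 20)
  # tethered: first flexible CA is bonded to the anchor's last C
  cf <- ens$conformers[[1]]
  lastC <- cf$xyz[max(which(cf$resno == 4 & cf$atom == "C")), ]
  firstN <- cf$xyz[which(cf$resno == 5 & cf$atom == "N")[1], ]
  expect_equal(sqrt(sum((lastC - firstN)^2)), 1.329, tolerance = 1e-3)
})

test_that("restraint sites outside the construct are rejected", {
  r <- gaussian_restraint(10, 200, mean = 30, sigma = 5)
  expect_error(build_raw_ensemble(paste(rep("A", 50), collapse = ""),
                                  restraints = list(r), n_target = 2),
               "outside")
})

test_that("coil-library ensembles reproduce random-coil scaling", {
  ens <- local_fus_ensemble(n = 1000, seed = 11)
  sf <- fit_scaling_law(segment_rms(ens))
  expect_gte(sf$nu, 0.50); expect_lte(sf$nu, 0.65)
  expect_gte(sf$b, 4.5); expect_lte(sf$b, 6.0)
})

test_that("ramachandran library densities are normalized and class-distinct", {
  lib <- ramachandran_library()
  for (d in lib$densities) {
    expect_true(all(d >= 0))
    expect_equal(sum(d), 1)
  }
  expect_gt(max(abs(lib$densities$gly - lib$densities$generic)), 1e-4)
  expect_gt(max(abs(lib$densities$pro - lib$densities$generic)), 1e-4)
  # plug-in density replaces a class
  u <- matrix(1, 36, 36)
  lib2 <- ramachandran_library(densities = list(generic = u))
  expect_equal(max(lib2$densities$generic), 1 / 36^2)
})
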