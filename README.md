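# ddrensemble

Ensemble modeling of weak protein domain structure from spin-label
distance distributions.

## What problem this solves

Intrinsically disordered protein domains (IDDs) can carry *weak*
structure: stretches of the chain that are systematically more compact or
extended than a random coil, without ever folding. Pulsed dipolar EPR
(DEER) measures full distance *distributions* between pairs of nitroxide
labels in the 15–80 Å range — exactly the kind of ensemble-level
observable that can detect such weak order. `ddrensemble` is an R toolkit
for the complete workflow, aimed at EPR spectroscopists and integrative
modelers:

1. **Forward model and inversion of DEER signals.** The two-pathway
   kernel
   `K(t,r) = [Λ0 + λ1·K0(t,r) + λ2·K0(t−T02,r)]·exp(−k(λ1|t| + λ2|t−T02|))`
   with the powder-averaged elementary kernel
   `K0(t,r) = ∫₀¹ cos[(1−3z²) ω_dd t] dz`, `ω_dd/2π = 52.04 MHz·(r/nm)⁻³`.
   Inversion by parametric fitting (single Gaussian, SAW-ν, multi-Gaussian
   with AIC/BIC component selection) or Tikhonov regularization with
   nonnegativity (`P = argmin ‖KP − V‖² + α²‖LP‖², P ≥ 0`).
2. **Restrained Monte-Carlo conformer generation** from residue-class
   Ramachandran coil statistics, with CA-level clash avoidance, optional
   tethering to a folded-domain anchor, and early rejection against
   Gaussian restraints (`⟨r⟩`, `√2·σ_r`, product threshold 0.75).
3. **Ensemble reweighting** by maximizing the geometric mean
   `ō = (∏ o_m)^(1/M)` of distribution overlaps
   `o_m = Σ_r min{P_pred, P_exp}` over the population simplex (a concave
   problem, solved to the global optimum), with adaptive block iteration
   and pruning of conformers below 1% of the top population.
4. **Weak-order analytics**: segment scaling law `R_k = b·k^ν`, the
   segment-length deviation matrix `ΔL_ij` (per-k zero-sum), ensemble
   width `Γ` (population-weighted RMS pairwise CA-RMSD after Kabsch
   superposition), radius of gyration.
5. **Jack-knife validation**: leave-one-restraint-out remodeling,
   prediction of the omitted distribution, outlier flagging, and a final
   refit on the merged "super-ensemble" basis.
6. **Synthetic data** for every stage: ideal chains, controllable
   weak-order motifs, simulated restraint files and noisy DEER traces.

See the methods vignette (`vignettes/weak-structure-from-deer.Rmd`) for
the models, calibrations, and limitations.

## Worked example

Build an unrestrained ensemble of the FUS N-terminal low-complexity
fragment (residues 1–100, shipped as a FASTA), check its random-coil
scaling, simulate three distance-distribution restraints from it, and
refit populations:

```r
library(ddrensemble)

fasta <- system.file("extdata", "fus_ntd_1_100.fasta", package = "ddrensemble")
fus <- read_sequence(fasta)

ens <- build_raw_ensemble(fus, n_target = 1000, rng_seed = 42)
fit_scaling_law(segment_rms(ens))
#> <scaling_fit> R_k = 4.984 * k^0.601 A (rmsd 0.76 A)

ld <- label_distance_distribution(ens, 10, 29, default_r_axis(2, 100, 0.5))
fg <- fit_gaussian(ld)
sprintf("label 10-29: mean %.1f A, sd %.1f A", fg$params$mean, fg$params$sigma)
#> "label 10-29: mean 31.4 A, sd 11.1 A"

restr <- simulate_restraints(ens, rbind(c(10, 29), c(30, 60), c(50, 90)),
                             seed = 1, r_axis = default_r_axis(2, 110, 0.5))
raw <- build_raw_ensemble(fus, restraints = restr, n_target = 200, rng_seed = 7)
fit <- fit_populations(raw, restr)
fit$provenance$gbar        # geometric mean overlap of the refined ensemble
#> 0.824
round(fit$provenance$overlaps, 3)
#> 0.855 0.812 0.807
```

The scaling fit says the unrestrained chain behaves like a random coil
with Kuhn-like prefactor ~5 Å and Flory exponent ~0.6 (between
theta- and good-solvent scaling, as expected for a hydrated
low-complexity sequence). The label-label distribution of section 10–29
is broader than and shifted from the underlying CA–CA distribution
because the nitroxide sits ~7.5 Å off the backbone and its rotamer cloud
adds spread. The population fit contracts 183 raw conformers to a
20-conformer refined ensemble whose predicted distributions overlap the
three target distributions by 0.81–0.86 each.

A thin command-line front end over the same functions ships in
`inst/exec/ddrensemble`
(`ddrensemble {invert|sample|fit|analyze|jackknife|synth}`, each with
`--seed`/`--out` and a JSON run report).

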