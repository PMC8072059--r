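---
title: "Modeling weak structure in disordered domains from spin-label distance distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling weak structure in disordered domains from spin-label distance distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddrensemble)
```

## The problem

Intrinsically disordered protein domains (IDDs) are functional without a
single well-defined structure, yet they are rarely featureless random
coils. Weak structure — segments of the chain that are systematically more
compact or more extended than a random coil of the same length — is hard
to detect precisely because it is weak. Pulsed dipolar EPR spectroscopy
(DEER) measures the *distribution* of distances between pairs of nitroxide
spin labels in the 15–80 Å window, not just a mean, and that distribution
shape carries exactly the kind of ensemble information needed here.

`ddrensemble` implements a complete desk-scale pipeline around this idea:

1. a forward model for the DEER signal and its inversion to distance
   distributions (parametric fits and Tikhonov regularization);
2. Monte-Carlo generation of backbone conformer ensembles from
   residue-class Ramachandran coil statistics, biased toward Gaussian
   distance restraints by early rejection;
3. a calibrated surrogate for the spin-label rotamer cloud;
4. reweighting of conformer populations against full experimental distance
   distributions by maximizing the geometric mean of distribution
   overlaps, with block iteration and low-population pruning;
5. weak-order analytics: segment scaling laws, the segment-length
   deviation matrix, ensemble width and radius of gyration;
6. jack-knife (leave-one-restraint-out) validation of the restraint set;
7. a synthetic-data module that makes every stage testable without any
   external data.

## The random-coil reference state

Deviation can only be defined against a reference. For chain segments the
reference is the scaling law of the root-mean-square (RMS) end-to-end
distance with segment sequence length $k$,

$$R_k = b\,k^{\nu},$$

with Kuhn-like prefactor $b$ (Å) and Flory exponent $\nu$ (1/3 poor
solvent, 1/2 theta solvent, 3/5 good solvent). The closed-form
end-to-end distance density of a self-avoiding walk (the SAW-$\nu$ model)
is implemented as

$$P(x) \propto x^{2+g}\exp(-\alpha x^{\delta}), \qquad x = r/R,$$

with $\delta = 1/(1-\nu)$, $g = (\gamma - 1)/\nu$ and the SAW
susceptibility exponent $\gamma \approx 1.1615$ (configurable in
`saw_nu_pdf()`). The two remaining constants are fixed analytically by
unit normalization and the second-moment condition
$\langle r^2 \rangle = R^2$:
$\alpha = [\Gamma((5+g)/\delta)/\Gamma((3+g)/\delta)]^{\delta/2}$.
The density is skewed with the steeper flank toward short distances;
skewness grows as $\nu$ decreases. For good-solvent $\nu = 3/5$ the
deviation from a Gaussian of equal mean and width is minor — which is why
Gaussian summaries are adequate *restraints* even when the underlying
ensemble is a self-avoiding coil, and why fitting the SAW-$\nu$ shape to
DEER data from ~20-residue segments is unreliable (fits drift to apparent
$\nu$ of 0.8 and higher; the fit box therefore extends to 0.95 and such
values should be read as "shape not resolvable", not as solvent quality).

```{r saw, fig.width = 6, fig.height = 4}
ax <- default_r_axis(1, 80, 0.5)
plot(ax, saw_nu_pdf(ax, saw_nu_params(30, 1/3))$p, type = "l", col = "red",
     xlab = "r [A]", ylab = "P(r)", main = "SAW-nu end-to-end densities")
lines(ax, saw_nu_pdf(ax, saw_nu_params(30, 3/5))$p, col = "darkgreen")
lines(ax, gaussian_pdf(ax, gaussian_params(28.2, sigma = 8.5))$p,
      col = "black", lty = 2)
legend("topright", c("nu = 1/3", "nu = 3/5", "Gaussian"), lty = c(1, 1, 2),
       col = c("red", "darkgreen", "black"), bty = "n")
```

## DEER forward model and inversion

The dipolar signal of a distance distribution $P(r)$ is
$V(t) = \sum_r P(r)\,K(t, r)$ with the two-pathway kernel

$$K(t,r) = \left[\Lambda_0 + \lambda_1 K_0(t,r) +
\lambda_2 K_0(t - T_{0,2}, r)\right]
e^{-k(\lambda_1 |t| + \lambda_2|t - T_{0,2}|)},$$

where $K_0(t,r) = \int_0^1 \cos[(1-3z^2)\,\omega_{dd}(r)\,t]\,dz$ is the
powder-averaged elementary dipolar kernel with
$\omega_{dd}/2\pi = 52.04\ \mathrm{MHz} \cdot (r/\mathrm{nm})^{-3}$,
$\Lambda_0$ the unmodulated amplitude, $\lambda_{1,2}$ the modulated
pathway amplitudes and $k$ the exponential background rate of remote
labels. $K_0$ is evaluated by the Fresnel-integral closed form (a series
expansion covers the small-phase limit); `elementary_kernel()` agrees with
a Monte-Carlo powder average to better than $10^{-3}$.

Inversion is ill-posed. Two routes are provided:

* `fit_parametric()` — joint bounded nonlinear least squares of a
  single-Gaussian, SAW-$\nu$ or multi-Gaussian distribution together with
  $\Lambda_0, \lambda_1, k$; the multi-Gaussian component count is chosen
  by AIC or BIC on the residual sum of squares.
* `tikhonov()` — $P \ge 0$ minimizing
  $\|KP - V\|^2 + \alpha^2\|LP\|^2$ with $L$ the second-difference
  operator, solved by nonnegative least squares on the stacked system.
  $\alpha$ may be fixed (the package follows the common convention in
  which $\alpha \approx 5$ is a reasonable fixed choice on a 0.5 Å grid;
  absolute $\alpha$ values are convention-dependent and not comparable
  across software) or selected by AIC/BIC with effective degrees of
  freedom equal to the trace of the unconstrained influence matrix, or by
  the discrepancy principle against the trace's noise estimate.

## Conformer generation

`build_raw_ensemble()` grows backbones residue by residue with ideal bond
geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, trans $\omega$) and
$(\phi,\psi)$ sampled from a Ramachandran coil library binned at 10°.
Five residue classes are distinguished (generic, Gly, Pro, pre-Pro, and
beta-branched Ile/Val/Thr); each class is a mixture of wrapped Gaussian
basins over the PPII, beta, $\alpha_R$, $\alpha_L$ and bridge regions.
The basin weights were calibrated once so that unrestrained ensembles of
a 100-residue glycine/serine-rich low-complexity sequence reproduce the
random-coil reference scaling ($b \approx 5$ Å, $\nu \approx 0.6$, with
the 20-residue section statistics within ~10% of the reference values
27.0/8.2 Å). A faithful residue-specific library can be substituted via
`ramachandran_library(densities = ...)` without touching the sampler.
Known limitation: the class-based library is slightly stiffer than a true
residue-specific coil library, so scaling exponents land nearer 0.60 than
0.57 and short-section mean distances run ~5–8% long.

Steric clashes are handled at the CA level (cutoff 4.0 Å for sequence
separation ≥ 3; 3.5 Å against anchor atoms), standing in for the
side-chain exclusion of all-atom samplers. Chains may be tethered to a
folded-domain anchor (multi-model PDB honored, conformers distributed
round-robin across models, construct numbering continued from the anchor).

Restraint biasing follows the distribution-restraint idea: as soon as both
sites of a restraint have coordinates, the label-label distance is scored
with the max-normalized Gaussian
$p = \exp[-(d-\langle r\rangle)^2/(2s^2)]$, $s = \sqrt{2}\sigma_r$, and
the conformer is abandoned as soon as the running product over evaluated
restraints falls below 0.75. Because every factor is ≤ 1 the product only
decreases, so early abandonment rejects exactly the conformers a final
check would reject — at a fraction of the cost. Two consequences are worth
knowing: the accepted set is hard-truncated at
$|d - \langle r\rangle| \lesssim 1.07\,\sigma_r$ per restraint, and the
acceptance rate decays roughly geometrically with the number of
simultaneously active restraints. The max-normalized form (rather than a
tail integral) is an interpretation choice: it is the only reading under
which a product over many restraints can stay above 0.75 at all.

## The label surrogate

Rotamer libraries are external artifacts; the pipeline only needs mean
label positions during sampling and broadened distributions during
fitting. The surrogate places the label at
`CA + radial_offset * u`, with `u` the ideal tetrahedral pseudo-CB
direction from the local N/CA/C frame, and broadens mean-position distance
histograms with a Gaussian of width
$\sigma_{conv} = \sqrt{2}\,\sigma_{label}$. The defaults
(`radial_offset = 7.5` Å, `sigma_label = 2.6` Å) were calibrated once so
that the reference mapping of full rotamer-library modeling is reproduced:
a CA–CA distribution of (27.0, 8.2) Å at 20-residue separation maps to a
label-label distribution within 0.5 Å of (29.7, 10.8) Å. Note that the
frame-attached offset directions themselves contribute distance variance
(about +1.6 Å in σ at this separation), which is why the calibrated
$\sigma_{conv}$ (3.7 Å) is smaller than the naive quadrature difference
$\sqrt{10.8^2 - 8.2^2} \approx 7$ Å. The surrogate treats the broadening
as site-independent, whereas real rotamer clouds are site- and
conformer-dependent; a plug-in returning per-site clouds can replace it.

## Population fitting

Given restraints with full experimental distributions $P_{DDR,m}$ (unit
sum on their own grids), each conformer contributes a unit-sum broadened
density column, the ensemble prediction is
$P_{pred} = \sum_i p_i P_i$, and the fit maximizes the geometric mean
$\bar o = (\prod_m o_m)^{1/M}$ of the overlaps
$o_m = \sum_r \min\{P_{pred}, P_{DDR}\}$ over the population simplex.
Since $o_m$ is concave and piecewise linear in $p$, the log objective is
concave: the optimum found by projected supergradient ascent (NNLS
initializer, monotone exact-objective line search) is global. On problems
small enough for exhaustive simplex search the solver agrees with the
grid optimum to better than $10^{-3}$ in $\bar o$.

Conformers are processed in blocks of 100 (generation order): fit, prune
conformers below 1% of the maximum population, admit the next block,
refit. When fewer than 10% of the block size are free the block grows by
50%; when the retained count later drops the block resets. Populations of
conformers with identical predictions are non-identifiable — only their
sum is constrained, which is how the package tests the degenerate case.

**Entropy regularization.** Pure overlap maximization tends to sparse
optima (tens of conformers), which reproduce the fitted restraints but
can misrepresent the ensemble at *unfitted* site pairs — visible as
unstable leave-one-out predictions. `fit_populations(entropy_weight = w)`
adds $w \cdot H(p)$ to the mean log overlap ($H$ the population entropy;
the objective stays concave). The default is 0 (the pure objective);
`run_jackknife()` defaults to $w = 0.05$, which in our synthetic studies
trades ~0.03 of $\bar o$ for reweightings spread over most of the basis
and markedly more stable left-out predictions. This is the package's
resolution of the optimum's near-degeneracy, in the spirit of
maximum-entropy ensemble reweighting.

## Weak-order analytics

* `segment_rms()` — population-weighted RMS CA–CA distance for every
  residue pair, each pair assigned to $k = j - i$.
* `fit_scaling_law()` — nonlinear least squares of $b k^\nu$ over all
  pairs in linear space (every pair one point, mirroring the
  scatter-plus-fit presentation; per-$k$-mean fitting is an option).
* `deviation_matrix()` — $\Delta L_{ij}$, the deviation of each pair's
  RMS distance from the mean over its $k$; entries at each $k$ sum to
  zero exactly. Negative = locally compact (blue), positive = extended
  (red). A normalized (relative) variant is an option flag.
* `ensemble_width()` — $\Gamma$, the population-weighted RMS pairwise
  CA-RMSD after Kabsch superposition.
* `radius_of_gyration()` — CA-only, conformers combined in quadrature
  (arithmetic-mean option provided; the choice is a convention, CA-only
  because the models are backbone-level).

## Jack-knife validation

`run_jackknife()` repeats the generate-and-fit pipeline once per
restraint with that restraint left out, predicts the omitted
distribution from the reduced fit, and scores it by overlap with
experiment. A restraint is flagged when its left-out overlap falls below
`median − max(2·MAD, 0.05)` of the *other* restraints' left-out overlaps
— leave-one-out statistics keep one gross inconsistency from inflating
the spread estimate and masking itself, and the absolute floor keeps
very tight sets from producing within-noise flags. (The numeric rule is
an artifact decision; visual judgment is the field's practice.) `build_super_ensemble()` merges the leave-one-out
ensembles (populations scaled by the reciprocal ensemble count, then
renormalized), and `final_refit()` refits the full restraint set on the
merged basis — a strictly larger basis, so fit quality cannot drop.
Everything is seeded deterministically from one master seed (run $m$ uses
`master_seed + m`).

## The synthetic-data module, and what passing tests do not show

`make_ideal_chain_ensemble()` (freely jointed 3.8 Å CA chains) supplies
the analytic null: $\nu \to 1/2$, $R_k \to 3.8\sqrt{k}$, $\Delta L \to 0$.
`make_weakly_ordered_ensemble()` adds controllable weak order by
geometric rescaling of a designated segment (the ground truth stays
analytic: bond length × factor inside the segment) or by two-state
mixing. `simulate_restraints()` and `simulate_trace()` complete the
loop from ground truth to noisy observables; every generator is a pure
function of its arguments and seed.

These fixtures emulate the *statistics* of disordered-chain experiments:
chain connectivity, coil-like distance distributions, rotamer broadening,
multiplicative distribution noise, white trace noise, exponential
background. They do not emulate residue-specific torsion statistics
beyond the five coil classes, side-chain packing, label-site
accessibility, correlated (non-white) spectrometer noise, fractal
background dimensions, or conformer-dependent rotamer clouds. Passing
tests therefore demonstrate internal consistency of the pipeline and its
statistical machinery at desk scale — not that any particular real
protein would yield the same numbers.

## Numerical choices and problem sizes

* Internal units Å and µs; file boundaries use nm (distribution and
  restraint files auto-convert).
* Default grid 0.5 Å from 10–120 Å; normalization by discrete sum, so
  overlaps are sums of bin-wise minima. Synthetic CA-level studies use
  grids from 2 Å to cover short ideal-chain distances.
* Predicted distributions are resampled onto the experimental grid, never
  the reverse.
* Multi-start bounded Levenberg–Marquardt for all distribution-level and
  trace-level fits (5 starts; ties by lowest RMSD, then lowest $\nu$).
* Overlaps are floored at $10^{-6}$ inside the log objective; an
  all-zero-overlap fit returns a diagnostic failure object.
* Density RMSDs are reported on unit-maximum-normalized densities by
  default (`rmsd_convention`), the convention that reproduces the
  magnitude of published fit RMSDs on our ensembles; unit-sum is the
  alternative.
* Test and acceptance runs use 1,000–2,000 conformers for reference-state
  statistics, 150–400 conformers per restrained run, 60–100-residue
  chains, and 5–6 restraints — sizes chosen so a complete run is a
  desk-scale computation while stochastic targets remain stable across
  seeds (checked at three seeds during calibration).

## Known limitations

* The class-based coil library is a calibrated approximation; absolute
  reference-state numbers carry a ~5–10% systematic offset (documented
  above) that a residue-specific plug-in library would remove.
* The label surrogate is site-independent; fits to real data with
  strongly buried or tethered sites would benefit from a true rotamer
  library behind the plug-in interface.
* Under the max-normalized-Gaussian product interpretation of restraint
  rejection, raw bases are hard-truncated near each restraint mean;
  combined with the narrow surrogate broadening this caps achievable
  fitted overlap for very broad experimental distributions well below
  what rotamer-library pipelines report. The entropy option mitigates the
  representativeness consequence but not the ceiling itself.
* Fitting directly to primary time traces, stretched-exponential
  backgrounds, neural-network inversion and two-phase signal separation
  are out of scope.
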