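---
title: "Compartmental T2 orientation dependence: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental T2 orientation dependence: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2orient)
```

## The model

White-matter voxels are modelled as two water pools with distinct
diffusion and relaxation behaviour. For an acquisition entry with
diffusion weighting $b$, unit gradient direction $\mathbf g$ and echo
time $TE$, and a fibre axis $\mathbf n$:

$$S = S_0\left[ f\, e^{-TE/T_{2,i}}\, e^{-b D_{\parallel,i} (\mathbf g\cdot\mathbf n)^2}
 + (1-f)\, e^{-TE/T_{2,e}}\, e^{-b\left[D_{\perp,e} + (D_{\parallel,e}-D_{\perp,e})(\mathbf g\cdot\mathbf n)^2\right]} \right].$$

The intra-axonal pool is a "stick" (zero perpendicular diffusivity); the
extra-axonal pool a "zeppelin" (axially symmetric tensor). Each carries
its own apparent $T_2$. Because the two pools differ strongly in
diffusion anisotropy, varying $b$ and $TE$ jointly identifies the
compartmental $T_2$s — a separation impossible from the $b=0$ decay
alone. Myelin water is deliberately absent: at the shortest echo time
modelled (54 ms) its signal has essentially decayed, which is why no
third pool or exchange term appears. Time-dependent diffusion and
finite axon radii are also out of scope; diffusion timings are fixed
across TE so they never enter the model.

When per-entry B-matrices are supplied (e.g. from gradient-nonlinearity
correction) the projections generalise to $\mathbf n^\top B \mathbf n$
and $\operatorname{tr}(BD)$; with $B = b\,\mathbf g\mathbf g^\top$ the
scalar forms are reproduced exactly (tested to 1e-12).

**Units.** One convention everywhere: $b$ in ms/μm² (1 ms/μm² =
1000 s/mm²), TE and $T_2$ in ms, rates $R_2$ in s⁻¹ with
$T_2\,[\mathrm{ms}] = 1000 / R_2\,[\mathrm{s^{-1}}]$ handled by
`t2_to_r2()` / `r2_to_t2()` only. Angles are degrees at every interface
and radians internally.

## Orientation dispersion (generative side only)

Real single-fibre voxels are not perfectly coherent. The generator can
disperse sub-compartments over a bipolar Watson distribution
$W(\mathbf u) \propto e^{\kappa(\boldsymbol\mu\cdot\mathbf u)^2}$, and —
crucially — each sub-compartment evaluates its own $R_2(\theta_u)$ law
at its own angle to $B_0$. The orientation dispersion index uses the
standard convention $OD = (2/\pi)\arctan(1/\kappa)$ (the source analysis
quotes OD values without defining the mapping; this is the field's usual
choice). The integral is evaluated by a deterministic antipodally
symmetric Fibonacci-lattice quadrature with density weights renormalised
to 1. The default order of 2048 directions keeps every grid entry
within ~0.1% of an 8192-point reference at OD = 0.16 (a 512-point
lattice is accurate to ~0.5% but degrades at small OD where the density
concentrates); the order is configurable and the suite validates it
against a 10⁶-sample Monte-Carlo rejection-sampling oracle.

The *estimation* model deliberately remains a delta fODF with one
effective $T_2$ per compartment: the fitted model captures dispersion
only through the diffusion dimension. This asymmetry is the point of the
dispersion-bias experiment: as OD grows while the fit model stays fixed,
the recovered extra-axonal anisotropy shrinks monotonically
(demonstrated in the acceptance suite at OD ∈ {0, 0.16, 0.32},
SNR = 100). The orientational coherence $p_2$ — the degree-2 Legendre
moment of the orientation distribution — is computed from $\kappa$ for
synthetic data or from the degree-2 rotational-invariant ratio of
supplied fODF spherical-harmonic coefficients (normalised so a delta
gives 1); the exact estimator used upstream of the original analysis is
not printed, so this documented definition is the stand-in.

## Voxel-wise estimation

- **Mono-exponential $T_2$**: nonlinear least squares of
  $S_0 e^{-TE/T_2}$ on the $b=0$ signals, log-linear initialisation,
  $T_2$ bounded to [1, 2000] ms (no bounds are printed for this fit;
  non-decaying series pin the upper bound and are flagged).
- **Compartmental fit**: bounded least squares of the seven parameters
  $(f, D_{\parallel,i}, D_{\parallel,e}, D_{\perp,e}, T_{2,i}, T_{2,e},
  S_0)$ with the published box
  $[0,0,0,0,30\,\mathrm{ms},30\,\mathrm{ms}]$ to
  $[1,3,3,2\,\mathrm{\mu m^2/ms},300\,\mathrm{ms},300\,\mathrm{ms}]$;
  $S_0$ is a seventh free parameter bounded by 10× the maximum observed
  signal since the printed bounds omit it. The optimiser works in
  unit-box coordinates (L-BFGS-B — the standard bounded quasi-Newton in
  base R, standing in for MATLAB's trust-region-reflective; at the
  optimum the estimators coincide) with **three deterministic restarts**
  at normalised 0.5, 0.25 and 0.75. The original description
  ("initialised three times within boundaries") does not give the
  points; determinism was chosen so fits are exactly reproducible.
  Entries are internally sorted into a canonical order so the fit is
  exactly invariant to the ordering of the acquisition table. Estimates
  within 1e-6 of a bound (normalised) raise `hit_boundary`, and such
  voxels are excluded downstream, mirroring the published exclusion.
  A line-search termination at machine resolution (L-BFGS-B code 52)
  from the winning restart counts as converged; iteration-limit exits do
  not.
- **Noise handling**: the generator produces Gaussian, Rician or
  noncentral-chi magnitudes; `rician_correct()` inverts the
  first-moment relation of the noncentral-chi distribution by bounded
  root finding (closed Bessel form for one coil, numeric noncentral-χ²
  moment otherwise), mapping observations at or below the noise floor
  to zero. Fitting is ordinary least squares on (bias-corrected)
  magnitudes; maximum likelihood on complex data is out of scope.
- **SFP selection**: second peak ≤ 10% of the first, first peak ≥ 0.1,
  CSF fraction ≤ 1%; boundary values accepted.

## R2(θ) representations and model selection

All five representation kinds are *linear in their coefficients*, so
pooled fits use (weighted) linear least squares even though the original
analysis used a nonlinear solver — at the optimum the results are
identical and reproducibility improves. Confidence intervals are
t-based with $N-K$ degrees of freedom (the CI construction is not
printed; this is the standard choice). Selection is two-stage:
anisotropic fits whose 85% CI of *any* anisotropy coefficient includes
zero are discarded (the "all coefficients" alternative is available by
argument, since the printed rule does not say how the two-coefficient
form is treated); among survivors within $\Delta AIC \le 2$ of the
minimum, the fewest-parameter fit wins, ties broken by lower AIC and
then the canonical kind order. $AIC = 2K + N\ln(RSS/N)$ exactly as
printed; an RSS of exactly zero yields $-\infty$ and is treated as an
exact interpolant (all such fits get $\Delta AIC = 0$). The anisotropy
magnitude summary is max − min of the fitted curve over θ ∈ [0°, 90°].

On *noise-free* synthetic data the selection stage can prefer an
anisotropic kind whose coefficients are numerically "significant" but
physically negligible (~1e-4 s⁻¹), because the only variation left is
optimizer round-off. Tests therefore assert the flatness of the
selected curve, not its label, in that regime.

## Tractometry and the tilt regression

The core streamline is the pointwise centroid of arc-length-resampled
streamlines, divided into 20 equal-arc-length segments. "Wholly
contained" is interpreted as: the voxel centre projects into the
segment's arc-length bin of the core's tubular neighbourhood (radius
configurable, unlimited by default) — the source text does not define
the region precisely. A voxel additionally must lie within 15° of the
segment tangent (antipodally folded). Segment orientation is the first
eigenvector of the scatter matrix $\sum \mathbf n\mathbf n^\top$.

The tilt-difference regression assumes $R_{2,iso}$ is tilt-invariant and
regresses $y = [R_2^s]_{0°} - [R_2^s]_{18°}$ through the origin on
$x = \sin^p\hat\theta^s_{0°} - \sin^p\hat\theta^s_{18°}$ ($p$ = 2 or 4),
weighted by the mean voxel count of the pair. Endpoint segments (20%
per side, i.e. segments 5–16 of 20) and pairs with fewer than 3 voxels
are excluded. The isotropic alternative ($x = 0$) enters the AIC table
with $K = 0$ and residuals $y$ — the printed comparison includes the
isotropic row without stating its $K$, and zero fitted parameters is the
defensible reading. The test-retest ICC is the pooled-moment form
$ICC = \frac{1}{N s^2}\sum_n (x_{1,n}-\bar x)(x_{2,n}-\bar x)$ with the
pooled mean and variance over both vectors.

## The synthetic world

The generator's defaults *are* the stated simulation conditions:
intra-axonal $R_{2,i} = 12$ s⁻¹ (orientation-independent), extra-axonal
$R_{2,e}(\theta) = 17 + 3\sin^2\theta$ s⁻¹, $f = 0.5$,
$D_{\parallel,i} = 2.5$, $D_{\parallel,e} = 2$, $D_{\perp,e} = 0.8$
μm²/ms, Gaussian noise with SNR = 100 defined on the $b=0, TE=0$ signal
(≈ 46–50 on the shortest-TE $b=0$ image), and coil tilts of 0° and 18°
about the left-right axis, modelled as rotations of the tissue
orientations with the field fixed (equivalent geometry, simpler
bookkeeping). The acquisition grid has 6 TEs spanning 54–130 ms and 9
b-shells {0, 0.5, 1, 1.5, 2, 2.5, 3, 4.5, 6} ms/μm²; only the 54 ms
anchor and the 6 × 9 shape are stated by the source (the remaining
values appear only graphically), so the other values are documented
package defaults, with 30 directions per shell and $b=0$ replicated 3
times per TE so the mono-exponential fit has replicates at every echo
time. Direction sets use a deterministic Fibonacci-sphere lattice
rather than seeded electrostatic repulsion: equivalent angular coverage
with no RNG and no iteration schedule to document.

Desk-scale choices made once and kept: the dispersion-bias sweep uses
10 fibre angles × 12 noisy voxels per OD (the original used the in-vivo
point cloud); the model-selection consistency study uses N = 2000
pooled voxels with θ uniform on [0°, 90°] and σ = 0.5 s⁻¹ over 200
replicates per generating kind (the in-vivo pooled SFP cloud has
thousands of voxels across subjects and tilts); the tract phantom is a
quarter-arc bundle of 9 streamlines whose tangents sweep 0–90°.

What a green suite does **not** establish: the generator contains no
imaging artefacts (no EPI distortion, motion, eddy currents, partial
volume, or spatially varying noise), its fODF is exactly Watson, and
its tilts are exact rigid rotations — so recovery results here bound
what preprocessing-perfect data would give, not what a scanner gives.
Real-data inputs (fODF peaks, CSF fractions, bundle segmentations)
are consumed, not estimated: spherical deconvolution and bundle
segmentation live upstream.

## I/O conventions

Gradient schemes are FSL-style `bval`/`bvec` text files plus a
one-TE-per-volume text file; b-values are s/mm² on disk and ms/μm² in
memory. Voxel data, streamlines and fit tables are plain CSV; configs
and result summaries are JSON. Volumetric neuroimaging containers and
binary streamline formats are intentionally not parsed here — no
suitable reader ships with this package's dependency set, and the
analysis itself is voxel-table-shaped.

## Known limitations

- Crossing-fibre voxels are excluded, not modelled; per-population T2
  in crossings is future work upstream.
- The delta-fODF estimation model makes the recovered anisotropy an
  underestimate whenever real dispersion is present (by design; see the
  dispersion-bias experiment).
- The tilt regression assumes a tilt-invariant isotropic rate; slow
  spatial variations of $R_{2,iso}$ across a segment pair would alias
  into the slope.
- Registration between tilt positions is deliberately avoided (the
  segment pairing is the correspondence); no image-space alignment is
  provided.
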