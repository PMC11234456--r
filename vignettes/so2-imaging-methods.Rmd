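---
title: "Modeling snapshot multispectral imaging of skin SO2: methods and design notes"
author: "msiSO2 maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling snapshot multispectral imaging of skin SO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Microcirculatory blood oxygen saturation (SO2) in skin can be imaged with a
snapshot multispectral camera: a CMOS sensor whose pixels carry 16 different
Fabry-Perot bandpass filters in a repeating 4x4 mosaic, covering roughly 470
to 650 nm. Estimating SO2 from the 16 normalized band intensities of a pixel
is an inverse problem through two physical layers: light transport in skin
(melanin-bearing epidermis over blood-bearing dermis) and the camera system
(complex per-band spectral responses, illumination spectrum, detector
noise). Inverse Monte Carlo fitting — matching measured spectra against a
Monte-Carlo-simulated forward model — is accurate but takes seconds to
minutes per spectrum. This package implements that forward model, the
inverse fit, and a small feed-forward neural network trained on synthetic
spectra from the same forward model, which reproduces the inverse-MC
estimate at a small fraction of its cost and thus enables video-rate SO2
maps.

# The tissue model

Skin is modeled as two layers that share a reduced-scattering power law

$$\mu_s'(\lambda) = \alpha\,(\lambda/600\,\mathrm{nm})^{-\beta},$$

with a Henyey-Greenstein phase function at anisotropy $g = 0.8$
($\mu_s = \mu_s'/(1-g)$). The epidermis (thickness $t_{epi}$, 2.5-490 um)
absorbs through melanin,

$$\mu_{a,epi}(\lambda) = f_{mel}\cdot 39.0\,\mathrm{mm^{-1}}\cdot
(\lambda/550\,\mathrm{nm})^{-3},$$

and the semi-infinite dermis through blood with saturation $s$,

$$\mu_{a,blood} = s\,\mu_{a,oxy} + (1-s)\,\mu_{a,red},\qquad
\mu_{a,derm} = f_{blood}\, c_{VD}\, \mu_{a,blood},$$

where the vessel-packaging factor
$c_{VD} = (1 - e^{-D \mu_{a,blood}})/(D \mu_{a,blood})$ corrects for blood
being confined in vessels of mean diameter $D$ rather than spread
homogeneously. Whole-blood absorption uses bundled oxy-/deoxyhemoglobin
extinction tables converted at 145 g/l hemoglobin ($M = 64500$ g/mol,
$\mu_a = \ln 10\, \varepsilon c / M$, reported in mm$^{-1}$). The bundled
tables are a reconstructed approximation of the standard public
compilations, built from their widely quoted characteristic values (files
are marked `_synthetic`); all estimation in the package is internally
consistent against these same tables, so their small deviations from the
published compilations do not enter any fit residual.

Two printed-formula choices deserve note. The vessel-packaging expression is
implemented in the standard form above — the convention with a *negative*
exponent and $\mu_{a,blood}$ as its argument — because the self-referential
variant (dermal absorption inside its own correction factor) is not
computable and diverges. The seven parameters are carried in mm and mm$^{-1}$
throughout. The stated hematological constants (hematocrit 0.43, 145 g/l
blood, 345 g/l RBC) are internally inconsistent at the percent level
(145/0.43 = 337, not 345); the conversion uses 145 g/l blood, the value that
enters the absorption formula directly.

# White Monte Carlo and the reflectance table

Because both layers share $\mu_s$ and $g$ and the simulation runs with zero
absorption, the transport medium is homogeneous: the layer boundary only
partitions each photon's pathlength into epidermis and dermis shares.
Photons enter as a pencil beam (specular entry loss excluded); Fresnel
reflection at the tissue-air boundary ($n = 1.4$ against 1.0, unpolarized,
sampled probabilistically) governs escape, and every photon exiting the top
surface is detected regardless of position or angle — by reciprocity this
matches wide-field illumination with pixel-wise detection, and the camera's
small acceptance angle is not modeled separately. Photon paths are capped at
400 mm total; with no absorption the capped fraction (about 1-3 percent,
scattering-dependent) is the only loss, it is logged in the table metadata,
and the energy-conservation test accounts for it explicitly.

Absorption is applied after the fact by Beer-Lambert weighting of the stored
per-photon pathlengths, so one transport run per (thickness, scattering)
node fills a 4-D table over $t_{epi}$ (9 log-spaced nodes, 0.0025-0.49 mm),
$\mu_s'(600)$ (9 log-spaced nodes, 1.0-90.5 mm$^{-1}$) and the two
absorption coefficients (24 log-spaced nodes each on $10^{-4}$-$10^2$
mm$^{-1}$ plus an exact zero node). Reflectance is interpolated
multilinearly in log coordinates (the absorption coordinate is
$\log(\mu_a + \mu_{a,min})$ so the zero node participates smoothly), and the
wavelength-dependent $\mu_s'(\lambda)$ queries the scalar scattering axis
independently per wavelength. The package default budget is 20000-30000
launched photons per node; at desk scale this leaves relative node noise of
order one percent, which is shared by every consumer of the table (training
data, inverse fits), so consistency checks between the two estimators are
largely insensitive to it. Tests use a coarser 5x5-node table for speed.

# The camera model and its normalizations

Detected band intensities follow
$I_T[n] = k_n \sum_\lambda r_n(\lambda) F(\lambda) L(\lambda) T(\lambda)$
over the 400-700 nm, 1 nm grid, with $r_n$ the per-band response, $F$ the
filter/polarizer transmission, $L$ the lamp, $T$ the tissue reflectance and
$k_n$ a pixel amplification. White normalization (division by the same
model at $T = 1$) and intensity normalization (division by the 16-band
mean) cancel $k_n$ and every global scale exactly; both invariances are
tested.

Synthetic training spectra add three hardware imperfections: temporal lamp
drift and angular emission deviation, each entering as
$L(1 + q_t\,\delta_{t,max})(1 + q_\theta\,\delta_{\theta,max})$ with
$q \sim U[0,1]$, and a multiplicative detector noise factor with variance
$a_n + I[n]/b_n$. The default deviation spectra place their weight at the
450-460 nm blue LED die with a weak smooth remainder across the phosphor
band, magnitudes up to 5 percent: for white LEDs both warm-up drift and
angular color shift are dominated by the blue-die/phosphor balance, and the
long-pass filter at 470 nm clips much of that region. The default noise
coefficients (0.1 percent floor, 0.5 percent relative SD at half scale)
describe *saved* frames: the acquisition chain averages eight consecutive
raw frames on the fly before anything is stored, so the white recordings
that calibrate the noise model — and the spectra the estimators ever see —
carry the raw shot-noise variance divided by eight. All shapes and
coefficients are configurable inputs, not constants.

Synthesis of one training spectrum follows six steps: draw tissue
parameters and interpolate $T(\lambda)$; draw $q_t, q_\theta$; draw a target
mean intensity $R_I \sim N(I_{max}/2,\,0.2 I_{max})$ truncated to
$(0.05 I_{max}, I_{max}]$ (the untruncated law admits nonphysical values);
scale the noiseless spectrum to $R_I$; draw band noise at the scaled
intensities; apply it. A white spectrum is generated the same way with
$T = 1$ and independent draws — white calibration and measurement happen at
different times and geometries, so coupling their imperfections would
understate the robustness the network must learn — and the ratio is
mean-normalized, giving spectra whose band mean is exactly 1.

The tissue-parameter distribution emulates the spread of real skin:
$t_{epi}$ log-uniform 0.025-0.3 mm; melanin *amount* ($f_{mel} t_{epi}$,
the physiologically varying quantity) log-uniform 2e-4 to 0.01 mm;
$f_{blood}$ log-uniform 0.001-0.1; $s$ uniform 0-100 percent; $D$
log-uniform 0.005-0.3 mm; $\alpha$ log-uniform 1-6 mm$^{-1}$ and $\beta$
uniform 0.5-2.5, rejection-sampled to keep $\mu_s'$ inside the simulated
1.0-90.5 mm$^{-1}$ range. These ranges are declared approximations of
skin-tissue statistics, not fitted values.

# Sensor-response calibration

A tunable narrowband filter (7 nm FWHM) sweeping 400-700 nm in 1 nm steps
gives, per band, 301 linear measurements of the unknown response through
$I_C[n,m] = \sum_\lambda r_n(\lambda) R_m(\lambda)$. The per-band estimate
minimizes the squared residual of the grand-mean-normalized intensities
plus 0.2 times an amplitude-normalized derivative penalty
$\Delta r = (r_{i+1} - r_i)/(0.5 r_i + 0.5 r_{i+1} + \langle r \rangle)$,
subject to $r \ge 0$, via Levenberg-Marquardt with an analytic Jacobian.
Bands couple only through the fixed grand mean, so they are solved
independently. Initialization is a ridge-regularized linear inversion
clipped at zero — the model is linear in $r$, so this lands close and only
the rational smoothness term needs iteration. Stopping: relative tolerance
$10^{-8}$, at most 400 iterations per band; non-converged bands are flagged
and return their best iterate. On synthetic sweeps the estimator recovers
known responses to below 1 percent max-normalized error noise-free and
below 3 percent at 1 percent intensity noise, and dual-peak responses keep
both peak positions within 2 nm; when two peaks have nearly equal
amplitude, their *ordering* can flip within the noise while the positions
stay put.

The detector-noise fit regresses the temporal variance of relative
fluctuations on mean intensity per band. Because a variance estimate
scatters in proportion to its value, the regression is weighted by
$1/\mathrm{var}^2$, and the bundled white-stack fixture records levels from
2 to 70 percent of full scale: the low levels identify the small intercept
$a_n$, the high levels the slope. Lamp variation extraction is pure
arithmetic on the ratio of endpoint spectra, with intermediate spectra
projected onto the maximal-deviation shape to recover their scale $q$.

# The two estimators

**Inverse MC.** Nonlinear least squares on per-band relative differences
$(N_{model} - N_{meas})/N_{meas}$ over the seven parameters within their
validated box (with $s$ extended to $[-0.2, 1.2]$ — estimates are
deliberately not clipped to the physiological range, so that systematic
errors remain visible rather than saturating at 0). The $\alpha$ lower
bound is 1.5 mm$^{-1}$ so that every $(\alpha, \beta)$ in the box keeps
$\mu_s'$ valid across the grid. Cold starts use Latin-hypercube points
(log-mapped for the scale-like parameters): 8 by default, which suffices
when a time series chains each frame's solution as the next frame's warm
start; an isolated cold fit on the fine look-up table benefits from more
(the package's self-checks use up to 64), because Monte Carlo node noise
leaves shallow false optima with residuals of a few hundredths of a
percent. Warm-started frames in a time series run under a small iteration
cap: they start near the optimum, and leaving the solver at a loose stop
reproduces the mild temporal inertia reference solvers show on recordings
instead of amplifying frame noise into parameter scatter. Transport queries are
clamped to the table hull during fitting so the solver can traverse the
full box.

**Network.** A 16-H-1 network (tanh hidden layer, linear output, H in
{5, 10, 15, 20}) maps a normalized spectrum to SO2 in percent. Training is
Levenberg-Marquardt on the flattened weights with the per-sample error
vector as residuals and an analytic Jacobian, on a 70/15/15
train/validation/test split; after every accepted step the validation error
is checked, training stops after 6 consecutive failures to improve
(patience), and the best-validation weights are kept. Initialization is
Nguyen-Widrow-like, adapted to the data: random hidden directions are
rescaled to unit pre-activation spread over the training inputs and
centered at the input mean — the inputs sit near 1, not 0, and without this
centering tanh units start saturated and the optimizer regularly stalls in
poor basins. A brief warm-up (5 candidate initializations, 10 LM steps
each, continue the best) guards individual sessions against the residual
basin lottery; with it, training is stable across seeds. Repeated training
with randomized initialization quantifies estimator stability as the
per-spectrum standard deviation of the predictions across 10 networks.

# Desk-scale study conditions

The package's self-checks run at sizes chosen for a single workstation and
state them explicitly: the reflectance table at 20000-30000 photons per
node (against tens of millions in a production table); training sets of
10000-20000 spectra (the reference workflow uses 50000, and the 70/15/15
split of 50000 — 35000/7500/7500 — is asserted exactly on the split
indices); 10 training repetitions at H = 15; and a 100-frame synthetic
occlusion-release sequence (SO2 sweeping 60 to 0 percent, a reactive
hyperemia peak at 85, return to baseline) as the stand-in for an in-vivo
recording that cannot be shipped. The sequence generator mirrors the
measurement chain rather than the training distribution: a warmed-up lamp
($q_t = 0$ for both tissue and white passes — the stable spectrum is
*defined* as the warmed-up one), one angular draw per recording shared
between the tissue and white passes (the angular deviation spans the
camera's 0-22 degree angle of view, so it is a property of the position in
the field; the white reference is recorded with the same geometry, and at a
fixed ROI the deviation cancels in the white normalization — a misaligned
white recording can be emulated by unsharing the draw), and detector noise
carrying the additional 5x5-pixel ROI averaging. Training data keep full
independent draws per spectrum; the network must be robust to them, while
any single recording experiences one fixed realization.

# What the synthetic tests do and do not show

Every quantitative check in this package closes over its own forward model:
the same reflectance table, response curves and noise laws generate the
data and drive both estimators. Passing therefore demonstrates internal
consistency — the network reproduces the inverse fit, calibration recovers
known responses, the pipeline inverts its own synthesis — under realistic
magnitudes of noise and drift. It does not demonstrate accuracy on real
skin: real tissue contains chromophores beyond melanin and hemoglobin,
layered structure beyond two layers, and sensor behavior (spatial response
variation, nonlinearity near the white-reference operating point) that the
model omits by design. Those limits apply equally to the approach this
package implements; its defense in practice is that the same tissue model
fits measured skin spectra with sub-percent residuals.

# Numerical choices and degenerate inputs

Boxcar resampling uses shrinking windows at the tabulation edges (no
extrapolation). The packaging factor switches to a series expansion below
$D\mu_a = 10^{-6}$. Zero-response wavelengths contribute zero smoothness
residual (guarded division). Demosaicing interpolates each band's own
4x4-subsampled lattice to the block-center grid separably with linear
border extrapolation, which keeps constant and affine images exact; dark
subtraction clips negative intensities at zero and counts them; nearest
dark-frame ties break toward the earlier frame; white-reference pixels with
nonpositive bands are masked with a warning. Noise factors are truncated at
$-0.999$ so intensities stay positive. ROI rectangles are 0-based,
half-open, rows before columns; bands are indexed 1-16 in mosaic row-major
order with the physical assignment configurable.

Persistence uses portable plain-text containers: JSON for the table,
camera models and trained networks (full double precision), CSV for
spectra and training sets, multi-page 32-bit TIFF for hypercubes.

# Known limitations

The reflectance table ignores the camera's finite acceptance angle and any
spatially resolved detection; polarization is not tracked. The per-node
photon budget leaves percent-level table noise that cancels between the two
estimators but would bias comparisons against an external reference. The
bundled hemoglobin tables are approximate reconstructions, adequate for the
package's closed-loop checks but not for absolute spectroscopy. The network
estimators inherit every simplification of the tissue model; on parameter
combinations with very little blood, SO2 is close to unidentifiable from
these 16 bands and both estimators (and their disagreement) degrade
accordingly.
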