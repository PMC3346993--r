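---
title: "Second-order calibration of HPLC-DAD data with trical"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second-order calibration of HPLC-DAD data with trical}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trical)
```

## The problem

A diode-array detector records a full UV--Vis spectrum at every
chromatographic time point, so one injection yields a matrix (elution time
x wavelength) and a set of samples yields a three-way cube. When analytes
co-elute with each other or with matrix components -- the rule rather than
the exception for drugs measured directly in plasma -- univariate peak
integration fails. Second-order calibration replaces the chromatographic
separation by a mathematical one: the cube is decomposed into per-species
elution profiles, spectra and per-sample abundances, and quantification
survives the presence of species that were never in the calibration set
(the *second-order advantage*).

## Model

`trical` fits the trilinear model

$$x_{ijk} = \sum_{n=1}^{N} a_{in}\, b_{jn}\, c_{kn} + e_{ijk},$$

where $x_{ijk}$ is the absorbance of sample $k$ at retention time $i$ and
wavelength $j$; column $n$ of $A$ ($I \times N$) is a species' elution
profile, column $n$ of $B$ ($J \times N$) its spectrum, and $c_{kn}$ its
relative concentration in sample $k$. Trilinearity assumes each species
elutes with the same profile, at the same retention time, in every sample;
shift or shape drift between runs violates the model and is *not* handled
here (no warping or alignment preprocessing is provided). Under mild
conditions the decomposition is unique up to permutation, sign and scale,
which is what makes the resolved $C$ usable for calibration. The package
resolves the scale indeterminacy by normalizing the columns of $A$ and $B$
to unit Euclidean norm so that all magnitude is carried by $C$, and the
sign indeterminacy by orienting each profile to have a positive sum (the
paired concentration column is flipped with it, leaving the reconstruction
unchanged).

## Fitting

Two engines share one contract (`fit_options()`, `LoadingSet`):

* **`parafac_als()`** minimizes the residual sum of squares by alternating
  exact least-squares updates of $A$, $B$, $C$. By default the two
  physical modes are constrained nonnegative (negative elution profiles or
  absorbances are not physical) through an exact row-wise nonnegative
  least-squares solver; $C$ is left free so calibration regression can see
  its unbiased scale. The objective is non-increasing across sweeps, which
  the test suite asserts on the stored fit trace.
* **`swatld()`** updates each mode as the average of two pseudo-inverse
  projections of the corresponding unfolding, column-weighted by the
  inverse squared norms of the partner modes. It typically converges in
  one to two dozen sweeps (versus hundreds for ALS on collinear profiles)
  and its extracted true factors are largely insensitive to an
  overestimated $N$, at the price of not monotonically minimizing a single
  objective. It runs unconstrained by default, as is customary.

Convergence is declared when the relative change in the residual sum of
squares between sweeps falls below `tol` (default $10^{-6}$), or when the
residual reaches $10^{-15}$ of the data's sum of squares -- a floor only
exactly trilinear data can reach. `max_iter` defaults to 2000.

Numerical choices worth knowing:

* Initialization is deterministic by default (leading singular vectors of
  the three unfoldings); random multi-start is available and seeded.
* Constrained ALS runs ten unconstrained sweeps first, orients the signs,
  and only then imposes nonnegativity. Clipping a negatively-oriented
  factor at the first sweep can annihilate it and strand the fit in a
  swamp; the burn-in removes that failure mode. The recorded fit trace
  covers the constrained phase only, so its monotonicity is preserved.
* The row-wise NNLS subproblems are solved exactly by support enumeration
  (vectorized over rows) for up to 10 components, falling back to
  Lawson--Hanson beyond that; the enumeration is tested against
  `pracma::lsqnonneg`.
* Pseudo-inverses use a relative singular-value cutoff of $10^{-10}$.
* If a loading column's norm falls below $10^{-12}$ it is re-randomized
  once; a second collapse aborts the run as degenerate. A corollary: an
  overfactored model of *exactly* noiseless data will abort, because the
  excess factor has nothing (not even noise) to span -- overfactoring
  behavior is therefore exercised at realistic noise levels.
* Alternating least squares works through Gram (normal-equation) matrices,
  which squares the conditioning of the profile matrices. On heavily
  overlapped noiseless profiles ALS parameters are accurate to roughly
  $10^{-5}$ relative; SWATLD's projection updates reach $10^{-7}$. Checks
  that require six significant digits therefore use SWATLD.

## How many components? (`scan_components()`, `corcondia()`)

The core consistency diagnostic compares the least-squares Tucker core of
the fitted loadings with the superdiagonal identity array: near 100 at or
below the true chemical rank, collapsing (often far below zero) once excess
components start interacting. The scan fits *unconstrained* models --
constraints distort the core -- and applies the customary rule: the chosen
rank is the largest candidate scoring at least 50. Two qualifications the
package enforces:

* At $N = 1$ a converged model scores exactly 100 (the scalar core equals
  1 at any ALS stationary point), so that value carries no information.
* Core consistency measures factor *interaction*, not signal: pure iid
  noise yields near-orthogonal factors and scores near 100 at every $N$.
  If even the largest scanned candidate passes the threshold, the collapse
  was never observed and the scan reports the rank as indeterminate rather
  than returning the top of the range.

## Calibration

With calibration and prediction samples (and blanks) decomposed jointly,
`align_factors()` matches factors to analytes by greedy maximal absolute
correlation between resolved and reference spectra (ties broken by column
order; leftover factors -- the interferents -- ordered by decreasing
concentration-loading norm). `score_regression()` then fits
$\mathrm{score} = k \cdot \mathrm{concentration}$ through the origin over
the calibration samples and predictions are $\hat y = \mathrm{score}/k$.
The single-coefficient formulation found in the study literature is
sometimes written with $k$ mapping in the opposite direction and then
applied multiplicatively, which is dimensionally inconsistent; the
through-the-origin regression used here reproduces the intended
proportionality. A one-shot pseudo-inverse route
(`direct_prediction()`, $\hat c = \mathrm{diag}(A^+ X_{un} (B^T)^+)$) is
provided for cross-checking; it requires every species in the unknown to
be modeled in $A$ and $B$, and the two routes agree to six significant
digits on noiseless data.

Report formatting follows the conventions of the determination-study
literature: per-sample recoveries at one decimal place, mean ± sd
(sample sd, $m-1$) as integer percent, RMSEP at two decimal places, all
rounded half-up. RMSEP is computed and reported in concentration units.

## Figures of merit

From the net-analyte-signal framework, with unit-norm loading matrices
including the interferent columns:

$$\mathrm{SEN}_n = k_n\{[(A^TA)^{-1}]_{nn}[(B^TB)^{-1}]_{nn}\}^{-1/2},
\qquad \mathrm{SEL}_n = \mathrm{SEN}_n / k_n,$$

and $\mathrm{LOD} = 3.3\,s_0$ where $s_0$ is the sample standard deviation
of concentration estimates for at least three blank samples. Blanks are
decomposed jointly with the other samples and converted by the same $k$
(the package always documents this route in its report). Selectivity lies
in $(0,1]$ under the unit-norm convention and decreases strictly with
profile overlap; the more spectrally distinct analyte shows higher
selectivity and lower detection limit.

## The synthetic-data generator

No instrument data ship with the package; every analysis is exercised on
simulated cubes whose ground truth is returned alongside the data
(`simulate_cube()`, `paperlike_dataset()`, `rank_study_dataset()`).

What it emulates, and the defaults chosen once for the study conditions:

* Grids: 0--5 min at 1/30 min (151 points) and 200--380 nm at 2 nm (91
  points) -- typical fast-LC/DAD settings. Cube dimensions are free
  parameters of the data model; the algorithms are dimension-agnostic.
* Design: 10 calibration samples spanning a fixed two-analyte grid (5--32
  mg/mL), 6 prediction samples spiked at the published added levels
  (vancomycin 15.15--30.30, cephalexin 10.18--30.54 mg/mL), 3 blanks.
  Interferents never appear in calibration samples -- the second-order-
  advantage scenario. Concentration units are carried as opaque,
  mutually consistent numbers; no unit conversion is performed.
* Peaks: symmetric Gaussians, analyte apices one peak-width apart
  (2.00 and 2.25 min, $\sigma$ = 0.25 min) with the plasma-like
  interferent eluting between them ($\sigma$ = 0.32 min) -- the
  incompletely-separated regime the method exists for. An exponential
  tailing constant is available (broadened peaks tail in practice) but off
  by default.
* Spectra: sums of broad Gaussian bands. The interferent is a broadband
  end-absorber (strong below 230 nm, decaying across the range), which is
  how plasma backgrounds look; cephalexin's spectrum is made the most
  distinct in shape so the selectivity ordering of the two analytes is
  meaningful. The resulting selectivities (~0.05--0.1) sit in the same
  regime as published values for this kind of assay.
* Noise: iid additive Gaussian at 0.5% of the maximum noiseless intensity
  (`noise_sd = 0.005`); published work on such assays is typically silent
  on noise, and 0.5--1% of full scale is a realistic DAD figure.
  Heteroscedastic noise is out of scope.
* Baseline: an optional constant offset, removable exactly (up to noise)
  by `subtract_blank()`.
* A single integer seed determines everything; the caller's RNG state is
  left untouched.

What it deliberately does **not** emulate: retention-time shift or peak
shape drift between samples (trilinearity would be violated; real assays
must verify this before trusting the model), detector saturation,
wavelength-correlated noise, and gradient-elution physics. Passing tests
on these cubes therefore demonstrate correctness of the algorithms under
the model's assumptions, not robustness to violations of them.

## Problem sizes used by the tests

The unit tests run on coarsened grids (typically 60--76 time points by
40--46 wavelengths) where fits take well under a second; the end-to-end
property checks use the full 151 x 91 x 19 study cube across five seeds,
and the rank-scan study uses a 100 x 60 x 16 four-component cube --
sizes chosen so the whole suite completes in a few minutes while keeping
the collinearity structure of the full-resolution problem.

## Known limitations

* No vendor format readers (ChemStation, netCDF/AIA, mzML) -- delimited
  text plus a YAML metadata file only.
* No Tucker3, MCR-ALS, GRAM/DTLD (beyond SVD initialization), no
  split-half or Monte-Carlo rank methods, no weighted or intercept
  calibration, no uncertainty intervals beyond the recovery sd.
* ALS accuracy is bounded by normal-equation conditioning (see above);
  for extreme collinearity prefer `swatld()` or tighten `tol`.
* Iteration counts are recorded in the `LoadingSet` but are data- and
  implementation-dependent; they are not a contract.
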