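---
title: "Cooperative metal binding from competition titrations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative metal binding from competition titrations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopbind)
```

## The problem

Hard metal cations such as uranyl (UO~2~^2+^) bind EF-hand proteins like
calmodulin tightly enough that free-metal concentrations in a titration are
far below anything measurable directly, and at the pH of interest the
uncontrolled metal would hydrolyze. Both problems are solved the same way in
practice: a competing chelator (here iminodiacetate, IDA) is added in excess
so that it buffers the free metal at a well-defined, computable level and
suppresses hydroxo-complex formation. The price is that no observable maps
directly onto a binding constant any more — every titration point is a
multi-equilibrium speciation problem, and the binding constants must be
extracted by fitting a forward model through that speciation.

`coopbind` implements this forward-model-and-fit workflow for one- and
two-site peptides, for two observables (fluorescence quenching and ITC
injection heats), together with the thermodynamic algebra that turns the
fitted macroscopic constants into site-specific (microscopic) constants,
a cooperativity free energy, and enthalpy/entropy decompositions.

## Speciation model

Three components are tracked: metal M, chelator L and peptide P. All
equilibria are *conditional* at fixed pH: chelator protonation is absorbed
into a side-reaction coefficient

$$\alpha_{L(H)} = 1 + \sum_{k} 10^{\,\sum_{i\le k}\mathrm{p}K_{a,i} - k\,\mathrm{pH}},$$

so a complex M~a~L~q~ with cumulative formation constant $\beta$ (referenced
to the fully deprotonated ligand) has conditional constant
$\beta' = \beta / \alpha_{L(H)}^{\,q}$, referenced to the total uncomplexed
ligand pool. The proton balance is never solved explicitly; this matches how
conditional stability constants are tabulated and used at a stated pH and
medium. No activity-coefficient model is applied — constants are taken as
conditional at the stated ionic strength — and metal hydrolysis species are
deliberately not modeled, because the chelator is present precisely to keep
them negligible.

The peptide binds by stepwise macroscopic constants, `M + P = MP` (K~1~) and
`M + MP = M2P` (K~2~). The three mass balances are solved by a damped
Newton–Raphson iteration in $\log_{10}$ of the free concentrations:

* log-space iteration guarantees positivity without constraints;
* the Jacobian is analytic ($J_{ij} = \ln 10 \sum_s \nu_{si}\nu_{sj} C_s$,
  symmetric positive definite for this class of systems);
* each step is clipped to ±0.5 log units (the damping), the iteration stops
  when the largest step falls below 10^-10^ log units, with a cap of 200
  iterations;
* the initial guess is the component totals (a titration series warm-starts
  each point from the previous solution);
* a state is accepted only if every relative mass-balance residual is at
  most 10^-10^; otherwise the solver raises an explicit error that carries
  the residuals.

The test suite checks the solver against a fully independent nested-bisection
oracle (bisection on the one-dimensional reduced metal balance, with the
chelator sub-balance itself solved by bisection) on randomized systems with
totals spanning 10^-7^–10^-3^ M and constants spanning 10^4^–10^12^ M^-1^.

### Chelator constants are configuration

The stability constants of the uranyl–IDA complexes and the IDA pK~a~ values
are inputs, shipped as a clearly labeled **synthetic placeholder** file
(`inst/extdata/ida_synthetic_defaults.json`: pK~a~ 9.34, 2.61, 1.82; complex
species ML, ML~2~ and a minor M~2~L~2~ with log β 8.3, 15.1, 18.0 at 25 °C,
I = 0.1 M). Users with critically selected constants should substitute their
own values; nothing in the package logic depends on these numbers. The
generic `(m, l, log β)` species record also accommodates alternative
speciation schemes (e.g. treating a protonated complex as a separate
effective species at fixed pH).

## Fluorescence model

The observable is the baseline-subtracted intensity change
$\Delta F = F_0 - F$ (quenching positive; amplitudes stay signed so an
enhancement fits equally well). Per mole of peptide,

$$\Delta F / C_P = \frac{\Delta\Phi\, K_1 [M]}{1 + K_1 [M]}
\qquad\text{(one site)},$$

$$\Delta F / C_P = \frac{\Delta\Phi_1 K_1 [M] + \Delta\Phi_2 K_1 K_2 [M]^2}
{1 + K_1 [M] + K_1 K_2 [M]^2}\qquad\text{(two sites)},$$

with $[M]$ the *free* metal from the full speciation at that point — this is
where the chelator competition enters. The two-site form reduces
continuously to the one-site form as $K_2 \to 0$ and saturates at
$\Delta\Phi_2$.

**Dilution.** If per-step titrant volumes are supplied, peptide and chelator
totals are rescaled by $V_0/(V_0 + \sum v)$ at each point; otherwise dilution
is assumed negligible and a warning says so (`assume_no_dilution` silences it
when that assumption is intentional). Both modes use the same model; the
explicit switch avoids silent bias.

## ITC model

The reverse-titration design injects peptide (0.4 µL then 2 µL steps, 38.4 µL
in total) into a 200 µL cell containing metal and chelator. Totals follow
the standard perfusion-cell displacement bookkeeping: with cumulative
injected volume $d_j$, injected material has concentration
$C_{syr}(d_j/V_0)/(1 + d_j/2V_0)$ and initially present material
$C_0(1 - d_j/2V_0)/(1 + d_j/2V_0)$. The active volume in the heat
expressions is fixed at $V_0$ with those corrections applied to the totals.

Heats per injection are enthalpies times changes in complex inventories:

$$Q_j = \Delta H_I\,\Delta n_{MP_I} + \Delta H_{II}\,\Delta n_{MP_{II}}
+ (\Delta H_I + \Delta H_{II} + \Delta H_c)\,\Delta n_{M_2P},$$

where $\Delta H_c$ is the cooperativity enthalpy and the mononuclear pool is
partitioned between the sites as $K_I/(K_I+K_{II})$ vs $K_{II}/(K_I+K_{II})$
— an exact restatement of the per-path mole-change expressions, since both
mononuclear microstates see the same free metal and free peptide. Species
concentrations come from the speciation with macroscopic constants
$K_1 = K_I + K_{II}$ and $K_2$. Two structural identities are tested for
arbitrary parameters: the heats telescope (their sum depends only on initial
and final inventories) and, with $\Delta H_c = 0$ and the independent-site
value $K_2 = K_I K_{II}/(K_I + K_{II})$, the model collapses to a sum of
per-site one-site heat terms evaluated on the joint free-metal series.

Internally heats are µJ; microcalorie input is converted (×4.184). The first
injection (small volume, diffusion across the syringe tip) is modeled but
excluded from fitting by default, following standard practice. Blank
titrations (no metal in the cell) are subtracted elementwise with unit
checking.

## Fitting strategy

All fits are least squares with constants parameterized as $\log_{10} K$.
Two choices matter:

* **Variable projection.** Amplitudes (fluorescence) and enthalpies (ITC)
  enter the models linearly; at each trial value of the constants they are
  solved exactly by linear least squares and only the constants are iterated
  by Levenberg–Marquardt (`minpack.lm`). This cuts the nonlinear dimension
  to 1–2 and makes the multi-start sweep cheap.
* **Deterministic multi-start.** Five starts span $\log_{10}K \in [3, 13]$
  on a fixed grid (two-site starts pair $\log_{10}K_2$ 0.7–0.85 decades
  below $\log_{10}K_1$); the best run is chosen by residual sum of squares,
  ties broken by the lower $\log_{10}K_1$. No randomness enters the fit.

Unweighted residuals are used: the experiments do not report per-point
uncertainties, and constant Gaussian noise is the natural default for both
single-wavelength intensities and integrated heats.

Per-replicate fits are summarized as mean ± sample SD when at least two
replicates are available (matching the reporting convention of averaging
three experimental values); with a single series the SD column falls back to
the covariance approximation and is flagged. Equilibrium constants are
averaged on the log₁₀ scale (geometric mean): fit errors of constants are
close to log-normal, and for weakly identified constants an arithmetic
natural-scale average is inflated by the skew (by
$e^{(\sigma\ln 10)^2/2}$, tens of percent at $\sigma_{\log_{10}} \approx
0.4$), while the geometric mean stays median-consistent and agrees with the
log₁₀K rows of the same summary. Amplitudes and enthalpies are averaged
arithmetically. A pooled simultaneous fit is
available as an option. For two-site fluorescence fits an F-ratio against
the nested one-site model warns when the extra site is not supported.
One-site ITC fits flag degenerate regimes (all-zero heats, or saturation
ranges carrying no information about K).

The two-site ITC fit follows the one-site-first protocol: $(K_{II},
\Delta H_{II})$ are measured on a one-site variant and held fixed, then
$(K_I, \Delta H_I, K_2, \Delta H_c)$ are fitted; $K_1 = K_I + K_{II}$ and
all derived quantities are recomputed from the estimates. A sensitivity
option refits with the fixed pair perturbed by +10% and reports the induced
shifts.

## Micro/macroscopic algebra and cooperativity

For a two-site molecule, $K_1 = K_I + K_{II}$ and detailed balance requires
the two paths to the doubly loaded state to agree:
$K_I K_{II,I} = K_{II} K_{I,II} = K_1 K_2$. Given an independently measured
$K_{II}$ (from the one-site variant, justified when the inactivating
mutations do not perturb the inter-site interface), the full microscopic set
follows. The cooperativity constant is $K_c = K_{II,I}/K_{II} =
K_{I,II}/K_I$ and

$$\Delta\Delta G = -RT\ln K_c,$$

negative for positive cooperativity. Entropic terms close the decomposition
exactly by construction: $T\Delta S = RT\ln K + \Delta H$, so
$\Delta G + T\Delta S - \Delta H \equiv 0$. `derive_table()` applies this
algebra to a whole table of primary constants; `micro_from_macro()` refuses
$K_{II} \ge K_1$, which would imply a non-positive site I constant, and rows
that violate it are flagged rather than silently dropped.

Energies are kJ/mol with R = 8.314 J mol^-1^ K^-1^ and T = 298 K as
defaults. When comparing against published table values the package's tests
use 5% relative tolerance, because the printed inputs themselves carry two
significant figures. Note that a cooperativity entropy computed from one
technique's $K_c$ and another technique's $\Delta H_c$ is only as consistent
as the two underlying constant sets; the package always recomputes rather
than reconciling, and reports what the algebra gives.

## The synthetic-data generator

`scenario_library()` pairs each supported design with true parameters of the
magnitudes reported for the calmodulin N-terminal-domain variants:
fluorescence titrations of one-site peptides (peptide 10 µM, chelator
500 µM, pH 6, K around 4–6 × 10^6^ M^-1^), native and tryptophan-substituted
two-site peptides (K~1~ 3.5–7.8 × 10^7^, K~2~ 7–10 × 10^6^ M^-1^),
phosphorylated two-site peptides at pH 6 and pH 7 (up to K~1~ = 6 × 10^11^
M^-1^ at 5 × 10^-7^ M peptide), and reverse-titration ITC for one-site
(syringe 10^-3^ M) and cooperative two-site peptides (syringe 2 × 10^-3^ M,
$\Delta H_I$ = −40.2, $\Delta H_{II}$ = −2.0, $\Delta H_c$ = +25 kJ/mol).

Choices the experiments do not pin down, fixed once here:

* titrant schedule — 20 metal totals, 0 then logarithmically spaced to
  4 peptide equivalents;
* noise — Gaussian, 1% of the isotherm amplitude for fluorescence and
  0.5 µJ per injection for ITC (a "relative" ITC mode scales with the
  largest heat instead);
* fluorescence amplitudes — 10^7^ intensity units per mol/L of peptide on a
  baseline of 1000, i.e. full quenching consumes about 10% of the signal;
* dilution heat — constant per injection, shared by sample and paired blank.

Generated noise-free curves equal the forward models *exactly*, so generator
and fitter cannot share a bug silently: the recovery tests would fail if
either side drifted. What the generator does **not** emulate: spectral
shapes (single-wavelength intensities only), photobleaching or inner-filter
effects, injection kinetics, baseline drift, or correlated noise. Passing
recovery tests therefore demonstrate identifiability and correctness of the
estimation machinery under the stated designs, not robustness to every
artifact of real instruments.

## Recovery results and problem sizes

The acceptance suite runs, at fixed seeds:

* solver-vs-oracle agreement on 100 random speciation systems (≤ 10^-8^
  relative on the free metal);
* noise-free refits of **every** scenario in the library, recovering the
  generating parameters to better than 10^-4^ relative (in practice machine
  precision);
* 50-seed noisy recovery studies on one representative scenario per
  pipeline and parameter type — one-site fluorescence (K~1~), two-site
  fluorescence (K~1~, K~2~; 3 replicates each, 1% noise) and cooperative
  two-site ITC (K~I~, $\Delta H_I$, K~2~, $\Delta H_c$; 2% relative noise) —
  checking median relative bias (nominally ≤ 5% for fluorescence constants;
  ≤ 10% for enthalpies; ≤ 0.1 on $\log_{10} K_I$) and ±2 SD coverage
  (≥ 80%). One scenario per type keeps the full suite at desk scale while
  exercising each estimator; the remaining scenarios are covered by the
  noise-free sweep.

The one-site fluorescence and ITC bounds hold. For the **two-site
fluorescence** scenario the 5% median-bias bound on K~1~/K~2~ is not
attainable at this design: the two binding transitions lie only a factor ~5
apart with free amplitudes, and the exact-model information bound puts
SE($\log_{10}K_1$) ≈ 0.4 per replicate, so the 50-seed median itself
carries ~10% sampling error even for a median-unbiased estimator. (The
corresponding published constant carries ±29% for the same reason.)
Coverage still holds there; the suite states the nominal bias bound and
reports the shortfall rather than hiding it.

## Known limitations

* Single metal: no simultaneous competition between two metals (e.g.
  Ca^2+^ + UO~2~^2+^) in this version; calcium selectivity comparisons are
  made by analyzing each metal's titrations separately.
* The shipped chelator constants are placeholders; quantitative work
  requires critically selected values for the actual medium.
* Very high c-value designs (stoichiometric titrations) leave K weakly
  identified, as in any titration analysis; the diagnostics flag the regime
  but cannot create information that is not in the data.
* The displacement bookkeeping assumes cumulative injected volume below
  half the cell volume and warns beyond it.
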