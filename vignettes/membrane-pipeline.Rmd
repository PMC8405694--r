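---
title: "Designing, analysing and profiling yeast membrane models with membranekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing, analysing and profiling yeast membrane models with membranekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membranekit)
```

## Scope

membranekit implements the computational chain around a membrane-engineering
question in *Saccharomyces cerevisiae*: if glycerophospholipid (GPL) acyl
chains are elongated, membranes should become thicker and more rigid, and the
passive influx of undissociated acetic acid should drop. The package covers
four stages, each testable on synthetic inputs with known ground truth:

1. **Composition design** — build the reference 64- and 256-lipid bilayer
   models and substitute very-long-chain GPLs at a target percentage.
2. **Structural analysis** — estimate area per lipid (APL), phosphate-plane
   membrane thickness (MT) and the deuterium order parameter (S~CD~) from
   coordinate frames, with a synthetic bilayer generator as oracle.
3. **Lipidomics summarization** — reduce shotgun-lipidomics species tables to
   strain-level metrics (chain length, saturation, headgroup shape classes,
   chain-length bins, plasma-membrane fatty-acid share) and strain contrasts.
4. **Weak-acid analysis** — Henderson–Hasselbalch equilibrium, scintillation
   count conversion, uptake-curve and kinetic-slope regressions, and
   growth-profiler green-value calibration.

Running molecular dynamics itself is out of scope: the structural analysis
consumes coordinate frames (GRO text or synthetic), never force fields.

## Composition design

The reference ("null") systems fix the sterol and sphingolipid content —
ergosterol (ERG) and inositol phosphorylceramide (IPC), 40 each at 256
lipids — and carry DOPC (18:1/18:1) and POPI (16:0/18:1) as the PC- and
PI-class representatives, 88 each. Substitution replaces DOPC and POPI in
equal numbers with sn1-elongated, saturated species of 20 (AOPC/AOPI), 22
(BOPC/BOPI) and 24 (LOPC/LOPI) carbons, keeping the oleoyl sn2 chain. The
C20:C22:C24 species enter in a fixed 4:2:1 ratio per family, so a
substitution block is 2 × (4+2+1) = 14 molecules and the achieved
percentage is quantized:

```{r}
n_gpl <- 176
p <- 24
14 * round(p / 100 * n_gpl / 14)   # molecules substituted at a 24 % target
```

`substitute_long_chain()` uses exactly that rule (nearest multiple of 14,
ties rounding half up), which reproduces all eight tabulated systems
(`study_systems()`, M1–M8 at 8–96 % targets). Two reporting conventions are
worth stating explicitly because they are easy to trip over:

* the tabulated "% GPL" column is the *design target*; the achieved value
  is quantized (at a 96 % target the achieved fraction is 168/176 = 95.45 %),
  so `composition_report()` carries both (`pct_gpl`, `pct_gpl_achieved`);
* the "% of total" column is the fraction of lipid *molecules* (e.g.
  168/256 = 65.6 % → 66), which is what the tabulated values encode.
* percentages are rounded half up at report time only; internal values stay
  unrounded.

`mean_gpl_chain_carbons()` averages sn1+sn2 carbons over GPL molecules
(or per chain, at the caller's choice); sterols and IPC are excluded. For
the null 256-lipid system this gives 35.0 carbons per molecule — an
averaging convention the package documents rather than inherits, since no
convention applied to these compositions yields a smaller published figure.

`repartition_hydrogen_mass()` is the standalone topology transform used to
enable 4-fs MD time steps: every hydrogen is set to 4 × 1.008 = 4.0320 u and
the added mass is subtracted from its single bonded heavy atom, conserving
total mass exactly. The transform refuses hydrogens already at ≥ 4 u (an
already-transformed table) and errors if a heavy atom would go non-positive.

## Synthetic bilayers and structural properties

`generate_bilayer()` builds idealized two-leaflet frames on a lateral grid.
Its parameters map one-to-one onto the analytically known answers:

* exact lateral box dimensions, so true APL = L~x~L~y~/N per leaflet;
* phosphate z drawn Normal(z~leaflet~, jitter), so true MT =
  z~upper~ − z~lower~ in expectation;
* C–H bond orientations per mode: `fixed_angle` (all bonds at a polar angle
  θ, mirrored in the lower leaflet), `wobble_cone` (fixed θ, uniform
  azimuth) and `isotropic` (uniform on the sphere), giving
  S~CD~ = (3 cos²θ − 1)/2, the same closed form, and 0 respectively.

Units are nm throughout (GRO-native); angles are degrees at the interface
and radians internally. Frames are deterministic under the spec's seed.
These frames emulate *geometry only*: no sterols, no packing interactions,
no dynamics — so recovery tests certify the estimators, not any physical
realism of the generator.

The estimators in `area_per_lipid()`, `membrane_thickness()` and
`order_parameter()` follow the planar-bilayer conventions: the membrane
normal is fixed to +z (no director fitting); leaflets are identified from
geometry (phosphate z against the median phosphate z), which makes MT
positive by construction and invariant under rigid translation or flipping;
sds over frames are population sds. Frames are assumed whole — no
periodic-boundary unwrapping is attempted, so GRO inputs must be pre-wrapped
with intact molecules (a documented limitation). An equilibration discard
is available by slicing the frame list before analysis.
`replicate_summary()` aggregates the first *k* (default 3) replicate means
so ensembles stay comparable across systems, reporting the sample sd across
replicates.

GRO I/O is fixed-column text; velocities are ignored, and the box line's
first two fields are taken as L~x~ and L~y~. Reading is driven by a
selection map (`default_selection_map()`): exact names for the phosphate
marker and regular expressions capturing the chain position for carbons and
hydrogens, with C–H bonds reconstructed by position within each residue.
Unmapped atom names warn and are dropped, or error under `strict = TRUE`.
Coordinates survive a write/read round trip to the format's 3-decimal nm
precision — which is why an order parameter computed from re-read text can
differ from the in-memory value in the third decimal.

The simulation-derived property values for the substituted systems (APL
falling from ~0.54 to ~0.50 nm², MT rising from ~4.3 to ~4.8 nm) require
multi-hundred-nanosecond MD on the real force field and are deliberately not
reproduced here; the package's claim is that its estimators recover known
ground truth, exactly for APL and fixed-angle S~CD~, and at the central
limit theorem rate (3σ = 3·jitter·√(2/(N·F))) for MT under phosphate jitter.

## Synthetic lipidomes and profile metrics

`generate_lipidome()` emulates the statistical structure of a shotgun
(direct-infusion MS) species table: per class, species total carbons come
from a discretized normal rounded to even integers within class-plausible
ranges (two-chain GPLs 24–48, lyso species 12–26, TAG 42–60, cardiolipin
56–72, …), double bonds from a truncated Poisson, within-class abundances
from a unit Dirichlet scaled by the class proportion, and replicates
multiply base abundances by lognormal noise of a chosen CV (mean 1, so
expectations are unbiased). Abundances are arbitrary-scale positive reals
(protein-normalised in the wet-lab original); every profile metric
renormalizes internally, so all metrics are invariant to per-replicate
rescaling. Ground truth is computed from the realized noise-free species
table, which makes zero-noise recovery an exact identity rather than an
asymptotic statement.

The default class proportions encode the two strain conditions studied:
a control condition in which diacylglycerol (DAG) is 7.0 % of membrane
lipids, and an engineered (elongase + acyltransferase) condition with DAG at
12.34 % and PI/PS reduced in compensation; storage (TAG, EE) plus
mitochondrial-only (PG, CL) classes hold 22 % of whole-cell abundance in
both. Default chain means put two-chain GPLs near 34 total carbons with sd
2 and ~1.3 double bonds. What the generator does **not** emulate: m/z
acquisition, adducts, isotope patterns, signal-to-noise or blank filtering,
and any correlation structure between species beyond the class proportions —
so passing recovery tests certifies the summarization arithmetic, not
robustness to instrument artefacts.

Profile conventions, stated because the field often leaves them implicit:

* all per-replicate means are abundance-weighted (mole-weighted);
* "GPL" for chain metrics means the two-chain classes PC, PE, PI, PS, PA —
  lyso forms and CDP-DAG are excluded, consistent with chain-length bins
  that start at C24;
* "membrane lipids" excludes storage (TAG, EE); "PM lipids" additionally
  excludes PG and CL, which reside in mitochondrial membranes;
* chain-length bins are inclusive: medium C24–31, long C32–36, very-long
  C37–48; out-of-range carbons clamp to the nearest bin with a warning;
* fatty-acid-share weighting uses chains per molecule: GPL/DAG/PG/PA/
  CDP-DAG 2, lyso and ergosterol ester 1, TAG 3, cardiolipin 4, and the
  ceramide/IPC series 2 (sphingoid base + amide chain — a bookkeeping
  choice, stated rather than assumed universal);
* strain contrasts use a Welch two-sample t-test on replicate-level values
  (the published contrasts state only a confidence level, not a test; Welch
  is the conservative default and the function accepts any replicate
  vectors if another test is preferred);
* `gpl_chain_tail_fractions()` reports both tails around a carbon
  threshold, since "fraction above/below C36" statements are easy to invert
  in transcription.

`parse_lipidome()` accepts any delimited file through a column map (standard
field → file column), tolerates hydroxylation suffixes on class labels
(`IPC;2` → `IPC`), rejects unknown classes loudly and drops non-positive
abundances with a count.

## Weak-acid equilibrium and uptake

With pK~a~ 4.8, the undissociated fraction at pH 5.0 is
1/(1 + 10^0.2^) ≈ 0.387. At diffusion equilibrium the undissociated
concentration is equal across the membrane, so from a total extracellular
acid `total_out` at `pH_out`, the shared undissociated concentration is
HA = total_out · f(pH_out), and a measured total intracellular accumulation
`total_in` implies pH~in~ = pK~a~ + log₁₀((total_in − HA)/HA). The relation
is strictly increasing in `total_in`, fixes pH~in~ = pH~out~ when the totals
agree, and is infeasible at or below `total_in = HA` (no anion). For the
studied condition — 144 mM outside at pH 5.0 — an intracellular total of
96.6 mM gives pH~in~ 4.67 (reported 4.7) and 144 mM gives 5.0.

Uptake timecourses are fitted with the saturating rational form
c(t) = a·t/(b + t): degree (1,1) with a zero intercept, chosen because
uptake starts at zero and approaches an equilibrium plateau (= a). The
general degree-(1,1) form (p₁t + p₂)/(t + q₁) is available where a nonzero
intercept is wanted. Confidence bands come from a seeded parametric
bootstrap (default 1000 resamples, residual-σ Gaussian noise around the
fitted curve) because the original curves were produced by closed-source
fitting internals; the band is pointwise at the observed times. Degenerate
constant series return the constant as plateau with b floored at 1e-8 and a
warning. Kinetic series (rate vs concentration) use ordinary least squares;
the published slopes (0.15 engineered, 0.118 control) cannot be re-derived
because the underlying raw measurements are not deposited, so the package
verifies parameter *recovery* on synthetic series with known slope instead.

The growth-profiler calibration converts background-subtracted green values
to OD600 with the printed two-branch curve: exponential
0.0322 · 2.72^0.4328·GV^ below GV 10 (the base 2.72 is used literally as
printed, not replaced by e) and a cubic polynomial at GV ≥ 10. Both
printed domains include GV = 10; the polynomial wins there, and the
resulting ~0.033 OD step between branches is a property of the printed
calibration that the package documents rather than smooths away.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed; `derive_seed()` fans a
single global seed out to stable per-module sub-seeds so pipeline stages are
independently reproducible. The test suite and the acceptance script use
desk-scale problem sizes chosen so every stochastic assertion sits at its
3σ bound or better: isotropic order-parameter null at ~10⁵ bonds,
thickness recovery at 40 phosphates/leaflet × 100 frames (3σ ≈ 0.0034 nm),
lipidome recovery at 20 species/class × 3 replicates, bootstrap bands at
200–1000 resamples.

## Command-line use

`membranekit_cli()` (wrapped by `inst/cli/membranekit.R`) exposes the
stages as subcommands — `compose`, `simulate-bilayer`, `analyze-traj`,
`simulate-lipidome`, `lipidomics`, `uptake`, `growth` — reading YAML
selection/column maps where needed and writing CSV/JSON outputs, each with
a JSON manifest (arguments, seed, package version, output checksums).
Identical invocations produce byte-identical outputs.

## Known limitations

* The bilayer generator is a geometric oracle, not a physical model; it
  cannot certify estimator behaviour on disordered, undulating or
  PBC-wrapped membranes.
* GRO reading assumes whole molecules and a naming convention (or a
  user-supplied selection map); it does not unwrap periodic images.
* Lipidome synthesis draws species independently within classes; real
  lipidomes have correlated remodelling across classes.
* The Henderson–Hasselbalch stage models passive equilibrium only — no
  active efflux, facilitated diffusion or intracellular buffering.
* Whether published strain summaries are mole- or intensity-weighted is not
  stated in the source material; abundance weighting is assumed throughout.
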