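---
title: "Characterizing disordered conformer ensembles: descriptors, mechanics, knots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing disordered conformer ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyknot)
```

## The problem

Homopolymeric tracts — runs of a single residue such as the polyglutamine
(polyQ) expansions of huntingtin — do not fold to a unique native state.
They populate a broad universe of transient conformations, and questions
about their disease relevance (why does pathology appear beyond roughly 35
glutamines?) become questions about the *statistics* of that universe: how
large and what shape are the conformers, how mechanically stable are they,
how long do they persist, and do they form knots?

`polyknot` implements the full characterization pipeline for such
ensembles: per-conformer structural descriptors, selection of independent
conformers from a trajectory, mechanical stability by coarse-grained
pulling, knot detection and localization, and residence-time statistics.
Conformer generation by enhanced-sampling molecular dynamics is outside the
package's scope; its synthetic generators (`make_ideal()`,
`make_self_avoiding_coil()`, `make_knotted_chain()`,
`make_sieve_fixture()`) produce chains with the structural features the
analysis operators assume, and every operator also accepts real multi-model
PDB input via `read_pdb()`.

## Structural descriptors

For a conformer of $N$ residues the package computes:

* **Radius of gyration** $R_g$: root-mean-square C$\alpha$ distance from the
  centroid (Å).
* **Shape parameter** $w$: with gyration-tensor eigenvalues
  $\lambda_1 \ge \lambda_2 \ge \lambda_3$ and mean $\bar\lambda$,
  $w = \prod_i (\lambda_i - \bar\lambda) / \bar\lambda^3$. The normalization
  is fixed by two closed-form anchors: a thin rod has
  $\lambda = (L^2/12, 0, 0)$ hence $w = 2$; a thin disk has
  $\lambda = (R^2/4, R^2/4, 0)$ hence $w = -0.25$; a sphere gives 0. Positive
  means elongated, negative flattened.
* **Secondary structure** via a compact Kabsch–Sander implementation
  (`assign_secondary_structure()`): the amide H is placed 1 Å from N along
  the preceding C=O direction, a hydrogen bond from CO($i$) to NH($j$)
  requires the electrostatic energy
  $0.084 \cdot 332\,(1/d_{ON} + 1/d_{CH} - 1/d_{OH} - 1/d_{CN})$ kcal/mol to
  fall below $-0.5$. Helix (H) needs two consecutive $i \to i+4$ turns;
  strands/bridges (E/B) follow the parallel and antiparallel bridge rules;
  turns (T) are the residues spanned by 3-, 4- or 5-turns. Only H counts as
  $\alpha$ (no 3₁₀ or π subclasses), E+B as $\beta$, T as turn; `ss_total`
  is their sum with components rounded to 0.1%.
* **Contacts** (`build_contact_map()`): residues $i, j$ with $j - i \ge 3$
  are in contact when any pair of heavy atoms, one from each, has
  overlapping van der Waals spheres enlarged by the factor 1.24. The radii
  are the standard heavy-atom set of the structure-based-model literature
  (sp³ C 1.88 Å, aromatic C 1.76 Å, carbonyl C 1.61 Å, N 1.64 Å, carbonyl O
  1.42 Å, hydroxyl O 1.46 Å, S 1.77 Å). Pairs at $|i-j| = 2$ are excluded
  because in a C$\alpha$-resolved chain they are dominated by covalent
  geometry rather than genuine packing. Synthetic conformers carry backbone
  heavy atoms only; the map records whether it was built in backbone or
  full heavy-atom mode.
* **Mean coordination** $\langle z \rangle$: peptide-bond neighbors (1 for
  chain ends, 2 otherwise) plus contact partners, averaged over residues.
* **Contact order** $CO = \frac{1}{L N_c} \sum_k S_k$ with $S_k$ the
  sequence separation of contact $k$.
* **Maxwell volatility**: a 3D frame of $N$ particles is rigid when
  constraints outnumber degrees of freedom, $N z / 2 \ge 3N - 6$, i.e.
  $z \ge 6 - 12/N$ (`stiff_limit()`). The classical large-$N$ threshold is
  6; a 60-mer needs only 5.8. Conformers strictly below the threshold are
  flagged volatile; a value exactly at the threshold counts as stiff.

## Selecting independent conformers

`run_sieve()` turns a time-ordered trajectory into independent conformers in
three stages, with all thresholds overridable:

1. **SS sieve**: keep frames with secondary-structure content strictly above
   30%. (The strict inequality at the boundary is a deliberate convention
   and is recorded in the result's parameters.)
2. **Time clustering**: split the surviving frames wherever the gap between
   successive structured frames exceeds 50 ps; each cluster is represented
   by its highest-SS member, earliest frame winning ties.
3. **Structural independence**: greedy leader clustering of the
   representatives in temporal order — a representative is kept when its
   optimally superposed C$\alpha$ RMSD to every previously kept conformer
   exceeds 2 Å. Leader clustering extends a sequential
   consecutive-representative comparison to the full set deterministically,
   which is why it was chosen over all-pairs alternatives.

The pipeline is monotone (`independent <= clusters <= structured <= frames`)
and invariant to a constant time offset. `independence_kinetics()` fits the
cumulative count of independent structures against time; on short
trajectories this accumulation is linear and the slope measures
conformational innovation per unit time.

## The structure-based pulling model

Mechanical stability is probed with a C$\alpha$-resolved structure-based
(Go-type) model built from each conformer's own contact map
(`build_go_model()`):

* native contacts get 12-6 Lennard-Jones potentials
  $V(r) = \varepsilon[(r_0/r)^{12} - 2 (r_0/r)^6]$, depth $\varepsilon$ and
  minimum exactly at the native C$\alpha$ distance $r_0$, so the native
  conformation has energy $-\varepsilon N_c$;
* consecutive C$\alpha$s are tied by stiff harmonic bonds at native lengths;
* each quadruplet of consecutive C$\alpha$s carries a harmonic penalty on
  the signed chirality
  $C_i = [(v_i \times v_{i+1}) \cdot v_{i+2}] / d_0^3$
  about its native value, which encodes local backbone handedness;
* all remaining pairs with $|i-j| \ge 3$ repel below $\sigma = 4$ Å
  (truncated, shifted 12-6). Keeping repulsion off the $|i-j| = 2$ pairs
  preserves the exact native-energy identity, because the overlap contact
  criterion guarantees every non-contact pair at $|i-j| \ge 3$ sits beyond
  4.66 Å.

Units are reduced: energy $\varepsilon$, length Å, time $\tau$ (about 1 ns
physically), mass 1, $k_B = 1$; forces in $\varepsilon$/Å convert to pN by
the calibration $\varepsilon = 110$ pN·Å (`eps_to_pN()`). Dynamics is
velocity-Verlet with a BAOAB Langevin thermostat at $T = 0.3\,
\varepsilon/k_B$, friction $2/\tau$, timestep $0.005\,\tau$. With the
thermostat off the integrator is symplectic; the test suite verifies energy
drift below $10^{-4}\,\varepsilon$ over $10^5$ steps (at a finer
$5 \times 10^{-4}\,\tau$ step, the appropriate regime for a conservation
check) and equipartition at $T = 0.3$ within 10%. The unspecified companion
parameters (bond stiffness 100 $\varepsilon$/Å², chirality stiffness 1
$\varepsilon$, spring constant 0.12 $\varepsilon$/Å²) follow the
established values of this model family and are all overridable through
`go_params()`.

**Pulling** (`pull_constant_speed()`): one terminus is tethered to a fixed
harmonic anchor, the other to a spring whose anchor retreats at
$v_p = 5 \times 10^{-3}$ Å/$\tau$ along the initial end-to-end axis. The
measured force is the moving-spring extension along that axis times the
spring constant, boxcar-averaged over 1 Å of displacement; the run ends
when the end-to-end extension reaches 95% of the contour length (a tight
knot can make that unreachable, in which case the run stops after the
anchor has travelled the full contour length plus 20 Å).

**Peaks** (`detect_force_peaks()`): local maxima of the averaged curve
whose height *and* topographic prominence exceed the thermal noise level of
0.1 $\varepsilon$/Å, after an additional 3-sample running mean. Peak heights
are absolute forces, not heights above a local baseline — the descriptive
remark that unstructured curves hover around 0.4 $\varepsilon$/Å is not
used algorithmically. The terminal monotone rise toward full extension has
no local maximum and is never counted. $F_\mathrm{max}$ is the height of
the largest peak, zero if there is none; $n_p$ the peak count.
`unfolding_scenario()` reports, per contact, the displacement at which its
C$\alpha$ distance last exceeded 1.5 times the native value (monitored
during the pull itself, so transient re-formation is handled exactly).

## Knots

Open chains are classified by closure statistics
(`classify_knot()`): the chain is first simplified by KMT reduction
(`kmt_reduce()` removes any interior vertex whose elimination triangle no
other segment crosses; segments sharing a triangle vertex are excluded from
that test since they can only touch at the shared corner), then closed 64
times through a sphere of radius $10 R_g$ — both termini extended radially
from the centroid, joined via a random sphere point — and each closure is
classified by the Alexander-invariant pair
$(|\Delta(-1)|, \mathrm{odd}(|\Delta(-2)|))$ computed from a generic planar
projection's crossing matrix. The pair separates everything in scope:
unknot $(1,1)$, trefoil $(3, \cdot)$, figure-eight $(5, 11)$, $5_1$
$(5, 31)$, three-twist $5_2$ $(7, \cdot)$; anything else reports "other",
as does a tied vote. Majority voting over closures makes the open-chain
call robust and deterministic per seed.

`knot_core()` localizes the knot by bidirectional trimming: residues are
removed one at a time from the N-terminus while the remainder still
classifies to the original type, then likewise from the C-terminus; the
surviving span $[k_-, k_+]$ has extension $\Delta k = k_+ - k_- + 1$.
Trimming order (N first) is a convention and is stated in the report.
`untying_under_stretch()` pulls a knotted model once per seed and counts
the runs whose *final* conformation classifies as the unknot (transient
mid-pull untying is ignored), reporting the untied fraction with its
binomial standard error.

Planted-knot generators: the trefoil, figure-eight and $5_1$ chains
resample the classical closed parametric curves at 3.8 Å arc spacing; the
$5_2$ chain embeds the closure of its minimal braid word
$\sigma_1^3 \sigma_2 \sigma_1^{-1} \sigma_2$ smoothly in an annulus, a
construction whose closed-curve invariants are verified in the test suite.
The closed curve is opened at its most peripheral point and straight tails
are appended radially, so the cut can never land inside the tangle. The
recorded ground-truth core is the span of interior vertices that KMT cannot
remove — a localization route independent of the trimming estimator it is
used to test. Knot types beyond this table (slipknots, composites, links)
are out of scope.

## Life span

`rmsd_series()` tracks the superposed C$\alpha$ RMSD of a free-dynamics
trajectory against its first frame. The residence time $t_R$ is the last
sampled time at or below 2 Å; a trajectory still inside the threshold at
the end of the run is censored. ("Last time below" and "first time finally
above" describe the same exit event; the implementation computes the last
sampled time at or below the threshold.) The escape probability $P_e(t)$ is the fraction
of conformers that left before $t$, with censored conformers kept in the
denominator — it is an escape fraction, not a Kaplan–Meier survival
estimate. The free-dynamics runs here use the coarse-grained model, and both statistics accept any
externally computed RMSD series, so all-atom traces can be analyzed
unchanged.

## Ensemble statistics

`characterize_ensemble()` combines descriptors, pulling (median
$F_\mathrm{max}$ over a configurable number of seeds; the default is the
median over 3 pulls, which suppresses the occasional thermally washed-out
run without averaging away genuine peaks) and knot
classification into one table, plus: the zero-peak fraction and knotted
fraction with bootstrap standard errors (2000 resamples), and the
$F_\mathrm{max}$ histogram (0.2 $\varepsilon$/Å bins over
[0, 3] $\varepsilon$/Å) in which zero-peak conformers are not drawn but
count toward normalization. `length_scan()` assembles per-length rows and
fits the two growth laws: $\chi_F(n) = a \ln(n/b)$ for the fraction of
mechanically stable conformers, and $F^M_\mathrm{max}(n) = c\, n^d$ for the
set maximum, by nonlinear least squares with a log-linear fallback when the
residuals vanish (a zero-residual fit is exactly log-linear, and `nls`
refuses it). `independence_cdf_gap()` computes
$\sup_{a,b} |F_{xy}(a,b) - F_x(a) F_y(b)|$ over the sample grid;
`correlation_screen()` is the companion least-squares screen. The
homopolymer utilities use the uniform-composition null $(1/20)^L$
(`tract_null_probability()`), with the exponent equal to the full tract
length $L$ — the convention consistent with the long-tract probabilities
the package reproduces.

## What the synthetic generators do and do not emulate

The generators supply exactly the features the operators consume: ideal
helices and hairpins with genuine hydrogen-bond geometry (for the secondary
structure and contact operators), self-avoiding coils with fixed 3.8 Å
bonds (for RMSD, clustering, shape statistics), knotted backbones with
known type and core (the cross-module oracle for the topology code), and
trajectories with planted cluster structure (for the sieve). They make no
claim of thermodynamic realism: coil statistics are not Flory-correct, no
side chains are built (contacts run in backbone mode on synthetic chains),
and sequence effects are absent. Consequently, green tests demonstrate
that the *operators* are correct on structures with known ground truth,
not that any particular biological ensemble has particular statistics;
applying the pipeline to real ensembles requires real conformers via
`read_pdb()`.

## Numerical choices and problem sizes

Tolerances and sizes used in the shipped tests were chosen to keep the
whole suite at a few minutes on one CPU while leaving each check
statistically meaningful: energy conservation over $10^5$ steps at
timestep $5 \times 10^{-4}\,\tau$; equipartition over $2 \times 10^5$ steps
of a 16-residue hairpin; pulling contracts on 16-residue chains (a full
pull is ~2 million steps); untying comparisons on 35-residue knotted
chains with 4 seeds per construction; knot-classifier exactness on
200-vertex closed curves over multiple projections; coil-independence
statistics over 60 seed pairs. Degenerate inputs are contracts, not
accidents: zero contacts make contact order an error (not 0), an empty
ensemble cannot be written, an unknotted chain has no core, and a
gyration tensor of coincident points is an error rather than NaN.

## Known limitations

* Only the first chain of a PDB file is read; mmCIF is unsupported.
* The Kabsch–Sander implementation assigns H/E/B/T only; G, I and
  solvent-related DSSP columns are absent by design.
* The Alexander pair cannot distinguish knots outside the implemented
  table; rarer types in a real ensemble would report "other".
* Pulling forces are comparable across conformers at the simulated speed
  but are not extrapolated to experimental loading rates.
* The acceptance materials report desk-scale quantities (unit conversions,
  thresholds, closed-form recoveries, planted-construction statistics);
  ensemble-scale statistics of real polyQ systems require externally
  generated conformers, which the package analyzes but does not produce.
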