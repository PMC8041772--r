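---
title: "Models and methods behind dgcswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dgcswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgcswitch)
```

`dgcswitch` analyses how a dimeric, receiver-domain-controlled diguanylate
cyclase is switched on. This vignette documents the models, their
assumptions, the defaults and the numerical choices, in enough detail that
a user can judge what a passing test does and does not demonstrate.

## The kinetic model

DGC dimers condense two GTP molecules into one c-di-GMP. The model has
three ingredients:

1. **Rapid-equilibrium substrate binding.** The two active sites of the
   dimer bind substrate independently with dissociation constant $K_d$
   (μM). The probability that a product-free dimer is doubly loaded — the
   only catalytically competent species — is
   $f(S) = \left(\frac{S}{K_d+S}\right)^2$.
2. **Turnover.** Competent dimers produce product at $k_{cat}$ (s⁻¹),
   consuming two substrates per product.
3. **Kinetic product binding.** Product binding to the allosteric
   (I-site) pocket is *not* at equilibrium: an effective second-order rate
   $k_{on}$ (μM⁻¹s⁻¹) converts active dimers into an inhibited pool, and a
   first-order $k_{off}$ (s⁻¹) releases them. The inhibitory constant is
   the derived quantity $K_i = k_{off}/k_{on}$. Because $k_{off}$ is slow,
   inhibition lags behind the initial burst — the signature biphasic shape
   of activated-enzyme progress curves. The model deliberately collapses
   the four physical product sites of the dimer into one effective site;
   this affects the nominal value of $K_i$ but not the shape of the model.

With $P_{syn}$ the total synthesised product and $I$ the inhibited pool,
the state equations reduce to two ODEs; substrate and active enzyme are
eliminated algebraically ($S = S_0 - 2 P_{syn}$, $A = E_0 - I$), which makes
both conservation laws exact rather than approximate, and keeps the system
small. Enzyme-bound product is subtracted from the free product that drives
further binding ($P = P_{syn} - I$); with $E_0 \ll S_0$ this is a small
correction, but conservation requires it. Whether the inhibited pool can
still bind substrate is unobservable under this scheme (it cannot
catalyse), so only the active/inhibited split is tracked.

Units are fixed package-wide to μM and seconds. Typical assay conditions
are 5 μM enzyme dimer and 500 μM GTP, and these are the defaults used
throughout the tests.

### Integration

The burst-to-plateau transition is stiff when $k_{on} P E_0 \gg k_{off}$,
so integration uses `deSolve::lsoda` with relative tolerance $10^{-8}$ and
absolute tolerance $10^{-10}$ μM. Integrator failure raises an error
carrying the last valid time rather than returning a truncated curve.

### Global fitting

`fitProgress()` minimises the unweighted joint residuals of all curves
(product series plus substrate series when observed) with
Levenberg–Marquardt (`minpack.lm`). Choices that matter:

- **Log-space parameters.** All four constants are fitted as logarithms,
  which enforces positivity without active box constraints. A parameter is
  pinned (including to zero, which log-space cannot represent) by
  collapsing its bounds, e.g. `bounds = list(kon = c(0, 0))` for an
  uninhibited reduced model.
- **Shared parameters.** Any subset of `{kcat, Kd, kon, koff}` can be tied
  across curves for global fits, e.g. one $k_{cat}$ for several variants.
- **The kcat–Kd valley.** At $S_0 \gg K_d$ the product $k_{cat} f(S_0)$ is
  well determined but $k_{cat}$ and $K_d$ separately sit in a narrow,
  curved, nearly-flat valley, with a genuine secondary minimum at large
  $K_d$. The optimiser therefore runs twice — directly, and staged with
  $K_d$ held at its guess before being released — takes the better
  deviance, and then restarts iteratively from the winner (each restart
  resets the trust region) until the deviance stops improving. Tolerances
  are deliberately tight (`ftol = ptol = 1e-13`, forward-difference step
  `epsfcn = 1e-10`): looser settings stall on the valley floor with
  parameter errors of several percent.

Standard errors come from the residual variance and the LM Hessian
approximation in log space, mapped to the linear scale as
$\mathrm{se}(\theta) \approx \theta\,\mathrm{se}(\log\theta)$. They are
honest only near a well-conditioned optimum; in the kcat–Kd valley they
mostly report the valley's flatness.

## Structural geometry

**Torsions.** Dihedrals follow the IUPAC convention (cis = 0°,
trans = 180°) and every angle or difference is wrapped to (−180°, 180°].
φ is undefined at the first residue, ψ/ω at the last, and all three across
chain breaks (consecutive C–N distance ≥ 2.0 Å) or missing backbone atoms
(logged, not fatal).

**Hinge detection.** A hinge is a residue whose |Δφ| or |Δψ| reaches the
threshold while the flanking backbone stays quiet (mean |Δ| in a ±4-residue
window ≤ 30°). The defaults — threshold 90°, flank window 4, flank max
30° — are chosen to isolate a single large outlier against a quiet
baseline, which is exactly the geometry of a localised inter-domain hinge;
they would under-report distributed conformational changes.

**Superposition and rigid-body rotation.** Superposition is least-squares
Kabsch via SVD with reflections excluded; Cα atoms are used unless the
caller selects otherwise, and residues missing from either conformer are
dropped pairwise with a logged count. The rigid-body rotation of a moving
segment is computed by superposing the conformers on the fixed segment and
extracting the residual rotation of the moving segment; the angle comes
from $\mathrm{tr}(R) = 1 + 2\cos\theta$ and the axis from the antisymmetric
part of $R$ (eigenvector route near 180°), with the sign chosen so the
rotation is ≤ 180°. Only the rotation computation on *given* segment sets
is provided — the package does not search for rigid-domain decompositions.

**Forward kinematics.** `applyTorsionChanges()` rotates everything
kinematically downstream of the edited bond rigidly about that bond, so
bond lengths and angles are preserved exactly and the re-measured torsion
equals the original plus the edit. Edits compose invertibly; applying the
negated edits in reverse order restores the input to numerical precision.

**Coordinate files.** PDB files are read with `bio3d`; mmCIF with a
minimal `atom_site` reader (model 1, ATOM records, whitespace-tokenised).
Altlocs keep the highest occupancy (ties by label order), hydrogens are
dropped, and insertion-coded residues stay in file order after their base
number.

## Coiled-coil register analysis

Helix axes are fitted by sliding 4-residue Cα centroids (one helical turn,
which cancels most of the wobble) followed by a principal-component line
fit. Knob contacts use the minimum heavy-atom side-chain distance (Cα for
glycine) between a residue and the hole neighbourhood (±3 residues) of its
symmetry mate, with a 4.5 Å default cutoff for knobs-into-holes packing;
the tighter 3.2 Å default of `interchainContacts()` is a separate setting
aimed at the receiver-domain dimer interface.

Heptad assignment enumerates all 7 phases for the two candidate patterns
({a,d} and {a,e}) and minimises violations. A 4-3-4 contact spacing fits
{a,d} in a shifted frame exactly as well as {a,e} (formally d′-a′-d′-a′),
so the package adopts the convention that the *first contact residue sits
at position a*, which makes the two registers distinguishable and matches
the field's labelling of native (a-d-a-d) versus activated (a-e-a-e)
states. If no phase is violation-free the best assignment is returned
flagged `non-canonical` rather than raising.

The lateral shift between two states superposes helix 1 of both states and
measures the mean Cα displacement of helix 2: its norm (total shift), its
projection on the helix-2 axis (axial component), and the change in mean
azimuth of helix 2 about its own axis relative to the inter-axis direction.
A register switch by pure translation gives a large shift with azimuth
change near zero; rolling helices would show the opposite. The 15°
azimuth threshold separating the two regimes is generous relative to the
<1° measured on ideal translated geometry.

Helical nets use the coiled-coil periodicity of 3.5 residues/turn (rise
1.5 Å, surface radius 2.3 Å), so residue i+7 sits exactly one heptad higher
at the same circumferential position — an ideal 3.6 residues/turn lattice
cannot have that exact property, and the net is a register diagram, not a
geometric model.

## Linker census

Linkers run from the KP motif of the receiver β5–α5 loop to the DxLT motif
at the GGDEF start. The length convention — K of KP inclusive to D of DxLT
exclusive, `length = dxlt - kp` — is fixed here and stated in all outputs;
the alternative end-to-start conventions shift every length by a constant
and leave the mod-7 structure untouched. Anchors: DxLT is D-x-L-T with x
any residue; the pair is the first DxLT preceded by a KP, with the last
such KP. Sequences with (S/N)PLT instead of DxLT form the divergent group
0 (different linkage, likely different activation mechanism) and are
excluded from length clustering. Sequences without an anchor pair are
rejected with a reason code, never dropped silently.

The redundancy filter is greedy in input order (deterministic and
idempotent): a sequence is kept only if its global-alignment identity to
every kept sequence is below the threshold (default 80%). Identity is
matches over alignment columns excluding terminal gap runs, with match +1,
mismatch 0, gap open −10, extend −0.5 (`Biostrings::pairwiseAlignment`).
A greedy filter was chosen over clustering because the upstream input
order is meaningful (first-seen representatives survive) and the result is
reproducible without tie-breaking rules.

Length clustering smooths the histogram with a ±1 triangular kernel
(weights 1-2-1), takes local maxima with raw count ≥ 5 as modes, and
assigns members to the nearest mode within ±1. The modal spacing is the
most common difference between adjacent modes — the quantity that comes
out as 7 for heptad-quantised linkers. Logos are anchored at the DxLT end
(right-justified), so column −j of every group is the same distance from
the anchor and groups differing by whole heptads align column-wise; gap
positions are excluded from the frequencies, which sum to 1 per non-empty
column.

Slippery-repeat scoring uses the last two heptads of the linker with the
phase convention that the e position of the final repeat sits at offset −3
from DxLT (a at −14/−7, d at −11/−4, e at −10/−3). Each register sums a
versioned propensity table (`inst/extdata/coil_propensity_v1.tsv`):
hydrophobics high at a, small polars (Ala/Ser/Asn/Thr) moderate at d/e,
proline strongly negative. A window viable in both registers (both scores
≥ 3 by default) is flagged ambiguous — the sequence signature of a binary
register switch. The table is a coarse classifier built from residue-class
reasoning, not a trained model; scores are comparable within, not across,
table versions.

## Synthetic data: what it emulates, and what it does not

Every generator returns the data together with the planted truth, and all
recovery tests compare against that truth. Fixed seeds make outputs
byte-identical, and per-replicate sub-streams mean extending a dataset
never changes earlier entries.

- `genProgressCurves`: model curves plus additive Gaussian noise clipped
  at zero. Real online ion-exchange assays also have baseline drift,
  calibration error and correlated residuals; none of that is emulated, so
  fit-recovery tests demonstrate estimator correctness, not robustness to
  instrument artefacts.
- `genHingedConformers`: ideal-geometry backbones (N–CA 1.458 Å, CA–C
  1.525 Å, C–N 1.329 Å, ω = 180°) with a seeded ±3° torsion wobble and a
  single planted ψ change applied by forward kinematics. Both conformers
  share every other torsion exactly, so hinge recovery is exact by
  construction; real conformer pairs add coordinate error and distributed
  small changes.
- `genCoiledCoil`: parametric helices (rise 1.5 Å/residue, 3.6
  residues/turn, Cα radius 2.3 Å) related by a twofold axis, with
  pseudo-side-chain knobs placed radially, and state 2 a pure axial
  translation of helix 2. There is no supercoiling and no side-chain
  rotamer realism.
- `genLinkerDataset`: stub–KP–linker–DxLT–stub sequences with leucines at
  a-phase positions (anchored one heptad before DxLT), group lengths
  spaced by 7, length jitter −1/0/+1 with probabilities 0.15/0.70/0.15
  (small enough that the planted length stays the histogram mode), and
  point mutations at 10% by default. Randomised positions exclude P and T
  so no spurious KP/DxLT/(S/N)PLT anchor can arise by chance — real
  sequences of course contain both letters, which is why anchor location
  keeps explicit multi-match rules.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data:
progress curves of ~100–200 time points over 20–60 min of reaction time,
backbones of 50–150 residues, 21-residue coiled coils, and censuses of 75
to 600 sequences (6 groups × 100 at the largest, 20 seeds for the
stability check). These sizes were chosen so each analysis runs in seconds
while leaving the statistics (peak detection, CLT checks, seed-stability
fractions) comfortably away from their thresholds.

## Known limitations

- The kinetic model fixes one effective product site and no explicit
  conformational transition step; fitted $K_i$ values are effective
  constants, not microscopic ones.
- Hinge detection reports isolated torsion outliers only; distributed
  hinges or compensating φ/ψ pairs within one residue need the full
  difference profile.
- No automatic rigid-domain segmentation: segment sets are caller-supplied.
- The census consumes pre-identified Rec-GGDEF sequences; domain detection
  (HMM searches) and database-dependent absolute counts are out of scope
  by design.
- The mmCIF reader covers standard single-model `atom_site` loops;
  exotic quoting or multi-datablock files should go through PDB format.
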