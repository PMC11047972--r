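---
title: "Branch confidence and artifact detection in neuron reconstructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch confidence and artifact detection in neuron reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroconf)
```

## The problem

Automatic neuron tracers (APP2 and its relatives) turn a 3D fluorescence
stack into an SWC tree quickly, but the result is rarely usable as-is:
branches get traced into noise, attached to the wrong parent, dropped
entirely, or cut short. Proofreading every branch by hand erases most of the
speed advantage. `neuroconf` scores every branch of a reconstruction with a
*connection confidence* and classifies suspicious branches into five
artifact categories, so a human proofreader only has to look where the tool
points. The intended workflow is iterative: detect, fix the flagged
branches, re-run, until only clean (white) and user-confirmed (fuchsine)
branches remain.

## The model

The reconstruction is decomposed into branches (maximal paths between
branching points) and each branch into *branching segments*: directed
pieces of fixed arc length `L`, resampled at unit spacing, anchored at a
branching point. The growth of a child branch depends on its parent branch
and on nothing else — a Markov property over parent–child segment pairs —
so the tree is a union of simple chains, and each link can be scored
independently.

A connection between a parent segment $A$ and a candidate segment $s$ costs
energy

$$U(A, s) = \alpha\,|\Delta I| + \beta\,|\Delta\sigma| \quad (\theta < 90^\circ),
\qquad U = \infty \quad (\theta \ge 90^\circ),$$

where $\Delta I$ and $\Delta\sigma$ are the differences in mean intensity
and intensity standard deviation sampled along the two segments (trilinear
interpolation, normalized by the image full-scale value so both terms are
commensurate), and $\theta$ is the angle between the segment directions.
The three features are exactly the ones that discriminate real parent–child
pairs in whole-brain mouse data: intensity similarity, intensity-spread
similarity, and a branching angle below 90 degrees (reverse growth is not
observed). Absolute differences keep the energy non-negative, which the
probability rule below requires.

The probability that $A$ connects to the current candidate $B$ competes
against every other segment whose minimum endpoint distance to $A$ lies
strictly inside $(0, T_d)$:

$$P(B \mid A) = 1 - \frac{U(A,B)}{Z(A)}, \qquad
Z(A) = \sum_{s \in S} U(A, s),\quad S = \{s : 0 < \mathrm{dist}(A,s) < T_d\} \cup \{B\}.$$

Two consequences of the strict lower bound deserve emphasis. First, every
segment sharing an endpoint with $A$ — in particular all co-children at the
same branching point — is excluded from $S$; the current candidate is added
back explicitly. Second, when $S = \{B\}$ the formula forces $P = 0$: an
isolated but correct branch is penalized. We implement the formula as
stated (with one exception: if every finite energy is exactly zero, the
probability mass is split uniformly), and mitigate the isolation problem by
drawing the candidate universe from *all* consecutive branch segments plus
skeleton endpoint segments, so in practice a segment almost always has
competitors. Infinite-energy candidates are excluded from $Z$ (otherwise
every finite candidate would be certain) and receive $P = 0$.

Each branch gets a global confidence `PG` (its proximal segment given the
parent's distal segment), a local confidence `PL` (each consecutive segment
given its predecessor, aggregated by the mean so `PL` stays in $[0,1]$; the
literal sum is available via `pl_sum = TRUE`), and

$$\mathrm{Confidence} = \min(\mathrm{PG}, \mathrm{PL}).$$

Branches below the threshold `tau` are marked low-confidence.

### Why `tau = 0.3`

With the competition form of $P$, a correct connection among $k$ equally
plausible candidates scores $1 - 1/k$; the commonest case is $k = 2$
(a bifurcation with one genuine competitor), which scores exactly 0.5. A
threshold at 0.5 would flag the median *correct* branch. `tau = 0.3`
corresponds to "the current candidate needs more than twice the energy of
its average competitor", which is the regime where a connection is really
suspicious. The parameter is exposed and can be raised for stricter audits.

## Skeleton branches: evidence from the image

Artifacts that involve *unreconstructed* signal (missing branches,
premature stops, reroutes onto interfering structures) need evidence from
the image itself. The pipeline is: percentile-truncated gamma enhancement
(`gamma = 0.6`, window 1–99.5 percent) to lift weak branches; fixed-threshold
binarization at `mean + k*sd` of the enhanced volume; topology-preserving
3D thinning (sequential simple-point border peeling over six directional
subiterations, validated by component/cycle preservation, idempotence and
fixed 1-voxel curves); multi-scale Frangi vesselness (scales 1, 1.5, 2
voxels, mask at 5 percent of the maximum response); removal of a 1.5×
inflated soma ball (vesselness is unreliable in the soma halo); then point
filtering — keep points that are tubular (a point or any of its 26
neighbors in the mask; the strict "all neighbors" reading would reject
every surface point of a thin tube), have 1–2 skeleton neighbors (dropping
isolated noise and branching points), and lie farther than `d_cover` from
every reconstructed node. Survivors are linked into undirected chains via
the 26-adjacency graph; near-collinear fragments with endpoint gaps up to 5
voxels are merged (thinning plus junction removal routinely splits one tube
into fragments), and chains shorter than 4 voxels are discarded as residual
noise.

Two defaults here differ from the obvious first choice and were set by
measurement on the synthetic study conditions. The binarization multiplier
is `k = 2`: after gamma enhancement the noise floor is lifted, and
`k = 0.5` binarizes roughly a quarter of the volume, which contradicts the
requirement that binarization isolate neuronal branches; `k = 2` matches
the volume actually occupied by tubular structure. Both `k` and the minimum
chain length are exposed parameters.

The enhancement is a percentile-truncation surrogate with the same
interface and intent (boost weak signal monotonically) as
derivative-truncated gamma transforms from the literature; the exact
derivative-based truncation-point selection is not reproduced.

## The five detectors

All detectors reduce to energy comparisons over a shared candidate set
(shared $Z$ cancels), plus a *connection legality* test for any link that
would bridge a gap: with $g$ the gap vector, the angles (current direction,
$g$), ($g$, candidate direction away from the gap) and (current direction,
candidate direction) must all be at most 90 degrees.

* **Over-tracing** (global, transitive): the branch meets its parent at
  $\theta \ge 90^\circ$, or fewer than 70 percent (inclusive) of its nodes
  are tubular. The two cases are disjunctive — the printed conjunction in
  the defining formula contradicts the accompanying description of "two
  distinct cases", and the disjunction is the only reading under which
  either case can fire. The 90-degree boundary is harmonized with the
  energy function (the boundary itself is illegal).
* **Branch–skeleton connection error** (global, transitive): some legal,
  tubular skeleton segment within $T_d$ of the parent's distal segment
  connects to the parent with higher probability than the current child —
  the child was traced onto an interfering structure while the true
  continuation remains in the image.
* **Branch–branch connection error** (local): a misconnection attaches a
  branch into the *interior* of another branch, creating a spurious
  branching point at which one "child" is simply the host's own
  continuation. The detector requires that signature: a co-child that
  continues the parent within `theta_cont` (15 degrees, measured over a
  doubled segment length so direction jitter averages out) and beats the
  current child's connection probability. The unrestricted comparison
  against every branch within $T_d$ fires on noise-level energy
  differences between two legitimately connected branches (10–20 percent
  of clean branches in measurement) and is deliberately not used.
* **Branch missing** (local, per skeleton chain): a tubular skeleton chain
  whose endpoint approaches a reconstructed branch within `D`, connects to
  it legally (both orientations of the host polyline are admissible — a
  side branch may sprout against the storage direction), is not better
  explained as the continuation of another skeleton chain, and is longer
  than such competitors. The host is the branch whose polyline comes
  closest.
* **Incomplete tracing** (local, terminals): a tubular skeleton chain
  endpoint strictly within `D` of the terminal tip, legally connectable —
  the tube continues where the tracer stopped. The gap must also be the
  chain's closest approach to the reconstruction: a chain that hugs a
  branch interior is missing-branch evidence, which resolves the overlap
  between the two categories (incomplete tracing is the terminal special
  case of a missing branch; for the same reason, interior missing-branch
  evidence may override a gap hint on the same host).

Branches are processed breadth-first from the soma. Over-tracing and
branch–skeleton errors are transitive: descendants inherit the label and
are not re-examined (an artifact in the parent invalidates the whole
subtree). Precedence within a branch is over-tracing, then branch–skeleton,
then branch–branch, then incomplete tracing; skeleton chains already used
as reroute or gap evidence are not re-used as missing-branch hints.
Remaining unlabeled branches below `tau` are marked low-confidence.
User-confirmed branches are skipped entirely.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `L` | 8 | voxels | branching-segment arc length |
| `alpha`, `beta` | 0.5, 0.5 | – | energy weights (intensities pre-normalized) |
| `Td` | 20 | voxels | candidate window for the partition sum |
| `D` | 10 | voxels | skeleton-connection gap bound (strict) |
| `tau` | 0.3 | – | low-confidence threshold |
| `d_cover` | 3 | voxels | reconstruction coverage distance |
| `d_match` | 2 | voxels | evaluation match distance |
| `theta_cont` | 15 | degrees | continuation signature bound |
| `binarize_k` | 2 | sd units | binarization threshold multiplier |
| vesselness scales | 1, 1.5, 2 | voxels | Frangi scale sweep |
| soma inflation | 1.5 | – | soma-removal radius multiplier |

`L` is a free choice (the model only requires "fixed length"); 8 voxels is
long enough for stable directions and intensity statistics at micrometer
resolution and short enough to stay inside one branch. Parent and child
segments use the same `L`.

## The synthetic testbed

`synth_config()` / `make_fixture()` generate the study conditions: a
recursive bifurcating tree in a 128³ voxel volume (soma at the center, as
in soma-centered crops of whole-brain images), branch lengths 18–30 voxels,
per-child deflection drawn in 20–60 degrees (the measured sub-90-degree
branching statistics, with a margin below the continuation threshold),
per-step direction jitter of 3 degrees, child intensity = parent intensity
plus zero-mean Gaussian noise (sd 8 on an 8-bit scale) emulating
parent–child intensity similarity, Gaussian-profile tubes of radius 1.8
voxels, a brighter soma ball, 2 interfering tubes of unrelated intensity
(60–220) from "other neurons", and additive Gaussian background noise
(mean 12, sd 4). Everything draws from a single seeded stream in a
documented order, so fixtures are bit-reproducible from the configuration
alone.

Each injector corrupts the reconstruction (never the ground truth) with
exactly one artifact: a spurious branch into background or at a reverse
angle; a terminal rerouted onto a dedicated interferer passing near its
branching point (the true tube stays only in the image); a child reattached
into the interior of a nearby foreign branch; a deleted subtree; a terminal
truncated by 30–60 percent. The injection record carries the ground-truth
site, and `match_injection()` / `injection_cleared()` score a detection
report against it.

What the generator does *not* emulate: optical point-spread anisotropy,
depth-dependent attenuation, Poisson shot noise (available but off by
default — the Gaussian model keeps tests deterministic at fixed seeds),
soma-adjacent halos beyond a simple bright ball, and the axial staircase
artifacts of anisotropic sampling. Passing the fixture suite therefore
demonstrates the mechanics of the method under controlled conditions, not
performance on real whole-brain data.

## Evaluation metrics

`precision_recall_f1()` counts distance-matched nodes (a node matches when
its nearest counterpart lies within `d_match`, 2 voxels by default, the
conventional tolerance for node-level neuron-distance scoring);
`esa_dsa_pds()` reports the mean bidirectional nearest-node distance (ESA),
the mean over nodes farther than the threshold (DSA, 0 when there are
none — not NaN), and the fraction of such nodes (PDS). Distances are
node-to-node, not node-to-edge, and ESA averages both directions, which
makes it symmetric. Self-comparison of any reconstruction gives
precision = recall = F1 = 1 and ESA = DSA = PDS = 0 exactly.

## Numerical choices and degenerate inputs

Angles use a clamped arccos (no NaN at numerically parallel vectors).
Segment resampling drops duplicated vertices and clamps the last sample to
the polyline end. A sole-candidate set yields $P = 0$ (formula-forced, see
above); an all-zero-energy set splits mass uniformly; an all-infinite set
yields 0. Ties in the misattachment search are broken by node-id order;
branch ids are assigned breadth-first in node-id order, making every pass
deterministic. Empty reconstructions produce empty reports; empty trees in
the evaluation module warn and return the 0/NA conventions stated in the
function documentation.

## Problem sizes

The default test suite runs 100 injected fixtures (seeds 0–99, one
artifact each, cycling through the five kinds), 20 clean fixtures, a
convergence re-run per injected fixture against the corrected
reconstruction, 1000 randomized partition-identity checks and 100
oracle-equivalence scenes — sizes chosen so the full suite completes in
roughly a quarter hour on a single core while still estimating detector
sensitivity to within a few percent.

## Known limitations

The energy function carries no geometric term below 90 degrees, so two
candidates with similar image statistics are indistinguishable regardless
of geometry; misconnections between branches of near-identical intensity
are invisible to the model by design. Detection quality degrades when a
missing branch hugs its sibling within the coverage distance (its skeleton
evidence is partially swallowed), and a rerouted branch onto an interferer
of closely matching intensity may be reported as over-tracing instead (the
label disagrees, the flag still points at the right place). Radius
information is ignored throughout (reconstructions are compared with radii
set to 1), and the tool never edits topology — it only flags.
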