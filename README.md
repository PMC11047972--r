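# neuroconf

Branch-confidence artifact detection for neuron reconstructions.

Automatic neuron tracers turn a 3D fluorescence stack into an SWC
morphology quickly but unreliably: branches get traced into noise
(over-tracing), attached to the wrong parent (connection errors), dropped
(branch missing), or cut short (incomplete tracing). `neuroconf` scores
every branch of a reconstruction with a connection confidence derived from
a Markov-chain model of parent–child branching segments and labels
suspicious branches with one of five artifact categories, so a human
proofreader only inspects what the tool flags — an iterative detect–modify
workflow that converges to a clean reconstruction.

## The model in brief

The tree is cut into branches and each branch into directed, unit-resampled
*branching segments* of arc length `L`. Connecting a parent segment *A* to
a candidate *s* costs

```
U(A,s) = α·|ΔI| + β·|Δσ|   if θ < 90°,   ∞ otherwise
```

(differences of mean intensity and intensity SD sampled from the image
along the two segments; θ the angle between their directions). The current
child *B* competes against every segment within distance `Td` of *A*:

```
P(B|A) = 1 − U(A,B) / Z(A),    Z(A) = Σ_{s∈S} U(A,s),
S = {s : 0 < dist(A,s) < Td} ∪ {B}
```

Each branch receives a global confidence `PG = P(child | parent)`, a local
confidence `PL` (per-segment chain along the branch, averaged), and
`Confidence = min(PG, PL)`. Detectors compare these probabilities against
alternatives recovered from the image itself: the volume is enhanced
(truncated-gamma), binarized, thinned with a topology-preserving 3D
algorithm and filtered by Frangi vesselness to extract *skeleton branches* —
tubular signal absent from the reconstruction — which serve as evidence for
reroutes, missing branches and premature stops.

## Worked example

```r
library(neuroconf)

# a synthetic 128^3 stack with a ground-truth tree and one injected artifact
fx  <- make_fixture(synth_config(seed = 8), kind = "BRANCH_MISSING")
rep <- classify_branches(fx$recon, fx$volume)
rep
#> <artifact_report> 29 branches, 3 skeleton branches
#>   BRANCH_MISSING             1
#>   NONE                       28

subset(rep$branches, label != "NONE")
#>    branch_id          label        PG        PL confidence low_confidence inherited evidence_kind evidence_id p_current
#> 15        15 BRANCH_MISSING 0.9328873 0.8552051  0.8552051          FALSE     FALSE      skeleton           3 0.8259178

write_outputs(rep, "out")   # out_annotated.swc, out_skeleton.swc,
                            # out_incomplete.marker, out_report.json
```

The deleted subtree was recovered from the image as skeleton branch 3 and
attached to host branch 15: the branch the proofreader should revisit. In
the annotated SWC the label is encoded in the type code (255 white = clean,
260 red = over-tracing, 261 yellow = branch–skeleton error, 262 blue =
branch–branch error, 263 green = branch-missing host, 264 = low
confidence, 256 fuchsine = user-confirmed); incomplete-tracing positions go
to the marker file.

Comparing a reconstruction against a reference:

```r
m <- compare_reconstructions(fx$recon, fx$truth)
str(m[c("precision", "recall", "f1", "esa")])
#> List of 4
#>  $ precision: num 1
#>  $ recall   : num 0.963
#>  $ f1       : num 0.981
#>  $ esa      : num 0.27
```

A thin command-line front end (`inst/cli/neuroconf`) exposes `detect`,
`simulate` and `evaluate` subcommands over these functions.

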