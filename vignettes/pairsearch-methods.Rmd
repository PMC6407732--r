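---
title: "Models and methods behind pairsearch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pairsearch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsearch)
```

pairsearch analyses paired visual search with *shared gaze*: two people
search the same 5x5 array of elements while each sees, in real time, an
outline around the hexagonal cell their partner is currently looking at.
The package covers the full chain from raw binocular gaze samples to the
coordination statistics that distinguish collaborating from competing
pairs, together with an agent-based simulator that generates ground-truthed
recordings so that every stage can be tested without human data.

## The search array

The display is a 5x5 hexagonal grid: 25 cells whose centres are 4.6
degrees of visual angle apart, each cell a regular hexagon with a
flat-to-flat diameter of 4.6 degrees, so the cells tile the array exactly.
Coordinates are display-centred degrees, x rightward and y downward; cells
are indexed 0-24 row-major from the top left, putting the middle cell (id
12, where searchers start each trial and where the target never appears) at
the origin.

Pixel-degree conversion uses the arc-length (radian) form
`deg = px * mm_per_px / distance_mm * 180 / pi` by default, under which the
1040-px stimulus square spans 25.8 degrees at a 65-cm viewing distance on
the 473-mm / 1680-px monitor; an exact-arctan variant is available via
`method = "arctan"`.

Three conventions were genuinely open and are fixed here as package
choices:

* **Orientation and offset.** Cells have vertical left/right edges
  (flat-to-flat along the horizontal neighbour direction); rows 1 and 3
  (0-based from the top) are shifted right by half the spacing, and the
  vertical row pitch is `4.6 * cos(pi/6)`.
* **Array extent.** With the middle cell centred, the offset rows of a
  hexagonal tiling necessarily reach about 13.8 degrees from the centre,
  slightly past the 12.9-degree half-width of the square stimulus bitmap;
  all cells remain comfortably inside the physical screen
  (about 41.7 x 26.1 degrees), which is the extent the package checks.
* **Borders.** `assign_hex()` resolves points on a shared border to the
  cell with the nearest centre, and exact ties to the lower id, so
  assignment is deterministic and testable.  Points inside no cell return
  `NA` ("outside").

## The online gaze marker

During a paired trial, each display frame outlines the cell the partner is
looking at.  `highlight_stream()` replays the rule: at each frame time `t`
the valid samples in the trailing half-open 30-ms window `(t - 0.03, t]`
are binocularly averaged, assigned to cells, and the modal cell wins.  When
every sample indicates a different cell, a saccade is assumed to be in
flight and the newest sample's cell is outlined.  Modal ties with repeated
cells are not covered by that pair of rules; the package breaks them toward
the cell whose supporting sample is most recent, which reduces to the
saccade rule when all counts are one.  An empty window holds the previous
frame's highlight (none at trial start), and samples outside every cell do
not vote.

`flicker_metric()` summarises visualised measurement error: highlight runs
shorter than 50 ms, which the viewer experiences as flicker, divided by all
stimulus frames.  A run of exactly 50 ms is not flicker; comparisons carry
a 1-ns tolerance so that frame-interval rounding cannot flip the boundary
case.

## From samples to events

Fixation detection is a dispersion (I-DT) pass over the binocularly
averaged signal: maximal runs whose bounding-box extent stays within 1.0
degree and that last at least 60 ms become fixations with centroid
positions; invalid samples split runs.  The published clustering-based
detector used for the original recordings is deliberately not
re-implemented - it is an external method, and every downstream analysis
consumes only fixation tables - so all event functions equally accept an
externally produced fixation table with `onset`, `offset`, `x`, `y`.

Dwells merge consecutive fixations on one cell; an outside fixation is
dropped but still breaks the merge, so a cell revisited across an outside
excursion yields two dwells.  Transitions are consecutive (non-outside)
fixation pairs on different cells, with amplitude the distance between the
bounding centroids.  Dwell rate is visits per second of search time
(stimulus onset to the trial-ending response); since "elements inspected
per second" could also be read as unique cells, a `unique_hex_rate` variant
is reported alongside.

Precision metrics (RMS sample-to-sample distance and positional SD) are
computed within fixation episodes and averaged across them, on the
binocular average.  Averaging two eyes with independent isotropic noise of
sd `sigma` per axis gives a per-axis sd of `sigma / sqrt(2)`, so the SD
metric `sqrt(var_x + var_y)` recovers `sigma` itself on binocular data and
`sigma * sqrt(2)` on monocular data; tests exercise both identities.  A
half-sample margin at episode boundaries keeps the first sample after a
saccade out of the episode.

## Coordination metrics

**Dwell overlap.**  A dwell overlaps when its cell was already shown as the
partner's marker before the dwell began - operationalised from the
highlight log (what the participant could actually see), not from the
partner's true dwells, with runs of 50 ms or less excluded as flicker.

**Cumulative overlap.**  Per participant and trial, the proportion of the
25 cells that both the participant (own dwells) and the partner
(qualifying highlight runs) have begun inspecting strictly before each
frame time.  The curve therefore starts at 0 at stimulus onset and is
non-decreasing, reaching 1 only if both searchers covered the whole array.
`aggregate_overlap_curves()` averages per-trial curves over the trials
still running at each time point and attaches a seeded 95%
percentile-bootstrap band (1,000 iterations by default, resampling whole
trials).

**Blind baseline.**  Expected joint performance of two non-interacting
searchers, built from their individual trials: trials are greedily matched
in order of occurrence on target location, and each artificial trial takes
the response and reaction time of the faster member.  Ties go to
participant A; unmatched trials are dropped.  For iid exponential
individual reaction times with mean `mu`, the baseline mean converges to
`mu / 2`, which the tests verify.

**Entropy.**  Two measures characterise scanning order.  The
dwell-distribution entropy `H_d = -sum p_i log2 p_i` (maximum `log2 25 =
4.64` bits) captures how evenly dwells spread over the array.  Transition
entropy comes in two variants because the field's printed formula and its
quoted maximum correspond to different quantities: the conditional form
`-sum_i p(i) sum_j p(j|i) log2 p(j|i)` (destination unpredictability given
origin, maximum `log2 24 = 4.58` bits) and the joint form over ordered
pairs (maximum `log2 600 = 9.23` bits).  `transition_entropy()` returns
both; they obey `joint = conditional + H(origin)`, which the tests check
against brute-force summation at 1e-12.

**Performance.**  Median reaction time, error rate, and targets found per
second; the last is defined here as correct trials over summed search
time, folding the speed-accuracy trade-off into one efficiency figure.
Overlooking is flagged when a searcher dwells on the target and then visits
two or more other distinct cells before the response.

## Statistical conventions

All non-time-series summaries use boxplot statistics with linearly
interpolated quartiles (type 7 - the convention is fixed so printed
quartiles are reproducible), whiskers to the most extreme points within
1.5 IQR fences, and outliers listed individually.  Paired comparisons use
the Wilcoxon signed-rank test (mid-ranks, zeros dropped from the test,
exact p for 25 or fewer non-zero differences without ties, otherwise
normal approximation with continuity correction) with the dominance effect
size `PS_dep = n+ / N`, where `N` deliberately counts all pairs including
zero differences.  Omnibus comparisons use Kruskal-Wallis with `eta^2`
obtained by mapping the chi-square p-value to the `(1 - p)` quantile of
`F(k - 1, N - k)` - the residual-df convention adopted here since the
source transform names no df - and `eta^2 = F df1 / (F df1 + df2)`.  With
no residual degrees of freedom the effect size is reported as `NA` rather
than a fabricated value.

## The synthetic paired-searcher generator

`simulate_pair()` runs two agents on a shared clock.  Each agent visits
elements under a scanning policy, spends one or more truncated-normal
fixations per visit (default mean 0.25 s, sd 0.05 s, floor 0.06 s -
plausible search fixations), and, once it fixates the target, reports it
after a 0.35-s identification-plus-motor delay unless it overlooks it
(default miss probability 0.1, which produces occasional revisit trials).
Saccades are instantaneous relocations: the analyses use no saccade
kinematics, only amplitudes, so modelling in-flight samples would add
nothing the pipeline consumes.  Gaze samples are emitted at 120 Hz with
independent isotropic Gaussian noise per eye; the default per-eye sd of
0.21 degrees makes the RMS sample-to-sample distance of the binocularly
averaged signal about 0.30 degrees, the precision class of the remote
eye trackers this emulates.  Element positions are jittered within their
cells anew each trial (uniform magnitude up to 0.805 degrees per axis,
random sign); area-of-interest assignment always uses the fixed hexagonal
cells.

Coupling consults the partner's highlighted-so-far set (first fixation
onset plus the 30-ms window) at each element decision.  The condition
defaults encode the study conditions as policies:

* *collaborate* - both agents raster their own column-half from opposite
  corners and always skip cells the partner has highlighted
  (`avoid_partner_prob = 1`): an idealised division of labour.
* *compete* - both agents scan unsystematically, jumping to a random
  not-yet-self-inspected tile, restricted to competitor-fresh tiles only
  half the time (`avoid_partner_prob = 0.5`), with slightly shorter
  fixations (0.22 s).  A nearest-frontier competitor was rejected as the
  default: greedy frontier coverage from distinct corners is emergent
  division of labour and produces collaborate-like zero overlap, whereas
  competing searchers are characterised by unsystematic, hard-to-predict
  scanning with overlap between the collaborate and blind levels.  The
  random-fresh-tile policy reproduces exactly that signature
  (near-maximal transition entropy, intermediate overlap).
* *blind* - independent serpentine rasters from neighbouring corners,
  ignoring the partner: two non-interacting searchers.

After exhausting unvisited elements agents revisit in itinerary order,
matching the observation that searchers continue into each other's sides
late in trials.  The trial ends at the first response; the other stream is
truncated there.  Responses click the target cell, or with probability
0.02 a neighbouring cell (an error rate of a few percent, typical of this
task).  All randomness flows from one integer seed per trial; sessions
derive per-trial seeds from a master seed, so re-runs are bit-identical.

What the generator does *not* emulate - and hence what passing tests do
and do not show about real data: smooth saccade trajectories and blinks
(validity flags exist but default to valid), clock drift and latency
jitter in the streamed samples, learning or strategy drift across trials,
verbal or extra-gaze communication, and any score-driven adaptation.
Quantities that depend on human idiosyncrasy (the study's absolute
medians) are treated as qualitative orderings, not targets: simulated
collaborate < compete < blind in dwell overlap, raster < random-walk in
transition entropy.

## Numerical choices and degenerate inputs

* Threshold comparisons at the 50-ms flicker boundary carry a 1e-9
  tolerance; runs of exactly the threshold duration count as real.
* `assign_hex()` uses the analytic hexagon-containment test with closed
  boundaries; ties break toward the nearest centre then the lower id.
* Entropy terms use the convention `0 log 0 = 0`; all-zero count vectors
  and empty transition matrices are errors (`undefined metric`), as are
  precision metrics on fewer than two valid samples and overlap on zero
  dwells.
* Bootstrap bands and `percentile_bootstrap()` are seeded; constant data
  give zero-width intervals.
* The pipeline (`run_pipeline()`) isolates per-trial failures: a corrupt
  trial is logged with its message in the failure table and the remaining
  trials are analysed.

## Problem sizes

The test suite simulates 100 trials per condition for the ordering checks
(the per-condition trial count of the emulated design), 10,000 matched
trials for the blind-baseline convergence check, and roughly 10,000-sample
streams for noise-recovery checks; the entropy oracles run on 100 random
small matrices.  These sizes make the stochastic checks stable at fixed
seeds while keeping a full run of the suite around a minute of CPU.

## Known limitations

The dispersion detector is a stand-in with different noise robustness than
clustering-based detection; on low-quality data its fixation boundaries
will differ, which is why external fixation tables are accepted
everywhere.  The agent policies are plausible instantiations, not fitted
models of human strategy - the competitor policy in particular is one
reasonable reading of "seeking fresh tiles".  Entropy estimates from few
trials are downward-biased (no bias correction is applied, matching the
source analyses), and the overlap measures inherit the 60-Hz frame
quantisation of the highlight log.
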