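---
title: "Calling genomic inversions by mining paired-end alignment signatures"
author: "InversionMiner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling genomic inversions by mining paired-end alignment signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(0)
```

## The problem

An inversion is a balanced structural variant: a genomic segment whose
orientation is reversed relative to the reference. Because no sequence is
gained or lost, read depth — the workhorse signal for deletions and
duplications — is nearly uninformative. What an inversion does leave
behind, in mapped paired-end data, is a characteristic constellation of
alignment anomalies concentrated around its two breakpoints:

* **same-strand read pairs** — when exactly one mate of a pair falls
  inside the inverted segment, the mapper places it at the mirrored
  position on the *opposite* strand, so the pair ends up both-forward or
  both-reverse instead of the usual opposite-strand configuration;
* **discordant insert sizes** — the observed distance between mates
  (ISPE, the insert size of paired-end reads) is distorted when one mate
  is reflected across the segment;
* **soft-clipped reads** — a read straddling a breakpoint aligns only on
  one side of it, with the remainder clipped;
* **one-end-unmapped pairs** — end-to-end mappers often fail entirely on
  breakpoint-straddling reads, leaving one mate unmapped;
* secondary channels: unique versus multiple placement (`XT`/`XA` tags),
  edit distance (`NM`), and the mapping-quality profile.

Single-signal callers exploit subsets of these signatures and disagree
with one another in practice. The approach implemented here treats their
*combination* as a classification problem: take candidate sites from
several existing callers, count fifteen signature features in a window
around each candidate's breakpoints, and let a support vector machine
trained on simulated inversions decide which candidates are real.

## The procedure

### Feature windows

For a region with breakpoints $(b_l, b_r)$, features are counted over the
window $[\max(1, b_l - \overline{ISPE}),\, b_r + \overline{ISPE}]$, where
$\overline{ISPE}$ is the library's mean insert size estimated from
concordantly oriented pairs (`estimateLibraryStats()`, pairs with
$0 < \mathrm{TLEN} < 10\,000$; the cap excludes chimeric artifacts).
One insert size of padding is the natural horizon: a read pair can carry
breakpoint evidence only if its fragment spans the breakpoint.

### The fifteen features

Per mapped primary record: uniquely mapped reads (f1), multiply mapped
reads (f2), pairs with one end unmapped (f3), clipped reads (f4, at
least `minClip` soft-clipped bases, default 5 to suppress adapter-trim
noise), error-free and with-error reads by `NM` (f5, f6; reads without
`NM` are excluded rather than guessed from CIGAR, because CIGAR `M`
conflates match and mismatch), summed mapping quality (f9) and MAPQ bins
(f10 low < 20, f12 high >= 40, f11 the remainder — conventional BWA MAPQ
regimes; configurable). Per fully mapped pair, counted once at the
leftmost mate inside the window (or at the in-window mate when the other
lies outside, so nothing is double counted): concordant pairs (f7,
opposite-strand with $|\mathrm{TLEN}|$ within
$\overline{ISPE} \pm 3\,\sigma_{ISPE}$, the standard proper-pair band),
discordant pairs (f8, the rest), both-reverse (f13), both-forward (f14)
and same-strand pairs (f15 = f13 + f14). Unique/multiple placement
prefers the `XT` tag where present and falls back to `XA`-present or
MAPQ 0 meaning multiple, since `XT` is written by legacy aligners only.

Three identities hold by construction and are asserted throughout the
test suite: f15 = f13 + f14; f10 + f11 + f12 equals the number of
MAPQ-scored reads; f5 + f6 equals the number of `NM`-scored reads.

### Feature mining

Each feature is scored against the binary inversion/wild-type label with
a count-data chi-square: for feature $j$, the observed class totals are
$O_c = \sum_{i: y_i = c} X_{ij}$, the expected totals under independence
are $E_c = p_c \sum_i X_{ij}$ with $p_c$ the class proportion, and

$$x^2_j = \sum_{c \in \{0,1\}} \frac{(O_c - E_c)^2}{E_c}.$$

More than one $O$/$E$ construction goes by this name; the
class-sum/class-prior construction above is the standard one for
non-negative count features (it is what mainstream feature-selection
libraries compute) and is the one adopted here, verified against an
independent brute-force implementation in the tests.
The top eight features by $x^2$ (ties broken by ascending ID, for
determinism) are kept, and two curated features — f3 (one-end-unmapped
pairs) and f9 (summed mapping quality), which domain experience marks as
informative even when outranked — are unioned in. On real training data
this mechanism yields the ten-feature set {2, 3, 4, 6, 8, 9, 11, 13, 14,
15}, exposed as `defaultFeatureIds()`. Which eight features top the
ranking depends on the training corpus: on this package's simulated
corpus the ranking differs in the tail (for instance f2 is constant at
zero without repeat decoys and cannot rank), so only the mechanism — not
a specific ranking — is contractual.

### Classification

Features are standardized to mean 0, spread 1 per column (population
standard deviation; zero-variance columns get spread 1). The default
scaling mode is **joint**: training features are standardized together
with the candidate features they will be scored against, which mirrors
a transductive normalization: simulated training features are placed on
the same scale as the real candidates they will be compared against.
Joint scaling leaks test-set statistics into training; `"train_only"` is
exposed and is the mode to prefer when candidates arrive incrementally.
`"joint"` stays the default deliberately — it reproduces the
transductive protocol faithfully rather than silently "fixing" it.

The classifier is a support vector machine with a linear kernel, penalty
factor $C = 0.1$ and $\gamma = 20$. $\gamma$ is inert for the linear
kernel; it is stored and reported anyway because it is part of the model
specification, and the radial kernel (where $\gamma$ matters) is
available for grid exploration. Classes are unweighted because training
data are balanced by construction (one wild-type window per inversion).

### Candidates, calling and evaluation

Candidate sites are the union of calls from upstream callers (VCF
records with `SVTYPE=INV` and an `END` or `SVLEN`, or BED intervals).
Two calls agreeing within `eps = 10` bp at both breakpoints are collapsed
(first-seen coordinates kept, sources unioned); `eps = 0` restricts the
collapse to exact duplicates. Candidates shorter than the mean ISPE are
dropped — below one insert size the read-pair signatures the model relies
on are not expressed — with equality surviving the filter.

A predicted inversion matches a benchmark entry when both breakpoints
agree within $k \times \overline{ISPE}$ ($k \in \{1,2,3\}$). Each call is
assigned to at most one benchmark entry, the nearest by summed breakpoint
distance with ties to the earlier entry (nearest-entry assignment is the natural deterministic choice when
several entries fall within the threshold). With TP the number of matching calls and
TP0 the number of distinct benchmark entries matched,

$$\mathrm{FP} = \mathrm{No.Calls} - \mathrm{TP}, \quad
  \mathrm{FN} = \mathrm{benchmark} - \mathrm{TP_0},$$
$$\mathrm{Precision} = \frac{\mathrm{TP}}{\mathrm{No.Calls}}, \quad
  \mathrm{Recall} = \frac{\mathrm{TP_0}}{\mathrm{benchmark}}, \quad
  F_1 = \frac{2PR}{P + R}.$$

In repeated k-fold cross-validation there is no benchmark denominator —
confusion counts are accumulated on held-out folds — so recall is
TP/(TP+FN) there, the standard fold-based definition. Metrics are
kept as exact proportions internally and rounded half-up to two decimals
on the percent scale only at report time.

## The simulator

Real validated inversions are scarce — public call sets hold at most a
few hundred validated inversions per chromosome across whole
low-coverage cohorts — far too few to train a classifier, so training
data are simulated. `simulateSample()` emits *aligned* records directly — it
models what a mapper would report, rather than emitting FASTQ and
invoking an external aligner — which keeps the package self-contained
and the signatures controllable:

* fragments are sampled uniformly at a rate giving the configured
  per-base depth, with lengths Normal($\overline{ISPE}$, $\sigma$)
  truncated at twice the read length;
* a read wholly inside an inverted segment is placed at the mirrored
  reference position on the opposite strand — this generates the
  same-strand-pair signal;
* a read crossing a breakpoint is soft-clipped at the breakpoint when its
  larger mapped anchor reaches `minAnchor` (default 20 bp, a typical
  clipping threshold; real mappers differ and do not document theirs), and with probability `pUnmappedCross` (default 0.35) is
  reported as an unmapped mate instead, modelling end-to-end aligners
  that fail on split reads — this populates the one-end-unmapped channel;
  the two failure modes never hit both mates of one pair;
* heterozygous inversions affect each fragment with probability 1/2;
* substitution errors are Binomial(aligned length, `errorRate`) per read
  and recorded in `NM`; MAPQ is 60 and `XT:A:U` for placed reads;
* TLEN is recomputed from final mapped positions and the stream is
  deterministic given config + seed.

The standard parameter ranges — inversion length 500–6000 bp, ISPE mean
300–500 bp, error rate 0.003–0.005, read length 70–150 bp, depth 4–25x —
are the ranges `drawSimulationConfigs()` samples uniformly, thirteen
parameter sets by default (parameter-set diversity guards the classifier
against overfitting any single library configuration). Recorded truth
breakpoints are additionally jittered by a uniform 20–30 bp in a random
direction, emulating the imprecision of real truth call sets; this
jitter interpretation of a truth-offset parameter is a design choice and
is flagged as such. The corpus defaults to 13 samples with 5 inversions
and 5 matched wild-type windows each (130 labeled windows), enough rows
for stable 10-fold cross-validation while keeping a full run in
seconds. Wild-type windows are placed at least
$2 \times \overline{ISPE}$ from any inversion so padded windows of
opposite labels can never overlap.

What the simulator does *not* model: repeats and segmental duplications
around real breakpoints (so f2, multiply mapped reads, is zero unless
repeat decoys are enabled), indels and other co-located SVs, quality
strings, PCR duplicates, multi-chromosome references and alignment
artifacts of specific mappers. Simulated inversion neighborhoods are therefore cleaner than real ones,
and passing recovery tests on this corpus demonstrates that the
pipeline's machinery is correct — not that real-data precision would
match.

## A worked run

```{r pipeline, eval = FALSE}
library(InversionMiner)

configs <- drawSimulationConfigs(n = 13, nInversions = 5, seed = 11)
training <- simulateTrainingSet(configs)
X <- featureMatrix(training$features)
y <- featureLabels(training$features)

selectFeatures(chiSquareScores(X, y))

cv <- crossValidate(X, y, selectedIds = defaultFeatureIds(),
                    nRepeats = 10, seed = 3)
cv

model <- trainInversionClassifier(X, y)
sim <- simulateSample(drawSimulationConfigs(1, seed = 99)[[1]])
st <- estimateLibraryStats(sim$alignments)
cand <- filterByLength(mergeCandidates(
    pseudoCallerCalls(sim$truth, maxJitter = 100, seed = 4)), st)
pred <- predictInversions(model,
    featureMatrix(extractFeatureMatrix(sim$alignments, cand, stats = st)))
matchCalls(cand[pred == 1],
           GenomicRanges::granges(sim$truth@inversions), st, k = 3)
```

The `pseudoCallerCalls()` helper stands in for upstream callers when
none are available: it jitters the truth breakpoints (up to 100 bp) and
adds the wild-type windows as decoy candidates, so the classifier has
both true and false candidates to separate. Running external callers is
out of scope by design; their outputs are consumed as files.

## Numerical and design notes

* Coordinates are `GRanges` (1-based closed) in memory; BED and the
  feature TSV use 0-based half-open at the file boundary, SAM and VCF
  are natively 1-based. One internal convention, converted at I/O edges.
* Secondary (0x100), supplementary (0x800) and, by default, duplicate
  (0x400) records are excluded from ISPE estimation and feature
  counting.
* Chi-square ties and fold assignment are seeded/deterministic; repeat
  $r$ of cross-validation uses `seed + r - 1`, and a training fold that
  loses a class triggers a logged reshuffle.
* Models are serialized with `saveRDS()` — a single self-contained file
  holding scaler, SVM and feature IDs.
* Degenerate inputs: empty windows yield the zero feature vector;
  zero-variance columns scale to zeros; zero-call evaluations define
  precision (and recall on an empty benchmark) as 0 with a warning.

## Limitations

The classifier is only as good as the candidate set: an inversion no
upstream caller proposes can never be recalled (the union construction
exists to soften exactly this). Inversions shorter than one insert size
are filtered out on principle. Clean simulations can train a classifier that transfers to real data,
but users applying the model to a new cohort should prefer `scalingMode = "train_only"` unless
they specifically want the transductive protocol, and should expect
real-data precision below the near-perfect synthetic recovery reported
by the acceptance script.
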