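---
title: "Calling m6A from base-calling error signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling m6A from base-calling error signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

Nanopore direct RNA sequencing reads native RNA molecules, but the
base-callers it relies on are trained almost exclusively on unmodified
nucleotides. When a modified base such as N6-methyladenosine (m6A) transits
the pore, the current deviates from the model's expectation and the
base-caller responds with systematic "errors": lowered per-base quality
scores, elevated mismatch frequencies, and elevated deletion frequencies at
and around the modified position. These errors are reproducible across
biological replicates, which makes them a usable signal rather than noise.
`epierr` turns that signal into a site-level m6A caller.

The pipeline has five stages:

1. **Design** (`design_curlcakes()`): synthetic training constructs that
   contain every 5-mer, so a classifier can see each sequence context in
   both its modified and unmodified form.
2. **Simulation** (`simulate_reads()`, `simulate_replicates()`,
   `mix_read_sets()`): a generative error model that reproduces the
   modification-dependent feature shifts, so the entire pipeline is testable
   without sequencing data.
3. **Feature extraction** (`per_site_features()`, `current_window_stats()`,
   `window_features()`): per-site coverage, mean quality, mismatch /
   insertion / deletion frequencies, and 5-mer window vectors holding those
   features at offsets −2..+2 plus window current statistics.
4. **Classification** (`train_svm()`, `predict()`, `roc_auc()`,
   `evaluate()`): an SVM over window features with Platt probability
   outputs.
5. **Site calling** (`scan_motif()`, `coverage_filter()`,
   `merge_replicate_scores()`, `call_modification()`): RRACH candidate
   scanning, replicate merging, and wild-type versus knockout differential
   calling.

## Sequence design

Training requires observing every 5-mer (there are $4^5 = 1024$). The
designer walks an Eulerian circuit on the de Bruijn graph whose nodes are
4-mers and whose edges are 5-mers; each edge carried with multiplicity $m$
yields a sequence of length $m \cdot 4^5 + 4$ containing every 5-mer exactly
$m$ times. Edge order is shuffled under the seed, so designs are random but
exactly reproducible. At $m = 10$ the construct is ~10 kb with a median
5-mer occurrence of 10, the scale used for the package's own studies; the
default $m = 1$ gives the minimal ~1 kb superstring.

In vitro transcription works poorly on self-complementary sequences, so
among `n_candidates` (default 20) random superstrings the designer keeps the
one with the smallest `structure_penalty()`: the number of position pairs
$(i, j)$, with $j - i$ larger than `min_loop_len + min_stem_len`, at which a
perfect reverse-complement match of at least `min_stem_len` bases begins
(defaults 3 and 6). This is a deliberate heuristic — a count of places where
a hairpin stem could nucleate — not a thermodynamic folding prediction; it
is deterministic, fast (implemented in C++), monotone in the amount of
self-complementary sequence, and pluggable. Full secondary-structure
prediction is out of scope.

The selected superstring is split into `n_parts` (default 4) contiguous
parts for synthesis. Consecutive parts share $k - 1$ boundary letters, so
every 5-mer of the superstring lies wholly inside at least one part and no
k-mer exists only across a junction. Parts are made as equal as possible; a
`part_length_tolerance` (default 10%) guards against degenerate splits.
Sequences are stored DNA-sense (T, not U; inputs normalize U→T and
lowercase→uppercase) because base-called FASTQ and BAM files use T.

## The simulator and its defaults

`error_model()` is the generative counterpart of the feature extractor. Its
defaults were chosen once, as typical direct RNA values, and define the
package's study conditions:

| parameter | default | meaning |
|---|---|---|
| `base_quality_mean` / `sd` | 12 / 3 | Phred quality of unmodified calls |
| `p_mismatch`, `p_deletion`, `p_insertion` | 0.05, 0.04, 0.03 | baseline per-base error rates |
| `quality_shift` | −3 | Phred delta at modified positions |
| `mismatch_delta`, `deletion_delta` | +0.10, +0.05 | error-rate increments at modified positions |
| `insertion_delta` | 0 | insertions carry no modification signal |
| `current_mean_baseline` / `current_sd` | 100 / 10 pA | window current level and spread |
| `current_shift` | +3 pA | shift for windows covering a modified base |
| `neighbor_bleed` | 0.25, 0.10 | fraction of each delta applied at ±1, ±2 |

The zero insertion delta encodes the observation that insertion frequencies
do not reproduce across replicates and are therefore uninformative about
modification status; insertion frequency is extracted but excluded from the
default model features for the same reason. The neighbor bleed reflects
that a modified base sits inside five consecutive 5-mer events, perturbing
base-calling at adjacent positions too; set it to `c(0, 0)` to confine the
signal.

Reads are full length (fragmentation contributes nothing to per-site
frequency statistics), qualities are normal draws rounded and clamped to
[1, 40], insertions are single uniform bases attached to the preceding
reference position (pileup convention), and the number of modified reads is
deterministic — `round(coverage * mod_fraction)` — rather than binomial, so
mixture experiments are exact rather than noisy in their design variable.
Raw squiggle synthesis and pore physics are out of scope: event tables are
drawn directly at the 5-mer level.

What passing simulation-based tests does **not** show: real base-callers
produce k-mer-dependent, asymmetric error profiles, homopolymer artifacts,
truncated reads and coverage gradients, none of which the generative model
emulates. The simulations validate the pipeline's statistical machinery,
not its accuracy on any particular sequencing run.

## Feature definitions

All frequencies share one denominator: spanning coverage, the number of
reads contributing either a call or a deletion at the site. This gives the
conservation property `mismatch + deletion + match = 1` and makes
frequencies comparable across sites. Insertions are orthogonal (a read can
match *and* carry a trailing insertion). Mean quality averages Phred values
arithmetically over non-deleted calls. Positions with zero coverage are
emitted with missing features, not dropped, so windows can flag themselves
incomplete. Coordinates are 1-based inclusive throughout the tables
(SAM/mpileup convention); BED interchange is 0-based half-open. Reads are
not quality- or MAPQ-filtered by default.

Window vectors hold quality, mismatch and deletion frequency at offsets
−2..+2 (15 numbers), the across-read current mean and standard deviation of
the window (sample SD, $n - 1$; 0 for a single read), and the minimum
coverage over the five positions.

## The classifier

`train_svm()` stratifies a 75/25 train/test split by label under the seed,
standardizes each feature with training-split statistics only (a leakage
guard asserted in the tests), fits `e1071::svm()` with linear, polynomial
and radial kernels, and keeps the kernel with the highest held-out accuracy
(ties resolve in that order). Regularization and kernel hyperparameters are
the library defaults, recorded in the fitted object. Probabilities are the
SVM's Platt-style outputs; the decision threshold is 0.5 unless overridden.

The default feature set is `combined3` — quality, mismatch and deletion
frequency at position 0. Current-intensity features are available
(`curr_mean`, `curr_sd`, `curr2`) but excluded from the default: they are
weaker predictors, and the full 15-feature neighborhood set (`extended15`),
while slightly more accurate on matched contexts, inflates false positives
on control k-mers whose neighbors — not centers — differ. Windows whose
5-mer contains more than one A are excluded from training and scoring
throughout: in a fully methylated construct every A is modified, so multi-A
k-mers carry several modifications at once and do not represent any
biological context. This exclusion is uniform and configurable
(`exclude via scan_motif()`'s `multi_A` flag).

AUC is the Mann–Whitney concordance (ties count one half), computed
rank-based and cross-checked in the tests against both an $O(n^2)$ pairwise
oracle and an independent ROC implementation.

## Site calling

Candidates are positions whose ±2 context matches RRACH (IUPAC R = A/G,
H = A/C/T), centered on the methylatable A. A site must reach
`min_coverage` (default 5 reads) in **every** sample to be analyzed; the
permissive variant (at least one read per sample) is available as
`min_coverage = 1`.

Per-replicate probabilities merge into a modification score
$$M = \begin{cases} 1 & \text{if } s_i \ge 0.5 \text{ for all replicates} \\
\frac{1}{n}\sum_i s_i & \text{otherwise,} \end{cases}$$
with the boundary inclusive ($s_i = 0.5$ counts as passing). The rule
generalizes to any replicate count with the same all-or-mean form; the
default expects 3. A site is called modified when
$M_{wt}/M_{ko} > 1.5$ **and** $M_{wt} > 0.5$, both strict. When
$M_{ko} = 0$ the ratio is treated as $+\infty$ — the site remains callable
on $M_{wt}$ alone; this zero-denominator policy is explicit and
configurable. Merging is permutation-invariant and monotone in each
replicate, and calling is monotone in $M_{wt}$; both properties are tested.

Stoichiometry — the fraction of molecules modified at a site — is estimated
by linear interpolation of the observed mismatch frequency between
calibration levels from 0%- and 100%-modified runs, clipped to [0, 1]. The
estimator is exact in expectation because the simulated (and, to first
order, observed) mismatch frequency is linear in the modified-read
fraction.

## Study design choices

Two end-to-end studies ship with the package and back its validation.

**Mixture study** (`mixture_curve()`): a classifier trained on fully
modified versus unmodified constructs is applied to read mixtures at
methylation ratios 0–100%. At a given ratio every candidate site of the
mixture is partially modified, so the ROC contrasts the mixture sample
(positives) against an independent, read-disjoint unmodified control sample
of the same depth (negatives). AUC falls smoothly with the ratio and is
~0.5 at ratio 0, where the two samples are exchangeable.

**Wild-type/knockout study** (`wtko_study()`): three wild-type replicates
at 50% methylated reads and three knockout replicates at 0% are simulated,
scored, merged and called. The classifier for this study is trained on a
dedicated training replicate simulated at the same conditions (train on one
replicate, validate on the others) rather than on the 100%/0% constructs.
The reason is structural: all three default features are linear in the
modified-read fraction, so a site at 50% stoichiometry lies exactly midway
between the 100% and 0% training classes — on the decision boundary of a
construct-trained SVM — and its probability hovers at 0.5 regardless of
coverage. Training at study conditions places the boundary between the wt
and ko populations instead, which is what a differential caller needs.
Construct-based training remains the right choice when the in vivo
stoichiometry is unknown; it trades recovery for generality.

Problem sizes for the shipped studies were fixed once: the four-part,
multiplicity-10 (~10 kb) design for training-accuracy and wt/ko studies at
coverage 100, the minimal ~1 kb superstring for mixtures (coverage 100 per
mixture) and stoichiometry (coverage 500), sizes at which every
Monte-Carlo margin in the validation suite is comfortable.

## Numerical and degenerate-input conventions

* Same seed ⇒ byte-identical output, for every randomized operation;
  replicate sub-seeds derive deterministically from (seed, condition,
  replicate) and stay below $2^{31}$.
* Kernel-selection ties break toward linear, then polynomial, then radial.
* Probability ties at the 0.5 threshold count as "modified" (`>=`) in
  `evaluate()`; the site-calling thresholds are strict (`>`), following the
  calling rule's definition.
* Empty inputs: an empty sequence has structure penalty 0; zero coverage
  produces empty tables; an empty known-site list makes recovery `NA`;
  `evaluate()` on empty input is an error.
* A single-class training table is an error; fewer than 10 windows per
  class is a recorded warning.
* Mixtures refuse to sample more reads than a pool holds, naming the
  shortfall.

## Limitations

The caller is site-level, not single-molecule: it aggregates all reads over
a position and cannot say which molecules are modified. It does not
distinguish modification types — any modification with a similar error
signature would be called. Its accuracies on simulated data reflect the
simulator's assumptions, not sequencing reality; on real data the
error-signature effect sizes are k-mer-dependent and generally smaller,
and recovery of known sites is correspondingly lower. The structure
penalty is a screening heuristic, not a folding energy. Training and
scoring exclude multi-A 5-mers, which silently removes a fraction of
genuine RRACH sites (those with R = A) from the callable space.
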