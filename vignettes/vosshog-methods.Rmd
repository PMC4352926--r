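---
title: "Methods: Voss-image descriptors and six-class mutation prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Voss-image descriptors and six-class mutation prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vosshog classifies nucleotide sequences into six somatic-mutation classes
relevant to non-small cell lung cancer: *normal* (an unmutated EGFR, KRAS or
TP53 coding sequence), *EGFR deletion*, *EGFR substitution*, *KRAS
substitution*, *TP53 deletion* and *TP53 substitution*. The route is: encode
the sequence as a binary image, summarise the image with a fixed-length
texture descriptor, and classify the descriptor with a neural network or a
kernel support vector machine, optionally wrapped in an ensemble. This
vignette is the package's account of each stage: the model, the parameters
that matter, the decisions taken where the design was genuinely open, and
what the bundled synthetic data can and cannot show.

## Voss indicator images

The Voss mapping turns a DNA string of length $N$ into four binary
indicator series $x_A(k), x_C(k), x_G(k), x_T(k)$: series $x_B$ has a 1 at
position $k$ exactly when base $k$ is $B$. Stacked in the fixed row order
A, C, G, T they form a $4 \times N$ binary image in which every column sums
to exactly 1. The mapping is a bijection on A/C/G/T strings;
`voss_decode()` inverts `voss_encode()` and rejects any matrix whose
columns do not sum to one. Ambiguity codes (IUPAC letters such as N) and
anything outside the strict four-letter alphabet are rejected at input
rather than coerced, because the indicator mapping is only defined on the
four unambiguous bases.

Mutation events are modelled minimally: a *substitution* replaces one base
(the replacement must differ from the reference base, so a no-op is a
specification error) and a *deletion* removes one contiguous run. Positions
are 0-based offsets, uniform with image-column indexing. Insertions and
complex rearrangements are out of scope.

## The HOG descriptor

The histogram-of-oriented-gradients descriptor summarises the indicator
image in four steps.

1. **Gradients.** The image is correlated with the 1-D centred masks
   $[-1, 0, 1]$ horizontally and vertically. Borders use replicate-edge
   padding so the derivative images keep the input shape and every pixel
   can vote. Magnitude is $G = \sqrt{I_x^2 + I_y^2}$; orientation is the
   two-argument arctangent folded into the unsigned range $[0°, 180°)$,
   with $(0,0)$ gradients assigned orientation 0 (they carry zero
   magnitude and thus no vote, which sidesteps the division by zero in the
   one-argument form).
2. **Orientation binning.** Each pixel casts its full magnitude into the
   single 20° bin containing its orientation — hard assignment, half-open
   bins $[lo, hi)$, a fold of exactly 180° wrapping to bin 0. With the
   unsigned range this gives $180/20 = 9$ channels, and the histogram mass
   of any window equals the sum of gradient magnitudes over that window.
3. **Blocks.** The full 4-row height acts as a single cell row; nine block
   windows are laid along the sequence axis with 50% overlap. The window
   rule is a single closed form: with $B$ blocks and overlap $o$, the
   continuous block width is $w = N / (1 + (B-1)(1-o))$ and block $j$
   spans columns $\lfloor (j-1)(1-o)w \rfloor + 1$ through
   $\lfloor ((j-1)(1-o)+1) w \rfloor$. For the defaults ($B = 9$,
   $o = 1/2$) this is the half-overlapping pairing of ten near-equal
   strips; every width from 5 columns up yields nine non-empty windows,
   and the error for narrower inputs names the computed minimum.
4. **Normalisation.** Each block's 9-bin histogram is normalised
   independently; the default is the L2 factor
   $v / \sqrt{\lVert v\rVert_2^2 + e^2}$ with $e = 10^{-5}$ (the L1 and
   L1-sqrt factors are available). With $e > 0$ the normalised block has
   Euclidean norm at most 1 and an all-zero block stays all-zero.

The concatenation of the nine normalised block histograms is the
descriptor: $9 \times 9 = 81$ values for **any** admissible sequence
length. That length-invariance is the property that makes genes of 567 and
3633 bases comparable in one classifier.

Two conventions deserve emphasis because the literature varies: votes are
hard-assigned (no bilinear interpolation across bins or blocks), and the
orientation range is unsigned. One consequence of treating the image as
genuinely two-dimensional is that a homopolymer (constant rows) still has
*vertical* gradients at the row transitions — its descriptor is constant
but not zero. Only the horizontal derivative vanishes.

The basic LBP descriptor is the alternative texture summary: each interior
pixel is coded by thresholding its eight radius-1 neighbours against the
centre (neighbour $\ge$ centre scores 1), reading the bits clockwise from
the top-left corner as an 8-bit code; the descriptor is the raw 256-bin
code histogram, which sums to the interior pixel count
$(\text{rows}-2)(\text{cols}-2)$. No uniform-pattern or
rotation-invariant variant is used.

## The network classifier

The network is a multilayer perceptron with 81 inputs (or 256 for LBP),
**two hidden layers of equal width** and 6 output units. All hidden and
output units use the hyperbolic tangent; each unit computes
$y = f(w_0 + \sum_i w_i x_i)$. Whether a swept "number of hidden neurons"
should apply to one or both layers is genuinely open; the package resolves
it as equal widths in both, swept 10–100 in steps of 10 by
`hidden_size_sweep()`, with a default width of 80.

Targets are the one-hot rows of the class table (`class_labels()`), used
directly as 0/1 regression targets for the tanh outputs; predictions
decode by argmax with ties to the lowest class index. The loss is the mean
squared error over samples *and* output units — the same `mse_metric()`
used for reporting, so network and SVM tables are on one scale.

Training is Møller's scaled conjugate gradient (no line search), with the
published initial constants $\sigma_0 = 5\times10^{-5}$ and
$\lambda_0 = 5\times10^{-7}$; one SCG step counts as one epoch, at most
500 by default. Inputs are min-max normalised to $[-1, 1]$ (statistics
fitted on the training rows and stored with the model) — a tanh network
saturates on raw count descriptors such as LBP histograms without this.
Weights initialise uniformly in $\pm 1/\sqrt{\text{fan-in}}$ from the
seeded generator, so a fit is a pure function of data, architecture and
seed. Early stopping follows the usual validation rule: data are split
70/15/15 (stratified by class), training stops after six consecutive
epochs without a new validation minimum, and the returned weights are
those of the epoch with minimum validation error.

Stratified splitting apportions each class by largest remainder, so the
splits are disjoint, exhaustive and exactly proportional whenever the
per-class counts allow it; a class smaller than the number of splits
triggers a warning and an unstratified fallback, and a class entirely
absent from the training portion is an error.

## Bagging and voting

The bagged ensemble trains 50 base networks, each on an independent
bootstrap resample (n-of-n with replacement) of the training table. Each
member uses its out-of-bag rows — in expectation $1/e \approx 36.8\%$ of
the data — for early stopping and for its selection accuracy; this is the
one set the member never trained on that costs no extra data. Members
with out-of-bag accuracy of roughly 95% or better (threshold 0.9475) are
retained, and the ensemble is completed to exactly 12 members by accuracy
rank, so small corpora that cannot reach the threshold still yield a full
ensemble. Prediction is plurality voting: the class with the most member
votes wins, no majority required, ties to the lowest class index. Voting
makes the ensemble invariant to member order.

## The SVM classifier

Multiclass classification is one-against-all: one binary soft-margin
machine per class (that class versus the rest), prediction by the largest
decision value, ties again to the lowest class index. The binary machines
are libsvm fits (via e1071) behind the package's interface; features are
standardised by training-set mean and standard deviation inside the fit
(stored with the model) because kernel machines are scale-sensitive and
raw LBP counts are otherwise numerically ill-conditioned.

Five kernels are exposed: linear; quadratic ($(\langle x,x'\rangle+1)^2$);
polynomial (degree 3 by default — the common default, kept distinct from
the separately named quadratic kernel); Gaussian RBF (width $1/d$ by
default); and the sigmoid "MLP kernel"
$\tanh(\langle x,x'\rangle/d - 1)$. The soft-margin constant is $C = 1$
and exposed in the configuration.

Evaluation uses 20 repeated seeded stratified 80/20 holdouts, reporting
the mean accuracy and mean MSE across rounds. (A literal 20-fold
cross-validation would imply 95/5 splits; repeated 80/20 holdout is the
only protocol consistent with both stated numbers, and is what
`repeated_holdout()` implements.) The SVM's MSE one-hot codes its
predictions before comparison with the one-hot targets, keeping the metric
identical to the network's. The bucket-of-models ensemble trains 50
machines on independent stratified re-splits and returns the single member
with the best holdout accuracy.

## Evaluation

`confusion_matrix()` counts (true, predicted) pairs on the fixed class
order; `accuracy()` is $100 \times \text{trace}/\text{total}$;
`summarize_grid()` assembles one row per classifier-by-descriptor
combination in the canonical eight-row order. Reports embed the seeds and
a configuration snapshot and always state which sample set (internal test
split, holdout, or all data) produced the numbers, since summaries of
"accuracy" are meaningless without that. The package also bundles the
published benchmark's summary tables (class counts, per-member ensemble
metrics, two SVM confusion matrices) as regression fixtures for this
arithmetic; they contain no sequence data.

## The synthetic corpus

The real benchmark corpus (mutation records for the three genes, six
classes, 6,406 acquired / 157 unique samples) is not redistributable, and
its construction from database records is under-specified, so the package
generates a structural stand-in. Three uniform-random A/C/G/T references
use the benchmark's coding-sequence lengths (EGFR 3633, KRAS 567, TP53
1182). Five mutation classes draw seeded single events against the
matching reference — substitutions at a uniform position to a uniformly
chosen different base; deletions of uniform length 3–24 bases (spanning
the in-frame deletion sizes typical of these genes) at a uniform
position — and the normal class is the three unmutated references. Class
counts follow the benchmark's acquired-count ratios 2640 : 975 : 2472 :
42 : 277 at a configurable scale (default 0.047, about 300 samples, with
a per-class floor of 3 so every class survives a stratified three-way
split). With `unique_only` no duplicate (class, sequence) pair is
emitted and impossible requests fail with a capacity error. The corpus —
references, samples and the per-sample event manifest — is a pure
function of its configuration, including the seed.

What the generator deliberately does **not** emulate: mutation hotspots,
codon structure and reading frames, germline variation between samples of
one class, sequencing error, and whatever windowing the original corpus
applied around each mutation. Consequently, passing results on the
synthetic corpus demonstrate that the pipeline's machinery — encoding,
descriptors, training, ensembling, evaluation — behaves correctly and
that the six classes are learnable from descriptor structure alone; they
do not certify the published real-data accuracies, which depend on data
this package does not ship.

## Problem sizes and observed behaviour

The test suite and the acceptance workflow run the full study at a
deliberately desk-sized scale, chosen once: a ~300-sample corpus at the
benchmark ratios, networks of two 80-unit hidden layers, ensembles of 50
base learners with 12 selected, and five-seed repeats for the
ensemble-versus-single comparison. At this scale all eight
classifier-by-descriptor combinations sit far above the 16.7% six-class
chance rate on held-out data, and the bagged network ensemble matches or
beats the median single network's held-out accuracy in at least four of
five seeds — the qualitative ordering the ensemble is for. Unit tests pin
the exact worked examples (the three published 10-mer Voss images, the
published confusion-matrix accuracies) and check both descriptors against
independently written brute-force loop implementations to $10^{-12}$ on
a hundred random images per run.

## Known limitations

* The block geometry on a 4-row image is a package decision; only the
  "9 bins × 9 blocks = 81" contract is externally fixed, and other
  geometries satisfying it would give different (equally valid)
  descriptor values.
* Single-event mutants make within-gene classes (e.g. EGFR deletion
  versus EGFR substitution) nearly concentric descriptor clouds; most
  residual confusion on the synthetic corpus lives there, and the small
  normal and TP53-deletion classes dominate the error bars.
* The SCG trainer is full-batch; corpora several orders of magnitude
  larger than the bundled scale would want mini-batching or a compiled
  backend.
* One published fixture is internally inconsistent: the per-member MSE
  rows of the HOG ensemble table average to 0.01725, not the printed
  0.0159 (the printed total and average agree with each other but not
  with the rows). `member_average()` reports what the rows actually give.
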