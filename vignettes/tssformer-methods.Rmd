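---
title: "tssformer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tssformer: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What the package models

Bacterial transcription starts at single-nucleotide, strand-specific
positions (TSSs). The sequence signals that determine a TSS sit almost
entirely upstream of it: hexamer boxes around -10 (consensus `TATAAT`)
and -35 (`TTGACA`) bound by sigma-factor regions of RNA polymerase, plus
assorted transcription-factor operators at characteristic distances.
`tssformer` trains a segment-recurrent, convolution-augmented multi-head
attention network to emit, for every genome position and strand, the
probability that a (shifted) TSS is present, and then asks the converse
question: *what did each attention head learn?* Each head is
characterised by its positional focus (where in the upstream window it
looks) and its preferred sequence (a position frequency matrix built
from the sequences it scores highest).

Because the interesting claims are about what the heads recover, the
package ships a synthetic-genome generator that *plants* the promoter
architecture: the recovery of the planted boxes by the trained heads is
then a testable, ground-truthed property rather than an anecdote.

# The model

The genome is processed in consecutive segments of length $l$ per
strand; the antisense strand is handled as the reverse complement in
its own coordinate system, so "upstream" always means upstream on the
feature's strand. Each nucleotide is embedded into a vector
$h^{(0)} \in \mathbb{R}^{E}$ and transformed through $k$ residual
blocks. In each block, query/key/value vectors are derived by a
width-$w$ convolution over the layer-normalised hidden states, so the
information carried about position $p$ is effectively the $w$-mer
centred at $p$ (default $w = 7$). Each of $H$ heads computes

$$z^{(n)} = \mathrm{softmax}\!\left(\frac{q^{(n)}\cdot K}{\sqrt{d_{head}}} + b_{h}[\,n - j\,]\right)\cdot V,$$

over the $l$ most recent positions $j \le n$ (the current segment's
prefix plus the cached previous segment, which is visible read-only:
segment recurrence). Heads are concatenated, linearly mixed, and added
back to the residual stream; a small two-layer head maps the final
hidden state to two-class probabilities.

**Relative positional encoding.** Position enters the score as a
learned per-head additive bias $b_h$ over the relative offset
$n - j \in \{0, \dots, l-1\}$. This is the simplest member of the
relative-encoding family: it is exactly shift-equivariant (two windows
with identical content give identical scores wherever they sit in the
genome, which the suite asserts bit-for-bit), it gives every offset a
distinct learnable value, and it lets a head become *purely* positional
— the behaviour needed to model operator-like elements at a fixed
distance. The alternative (content-dependent projections of a relative
encoding, as in the segment-recurrent architecture this model descends
from) is strictly more expressive but was not needed for any property
this package claims; the bias is kept as a swappable strategy.

**Causality and the label shift.** Attention is strictly causal
($j \le n$), but the convolution is centred, so q/k/v at $p$ see
$p \pm (w-1)/2$. Downstream sequence context is instead supplied by
construction: labels are shifted 20 nt downstream of the TSS, so the
model answers "was there a TSS 20 nt ago?" with the full promoter in
its upstream window. Two receptive-field facts follow and are tested
exactly: output at $n$ cannot depend on anything more than
$k\,(l + w)$ upstream, nor beyond $3k$ nt downstream.

**Memory is detached.** Gradients never flow into the cached previous
segment; its keys/values are recomputed from the cache with the live
weights (the cache's layer-norm still contributes gain/bias gradients).

# Training

Training follows the full-genome regime: contiguous
train/test/validation arcs (70/20/10 by default; explicit boundary
coordinates are supported, with the arc after the third boundary
rejoining the training set, since three cut points on a circular genome
leave three arcs), both strands of an arc in the same split, and an
*unweighted* two-class cross-entropy over every position — no negative
subsampling, despite a positive rate of order $10^{-3}$. One segment in
genomic order is one optimiser step, memory carried across consecutive
segments within an arc. The checkpoint with minimal validation loss is
kept and training stops after `patience` epochs without improvement.

The optimiser is Adam with decoupled weight decay on the weight
matrices only (not on biases, layer norms, embeddings or positional
biases). The defaults — `lr = 3e-3`, `beta2 = 0.98`,
`weightDecay = 0.2`, `pos_bias_init_sd = 2`, up to 30 epochs, patience
5 — were chosen on a 50 kb pilot genome and then frozen. Two of them
deserve comment, because the regime is unusual: with so few positive
positions, a model of this capacity can memorise the training positives
from their unique 128-nt window fingerprints instead of learning the
planted motifs. Strong weight decay penalises exactly the memorisation
channel (sharp, idiosyncratic query-key structure), while the motif
circuit — shared across hundreds of sites — survives it. And drawing
the initial positional biases with spread 2 gives every head a weak
random positional preference from the start; symmetry breaking
otherwise consumes many epochs of the budget. Both effects were clearly
visible in the pilot: with decay 0.05 the validation loss never dropped
below the label-frequency entropy, with decay 0.2 it fell well below
it once the positional biases locked onto the planted boxes.

Numerical choices: layer norm uses $\varepsilon = 10^{-5}$; softmax is
computed with max-subtraction; cross-entropy clamps probabilities at
$10^{-300}$; analytic gradients for every parameter are verified
against central finite differences at $10^{-5}$ tolerance in the test
suite. All randomness (generator, initialisation, sampling) flows
through explicit seeds; two runs with the same seeds are identical to
the last bit.

# The synthetic study conditions

The generator defines the conditions under which every end-to-end
claim is tested:

* background: i.i.d. sequence, GC 0.5, 200 kb;
* 400 TSSs on both strands, same-strand spacing at least 300 nt (and
  cross-strand spacing large enough that planted windows never
  collide, so planting fidelity is exact);
* planted elements: `TATAAT` starting at -12 (the -10 box, occupying
  -12..-7) and `TTGACA` at -35 (-35..-30), each with 10% per-base
  substitution and ±1 nt offset jitter; optionally a third, purely
  position-specific box `TGTGAG` at -85 (near the -82 operator
  distance);
* noisy annotation sets for the curation stage: per-site dropout,
  ±`maxShift` jitter (capped at 5 nt so noise respects the sharing
  window), and uniformly placed false positives kept at least
  `maxShift + 1` nt from any true site so that evaluation against the
  truth is unambiguous.

What this emulates — and what it does not. Real TSS maps disagree
across techniques by a few nucleotides, miss sites, and contain
spurious calls; the noise model reproduces those three failure modes
with known rates. It does *not* reproduce sigma-factor diversity,
condition-dependent promoter usage, GC skew, repeats, or transcription
interference between neighbouring units. A pass on synthetic data
therefore demonstrates that the pipeline's machinery — training,
evaluation, curation, head characterisation — does what it claims
under controlled conditions; it does not by itself certify performance
on a real genome. The noise magnitudes are chosen for testability, as
no per-technique error rates are available to calibrate against.

# Curation of multi-source annotations

Annotations from different sources are "shared" when within 5 nt on
the same strand. Sharing is extended to connected components of the
pairwise relation, so a chain 10–14–18 is one cluster even though its
ends are 8 nt apart; clusters wider than the window are reported when
they occur. Curation then applies three rules: a cluster supported by
at least two distinct sources contributes one curated site (rule 1) at
the modal voted position (rule 2) — one vote per source, a
multi-position source voting with its position closest to the cluster
median (ties to the smaller coordinate), and positional ties resolved
in favour of the newest technique — and finally every annotation of a
designated preferred source not already within the window of a curated
site is added verbatim (rule 3), checking also against sites added
earlier within rule 3 so near-duplicates cannot accumulate. Strands
never mix. Vote counting per *source* (not per annotation) and the
rule-3 deduplication are design decisions on points the rule statement
leaves open; both are pinned by an independent brute-force oracle in
the tests.

# Head characterisation

Attention records are re-collected in inference mode over the same
interval structure used for prediction, so recorded scores equal the
forward pass bit for bit. For a sampled set of query positions
(about 1% of the test split, plus the 500 highest- and 500
lowest-output positions), each head yields its score vector over the
upstream offsets. Offset 0 is the query; since labels sit 20 nt
downstream of the TSS, TSS-relative positions are offset + 20.

Head characterisation pools the whole frame — the random sample plus
both extreme groups. This matters at desk scale: among a few hundred
random background 7-mers the expected number of exact hexamer-box
instances is below one, so a background-only pool cannot yield 50
strong motif instances no matter how selective a head is; the
top-output group contributes the predicted promoters whose planted
boxes the motif construction needs.

Per head, the package computes the mean and max positional profile
(mean profiles of full-context records sum to 1; min–max normalisation
exists for display only and is never fed into statistics); the top-50
motif — the 7-mers centred at query + anchor for the 50 records scoring
highest *at the anchor offset* (the mean-profile peak), ties broken by
coordinate, out-of-bounds windows skipped with replacement — counted
into a position frequency matrix with per-column information content
in bits. When a motif matrix is compared against a planted consensus,
the consensus slides over the matrix including partial-overlap
alignments (at least 4 of its columns): a head that prefers one jitter
frame clips the box by a column at the extraction-window edge, and
requiring full overlap would misreport a cleanly recovered motif.
The remaining head statistics are Spearman correlations of per-offset
scores with the model output (zero-variance offsets reported as
missing); top-vs-bottom group contrasts per offset with Wilcoxon
rank-sum tests and Benjamini–Hochberg correction across offsets (the
correction procedure is a package choice); and the head–head Spearman
matrix over flattened (sample × offset) score vectors.

# Output-profile summaries

Median (never mean) summaries characterise the prediction track:
metaplots over a 1201-nt window centred on a site list, strand-locally
oriented so offsets increase downstream, with the opposite strand as
the antisense trace; per-region-class medians (coding if covered by a
coding interval on either strand, intergenic if covered by nothing,
operon-gap and pseudogene independently — classes may overlap by
construction); and the median of per-region maxima for short regions
whose peaks matter more than their level. Even-length medians use the
midpoint convention.

# Problem sizes and defaults

The shipped desk-scale configuration is $l = 128$, $k = 2$, $H = 4$,
$d_{head} = 8$, $E = 32$, trained on the 200 kb / 400-site fixture
above; at these sizes a full training run takes minutes on one core.
The published full-scale geometry ($l = 512$, $k = 6$, $H = 6$) is
available via `modelConfigFullScale()` and is exercised arithmetically
(parameter layout, attention-score counting) rather than trained in
the test suite. Analysis sampling uses fraction 0.01 and 500-strong
extreme groups, scaled to the fixture's split sizes.

# Known limitations

* The per-head positional bias cannot express content-*conditional*
  positional preferences within a single head; such behaviour needs
  two layers (and is one reason the second layer helps).
* Centred convolution means outputs within 3k nt of a segment end see
  zero-padding rather than sequence; segment boundaries are therefore
  very slightly degraded. Training and prediction share the same
  segmentation, so this is consistent between phases.
* The curated-set machinery assumes single-replicon coordinates;
  multi-chromosome genomes and assembly liftover are out of scope.
* With planted-motif signal strengths near the noise floor (mutation
  rates well above ~0.2), the default budget of 30 epochs may stop at
  the base-rate solution; the generator defaults stay well inside the
  learnable regime.
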