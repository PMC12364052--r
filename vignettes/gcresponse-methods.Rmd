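---
title: "Methods: simulation-based inference of the germinal-center affinity-fitness response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-based inference of the germinal-center affinity-fitness response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Germinal centers (GCs) are the micro-anatomical sites where B cells mutate
their receptors (BCRs) and compete for survival signals on the basis of
antigen-binding affinity. The quantity this package infers is the
*affinity-fitness response function*: the map from a cell's affinity to its
intrinsic division rate. It cannot be measured in vitro, because a B cell's
fitness is an emergent property of the whole evolving GC; it has to be
inferred from the shapes of the phylogenies that GCs leave behind. Because
the forward model couples every cell to every other cell through a
population-size constraint, its likelihood is intractable, so inference is
simulation-based: simulate many GCs under known parameters, encode their
phylogenies, train a convolutional network to regress the response
parameters, and hand the remaining parameters to summary-statistic
matching.

## The forward model

A GC is a collection of cells, each carrying a nucleotide sequence. Three
event types compete in continuous time:

* **Birth.** Cell $i$ divides at rate $m\,\lambda_i$, where
  $\lambda_i = \lambda(x_i)$ is the sigmoid response
  $$\lambda(x) = \frac{y_c}{1 + e^{-x_c (x - x_h)}} + y_h$$
  evaluated at the cell's affinity $x_i$, and $m$ is the carrying-capacity
  factor below. $x_c$ (1/affinity-unit) sets the steepness, $x_h$ the
  affinity midpoint, $y_c + y_h$ (1/day) the fitness ceiling, and $y_h$ the
  floor rate due to tonic signalling.
* **Death.** Constant rate $\mu_f$ for functional cells, $\mu_s$
  (10/day) for cells whose sequence has acquired a stop codon.
* **Mutation.** Rate equal to the sequence's 5-mer-context mutability
  (summed over positions and multiplied by a global multiplier). A
  mutation picks a position proportional to per-position mutability and a
  new base from that motif's substitution distribution.

Affinity is the log-fold change in dissociation constant relative to the
naive antibody, $x = -\log_{10}(K_D / K_D^{\mathrm{naive}})$, and is
computed from the sequence by translating it and summing per-site,
per-amino-acid effects from a deep mutational scan (DMS) table — strictly
additively, with no epistasis. Synonymous changes are neutral. A sequence
that gains a stop codon keeps its last computed affinity (and hence birth
rate) but switches to the stop-codon death rate; the model drives
nonfunctionality through death, not through the affinity map. Whether
nonfunctional cells should also lose their birth rate is not determined by
the biology we emulate, so it is exposed as the
`zero_birth_nonfunctional` switch, off by default.

**Carrying capacity.** With $N$ living cells and capacity $N_0$, birth
rates are modulated by
$$m = \left(\frac{\sum_i \mu_i}{\sum_i \lambda_i}\right)^{N/N_0},$$
which leaves small populations untouched (exponent near 0) and makes the
process exactly critical at $N = N_0$. Death-rate modulation (reciprocal
base) and a "hard" rule (kill a random cell on overflow) are implemented
as alternatives but all headline behavior uses birth modulation.

**Initialization, stopping, sampling.** The GC starts from one naive cell
that undergoes zero-time binary splitting to the initial population size
(splitting one cell at a time, so any integer size is reachable). The
process stops at the sampling time $T$; runs that die out, or hold fewer
than `min_viable = 10` cells at $T$, are discarded and retried, with a
hard error after `max_tries` attempts so that degenerate parameter sets
fail loudly instead of spinning. Sampled cells are drawn uniformly without
replacement; the returned tree is the induced subtree on the sampled
leaves and their ancestors with unifurcations collapsed, every leaf placed
at exactly $T$.

**Event algorithm.** The specification of the process is per-cell
first-reaction competition: every (cell, event-type) pair draws an
exponential waiting time and the minimum fires. Because exponential clocks
are memoryless, this is distribution-identical to the direct construction
(one exponential at the total rate plus a categorical draw), which is what
the C++ core implements with Fenwick-tree categorical sampling at
$O(\log N)$ per event. The literal first-reaction draw is kept in R
(`draw_event(method = "first-reaction")`) and the test suite checks the
two constructions against each other and against the exact event
probabilities. $m$ is recomputed after every event.

## Synthetic study inputs

The real experiment this model emulates (identically-seeded GCs in
engineered mice, with a DMS on the naive antibody) provides a naive
sequence, a DMS table, and a published 5-mer hypermutation model. Those
data files are not shipped; instead the package generates synthetic
stand-ins, clearly labelled as such:

* `synth_naive_seq()` — a random in-frame, stop-free coding sequence
  (default 100 codons; real BCR V regions are of this order).
* `synth_dms()` — per-site effects with a gamma-shaped deleterious bulk
  and a small beneficial tail (5% of substitutions, scale 0.3). The tail
  is calibrated against the published properties of *observed* (selected)
  sequences: under data-mimic selection, sampled affinities span roughly
  $-20$ to $+3$ with mean near $-0.5$ and median near $+0.5$, matching
  the reported range ($-37$ to $3$, mean $-0.3$, median $0.3$). The
  calibration matters: with a weaker tail no sampled cell ever reaches
  the sigmoid's transition region and the upper curve becomes
  unidentifiable.
* `synth_shm_model()` — log-normal motif mutabilities (hot and cold
  spots) with Dirichlet substitution rows, scaled so a 300-nt sequence
  mutates at 1/day before the global multiplier. Data-mimic samples
  (multiplier 0.5, 20 days) then carry about 6 observed mutations per
  sequence with a maximum near 19, as in real extracted-GC data
  (mean 6.3, range 0–19).

What the generator does **not** emulate: the actual measured effect sizes
of the real DMS (so inferred curves are not comparable to published
curves numerically), epistasis, framework/CDR rate structure,
affinity-dependent hypermutation, and phylogeny re-inference from
sequences (trees enter the encoder with their true simulated branch
lengths; the real-data path consumes externally inferred, annotated
Newick). Passing tests therefore demonstrate the inference machinery
recovers parameters of its own generative process at realistic sizes and
noise levels — not that any particular biological curve is correct.

## Parameter ranges

Training simulations draw each GC's parameters independently:
$x_c \in [0.01, 2]$, $x_h \in [-0.5, 3]$, $y_c \in [0.5, 35]$ (1/day),
$y_h \in [0, 0.6]$ (1/day), carrying capacity $[500, 2000]$ cells,
sampling time $[10, 35]$ days, initial population $[8, 128]$ cells,
functional death rate $[0.05, 0.5]$ /day, 50–130 sampled sequences per
GC, mutability multiplier 0.68. The naive (zero-affinity) birth rate
$\lambda_0 = y_c / (1 + e^{x_c x_h})$ is constrained to $[0.1, 15]$ /day:
after drawing $x_c$, the feasible $x_h$ interval implied by the $y_c$ box
and the $\lambda_0$ bounds is intersected with the $x_h$ box (one-sided
constraints whose log argument is non-positive are vacuous), then $y_c$
is drawn inside its implied interval; $y_h$ is drawn independently, since
the tonic floor is small against the fitness signal. When $x_c$ is tiny
the implied $x_h$ interval can be enormous — it is clipped to the box
first, the box being a hard constraint.

The data-mimic operating point (the package default `gc_config()`) is
$(x_c, x_h, y_c, y_h) = (1.6, 2, 18.2, 0.4)$, capacity 500, initial
population 128, $T = 20$ days, 60–95 sequences, death rate 0.2/day,
multiplier 0.5. The four sigmoid values are primary; the naive rate they
imply ($\approx 1.11$/day) is derived, not separately configurable.

## Tree encoding

Trees are scaled to mean unit leaf depth, then encoded as a $4 \times W$
matrix ($W = 200$): a ladderized traversal visits the tips; column $j$
holds the $j$-th tip's height, the height of the node where that tip's
subtree attaches to the previously traversed tree (0 for the first tip),
and the affinities of those two nodes. Columns beyond the tip count are
zero padding.

Ladderization orders sibling subtrees by (node time, ancestor time, node
affinity). Two situations this key set cannot resolve arise **only**
because simulated sampled trees skip external tree re-inference: (i)
sibling internal nodes from the zero-time initial expansion (identical
times, shared ancestor, identical naive affinity), and (ii) ultrametric
cherries of two sampled copies of one genotype. Both are *full-key* ties:
the competing subtrees are observationally identical in every time and
affinity, so the encoded matrix is the same whichever order is chosen.
The package therefore resolves ties by recursing into the (already
canonically ordered) children and comparing key sequences; a remaining
full-subtree tie is provably encoding-invariant. `ladderize_order()`
still raises a tie error by default — the behavior appropriate for real,
re-inferred trees where a tie would signal duplicated data — while the
encoder runs with `on_tie = "keep"`.

Feature standardization maps all height entries to mean 0 / variance 1
(one statistic pair pooled over rows 1–2), all affinity entries likewise
(rows 3–4), and each non-sigmoid input separately. Structural padding
zeros are excluded from the statistics and restored to exactly zero after
the transform; including them would make the feature scale depend on tree
size. The scaler is fitted on the training sample and stored with the
model; it is applied exactly once per input (the transform is not
idempotent), and inverted for auxiliary values on output.

## Network, loss, and training

The regression network is fixed: conv(25 filters, kernel 4) →
conv(25, 4) → max-pool(2, stride 2) → conv(40, 4) → global average
pooling → dense 48 → 32 → 16 → 8 → linear output, ELU activations, valid
padding, input $4 \times 200$. With auxiliary inputs disabled the
parameter counts of those layers are 425 / 2,525 / 4,040 / 1,968 / 1,568
/ 528 / 136. The three standardized non-sigmoid values (capacity,
initial population, death rate) are concatenated onto the pooled
40-vector entering the first dense layer, making the first dense count
2,112; the network thus predicts sigmoid parameters *conditional on* an
assumed non-sigmoid setting. The sigmoid head has 4 outputs; the per-bin
variant replaces it with one output per affinity bin (12 bins on
$[-2.5, 3]$ by default) and is otherwise identical plumbing.

Outputs are clamped ("clip function") to $x_c \in [0.001, 3.5]$,
$x_h \in [-1.5, 5]$, $y_c \in [0.1, 65]$, $y_h \in [0, 10]$ — wider than
the simulation bounds but not unboundedly so. The clamp is applied in the
forward pass with straight-through gradients, the simplest differentiable
reading of clipping during training.

The loss is the **curve difference**: the $L_1$ area between the true and
predicted response curves divided by the area under the true curve, on
the affinity domain $[-2.5, 3]$ (below $-2.5$ all curves flatten to the
floor; above 3 they diverge where no data constrain them). Quadrature is
trapezoidal on a fixed 512-point grid, which makes the loss and its exact
gradient with respect to the four predicted parameters cheap closed-form
batch computations. Mean squared error on raw parameters is deliberately
not used: parameter combinations trade off against each other and only
the curve shape is identified. The per-bin model uses the same loss at
its coarser bin-centre grid.

Training uses Adam (learning rate 0.01, $\beta_1 = 0.9$,
$\beta_2 = 0.999$), an exponential moving average of the weights with
momentum 0.99 (EMA weights are used for validation and prediction), batch
size 32, 35 epochs, no dropout; 20% of the sample is held out for
testing and 10% of the remainder for validation. There is no
deep-learning framework in this package's dependency set; the forward and
backward passes are written directly on BLAS-backed matrix operations
(im2col convolutions), and the backward pass is verified against central
finite differences in the test suite. Training is reproducible given a
seed up to the usual floating-point nondeterminism; tests assert
tolerance bands, never bit equality.

## Non-sigmoid inference and the medoid curve

Carrying capacity, initial population, and death rate are inferred by
scanning the $4 \times 3 \times 4$ grid
$(500, 750, 1000, 2000) \times (8, 32, 128) \times
(0.05, 0.1, 0.2, 0.4)$: at each grid point the network predicts per-GC
sigmoid parameters with the grid values as auxiliary inputs, the medoid
curve summarizes them, a mimic sample is simulated with (medoid sigmoid +
grid non-sigmoid) values, and its summary statistics are compared with
the target sample. The reference analysis never enumerated its statistic
set or match metric, so both are package definitions, kept behind
`summary_statistics()` / `stats_distance()` so alternatives can be
swapped:

* five pooled distributions — copies per distinct sampled sequence,
  sampled-leaf affinities, nucleotide distances to naive, root-to-tip
  divergence, and leaves per GC;
* distance — the mean over statistics of the 1-Wasserstein distance
  between pooled samples, each statistic first divided by its pooled
  standard deviation (comparable scales; symmetry and $d(a,a)=0$ hold,
  the triangle inequality is not guaranteed after scaling). Zero-variance
  statistics are skipped with a warning.

Root-to-tip divergence is counted in mutation events along the lineage
rather than in time, because on true time trees every sampled leaf sits
exactly at $T$ and the statistic would be degenerate; mutation units are
what re-inferred branch lengths measure anyway. Each grid point's mimic
simulation is seeded from the point's own values, so the scan ranking is
invariant to grid ordering; simulation failures at a grid point score an
infinite distance rather than aborting the scan.

The **medoid** curve of a set of predictions is the member minimizing the
summed squared pointwise differences to all other members on the
$[-2.5, 3]$ grid (first index on ties) — a member, never an average,
because averaging sigmoid parameters does not produce a representative
curve. The $L_1$ curve difference is available as an alternative metric
via `curve_difference_loss()`, but squared differences are the
operational definition used by `medoid_curve()`.

## Effective birth rates

The response function is an *intrinsic* rate. The realized net growth
rate of cell $i$ at any moment is $m \lambda_i - \mu_i$, with $m$ the
current modulation factor; at carrying capacity its population mean is
exactly zero (criticality), and in mimic-scale simulations it is
compressed into roughly $[-0.2, 1]$ /day even while intrinsic rates span
an order of magnitude. `effective_birth_rates()` reports it for the
final living population; it is only defined at affinities where cells
actually live, because adding a hypothetical cell would change $m$.

## Numerical choices and degenerate inputs

* Sigmoid evaluation goes through `plogis` (no overflow at extreme
  affinities); the asymptotes are returned exactly.
* Trapezoid weights on 512 points for losses and medoids; 512 is far past
  visual convergence for curves in the clip box while keeping the exact
  loss gradient cheap.
* N-padded boundary motifs (first/last two positions) average the
  mutability and substitution rows of all matching full motifs —
  standard practice for 5-mer models, precomputed once per model.
* A population whose total event rate is zero (e.g. death rate and
  multiplier both zero under birth modulation, which pins $m = 0$) is
  carried unchanged to the sampling time rather than looping.
* `run_gc` retries a fixed parameter set at most `max_tries` (default
  1,000) times; `make_training_set` additionally redraws the parameter
  set after 10 failed attempts, conditioning the training distribution on
  viability exactly as any discard-and-retry pipeline does.
* Per-grid-point scan seeds are derived from the grid values, not the
  loop index.

## Problem sizes used by the test suite

The reference analysis trained on 50,000 GC trees. The package's own
validation uses a scaled-down protocol chosen to keep the full suite
comfortably re-runnable: 5,000 training trees (held-out single-GC curve
loss is checked against the band \[0.4, 1.0\] around the reference's
single-GC value of ≈0.7), a 120-GC identical-parameter mimic sample for
medoid recovery (< 0.35 curve difference to truth), and scan
self-consistency over the full 48-point grid with 119-GC targets (the
real experiment's sample size) and 100 mimic GCs per grid point, 5
seeded repeats. `scripts/acceptance.R` re-runs the same pipeline at
2,500 trees and reports the quantities it computes.

A caution on the scan's capacity axis: control experiments show that
even with the *true* sigmoid substituted for the network prediction, the
best-matching grid point for a given 119-GC target realization is the
generating one only about half to two-thirds of the time, with adjacent
capacities (500 vs 750) separated by less than the target-realization
noise in the distance. Death rate is recovered essentially always and
initial population usually; the carrying-capacity axis sits at the
identifiability limit of these summary statistics at this sample size.

## Known limitations

Single constant functional death rate; no dark-zone/light-zone phase
structure or clonal bursts; uniform sampling of living cells; no
affinity-dependent hypermutation; substitution-only evolution (no
indels); sigmoid-only response family (the per-bin head is still trained
on sigmoid-generated data and cannot express strongly non-sigmoid
shapes); no tree re-inference inside the package, so simulated training
trees are noiseless in branch lengths relative to a re-inferred real
tree. The inferred non-sigmoid values are "effective" parameters of this
model, not direct biological measurements.
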