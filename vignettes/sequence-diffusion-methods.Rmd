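---
title: "Diffusion modelling of protein sequence families: methods and design choices"
author: "ProtDiffuser"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion modelling of protein sequence families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProtDiffuser)
```

## The model

ProtDiffuser is a denoising diffusion probabilistic model (DDPM) over
protein sequences represented in a continuous physicochemical space. Each
canonical amino acid is encoded as its eight VHSE descriptors — principal
component scores of hydrophobic, steric and electronic side-chain
properties — so a sequence becomes an $L \times 8$ real matrix in a fixed
frame of $L$ positions (560 for a full cytochrome P450 family frame).
Positions past the end of the sequence are encoded as exact zero vectors
("gaps"), which lets a fixed-size network model variable-length proteins.

The forward process corrupts a clean encoding $x_0$ through a Gaussian
Markov chain with per-step rates $\beta_t$:

$$q(x_t \mid x_0) = \mathcal{N}\!\left(\sqrt{\bar\alpha_t}\,x_0,\;
(1-\bar\alpha_t)\,I\right), \qquad
\bar\alpha_t = \prod_{s \le t} (1 - \beta_s).$$

A denoiser $\hat\epsilon_\theta(x_t, t)$ is trained with the standard
mean-squared-error objective on the added noise, with $t$ drawn uniformly
on $\{1, \dots, T\}$, and sequences are generated by ancestral sampling:

$$x_{t-1} = \frac{1}{\sqrt{\alpha_t}}\left(x_t -
\frac{\beta_t}{\sqrt{1-\bar\alpha_t}}\,\hat\epsilon_\theta(x_t, t)\right) +
\sigma_t z, \qquad \sigma_t^2 = \beta_t,\; z = 0 \text{ at } t = 1.$$

Generated matrices are decoded back to sequences by nearest-neighbour
assignment among the 21 code vectors (20 residues plus the zero gap
vector), with trailing gaps trimmed.

## Key parameters and defaults

* **Frame length** (`frameLength`, default 560): the padded sequence
  frame. It is a first-class parameter so that desk-scale studies can use
  short frames (64 in the benchmark bundle) while keeping the full frame
  exercisable.
* **Diffusion steps** (`steps`, default 600): the sampling depth used for
  full-scale generation; training draws timesteps from the same range,
  and partial-depth sampling is supported.
* **Schedule bounds** (`betaMin`, `betaMax`): linear schedule with
  defaults scaling inversely with $T$ ($0.06/T$ and $\min(24/T,\,0.5)$;
  at $T = 600$: $10^{-4}$ and $0.04$). The conventional constants
  $(10^{-4}, 0.02)$ implicitly assume a 1000-step chain; keeping them at
  $T = 600$ leaves $\bar\alpha_T \approx 2\cdot10^{-3}$, and since VHSE
  entries reach 3.56 the terminal state would retain a statistically
  detectable trace of the signal ($\sqrt{\bar\alpha_T}\,|x_0| \approx
  0.17$) — contradicting the premise that reverse generation may start
  from pure noise. Scaling the bounds keeps the total accumulated noise
  (hence $\bar\alpha_T \approx 5\cdot10^{-6}$) invariant under the choice
  of $T$. The test suite verifies per-coordinate Kolmogorov–Smirnov
  indistinguishability of the terminal distribution from $\mathcal N(0,1)$.
* **Optimizer**: AdamW at learning rate $2\cdot10^{-4}$ (decoupled weight
  decay 0.01), batch size 64, no learning-rate schedule and no gradient
  clipping. The $2\cdot10^{-4}$ default is calibrated to full-scale runs
  of order $10^5$ steps; desk-scale studies of a few thousand steps use a
  proportionally larger rate ($3\cdot10^{-3}$ in the shipped end-to-end
  tests), without which the slow-learning position-specific component of
  the denoiser never converges in the step budget.
* **Emphasis ratio** (default 600): fine-tuning batches are drawn with
  replacement, record $i$ with probability $w_i / \sum_k w_k$, where an
  emphasized subfamily (30 records in the reference configuration)
  carries weight 600 against background weight 1. Sampling with
  replacement per draw is the simplest law consistent with a stated
  *sampling weight ratio*; with 30 emphasized among 19,234 records the
  expected emphasized fraction of a batch is $18{,}000/37{,}204 \approx
  0.484$.
* **VHSE table**: used exactly as published, no rescaling (a
  standardization switch exists but is off by default; nothing in the
  reference training setup suggests standardized descriptors).

## The denoiser

The denoiser is a U-shaped 1-D convolutional network over the VHSE
channel axis: three resolution levels ($L$, $L/2$, $L/4$; default channel
widths 32/64/128), a single-head self-attention block at the bottleneck,
and a sinusoidal-then-linear timestep embedding added as a per-channel
bias inside every residual block ("embedding the timestep linearly into
the convolutions"). Three design details are worth stating explicitly:

* **Positional channels.** Fixed sinusoidal positional encodings are
  concatenated to the 8 input channels. A purely convolutional stack is
  translation-equivariant, but conservation in a protein family is tied
  to absolute frame position; without position information the model
  could not express, say, an invariant tryptophan at position 5.
* **Zero-initialized closers.** The second convolution of each residual
  block, the attention output projection and the final output convolution
  start at zero, so the fresh network predicts zero noise (loss exactly
  the noise variance, 1) and optimization starts from an identity-like
  regime. The backward pass is hand-derived and is verified against
  central finite differences in the unit tests.
* **Position-gated output head.** The ideal noise predictor at a fully
  conserved position $j$ is affine in $x_t$ with a position-specific
  offset $-\sqrt{\bar\alpha_t}/\sqrt{1-\bar\alpha_t}\; v_j$ (where
  $v_j$ is the conserved VHSE vector) — a separable product of a time
  scalar and a static positional vector. The output therefore adds a
  learned per-position bias matrix gated per channel by the timestep
  embedding, which lets conservation structure be learned directly
  instead of only through the convolutional trunk. The gate is
  zero-initialized, so the head is inert at initialization.

All sizes are configurable; desk-scale tests use widths like 12/24/48 on
a 64-position frame.

## Constrained (inpainting) generation and screening

Fixed catalytic residues — by default the five founder residues T114,
F123, A220, M248 and A317 that jointly confer flavone 6-hydroxylase
activity in the CYP706X frame — are enforced by clamping: after every
reverse step to level $t$, the constrained rows are replaced by the
closed-form forward noising of their target VHSE vectors at level $t$,
and by the exact vectors at the final step. The wording "random sequences
with the founder residues as the starting sequence" admits a weaker
reading in which the constraints are written only into the starting
state; both modes are implemented (`clamp = "every-step"` is the default,
`"seed-only"` the literal reading, and `start = "encoded-random"` starts
from an encoded random sequence instead of noise). Clamping makes
constraint satisfaction exact for *any* model, trained or not, which the
tests quantify as 5/5 matched positions in 100% of decoded samples; the
`motifFilter()` screening stage is then a left inverse on constrained
output and is the first stage of any larger screening funnel.

Decoded samples may contain internal gap calls (rows nearest to the zero
vector before the last residue). Since the model emits proteins rather
than alignments, internal gaps are removed from emitted sequences and
counted per sequence in an `internalGaps` field; frame-coordinate strings
(gaps kept as `-`) are available for motif screening and column
statistics.

## The synthetic family generator

`makeBenchmarkSuite()` emulates the structure of the reference corpus at
desk scale: a background family (default 2,000 sequences on a 64-position
frame) with a realistic mixture of fully conserved columns (about 12% of
positions), biased columns (2–4 plausible residues with a dominant one)
and two injected covarying pairs; plus an emphasized subfamily (default
30 sequences) that fixes five founder positions — near-uniform in the
background, so a background sequence matches the full motif with
probability about $20^{-5}$ — and a handful of additional
subfamily-specific conserved positions. Sizes 2,000/30 and ratio 600
mirror the reference fine-tuning configuration at desk scale; 64-position
frames keep a full training-plus-generation cycle in CPU minutes.

What the generator does *not* emulate: phylogenetic correlation between
sequences (records are i.i.d. given the profile), realistic domain
architecture or transmembrane segments, insertion/deletion structure
(all sequences fill the frame), and amino-acid composition biases beyond
the per-column profiles. Passing tests therefore demonstrate that the
machinery recovers designed conservation, covariation and subfamily
structure — not that it matches the statistics of real P450 alignments.

## Numerical choices and degenerate inputs

* Decoding ties (measure zero in practice) break alphabetically; a row
  becomes a gap only when strictly closer to the zero vector, with an
  optional `gapMargin`. Decoding is provably stable under perturbations
  of norm below half the minimal code distance (about 0.54).
* Column statistics exclude gaps from frequency normalization and track
  them separately; entropies and mutual information are in bits. MI is
  reported without average-product correction by default (APC optional).
* The k-tuple distance uses $k = 3$ by default and normalizes shared
  k-mer counts by the smaller k-mer total, giving a symmetric distance in
  $[0,1]$ with zero diagonal. Identity clustering uses a greedy
  longest-first pass over a k-mer identity estimate (CD-HIT-like); the
  exact all-pairs construction appears only as a test oracle.
* Empty sequences encode to all-gap frames and decode back to empty
  strings; zero-step training returns the model unchanged; `n = 0`
  sampling returns an empty batch of the declared shape.
* Every stochastic entry point takes an explicit seed; there is no hidden
  global-RNG contract, and the weighted sampler maintains its own stream.

## Desk-scale problem sizes

The test suite trains on the benchmark bundle (frame 64, 2,000 background
sequences, $T = 100$, 2,000 pretraining steps at batch 64 and learning
rate $3\cdot10^{-3}$, then 800 weighted fine-tuning steps), with the toy
schedule bounds $(6\cdot10^{-4}, 0.12)$ — slightly gentler than the
$24/T$ default, trading a small terminal signal residue
($\bar\alpha_{100} \approx 2\cdot10^{-3}$) for finer reverse steps at
high noise, which measurably improves sample fidelity at $T = 100$.
These are sizes at which per-column frequency recovery
(Spearman $\rho \ge 0.7$ against the training family) and the
fine-tuning shift towards the emphasized subfamily are reliably
observable on a single CPU. The acceptance script trains a short 560-frame
model (400 sequences, 150 steps) solely to exercise founder-constrained
generation at the native coordinates of the founder residues; constraint
satisfaction does not depend on training quality, by construction of the
clamp. Full-scale training (hundreds of thousands of sequences and
training steps on GPUs) is out of scope.

## Known limitations

* The reverse-process variance uses the simplest choice
  $\sigma_t^2 = \beta_t$; no learned or lower-bound-optimal variances.
* One attention head at one resolution; no normalization layers (stable
  at desk scale thanks to the zero-init residual design, but full-scale
  training would likely want group normalization).
* The k-tuple distance is a documented, oracle-tested member of the
  k-tuple family; numerical agreement with any particular external
  implementation is not claimed.
* Greedy identity clustering depends on input order (longest first) and
  a k-mer identity estimate, like the fast clustering tools it mirrors;
  it is not an exact-identity partition.
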