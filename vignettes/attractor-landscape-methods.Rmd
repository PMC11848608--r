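---
title: "Quantifying tumor attractor landscapes and screening reversion switches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor attractor landscapes and screening reversion switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolscape)
```

## The model

boolscape treats tumorigenesis as a trajectory on a Waddington-style
epigenetic landscape whose wells are the attractors of a Boolean gene
regulatory network (GRN). A normal tissue state and a tumor state are two
stable attractors of one shared network; in between lies a *transition
state* in which cells of normal and cancer origin coexist and hop
stochastically between basins. Under an ergodic reading of a single-cell
snapshot, the cross-sectional heterogeneity of a patient sample traces out
that whole temporal process, which is what makes a mechanistic model
identifiable from one snapshot.

The pipeline has four stages, each usable on its own:

1. **Transition-state calling.** Cells are placed on a BIONJ phylogeny built
   from Euclidean distances between per-cell copy-number profiles. The tree
   is cut into clades (default 30) by greedily removing the longest internal
   edges, and each clade's normal/cancer mixture is scored by binary Shannon
   entropy \(H = -p\log_2 p - (1-p)\log_2(1-p)\), \(p = N_n/(N_n+N_c)\).
   Clades with \(H \ge 0.8\) bits are called the transition state. The 0.8
   bit default is our choice where only a "marked increase" is specified: it
   is the smallest round threshold that admits a 3:1 mixture
   (\(H \approx 0.811\)) while excluding anything purer. The
   critical-transition index — mean absolute pairwise Pearson correlation
   between genes divided by the same between cells — is provided as an
   independent tipping-point diagnostic; we use Pearson with absolute
   values, following the index's original literature, since the choice is
   otherwise underdetermined.

2. **GRN skeleton construction.** Expression along a supplied pseudotime
   ordering is smoothed by a centered moving average (default window 8% of
   the cell count, inside the 10% bound; edges truncate), binarized per gene
   by exact 1-D two-means (higher-mean cluster is 1; a constant gene flags
   itself and maps to 0), and used to prune a prior signed network: an edge
   survives if |Spearman ρ| between its endpoints' smoothed profiles is at
   least the cutoff (default 0.7), and its sign is taken from the data,
   overriding the prior on conflict. Terminal (outdegree-0) nodes are
   removed iteratively, the union of strongly connected components of size
   ≥ 2 is kept (singleton SCCs carry no feedback; bridges between retained
   nodes stay), and any node left without an activating input receives a
   self-activation edge. Pruning is applied to prior edges only, not to all
   gene pairs: the filter's role is to remove unsupported *interactions*,
   not to invent new ones.

3. **Rule inference.** For each gene we form input–output pairs
   \((I_t, O_{t+k})\) from the binarized matrix, where \(I_t\) is the
   regulator state at ordered position \(t\) and \(k\) strictly exceeds the
   smoothing window so input and output windows cannot overlap. Candidate
   Boolean functions are all truth tables over the gene's regulators that
   are monotone consistent with each edge sign and essential in every
   regulator; with at most 4 regulators (larger sets are cut to the four
   strongest |Spearman| partners) the class is small enough to enumerate
   exhaustively and deterministically, which replaces a SAT/SMT-solver
   dependency with a reproducible search over an explicit class. Each
   candidate is scored by \(S(f) = \sum_t [f(I_t) = O_{t+k}]\); the argmax
   is selected, and ties at the maximum are combined by pointwise OR with
   the tied set recorded and the combined rule re-scored.

4. **Landscape quantification and screening.** Under synchronous update the
   network's attractors and basins are found either exhaustively (all
   \(2^n\) states, the default up to 14 genes) or from random initial
   states (default 1000). Anchors \(v_N, v_C\) are the per-gene rounded
   means of the binarized profiles of cells within 20% of either pseudotime
   end (ties round to 1). Every attractor gets
   \(d = (v - v_N)\cdot(v_C - v_N) / |v_C - v_N|^2\) (cyclic attractors:
   the mean over cycle states), a basin fraction, and an *attractor
   entropy*: from each (sampled) basin state, repeatedly pick one gene at
   random, randomly permute its truth-table outputs, relax the perturbed
   network, and map the outcome back to an original attractor by
   re-converging it under the original rules; \(S_i^j\) is the entropy of
   the outcome distribution and \(S_k\) its basin mean. The scalar summary
   is
   \[\mathrm{CancerScore} = \sum_k \Big(1-\frac{S_k}{S_{max}}\Big)\cdot
   \frac{B_k}{\sum_j B_j}\cdot d_k, \qquad S_{max} = \log_2 N.\]
   The screen fixes each gene to 0 (knockdown) or 1 (overexpression),
   re-quantifies the landscape per fixation with a deterministic seed
   offset, ranks by ascending score, then evaluates all pairs among the top
   5 distinct single hits; a final score ≤ 0.1 counts as successful
   reversion. The ensemble scan repeats everything over a hyperparameter
   grid, admits runs with 10–30 network genes and initial score > 0.5, and
   tallies perturbation sets scoring < 0.15 across admitted runs.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| smoothing window | 8% of cells | cells | inside the 10% bound; wide enough to kill flip noise |
| step size k | window + 1 or the generator's dwell | cells | smallest non-overlapping step; must exceed the window |
| correlation cutoff | 0.7 | – | prior-edge admission threshold |
| entropy threshold | 0.8 | bits | admits a 3:1 clade mixture, excludes purer clades |
| n_clades | 30 | – | resolution of the phylogeny cut |
| random initial states | 1000 | states | basin estimation in sampled mode |
| perturbations/state | 100 | trials | attractor-entropy resolution |
| basin cap | 512 | states | entropy sampling bound per basin |
| max regulators | 4 | – | keeps the candidate class enumerable (≤ 168 tables) |

## What the synthetic generator emulates — and what it does not

`make_bistable_network()` builds a sign-labelled network with a
*master toggle switch* (gene 1: self-activation plus mutual inhibition with
gene 2) whose two poles are verified fixed points, designated normal and
cancer. Secondary pairs are mutually inhibiting modules slaved to the
master poles with staggered response times; remaining genes are
identity/NOT followers. `simulate_trajectory()` produces the
normal-to-cancer path as a *driven relaxation*: the master gene is
exogenously flipped to its cancer value and the network relaxes
synchronously to the cancer attractor, with each intermediate macro-state
dwelling exactly `dwell` consecutive cells (leftover cells extend the
stable ends, centering the cascade). Two design choices deserve emphasis:

* **Why a driven relaxation rather than independent per-gene
  changepoints.** An interpolated backbone with arbitrary changepoints is
  inconsistent with *any* static Boolean rule near a switch: the input
  precedes the change, the output follows it, and the same input state
  appears with both outputs. A driven relaxation sampled at the step size
  \(k = \text{dwell}\) makes every gene's input–output pairs exactly
  consistent with its generating rule — except the exogenously driven
  master gene itself, whose true rule is still the strict argmax. This is
  what makes exact rule recovery a meaningful test rather than a lottery.
* **Why expression carries a drift term.** Continuous expression is the
  binary value plus a bounded jitter in \([0, 0.3]\), 70% of which is a
  monotone drift toward the gene's cancer-pole value. Real transition
  trajectories change expression progressively, not only at a switch; a
  flat plateau with i.i.d. jitter would also make within-plateau ranks
  random and structurally attenuate the Spearman correlations the pruning
  stage relies on.

The generator does **not** emulate scRNA-seq count noise (dropout, library
size, overdispersion), doublets, cell-cycle structure, or CNV inference
error; its CNV fixture plants one shared gain/loss profile with Gaussian
bin noise and a mixed clade halfway between the poles. Passing tests
therefore demonstrate that the machinery is correct under the model's own
assumptions, not that those assumptions hold in any particular dataset.

## Numerical choices and degenerate inputs

* Binarization is *exact* 1-D two-means (exhaustive split minimizing
  within-cluster sum of squares; first minimum on ties), not Lloyd
  iteration, so it is deterministic; constant genes binarize to 0 with a
  flag.
* Attractor cycles are canonicalized by rotating the lexicographically
  smallest state first; attractors order by descending basin, then
  lexicographic state, so results are stable across runs.
* Negative NJ branch lengths (a known neighbor-joining artefact) clamp
  to 0. Clade cutting skips an edge whose removal would strand a leaf-free
  component, and falls back to pendant edges when internal edges run out
  (so `n_clades = n_leaves` yields singletons). Ties break by edge order.
* In Spearman pruning, a correlation that is NA (constant profile) drops
  the edge; an empty pruned network raises an explicit error, as does a
  network with no SCC of size ≥ 2 (no feedback, hence no multistability to
  analyze).
* A single-attractor landscape has \(S_{max} = \log_2 1 = 0\); the depth
  weight \(1 - S_k/S_{max}\) is defined as 1 there (both terms vanish), so
  the score degenerates to that attractor's clamped \(d\).
* \(d\) is clamped at 0 inside the cancer score only — a valley "behind"
  the normal anchor contributes no malignancy — and reported unclamped
  elsewhere. For binary states and binary anchors \(d\) always lies in
  \([0,1]\); the clamp matters only for non-binary inputs.
* Perturbed relaxations that land in an attractor the original search never
  saw (possible in sampled mode) count as their own outcome category, so
  outcome probabilities still sum to 1.
* The per-fixation seed is the screen seed plus the fixation index, so any
  single fixation can be reproduced bit-identically outside the screen.

## Problem sizes used in the tests

The test-suite and the acceptance script run entirely on synthetic data at
desk scale, chosen so the full suite completes in well under a minute of
compute per module: 8-gene fixtures with 2 toggle pairs and 200 cells for
recovery and screening (20 seeds each), a 14-gene / 5-pair fixture for the
ensemble scan (where the 10-node SCC lands inside the 10–30 admission
window), 60-cell CNV fixtures, exhaustive attractor search (≤ 2^12 states),
and 15–100 perturbation trials per basin state with basin caps of 32–128.
These are resolution knobs of the analysis, not of the model: the paper-
scale defaults (1000 initial states, 100 trials, cap 512) remain the
function defaults.

## Known limitations

* Rule inference assumes the pruned skeleton's regulator sets are correct;
  it cannot add a regulator the prior lacks, and candidate functions never
  include regulators outside the skeleton.
* OR-combination of tied rules biases toward permissive (easily activated)
  logic; with short trajectories this can make rising genes "sticky"
  (self-sustaining), which is faithful to the tie-handling rule but worth
  remembering when interpreting screens.
* Attractor entropy is a sampling estimate; two screens agree only when run
  with the same seed policy and budgets.
* Exhaustive attractor search is capped at 25 genes by contract (and is
  practical well below that); beyond it, sampled mode can miss small
  basins, and basin fractions are estimates of basin measure under the
  uniform initial distribution.
* The critical-transition index is reported, not thresholded: its absolute
  scale depends on the noise model, so only its relative rise along a
  trajectory is interpretable.
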