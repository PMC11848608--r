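# boolscape

Boolean attractor-landscape analysis of tumor transition states, and in-silico
screening for gene perturbations that revert a cancerous landscape back to the
normal state.

## Who this is for

Systems biologists working with single-cell transcriptomes of tumors who want
to go beyond clustering: identify the *transition state* where normal- and
cancer-origin cells mix, build an executable Boolean model of the core
regulatory circuit driving the transition, and ask — quantitatively — which one
or two gene fixations (knockdown or overexpression) would collapse the cancer
valley of the landscape.

## The model in brief

Cell states are binary vectors over a small gene regulatory network (GRN);
dynamics are synchronous Boolean updates, whose attractors are the stable cell
fates. The package:

1. calls the **transition state** from a CNV-based BIONJ phylogeny by cutting
   it into clades and scoring each clade's normal/cancer mixture with binary
   Shannon entropy, H = −p·log₂p − (1−p)·log₂(1−p), flagging clades with
   H ≥ 0.8 bits; a critical-transition index (mean |gene–gene correlation| /
   mean |cell–cell correlation|) is provided as a tipping-point diagnostic;
2. builds a **GRN skeleton** from a prior signed network by smoothing
   pseudotime-ordered expression (moving average, window < 10% of cells),
   pruning edges with |Spearman ρ| < 0.7, removing terminal nodes, keeping the
   strongly connected feedback core, and adding self-activation where a node
   lacks activating input;
3. infers per-gene **Boolean rules** by exhaustively scoring every
   sign-monotone, all-regulators-essential truth table against input–output
   pairs (I_t, O_{t+k}) along pseudotime, S(f) = Σ_t [f(I_t) = O_{t+k}],
   OR-combining tied optima;
4. quantifies the **attractor landscape**: basin sizes from exhaustive or
   sampled search, projection of each attractor onto the normal–cancer axis,
   d = (v − v_N)·(v_C − v_N)/|v_C − v_N|², perturbation-based attractor
   entropy S_k, and the scalar

   CancerScore = Σ_k (1 − S_k/S_max) · (B_k / Σ_j B_j) · d_k,  S_max = log₂N;

5. **screens** all single and top-5-pair double gene fixations for cancer-score
   minimization (success: final score ≤ 0.1), scans a hyperparameter ensemble
   for robust targets, and extracts common targets of two transcription
   factors from a regulon edge list.

A first-class synthetic-data module generates ground-truth bistable networks,
driven normal-to-cancer trajectories, and CNV matrices with a planted mixed
clade, so the full pipeline is testable without any external data.

## Worked example

```r
library(boolscape)

gt <- make_bistable_network(n_genes = 8, n_toggle_pairs = 2, seed = 7)
tr <- simulate_trajectory(gt, n_cells = 200, flip_noise = 0.05, seed = 7)

build <- build_grn(tr, network_edges(gt$network), window = max(1, tr$dwell %/% 2))
net <- infer_network(build$binarized[, build$skeleton$nodes], build$skeleton,
                     k = tr$dwell, window = build$window)
net
#> Boolean network with 4 genes
#>   g01 <- (g01 & !g02)
#>   g02 <- (!g01 & !g02) | (!g01 & g02) | (g01 & g02)
#>   g03 <- (!g02 & !g03 & !g04) | (!g02 & g03 & !g04) | (!g02 & g03 & g04)
#>   g04 <- (g02 & !g03)
```

The pipeline reduced the 8-gene fixture to its 4-gene feedback core and
recovered executable rules (average agreement level 0.976 across genes, i.e.
the rules reproduce 97.6% of the lagged input–output pairs despite 5% flip
noise). Now quantify the landscape between the pseudotime-end anchors and
screen perturbations:

```r
an  <- anchor_states(tr, genes = net$genes)
ls0 <- landscape_summary(net, an$v_n, an$v_c, method = "exhaustive", seed = 1)
ls0
#> Attractor landscape: 2 attractor(s), S_max = 1, cancer score = 0.75
#>  attractor length basin fraction d      S
#>          1      1    12     0.75 1 0.0000
#>          2      1     4     0.25 0 0.9531

pp <- default_screen_params(method = "exhaustive")
sg <- screen_single(net, an$v_n, an$v_c, params = pp, seed = 1)
db <- screen_double(net, an$v_n, an$v_c, sg, params = pp, seed = 1)
head(db, 3)
#>        label gene1 value1 gene2 value2 cancer_score n_attractors success rank
#>  g02=0+g01=1   g02      0   g01      1    0.0000000            1    TRUE    1
#>  g02=0+g04=0   g02      0   g04      0    0.1352974            2   FALSE    2
#>  g02=0+g03=1   g02      0   g03      1    0.1487337            2   FALSE    3
```

Reading the numbers: the unperturbed landscape is malignant — the cancer
attractor (d = 1) is deep (entropy 0) and owns 75% of state space, giving
cancer score 0.75. The top-ranked double fixation knocks down gene g02 and
overexpresses g01 — exactly the two poles of the master toggle switch the
generator planted — leaving a single attractor at the normal state and a
cancer score of 0, a successful in-silico reversion (≤ 0.1).

A thin command-line wrapper over the same functions ships at
`inst/cli/boolscape.R` (subcommands `simulate`, `transition`, `build-grn`,
`infer-rules`, `landscape`, `screen`, `common-targets`).

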