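# Shared fixtures, built in code.

# the canonical toggle switch: A = !B, B = !A
toggle_net <- function() {
  boolean_network(list(
    boolean_rule("A", "B", c(1L, 0L), -1L),
    boolean_rule("B", "A", c(1L, 0L), -1L)
  ))
}

# A activates B, B inhibits A: A' = !B, B' = A (one 4-cycle)
cycle_net <- function() {
  boolean_network(list(
    boolean_rule("A", "B", c(1L, 0L), -1L),
    boolean_rule("B", "A", c(0L, 1L), 1L)
  ))
}

# full pipeline on the synthetic bistable fixture: simulate -> build -> infer
run_pipeline <- function(seed, n_genes = 8L, n_pairs = 2L, n_cells = 200L,
                         flip_noise = 0) {
  gt <- make_bistable_network(n_genes, n_pairs, seed = seed)
  tr <- simulate_trajectory(gt, n_cells, flip_noise, seed = seed)
  window <- max(1L, tr$dwell %/% 2L)
  build <- build_grn(tr, network_edges(gt$network), window = window)
  net <- infer_network(build$binarized[, build$skeleton$nodes, drop = FALSE],
                       build$skeleton, k = tr$dwell, window = window)
  anchors <- anchor_states(tr, genes = net$genes)
  list(gt = gt, tr = tr, build = build, net = net, anchors = anchors)
}

fast_params <- function() {
  default_screen_params(method = "exhaustive", n_perturbations = 30L,
                        basin_cap = 64L)
}
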