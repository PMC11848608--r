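# Synthetic ground truth: bistable toggle-switch networks, driven
# normal-to-cancer trajectories, and two-clade CNV matrices with a planted
# mixed (transition) clade. Everything is bit-reproducible under a seed.

#' Generate a bistable ground-truth Boolean network
#'
#' Builds a sign-labelled network containing \code{n_toggle_pairs}
#' mutual-inhibition pairs plus identity/NOT follower genes, with two verified
#' point attractors designated the normal and cancer states. The first pair is
#' the master switch: gene 1 carries self-activation and is the gene whose
#' exogenous flip drives the normal-to-cancer transition in
#' \code{\link{simulate_trajectory}}.
#'
#' @param n_genes total gene count (2 to 30).
#' @param n_toggle_pairs number of mutual-inhibition pairs (>= 1);
#'   requires \code{n_genes >= 2 * n_toggle_pairs}.
#' @param seed integer seed controlling follower wiring.
#' @return an object of class \code{ground_truth} with elements
#'   \code{network}, \code{normal_state}, \code{cancer_state} (named 0/1
#'   vectors), \code{master} (the driver gene) and \code{seed}.
#' @export
make_bistable_network <- function(n_genes, n_toggle_pairs = 1L, seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_toggle_pairs <- as.integer(n_toggle_pairs)
  if (n_genes < 2L || n_genes > 30L) stop("n_genes must be in [2, 30]")
  if (n_toggle_pairs < 1L) stop("n_toggle_pairs must be >= 1")
  if (n_genes < 2L * n_toggle_pairs) stop("n_genes must be >= 2 * n_toggle_pairs")
  genes <- sprintf("g%02d", seq_len(n_genes))
  set.seed(seed)
  rules <- vector("list", n_genes)
  normal <- integer(n_genes)
  cancer <- integer(n_genes)
  # master pair: g1 = g1 & !g2 (self-activation + cross-inhibition), g2 = !g1
  rules[[1]] <- boolean_rule(genes[1], genes[1:2], c(0L, 0L, 1L, 0L), c(1L, -1L))
  rules[[2]] <- boolean_rule(genes[2], genes[1], c(1L, 0L), -1L)
  normal[1:2] <- c(1L, 0L); cancer[1:2] <- c(0L, 1L)
  if (n_toggle_pairs > 1L) {
    for (i in 2:n_toggle_pairs) {
      p <- 2L * i - 1L; q <- 2L * i
      # secondary mutual-inhibition pairs slaved to the master poles:
      # p = p & !g2 & !q (self-sustaining until the master flips),
      # q = g2 & !p. Their switch times are staggered one step apart along
      # the driven relaxation, which keeps each rule uniquely identifiable
      # from lagged input-output pairs.
      rules[[p]] <- boolean_rule(genes[p], c(genes[2], genes[p], genes[q]),
                                 c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
                                 c(-1L, 1L, -1L))
      rules[[q]] <- boolean_rule(genes[q], c(genes[2], genes[p]),
                                 c(0L, 0L, 1L, 0L), c(1L, -1L))
      normal[c(p, q)] <- c(1L, 0L); cancer[c(p, q)] <- c(0L, 1L)
    }
  }
  first_follower <- 2L * n_toggle_pairs + 1L
  if (first_follower <= n_genes) {
    for (j in first_follower:n_genes) {
      reg <- sample.int(j - 1L, 1L)
      negate <- stats::runif(1) < 0.5
      tab <- if (negate) c(1L, 0L) else c(0L, 1L)
      rules[[j]] <- boolean_rule(genes[j], genes[reg], tab,
                                 if (negate) -1L else 1L)
      normal[j] <- if (negate) 1L - normal[reg] else normal[reg]
      cancer[j] <- if (negate) 1L - cancer[reg] else cancer[reg]
    }
  }
  net <- boolean_network(rules)
  names(normal) <- genes; names(cancer) <- genes
  compiled <- compile_network(net)
  if (!identical(synchronous_step(net, normal, compiled), unname(normal)) ||
      !identical(synchronous_step(net, cancer, compiled), unname(cancer))) {
    stop("internal error: designated states are not fixed points")
  }
  if (identical(normal, cancer)) stop("internal error: degenerate poles")
  structure(list(network = net, normal_state = normal, cancer_state = cancer,
                 master = genes[1], seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", length(x$network$genes), "genes, master switch", x$master, "\n")
  cat("  normal:", paste(x$normal_state, collapse = ""), "\n")
  cat("  cancer:", paste(x$cancer_state, collapse = ""), "\n")
  invisible(x)
}

#' Simulate a pseudotime trajectory between the network's two poles
#'
#' The noiseless backbone is a driven synchronous relaxation: the master
#' switch gene is exogenously fixed to its cancer-pole value and the network
#' is iterated from the normal state until it settles in the cancer state.
#' Each macro-state dwells exactly \code{dwell} consecutive cells, so an
#' input-output pair taken at step size \code{k = dwell} is exactly consistent
#' with the generating rules for every gene except the driven master (whose
#' flip is exogenous by construction). Leftover cells extend the first
#' (normal) and last (cancer) blocks. Binarized entries are then flipped
#' independently with probability \code{flip_noise}, and continuous expression
#' is the binary value plus Uniform(0, 0.3) jitter, so two-means binarization
#' is exactly recoverable.
#'
#' @param gt a \code{\link{make_bistable_network}} result.
#' @param n_cells number of cells.
#' @param flip_noise per-entry flip probability, in [0, 0.5).
#' @param seed integer seed.
#' @param dwell cells per macro-state; default spreads macro-states evenly.
#' @return an object of class \code{trajectory_data}: pseudotime-ordered cell
#'   ids, pseudotime in [0, 1], raw expression, binarized and noiseless
#'   backbone matrices, origin labels, and the \code{dwell} to use as the
#'   inference step size.
#' @export
simulate_trajectory <- function(gt, n_cells, flip_noise = 0, seed = 1L, dwell = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  n_cells <- as.integer(n_cells)
  if (!is.numeric(flip_noise) || flip_noise < 0 || flip_noise >= 0.5) {
    stop("flip_noise must be in [0, 0.5)")
  }
  net <- gt$network
  n <- length(net$genes)
  driven <- apply_fixation(net, stats::setNames(gt$cancer_state[gt$master], gt$master))
  compiled <- compile_network(driven)
  macro <- list(unname(gt$normal_state))
  cur <- unname(gt$normal_state)
  for (step in seq_len(4L * n + 8L)) {
    nxt <- synchronous_step(driven, cur, compiled)
    if (identical(nxt, cur)) break
    macro[[length(macro) + 1L]] <- nxt
    cur <- nxt
  }
  if (!identical(cur, unname(gt$cancer_state))) {
    stop("driven relaxation did not reach the cancer state")
  }
  L <- length(macro)
  # default dwell compresses the cascade around the pseudotime centre so that
  # genes adjacent in the regulatory cascade (one dwell apart in changepoint)
  # stay strongly rank-correlated for downstream pruning
  if (is.null(dwell)) dwell <- max(1L, n_cells %/% (2L * L))
  dwell <- as.integer(dwell)
  if (n_cells < L * dwell) stop("n_cells too small for ", L,
                                " macro-states at dwell ", dwell)
  extra <- n_cells - L * dwell
  lens <- rep(dwell, L)
  lens[1] <- lens[1] + extra %/% 2L
  lens[L] <- lens[L] + extra - extra %/% 2L
  backbone <- do.call(rbind, mapply(function(st, l) {
    matrix(st, nrow = l, ncol = n, byrow = TRUE)
  }, macro, lens, SIMPLIFY = FALSE))
  colnames(backbone) <- net$genes
  set.seed(seed)
  flips <- matrix(stats::rbinom(n_cells * n, 1L, flip_noise), nrow = n_cells)
  binarized <- abs(backbone - flips)
  # bounded positive jitter in [0, 0.3]: 70% a monotone drift toward the
  # gene's cancer-pole value (expression changes progressively along the
  # trajectory, not only at the switch) + 30% uniform noise; the plateaus
  # stay separated so two-means binarization recovers the binary values
  pt <- seq(0, 1, length.out = n_cells)
  rising <- gt$cancer_state >= gt$normal_state
  drift <- outer(pt, ifelse(rising, 1, -1))
  drift <- (drift + 1) / 2    # in [0,1], increasing toward the cancer value
  jitter <- 0.3 * (0.7 * drift + 0.3 * matrix(stats::runif(n_cells * n), n_cells))
  expr <- binarized + jitter
  colnames(expr) <- net$genes
  cell_ids <- sprintf("cell_%04d", seq_len(n_cells))
  rownames(backbone) <- rownames(binarized) <- rownames(expr) <- cell_ids
  d_norm <- rowSums(backbone != matrix(gt$normal_state, n_cells, n, byrow = TRUE))
  d_canc <- rowSums(backbone != matrix(gt$cancer_state, n_cells, n, byrow = TRUE))
  labels <- ifelse(d_norm <= d_canc, "normal", "cancer")
  structure(list(cell_ids = cell_ids,
                 pseudotime = seq(0, 1, length.out = n_cells),
                 expr = expr, binarized = binarized, backbone = backbone,
                 smoothed = NULL,
                 labels = data.frame(cell_id = cell_ids, origin = labels,
                                     stringsAsFactors = FALSE),
                 genes = net$genes, dwell = dwell, n_macro = L, seed = seed),
            class = "trajectory_data")
}

#' @export
print.trajectory_data <- function(x, ...) {
  cat("Trajectory:", length(x$cell_ids), "cells x", length(x$genes),
      "genes;", x$n_macro, "macro-states, dwell", x$dwell, "\n")
  invisible(x)
}

#' Generate a cell-by-bin CNV fixture with a planted mixed clade
#'
#' Normal cells sit at a flat diploid baseline, cancer cells share a planted
#' segment-level gain/loss profile, and mixed cells sit halfway between the
#' two with labels split evenly between normal and cancer origin -- so the
#' downstream phylogeny contains two pure clades plus one maximally mixed
#' (high-entropy) clade.
#'
#' @param n_normal,n_cancer,n_mixed cell counts (mixed may be 0).
#' @param n_bins genomic bin count.
#' @param seed integer seed.
#' @param noise_sd per-bin Gaussian noise standard deviation.
#' @return list with \code{cnv} (cells x bins matrix, rownames = cell ids),
#'   \code{labels} (data.frame cell_id, origin) and \code{profile} (the
#'   planted cancer gain/loss vector).
#' @export
make_cnv_fixture <- function(n_normal, n_cancer, n_mixed = 0L, n_bins = 200L,
                             seed = 1L, noise_sd = 0.05) {
  stopifnot(n_normal >= 1L, n_cancer >= 1L, n_mixed >= 0L, n_bins >= 10L)
  set.seed(seed)
  n_seg <- max(2L, n_bins %/% 20L)
  seg <- sort(rep_len(seq_len(n_seg), n_bins))
  repeat {
    delta_seg <- sample(c(-1, 0, 1), n_seg, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    if (any(delta_seg != 0)) break
  }
  profile <- delta_seg[seg]
  ids <- c(sprintf("norm_%03d", seq_len(n_normal)),
           sprintf("canc_%03d", seq_len(n_cancer)),
           if (n_mixed) sprintf("mix_%03d", seq_len(n_mixed)))
  w <- c(rep(0, n_normal), rep(1, n_cancer),
         if (n_mixed) 0.5 + stats::runif(n_mixed, -0.05, 0.05))
  n_cells <- length(ids)
  cnv <- matrix(2, n_cells, n_bins) + outer(w, profile) +
    matrix(stats::rnorm(n_cells * n_bins, 0, noise_sd), n_cells)
  rownames(cnv) <- ids
  colnames(cnv) <- sprintf("bin_%04d", seq_len(n_bins))
  origin <- c(rep("normal", n_normal), rep("cancer", n_cancer),
              if (n_mixed) rep_len(c("normal", "cancer"), n_mixed))
  list(cnv = cnv,
       labels = data.frame(cell_id = ids, origin = origin, stringsAsFactors = FALSE),
       profile = profile)
}
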