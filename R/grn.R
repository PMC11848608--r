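# Network skeleton construction: smoothing, binarization, correlation
# pruning, terminal-node removal, SCC extraction, self-activation.

#' Centered moving average with truncated edges
#'
#' Window positions falling outside the series are truncated, so the output
#' has the same length as the input. For even windows the extra position is
#' taken on the right.
#'
#' @param x numeric series over pseudotime-ordered cells.
#' @param window full window width (>= 1, <= length(x)).
#' @param max_fraction optional cap on window as a fraction of the series
#'   length (the pipeline uses 0.10).
#' @return smoothed numeric vector, same length as \code{x}.
#' @export
smooth_series <- function(x, window, max_fraction = NULL) {
  n <- length(x)
  window <- as.integer(window)
  if (window < 1L || window > n) stop("window must be in [1, length(x)]")
  if (!is.null(max_fraction) && window > floor(max_fraction * n)) {
    stop("window exceeds ", max_fraction * 100, "% of the cell count")
  }
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth every gene of an expression matrix
#' @param expr cells x genes matrix, rows in pseudotime order.
#' @inheritParams smooth_series
#' @return matrix of the same shape.
#' @export
smooth_matrix <- function(expr, window, max_fraction = NULL) {
  out <- apply(expr, 2, smooth_series, window = window, max_fraction = max_fraction)
  dimnames(out) <- dimnames(expr)
  out
}

#' Binarize a smoothed series by exact two-means clustering
#'
#' Optimal 1-D 2-means: every split of the sorted values is scored by total
#' within-cluster sum of squares and the minimiser chosen (first minimum on
#' ties); the cluster with the higher mean maps to 1. A constant series
#' binarizes to all zeros and carries attribute \code{constant = TRUE}.
#'
#' @param x numeric series.
#' @return integer 0/1 vector; attribute \code{constant} flags degenerate
#'   input.
#' @export
binarize_series <- function(x) {
  n <- length(x)
  if (length(unique(x)) == 1L) {
    out <- integer(n)
    attr(out, "constant") <- TRUE
    return(out)
  }
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  splits <- which(diff(xs) > 0)     # split after position s; clusters by value
  wss <- vapply(splits, function(s) {
    (cs2[s] - cs[s]^2 / s) +
      ((cs2[n] - cs2[s]) - (cs[n] - cs[s])^2 / (n - s))
  }, numeric(1))
  s <- splits[which.min(wss)]
  thr <- (xs[s] + xs[s + 1L]) / 2
  as.integer(x > thr)
}

#' Binarize every gene of a smoothed matrix
#' @param expr cells x genes matrix.
#' @return integer matrix of the same shape; attribute
#'   \code{constant_genes} lists genes that were constant.
#' @export
binarize_matrix <- function(expr) {
  cols <- lapply(seq_len(ncol(expr)), function(j) binarize_series(expr[, j]))
  out <- do.call(cbind, cols)
  dimnames(out) <- dimnames(expr)
  const <- vapply(cols, function(cl) isTRUE(attr(cl, "constant")), logical(1))
  attr(out, "constant_genes") <- colnames(expr)[const]
  out
}

#' Prune a prior network by Spearman correlation on smoothed expression
#'
#' Keeps edges whose endpoints correlate with \code{|rho| >= cutoff}; the
#' retained edge's sign is the sign of the correlation, overriding any prior
#' sign (disagreements are reported via \code{message}). Nodes absent from
#' the expression matrix are dropped.
#'
#' @param prior a \code{\link{signed_network}}.
#' @param smoothed cells x genes smoothed expression matrix.
#' @param cutoff absolute Spearman correlation cutoff (default 0.7).
#' @return the pruned \code{\link{signed_network}}.
#' @export
prune_by_correlation <- function(prior, smoothed, cutoff = 0.7) {
  stopifnot(inherits(prior, "signed_network"))
  genes <- colnames(smoothed)
  keep_nodes <- intersect(prior$nodes, genes)
  e <- prior$edges
  e <- e[e$source %in% keep_nodes & e$target %in% keep_nodes, , drop = FALSE]
  if (!nrow(e)) stop("no prior edges reference genes in the expression matrix")
  rho <- vapply(seq_len(nrow(e)), function(i) {
    suppressWarnings(stats::cor(smoothed[, e$source[i]], smoothed[, e$target[i]],
                                method = "spearman"))
  }, numeric(1))
  keep <- !is.na(rho) & abs(rho) >= cutoff
  if (!any(keep)) stop("correlation pruning removed every edge (empty network)")
  new_sign <- as.integer(sign(rho[keep]))
  old_sign <- e$sign[keep]
  conflicts <- sum(!is.na(old_sign) & old_sign != new_sign)
  if (conflicts > 0) {
    message(conflicts, " edge sign(s) overridden by data correlation")
  }
  e <- e[keep, , drop = FALSE]
  e$sign <- new_sign
  signed_network(e, nodes = keep_nodes)
}

#' Iteratively remove terminal (outdegree-zero) nodes
#'
#' Genes that regulate nothing cannot influence the dynamics; removing them
#' may expose new terminal nodes, so deletion iterates to a fixpoint. A
#' self-loop counts as outdegree.
#'
#' @param net a \code{\link{signed_network}}.
#' @return the trimmed \code{\link{signed_network}} (possibly empty).
#' @export
remove_terminal_nodes <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  nodes <- net$nodes
  e <- net$edges
  repeat {
    terminal <- setdiff(nodes, unique(e$source))
    if (!length(terminal)) break
    nodes <- setdiff(nodes, terminal)
    e <- e[!(e$source %in% terminal) & !(e$target %in% terminal), , drop = FALSE]
  }
  signed_network(e, nodes = nodes)
}

#' Extract the feedback core: strongly connected components of size >= 2
#'
#' Keeps every node belonging to a nontrivial SCC, plus all edges among
#' retained nodes (including bridges between SCCs). Singleton SCCs carry no
#' feedback and are excluded.
#'
#' @param net a \code{\link{signed_network}}.
#' @return the SCC-restricted \code{\link{signed_network}}.
#' @export
extract_scc <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  if (!nrow(net$edges)) stop("network contains no feedback (no SCC of size >= 2)")
  g <- igraph::graph_from_data_frame(net$edges[, c("source", "target")],
                                     directed = TRUE, vertices = net$nodes)
  comp <- igraph::components(g, mode = "strong")
  big <- which(tabulate(comp$membership) >= 2L)
  if (!length(big)) stop("network contains no feedback (no SCC of size >= 2)")
  keep <- net$nodes[comp$membership %in% big]
  e <- net$edges[net$edges$source %in% keep & net$edges$target %in% keep, , drop = FALSE]
  signed_network(e, nodes = keep)
}

#' Add self-activation to nodes lacking any activating input
#'
#' @param net a \code{\link{signed_network}}.
#' @return the \code{\link{signed_network}} with \code{(node, node, +1)}
#'   edges added where needed.
#' @export
add_self_activation <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges
  activated <- unique(e$target[!is.na(e$sign) & e$sign > 0])
  lacking <- setdiff(net$nodes, activated)
  if (length(lacking)) {
    e <- rbind(e, data.frame(source = lacking, target = lacking, sign = 1L,
                             stringsAsFactors = FALSE))
  }
  signed_network(e, nodes = net$nodes)
}

#' Build a pruned GRN skeleton from a trajectory and a prior network
#'
#' Runs the full structural pipeline: smooth (window defaults to 8% of the
#' cell count, within the 10% bound), binarize, prune prior edges at the
#' correlation cutoff, iteratively remove terminal nodes, restrict to the
#' strongly connected feedback core, and add self-activation where a node
#' lacks activating input.
#'
#' @param traj a \code{\link{simulate_trajectory}} result, or any list with
#'   \code{expr} (cells x genes, pseudotime-ordered) and \code{pseudotime}.
#' @param prior a \code{\link{signed_network}}.
#' @param cutoff Spearman cutoff (default 0.7).
#' @param window smoothing window; default \code{floor(0.08 * n_cells)}.
#' @return list of class \code{grn_build}: \code{skeleton}
#'   (\code{signed_network}), \code{smoothed}, \code{binarized}, and
#'   \code{window}.
#' @export
build_grn <- function(traj, prior, cutoff = 0.7, window = NULL) {
  expr <- traj$expr
  ord <- order(traj$pseudotime)
  expr <- expr[ord, , drop = FALSE]
  n_cells <- nrow(expr)
  if (is.null(window)) window <- max(1L, floor(0.08 * n_cells))
  smoothed <- smooth_matrix(expr, window, max_fraction = 0.10)
  binarized <- binarize_matrix(smoothed)
  skel <- prune_by_correlation(prior, smoothed, cutoff = cutoff)
  skel <- remove_terminal_nodes(skel)
  skel <- extract_scc(skel)
  skel <- add_self_activation(skel)
  structure(list(skeleton = skel, smoothed = smoothed, binarized = binarized,
                 window = window, cutoff = cutoff),
            class = "grn_build")
}
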