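# Transition-state calling from a CNV phylogeny, plus the critical-transition
# index on expression.

#' Build a neighbor-joining tree from a cell-by-bin CNV matrix
#'
#' Euclidean cell-cell distances, BIONJ agglomeration (ape). Negative branch
#' lengths, an occasional numerical artefact of neighbor joining, are clamped
#' to zero.
#'
#' @param cnv numeric matrix, cells in rows (rownames = cell ids), bins in
#'   columns; no missing values.
#' @return an unrooted \code{phylo} tree with leaf names equal to cell ids.
#' @export
build_nj_tree <- function(cnv) {
  cnv <- as.matrix(cnv)
  if (nrow(cnv) < 4L) stop("need at least 4 cells to build a tree")
  if (anyNA(cnv)) stop("CNV matrix contains missing values")
  if (is.null(rownames(cnv))) rownames(cnv) <- sprintf("cell_%04d", seq_len(nrow(cnv)))
  tree <- ape::bionj(stats::dist(cnv))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Partition tree leaves into clades by cutting long edges
#'
#' Greedily removes the longest internal edges (ties broken by edge order in
#' the tree), falling back to pendant edges once internal ones are exhausted,
#' until the leaves fall into exactly \code{n_clades} connected groups. An
#' edge whose removal would strand a leaf-free component is skipped.
#'
#' @param tree a \code{phylo} object.
#' @param n_clades number of clades, between 2 and the number of leaves.
#' @return data.frame with columns \code{cell_id} and \code{clade}
#'   (\code{"clade_01"}, ... numbered by first member leaf).
#' @export
partition_clades <- function(tree, n_clades) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  n_clades <- as.integer(n_clades)
  if (n_clades < 2L || n_clades > n_tip) stop("n_clades must be in [2, n_leaves]")
  edges <- tree$edge
  lens <- tree$edge.length
  if (is.null(lens)) lens <- rep(1, nrow(edges))
  is_internal <- edges[, 1] > n_tip & edges[, 2] > n_tip
  ord <- order(!is_internal, -lens, seq_along(lens))
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = FALSE)
  tips <- as.character(seq_len(n_tip))
  n_groups <- function(gr) {
    comp <- igraph::components(gr)$membership
    length(unique(comp[tips]))
  }
  cur <- g
  for (ei in ord) {
    if (n_groups(cur) >= n_clades) break
    cand <- igraph::delete_edges(
      cur, igraph::get_edge_ids(cur, as.character(edges[ei, ])))
    if (n_groups(cand) > n_groups(cur)) cur <- cand
  }
  comp <- igraph::components(cur)$membership
  tip_comp <- comp[tips]
  if (length(unique(tip_comp)) != n_clades) {
    stop("could not split the tree into ", n_clades, " leaf groups")
  }
  clade_id <- match(tip_comp, unique(tip_comp))
  data.frame(cell_id = tree$tip.label,
             clade = sprintf("clade_%02d", clade_id),
             stringsAsFactors = FALSE)
}

#' Shannon entropy of a clade's normal/cancer mixture
#'
#' Binary entropy, in bits, of the origin composition of a clade:
#' \deqn{H = -p \log_2 p - (1-p) \log_2 (1-p), \quad p = N_n / (N_n + N_c)}
#' with the convention \eqn{0 \log 0 = 0}.
#'
#' @param n_normal,n_cancer non-negative cell counts, summing to >= 1.
#' @return entropy in bits, in [0, 1]. Vectorised.
#' @export
clade_entropy <- function(n_normal, n_cancer) {
  if (any(n_normal < 0) || any(n_cancer < 0)) stop("counts must be non-negative")
  tot <- n_normal + n_cancer
  if (any(tot < 1)) stop("each clade must contain at least one cell")
  p <- n_normal / tot
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  -(plogp(p) + plogp(1 - p))
}

#' Tabulate clade composition and entropy
#'
#' @param clades data.frame from \code{\link{partition_clades}}.
#' @param labels data.frame with columns \code{cell_id} and \code{origin}
#'   (\code{"normal"} or \code{"cancer"}).
#' @return data.frame: clade, n_normal, n_cancer, H.
#' @export
clade_counts <- function(clades, labels) {
  stopifnot(all(c("cell_id", "clade") %in% names(clades)),
            all(c("cell_id", "origin") %in% names(labels)))
  origin <- labels$origin[match(clades$cell_id, labels$cell_id)]
  if (anyNA(origin)) stop("labels missing for some cells")
  if (!all(origin %in% c("normal", "cancer"))) {
    stop("origin labels must be 'normal' or 'cancer'")
  }
  tab <- table(clades$clade, factor(origin, levels = c("normal", "cancer")))
  out <- data.frame(clade = rownames(tab),
                    n_normal = as.integer(tab[, "normal"]),
                    n_cancer = as.integer(tab[, "cancer"]),
                    stringsAsFactors = FALSE)
  out$H <- clade_entropy(out$n_normal, out$n_cancer)
  rownames(out) <- NULL
  out
}

#' Flag high-entropy clades as the tumor transition state
#'
#' @param counts data.frame from \code{\link{clade_counts}}.
#' @param threshold entropy threshold in bits (default 0.8; a 3:1 mixture
#'   qualifies).
#' @param clades optional clade assignment, to resolve member cell ids.
#' @return object of class \code{transition_call}: flagged clade ids, member
#'   cells (if \code{clades} given), the threshold, and the counts table.
#' @export
call_transition_state <- function(counts, threshold = 0.8, clades = NULL) {
  if (is.null(counts) || !nrow(counts)) stop("counts must contain at least one clade")
  stopifnot(all(c("clade", "H") %in% names(counts)))
  flagged <- counts$clade[counts$H >= threshold]
  cells <- if (!is.null(clades)) clades$cell_id[clades$clade %in% flagged] else character(0)
  structure(list(flagged = flagged, cells = cells, threshold = threshold,
                 counts = counts),
            class = "transition_call")
}

#' @export
print.transition_call <- function(x, ...) {
  cat("Transition call at H >=", x$threshold, "bits:",
      length(x$flagged), "clade(s)")
  if (length(x$flagged)) cat(" [", paste(x$flagged, collapse = ", "), "]", sep = "")
  cat("\n")
  if (length(x$cells)) cat("  ", length(x$cells), "member cells\n")
  invisible(x)
}

#' Critical-transition index of an expression matrix
#'
#' Ratio of the mean absolute pairwise Pearson correlation between genes to
#' the mean absolute pairwise Pearson correlation between cells (diagonals
#' excluded). A rise in this index signals loss of coordinated cell states
#' near a tipping point. Constant rows/columns are excluded before
#' correlation.
#'
#' @param expr numeric matrix, cells in rows, genes in columns; at least 3
#'   non-constant cells and genes.
#' @return a single numeric ratio.
#' @export
critical_transition_index <- function(expr) {
  expr <- as.matrix(expr)
  keep_g <- apply(expr, 2, stats::sd) > 0
  keep_c <- apply(expr, 1, stats::sd) > 0
  expr <- expr[keep_c, keep_g, drop = FALSE]
  if (ncol(expr) < 3L || nrow(expr) < 3L) {
    stop("need at least 3 non-constant cells and 3 non-constant genes")
  }
  mean_offdiag <- function(m) {
    a <- abs(m); mean(a[row(a) != col(a)])
  }
  gene_cor <- stats::cor(expr)
  cell_cor <- stats::cor(t(expr))
  mean_offdiag(gene_cor) / mean_offdiag(cell_cor)
}
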