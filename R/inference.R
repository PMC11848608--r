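# Boolean rule inference from pseudotime input-output pairs: candidate
# enumeration over sign-monotone, all-regulators-essential truth tables,
# scored by agreement with the observed pairs; ties are OR-combined.

.bs_cache <- new.env(parent = emptyenv())

# All 2^(2^r) truth tables as a matrix (rows = tables, columns = input rows in
# lexicographic order, first regulator most significant). Cached per r.
all_tables <- function(r) {
  key <- paste0("tables_", r)
  if (!is.null(.bs_cache[[key]])) return(.bs_cache[[key]])
  if (r > 4L) stop("candidate enumeration supports at most 4 regulators")
  n_rows <- 2L^r
  n_tab <- 2L^n_rows
  codes <- 0:(n_tab - 1L)
  # table t's output for input row s = bit (n_rows - s) of t, so tables are
  # ordered by their output vector read as a binary word (row 1 most
  # significant)
  M <- vapply(seq_len(n_rows), function(s) {
    bitwAnd(codes %/% 2L^(n_rows - s), 1L)
  }, integer(n_tab))
  .bs_cache[[key]] <- M
  M
}

#' Enumerate candidate Boolean functions for a signed regulator set
#'
#' Returns every truth table over the regulators that is (a) monotone
#' consistent with each regulator's sign (non-decreasing in activators,
#' non-increasing in inhibitors) and (b) essential in every regulator (each
#' input changes the output in some context). Enumeration order is
#' deterministic (ascending lexicographic truth tables).
#'
#' @param signs integer vector of +1/-1 regulator signs (1 to 4 regulators).
#' @return integer matrix, one candidate truth table per row.
#' @export
enumerate_candidates <- function(signs) {
  r <- length(signs)
  if (r < 1L) stop("at least one regulator is required")
  if (r > 4L) stop("at most 4 regulators are supported")
  if (!all(signs %in% c(-1L, 1L))) stop("signs must be +1 or -1")
  key <- paste0("cand_", paste(signs, collapse = ""))
  if (!is.null(.bs_cache[[key]])) return(.bs_cache[[key]])
  M <- all_tables(r)
  rows <- 0:(2L^r - 1L)
  keep <- rep(TRUE, nrow(M))
  for (j in seq_len(r)) {
    bit <- bitwAnd(rows %/% 2L^(r - j), 1L)
    lo <- M[, bit == 0L, drop = FALSE]
    hi <- M[, bit == 1L, drop = FALSE]
    mono <- if (signs[j] > 0) rowSums(hi < lo) == 0L else rowSums(hi > lo) == 0L
    essential <- rowSums(hi != lo) > 0L
    keep <- keep & mono & essential
  }
  out <- M[keep, , drop = FALSE]
  .bs_cache[[key]] <- out
  out
}

#' Build input-output pairs from a binarized pseudotime matrix
#'
#' Pairs the regulator state at ordered position \code{t} with the gene's
#' value at position \code{t + k}, for \code{t = 1..(n_cells - k)}. The step
#' size must exceed the smoothing window so input and output windows do not
#' overlap.
#'
#' @param binmat integer cells x genes matrix, rows in pseudotime order.
#' @param gene target gene name.
#' @param regulators ordered regulator names (columns of \code{binmat}).
#' @param k step size.
#' @param window smoothing window used upstream (for the \code{k > window}
#'   check; default 0 = unsmoothed).
#' @return object of class \code{io_pairs}: \code{inputs} (m x r matrix),
#'   \code{outputs} (length m), \code{k}, \code{m}.
#' @export
make_io_pairs <- function(binmat, gene, regulators, k, window = 0L) {
  k <- as.integer(k)
  n <- nrow(binmat)
  if (k <= window) stop("step size k must exceed the smoothing window (k >= window + 1)")
  if (n <= k) stop("need more cells than the step size")
  missing_cols <- setdiff(c(gene, regulators), colnames(binmat))
  if (length(missing_cols)) stop("genes absent from matrix: ",
                                 paste(missing_cols, collapse = ", "))
  m <- n - k
  inputs <- binmat[seq_len(m), regulators, drop = FALSE]
  outputs <- binmat[seq_len(m) + k, gene]
  structure(list(gene = gene, regulators = regulators,
                 inputs = matrix(as.integer(inputs), nrow = m,
                                 dimnames = list(NULL, regulators)),
                 outputs = as.integer(outputs), k = k, m = m),
            class = "io_pairs")
}

#' Score candidate truth tables against input-output pairs
#'
#' The score of a function is the number of pairs it reproduces:
#' \eqn{S(f) = \sum_t [f(I_t) = O_{t+k}]}, between 0 and m.
#'
#' @param tables integer matrix of truth tables (rows = candidates) or a
#'   single table vector.
#' @param pairs an \code{\link{make_io_pairs}} result.
#' @return integer vector of scores, one per table.
#' @export
score_function <- function(tables, pairs) {
  if (is.null(dim(tables))) tables <- matrix(tables, nrow = 1L)
  r <- length(pairs$regulators)
  if (ncol(tables) != 2L^r) stop("table width does not match regulator count")
  idx <- if (r > 0) as.integer(1 + pairs$inputs %*% 2^((r - 1):0)) else rep(1L, pairs$m)
  n1 <- tabulate(idx[pairs$outputs == 1L], nbins = 2L^r)
  n0 <- tabulate(idx[pairs$outputs == 0L], nbins = 2L^r)
  as.integer(tables %*% n1 + (1L - tables) %*% n0)
}

#' Infer the best-scoring Boolean rule for one gene
#'
#' Selects the argmax-scoring candidate; when several candidates tie at the
#' maximum they are combined by pointwise logical OR, and the reported score
#' is recomputed for the combined table. Provenance records the tied set.
#'
#' @param pairs an \code{\link{make_io_pairs}} result.
#' @param signs regulator signs matching \code{pairs$regulators}.
#' @param candidates optional candidate matrix; defaults to
#'   \code{enumerate_candidates(signs)}.
#' @return a \code{\link{boolean_rule}} with attributes \code{score},
#'   \code{m}, \code{n_tied}, and \code{tied_tables}.
#' @export
infer_rule <- function(pairs, signs, candidates = NULL) {
  if (is.null(candidates)) candidates <- enumerate_candidates(signs)
  if (!nrow(candidates)) stop("empty candidate list for gene ", pairs$gene)
  scores <- score_function(candidates, pairs)
  best <- max(scores)
  tied <- which(scores == best)
  tab <- if (length(tied) == 1L) candidates[tied, ] else
    as.integer(apply(candidates[tied, , drop = FALSE], 2, max))
  rule <- boolean_rule(pairs$gene, pairs$regulators, tab, signs)
  attr(rule, "score") <- score_function(tab, pairs)
  attr(rule, "m") <- pairs$m
  attr(rule, "n_tied") <- length(tied)
  attr(rule, "tied_tables") <- candidates[tied, , drop = FALSE]
  rule
}

#' Infer a full Boolean network from a binarized matrix and a skeleton
#'
#' One rule per skeleton node; regulators are the node's incoming edges,
#' sorted alphabetically for a canonical truth-table layout. Nodes with more
#' than \code{max_regulators} inputs keep the regulators with the largest
#' absolute Spearman correlation to the target (with a warning).
#'
#' @param binmat integer cells x genes matrix in pseudotime order.
#' @param skeleton a \code{\link{signed_network}} whose nodes are columns of
#'   \code{binmat}.
#' @param k step size for input-output pairs (must exceed \code{window}).
#' @param max_regulators regulator cap (default 4).
#' @param window smoothing window used upstream (default 0).
#' @return a \code{\link{boolean_network}} with attributes \code{agreement}
#'   (mean per-gene S(f)/m) and \code{per_gene} (data.frame of scores).
#' @export
infer_network <- function(binmat, skeleton, k, max_regulators = 4L, window = 0L) {
  stopifnot(inherits(skeleton, "signed_network"))
  missing_nodes <- setdiff(skeleton$nodes, colnames(binmat))
  if (length(missing_nodes)) stop("skeleton nodes absent from matrix: ",
                                  paste(missing_nodes, collapse = ", "))
  e <- skeleton$edges
  rules <- vector("list", length(skeleton$nodes))
  stats_df <- data.frame(gene = skeleton$nodes, score = NA_integer_,
                         m = NA_integer_, n_regulators = NA_integer_,
                         n_tied = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(skeleton$nodes)) {
    gene <- skeleton$nodes[i]
    inc <- e[e$target == gene, , drop = FALSE]
    if (!nrow(inc)) stop("skeleton node ", gene, " has no regulators")
    inc <- inc[order(inc$source), , drop = FALSE]
    if (nrow(inc) > max_regulators) {
      rho <- vapply(inc$source, function(src) {
        suppressWarnings(abs(stats::cor(binmat[, src], binmat[, gene],
                                        method = "spearman")))
      }, numeric(1))
      rho[is.na(rho)] <- 0
      keep <- order(-rho, inc$source)[seq_len(max_regulators)]
      warning("gene ", gene, ": regulator set reduced from ", nrow(inc),
              " to ", max_regulators, " by |Spearman|")
      inc <- inc[sort(keep), , drop = FALSE]
    }
    pairs <- make_io_pairs(binmat, gene, inc$source, k, window = window)
    rules[[i]] <- infer_rule(pairs, inc$sign)
    stats_df$score[i] <- attr(rules[[i]], "score")
    stats_df$m[i] <- attr(rules[[i]], "m")
    stats_df$n_regulators[i] <- nrow(inc)
    stats_df$n_tied[i] <- attr(rules[[i]], "n_tied")
  }
  net <- boolean_network(rules)
  attr(net, "agreement") <- mean(stats_df$score / stats_df$m)
  attr(net, "per_gene") <- stats_df
  net
}
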