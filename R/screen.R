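# In-silico reversion screening: single and double gene fixations ranked by
# cancer score, the hyperparameter-ensemble robustness scan, and common-target
# extraction from a TF -> target edge list.

fixation_label <- function(genes, values) {
  if (!length(genes)) return("baseline")
  paste(paste0(genes, "=", values), collapse = "+")
}

eval_fixation <- function(net, fixes, v_n, v_c, params, seed) {
  pnet <- apply_fixation(net, fixes)
  landscape_summary(pnet, v_n, v_c,
                    method = params$method, n_init = params$n_init,
                    n_perturbations = params$n_perturbations,
                    basin_cap = params$basin_cap, seed = seed)
}

#' Screening parameters
#'
#' Bundles the landscape-resolution knobs shared by the screens: attractor
#' search mode, number of random initial states (sampled mode), perturbation
#' trials per basin state, and the basin sampling cap for entropy
#' estimation.
#'
#' @param method,n_init,n_perturbations,basin_cap see
#'   \code{\link{landscape_summary}}.
#' @return a named list.
#' @export
default_screen_params <- function(method = "auto", n_init = 1000L,
                                  n_perturbations = 100L, basin_cap = 512L) {
  list(method = method, n_init = n_init, n_perturbations = n_perturbations,
       basin_cap = basin_cap)
}

#' Screen all single-gene fixations for cancer-score reduction
#'
#' Evaluates the unperturbed baseline plus every gene fixed to 0 (knockdown)
#' and to 1 (overexpression) -- \code{2n + 1} landscapes in total, each with
#' a deterministic seed offset so the screen is reproducible -- and ranks
#' them by ascending cancer score.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param v_n,v_c anchor states over the network genes.
#' @param params list from \code{\link{default_screen_params}}.
#' @param seed base seed; fixation \code{i} uses \code{seed + i}.
#' @return data.frame: label, gene, value, cancer_score, n_attractors,
#'   best_normal_fraction (basin fraction of the attractor nearest the
#'   normal anchor), rank.
#' @export
screen_single <- function(net, v_n, v_c, params = default_screen_params(),
                          seed = 1L) {
  genes <- net$genes
  fix_list <- c(list(list(genes = character(0), values = integer(0))),
                unlist(lapply(genes, function(g) {
                  list(list(genes = g, values = 0L), list(genes = g, values = 1L))
                }), recursive = FALSE))
  rows <- lapply(seq_along(fix_list), function(i) {
    fx <- fix_list[[i]]
    fixes <- stats::setNames(as.list(fx$values), fx$genes)
    ls <- eval_fixation(net, fixes, v_n, v_c, params, seed + i)
    data.frame(label = fixation_label(fx$genes, fx$values),
               gene = if (length(fx$genes)) fx$genes else NA_character_,
               value = if (length(fx$values)) fx$values else NA_integer_,
               cancer_score = ls$cancer_score,
               n_attractors = nrow(ls$table),
               best_normal_fraction = ls$table$fraction[which.min(ls$table$d)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(out$cancer_score, ties.method = "first")
  out[order(out$rank), ]
}

#' Screen double fixations among the top single hits
#'
#' Takes the \code{top_n} distinct genes most effective in the single screen
#' (each at its winning direction), evaluates every pair, and flags
#' successful reversions (cancer score at or below
#' \code{success_threshold}, default 0.1).
#'
#' @param net a \code{\link{boolean_network}}.
#' @param v_n,v_c anchor states.
#' @param singles result of \code{\link{screen_single}}.
#' @param top_n number of top single genes to combine (default 5).
#' @param success_threshold reversion-success cutoff on the cancer score.
#' @param params list from \code{\link{default_screen_params}}.
#' @param seed base seed; pair \code{i} uses \code{seed + 1000 + i}.
#' @return data.frame: label, gene1, value1, gene2, value2, cancer_score,
#'   n_attractors, success, rank.
#' @export
screen_double <- function(net, v_n, v_c, singles, top_n = 5L,
                          success_threshold = 0.1,
                          params = default_screen_params(), seed = 1L) {
  hits <- singles[!is.na(singles$gene), ]
  hits <- hits[order(hits$cancer_score), ]
  hits <- hits[!duplicated(hits$gene), ]
  hits <- utils::head(hits, top_n)
  if (nrow(hits) < 2L) {
    warning("degenerate screen: fewer than 2 distinct genes among top singles")
    return(data.frame(label = character(0), gene1 = character(0),
                      value1 = integer(0), gene2 = character(0),
                      value2 = integer(0), cancer_score = numeric(0),
                      n_attractors = integer(0), success = logical(0),
                      rank = integer(0)))
  }
  combos <- utils::combn(nrow(hits), 2L)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    fixes <- stats::setNames(list(hits$value[a], hits$value[b]),
                             c(hits$gene[a], hits$gene[b]))
    ls <- eval_fixation(net, fixes, v_n, v_c, params, seed + 1000L + i)
    data.frame(label = fixation_label(names(fixes), unlist(fixes)),
               gene1 = hits$gene[a], value1 = hits$value[a],
               gene2 = hits$gene[b], value2 = hits$value[b],
               cancer_score = ls$cancer_score,
               n_attractors = nrow(ls$table),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$success <- out$cancer_score <= success_threshold
  out$rank <- rank(out$cancer_score, ties.method = "first")
  out[order(out$rank), ]
}

#' Hyperparameter-ensemble robustness scan
#'
#' Reruns the build -> infer -> landscape -> screen pipeline for each row of
#' a hyperparameter grid, admits records whose inferred network size lies in
#' \code{size_range} and whose initial cancer score exceeds
#' \code{init_threshold}, and tallies how often each perturbation set drives
#' the score below \code{collect_threshold} across admitted records.
#'
#' @param traj a trajectory (see \code{\link{build_grn}}).
#' @param prior a \code{\link{signed_network}} prior.
#' @param grid data.frame with columns \code{window}, \code{k},
#'   \code{cutoff}.
#' @param size_range admissible network size (default \code{c(10, 30)}).
#' @param init_threshold minimum initial cancer score (default 0.5).
#' @param collect_threshold post-perturbation collection cutoff
#'   (default 0.15).
#' @param top_n,params,seed screening controls (see
#'   \code{\link{screen_double}}).
#' @param max_regulators regulator cap for rule inference.
#' @return list: \code{records} (per grid row: hyperparameters, admission,
#'   network size, initial score, screens), \code{consensus} (data.frame of
#'   perturbation sets with counts across admitted records), \code{n_admitted}.
#' @export
ensemble_scan <- function(traj, prior, grid, size_range = c(10L, 30L),
                          init_threshold = 0.5, collect_threshold = 0.15,
                          top_n = 5L, params = default_screen_params(),
                          seed = 1L, max_regulators = 4L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L,
            all(c("window", "k", "cutoff") %in% names(grid)))
  records <- vector("list", nrow(grid))
  hit_sets <- character(0)
  n_admitted <- 0L
  for (i in seq_len(nrow(grid))) {
    rec <- list(window = grid$window[i], k = grid$k[i], cutoff = grid$cutoff[i],
                admitted = FALSE, reason = NA_character_)
    result <- tryCatch({
      build <- build_grn(traj, prior, cutoff = grid$cutoff[i], window = grid$window[i])
      net <- infer_network(build$binarized, build$skeleton, k = grid$k[i],
                           max_regulators = max_regulators, window = build$window)
      anchors <- anchor_states(traj, genes = net$genes)
      base <- landscape_summary(net, anchors$v_n, anchors$v_c,
                                method = params$method, n_init = params$n_init,
                                n_perturbations = params$n_perturbations,
                                basin_cap = params$basin_cap, seed = seed)
      list(net = net, anchors = anchors, base = base)
    }, error = function(e) e)
    if (inherits(result, "error")) {
      rec$reason <- conditionMessage(result)
      records[[i]] <- rec
      next
    }
    rec$network_size <- length(result$net$genes)
    rec$initial_score <- result$base$cancer_score
    if (rec$network_size < size_range[1] || rec$network_size > size_range[2]) {
      rec$reason <- "network size outside admissible range"
      records[[i]] <- rec
      next
    }
    if (rec$initial_score <= init_threshold) {
      rec$reason <- "initial cancer score not above threshold"
      records[[i]] <- rec
      next
    }
    rec$admitted <- TRUE
    n_admitted <- n_admitted + 1L
    singles <- screen_single(result$net, result$anchors$v_n, result$anchors$v_c,
                             params = params, seed = seed + 10000L * i)
    doubles <- screen_double(result$net, result$anchors$v_n, result$anchors$v_c,
                             singles, top_n = top_n, params = params,
                             seed = seed + 10000L * i)
    rec$singles <- singles
    rec$doubles <- doubles
    eff <- c(singles$label[!is.na(singles$gene) &
                             singles$cancer_score < collect_threshold],
             doubles$label[doubles$cancer_score < collect_threshold])
    hit_sets <- c(hit_sets, unique(eff))
    records[[i]] <- rec
  }
  consensus <- if (length(hit_sets)) {
    tb <- sort(table(hit_sets), decreasing = TRUE)
    data.frame(perturbation = names(tb), count = as.integer(tb),
               stringsAsFactors = FALSE)
  } else {
    data.frame(perturbation = character(0), count = integer(0))
  }
  list(records = records, consensus = consensus, n_admitted = n_admitted)
}

#' Common targets of two transcription factors
#'
#' Splits the targets regulated by both TFs into a positively co-regulated
#' set (+1 edges from both) and a negatively co-regulated set (-1 from
#' both); mixed-sign targets belong to neither.
#'
#' @param tfs character vector of exactly two TF names.
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{sign} (a TF -> target regulon edge list).
#' @return list with character vectors \code{positive} and \code{negative}.
#' @export
common_targets <- function(tfs, edges) {
  stopifnot(length(tfs) == 2L,
            all(c("source", "target", "sign") %in% names(edges)))
  missing_tf <- setdiff(tfs, edges$source)
  if (length(missing_tf)) stop("TF(s) absent from edge list: ",
                               paste(missing_tf, collapse = ", "))
  sign_of <- function(tf, tg) {
    s <- unique(edges$sign[edges$source == tf & edges$target == tg])
    if (length(s) == 1L) s else NA_integer_   # conflicting duplicates -> mixed
  }
  shared <- intersect(edges$target[edges$source == tfs[1]],
                      edges$target[edges$source == tfs[2]])
  s1 <- vapply(shared, sign_of, integer(1), tf = tfs[1])
  s2 <- vapply(shared, sign_of, integer(1), tf = tfs[2])
  list(positive = sort(shared[!is.na(s1) & !is.na(s2) & s1 == 1L & s2 == 1L]),
       negative = sort(shared[!is.na(s1) & !is.na(s2) & s1 == -1L & s2 == -1L]))
}

#' Combine two per-gene score columns by mean of ranks
#'
#' Generic plumbing for merging externally supplied per-gene evidence (for
#' example a dependency score and an enrichment score): each column is
#' ranked (smaller = stronger by default) and the mean rank reported.
#'
#' @param df data.frame with a \code{gene} column and two numeric columns.
#' @param cols names of the two score columns.
#' @param decreasing logical of length 2; TRUE ranks that column with larger
#'   values as stronger.
#' @return \code{df} with \code{mean_rank} appended, sorted ascending.
#' @export
combine_rank_scores <- function(df, cols, decreasing = c(FALSE, FALSE)) {
  stopifnot(length(cols) == 2L, all(cols %in% names(df)))
  r1 <- rank(if (decreasing[1]) -df[[cols[1]]] else df[[cols[1]]])
  r2 <- rank(if (decreasing[2]) -df[[cols[2]]] else df[[cols[2]]])
  df$mean_rank <- (r1 + r2) / 2
  df[order(df$mean_rank), ]
}
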