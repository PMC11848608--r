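# Attractor-landscape quantification: normal/cancer anchors from pseudotime
# ends, projection onto the normal-cancer axis, perturbation-based attractor
# entropy, and the scalar cancer score.

#' Anchor states from the ends of the pseudotime order
#'
#' Per-gene mean of the binarized expression of cells within
#' \code{fraction} of each end of the pseudotime order, rounded at 0.5
#' (ties round to 1). These anchors play the role of the normal and cancer
#' attractor states on the landscape axis.
#'
#' @param traj a \code{trajectory_data} object (or list with
#'   \code{binarized} and \code{pseudotime}).
#' @param fraction end-window fraction (default 0.2).
#' @param genes optional gene subset/ordering (e.g. the network genes).
#' @return list with binary named vectors \code{v_n} and \code{v_c}.
#' @export
anchor_states <- function(traj, fraction = 0.2, genes = NULL) {
  b <- traj$binarized[order(traj$pseudotime), , drop = FALSE]
  if (!is.null(genes)) b <- b[, genes, drop = FALSE]
  n <- nrow(b)
  if (n < 5L) stop("need at least 5 cells to define anchors")
  n_end <- max(1L, floor(fraction * n))
  v_n <- as.integer(colMeans(b[seq_len(n_end), , drop = FALSE]) >= 0.5)
  v_c <- as.integer(colMeans(b[seq(n - n_end + 1L, n), , drop = FALSE]) >= 0.5)
  names(v_n) <- names(v_c) <- colnames(b)
  if (all(v_n == v_c)) stop("degenerate normal-cancer axis: anchors coincide")
  list(v_n = v_n, v_c = v_c)
}

#' Effective distance along the normal-cancer axis
#'
#' Scalar projection of \code{v - v_n} onto \code{v_c - v_n}, normalised by
#' \eqn{|v_c - v_n|^2}: 0 at the normal anchor, 1 at the cancer anchor;
#' values outside [0, 1] indicate states beyond the anchors.
#'
#' @param v a binary state vector, or a matrix of states (rows).
#' @param v_n,v_c the normal and cancer anchor states (must differ).
#' @return numeric scalar (or vector for a matrix input).
#' @export
effective_distance <- function(v, v_n, v_c) {
  axis <- v_c - v_n
  denom <- sum(axis^2)
  if (denom == 0) stop("degenerate normal-cancer axis: anchors coincide")
  if (is.matrix(v)) {
    as.numeric((v - matrix(v_n, nrow(v), length(v_n), byrow = TRUE)) %*% axis) / denom
  } else {
    sum((v - v_n) * axis) / denom
  }
}

# Landing state (a state on the attractor cycle) reached from `start` under
# the network with gene `g`'s truth table replaced by `perm`. Fast O(1)-per-
# step path when the exhaustive engine cached per-state rule rows.
perturbed_landing <- function(set, g, perm, start) {
  eng <- set$engine
  n <- set$n_genes
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cur <- start
  if (set$mode == "exhaustive" && !is.null(eng$idx_cache)) {
    w <- 2^(g - 1)
    nxt <- eng$nxt
    idx_g <- eng$idx_cache[[g]]
    repeat {
      key <- as.character(cur)
      if (!is.null(seen[[key]])) return(cur)
      seen[[key]] <- TRUE
      nc <- nxt[cur]
      ob <- bitwAnd(as.integer((nc - 1) %/% w), 1L)
      cur <- nc + (perm[idx_g[cur]] - ob) * w
    }
  }
  compiled <- eng$compiled
  compiled[[g]]$table <- perm
  repeat {
    key <- as.character(cur)
    if (!is.null(seen[[key]])) return(cur)
    seen[[key]] <- TRUE
    v <- decode_state(cur, n)
    out <- integer(n)
    for (j in seq_len(n)) out[j] <- compiled[[j]]$table[rule_row_index(compiled[[j]], v)]
    cur <- encode_state(out)
  }
}

#' Perturbation-based attractor entropy
#'
#' For each (sampled) state in each basin, repeatedly perturb the network --
#' pick one gene at random and randomly permute the output column of its
#' truth table -- iterate the perturbed network from that state to its
#' attractor, and re-converge that attractor under the original rules to map
#' it back to an original attractor. The entropy of the resulting convergence
#' distribution, \eqn{S_i^j = -\sum_k P_k \log_2 P_k}, measures how easily
#' the state hops to other valleys; the attractor's entropy \eqn{S_i} is the
#' mean over its basin states. Perturbed runs that land in an attractor never
#' seen by the original search count as their own outcome category.
#'
#' @param net the \code{\link{boolean_network}} (for interface symmetry; the
#'   dynamics come from \code{set}).
#' @param set an \code{\link{find_attractors}} result for \code{net}.
#' @param n_perturbations perturbation trials per basin state (default 100).
#' @param basin_cap maximum basin states sampled per attractor (default 512;
#'   full enumeration below the cap).
#' @param seed integer seed.
#' @return list with \code{S} (per-attractor mean entropy), \code{S_max}
#'   (\eqn{\log_2 N}), and \code{per_state} (per-attractor vectors of
#'   \eqn{S_i^j}).
#' @export
attractor_entropy <- function(net, set, n_perturbations = 100L, basin_cap = 512L,
                              seed = 1L) {
  stopifnot(inherits(set, "attractor_set"), n_perturbations >= 1L)
  set.seed(seed)
  n <- set$n_genes
  compiled <- set$engine$compiled
  n_attr <- length(set$attractors)
  S <- numeric(n_attr)
  per_state <- vector("list", n_attr)
  for (i in seq_len(n_attr)) {
    bs <- set$basin_states[[i]]
    if (length(bs) > basin_cap) bs <- sample(bs, basin_cap)
    s_ij <- vapply(bs, function(j) {
      cats <- character(n_perturbations)
      for (trial in seq_len(n_perturbations)) {
        g <- sample.int(n, 1L)
        tab <- compiled[[g]]$table
        perm <- if (length(tab) > 1L) sample(tab) else tab
        landing <- perturbed_landing(set, g, perm, j)
        res <- converge_original(set, landing)
        cats[trial] <- if (!is.na(res$id)) as.character(res$id) else paste0("new:", res$key)
      }
      p <- table(cats) / n_perturbations
      -sum(p * log2(p))
    }, numeric(1))
    per_state[[i]] <- s_ij
    S[i] <- mean(s_ij)
  }
  list(S = S, S_max = if (n_attr > 1L) log2(n_attr) else 0,
       per_state = per_state)
}

#' Cancer score of an attractor landscape
#'
#' \deqn{\mathrm{CS} = \sum_k \left(1 - \frac{S_k}{S_{max}}\right)
#'   \cdot \frac{B_k}{\sum_j B_j} \cdot d_k}
#' Deep (low-entropy), wide (large-basin) valleys near the cancer anchor
#' (\eqn{d_k \to 1}) drive the score up. Distances are clamped at 0 so a
#' valley behind the normal anchor contributes no malignancy. With a single
#' attractor the depth weight is taken as 1 (\eqn{S_k = S_{max} = 0}).
#'
#' @param d per-attractor effective distances.
#' @param S per-attractor entropies (>= 0).
#' @param B per-attractor basin sizes (>= 0, summing > 0).
#' @param S_max maximum entropy \eqn{\log_2 N}; default from
#'   \code{length(d)}.
#' @return the scalar cancer score (>= 0).
#' @export
cancer_score <- function(d, S, B, S_max = NULL) {
  stopifnot(length(d) == length(S), length(S) == length(B))
  if (any(S < 0) || any(B < 0)) stop("entropies and basin sizes must be non-negative")
  if (sum(B) <= 0) stop("total basin size must be positive")
  if (is.null(S_max)) S_max <- if (length(d) > 1L) log2(length(d)) else 0
  w <- if (S_max > 0) 1 - S / S_max else rep(1, length(d))
  sum(w * (B / sum(B)) * pmax(d, 0))
}

#' Quantify the full attractor landscape of a network
#'
#' Runs the attractor search, projects each attractor onto the
#' normal-cancer axis (cyclic attractors use the mean over their cycle
#' states), estimates per-attractor entropies by rule perturbation, and
#' reduces everything to the scalar cancer score.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param v_n,v_c anchor states over the network genes.
#' @param method,n_init passed to \code{\link{find_attractors}}
#'   (\code{n_init} = random initial states in sampled mode; default 1000).
#' @param n_perturbations,basin_cap passed to
#'   \code{\link{attractor_entropy}}.
#' @param seed integer seed (attractor sampling uses \code{seed}, entropy
#'   \code{seed + 1}).
#' @return object of class \code{landscape_summary}: \code{table} (one row
#'   per attractor: basin, fraction, d, S), \code{S_max},
#'   \code{cancer_score}, and the underlying \code{attractor_set}.
#' @export
landscape_summary <- function(net, v_n, v_c, method = "auto", n_init = 1000L,
                              n_perturbations = 100L, basin_cap = 512L,
                              seed = 1L) {
  stopifnot(inherits(net, "boolean_network"))
  if (!is.null(names(v_n))) v_n <- v_n[net$genes]
  if (!is.null(names(v_c))) v_c <- v_c[net$genes]
  set <- find_attractors(net, method = method, n_random = n_init, seed = seed)
  d <- vapply(set$attractors, function(a) mean(effective_distance(a$states, v_n, v_c)),
              numeric(1))
  ent <- attractor_entropy(net, set, n_perturbations = n_perturbations,
                           basin_cap = basin_cap, seed = seed + 1L)
  cs <- cancer_score(d, ent$S, set$basin_counts, ent$S_max)
  tab <- data.frame(attractor = seq_along(d),
                    length = vapply(set$attractors, function(a) nrow(a$states), integer(1)),
                    basin = set$basin_counts,
                    fraction = set$basin_counts / set$total,
                    d = d, S = ent$S)
  structure(list(table = tab, S_max = ent$S_max, cancer_score = cs,
                 attractor_set = set, v_n = v_n, v_c = v_c,
                 per_state_entropy = ent$per_state),
            class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat("Attractor landscape: ", nrow(x$table), " attractor(s), S_max = ",
      round(x$S_max, 4), ", cancer score = ", round(x$cancer_score, 4), "\n", sep = "")
  print(transform(x$table, fraction = round(fraction, 4), d = round(d, 4),
                  S = round(S, 4)), row.names = FALSE)
  invisible(x)
}

#' Map single cells onto the attractor landscape
#'
#' Each cell's binarized expression vector is used as an initial state and
#' iterated to its attractor; the cell is reported with its own projection
#' onto the normal-cancer axis, the attractor it converges to, that
#' attractor's projection, and the number of synchronous steps taken to
#' reach the attractor cycle.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param cells binarized cells x genes matrix (columns must cover the
#'   network genes).
#' @param v_n,v_c anchor states.
#' @param set optional precomputed \code{\link{find_attractors}} result.
#' @return data.frame: cell_id, attractor, d_cell, d_attractor, steps.
#' @export
map_cells_to_landscape <- function(net, cells, v_n, v_c, set = NULL) {
  cells <- as.matrix(cells)[, net$genes, drop = FALSE]
  if (is.null(set)) set <- find_attractors(net)
  if (!is.null(names(v_n))) v_n <- v_n[net$genes]
  if (!is.null(names(v_c))) v_c <- v_c[net$genes]
  compiled <- set$engine$compiled
  n <- set$n_genes
  d_attr <- vapply(set$attractors, function(a) mean(effective_distance(a$states, v_n, v_c)),
                   numeric(1))
  cycle_codes <- lapply(set$attractors, `[[`, "codes")
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    v <- as.integer(cells[ci, ])
    code <- encode_state(v)
    res <- converge_original(set, code)
    id <- res$id
    # step count until first state on the attractor cycle
    steps <- 0L
    cur <- v
    if (!is.na(id)) {
      while (!(encode_state(cur) %in% cycle_codes[[id]]) && steps <= 2L^n) {
        cur <- synchronous_step(net, cur, compiled)
        steps <- steps + 1L
      }
    } else steps <- NA_integer_
    data.frame(attractor = if (is.na(id)) NA_integer_ else id,
               d_cell = effective_distance(v, v_n, v_c),
               d_attractor = if (is.na(id)) NA_real_ else d_attr[id],
               steps = steps)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(cell_id = if (!is.null(rownames(cells))) rownames(cells)
                          else sprintf("cell_%04d", seq_len(nrow(cells))),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
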