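# Attractor search under synchronous update.
#
# Two engines share one result shape:
#   * exhaustive -- enumerates all 2^n states, builds the full successor array
#     of the functional state-transition graph and colours it; basins are exact.
#   * sampled    -- iterates from random (or user-supplied) initial states with
#     a memoised walk; basins are counts of initial states per attractor.
#
# States are encoded as 1-based integer codes with gene 1 the least significant
# bit. Attractor cycles are canonicalised by rotating them so the
# lexicographically smallest state (gene 1 most significant when read as a
# word) comes first; identical cycles therefore merge exactly.

MAX_EXHAUSTIVE_GENES <- 25L   # contract limit
MAX_FAST_ENGINE_GENES <- 14L  # per-state rule-row caches kept below this

# Lexicographic word value of a state (gene 1 most significant), used only
# for canonical ordering.
state_word <- function(v) sum(v * 2^(rev(seq_along(v)) - 1))

canonical_cycle <- function(codes, n) {
  words <- vapply(codes, function(cd) state_word(decode_state(cd, n)), numeric(1))
  i <- which.min(words)
  if (i > 1L) codes <- c(codes[i:length(codes)], codes[seq_len(i - 1L)])
  codes
}

#' Find attractors and basins of a Boolean network
#'
#' Iterates synchronous dynamics from every state (exhaustive mode) or from
#' random initial states until each trajectory closes a cycle; identical
#' cycles are merged under rotation. Attractors are ordered by descending
#' basin count, ties broken by the lexicographically smallest state.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param method \code{"auto"} (exhaustive when the network has at most
#'   14 genes), \code{"exhaustive"}, or \code{"sampled"}.
#' @param n_random number of random initial states in sampled mode
#'   (default 1000).
#' @param initial_states optional matrix (rows = states) or list of explicit
#'   initial states; forces sampled mode accounting over exactly these states.
#' @param seed integer seed for random initial states.
#' @return an object of class \code{attractor_set}: attractors (each a matrix
#'   of cycle states), basin counts, basin state codes, and engine caches used
#'   by \code{\link{attractor_entropy}}.
#' @export
find_attractors <- function(net, method = c("auto", "exhaustive", "sampled"),
                            n_random = 1000L, initial_states = NULL, seed = 1L) {
  method <- match.arg(method)
  n <- length(net$genes)
  if (!is.null(initial_states)) method <- "sampled"
  if (method == "auto") method <- if (n <= MAX_FAST_ENGINE_GENES) "exhaustive" else "sampled"
  if (method == "exhaustive") {
    if (n > MAX_EXHAUSTIVE_GENES) stop("exhaustive mode supports at most ",
                                       MAX_EXHAUSTIVE_GENES, " genes")
    if (n > 22L) stop("exhaustive enumeration of 2^", n, " states is too large")
    find_attractors_exhaustive(net)
  } else {
    find_attractors_sampled(net, n_random = n_random,
                            initial_states = initial_states, seed = seed)
  }
}

find_attractors_exhaustive <- function(net) {
  n <- length(net$genes)
  N <- 2^n
  compiled <- compile_network(net)
  # bit matrix of all states: column g = value of gene g
  codes0 <- 0:(N - 1)
  S <- vapply(seq_len(n), function(g) bitwAnd(codes0 %/% 2L^(g - 1L), 1L),
              integer(N))
  if (n == 1L) S <- matrix(S, ncol = 1L)
  # per-gene successor bits, vectorised over all states
  idx_cache <- if (n <= MAX_FAST_ENGINE_GENES) vector("list", n) else NULL
  nxt <- rep(1, N)
  for (g in seq_len(n)) {
    cg <- compiled[[g]]
    idx <- if (length(cg$weights)) {
      as.integer(1 + S[, cg$reg_idx, drop = FALSE] %*% cg$weights)
    } else rep(1L, N)
    if (!is.null(idx_cache)) idx_cache[[g]] <- idx
    nxt <- nxt + cg$table[idx] * 2^(g - 1L)
  }
  # colour the functional graph
  attr_of <- integer(N)        # 0 = unassigned
  attractors <- list()
  for (s in seq_len(N)) {
    if (attr_of[s]) next
    path <- numeric(0)
    pos <- new.env(hash = TRUE, parent = emptyenv())
    cur <- s
    repeat {
      a <- attr_of[cur]
      if (a) { aid <- a; break }
      k <- pos[[as.character(cur)]]
      if (!is.null(k)) {
        cyc <- canonical_cycle(path[k:length(path)], n)
        attractors[[length(attractors) + 1L]] <- cyc
        aid <- length(attractors)
        break
      }
      path <- c(path, cur)
      pos[[as.character(cur)]] <- length(path)
      cur <- nxt[cur]
    }
    attr_of[path] <- aid
  }
  basin <- tabulate(attr_of, nbins = length(attractors))
  basin_states <- split(seq_len(N), attr_of)
  make_attractor_set(net, attractors, basin, basin_states, total = N,
                     mode = "exhaustive",
                     engine = list(nxt = nxt, attr_of = attr_of,
                                   idx_cache = idx_cache, compiled = compiled))
}

# Walk from one state under `compiled` rules, memoising attractor ids in `memo`
# (an environment keyed by state code). `reg` is a mutable registry environment
# holding attractors found so far (list `cycles`, keyed lookup `by_key`).
walk_to_attractor <- function(compiled, n, start_code, memo, reg) {
  path <- numeric(0)
  pos <- new.env(hash = TRUE, parent = emptyenv())
  cur <- start_code
  repeat {
    known <- memo[[as.character(cur)]]
    if (!is.null(known)) { aid <- known; break }
    k <- pos[[as.character(cur)]]
    if (!is.null(k)) {
      cyc <- canonical_cycle(path[k:length(path)], n)
      key <- paste(cyc, collapse = ",")
      aid <- reg$by_key[[key]]
      if (is.null(aid)) {
        reg$cycles[[length(reg$cycles) + 1L]] <- cyc
        aid <- length(reg$cycles)
        reg$by_key[[key]] <- aid
      }
      break
    }
    path <- c(path, cur)
    pos[[as.character(cur)]] <- length(path)
    v <- decode_state(cur, n)
    out <- integer(n)
    for (g in seq_len(n)) out[g] <- compiled[[g]]$table[rule_row_index(compiled[[g]], v)]
    cur <- encode_state(out)
  }
  for (p in path) memo[[as.character(p)]] <- aid
  aid
}

find_attractors_sampled <- function(net, n_random = 1000L, initial_states = NULL,
                                    seed = 1L) {
  n <- length(net$genes)
  compiled <- compile_network(net)
  if (is.null(initial_states)) {
    set.seed(seed)
    init <- matrix(stats::rbinom(n_random * n, 1L, 0.5), ncol = n)
  } else {
    if (is.list(initial_states)) initial_states <- do.call(rbind, initial_states)
    init <- as.matrix(initial_states)
    if (ncol(init) != n) stop("initial states must have one column per gene")
  }
  codes <- apply(init, 1L, encode_state)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  reg <- new.env(parent = emptyenv()); reg$cycles <- list(); reg$by_key <- list()
  assign_id <- vapply(codes, function(cd) walk_to_attractor(compiled, n, cd, memo, reg),
                      numeric(1))
  basin <- tabulate(assign_id, nbins = length(reg$cycles))
  basin_states <- lapply(split(codes, assign_id), unique)
  make_attractor_set(net, reg$cycles, basin, basin_states, total = length(codes),
                     mode = "sampled",
                     engine = list(memo = memo, reg = reg, compiled = compiled))
}

make_attractor_set <- function(net, cycles, basin, basin_states, total, mode, engine) {
  n <- length(net$genes)
  # canonical ordering: descending basin, then lexicographic first state
  words <- vapply(cycles, function(cyc) state_word(decode_state(cyc[1], n)), numeric(1))
  ord <- order(-basin, words)
  cycles <- cycles[ord]
  basin <- basin[ord]
  names(basin_states) <- NULL
  basin_states <- basin_states[ord]
  attractors <- lapply(cycles, function(cyc) {
    states <- t(vapply(cyc, decode_state, integer(n), n = n))
    colnames(states) <- net$genes
    list(codes = cyc, states = states, is_point = length(cyc) == 1L)
  })
  structure(list(genes = net$genes, n_genes = n, mode = mode,
                 attractors = attractors, basin_counts = basin,
                 basin_states = basin_states, total = total,
                 order_map = ord, engine = engine),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat("Attractor set (", x$mode, " mode): ", length(x$attractors),
      " attractor(s) over ", x$total, " initial states\n", sep = "")
  for (i in seq_along(x$attractors)) {
    a <- x$attractors[[i]]
    kind <- if (a$is_point) "point" else paste0(nrow(a$states), "-cycle")
    cat(sprintf("  A%d [%s] basin %d (%.3f): %s\n", i, kind, x$basin_counts[i],
                x$basin_counts[i] / x$total,
                paste(apply(a$states, 1, paste, collapse = ""), collapse = " -> ")))
  }
  invisible(x)
}

# Attractor id (index into set$attractors) reached from `code` under the
# ORIGINAL network of the set; NA_character_-free: returns list(id, key).
# For attractors never seen before (possible in sampled mode), id is NA and
# `key` identifies the new cycle.
converge_original <- function(set, code) {
  if (set$mode == "exhaustive") {
    id0 <- set$engine$attr_of[code]
    return(list(id = match(id0, set$order_map), key = NULL))
  }
  reg <- set$engine$reg
  n_before <- length(reg$cycles)
  aid <- walk_to_attractor(set$engine$compiled, set$n_genes, code,
                           set$engine$memo, reg)
  id <- match(aid, set$order_map)
  if (is.na(id)) {
    key <- paste(reg$cycles[[aid]], collapse = ",")
    list(id = NA_integer_, key = key)
  } else list(id = id, key = NULL)
}
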