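# brute-force reference: enumerate every truth table over r inputs and filter
# by sign-monotonicity and essentiality directly on vectors
brute_candidates <- function(signs) {
  r <- length(signs)
  rows <- 0:(2^r - 1)
  bits <- sapply(seq_len(r), function(j) bitwAnd(rows %/% 2^(r - j), 1))
  if (r == 1) bits <- matrix(bits, ncol = 1)
  keep <- list()
  for (code in 0:(2^(2^r) - 1)) {
    tab <- as.integer(bitwAnd(code %/% 2^((2^r - 1):0), 1))
    ok <- TRUE
    for (j in seq_len(r)) {
      lo <- tab[bits[, j] == 0]; hi <- tab[bits[, j] == 1]
      mono <- if (signs[j] > 0) all(hi >= lo) else all(hi <= lo)
      if (!mono || all(hi == lo)) { ok <- FALSE; break }
    }
    if (ok) keep[[length(keep) + 1]] <- tab
  }
  do.call(rbind, keep)
}

test_that("candidate enumeration matches brute force for 1-2 regulators", {
  # one activator -> identity only; one inhibitor -> NOT only
  expect_equal(enumerate_candidates(1L), matrix(c(0L, 1L), 1))
  expect_equal(enumerate_candidates(-1L), matrix(c(1L, 0L), 1))
  # two activators -> exactly AND and OR
  two_act <- enumerate_candidates(c(1L, 1L))
  expect_equal(nrow(two_act), 2L)
  expect_true(any(apply(two_act, 1, identical, y = c(0L, 0L, 0L, 1L))))  # AND
  expect_true(any(apply(two_act, 1, identical, y = c(0L, 1L, 1L, 1L))))  # OR
  # full agreement with the brute-force filter for several sign patterns
  for (signs in list(1L, -1L, c(1L, 1L), c(1L, -1L), c(-1L, -1L),
                     c(1L, 1L, -1L))) {
    a <- enumerate_candidates(signs)
    b <- brute_candidates(signs)
    expect_equal(a[order(apply(a, 1, paste, collapse = "")), , drop = FALSE],
                 b[order(apply(b, 1, paste, collapse = "")), , drop = FALSE])
  }
})

test_that("input-output pairs have m = n_cells - k and respect the window", {
  set.seed(3)
  bm <- matrix(rbinom(30, 1, 0.5), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  p <- make_io_pairs(bm, "a", c("b", "c"), k = 3)
  expect_equal(p$m, 7L)
  expect_equal(nrow(p$inputs), 7L)
  expect_equal(p$outputs, unname(bm[4:10, "a"]))
  # boundary: k = n - 1 -> a single pair
  expect_equal(make_io_pairs(bm, "a", "b", k = 9)$m, 1L)
  # regulator order permutation permutes input columns consistently
  p2 <- make_io_pairs(bm, "a", c("c", "b"), k = 3)
  expect_equal(p2$inputs[, "b"], p$inputs[, "b"])
  expect_error(make_io_pairs(bm, "a", "b", k = 2, window = 2), "step size")
  expect_error(make_io_pairs(bm, "a", "b", k = 10), "more cells")
})

test_that("score function counts reproduced pairs", {
  set.seed(8)
  a <- rbinom(11, 1, 0.5)
  b <- c(0L, 1L - a[1:10])               # b_{t+1} = !a_t exactly
  bm <- cbind(a = a, b = b)
  p <- make_io_pairs(bm, "b", "a", k = 1)
  expect_equal(score_function(c(1L, 0L), p), p$m)      # perfect fit
  expect_equal(score_function(c(0L, 1L), p), 0L)       # complement scores 0
  # constant-0 scores the number of zero outputs
  expect_equal(score_function(c(0L, 0L), p), sum(p$outputs == 0L))
})

test_that("argmax property holds and ties are OR-combined", {
  # data generated by f = a AND b (noiseless): unique argmax recovers it
  set.seed(9)
  n <- 41
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  g <- integer(n)
  g[2:n] <- a[1:(n - 1)] & b[1:(n - 1)]
  bm <- cbind(a = a, b = b, g = g)
  p <- make_io_pairs(bm, "g", c("a", "b"), k = 1)
  rule <- infer_rule(p, c(1L, 1L))
  expect_equal(rule$table, c(0L, 0L, 0L, 1L))
  expect_equal(attr(rule, "score"), p$m)
  # exhaustive re-scoring: no candidate beats the selected rule
  cands <- enumerate_candidates(c(1L, 1L))
  expect_true(all(score_function(cands, p) <= attr(rule, "score")))
  # noisy outputs: some rule is still returned without error
  set.seed(10)
  bm_noise <- cbind(a = rbinom(30, 1, 0.5), b = rbinom(30, 1, 0.5),
                    g = rbinom(30, 1, 0.5))
  rn <- infer_rule(make_io_pairs(bm_noise, "g", c("a", "b"), k = 2), c(1L, 1L))
  expect_lte(attr(rn, "score"), attr(rn, "m"))
  # forced tie: both AND and OR fit data seen only at inputs where they
  # agree (g lags the coherent (a, b) switch by exactly the step size)
  bm2 <- cbind(a = c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L),
               b = c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L),
               g = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  p2 <- make_io_pairs(bm2, "g", c("a", "b"), k = 1)
  r2 <- infer_rule(p2, c(1L, 1L))
  expect_equal(attr(r2, "n_tied"), 2L)
  expect_equal(r2$table, as.integer(apply(attr(r2, "tied_tables"), 2, max)))
  # OR of tied perfect fits still fits perfectly
  expect_equal(attr(r2, "score"), p2$m)
})

test_that("OR-combination never scores below tied optimum minus disagreements", {
  set.seed(11)
  for (trial in 1:5) {
    bm <- matrix(rbinom(90, 1, 0.5), 30, 3,
                 dimnames = list(NULL, c("a", "b", "g")))
    p <- make_io_pairs(bm, "g", c("a", "b"), k = 2)
    signs <- c(1L, -1L)
    cands <- enumerate_candidates(signs)
    scores <- score_function(cands, p)
    tied <- cands[scores == max(scores), , drop = FALSE]
    rule <- infer_rule(p, signs)
    idx <- 1 + p$inputs %*% c(2, 1)
    disagree <- sum(apply(tied, 2, function(col) length(unique(col)) > 1)[idx])
    expect_gte(attr(rule, "score"), max(scores) - disagree)
  }
})

test_that("noiseless rules are recovered and round-trip through rule files", {
  gt <- make_bistable_network(8, 2, seed = 7)
  tr <- simulate_trajectory(gt, 200, 0, seed = 1)
  net <- infer_network(tr$binarized, network_edges(gt$network),
                       k = tr$dwell, window = 0)
  expect_equal(network_agreement(gt$network, net, tr$backbone), 1.0)
  # per-gene scores are perfect except the driven master switch
  pg <- attr(net, "per_gene")
  expect_true(all(pg$score[pg$gene != gt$master] ==
                    pg$m[pg$gene != gt$master]))
  # BoolNet-style file round trip is byte-identical
  f1 <- tempfile(fileext = ".bnet"); f2 <- tempfile(fileext = ".bnet")
  write_rules(net, f1)
  write_rules(read_rules(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(readLines(f1)[1], "targets, factors")
  back <- read_rules(f1)
  states <- matrix(rbinom(160, 1, 0.5), 20, 8,
                   dimnames = list(NULL, net$genes))
  expect_equal(network_agreement(net, back, states), 1.0)
})

test_that("regulator cap keeps the strongest correlates with a warning", {
  set.seed(5)
  n <- 60
  g <- rbinom(n, 1, 0.5)
  bm <- cbind(g = g,
              r1 = g, r2 = ifelse(runif(n) < 0.9, g, 1 - g),
              r3 = ifelse(runif(n) < 0.8, g, 1 - g),
              r4 = ifelse(runif(n) < 0.7, g, 1 - g),
              r5 = rbinom(n, 1, 0.5))
  skel <- signed_network(data.frame(
    source = c(paste0("r", 1:5), "g"), target = c(rep("g", 5), "r1"),
    sign = 1L))
  skel <- signed_network(rbind(skel$edges,
                               data.frame(source = "g", target = paste0("r", 2:5),
                                          sign = 1L)))
  expect_warning(net <- infer_network(bm, skel, k = 2, max_regulators = 4L),
                 "reduced")
  expect_length(net$rules[["g"]]$regulators, 4L)
  expect_false("r5" %in% net$rules[["g"]]$regulators)
})
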