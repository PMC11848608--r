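#' Construct a Boolean regulation rule
#'
#' A rule is a truth table over an ordered set of regulators. Truth-table rows
#' are in lexicographic order of the regulator assignment with the *first*
#' regulator as the most significant bit: row \code{i} corresponds to the
#' assignment whose bits are \code{(i - 1)} written in base 2 over
#' \code{length(regulators)} digits.
#'
#' @param gene target gene name.
#' @param regulators character vector of regulator gene names (may be empty
#'   for a constant rule). Duplicates are not allowed.
#' @param table integer/numeric vector of 0/1 outputs, length
#'   \code{2^length(regulators)}.
#' @param signs optional integer vector of regulator signs (+1 activation,
#'   -1 inhibition, NA unknown), same length as \code{regulators}. If missing,
#'   signs are derived from the table's monotonicity (NA when non-monotone).
#' @return an object of class \code{boolean_rule}.
#' @export
boolean_rule <- function(gene, regulators, table, signs = NULL) {
  stopifnot(is.character(gene), length(gene) == 1L)
  regulators <- as.character(regulators)
  if (anyDuplicated(regulators)) stop("duplicate regulators for gene ", gene)
  table <- as.integer(table)
  if (length(table) != 2L^length(regulators)) {
    stop("truth table for ", gene, " must have length 2^", length(regulators))
  }
  if (!all(table %in% c(0L, 1L))) stop("truth table entries must be 0/1")
  if (is.null(signs)) {
    signs <- table_signs(table, length(regulators))
  } else {
    signs <- as.integer(signs)
    stopifnot(length(signs) == length(regulators))
  }
  structure(
    list(gene = gene, regulators = regulators, table = table, signs = signs),
    class = "boolean_rule"
  )
}

#' Construct a Boolean network
#'
#' @param rules list of \code{\link{boolean_rule}} objects, one per gene. Every
#'   regulator must itself be a gene of the network.
#' @param genes optional explicit gene ordering; defaults to the order of
#'   \code{rules}.
#' @return an object of class \code{boolean_network}.
#' @export
boolean_network <- function(rules, genes = NULL) {
  stopifnot(is.list(rules), length(rules) >= 1L)
  rule_genes <- vapply(rules, function(r) r$gene, character(1))
  if (anyDuplicated(rule_genes)) stop("duplicate rules for genes: ",
                                      paste(unique(rule_genes[duplicated(rule_genes)]), collapse = ", "))
  if (is.null(genes)) genes <- rule_genes
  if (!setequal(genes, rule_genes)) stop("rules and gene set disagree")
  names(rules) <- rule_genes
  rules <- rules[genes]
  regs <- unique(unlist(lapply(rules, `[[`, "regulators")))
  unknown <- setdiff(regs, genes)
  if (length(unknown)) stop("regulators not in gene set: ", paste(unknown, collapse = ", "))
  structure(list(genes = genes, rules = rules), class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network with", length(x$genes), "genes\n")
  for (r in x$rules) {
    cat("  ", r$gene, " <- ", rule_to_expression(r), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.boolean_rule <- function(x, ...) {
  cat(x$gene, "<-", rule_to_expression(x), "\n")
  invisible(x)
}

# Derive per-regulator signs from a truth table: +1 if the output is
# non-decreasing in that input (and the input is essential), -1 if
# non-increasing, NA if non-monotone, 0 if inessential.
table_signs <- function(table, n_reg) {
  if (n_reg == 0L) return(integer(0))
  signs <- integer(n_reg)
  rows <- 0:(length(table) - 1L)
  for (j in seq_len(n_reg)) {
    bit <- bitwAnd(rows %/% 2L^(n_reg - j), 1L)
    lo <- table[bit == 0L]
    hi <- table[bit == 1L]
    if (all(lo == hi)) signs[j] <- 0L
    else if (all(hi >= lo)) signs[j] <- 1L
    else if (all(hi <= lo)) signs[j] <- -1L
    else signs[j] <- NA_integer_
  }
  signs
}

# Precompute fast-lookup structures: per gene, integer positions of its
# regulators in the gene vector and the weight of each regulator bit.
compile_network <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  lapply(net$rules, function(r) {
    nr <- length(r$regulators)
    list(
      reg_idx = match(r$regulators, net$genes),
      weights = if (nr) 2^((nr - 1):0) else numeric(0),
      table = r$table
    )
  })
}

#' One synchronous update step
#'
#' All genes are updated simultaneously from the current state, so the
#' dynamics are deterministic.
#'
#' @param net a \code{boolean_network}.
#' @param state binary vector in the order of \code{net$genes}.
#' @param compiled optional result of an internal pre-compilation; used by the
#'   attractor machinery to avoid repeated setup.
#' @return the successor state (integer 0/1 vector).
#' @export
synchronous_step <- function(net, state, compiled = NULL) {
  if (is.null(compiled)) compiled <- compile_network(net)
  state <- as.integer(state)
  if (length(state) != length(compiled)) stop("state length does not match network")
  if (!all(state %in% c(0L, 1L))) stop("state entries must be 0/1")
  out <- integer(length(state))
  for (g in seq_along(compiled)) {
    cg <- compiled[[g]]
    idx <- if (length(cg$weights)) 1 + sum(state[cg$reg_idx] * cg$weights) else 1
    out[g] <- cg$table[idx]
  }
  out
}

# State <-> integer code. Gene 1 is the least significant bit; codes are
# 1-based so they can index R vectors directly. Only used for n <= 25.
encode_state <- function(v) 1 + sum(v * 2^(seq_along(v) - 1))

decode_state <- function(code, n) as.integer(bitwAnd((code - 1) %/% 2L^(0:(n - 1L)), 1L))

# Row index into a rule's truth table for a full network state.
rule_row_index <- function(cg, state) {
  if (!length(cg$weights)) return(1L)
  as.integer(1 + sum(state[cg$reg_idx] * cg$weights))
}

#' Fix genes to constant values
#'
#' Replaces the rule of each fixed gene by a constant (knockdown = 0,
#' overexpression = 1). Other rules are untouched; they may still list the
#' fixed gene as a regulator, whose value simply never changes.
#'
#' @param net a \code{boolean_network}.
#' @param fixes named numeric/integer vector or named list, names = genes,
#'   values in \{0, 1\}. An empty fixation returns the network unchanged.
#' @return the perturbed \code{boolean_network}.
#' @export
apply_fixation <- function(net, fixes) {
  stopifnot(inherits(net, "boolean_network"))
  fixes <- unlist(fixes)
  if (!length(fixes)) return(net)
  if (is.null(names(fixes)) || any(!nzchar(names(fixes)))) stop("fixes must be named by gene")
  unknown <- setdiff(names(fixes), net$genes)
  if (length(unknown)) stop("unknown gene(s) in fixation: ", paste(unknown, collapse = ", "))
  if (!all(fixes %in% c(0, 1))) stop("fixation values must be 0 or 1")
  for (g in names(fixes)) {
    net$rules[[g]] <- boolean_rule(g, character(0), as.integer(fixes[[g]]))
  }
  net
}

#' Agreement between two networks on observed states
#'
#' For every unique state observed in \code{states} and every gene, compares
#' the one-step predictions of the two networks; returns the fraction of
#' (state, gene) predictions that agree. Used to measure how well inferred
#' rules reproduce a ground-truth network on the input states that actually
#' occur in the data.
#'
#' @param net_a,net_b two \code{\link{boolean_network}}s over the same genes.
#' @param states matrix of binary states (rows), columns covering the
#'   networks' genes.
#' @return fraction in [0, 1].
#' @export
network_agreement <- function(net_a, net_b, states) {
  stopifnot(setequal(net_a$genes, net_b$genes))
  states <- unique(as.matrix(states)[, net_a$genes, drop = FALSE])
  ca <- compile_network(net_a)
  net_b_ord <- net_b$rules[net_a$genes]
  cb <- compile_network(boolean_network(net_b_ord, genes = net_a$genes))
  hits <- 0L
  for (i in seq_len(nrow(states))) {
    v <- as.integer(states[i, ])
    hits <- hits + sum(synchronous_step(net_a, v, ca) == synchronous_step(net_a, v, cb))
  }
  hits / (nrow(states) * length(net_a$genes))
}
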