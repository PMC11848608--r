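# Plain-text interchange: BoolNet-style rule files ("targets, factors") and
# SIF-style signed edge lists.

#' Render a rule as a Boolean expression
#'
#' Constant rules render as \code{"0"}/\code{"1"}; otherwise the canonical
#' full disjunctive normal form over the rule's regulators (one parenthesised
#' product term per true row, terms joined by \code{|}). The rendering is
#' deterministic, so write -> read -> write round-trips byte-identically.
#'
#' @param rule a \code{\link{boolean_rule}}.
#' @return a single character string.
#' @export
rule_to_expression <- function(rule) {
  r <- length(rule$regulators)
  if (r == 0L) return(as.character(rule$table[1]))
  if (all(rule$table == 0L)) return("0")
  if (all(rule$table == 1L)) return("1")
  rows <- which(rule$table == 1L) - 1L
  terms <- vapply(rows, function(row) {
    bits <- bitwAnd(row %/% 2L^((r - 1L):0), 1L)
    lits <- ifelse(bits == 1L, rule$regulators, paste0("!", rule$regulators))
    term <- paste(lits, collapse = " & ")
    if (r > 1L) paste0("(", term, ")") else term
  }, character(1))
  paste(terms, collapse = " | ")
}

# Parse a Boolean expression into a rule. Regulator order = order of first
# appearance in the expression text. Only !, &, |, parentheses, 0/1 and gene
# names are allowed.
expression_to_rule <- function(gene, text) {
  text <- trimws(text)
  if (text %in% c("0", "1")) {
    return(boolean_rule(gene, character(0), as.integer(text)))
  }
  if (!grepl("^[A-Za-z0-9_.[:space:]!&|()-]+$", text)) {
    stop("disallowed characters in rule for ", gene, ": ", text)
  }
  vars <- unique(unlist(regmatches(text, gregexpr("[A-Za-z._][A-Za-z0-9._-]*", text))))
  expr <- str2lang(text)
  ok <- setdiff(all.names(expr), c("!", "&", "|", "(", vars))
  if (length(ok)) stop("disallowed tokens in rule for ", gene, ": ",
                       paste(ok, collapse = ", "))
  r <- length(vars)
  if (r > 16L) stop("too many regulators in rule for ", gene)
  tab <- integer(2L^r)
  for (row in 0:(2L^r - 1L)) {
    bits <- bitwAnd(row %/% 2L^((r - 1L):0), 1L)
    env <- as.list(as.logical(bits))
    names(env) <- vars
    val <- eval(expr, envir = env, enclos = baseenv())
    tab[row + 1L] <- as.integer(as.logical(val))
  }
  boolean_rule(gene, vars, tab)
}

#' Write a Boolean network as a BoolNet-style rule file
#'
#' First line is \code{"targets, factors"}, then one \code{GENE, expression}
#' line per gene in network order.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param path output file path.
#' @export
write_rules <- function(net, path) {
  stopifnot(inherits(net, "boolean_network"))
  lines <- c("targets, factors",
             vapply(net$rules, function(r) paste0(r$gene, ", ", rule_to_expression(r)),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BoolNet-style rule file
#'
#' @param path path to a plain-text rule file with a \code{targets, factors}
#'   header.
#' @return a \code{\link{boolean_network}}.
#' @export
read_rules <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || tolower(gsub("[[:space:]]", "", lines[1])) != "targets,factors") {
    stop("rule file must start with a 'targets, factors' header")
  }
  rules <- lapply(lines[-1], function(ln) {
    m <- regexpr(",", ln, fixed = TRUE)
    if (m < 0) stop("malformed rule line: ", ln)
    gene <- trimws(substr(ln, 1, m - 1))
    expression_to_rule(gene, substr(ln, m + 1, nchar(ln)))
  })
  genes <- vapply(rules, `[[`, character(1), "gene")
  regs <- unique(unlist(lapply(rules, `[[`, "regulators")))
  dangling <- setdiff(regs, genes)
  if (length(dangling)) stop("regulators without rules: ", paste(dangling, collapse = ", "))
  boolean_network(rules)
}

#' Construct a signed directed network
#'
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{sign} (+1 / -1, NA allowed before pruning).
#' @param nodes optional node set; defaults to all endpoint genes.
#' @return an object of class \code{signed_network}.
#' @export
signed_network <- function(edges, nodes = NULL) {
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        sign = integer(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source", "target", "sign") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  key <- paste(edges$source, edges$target)
  if (anyDuplicated(key)) stop("duplicate (source, target) edges")
  if (is.null(nodes)) nodes <- unique(c(edges$source, edges$target))
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = as.character(nodes)),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat("Signed network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    arrows <- ifelse(is.na(x$edges$sign), "-?", ifelse(x$edges$sign > 0, "->", "-|"))
    shown <- utils::head(paste0("  ", x$edges$source, " ", arrows, " ", x$edges$target), 20L)
    cat(shown, sep = "\n")
    if (nrow(x$edges) > 20L) cat("  ...\n")
  }
  invisible(x)
}

#' Read a SIF-style signed edge list
#'
#' Tab-separated lines \code{source<TAB>sign<TAB>target}; sign may be
#' \code{+1/-1}, \code{+/-}, or \code{activates/inhibits}.
#'
#' @param path input file path.
#' @return a \code{\link{signed_network}}.
#' @export
read_sif <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("source", "sign_raw", "target"),
                          colClasses = "character")
  sgn <- c("+1" = 1L, "1" = 1L, "+" = 1L, "activates" = 1L, "activate" = 1L,
           "-1" = -1L, "-" = -1L, "inhibits" = -1L, "inhibit" = -1L)
  s <- sgn[tolower(df$sign_raw)]
  if (anyNA(s)) stop("unrecognised sign value(s): ",
                     paste(unique(df$sign_raw[is.na(s)]), collapse = ", "))
  signed_network(data.frame(source = df$source, target = df$target, sign = s))
}

#' Write a signed network as SIF
#' @param net a \code{\link{signed_network}}.
#' @param path output path.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges
  writeLines(paste(e$source, ifelse(e$sign > 0, "+1", "-1"), e$target, sep = "\t"),
             path)
  invisible(path)
}

#' Signed edge list of a Boolean network's regulator structure
#' @param net a \code{\link{boolean_network}}.
#' @return a \code{\link{signed_network}} with one edge per regulator.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  rows <- do.call(rbind, lapply(net$rules, function(r) {
    if (!length(r$regulators)) return(NULL)
    data.frame(source = r$regulators, target = r$gene, sign = r$signs,
               stringsAsFactors = FALSE)
  }))
  signed_network(rows, nodes = net$genes)
}
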