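#' Create a Boolean update rule from an explicit truth table
#'
#' A rule maps every combination of its regulators' values to the target's
#' next value. The table is stored flat: entry `i` corresponds to the
#' regulator assignment whose bits are the binary expansion of `i - 1` with
#' the *first* regulator in the least significant position.
#'
#' @param target Name of the regulated node.
#' @param regulators Character vector of regulator node names (may be empty
#'   for a constant rule). Duplicates are not allowed.
#' @param table Integer/logical vector of length `2^length(regulators)` with
#'   values in `{0, 1}`.
#' @return An object of class `logic_rule`.
#' @seealso [rule_from_expression()] for the expression front end.
#' @export
logic_rule <- function(target, regulators, table) {
  regulators <- as.character(regulators)
  if (anyDuplicated(regulators))
    abort2("duplicate regulators in rule for node '", target, "'")
  table <- as.integer(table)
  k <- length(regulators)
  if (length(table) != 2L^k)
    abort2("rule for '", target, "': table must have exactly 2^", k,
           " entries, got ", length(table))
  if (!all(table %in% c(0L, 1L)))
    abort2("rule for '", target, "': table entries must be 0 or 1")
  structure(list(target = target, regulators = regulators, table = table),
            class = "logic_rule")
}

#' Identity rule used for input (extrinsic) nodes
#' @param node Node name.
#' @return A `logic_rule` whose next value equals the node's current value.
#' @export
identity_rule <- function(node) logic_rule(node, node, c(0L, 1L))

is_identity_rule <- function(rule) {
  length(rule$regulators) == 1L &&
    rule$regulators == rule$target &&
    identical(rule$table, c(0L, 1L))
}

## ---- Boolean expression parser -------------------------------------------
## Grammar: expr := term ('|' term)* ; term := factor ('&' factor)* ;
##          factor := '!' factor | '(' expr ')' | name | '0' | '1'

tokenize_expr <- function(text) {
  pat <- "[A-Za-z_][A-Za-z0-9_.]*|[!&|()]|0|1"
  starts <- gregexpr(pat, text)[[1]]
  if (starts[1] == -1) abort2("empty Boolean expression")
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  stripped <- gsub("\\s+", "", text)
  if (nchar(paste(toks, collapse = "")) != nchar(stripped))
    abort2("cannot tokenize Boolean expression: '", text, "'")
  toks
}

parse_bool_expr <- function(text) {
  toks <- tokenize_expr(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && peek() == "|") { take()
      node <- list(op = "or", a = node, b = parse_term()) }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.na(peek()) && peek() == "&") { take()
      node <- list(op = "and", a = node, b = parse_factor()) }
    node
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) abort2("unexpected end of Boolean expression: '", text, "'")
    if (t == "!") { take(); return(list(op = "not", a = parse_factor())) }
    if (t == "(") {
      take(); node <- parse_expr()
      if (is.na(peek()) || peek() != ")")
        abort2("unbalanced parentheses in expression: '", text, "'")
      take(); return(node)
    }
    if (t %in% c("0", "1")) { take(); return(list(op = "const", value = as.integer(t))) }
    if (grepl("^[A-Za-z_]", t)) { take(); return(list(op = "var", name = t)) }
    abort2("unexpected token '", t, "' in expression: '", text, "'")
  }
  ast <- parse_expr()
  if (pos <= length(toks))
    abort2("trailing tokens in expression: '", text, "'")
  ast
}

ast_vars <- function(ast) {
  switch(ast$op,
         var = ast$name,
         const = character(0),
         not = ast_vars(ast$a),
         unique(c(ast_vars(ast$a), ast_vars(ast$b))))
}

eval_ast <- function(ast, env) {
  switch(ast$op,
         var = env[[ast$name]],
         const = rep(ast$value, length(env[[1]]) %||% 1L),
         not = 1L - eval_ast(ast$a, env),
         and = pmin(eval_ast(ast$a, env), eval_ast(ast$b, env)),
         or = pmax(eval_ast(ast$a, env), eval_ast(ast$b, env)))
}

#' Build a rule from a Boolean expression string
#'
#' Supported operators: `!` (not), `&` (and), `|` (or), parentheses, and the
#' constants `0`/`1`. Regulators are taken in order of first appearance.
#'
#' @param target Target node name.
#' @param expression Expression string, e.g. `"(A | B) & !C"`.
#' @return A `logic_rule` with the truth table evaluated exhaustively.
#' @export
rule_from_expression <- function(target, expression) {
  ast <- parse_bool_expr(expression)
  vars <- ast_vars(ast)
  k <- length(vars)
  n <- 2L^k
  codes <- 0:(n - 1L)
  env <- stats::setNames(
    lapply(seq_len(max(k, 1L)), function(j)
      if (k == 0L) integer(0) else bit_of(codes, j)),
    if (k == 0L) "..dummy" else vars)
  tab <- if (k == 0L) {
    env0 <- list(`..dummy` = 0L)
    rep(eval_ast(ast, env0)[1], 1L)
  } else eval_ast(ast, env)
  logic_rule(target, vars, as.integer(tab))
}

#' Convert a rule's truth table to a Boolean expression (DNF)
#'
#' Constant rules yield `"0"`/`"1"`; otherwise a disjunction of minterms over
#' the rule's regulators.
#' @param rule A `logic_rule`.
#' @return A single expression string that re-parses to an identical table.
#' @export
expression_from_rule <- function(rule) {
  k <- length(rule$regulators)
  if (all(rule$table == 0L)) return("0")
  if (all(rule$table == 1L)) return("1")
  ones <- which(rule$table == 1L) - 1L
  terms <- vapply(ones, function(code) {
    lits <- vapply(seq_len(k), function(j) {
      if (bit_of(code, j) == 1L) rule$regulators[j]
      else paste0("!", rule$regulators[j])
    }, character(1))
    paste0("(", paste(lits, collapse = " & "), ")")
  }, character(1))
  paste(terms, collapse = " | ")
}

#' Construct a logical (Boolean) network
#'
#' A network is an ordered set of named nodes, one update rule per node, and
#' a designated subset of input nodes. Input nodes must carry the identity
#' rule so that they hold their value along every trajectory; they model
#' extrinsic signals whose level is set by the surroundings, not by the
#' network.
#'
#' @param rules List of `logic_rule` objects, one per node; node order is the
#'   declaration order used for state vectors and canonical forms.
#' @param inputs Character vector of input node names (default none).
#' @param categories Optional named character vector assigning each node one
#'   of `"transcription_factor"`, `"intrinsic_pathway"`, `"extrinsic_cytokine"`,
#'   `"other"`.
#' @param metadata Free-form provenance list (model id, source file, ...).
#' @return An object of class `logic_network`.
#' @export
logic_network <- function(rules, inputs = character(0), categories = NULL,
                          metadata = list()) {
  if (!length(rules)) abort2("a logic network needs at least one rule")
  targets <- vapply(rules, function(r) r$target, character(1))
  names(rules) <- targets
  net <- structure(list(nodes = targets, rules = rules,
                        inputs = as.character(inputs),
                        categories = categories, metadata = metadata),
                   class = "logic_network")
  validate_logic_network(net)
  net
}

#' Validate the structural invariants of a logical network
#'
#' Checks: unique node names; exactly one rule per node; every regulator
#' names a node of the network; inputs are nodes and carry the identity
#' rule; truth tables are total; extrinsic-cytokine category implies input.
#'
#' @param net A `logic_network`.
#' @return `net`, invisibly; errors describe the first violation found.
#' @export
validate_logic_network <- function(net) {
  nodes <- net$nodes
  if (anyDuplicated(nodes))
    abort2("duplicate node names: ",
           paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  for (r in net$rules) {
    missing <- setdiff(r$regulators, nodes)
    if (length(missing))
      abort2("rule for '", r$target, "' references undeclared regulator(s): ",
             paste(missing, collapse = ", "))
    if (length(r$table) != 2L^length(r$regulators))
      abort2("rule for '", r$target, "' has a non-total truth table")
  }
  bad <- setdiff(net$inputs, nodes)
  if (length(bad))
    abort2("inputs not among nodes: ", paste(bad, collapse = ", "))
  for (inp in net$inputs)
    if (!is_identity_rule(net$rules[[inp]]))
      abort2("input node '", inp, "' must carry the identity rule")
  if (!is.null(net$categories)) {
    extr <- names(net$categories)[net$categories == "extrinsic_cytokine"]
    nonin <- setdiff(extr, net$inputs)
    if (length(nonin))
      abort2("extrinsic_cytokine node(s) not declared as inputs: ",
             paste(nonin, collapse = ", "))
  }
  invisible(net)
}

#' @export
print.logic_network <- function(x, ...) {
  cat("logic_network: ", length(x$nodes), " nodes (",
      length(x$inputs), " inputs)\n", sep = "")
  for (nd in x$nodes) {
    r <- x$rules[[nd]]
    cat(sprintf("  %-8s <- %s\n", nd, expression_from_rule(r)))
  }
  invisible(x)
}

#' Number of nodes of a logical network
#' @param net A `logic_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

rules_equal <- function(a, b) {
  # rule equivalence regardless of regulator order / redundant regulators
  vars <- union(a$regulators, b$regulators)
  k <- length(vars)
  codes <- 0:(2L^k - 1L)
  env <- stats::setNames(lapply(seq_len(max(k, 1L)), function(j)
    if (k == 0L) 0L else bit_of(codes, j)), if (k == 0L) "..d" else vars)
  ev <- function(r) {
    if (!length(r$regulators)) return(rep(r$table, length(codes)))
    idx <- rep(1L, length(codes))
    for (j in seq_along(r$regulators))
      idx <- idx + env[[r$regulators[j]]] * 2L^(j - 1L)
    r$table[idx]
  }
  identical(ev(a), ev(b))
}

#' Test two networks for rule equivalence
#'
#' Networks are equivalent when they have the same node set, same inputs and
#' logically equivalent update rules (truth-table equality over the union of
#' regulators), regardless of textual form.
#' @param a,b `logic_network` objects.
#' @return Logical scalar.
#' @export
networks_equivalent <- function(a, b) {
  if (!setequal(a$nodes, b$nodes)) return(FALSE)
  if (!setequal(a$inputs, b$inputs)) return(FALSE)
  all(vapply(a$nodes, function(nd)
    rules_equal(a$rules[[nd]], b$rules[[nd]]), logical(1)))
}
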