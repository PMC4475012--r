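#' Read a logical network from a BoolNet-style rule file
#'
#' The format is the plain-text `targets, factors` dialect: a header line
#' `targets, factors`, then one line per node of the form
#' `NODE, <Boolean expression>` using `!`, `&`, `|`, parentheses and the
#' constants 0/1. Two extensions are accepted:
#'
#' * metadata comments `#! inputs: A B C` (authoritative input declaration;
#'   an empty list declares an input-free network) and
#'   `#! category: NODE kind` lines assigning node categories;
#' * explicit truth-table blocks for rules inconvenient as expressions:
#'   ```
#'   @table NODE: REG1 REG2
#'   00: 0
#'   01: 1
#'   10: 1
#'   11: 0
#'   ```
#'   Bit strings list regulators in the declared order, first regulator
#'   leftmost; all `2^k` rows must be present.
#'
#' If no `#! inputs:` comment is present, nodes whose rule is the identity
#' on themselves are taken as inputs.
#'
#' @param path File path.
#' @return A validated `logic_network`.
#' @export
read_bnet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rules <- list()
  inputs <- NULL
  categories <- character(0)
  header_seen <- FALSE
  i <- 1L
  nline <- length(lines)
  while (i <= nline) {
    raw <- lines[i]
    line <- trimws(raw)
    if (startsWith(line, "#!")) {
      meta <- trimws(sub("^#!", "", line))
      if (grepl("^inputs\\s*:", meta)) {
        lst <- trimws(sub("^inputs\\s*:", "", meta))
        inputs <- if (nzchar(lst)) strsplit(lst, "[,[:space:]]+")[[1]] else character(0)
      } else if (grepl("^category\\s*:", meta)) {
        parts <- strsplit(trimws(sub("^category\\s*:", "", meta)), "[[:space:]]+")[[1]]
        if (length(parts) != 2L)
          abort2(path, ": line ", i, ": malformed category comment")
        categories[parts[1]] <- parts[2]
      }
      i <- i + 1L; next
    }
    if (line == "" || startsWith(line, "#")) { i <- i + 1L; next }
    if (!header_seen) {
      if (!grepl("^targets\\s*,\\s*factors$", line))
        abort2(path, ": line ", i, ": expected header 'targets, factors'")
      header_seen <- TRUE; i <- i + 1L; next
    }
    if (startsWith(line, "@table")) {
      m <- regmatches(line, regexec("^@table\\s+([A-Za-z_][A-Za-z0-9_.]*)\\s*:\\s*(.*)$", line))[[1]]
      if (length(m) != 3L) abort2(path, ": line ", i, ": malformed @table header")
      target <- m[2]
      regs <- if (nzchar(trimws(m[3])))
        strsplit(trimws(m[3]), "[,[:space:]]+")[[1]] else character(0)
      k <- length(regs)
      tab <- rep(NA_integer_, 2L^k)
      for (row in seq_len(2L^k)) {
        i <- i + 1L
        if (i > nline) abort2(path, ": truncated @table block for '", target, "'")
        rl <- trimws(lines[i])
        rm_ <- regmatches(rl, regexec("^([01]*)\\s*:\\s*([01])$", rl))[[1]]
        if (length(rm_) != 3L || nchar(rm_[2]) != k)
          abort2(path, ": line ", i, ": malformed truth-table row")
        bits <- as.integer(strsplit(rm_[2], "")[[1]])
        # leftmost bit = first regulator
        idx <- 1L + sum(bits * 2L^(seq_len(k) - 1L))
        if (!is.na(tab[idx]))
          abort2(path, ": line ", i, ": duplicate truth-table row")
        tab[idx] <- as.integer(rm_[3])
      }
      rules[[target]] <- logic_rule(target, regs, tab)
      i <- i + 1L; next
    }
    cm <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\s*,\\s*(.+)$", line))[[1]]
    if (length(cm) != 3L)
      abort2(path, ": line ", i, ": cannot parse rule line: '", line, "'")
    rules[[cm[2]]] <- tryCatch(rule_from_expression(cm[2], cm[3]),
      error = function(e)
        abort2(path, ": line ", i, ": ", conditionMessage(e)))
    i <- i + 1L
  }
  if (!header_seen) abort2(path, ": line 1: missing 'targets, factors' header")
  if (!length(rules)) abort2(path, ": no rules found")
  if (is.null(inputs))
    inputs <- names(rules)[vapply(rules, is_identity_rule, logical(1))]
  cats <- if (length(categories)) categories else NULL
  logic_network(rules, inputs = inputs, categories = cats,
                metadata = list(source = path))
}

#' Write a logical network as a BoolNet-style rule file
#'
#' Rules are serialized as Boolean expressions (disjunctive normal form when
#' no simpler form is stored); reading the result back yields a network that
#' is rule-equivalent to `net`.
#'
#' @param net A `logic_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bnet <- function(net, path) {
  out <- c(paste0("#! inputs: ", paste(net$inputs, collapse = " ")))
  if (!is.null(net$categories))
    out <- c(out, paste0("#! category: ", names(net$categories), " ",
                         net$categories))
  out <- c(out, "targets, factors")
  for (nd in net$nodes)
    out <- c(out, paste0(nd, ", ", expression_from_rule(net$rules[[nd]])))
  writeLines(out, path)
  invisible(path)
}
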