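# In-silico mutant validation of the TSRN.

DEFAULT_MUTANT_PANEL <- c("TBET", "GATA3", "RORGT", "FOXP3", "BCL6",
                          "IFNG", "IL2", "IL4", "IL21", "IL9", "TGFB", "IL10")

#' Knock-out / over-expression validation table
#'
#' Simulates, for each node of the panel, the knock-out (clamp 0) and
#' over-expression (clamp 1) mutants across every fully specified
#' micro-environment, and reports which phenotype classes retain at least
#' one attractor. The wild type (no clamp) is included as reference.
#'
#' @param net The TSRN `logic_network`.
#' @param panel Nodes to mutate (default: all intrinsic nodes).
#' @param rules Phenotype rules.
#' @return List: `table` (data frame mutant x class -> total basin across
#'   environments), `classes_present` (named list of class sets per mutant).
#' @export
validate_mutant_table <- function(net, panel = DEFAULT_MUTANT_PANEL,
                                  rules = phenotype_rules()) {
  panel <- intersect(panel, net$nodes)
  envs <- all_environments(net)
  run <- function(clamp_node, clamp_value) {
    total <- list()
    for (env in envs) {
      clamp <- env$clamped
      if (!is.null(clamp_node)) {
        if (clamp_node %in% names(clamp)) {
          if (clamp[[clamp_node]] != clamp_value) next  # env conflicts: skip
        } else clamp <- c(clamp, stats::setNames(clamp_value, clamp_node))
      }
      at <- enumerate_attractors(net, clamp = clamp)
      labs <- classify_attractors(at, rules)
      basins <- vapply(at$attractors, function(a) a$basin_size, numeric(1))
      for (i in seq_along(labs))
        total[[labs[i]]] <- (total[[labs[i]]] %||% 0) + basins[i]
    }
    unlist(total)
  }
  rows <- list()
  rows[["WT"]] <- run(NULL, NA)
  for (nd in panel) {
    rows[[paste0(nd, "_KO")]] <- run(nd, 0L)
    rows[[paste0(nd, "_OE")]] <- run(nd, 1L)
  }
  classes <- sort(unique(unlist(lapply(rows, names))))
  tab <- do.call(rbind, lapply(rows, function(r) {
    out <- stats::setNames(rep(0, length(classes)), classes)
    out[names(r)] <- r
    out
  }))
  tab <- data.frame(mutant = rownames(tab), tab, row.names = NULL,
                    check.names = FALSE)
  list(table = tab,
       classes_present = lapply(rows, function(r) names(r)[r > 0]))
}
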