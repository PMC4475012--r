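# Phenotype classification of attractors into CD4+ T cell types.
#
# Each attractor is labeled from the activity pattern of marker nodes:
# master transcription factors plus the main intrinsic cytokines. Rules are
# declarative (required-on / required-off conditions with a priority rank);
# the highest-priority matching rule wins, so compound states take their
# most specific label (a Foxp3+ regulatory state is iTreg, not TrFoxp3-).

#' Load the phenotype classification rules
#'
#' The bundled rule table declares, per cell-type label, the marker
#' conditions and a priority. `required_on` is a semicolon-separated list of
#' AND-groups; within a group, `|` separates alternatives (e.g.
#' `FOXP3;TGFB|IL10` reads "Foxp3 and (TGF-B or IL-10)"). `required_off`
#' lists nodes that must be inactive. Rules flagged `variant_only` describe
#' classes that only arise in derived model variants; they are part of the
#' closed label vocabulary and applying them to the wild-type model is
#' harmless because their marker combinations do not occur there.
#'
#' @param path CSV file; defaults to the bundled table.
#' @return Data frame of class `phenotype_rules`, ordered by priority.
#' @export
phenotype_rules <- function(path = NULL) {
  if (is.null(path)) path <- model_file("phenotype_rules.csv")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "required_on", "required_off", "priority")
  if (!all(need %in% names(d)))
    abort2("phenotype rule table must have columns: ",
           paste(need, collapse = ", "))
  d <- d[order(d$priority), , drop = FALSE]
  class(d) <- c("phenotype_rules", "data.frame")
  d
}

parse_groups <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) return(list())
  lapply(strsplit(txt, ";", fixed = TRUE)[[1]],
         function(g) strsplit(g, "|", fixed = TRUE)[[1]])
}

#' Classify one attractor into a cell-type label
#'
#' Marker activity is evaluated on nodes that are ON in *every* state of the
#' attractor (and OFF in every state for required-off conditions); for fixed
#' points this is simply the state itself. Attractors whose marker nodes
#' oscillate match no rule and come back `"unclassified"`.
#'
#' @param attractor Either an attractor entry from an [enumerate_attractors()]
#'   result or a 0/1 state matrix/vector with named columns.
#' @param rules A `phenotype_rules` table (default: bundled).
#' @return A single label string; `"unclassified"` when no rule matches.
#' @export
classify_attractor <- function(attractor, rules = phenotype_rules()) {
  states <- if (is.list(attractor) && !is.null(attractor$states))
    attractor$states else attractor
  if (is.null(dim(states))) states <- matrix(states, nrow = 1,
                                             dimnames = list(NULL, names(states)))
  on_all <- colnames(states)[colSums(states) == nrow(states)]
  off_all <- colnames(states)[colSums(states) == 0L]
  for (i in seq_len(nrow(rules))) {
    ok <- TRUE
    for (grp in parse_groups(rules$required_on[i]))
      if (!any(grp %in% on_all)) { ok <- FALSE; break }
    if (ok)
      for (grp in parse_groups(rules$required_off[i]))
        if (!all(grp %in% off_all)) { ok <- FALSE; break }
    if (ok) return(rules$label[i])
  }
  "unclassified"
}

#' Classify every attractor of an attractor set
#'
#' @param attrs An `attractor_set`.
#' @param rules A `phenotype_rules` table.
#' @return Character vector of labels, one per attractor.
#' @export
classify_attractors <- function(attrs, rules = phenotype_rules()) {
  vapply(attrs$attractors, classify_attractor, character(1), rules = rules)
}
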