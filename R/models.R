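# Bundled CD4+ T-cell models.
#
# The rule files under inst/extdata encode a minimal transcriptional network
# (TRN, 5 master regulators, no inputs) and the 18-node transcriptional-
# signaling network (TSRN: 5 transcription factors, 7 intrinsic cytokine
# pathways, 6 extrinsic cytokine inputs). The truth tables are a
# reconstruction constrained by the published attractor repertoire, the
# micro-environment dependencies of Th17/iTreg/Th9, the SOCS-removal
# behaviour and the reported mutant phenotypes; see the methods vignette
# for the construction criteria. Files are checksum-guarded against drift.

MODEL_CHECKSUMS <- c(
  trn.bnet = "615f9779dcb5c1c418c0167f6280f0bd",
  tsrn.bnet = "6689e7257a47de28ac631632553c2b50",
  tsrn_socs_edges.csv = "ea427d6d4737886ac76fcb6784b4fa07",
  phenotype_rules.csv = "058213aad71ab74bb63d5366ee2fcb19"
)

model_file <- function(name) {
  path <- system.file("extdata", name, package = "cd4logic")
  if (path == "") abort2("bundled file '", name, "' not found")
  expected <- MODEL_CHECKSUMS[[name]]
  actual <- unname(tools::md5sum(path))
  if (!grepl("^@", expected) && !identical(actual, expected))
    abort2("checksum mismatch for bundled file '", name, "' (expected ",
           expected, ", got ", actual, "); refusing to load a modified model")
  path
}

#' Load a bundled CD4+ T-cell model variant
#'
#' @param variant One of `"TRN"` (5-node transcription-factor core),
#'   `"TSRN"` (18-node transcriptional-signaling network) or
#'   `"TSRN_noSOCS"` (TSRN with all SOCS-mediated inhibitions removed; always
#'   derived programmatically from the TSRN, never hand-edited).
#' @return A `logic_network` with categories, inputs and provenance metadata.
#' @export
load_model <- function(variant = c("TRN", "TSRN", "TSRN_noSOCS")) {
  variant <- match.arg(variant)
  if (variant == "TSRN_noSOCS")
    return(derive_socs_removed(load_model("TSRN")))
  file <- switch(variant, TRN = "trn.bnet", TSRN = "tsrn.bnet")
  net <- read_bnet(model_file(file))
  net$metadata$variant <- variant
  net
}

#' Read the annotated SOCS-mediated inhibition edges of the TSRN
#'
#' @return Data frame with columns `source`, `target`.
#' @export
socs_edges <- function() {
  utils::read.csv(model_file("tsrn_socs_edges.csv"),
                  stringsAsFactors = FALSE)
}

#' Remove an inhibitory regulator from one rule
#'
#' The regulator must act purely inhibitorily on the target (flipping it
#' from 0 to 1 never increases the rule's output); the literal is removed by
#' fixing the regulator at 0 and recomputing the truth table.
#'
#' @param net A `logic_network`.
#' @param source Inhibiting regulator to remove.
#' @param target Node whose rule loses the inhibition.
#' @return The modified network.
#' @export
remove_inhibition <- function(net, source, target) {
  if (!target %in% net$nodes) abort2("unknown target node '", target, "'")
  r <- net$rules[[target]]
  j <- match(source, r$regulators)
  if (is.na(j))
    abort2("annotated edge ", source, " -> ", target,
           " absent from the rule (annotation/rule file drift)")
  k <- length(r$regulators)
  codes <- 0:(2L^k - 1L)
  b <- bit_of(codes, j)
  f0 <- r$table[codes[b == 0L] + 1L]
  f1 <- r$table[codes[b == 1L] + 1L]
  if (any(f1 > f0))
    abort2("edge ", source, " -> ", target,
           " is not purely inhibitory; refusing to remove it")
  keep <- which(b == 0L)
  sub <- codes[keep]
  # drop bit j, repack remaining regulators
  low <- bitwAnd(sub, 2L^(j - 1L) - 1L)
  high <- bitwShiftR(bitwAnd(sub, bitwNot(2L^j - 1L)), 1L)
  newcode <- low + high
  newtab <- integer(2L^(k - 1L))
  newtab[newcode + 1L] <- r$table[sub + 1L]
  net$rules[[target]] <- logic_rule(target, r$regulators[-j], newtab)
  validate_logic_network(net)
}

#' Derive the SOCS-removed TSRN variant
#'
#' Deletes every annotated SOCS-mediated inhibition from the corresponding
#' rule; the node set is unchanged. With an empty edge table the network is
#' returned unmodified.
#'
#' @param tsrn The TSRN `logic_network`.
#' @param edges Data frame of `source`,`target` pairs; defaults to the
#'   bundled annotation file.
#' @return The derived `logic_network` (variant `TSRN_noSOCS`).
#' @export
derive_socs_removed <- function(tsrn, edges = socs_edges()) {
  net <- tsrn
  if (nrow(edges))
    for (i in seq_len(nrow(edges)))
      net <- remove_inhibition(net, edges$source[i], edges$target[i])
  net$metadata$variant <- "TSRN_noSOCS"
  net$metadata$derived_from <- "TSRN"
  net
}
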