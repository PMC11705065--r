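#' The published resistance lncRNA-mRNA pair table
#'
#' Loads the bundled table of reported cisplatin-resistance competing
#' interaction pairs in lung adenocarcinoma: co-expressed lncRNA-mRNA
#' pairs with their shared miRNAs (semicolon-joined) and the reported
#' purity-adjusted co-expression statistics. All molecules follow the
#' lncRNA-up/miRNA-down/mRNA-up resistance pattern.
#'
#' @param path optional path to a pair table TSV with columns
#'   `lncrna_id`, `mrna_id`, `shared_mirnas`, `pcc`, `p_value`; defaults
#'   to the bundled table.
#' @return data.frame of pairs.
#' @export
published_resistance_pairs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "resistance_pairs.tsv",
                        package = "ceRNAresist")
  }
  utils::read.delim(path, sep = "\t", colClasses = c(
    lncrna_id = "character", mrna_id = "character",
    shared_mirnas = "character", pcc = "numeric", p_value = "numeric"))
}

#' Reconstruct a ceRNA network from a reported pair table
#'
#' Rebuilds the triplet set and network that a co-expressed pair table
#' implies, running the same machinery as the full pipeline: the pairs'
#' miRNA wiring is expanded into active interactions, merged into
#' candidate triplets on shared miRNAs (the cross-product can exceed the
#' reported triplets), then filtered by the reported co-expression
#' statistics — pairs absent from the table carry no co-expression
#' evidence and drop — and assembled into the typed network. Directions
#' follow the lncRNA-up/miRNA-down/mRNA-up resistance pattern.
#'
#' @param pairs data.frame from [published_resistance_pairs()].
#' @param pcc_min,p_max co-expression thresholds (defaults 0.2, 0.05).
#' @return list with `dysregulated`, `active`, `candidate_triplets`,
#'   `triplets`, `network`.
#' @export
reconstruct_pair_network <- function(pairs = published_resistance_pairs(),
                                     pcc_min = 0.2, p_max = 0.05) {
  mir_lists <- strsplit(pairs$shared_mirnas, ";", fixed = TRUE)
  lnc <- unique(pairs$lncrna_id)
  mrna <- unique(pairs$mrna_id)
  mir <- unique(unlist(mir_lists))
  dys <- data.frame(
    molecule_id = c(lnc, mir, mrna),
    gene_class = c(rep("lncRNA", length(lnc)), rep("miRNA", length(mir)),
                   rep("mRNA", length(mrna))),
    direction = c(rep("up", length(lnc)), rep("down", length(mir)),
                  rep("up", length(mrna))))
  rows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    rbind(
      data.frame(mirna_id = mir_lists[[i]], target_id = pairs$lncrna_id[i],
                 target_class = "lncRNA", evidence_tag = "reported"),
      data.frame(mirna_id = mir_lists[[i]], target_id = pairs$mrna_id[i],
                 target_class = "mRNA", evidence_tag = "reported"))
  }))
  active <- filter_active_interactions(interaction_table(rows), dys)
  candidates <- assemble_triplets(active)
  pair_stats <- data.frame(lncrna_id = pairs$lncrna_id,
                           mrna_id = pairs$mrna_id, pcc = pairs$pcc,
                           p_value = pairs$p_value)
  triplets <- filter_coexpressed(candidates, pair_stats,
                                 pcc_min = pcc_min, p_max = p_max)
  list(dysregulated = dys, active = active,
       candidate_triplets = candidates, triplets = triplets,
       network = build_network(triplets, dys))
}
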