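#!/usr/bin/env Rscript
# Generates the full synthetic input bundle (paired resistant/sensitive
# cell-line profiles for three RNA classes, miRNA-target interaction
# tables, a purity-confounded tumor cohort with survival, a single-cell
# dataset with functional-state signatures, and a cell-line drug panel)
# and writes every input as the plain-text formats the pipeline reads.
# The planted truth: 10 competing triplets over 2 lncRNAs (up), 5 miRNAs
# (down) and 5 mRNAs (up), with 6 truly co-expressed lncRNA-mRNA pairs.

suppressPackageStartupMessages(library(ceRNAresist))

seed <- 1
out <- "results/synthetic_bundle"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- synthetic_truth(seed = seed)
bundle <- generate_input_bundle(truth)
message(sprintf("planted: %d triplets, %d co-expressed pairs (seed %d)",
                nrow(truth$planted_triplets),
                nrow(truth$coexpressed_pairs), seed))

# cell-line profiles: matrix + side-car annotations per class
for (cl in names(bundle$exprs)) {
  write_expression(
    bundle$exprs[[cl]],
    file.path(out, paste0("cellline_", cl, ".tsv")),
    sample_annotation_path = file.path(out, "cellline_samples.tsv"))
}

# interaction tables
write_interactions(bundle$interactions$mirna_lncrna,
                   file.path(out, "interactions_mirna_lncrna.tsv"))
write_interactions(bundle$interactions$mirna_mrna,
                   file.path(out, "interactions_mirna_mrna.tsv"))

# tumor cohort: expression matrix + gene classes + per-sample purity/survival
write_expression(bundle$cohort$expression,
                 file.path(out, "cohort_expression.tsv"),
                 gene_annotation_path = file.path(out, "cohort_genes.tsv"))
write.table(
  data.frame(sample_id = names(bundle$cohort$purity),
             purity = bundle$cohort$purity,
             survival_time = bundle$cohort$survival_time,
             event = bundle$cohort$event),
  file.path(out, "cohort_samples.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

# single-cell dataset + state signatures
write_expression(bundle$cells, file.path(out, "singlecell_expression.tsv"))
write_gmt(bundle$signatures, file.path(out, "state_signatures.gmt"))
write.table(
  data.frame(gene = names(attr(bundle$cells, "target_states")),
             state = attr(bundle$cells, "target_states")),
  file.path(out, "singlecell_target_states.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

# drug panel
write_expression(bundle$drug$panel, file.path(out, "panel_expression.tsv"))
write.table(as.data.frame(bundle$drug$ic50),
            file.path(out, "drug_ic50.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# the planted truth, for downstream recovery checks
write.table(truth$planted_triplets, file.path(out, "planted_triplets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote input bundle to ", out)
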