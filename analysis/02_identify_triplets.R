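#!/usr/bin/env Rscript
# Reads the synthetic input bundle back from disk and runs the triplet
# identification pipeline: per-pair moderated differential expression,
# direction-consistent intersection, the opposite-direction activity
# filter on the interaction tables, triplet assembly on shared miRNAs,
# and purity-adjusted co-expression filtering on the tumor cohort.
# Run analysis/01_simulate_inputs.R first.

suppressPackageStartupMessages(library(ceRNAresist))

inp <- "results/synthetic_bundle"
out <- "results"
stopifnot(dir.exists(inp))

exprs <- sapply(c("lncRNA", "miRNA", "mRNA"), function(cl)
  read_expression(file.path(inp, paste0("cellline_", cl, ".tsv")),
                  mode = "cellline", gene_class = cl,
                  sample_annotation = file.path(inp, "cellline_samples.tsv")),
  simplify = FALSE)
interactions <- list(
  mirna_lncrna = read_interactions(file.path(inp, "interactions_mirna_lncrna.tsv")),
  mirna_mrna = read_interactions(file.path(inp, "interactions_mirna_mrna.tsv")))
samples <- read.delim(file.path(inp, "cohort_samples.tsv"))
cohort <- tumor_cohort(
  read_expression(file.path(inp, "cohort_expression.tsv"), mode = "cohort",
                  gene_class = file.path(inp, "cohort_genes.tsv")),
  purity = setNames(samples$purity, samples$sample_id),
  survival_time = samples$survival_time, event = samples$event)

res <- run_pipeline(exprs, interactions, cohort)

message(sprintf(
  "dysregulated molecules: %d (%s)", nrow(res$dysregulated),
  paste(sprintf("%s=%d", names(table(res$dysregulated$gene_class)),
                table(res$dysregulated$gene_class)), collapse = ", ")))
message(sprintf(
  "active interactions: %d; candidate triplets: %d; retained: %d",
  nrow(res$active), nrow(res$candidate_triplets), nrow(res$triplets)))

planted <- read.delim(file.path(inp, "planted_triplets.tsv"))
rec <- triplet_recovery(res$triplets,
                        structure(list(planted_triplets = planted),
                                  class = "synthetic_truth"))
message(sprintf("recovery vs planted truth: precision %.2f, recall %.2f",
                rec$precision, rec$recall))

write.table(res$dysregulated, file.path(out, "dysregulated.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$triplets, file.path(out, "triplets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$pair_summary, file.path(out, "triplet_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote dysregulated.tsv, triplets.tsv, triplet_pairs.tsv to ", out)
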