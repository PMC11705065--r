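#!/usr/bin/env Rscript
# The three downstream validation analyses on the synthetic bundle:
# (1) single-cell functional-state scoring and Spearman correlation with
# the network's target mRNAs; (2) per-ceRNA-pair Cox risk scores with
# median-split Kaplan-Meier stratification and log-rank tests; (3) Pearson
# correlation of upstream lncRNA expression with drug IC50 across the
# cell-line panel. Run 01 and 02 first.

suppressPackageStartupMessages(library(ceRNAresist))

inp <- "results/synthetic_bundle"
out <- "results"
triplets <- read.delim(file.path(out, "triplets.tsv"))
pairs <- unique(triplets[, c("lncrna_id", "mrna_id")])
targets <- unique(triplets$mrna_id)
lncrnas <- unique(triplets$lncrna_id)

## single-cell functional states
cells <- read_expression(file.path(inp, "singlecell_expression.tsv"),
                         mode = "cohort")
signatures <- read_gmt(file.path(inp, "state_signatures.gmt"))
scores <- score_functional_states(cells, signatures)
states <- correlate_states(scores, cells, targets)
write.table(states, file.path(out, "state_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
truth_states <- read.delim(file.path(inp, "singlecell_target_states.tsv"))
hits <- merge(states[states$pass, ], truth_states,
              by.x = c("gene", "state"), by.y = c("gene", "state"))
message(sprintf(
  "state correlations: %d/%d gene-state pairs pass; %d of %d planted gene-state links recovered",
  sum(states$pass), nrow(states), nrow(hits),
  sum(truth_states$gene %in% targets)))

## survival stratification per ceRNA pair
samples <- read.delim(file.path(inp, "cohort_samples.tsv"))
cohort <- tumor_cohort(
  read_expression(file.path(inp, "cohort_expression.tsv"), mode = "cohort",
                  gene_class = file.path(inp, "cohort_genes.tsv")),
  purity = setNames(samples$purity, samples$sample_id),
  survival_time = samples$survival_time, event = samples$event)
surv <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
  mols <- c(pairs$lncrna_id[i], pairs$mrna_id[i])
  model <- fit_risk_model(cohort, mols)
  strat <- risk_stratify(model, cohort)
  data.frame(lncrna_id = mols[1], mrna_id = mols[2],
             beta_lncrna = model$beta[1], beta_mrna = model$beta[2],
             n_high = sum(strat$group == "high"),
             n_low = sum(strat$group == "low"),
             logrank_chisq = strat$logrank_chisq,
             logrank_p = strat$logrank_p)
}))
write.table(surv, file.path(out, "survival_stratification.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "survival: %d/%d ceRNA pairs stratify the cohort at log-rank p < 0.05",
  sum(surv$logrank_p < 0.05), nrow(surv)))

## drug activity correlation
panel <- read_expression(file.path(inp, "panel_expression.tsv"),
                         mode = "panel", gene_class = "lncRNA")
ic50 <- drug_activity_table(read.delim(file.path(inp, "drug_ic50.tsv")))
drug <- correlate_drug_activity(panel, ic50, lncrnas)
write.table(drug, file.path(out, "drug_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(drug))) {
  message(sprintf("  %s: r = %.2f, p = %.2e -> %s", drug$gene[i],
                  drug$r[i], drug$p_value[i], drug$direction_call[i]))
}
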