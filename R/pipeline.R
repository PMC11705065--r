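#' Default pipeline configuration
#'
#' All thresholds of the pipeline in one declarative list; the defaults
#' are the study regime (raw p < 0.05, fold change > 1.5 for lncRNA/mRNA,
#' partial correlation > 0.2, validation correlations > 0.3).
#'
#' @return nested named list of configuration keys.
#' @export
default_config <- function() {
  list(
    de = list(p_max = 0.05, fc_min = 1.5, method = "moderated",
              adjust_method = "none", allow_single_pair = FALSE),
    triplets = list(pcc_min = 0.2, p_max = 0.05, use_purity = TRUE),
    states = list(r_min = 0.3, p_max = 0.05),
    drug = list(r_min = 0.3, p_max = 0.05))
}

#' Validate a pipeline configuration
#'
#' @param config nested list as returned by [default_config()]; partial
#'   lists are completed with defaults.
#' @return the completed, validated configuration.
#' @export
validate_config <- function(config = list()) {
  def <- default_config()
  for (sec in names(def)) {
    if (is.null(config[[sec]])) config[[sec]] <- list()
    unknown <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(unknown)) {
      stop("unknown config key(s) in '", sec, "': ",
           paste(unknown, collapse = ", "))
    }
    config[[sec]] <- utils::modifyList(def[[sec]], config[[sec]])
  }
  unknown_sec <- setdiff(names(config), names(def))
  if (length(unknown_sec)) {
    stop("unknown config section(s): ", paste(unknown_sec, collapse = ", "))
  }
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || x < 0 || x > 1) stop(nm, " must lie in [0, 1]")
  }
  chk01(config$de$p_max, "de.p_max")
  chk01(config$triplets$p_max, "triplets.p_max")
  chk01(config$states$p_max, "states.p_max")
  chk01(config$drug$p_max, "drug.p_max")
  if (config$de$fc_min < 1) stop("de.fc_min must be >= 1 (ratio scale)")
  if (!is.numeric(config$triplets$pcc_min) ||
      config$triplets$pcc_min < -1 || config$triplets$pcc_min > 1) {
    stop("triplets.pcc_min must lie in [-1, 1]")
  }
  if (abs(config$states$r_min) > 1 || abs(config$drug$r_min) > 1) {
    stop("correlation thresholds must lie in [-1, 1]")
  }
  if (!config$de$method %in% c("moderated", "ordinary")) {
    stop("de.method must be 'moderated' or 'ordinary'")
  }
  config
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the keys in
#'   [default_config()]; missing keys take defaults.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  validate_config(yaml::read_yaml(path))
}

#' Run the triplet-identification pipeline end to end
#'
#' Executes, in order: per-pair moderated differential expression on each
#' gene-class matrix; threshold calling and direction-consistent
#' intersection across pairs; the opposite-direction activity filter on
#' the candidate interaction tables; triplet assembly on shared miRNAs;
#' purity-adjusted co-expression filtering on the tumor cohort; and
#' network construction. Downstream validation analyses
#' ([score_functional_states()], [fit_risk_model()],
#' [correlate_drug_activity()]) operate on the result separately.
#'
#' The run is fully deterministic given its inputs (no randomness is
#' consumed).
#'
#' @param exprs named list of cellline-mode [expr_matrix()] objects (any
#'   subset of classes; typically `lncRNA`, `miRNA`, `mRNA`).
#' @param interactions list with [interaction_table()]s `mirna_lncrna`
#'   and `mirna_mrna`.
#' @param cohort [tumor_cohort()] for co-expression filtering.
#' @param config configuration list (completed via [validate_config()]).
#' @return list with elements `per_pair_de`, `called`, `dysregulated`,
#'   `active`, `candidate_triplets`, `pair_stats`, `triplets`,
#'   `pair_summary`, `network`, `config`.
#' @export
run_pipeline <- function(exprs, interactions, cohort,
                         config = default_config()) {
  config <- validate_config(config)
  pairs <- unique(unlist(lapply(exprs, function(e) unique(e$pair_id))))

  per_pair_de <- list()
  called <- list()
  for (p in pairs) {
    recs <- do.call(rbind, lapply(exprs, fit_moderated_de, pair = p,
                                  method = config$de$method))
    rownames(recs) <- NULL
    per_pair_de[[p]] <- recs
    called[[p]] <- call_dysregulated(recs, p_max = config$de$p_max,
                                     fc_min = config$de$fc_min,
                                     adjust_method = config$de$adjust_method)
  }
  dys <- intersect_consistent(called,
                              allow_single_pair = config$de$allow_single_pair)

  candidates <- rbind(as.data.frame(interactions$mirna_lncrna),
                      as.data.frame(interactions$mirna_mrna))
  active <- filter_active_interactions(candidates, dys)
  candidate_triplets <- assemble_triplets(active)

  if (nrow(candidate_triplets)) {
    pair_stats <- pair_coexpression(candidate_triplets, cohort,
                                    use_purity = config$triplets$use_purity)
    triplets <- filter_coexpressed(candidate_triplets, pair_stats,
                                   pcc_min = config$triplets$pcc_min,
                                   p_max = config$triplets$p_max)
  } else {
    pair_stats <- data.frame(lncrna_id = character(0),
                             mrna_id = character(0), pcc = numeric(0),
                             p_value = numeric(0), n = integer(0))
    triplets <- cbind(candidate_triplets, pcc = numeric(0),
                      pcc_p = numeric(0))
  }
  network <- build_network(triplets, dys)

  list(per_pair_de = per_pair_de, called = called, dysregulated = dys,
       active = active, candidate_triplets = candidate_triplets,
       pair_stats = pair_stats, triplets = triplets,
       pair_summary = summarise_triplet_pairs(triplets),
       network = network, config = config)
}

#' Generate the complete synthetic input bundle
#'
#' Convenience wrapper producing every input [run_pipeline()] and the
#' downstream validations consume, from one [synthetic_truth()].
#'
#' @param truth [synthetic_truth()].
#' @param n_pairs,n_reps,n_genes_per_class,sigma passed to
#'   [generate_cellline_profiles()].
#' @param n_samples cohort size for [generate_tumor_cohort()].
#' @param n_cells cells for [generate_singlecell_dataset()].
#' @param n_lines cell lines for [generate_drug_activity()].
#' @param signatures functional-state signatures (default
#'   [synthetic_state_signatures()]).
#' @return list with `exprs`, `interactions`, `cohort`, `cells`,
#'   `signatures`, `drug`, and `truth`.
#' @export
generate_input_bundle <- function(truth, n_pairs = 2, n_reps = 3,
                                  n_genes_per_class = 50, sigma = 0.2,
                                  n_samples = 500, n_cells = 100,
                                  n_lines = 48,
                                  signatures = synthetic_state_signatures()) {
  list(
    exprs = generate_cellline_profiles(truth, n_pairs = n_pairs,
                                       n_reps = n_reps,
                                       n_genes_per_class = n_genes_per_class,
                                       sigma = sigma),
    interactions = generate_interaction_db(truth,
                                           n_genes_per_class = n_genes_per_class),
    cohort = generate_tumor_cohort(truth, n_samples = n_samples,
                                   n_genes_per_class = n_genes_per_class),
    cells = generate_singlecell_dataset(truth, n_cells = n_cells,
                                        signatures = signatures),
    signatures = signatures,
    drug = generate_drug_activity(truth, n_lines = n_lines,
                                  n_genes_per_class = n_genes_per_class),
    truth = truth)
}

#' Precision and recall of recovered triplets against planted truth
#'
#' @param recovered data.frame with `lncrna_id`, `mirna_id`, `mrna_id`.
#' @param truth [synthetic_truth()].
#' @return list with `precision`, `recall`, `n_recovered`, `n_planted`.
#' @export
triplet_recovery <- function(recovered, truth) {
  key <- function(d) paste(d$lncrna_id, d$mirna_id, d$mrna_id)
  rec <- unique(key(recovered))
  pl <- unique(key(truth$planted_triplets))
  tp <- length(intersect(rec, pl))
  list(precision = if (length(rec)) tp / length(rec) else NA_real_,
       recall = tp / length(pl),
       n_recovered = length(rec), n_planted = length(pl))
}
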