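#' Ground truth for a synthetic study
#'
#' Fixes the planted biology every generator draws from: a wiring of
#' competing triplets with the lncRNA-up/miRNA-down/mRNA-up pattern, the
#' set of truly co-expressed lncRNA-mRNA pairs, effect sizes, cohort
#' co-expression and purity-confounding strengths, survival effects, and
#' the IC50 slope. The default wiring has 10 triplets over 2 lncRNAs,
#' 5 miRNAs and 5 mRNAs, with 6 co-expressed pairs — the same topology
#' shape a small published resistance ceRNA network exhibits — so the
#' whole pipeline can be exercised at desk scale.
#'
#' The wiring's candidate cross-product (merging on shared miRNAs)
#' contains 12 triplets; two of them pair a lncRNA and mRNA that are NOT
#' co-expressed in truth, and must be removed by the co-expression filter.
#' `planted_triplets` holds the 10 true triplets;
#' `candidate_triplets()` of the wiring yields the 12.
#'
#' All generators derive their RNG stream from `seed` plus a fixed
#' per-generator offset (R's default Mersenne-Twister), so a seed fully
#' determines every output.
#'
#' @param seed integer master seed.
#' @param effect_size_log2fc log2 fold change planted in resistant
#'   cell-line samples (default 1.5).
#' @param cohort_coexpr_strength shared-signal variance fraction for
#'   co-expressed pairs in the tumor cohort; approximately the planted
#'   purity-adjusted partial correlation (default 0.6).
#' @param purity_confounding_strength loading of standardized tumor
#'   purity on every gene (default 0.8); inflates naive Pearson
#'   correlation between otherwise independent genes.
#' @param survival_beta either a single log-hazard-ratio applied to every
#'   planted lncRNA and mRNA, or a named vector per molecule (default
#'   0.4; 0 gives a survival null).
#' @param ic50_slope slope tying IC50 to the planted lncRNAs' shared
#'   resistance factor (default 1; 0 gives a drug-activity null).
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed = 1,
                            effect_size_log2fc = 1.5,
                            cohort_coexpr_strength = 0.6,
                            purity_confounding_strength = 0.8,
                            survival_beta = 0.4,
                            ic50_slope = 1) {
  lnc <- c("LNC01", "LNC02")
  mir <- sprintf("MIR%02d", 1:5)
  mrna <- sprintf("MRNA%02d", 1:5)
  triplets <- data.frame(
    lncrna_id = lnc[c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2)],
    mirna_id  = mir[c(1, 2, 2, 3, 4, 5, 4, 5, 4, 5)],
    mrna_id   = mrna[c(1, 2, 3, 3, 4, 4, 4, 4, 5, 5)])
  pairs <- unique(triplets[, c("lncrna_id", "mrna_id")])
  rownames(pairs) <- NULL
  directions <- c(stats::setNames(rep("up", 2), lnc),
                  stats::setNames(rep("down", 5), mir),
                  stats::setNames(rep("up", 5), mrna))
  if (length(survival_beta) == 1L && is.null(names(survival_beta))) {
    survival_beta <- stats::setNames(rep(survival_beta, 7), c(lnc, mrna))
  }
  structure(list(
    seed = as.integer(seed),
    planted_lncrnas = lnc, planted_mirnas = mir, planted_mrnas = mrna,
    planted_triplets = triplets,
    coexpressed_pairs = pairs,
    planted_directions = directions,
    effect_size_log2fc = effect_size_log2fc,
    cohort_coexpr_strength = cohort_coexpr_strength,
    purity_confounding_strength = purity_confounding_strength,
    survival_beta = survival_beta,
    ic50_slope = ic50_slope),
    class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> seed %d: %d planted triplets (%d lncRNA / %d miRNA / %d mRNA), effect %.2f log2\n",
    x$seed, nrow(x$planted_triplets), length(x$planted_lncrnas),
    length(x$planted_mirnas), length(x$planted_mrnas),
    x$effect_size_log2fc))
  invisible(x)
}

synthetic_gene_ids <- function(truth, n_genes_per_class) {
  pad <- function(prefix, planted, n) {
    if (n < length(planted)) stop("n_genes_per_class below planted count")
    c(planted, sprintf("%s%02d", prefix, seq_len(n - length(planted)) +
                         length(planted)))
  }
  list(lncRNA = pad("LNC", truth$planted_lncrnas, n_genes_per_class),
       miRNA = pad("MIR", truth$planted_mirnas, n_genes_per_class),
       mRNA = pad("MRNA", truth$planted_mrnas, n_genes_per_class))
}

# per-generator seed offsets (documented RNG stream discipline)
.seed_offsets <- c(cellline = 101L, interactions = 202L, cohort = 303L,
                   singlecell = 404L, drug = 505L)

with_stream <- function(truth, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(truth$seed + .seed_offsets[[stream]])
  expr
}

#' Generate paired resistant/sensitive cell-line expression profiles
#'
#' One matrix per gene class. Baseline per-gene means are drawn from
#' Uniform(4, 10) (log2 scale) with Gaussian noise `sigma` per sample.
#' Planted molecules are shifted by the effect size in resistant samples
#' of ALL pairs, in their planted direction (lncRNA/mRNA up, miRNA down).
#' A stated number of decoys per class are shifted inconsistently — in one
#' pair only, or in opposite directions across pairs — so the
#' direction-consistency filter must remove them.
#'
#' @param truth [synthetic_truth()].
#' @param n_pairs number of cell-line pairs (>= 2; default 2).
#' @param n_reps replicates per condition per pair (>= 2; default 3).
#' @param n_genes_per_class genes per class including planted (default 50).
#' @param sigma per-sample Gaussian noise sd (default 0.2); 0 recovers
#'   planted log2 fold changes exactly.
#' @param n_inconsistent_decoys inconsistently shifted decoys per class
#'   (default 6: half single-pair, half opposite-direction).
#' @return named list of three cellline-mode [expr_matrix()] objects
#'   (`lncRNA`, `miRNA`, `mRNA`), with attribute `inconsistent_decoys`.
#' @export
generate_cellline_profiles <- function(truth, n_pairs = 2, n_reps = 3,
                                       n_genes_per_class = 50, sigma = 0.2,
                                       n_inconsistent_decoys = 6) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_reps < 2) stop("n_reps must be >= 2 (variance undefined otherwise)")
  if (n_pairs < 2) stop("n_pairs must be >= 2 (consistency filter needs >= 2 pairs)")
  ids <- synthetic_gene_ids(truth, n_genes_per_class)
  pair_ids <- sprintf("PAIR%d", seq_len(n_pairs))
  cond <- rep(rep(c("resistant", "sensitive"), each = n_reps), n_pairs)
  pair <- rep(pair_ids, each = 2 * n_reps)
  sample_ids <- sprintf("%s_%s_%d", pair, substr(cond, 1, 3),
                        rep(seq_len(n_reps), 2 * n_pairs))
  ns <- length(sample_ids)

  with_stream(truth, "cellline", {
    out <- list()
    decoy_info <- list()
    for (cl in c("lncRNA", "miRNA", "mRNA")) {
      g <- ids[[cl]]
      planted <- intersect(g, names(truth$planted_directions))
      decoys <- setdiff(g, planted)
      mu <- stats::runif(length(g), 4, 10)
      v <- matrix(stats::rnorm(length(g) * ns, sd = sigma), nrow = length(g)) + mu
      dimnames(v) <- list(g, sample_ids)
      res <- cond == "resistant"
      for (p in planted) {
        shift <- ifelse(truth$planted_directions[[p]] == "up", 1, -1) *
          truth$effect_size_log2fc
        v[p, res] <- v[p, res] + shift
      }
      n_inc <- min(n_inconsistent_decoys, length(decoys))
      inc <- decoys[seq_len(n_inc)]
      half <- ceiling(n_inc / 2)
      single_pair <- inc[seq_len(half)]
      opposite <- setdiff(inc, single_pair)
      for (d in single_pair) {  # shifted in the first pair only
        sel <- res & pair == pair_ids[1L]
        v[d, sel] <- v[d, sel] + truth$effect_size_log2fc
      }
      for (d in opposite) {     # up in the first pair, down in the rest
        sel1 <- res & pair == pair_ids[1L]
        sel2 <- res & pair != pair_ids[1L]
        v[d, sel1] <- v[d, sel1] + truth$effect_size_log2fc
        v[d, sel2] <- v[d, sel2] - truth$effect_size_log2fc
      }
      decoy_info[[cl]] <- list(single_pair = single_pair,
                               opposite = opposite)
      out[[cl]] <- expr_matrix(v, cl, mode = "cellline",
                               sample_condition = cond, pair_id = pair)
    }
    attr(out, "inconsistent_decoys") <- decoy_info
    out
  })
}

#' Generate synthetic miRNA-target interaction tables
#'
#' Contains every edge implied by the planted triplet wiring plus
#' `n_decoy_edges` random edges with at least one non-planted endpoint
#' (so decoys can never duplicate planted wiring and are guaranteed to be
#' removed by the dysregulated-membership rule).
#'
#' @param truth [synthetic_truth()].
#' @param n_decoy_edges decoy edges per table (default 30).
#' @param n_genes_per_class decoy molecule universe size per class,
#'   matching [generate_cellline_profiles()] (default 50).
#' @return list of two [interaction_table()]s: `mirna_lncrna`,
#'   `mirna_mrna`.
#' @export
generate_interaction_db <- function(truth, n_decoy_edges = 30,
                                    n_genes_per_class = 50) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ids <- synthetic_gene_ids(truth, n_genes_per_class)
  planted_ml <- unique(truth$planted_triplets[, c("mirna_id", "lncrna_id")])
  planted_mm <- unique(truth$planted_triplets[, c("mirna_id", "mrna_id")])

  with_stream(truth, "interactions", {
    decoy_edges <- function(target_pool, planted_targets, n) {
      if (n == 0L) {
        return(data.frame(mirna_id = character(0), target_id = character(0)))
      }
      decoy_mirnas <- setdiff(ids$miRNA, truth$planted_mirnas)
      decoy_targets <- setdiff(target_pool, planted_targets)
      # one endpoint is always non-planted
      kind <- sample(c("dm", "dt"), n, replace = TRUE)
      data.frame(
        mirna_id = ifelse(kind == "dm",
                          sample(decoy_mirnas, n, replace = TRUE),
                          sample(ids$miRNA, n, replace = TRUE)),
        target_id = ifelse(kind == "dm",
                           sample(target_pool, n, replace = TRUE),
                           sample(decoy_targets, n, replace = TRUE)))
    }
    make <- function(planted, pool, planted_targets, class) {
      dec <- decoy_edges(pool, planted_targets, n_decoy_edges)
      df <- rbind(
        data.frame(mirna_id = planted[[1L]], target_id = planted[[2L]],
                   evidence_tag = "planted"),
        if (nrow(dec)) data.frame(mirna_id = dec$mirna_id,
                                  target_id = dec$target_id,
                                  evidence_tag = "decoy"))
      df$target_class <- class
      interaction_table(df)
    }
    list(
      mirna_lncrna = make(planted_ml, ids$lncRNA, truth$planted_lncrnas,
                          "lncRNA"),
      mirna_mrna = make(planted_mm, ids$mRNA, truth$planted_mrnas, "mRNA"))
  })
}

#' Generate a purity-confounded synthetic tumor cohort
#'
#' Emulates the statistical structure of a bulk tumor cohort: per-sample
#' tumor purity from Beta(5, 2), a shared latent factor per planted
#' lncRNA driving the expression of that lncRNA and of its truly
#' co-expressed mRNA partners, and a purity component loaded on EVERY
#' gene. Non-co-expressed pairs therefore share only the purity component:
#' their naive Pearson correlation is inflated while their purity-adjusted
#' partial correlation is near zero. With
#' `purity_confounding_strength = 0` the partial correlation reduces to
#' plain Pearson. The planted partial correlation of a co-expressed pair
#' is approximately `cohort_coexpr_strength` (a pair whose mRNA is shared
#' between two lncRNAs loads on both factors and correlates with each at
#' strength/sqrt(2)).
#'
#' Survival times are exponential with hazard proportional to
#' exp(sum of survival_beta * centered expression), with independent
#' exponential censoring targeting `censoring_frac`.
#'
#' @param truth [synthetic_truth()].
#' @param n_samples cohort size (>= 30; default 500).
#' @param n_genes_per_class lncRNA/mRNA universe size (default 50).
#' @param censoring_frac target censoring fraction (default 0.4).
#' @return [tumor_cohort()] (expression over lncRNA + mRNA classes).
#' @export
generate_tumor_cohort <- function(truth, n_samples = 500,
                                  n_genes_per_class = 50,
                                  censoring_frac = 0.4) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_samples < 30) stop("n_samples must be >= 30")
  ids <- synthetic_gene_ids(truth, n_genes_per_class)
  genes <- c(ids$lncRNA, ids$mRNA)
  gene_class <- rep(c("lncRNA", "mRNA"), each = n_genes_per_class)
  cc <- truth$cohort_coexpr_strength
  q <- truth$purity_confounding_strength

  with_stream(truth, "cohort", {
    purity <- stats::rbeta(n_samples, 5, 2)
    z <- as.numeric(scale(purity))
    factors <- matrix(stats::rnorm(n_samples * length(truth$planted_lncrnas)),
                      nrow = n_samples,
                      dimnames = list(NULL, truth$planted_lncrnas))
    signal <- matrix(0, nrow = length(genes), ncol = n_samples,
                     dimnames = list(genes, NULL))
    for (g in genes) {
      if (g %in% truth$planted_lncrnas) {
        shared <- sqrt(cc) * factors[, g]
      } else {
        partners <- truth$coexpressed_pairs$lncrna_id[
          truth$coexpressed_pairs$mrna_id == g]
        shared <- if (length(partners)) {
          sqrt(cc / length(partners)) *
            rowSums(factors[, partners, drop = FALSE])
        } else 0
      }
      signal[g, ] <- shared + q * z +
        sqrt(1 - cc * (g %in% unlist(truth$coexpressed_pairs) ||
                         g %in% truth$planted_lncrnas)) *
          stats::rnorm(n_samples)
    }
    values <- signal + 6  # shift to a log2-expression-like location
    sample_ids <- sprintf("S%04d", seq_len(n_samples))
    colnames(values) <- sample_ids
    em <- expr_matrix(values, gene_class, mode = "cohort")

    beta <- truth$survival_beta[names(truth$survival_beta) %in% genes]
    lp <- if (length(beta)) {
      colSums((values[names(beta), , drop = FALSE] - 6) * beta)
    } else rep(0, n_samples)
    base_rate <- 0.01
    t_event <- stats::rexp(n_samples, rate = base_rate * exp(lp))
    cens_rate <- base_rate * mean(exp(lp)) *
      censoring_frac / max(1 - censoring_frac, 1e-6)
    t_cens <- stats::rexp(n_samples, rate = cens_rate)
    tumor_cohort(em, purity = stats::setNames(purity, sample_ids),
                 survival_time = pmin(t_event, t_cens),
                 event = as.numeric(t_event <= t_cens))
  })
}

#' Generate a synthetic single-cell dataset tied to functional states
#'
#' Each functional state gets a per-cell latent activity; the state's
#' signature genes and any mRNAs designated as targets of that state are
#' driven by the same activity. With `driving_correlation = 1` and
#' `noise_sd = 0`, a target mRNA's expression is a monotone function of
#' the state activity, so its Spearman correlation with the state score
#' approaches 1; with `driving_correlation = 0` targets are independent
#' of the states.
#'
#' @param truth [synthetic_truth()].
#' @param n_cells number of cells (default 100).
#' @param signatures named list of gene sets; see
#'   [synthetic_state_signatures()] for a convenient default.
#' @param driving_correlation correlation tying each target mRNA to its
#'   assigned state activity (default 0.7).
#' @param noise_sd Gaussian noise sd on signature-gene expression
#'   (default 0.5).
#' @param target_genes mRNAs to tie to states (default the planted
#'   mRNAs), assigned to states in round-robin order.
#' @param genes optional explicit gene universe; every signature gene
#'   must be present in it (error lists missing genes). Defaults to the
#'   union of signature genes, target genes, and 50 background genes.
#' @param n_background background genes when `genes` is NULL.
#' @return cohort-mode [expr_matrix()] with attributes `state_activity`
#'   (states x cells) and `target_states` (named character).
#' @export
generate_singlecell_dataset <- function(truth, n_cells = 100, signatures,
                                        driving_correlation = 0.7,
                                        noise_sd = 0.5,
                                        target_genes = truth$planted_mrnas,
                                        genes = NULL, n_background = 50) {
  stopifnot(inherits(truth, "synthetic_truth"))
  sig_genes <- unique(unlist(signatures))
  if (is.null(genes)) {
    genes <- unique(c(sig_genes, target_genes,
                      sprintf("BG%03d", seq_len(n_background))))
  } else {
    missing_g <- setdiff(sig_genes, genes)
    if (length(missing_g)) {
      stop("signature genes absent from gene universe: ",
           paste(missing_g, collapse = ", "))
    }
  }
  states <- names(signatures)
  target_states <- stats::setNames(
    states[(seq_along(target_genes) - 1L) %% length(states) + 1L],
    target_genes)

  with_stream(truth, "singlecell", {
    activity <- matrix(stats::rnorm(length(states) * n_cells),
                       nrow = length(states),
                       dimnames = list(states,
                                       sprintf("CELL%04d", seq_len(n_cells))))
    v <- matrix(0, nrow = length(genes), ncol = n_cells,
                dimnames = list(genes, colnames(activity)))
    base <- stats::setNames(stats::runif(length(genes), 2, 8), genes)
    v[] <- base  # constant per-gene baseline across cells
    for (s in states) {
      gs <- intersect(signatures[[s]], genes)
      v[gs, ] <- v[gs, , drop = FALSE] +
        matrix(rep(activity[s, ], each = length(gs)), nrow = length(gs)) +
        matrix(stats::rnorm(length(gs) * n_cells, sd = noise_sd),
               nrow = length(gs))
    }
    rho <- driving_correlation
    for (g in target_genes) {
      a <- activity[target_states[[g]], ]
      v[g, ] <- base[[g]] + rho * a +
        sqrt(max(0, 1 - rho^2)) * stats::rnorm(n_cells) +
        stats::rnorm(n_cells, sd = noise_sd)
    }
    bg <- setdiff(genes, c(sig_genes, target_genes))
    if (length(bg) && noise_sd > 0) {
      v[bg, ] <- v[bg, , drop = FALSE] +
        matrix(stats::rnorm(length(bg) * n_cells, sd = noise_sd),
               nrow = length(bg))
    }
    em <- expr_matrix(v, "mRNA", mode = "cohort")
    attr(em, "state_activity") <- activity
    attr(em, "target_states") <- target_states
    em
  })
}

#' Default synthetic functional-state signatures
#'
#' @param n_states number of states (default 14, the usual functional
#'   state atlas size).
#' @param genes_per_state signature size (default 20).
#' @return named list of disjoint gene sets (`STATE01`...).
#' @export
synthetic_state_signatures <- function(n_states = 14, genes_per_state = 20) {
  sets <- lapply(seq_len(n_states), function(i)
    sprintf("SIG%02d_%03d", i, seq_len(genes_per_state)))
  names(sets) <- sprintf("STATE%02d", seq_len(n_states))
  sets
}

#' Generate a synthetic cell-line panel with drug IC50 values
#'
#' The planted lncRNAs share a latent per-line resistance factor; their
#' expression is the factor plus noise, and IC50 is
#' `intercept + ic50_slope * factor + noise`. With both noise terms at 0
#' and a positive slope, each planted lncRNA's expression correlates
#' perfectly with IC50; with `ic50_slope = 0` the IC50 is independent of
#' expression (a null panel). Decoy lncRNAs are independent noise.
#'
#' @param truth [synthetic_truth()].
#' @param n_lines number of cell lines (default 48).
#' @param n_genes_per_class lncRNA universe size (default 50).
#' @param expr_noise_sd per-gene expression noise sd (default 0.5).
#' @param ic50_noise_sd IC50 noise sd (default 0.5).
#' @param intercept IC50 intercept on the natural-log scale (default 2).
#' @return list with `ic50` ([drug_activity_table()]) and `panel`
#'   (panel-mode [expr_matrix()] of lncRNAs).
#' @export
generate_drug_activity <- function(truth, n_lines = 48,
                                   n_genes_per_class = 50,
                                   expr_noise_sd = 0.5, ic50_noise_sd = 0.5,
                                   intercept = 2) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ids <- synthetic_gene_ids(truth, n_genes_per_class)$lncRNA
  with_stream(truth, "drug", {
    lines <- sprintf("LINE%02d", seq_len(n_lines))
    fac <- stats::rnorm(n_lines)
    v <- matrix(stats::rnorm(length(ids) * n_lines, mean = 6,
                             sd = max(expr_noise_sd, 1e-12)),
                nrow = length(ids), dimnames = list(ids, lines))
    for (g in truth$planted_lncrnas) {
      v[g, ] <- 6 + fac + stats::rnorm(n_lines, sd = expr_noise_sd)
    }
    ic50 <- intercept + truth$ic50_slope * fac +
      stats::rnorm(n_lines, sd = ic50_noise_sd)
    list(
      ic50 = drug_activity_table(
        data.frame(cell_line_id = lines, ic50 = ic50)),
      panel = expr_matrix(v, "lncRNA", mode = "panel"))
  })
}
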