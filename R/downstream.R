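#' Validate a per-cell-line drug activity table
#'
#' IC50 values are used on the scale provided by the source (GDSC
#' distributes natural-log IC50); no re-transformation is applied. Higher
#' IC50 means lower drug sensitivity (more resistant).
#'
#' @param df data.frame with columns `cell_line_id`, `ic50`.
#' @return validated data.frame with class `drug_activity_table`.
#' @export
drug_activity_table <- function(df) {
  if (!all(c("cell_line_id", "ic50") %in% names(df))) {
    stop("need columns cell_line_id, ic50")
  }
  df <- as.data.frame(df)[, c("cell_line_id", "ic50")]
  df$cell_line_id <- as.character(df$cell_line_id)
  df$ic50 <- as.numeric(df$ic50)
  if (anyDuplicated(df$cell_line_id)) stop("duplicate cell_line_ids")
  if (!all(is.finite(df$ic50))) stop("ic50 must be finite")
  rownames(df) <- NULL
  class(df) <- c("drug_activity_table", "data.frame")
  df
}

ssgsea_cell <- function(vals, in_sig, alpha) {
  # tie convention: a cell with zero expression variance scores 0
  if (length(unique(vals)) == 1L) return(0)
  n <- length(vals)
  r <- rank(vals, ties.method = "average")
  ord <- order(vals, decreasing = TRUE)
  in_ord <- in_sig[ord]
  w <- r[ord]^alpha
  step_in <- w * in_ord / sum(w[in_ord])
  step_out <- (!in_ord) / (n - sum(in_sig))
  running <- cumsum(step_in - step_out)
  sum(running) / n
}

#' Rank-based single-sample functional-state scores
#'
#' Scores each signature (functional state) in each cell with a
#' single-sample enrichment statistic: genes are ranked by expression
#' within the cell, and the score is the normalized integral of the
#' weighted Kolmogorov-Smirnov running sum of the signature versus its
#' complement (signature genes step up proportionally to rank^alpha,
#' others step down uniformly). Using ranks only makes the score invariant
#' to any monotone transform of a cell's expression values. This is a
#' ssGSEA-style statistic, not a reimplementation of GSVA's kernel-density
#' scoring; the two agree qualitatively but not numerically.
#'
#' @param cells [expr_matrix()] (genes x cells).
#' @param signatures named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param alpha rank-weighting exponent (default 0.25).
#' @param standardize z-score each state's scores across cells so states
#'   are comparable (default `TRUE`).
#' @param min_frac warn when less than this fraction of a signature's
#'   genes is present (default 0.5).
#' @return numeric matrix, states x cells.
#' @export
score_functional_states <- function(cells, signatures, alpha = 0.25,
                                    standardize = TRUE, min_frac = 0.5) {
  stopifnot(inherits(cells, "expr_matrix"))
  v <- cells$values
  scores <- matrix(NA_real_, nrow = length(signatures), ncol = ncol(v),
                   dimnames = list(names(signatures), colnames(v)))
  for (nm in names(signatures)) {
    present <- intersect(signatures[[nm]], rownames(v))
    if (length(present) < 2L) {
      stop(sprintf("signature '%s' has fewer than 2 genes in the matrix", nm))
    }
    if (length(present) < min_frac * length(signatures[[nm]])) {
      warning(sprintf("signature '%s': only %d/%d genes present", nm,
                      length(present), length(signatures[[nm]])))
    }
    in_sig <- rownames(v) %in% present
    scores[nm, ] <- apply(v, 2L, ssgsea_cell, in_sig = in_sig,
                          alpha = alpha)
  }
  if (standardize) {
    sds <- apply(scores, 1L, stats::sd)
    sds[sds == 0] <- 1
    scores <- (scores - rowMeans(scores)) / sds
  }
  scores
}

#' Spearman correlation between gene expression and functional-state scores
#'
#' For each (gene, state) combination, the Spearman rank correlation with
#' a two-sided p-value; a combination passes when rho > `r_min` and
#' p < `p_max` (one-sided positive rule). Constant vectors yield an
#' undefined result, flagged and excluded from cross-dataset averages.
#'
#' @param scores states x cells matrix from [score_functional_states()].
#' @param cells [expr_matrix()] the scores were computed from.
#' @param targets gene ids to correlate (e.g. the network's target mRNAs).
#' @param r_min,p_max pass thresholds (defaults 0.3 and 0.05).
#' @return data.frame with `gene`, `state`, `rho`, `p_value`, `pass`,
#'   `defined`.
#' @export
correlate_states <- function(scores, cells, targets, r_min = 0.3,
                             p_max = 0.05) {
  if (ncol(scores) < 10L) stop("need >= 10 cells")
  v <- cells$values
  missing_g <- setdiff(targets, rownames(v))
  if (length(missing_g)) {
    stop("target genes absent from matrix: ",
         paste(missing_g, collapse = ", "))
  }
  grid <- expand.grid(gene = targets, state = rownames(scores),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- v[grid$gene[i], ]
    y <- scores[grid$state[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(rho = NA_real_, p_value = NA_real_,
                        pass = FALSE, defined = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate)
    data.frame(rho = rho, p_value = ct$p.value,
               pass = rho > r_min & ct$p.value < p_max, defined = TRUE)
  })
  out <- cbind(grid, do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Average state correlations across single-cell datasets
#'
#' Reports the mean Spearman rho per (gene, state) across datasets,
#' computed over datasets where the correlation is defined; per-dataset
#' p-values are not combined.
#'
#' @param results list of data.frames from [correlate_states()].
#' @return data.frame with `gene`, `state`, `mean_rho`, `n_datasets`.
#' @export
average_state_correlations <- function(results) {
  all <- do.call(rbind, results)
  all <- all[all$defined, , drop = FALSE]
  key <- paste(all$gene, all$state, sep = "\r")
  agg <- stats::aggregate(all$rho, by = list(key = key), FUN = mean)
  cnt <- stats::aggregate(all$rho, by = list(key = key), FUN = length)
  parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  data.frame(gene = parts[, 1L], state = parts[, 2L],
             mean_rho = agg$x, n_datasets = cnt$x)
}

#' Univariate Cox regression coefficient for one molecule
#'
#' Fits a proportional-hazards model of overall survival on a single
#' expression covariate, maximizing the partial likelihood with Efron tie
#' handling.
#'
#' @param expr numeric expression vector.
#' @param time positive survival times.
#' @param event 0/1 event indicators (1 = death observed).
#' @return list with `beta`, `se`, `p_value`, `n`, `n_events`.
#' @export
fit_cox_beta <- function(expr, time, event) {
  ok <- !is.na(expr) & !is.na(time) & !is.na(event)
  expr <- expr[ok]; time <- time[ok]; event <- event[ok]
  if (length(expr) < 10L) stop("need >= 10 samples with survival data")
  if (sum(event) == 0L) stop("no events observed")
  if (sum(event) < 3L) stop("need >= 3 events")
  fit <- survival::coxph(
    survival::Surv(time, event) ~ expr, ties = "efron",
    control = survival::coxph.control(eps = 1e-9, iter.max = 50))
  beta <- unname(stats::coef(fit))
  if (!is.finite(beta)) stop("Cox fit did not converge (beta not finite)")
  se <- sqrt(unname(stats::vcov(fit)[1L, 1L]))
  list(beta = beta, se = se,
       p_value = unname(summary(fit)$coefficients[1L, "Pr(>|z|)"]),
       n = length(expr), n_events = sum(event))
}

#' Fit a ceRNA-interaction risk model on a tumor cohort
#'
#' One univariate Cox coefficient per molecule; the per-sample risk score
#' is the linear combination of the molecules' expression values weighted
#' by those coefficients, score_s = sum_i beta_i * expr_{i,s}.
#'
#' @param cohort [tumor_cohort()] with survival data.
#' @param molecules gene ids entering the score (e.g. the lncRNA and mRNA
#'   of a ceRNA pair, or all molecules of an interaction).
#' @return object of class `risk_model`: list with `molecules`, `beta`
#'   (named), and per-molecule `se`, `p_value`.
#' @export
fit_risk_model <- function(cohort, molecules) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  if (is.null(cohort$survival_time)) stop("cohort lacks survival data")
  v <- cohort$expression$values
  missing_g <- setdiff(molecules, rownames(v))
  if (length(missing_g)) {
    stop("molecules absent from cohort: ", paste(missing_g, collapse = ", "))
  }
  fits <- lapply(molecules, function(g)
    fit_cox_beta(v[g, ], cohort$survival_time, cohort$event))
  structure(list(
    molecules = molecules,
    beta = stats::setNames(vapply(fits, `[[`, 0, "beta"), molecules),
    se = stats::setNames(vapply(fits, `[[`, 0, "se"), molecules),
    p_value = stats::setNames(vapply(fits, `[[`, 0, "p_value"), molecules)),
    class = "risk_model")
}

#' Per-sample risk scores under a risk model
#'
#' @param model [fit_risk_model()] result (or a list with named `beta`).
#' @param cohort [tumor_cohort()].
#' @return named numeric vector of scores per sample.
#' @export
risk_scores <- function(model, cohort) {
  v <- cohort$expression$values[names(model$beta), , drop = FALSE]
  colSums(v * model$beta)
}

#' Median-split risk stratification with Kaplan-Meier and log-rank test
#'
#' Samples without survival data are excluded. The median risk score over
#' the remaining samples is the cut-off: scores strictly above the median
#' form the high-risk group; scores at or below it (including median ties)
#' form the low-risk group. Survival curves come from the Kaplan-Meier
#' estimator and the two groups are compared with the log-rank test
#' (chi-square on 1 df).
#'
#' @param model [fit_risk_model()] result.
#' @param cohort [tumor_cohort()] with survival data.
#' @return list with `group` (named factor `"high"`/`"low"`), `score`,
#'   `cutoff`, `km` ([survival::survfit()] object), `logrank_chisq`,
#'   `logrank_p`.
#' @export
risk_stratify <- function(model, cohort) {
  if (is.null(cohort$survival_time)) stop("cohort lacks survival data")
  score <- risk_scores(model, cohort)
  ok <- !is.na(cohort$survival_time) & !is.na(cohort$event)
  score <- score[ok]
  time <- cohort$survival_time[ok]
  event <- cohort$event[ok]
  if (length(unique(score)) == 1L) stop("degenerate stratification: all risk scores identical")
  cutoff <- stats::median(score)
  group <- factor(ifelse(score > cutoff, "high", "low"),
                  levels = c("low", "high"))
  if (nlevels(droplevels(group)) < 2L) {
    stop("degenerate stratification: median split produced one group")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  km <- survival::survfit(survival::Surv(time, event) ~ group)
  list(group = stats::setNames(group, names(score)), score = score,
       cutoff = cutoff, km = km, logrank_chisq = unname(sd$chisq),
       logrank_p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Correlate lncRNA expression with drug IC50 across a cell-line panel
#'
#' Pearson correlation between each lncRNA's expression and IC50 over the
#' cell lines shared by both tables. A positive correlation passing the
#' thresholds (r > `r_min`, p < `p_max`) is labelled
#' `"resistance-associated"` (high expression, high IC50, low
#' sensitivity); a symmetric negative result is labelled
#' `"sensitivity-associated"`; anything else `"none"`. The `pass` flag
#' follows the one-sided positive rule.
#'
#' @param panel_expr [expr_matrix()] in panel mode (samples = cell lines).
#' @param ic50 [drug_activity_table()].
#' @param lncrnas gene ids to test.
#' @param r_min,p_max thresholds (defaults 0.3 and 0.05).
#' @return data.frame with `gene`, `r`, `p_value`, `n`, `pass`,
#'   `direction_call`.
#' @export
correlate_drug_activity <- function(panel_expr, ic50, lncrnas,
                                    r_min = 0.3, p_max = 0.05) {
  stopifnot(inherits(panel_expr, "expr_matrix"))
  shared <- intersect(colnames(panel_expr$values), ic50$cell_line_id)
  if (length(shared) < 10L) {
    stop("need >= 10 shared cell lines (got ", length(shared), ")")
  }
  y <- ic50$ic50[match(shared, ic50$cell_line_id)]
  missing_g <- setdiff(lncrnas, rownames(panel_expr$values))
  if (length(missing_g)) {
    stop("genes absent from panel: ", paste(missing_g, collapse = ", "))
  }
  rows <- lapply(lncrnas, function(g) {
    x <- panel_expr$values[g, shared]
    ct <- stats::cor.test(x, y)
    r <- unname(ct$estimate)
    p <- ct$p.value
    call <- if (r > r_min && p < p_max) "resistance-associated"
            else if (r < -r_min && p < p_max) "sensitivity-associated"
            else "none"
    data.frame(gene = g, r = r, p_value = p, n = length(shared),
               pass = r > r_min & p < p_max, direction_call = call)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
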