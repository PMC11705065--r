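#' Inverse of the trigamma function
#'
#' Newton iteration on `trigamma(x) = y`, used when matching moments of
#' log sample variances to a scaled inverse-chi-square prior.
#' @param y positive numeric.
#' @return x with trigamma(x) = y.
#' @keywords internal
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Estimate a variance prior by moment matching on log sample variances
#'
#' Fits a scaled inverse-chi-square prior (`prior_df` d0, `prior_var` s0^2)
#' to per-gene sample variances s_g^2 on d residual degrees of freedom, by
#' matching the mean and variance of log(s_g^2) to the theoretical moments
#' of a scaled F distribution. Genes with zero sample variance are excluded
#' from the fit but still receive the shrunken variance.
#'
#' @param s2 numeric vector of per-gene sample variances.
#' @param df residual degrees of freedom (scalar).
#' @return list with `prior_df` (possibly `Inf`) and `prior_var`.
#' @export
estimate_variance_prior <- function(s2, df) {
  pos <- s2 > 0
  if (sum(pos) < 2L) {
    return(list(prior_df = 0, prior_var = NA_real_))
  }
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    prior_df <- 2 * trigamma_inverse(evar)
    prior_var <- exp(mean(e) + digamma(prior_df / 2) - log(prior_df / 2))
  } else {
    prior_df <- Inf
    prior_var <- exp(mean(e))
  }
  list(prior_df = prior_df, prior_var = prior_var)
}

#' Moderated two-sample differential expression for one cell-line pair
#'
#' For each gene, computes log2 fold change as mean(resistant) minus
#' mean(sensitive) and a two-sided p-value from a moderated t-statistic:
#' the pooled two-sample variance is shrunk towards a prior estimated by
#' moment matching across all genes (empirical Bayes), and the t reference
#' distribution gains the prior degrees of freedom. With `prior_df = 0`
#' the statistic is exactly the ordinary equal-variance two-sample t.
#'
#' @param expr [expr_matrix()] in cellline mode.
#' @param pair pair_id label selecting the cell-line pair to test.
#' @param method `"moderated"` (default) or `"ordinary"` (equivalent to
#'   `prior_df = 0`).
#' @param prior_df optional numeric overriding the estimated prior degrees
#'   of freedom (0 disables moderation; `Inf` fully shrinks to the prior
#'   variance).
#' @return data.frame with columns `molecule_id`, `gene_class`, `pair_id`,
#'   `log2_fc`, `t`, `df`, `p_value`, `direction`.
#' @export
fit_moderated_de <- function(expr, pair, method = c("moderated", "ordinary"),
                             prior_df = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  method <- match.arg(method)
  if (expr$mode != "cellline") stop("differential expression requires cellline mode")
  sel <- expr$pair_id == pair
  if (!any(sel)) stop("unknown pair_id: ", pair)
  v <- expr$values[, sel, drop = FALSE]
  cond <- expr$sample_condition[sel]
  n1 <- sum(cond == "resistant")
  n2 <- sum(cond == "sensitive")
  if (n1 < 2L || n2 < 2L) {
    stop(sprintf("pair '%s' needs >=2 replicates per arm (got %d resistant, %d sensitive)",
                 pair, n1, n2))
  }
  vr <- v[, cond == "resistant", drop = FALSE]
  vs <- v[, cond == "sensitive", drop = FALSE]
  mr <- rowMeans(vr)
  ms <- rowMeans(vs)
  fc <- mr - ms
  df_resid <- n1 + n2 - 2L
  s2 <- (rowSums((vr - mr)^2) + rowSums((vs - ms)^2)) / df_resid

  if (method == "ordinary" && is.null(prior_df)) prior_df <- 0
  if (is.null(prior_df)) {
    prior <- estimate_variance_prior(s2, df_resid)
    prior_df <- prior$prior_df
    prior_var <- prior$prior_var
  } else if (prior_df > 0) {
    prior <- estimate_variance_prior(s2, df_resid)
    prior_var <- prior$prior_var
  } else {
    prior_var <- 0
  }

  if (prior_df == 0) {
    svar <- s2
    df_total <- rep(df_resid, length(s2))
  } else if (is.infinite(prior_df)) {
    svar <- rep(prior_var, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    svar <- (prior_df * prior_var + df_resid * s2) / (prior_df + df_resid)
    df_total <- rep(prior_df + df_resid, length(s2))
  }

  se <- sqrt(svar * (1 / n1 + 1 / n2))
  tstat <- fc / se
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  degenerate <- se == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " gene(s) with zero variance and no prior; ",
            "p set to 0 where means differ, 1 otherwise")
    tstat[degenerate] <- ifelse(fc[degenerate] != 0, Inf, 0) *
      sign(fc[degenerate] + (fc[degenerate] == 0))
    p[degenerate] <- ifelse(fc[degenerate] != 0, 0, 1)
  }

  data.frame(
    molecule_id = rownames(v),
    gene_class = unname(expr$gene_class),
    pair_id = pair,
    log2_fc = unname(fc),
    t = unname(tstat),
    df = unname(df_total),
    p_value = unname(p),
    direction = ifelse(fc > 0, "up", "down"),
    row.names = NULL)
}

#' Call dysregulated molecules from differential records
#'
#' Thresholds are asymmetric by gene class: lncRNAs and mRNAs must pass
#' both the p-value cut and a fold-change gate (|log2FC| > log2(fc_min),
#' two-sided on the ratio scale); miRNAs need only the p-value cut.
#' Direction is the sign of log2FC.
#'
#' @param records data.frame from [fit_moderated_de()].
#' @param p_max p-value threshold (default 0.05).
#' @param fc_min fold-change threshold on the ratio scale (default 1.5),
#'   applied to lncRNA/mRNA only.
#' @param adjust_method multiple-testing correction passed to
#'   [stats::p.adjust()]; default `"none"` (raw p-values).
#' @return the subset of `records` passing the thresholds.
#' @export
call_dysregulated <- function(records, p_max = 0.05, fc_min = 1.5,
                              adjust_method = "none") {
  p <- stats::p.adjust(records$p_value, method = adjust_method)
  needs_fc <- records$gene_class %in% c("lncRNA", "mRNA")
  keep <- p < p_max &
    (!needs_fc | abs(records$log2_fc) > log2(fc_min))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect per-pair called sets with direction consistency
#'
#' A molecule enters the dysregulated set only if it was called in every
#' cell-line pair with the same direction. Per-pair statistics are carried
#' along as `log2_fc.<pair>` / `p_value.<pair>` columns.
#'
#' @param per_pair_sets list of called sets (one per pair) from
#'   [call_dysregulated()].
#' @param allow_single_pair permit a single pair (consistency cannot be
#'   checked; off by default).
#' @return data.frame with columns `molecule_id`, `gene_class`,
#'   `direction`, and per-pair statistic columns.
#' @export
intersect_consistent <- function(per_pair_sets, allow_single_pair = FALSE) {
  if (length(per_pair_sets) < 2L && !allow_single_pair) {
    stop("need called sets from >=2 cell-line pairs; pass ",
         "`allow_single_pair = TRUE` to override (logged as a deviation ",
         "from the consistency rule)")
  }
  common <- Reduce(intersect, lapply(per_pair_sets, `[[`, "molecule_id"))
  if (!length(common)) {
    return(data.frame(molecule_id = character(0), gene_class = character(0),
                      direction = character(0)))
  }
  dirs <- vapply(per_pair_sets, function(s)
    s$direction[match(common, s$molecule_id)], character(length(common)))
  dirs <- matrix(dirs, nrow = length(common))
  consistent <- apply(dirs, 1L, function(x) length(unique(x)) == 1L)
  common <- common[consistent]
  first <- per_pair_sets[[1L]]
  out <- data.frame(
    molecule_id = common,
    gene_class = first$gene_class[match(common, first$molecule_id)],
    direction = first$direction[match(common, first$molecule_id)])
  for (s in per_pair_sets) {
    pid <- s$pair_id[1L]
    m <- match(common, s$molecule_id)
    out[[paste0("log2_fc.", pid)]] <- s$log2_fc[m]
    out[[paste0("p_value.", pid)]] <- s$p_value[m]
  }
  rownames(out) <- NULL
  out
}
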