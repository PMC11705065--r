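#' Tumor cohort: expression, purity, and optional survival
#'
#' Bundles a cohort-mode expression matrix with a per-sample tumor purity
#' vector and, optionally, overall-survival time and event indicators.
#' Purity is the estimated fraction of malignant cells in each bulk sample
#' (e.g. from expression-signature methods such as ESTIMATE); it is taken
#' as an input, not computed here.
#'
#' @param expression [expr_matrix()] in cohort mode.
#' @param purity numeric vector in (0, 1], named by sample id or in column
#'   order.
#' @param survival_time optional positive numeric vector per sample.
#' @param event optional 0/1 vector per sample (1 = death observed).
#' @return object of class `tumor_cohort`.
#' @export
tumor_cohort <- function(expression, purity, survival_time = NULL,
                         event = NULL) {
  stopifnot(inherits(expression, "expr_matrix"))
  if (expression$mode != "cohort") stop("expression must be in cohort mode")
  ids <- colnames(expression$values)
  if (!is.null(names(purity))) {
    missing_p <- setdiff(ids, names(purity))
    if (length(missing_p)) {
      stop("samples missing purity: ", paste(missing_p, collapse = ", "))
    }
    purity <- purity[ids]
  }
  if (length(purity) != length(ids)) stop("one purity value per sample required")
  if (any(!is.finite(purity)) || any(purity <= 0) || any(purity > 1)) {
    stop("purity must lie in (0, 1]")
  }
  names(purity) <- ids
  if (!is.null(survival_time)) {
    if (length(survival_time) != length(ids) || length(event) != length(ids)) {
      stop("survival_time and event must have one entry per sample")
    }
    if (any(survival_time <= 0, na.rm = TRUE)) stop("survival_time must be positive")
    if (!all(event %in% c(0, 1) | is.na(event))) stop("event must be 0/1")
    names(survival_time) <- ids
    names(event) <- ids
  }
  structure(list(expression = expression, purity = purity,
                 survival_time = survival_time, event = event),
            class = "tumor_cohort")
}

#' @export
print.tumor_cohort <- function(x, ...) {
  cat(sprintf("<tumor_cohort> %d genes x %d samples%s\n",
              nrow(x$expression$values), ncol(x$expression$values),
              if (is.null(x$survival_time)) "" else
                sprintf(", survival for %d samples (%d events)",
                        sum(!is.na(x$survival_time)),
                        sum(x$event, na.rm = TRUE))))
  invisible(x)
}

#' Merge active interactions into candidate competing triplets
#'
#' An active miRNA-lncRNA interaction and an active miRNA-mRNA interaction
#' sharing the same miRNA are merged into one (lncRNA, miRNA, mRNA)
#' candidate triplet. For a miRNA with L lncRNA partners and M mRNA
#' partners this produces L x M candidates; duplicates are removed.
#'
#' @param active data.frame of active interactions from
#'   [filter_active_interactions()] (both target classes in one table, or
#'   rbind of two).
#' @return data.frame of candidate triplets with columns `lncrna_id`,
#'   `mirna_id`, `mrna_id` (co-expression statistics unset).
#' @export
assemble_triplets <- function(active) {
  lnc <- active[active$target_class == "lncRNA", , drop = FALSE]
  mr <- active[active$target_class == "mRNA", , drop = FALSE]
  shared <- intersect(unique(lnc$mirna_id), unique(mr$mirna_id))
  out <- list()
  for (mi in shared) {
    L <- unique(lnc$target_id[lnc$mirna_id == mi])
    M <- unique(mr$target_id[mr$mirna_id == mi])
    out[[mi]] <- expand.grid(lncrna_id = L, mrna_id = M,
                             stringsAsFactors = FALSE)
    out[[mi]]$mirna_id <- mi
  }
  if (!length(out)) {
    return(data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0)))
  }
  res <- do.call(rbind, out)[, c("lncrna_id", "mirna_id", "mrna_id")]
  res <- unique(res)
  rownames(res) <- NULL
  res
}

#' First-order partial correlation controlling for tumor purity
#'
#' The co-expression statistic of the pipeline: the Pearson correlation
#' between lncRNA expression x and mRNA expression y after removing the
#' linear effect of tumor purity z,
#' \deqn{pcc = (r_{xy} - r_{xz} r_{yz}) /
#'   \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}
#' with a two-sided p-value from \eqn{t = pcc \sqrt{(n-3)/(1-pcc^2)}} on
#' n - 3 degrees of freedom.
#'
#' @param x,y numeric expression vectors (equal length n >= 4).
#' @param z numeric covariate vector (tumor purity).
#' @return list with `pcc`, `p_value`, `n`, and the pairwise Pearson
#'   correlations `r_xy`, `r_xz`, `r_yz`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 4L) stop("need n >= 4 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0) {
    stop("zero variance input")
  }
  r_xy <- stats::cor(x, y)
  r_xz <- stats::cor(x, z)
  r_yz <- stats::cor(y, z)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    stop("purity collinear with expression")
  }
  pcc <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  pcc <- max(-1, min(1, pcc))
  tstat <- pcc * sqrt((n - 3) / max(1 - pcc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 3)
  list(pcc = pcc, p_value = p, n = n, r_xy = r_xy, r_xz = r_xz, r_yz = r_yz)
}

#' Purity-adjusted co-expression statistics for candidate lncRNA-mRNA pairs
#'
#' Computes the partial correlation (controlling tumor purity) for every
#' distinct (lncRNA, mRNA) pair appearing in the candidate triplets. When
#' `use_purity = FALSE` a plain Pearson correlation is used instead, with a
#' warning (intended for cohorts lacking purity estimates).
#'
#' @param candidates data.frame of candidate triplets from
#'   [assemble_triplets()].
#' @param cohort [tumor_cohort()].
#' @param use_purity control for tumor purity (default `TRUE`).
#' @return data.frame with one row per distinct pair: `lncrna_id`,
#'   `mrna_id`, `pcc`, `p_value`, `n`.
#' @export
pair_coexpression <- function(candidates, cohort, use_purity = TRUE) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  pairs <- unique(candidates[, c("lncrna_id", "mrna_id")])
  v <- cohort$expression$values
  missing_g <- setdiff(unique(c(pairs$lncrna_id, pairs$mrna_id)), rownames(v))
  if (length(missing_g)) {
    stop("genes missing from cohort expression: ",
         paste(missing_g, collapse = ", "))
  }
  if (!use_purity) {
    warning("computing plain Pearson correlation without purity adjustment")
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- v[pairs$lncrna_id[i], ]
    y <- v[pairs$mrna_id[i], ]
    if (use_purity) {
      pc <- partial_correlation(x, y, cohort$purity)
      data.frame(pcc = pc$pcc, p_value = pc$p_value, n = pc$n)
    } else {
      ct <- stats::cor.test(x, y)
      data.frame(pcc = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
    }
  })
  out <- cbind(pairs, do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Filter candidate triplets by positive co-expression
#'
#' A triplet is retained only when its (lncRNA, mRNA) pair is positively
#' co-expressed: pcc > `pcc_min` (signed, one-sided positive — the ceRNA
#' model predicts positive lncRNA-mRNA correlation) and p < `p_max`.
#' Pairs absent from `pair_stats` carry no co-expression evidence and are
#' dropped.
#'
#' @param candidates data.frame from [assemble_triplets()].
#' @param pair_stats data.frame from [pair_coexpression()] (or any table
#'   with `lncrna_id`, `mrna_id`, `pcc`, `p_value`).
#' @param pcc_min partial-correlation threshold (default 0.2).
#' @param p_max p-value threshold (default 0.05).
#' @return data.frame of retained triplets with `pcc` and `pcc_p` columns.
#' @export
filter_coexpressed <- function(candidates, pair_stats, pcc_min = 0.2,
                               p_max = 0.05) {
  key <- function(d) paste(d$lncrna_id, d$mrna_id, sep = "\r")
  pass <- pair_stats$pcc > pcc_min & pair_stats$p_value < p_max
  m <- match(key(candidates), key(pair_stats))
  keep <- !is.na(m) & pass[m]
  out <- candidates[keep, , drop = FALSE]
  out$pcc <- pair_stats$pcc[m[keep]]
  out$pcc_p <- pair_stats$p_value[m[keep]]
  rownames(out) <- NULL
  out
}

#' Summarise retained triplets as lncRNA-mRNA pairs with shared miRNAs
#'
#' One row per co-expressed (lncRNA, mRNA) pair with its shared miRNAs
#' semicolon-joined — the tabular form in which competing interactions are
#' usually reported.
#'
#' @param triplets data.frame from [filter_coexpressed()].
#' @return data.frame with `lncrna_id`, `mrna_id`, `shared_mirnas`,
#'   `pcc`, `pcc_p`.
#' @export
summarise_triplet_pairs <- function(triplets) {
  if (!nrow(triplets)) {
    return(data.frame(lncrna_id = character(0), mrna_id = character(0),
                      shared_mirnas = character(0), pcc = numeric(0),
                      pcc_p = numeric(0)))
  }
  key <- paste(triplets$lncrna_id, triplets$mrna_id, sep = "\r")
  first <- !duplicated(key)
  mir <- vapply(split(triplets$mirna_id, key), function(x)
    paste(sort(unique(x)), collapse = ";"), character(1))
  out <- triplets[first, c("lncrna_id", "mrna_id", "pcc", "pcc_p")]
  out$shared_mirnas <- unname(mir[key[first]])
  out <- out[, c("lncrna_id", "mrna_id", "shared_mirnas", "pcc", "pcc_p")]
  rownames(out) <- NULL
  out
}
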