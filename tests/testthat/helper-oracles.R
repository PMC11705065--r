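# Independent brute-force oracles and small fixture builders shared by the
# suite. Each oracle is a naive, direct implementation kept deliberately
# separate from the package code paths it checks.

# small cellline expr_matrix: one pair, n-vs-n, values given per gene as
# list(gene = c(resistant..., sensitive...))
toy_cellline <- function(gene_values, gene_class = "mRNA",
                         pair = "P1", n_res = NULL) {
  v <- do.call(rbind, gene_values)
  rownames(v) <- names(gene_values)
  if (is.null(n_res)) n_res <- ncol(v) / 2
  colnames(v) <- sprintf("%s_s%d", pair, seq_len(ncol(v)))
  expr_matrix(v, gene_class, mode = "cellline",
              sample_condition = rep(c("resistant", "sensitive"),
                                     c(n_res, ncol(v) - n_res)),
              pair_id = rep(pair, ncol(v)))
}

# naive sliding-window exact-substring scan
naive_scan <- function(pattern, target) {
  lp <- nchar(pattern)
  hits <- integer(0)
  for (i in seq_len(nchar(target) - lp + 1L)) {
    if (substr(target, i, i + lp - 1L) == pattern) hits <- c(hits, i)
  }
  hits
}

naive_revcomp <- function(s) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force walk of the single-sample rank running-sum statistic
ssgsea_oracle <- function(vals, sig_genes, alpha = 0.25) {
  if (length(unique(vals)) == 1L) return(0)
  n <- length(vals)
  r <- rank(vals, ties.method = "average")
  ord <- names(vals)[order(vals, decreasing = TRUE)]
  in_sig <- ord %in% sig_genes
  wsum <- sum(r[names(vals) %in% sig_genes]^alpha)
  running <- 0; total <- 0
  for (i in seq_len(n)) {
    if (in_sig[i]) {
      running <- running + r[ord[i]]^alpha / wsum
    } else {
      running <- running - 1 / (n - sum(in_sig))
    }
    total <- total + running
  }
  unname(total / n)
}

# two-group log-rank observed-minus-expected tabulation
logrank_oracle <- function(time, event, group) {
  g1 <- levels(factor(group))[1L]
  o_minus_e <- 0; varsum <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) {
      varsum <- varsum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chisq <- o_minus_e^2 / varsum
  list(o_minus_e = o_minus_e, chisq = chisq,
       p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# written-out Cox partial log-likelihood (Breslow form; valid with no ties)
cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
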