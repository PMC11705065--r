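toy_cells <- function(values) {
  expr_matrix(values, "mRNA", mode = "cohort")
}

test_that("state score matches a brute-force walk and its extremes", {
  set.seed(31)
  genes <- sprintf("g%02d", 1:10)
  sig <- list(S = c("g01", "g02", "g03"))
  v <- matrix(rnorm(30, 5), nrow = 10, dimnames = list(genes, c("c1", "c2", "c3")))
  # cell c1: signature genes occupy the top |S| ranks
  v[, "c1"] <- c(9, 8.5, 8, rnorm(7, 3, 0.3))
  # cell c3: all genes tied
  v[, "c3"] <- 4
  sc <- score_functional_states(toy_cells(v), sig, standardize = FALSE)
  for (cl in colnames(v)) {
    expect_equal(sc["S", cl],
                 ssgsea_oracle(setNames(v[, cl], genes), sig$S),
                 tolerance = 1e-12)
  }
  expect_equal(sc["S", "c3"], 0)  # tie convention
  # top-ranked signature gives the maximal possible score for that cell:
  # no permutation of gene values can score higher
  perms <- replicate(50, {
    ssgsea_oracle(setNames(sample(v[, "c1"]), genes), sig$S)
  })
  expect_true(all(perms <= sc["S", "c1"] + 1e-12))
})

test_that("state score is invariant to monotone transforms of a cell", {
  set.seed(32)
  genes <- sprintf("g%02d", 1:20)
  v <- matrix(rnorm(40, 5), nrow = 20, dimnames = list(genes, c("a", "b")))
  sig <- list(S = genes[1:5])
  base <- score_functional_states(toy_cells(v), sig, standardize = FALSE)
  v2 <- v
  v2[, "a"] <- exp(v2[, "a"])          # strictly monotone
  v2[, "b"] <- 3 * v2[, "b"] - 100
  trans <- score_functional_states(toy_cells(v2), sig, standardize = FALSE)
  expect_equal(trans, base)
})

test_that("state scoring guards signature coverage", {
  v <- matrix(rnorm(20), nrow = 5,
              dimnames = list(sprintf("g%d", 1:5), sprintf("c%d", 1:4)))
  expect_error(score_functional_states(toy_cells(v), list(S = c("g1", "zz"))),
               "fewer than 2")
  expect_warning(
    score_functional_states(toy_cells(v),
                            list(S = c("g1", "g2", "z1", "z2", "z3"))),
    "2/5 genes present")
})

test_that("state correlation follows the exact rank formula and pass rule", {
  set.seed(33)
  n <- 12
  v <- matrix(rnorm(3 * n, 5), nrow = 3,
              dimnames = list(c("mono", "anti", "noisy"),
                              sprintf("c%02d", 1:n)))
  scores <- matrix(seq_len(n), nrow = 1,
                   dimnames = list("S", colnames(v)))
  v["mono", ] <- sort(v["mono", ])        # perfectly monotone with score
  v["anti", ] <- rev(sort(v["anti", ]))   # anti-monotone
  res <- correlate_states(scores, toy_cells(v), c("mono", "anti", "noisy"))
  expect_equal(res$rho[res$gene == "mono"], 1)
  expect_equal(res$rho[res$gene == "anti"], -1)
  expect_false(res$pass[res$gene == "anti"])  # one-sided positive rule
  expect_true(res$pass[res$gene == "mono"])
  # no ties: rho must equal 1 - 6*sum(d^2)/(n(n^2-1))
  d <- rank(v["noisy", ]) - rank(scores["S", ])
  expect_equal(res$rho[res$gene == "noisy"],
               1 - 6 * sum(d^2) / (n * (n^2 - 1)), tolerance = 1e-12)

  # constant vectors are flagged undefined and excluded from averages
  v["noisy", ] <- 2
  res2 <- correlate_states(scores, toy_cells(v), "noisy")
  expect_false(res2$defined)
  avg <- average_state_correlations(list(res, res2))
  expect_equal(avg$n_datasets[avg$gene == "noisy"], 1)
  expect_equal(avg$mean_rho[avg$gene == "mono"], 1)
  expect_error(correlate_states(scores[, 1:5, drop = FALSE],
                                toy_cells(v[, 1:5]), "mono"), ">= 10 cells")
})

test_that("Cox beta maximizes the written-out partial likelihood", {
  # no ties, so Efron and Breslow coincide with the plain partial likelihood
  set.seed(34)
  x <- c(0.1, 0.9, 0.35, 0.7, 0.5, 0.15, 0.8, 0.45, 0.6, 0.25, 0.95, 0.05)
  time <- c(2.1, 0.9, 3.3, 1.2, 2.8, 4.1, 1.05, 2.45, 1.7, 3.8, 0.6, 4.5)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1, 1, 0, 1, 1)
  fit <- fit_cox_beta(x, time, event)
  oracle <- optimize(function(b) cox_loglik(b, x, time, event),
                     interval = c(-20, 20), maximum = TRUE,
                     tol = 1e-10)$maximum
  expect_equal(fit$beta, oracle, tolerance = 1e-6)
  # rescaling the covariate by c rescales beta by 1/c
  fit4 <- fit_cox_beta(4 * x, time, event)
  expect_equal(fit4$beta, fit$beta / 4, tolerance = 1e-6)
  expect_error(fit_cox_beta(x, time, rep(0, 12)), "no events")
  expect_error(fit_cox_beta(x[1:5], time[1:5], event[1:5]), ">= 10 samples")
})

test_that("risk scores are the coefficient-weighted expression sum", {
  v <- matrix(c(2, 1), nrow = 2,
              dimnames = list(c("A", "B"), "s1"))
  cohort <- tumor_cohort(expr_matrix(v, "mRNA", mode = "cohort"),
                         purity = 0.8)
  model <- structure(list(beta = c(A = 0.5, B = -0.2)), class = "risk_model")
  expect_equal(unname(risk_scores(model, cohort)), 0.8)
})

test_that("median-split stratification and log-rank match hand computation", {
  # 8-sample toy: groups by score {1,2,3,4,5,6,7,8} split at median 4.5
  v <- matrix(1:8, nrow = 1, dimnames = list("G", sprintf("s%d", 1:8)))
  time <- c(5, 6, 7, 8, 1, 2, 3, 4.5)
  event <- c(1, 0, 1, 1, 1, 1, 1, 0)
  cohort <- tumor_cohort(expr_matrix(v, "mRNA", mode = "cohort"),
                         purity = rep(0.7, 8),
                         survival_time = time, event = event)
  model <- structure(list(beta = c(G = 1)), class = "risk_model")
  strat <- risk_stratify(model, cohort)
  expect_equal(sum(strat$group == "high"), 4L)
  expect_equal(sum(strat$group == "low"), 4L)
  oracle <- logrank_oracle(time, event, strat$group)
  expect_equal(strat$logrank_chisq, oracle$chisq, tolerance = 1e-10)
  expect_equal(strat$logrank_p, oracle$p, tolerance = 1e-10)

  # Kaplan-Meier curves: start at 1, non-increasing, drop only at events
  km <- summary(strat$km)
  expect_true(all(km$surv <= 1))
  for (g in unique(km$strata)) {
    expect_true(all(diff(km$surv[km$strata == g]) <= 0))
  }
  expect_setequal(km$time, sort(unique(time[event == 1])))

  vc <- matrix(1, nrow = 1, ncol = 8, dimnames = list("G", sprintf("s%d", 1:8)))
  cohort2 <- tumor_cohort(expr_matrix(vc, "mRNA", mode = "cohort"),
                          purity = rep(0.7, 8),
                          survival_time = time, event = event)
  expect_error(risk_stratify(model, cohort2), "degenerate")
})

test_that("drug-activity correlation labels resistance direction", {
  lines <- sprintf("L%02d", 1:12)
  v <- matrix(seq(1, 12), nrow = 1, dimnames = list("LNC", lines))
  panel <- expr_matrix(v, "lncRNA", mode = "panel")
  up <- drug_activity_table(data.frame(cell_line_id = lines,
                                       ic50 = 2 + 0.5 * seq(1, 12)))
  res <- correlate_drug_activity(panel, up, "LNC")
  expect_equal(res$r, 1)
  expect_equal(res$direction_call, "resistance-associated")
  down <- drug_activity_table(data.frame(cell_line_id = lines,
                                         ic50 = 5 - 0.3 * seq(1, 12)))
  res2 <- correlate_drug_activity(panel, down, "LNC")
  expect_equal(res2$r, -1)
  expect_equal(res2$direction_call, "sensitivity-associated")
  expect_false(res2$pass)
  expect_error(
    correlate_drug_activity(panel, up[1:5, ], "LNC"), ">= 10 shared")
  expect_error(drug_activity_table(data.frame(cell_line_id = c("a", "a"),
                                              ic50 = 1:2)), "duplicate")
})
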