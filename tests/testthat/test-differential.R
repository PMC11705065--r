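test_that("identical arms give log2FC 0 and p 1", {
  em <- toy_cellline(list(
    FLAT = c(5, 6, 7, 5, 6, 7),
    VAR1 = c(1, 2, 3, 4, 5, 6),
    VAR2 = c(2, 1, 2, 1, 2, 1)))
  de <- fit_moderated_de(em, "P1")
  expect_equal(de$log2_fc[de$molecule_id == "FLAT"], 0)
  expect_equal(de$p_value[de$molecule_id == "FLAT"], 1)
})

test_that("zero prior weight reduces exactly to the ordinary two-sample t", {
  set.seed(5)
  vals <- lapply(1:30, function(i) rnorm(6, mean = 6, sd = runif(1, .1, 1)))
  names(vals) <- sprintf("G%02d", 1:30)
  em <- toy_cellline(vals)
  de <- fit_moderated_de(em, "P1", prior_df = 0)
  for (g in names(vals)) {
    tt <- t.test(vals[[g]][1:3], vals[[g]][4:6], var.equal = TRUE)
    expect_equal(de$p_value[de$molecule_id == g], tt$p.value,
                 tolerance = 1e-12)
    expect_equal(de$t[de$molecule_id == g], unname(tt$statistic),
                 tolerance = 1e-12)
  }
  expect_equal(fit_moderated_de(em, "P1", method = "ordinary"), de)
})

test_that("moderated statistics agree with the reference eBayes implementation", {
  skip_if_not_installed("limma")
  set.seed(7)
  n <- 150
  v <- matrix(rnorm(n * 6, mean = 6, sd = runif(n, .1, .8)), nrow = n,
              dimnames = list(sprintf("G%03d", 1:n), sprintf("S%d", 1:6)))
  em <- expr_matrix(v, "mRNA", mode = "cellline",
                    sample_condition = rep(c("resistant", "sensitive"),
                                           each = 3),
                    pair_id = rep("P1", 6))
  de <- fit_moderated_de(em, "P1")
  design <- cbind(R = rep(1:0, each = 3), S = rep(0:1, each = 3))
  fit <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(v, design),
    limma::makeContrasts(R - S, levels = design)))
  expect_equal(de$p_value, unname(fit$p.value[, 1]), tolerance = 1e-10)
  expect_equal(de$df[1] - 4, unname(fit$df.prior), tolerance = 1e-8)
})

test_that("replicate and degeneracy guards fire", {
  em <- toy_cellline(list(G = c(1, 2, 3)), n_res = 1)
  expect_error(fit_moderated_de(em, "P1"), ">=2 replicates")
  expect_error(fit_moderated_de(toy_cellline(list(G = 1:4)), "P9"),
               "unknown pair_id")
  # zero-variance gene with prior weight zero: degenerate p with warning
  em2 <- toy_cellline(list(SAME = c(2, 2, 2, 2), DIFF = c(3, 3, 1, 1)))
  expect_warning(de <- fit_moderated_de(em2, "P1", prior_df = 0),
                 "zero variance")
  expect_equal(de$p_value[de$molecule_id == "SAME"], 1)
  expect_equal(de$p_value[de$molecule_id == "DIFF"], 0)
})

test_that("calling applies the class-asymmetric thresholds", {
  recs <- data.frame(
    molecule_id = c("a", "b", "c", "d"),
    gene_class = c("mRNA", "mRNA", "miRNA", "lncRNA"),
    log2_fc = c(1.0, 0.5, 0.1, -0.7),
    p_value = c(0.01, 0.001, 0.03, 0.04),
    pair_id = "P1")
  out <- call_dysregulated(recs)
  # mRNA at |log2FC|=1 kept; mRNA at 0.5 (FC~1.41) fails the gate even at
  # p=0.001; miRNA has no FC gate; down-regulated lncRNA kept two-sided
  expect_setequal(out$molecule_id, c("a", "c", "d"))

  # monotonicity: tightening either threshold never grows the called set
  set.seed(9)
  recs2 <- data.frame(molecule_id = sprintf("g%d", 1:300),
                      gene_class = sample(c("lncRNA", "miRNA", "mRNA"),
                                          300, TRUE),
                      log2_fc = rnorm(300), p_value = runif(300),
                      pair_id = "P1")
  base <- call_dysregulated(recs2, p_max = 0.05, fc_min = 1.5)
  expect_true(all(call_dysregulated(recs2, p_max = 0.01,
                                    fc_min = 1.5)$molecule_id %in%
                    base$molecule_id))
  expect_true(all(call_dysregulated(recs2, p_max = 0.05,
                                    fc_min = 2)$molecule_id %in%
                    base$molecule_id))
})

test_that("consistent intersection keeps same-direction calls only", {
  a <- data.frame(molecule_id = c("x", "y", "z"), gene_class = "mRNA",
                  log2_fc = c(1, 1, 1), p_value = 0.01,
                  direction = c("up", "up", "up"), pair_id = "A")
  b <- data.frame(molecule_id = c("x", "y"), gene_class = "mRNA",
                  log2_fc = c(1, -1), p_value = 0.01,
                  direction = c("up", "down"), pair_id = "B")
  out <- intersect_consistent(list(a, b))
  expect_equal(out$molecule_id, "x")   # y flips direction, z absent in B
  expect_equal(out$direction, "up")
  expect_true(all(c("log2_fc.A", "p_value.B") %in% names(out)))
  expect_error(intersect_consistent(list(a)), "single")
  expect_equal(intersect_consistent(list(a), allow_single_pair = TRUE)$molecule_id,
               c("x", "y", "z"))
})

test_that("noiseless synthetic profiles are recovered exactly", {
  tr <- synthetic_truth(seed = 3)
  exprs <- generate_cellline_profiles(tr, sigma = 0)
  # planted log2FC equals the effect size exactly
  suppressWarnings({
    de <- fit_moderated_de(exprs$lncRNA, "PAIR1")
    expect_equal(de$log2_fc[de$molecule_id == "LNC01"], 1.5)
    de_mir <- fit_moderated_de(exprs$miRNA, "PAIR2")
    expect_equal(de_mir$log2_fc[de_mir$molecule_id == "MIR03"], -1.5)
    # the consistency-filtered set equals the planted set exactly
    called <- lapply(c("PAIR1", "PAIR2"), function(p) {
      recs <- do.call(rbind, lapply(exprs, fit_moderated_de, pair = p))
      call_dysregulated(recs)
    })
  })
  dys <- intersect_consistent(called)
  expect_setequal(dys$molecule_id, names(tr$planted_directions))
  expect_equal(setNames(dys$direction, dys$molecule_id)[names(tr$planted_directions)],
               tr$planted_directions)
})
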