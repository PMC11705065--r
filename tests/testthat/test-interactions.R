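test_that("interaction tables de-duplicate and validate", {
  df <- data.frame(
    mirna_id = c("miR-a", "miR-a", "miR-b", "miR-c"),
    target_id = c("GENE1", "GENE1", "GENE2", "GENE3"),
    target_class = c("mRNA", "mRNA", "mRNA", "lncRNA"),
    evidence_tag = c("clip", "lucif", "clip", "clip"))
  tab <- interaction_table(df)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$evidence_tag[tab$mirna_id == "miR-a"], "clip;lucif")

  # 3 distinct records in, 3 out
  expect_equal(nrow(interaction_table(df[2:4, ])), 3L)

  df$target_class[1] <- "protein"
  expect_error(interaction_table(df), "unknown target_class")
  df2 <- data.frame(mirna_id = c("a", "b"), target_id = c("G", "G"),
                    target_class = c("mRNA", "lncRNA"), evidence_tag = "x")
  expect_error(interaction_table(df2), "inconsistent target_class")

  f <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(tab, f)
  expect_equal(as.data.frame(read_interactions(f)), as.data.frame(tab))
})

test_that("canonical seed sites are the reverse complement of the seed", {
  # miRNA 5'-UAGGUAGU...-3': seed nt2-7 = AGGUAG, 6mer site = CUACCU
  mir <- c(mir1 = "UAGGUAGUUUCAUGUU")
  hit <- predict_seed_matches(mir, c(t1 = "GGGCUACCUGGG"),
                              site_types = "6mer")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$evidence_tag, "6mer:4")

  # target lacking any seed complement yields no record
  none <- predict_seed_matches(mir, c(t2 = "AAAAAAAAAAAA"))
  expect_equal(nrow(none), 0L)

  # 7mer-m8 adds the nt8 complement 5' of the core; A1 adds an A 3' of it
  m8 <- predict_seed_matches(mir, c(t3 = "GGACUACCUGG"),
                             site_types = "7mer-m8")
  expect_equal(m8$evidence_tag, "7mer-m8:3")
  a1 <- predict_seed_matches(mir, c(t4 = "GGCUACCUAGG"),
                             site_types = "7mer-A1")
  expect_equal(a1$evidence_tag, "7mer-A1:3")
  e8 <- predict_seed_matches(mir, c(t5 = "GACUACCUAG"),
                             site_types = "8mer")
  expect_equal(e8$evidence_tag, "8mer:2")

  # T accepted and mapped to U
  dna <- predict_seed_matches(c(mir1 = "TAGGTAGTTTCATGTT"),
                              c(t1 = "GGGCTACCTGGG"), site_types = "6mer")
  expect_equal(dna$evidence_tag, "6mer:4")

  expect_error(predict_seed_matches(c(m = "UAGGUNGUU"), c(t = "ACGU")),
               "invalid characters.*m")
  expect_error(predict_seed_matches(mir, c(tX = "ACGX")), "tX")
})

test_that("seed-scan hit positions equal a naive sliding-window scan", {
  set.seed(11)
  mirs <- setNames(
    vapply(1:4, function(i)
      paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE), collapse = ""),
      character(1)),
    sprintf("mir%d", 1:4))
  targets <- setNames(
    vapply(1:3, function(i)
      paste(sample(c("A", "C", "G", "U"), 1000, replace = TRUE),
            collapse = ""),
      character(1)),
    sprintf("t%d", 1:3))
  got <- predict_seed_matches(mirs, targets, site_types = "6mer")
  for (mi in names(mirs)) {
    pat <- naive_revcomp(substr(mirs[[mi]], 2, 7))
    for (ti in names(targets)) {
      expected <- naive_scan(pat, targets[[ti]])
      row <- got[got$mirna_id == mi & got$target_id == ti, ]
      if (length(expected) == 0L) {
        expect_equal(nrow(row), 0L)
      } else {
        expect_equal(row$evidence_tag,
                     paste(paste0("6mer:", expected), collapse = ";"))
      }
    }
  }
})

test_that("interaction intersection is a pairwise set intersection", {
  mk <- function(m, t, cls = "lncRNA", tag = "x")
    interaction_table(data.frame(mirna_id = m, target_id = t,
                                 target_class = cls, evidence_tag = tag))
  a <- mk(c("m1", "m2"), c("L1", "L2"))
  b <- mk(c("m3", "m4"), c("L1", "L9"))
  expect_equal(nrow(intersect_interactions(a, b)), 0L)

  # predicted subset of supported -> output = predicted pairs
  b2 <- mk(c("m1", "m2", "m9"), c("L1", "L2", "L9"), tag = "clip")
  out <- intersect_interactions(a, b2)
  expect_equal(as.data.frame(out)[, c("mirna_id", "target_id")],
               as.data.frame(a)[, c("mirna_id", "target_id")])
  expect_true(all(grepl("clip", out$evidence_tag)))

  # random tables vs explicit set intersection
  set.seed(3)
  ra <- mk(sample(sprintf("m%d", 1:6), 15, TRUE),
           sample(sprintf("L%d", 1:6), 15, TRUE))
  rb <- mk(sample(sprintf("m%d", 1:6), 15, TRUE),
           sample(sprintf("L%d", 1:6), 15, TRUE))
  key <- function(d) paste(d$mirna_id, d$target_id)
  expect_setequal(key(intersect_interactions(ra, rb)),
                  intersect(key(ra), key(rb)))
})

test_that("active interactions require membership and opposite directions", {
  dys <- data.frame(
    molecule_id = c("m-down", "m-up", "L-up", "G-down", "G-up"),
    gene_class = c("miRNA", "miRNA", "lncRNA", "mRNA", "mRNA"),
    direction = c("down", "up", "up", "down", "up"))
  cand <- interaction_table(data.frame(
    mirna_id = c("m-down", "m-down", "m-up", "m-down"),
    target_id = c("L-up", "G-down", "L-absent", "G-up"),
    target_class = c("lncRNA", "mRNA", "lncRNA", "mRNA"),
    evidence_tag = "e"))
  act <- filter_active_interactions(cand, dys)
  # miRNA down + lncRNA up and miRNA down + mRNA up are active;
  # same-direction and non-member pairs are rejected
  expect_setequal(act$target_id, c("L-up", "G-up"))
  expect_true(all(act$mirna_direction != act$target_direction))

  # filtering is idempotent and output is a subset of the candidates
  act2 <- filter_active_interactions(
    interaction_table(cbind(act[, c("mirna_id", "target_id", "target_class")],
                            evidence_tag = "e")), dys)
  expect_equal(act2[, 1:3], act[, 1:3])
})
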