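#' Build a validated miRNA-target interaction table
#'
#' Interaction tables record candidate miRNA binding relationships:
#' miRNA-lncRNA pairs (e.g. CLIP-seq supported) and miRNA-mRNA pairs (e.g.
#' curated, experimentally validated). Duplicate (mirna_id, target_id)
#' records are collapsed, with evidence tags merged (`;`-joined, unique).
#'
#' @param df data frame with columns `mirna_id`, `target_id`,
#'   `target_class` (`"lncRNA"` or `"mRNA"`), `evidence_tag`.
#' @return a de-duplicated data.frame with class `interaction_table`.
#' @export
interaction_table <- function(df) {
  need <- c("mirna_id", "target_id", "target_class", "evidence_tag")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  for (cl in need) df[[cl]] <- as.character(df[[cl]])
  bad <- setdiff(unique(df$target_class), c("lncRNA", "mRNA"))
  if (length(bad)) stop("unknown target_class: ", paste(bad, collapse = ", "))
  # a target id must carry a single class across all records
  cls_per_target <- tapply(df$target_class, df$target_id,
                           function(x) length(unique(x)))
  if (any(cls_per_target > 1L)) {
    stop("inconsistent target_class for: ",
         paste(names(cls_per_target)[cls_per_target > 1L], collapse = ", "))
  }
  key <- paste(df$mirna_id, df$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    tags <- tapply(df$evidence_tag, key, function(x)
      paste(unique(x), collapse = ";"))
    df <- df[!duplicated(key), , drop = FALSE]
    df$evidence_tag <- as.character(tags[paste(df$mirna_id, df$target_id,
                                               sep = "\r")])
  }
  rownames(df) <- NULL
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Read a miRNA-target interaction table from TSV
#'
#' @param path TSV with columns `mirna_id`, `target_id`, `target_class`,
#'   `evidence_tag`.
#' @return [interaction_table()]
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character")
  if (nrow(df) == 0L) stop("no records in ", path)
  interaction_table(df)
}

#' Write an interaction table to TSV
#' @param tab [interaction_table()]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

revcomp_rna <- function(seq) {
  chartr("ACGU", "UGCA",
         vapply(strsplit(seq, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), character(1)))
}

#' Scan target sequences for canonical miRNA seed-match sites
#'
#' A deliberately simple canonical seed-site scan, provided as a
#' transparent stand-in for full miRNA target prediction software
#' (TargetScan, miRanda, PITA, RNAhybrid). It reports perfect
#' Watson-Crick complementarity to the miRNA seed region only — no
#' thermodynamics, conservation, or context scoring. For real analyses the
#' primary supported path is to supply pre-computed predicted-interaction
#' tables and intersect them with CLIP-supported interactions via
#' [intersect_interactions()].
#'
#' Site types (miRNA positions are 1-based from the 5' end; sites are the
#' reverse complement on the target, read 5' to 3'):
#' \describe{
#'   \item{6mer}{complement of miRNA nt 2-7.}
#'   \item{7mer-m8}{complement of miRNA nt 2-8.}
#'   \item{7mer-A1}{complement of nt 2-7 followed by an A opposite
#'     miRNA position 1.}
#'   \item{8mer}{complement of nt 2-8 followed by an A.}
#' }
#'
#' @param mirna_seqs named character vector, miRNA id -> mature sequence
#'   (5'->3', RNA; T is accepted and mapped to U).
#' @param target_seqs named character vector, target id -> sequence.
#' @param target_class class label recorded for all targets (`"lncRNA"` or
#'   `"mRNA"`).
#' @param site_types subset of `c("6mer", "7mer-m8", "7mer-A1", "8mer")`.
#' @return [interaction_table()] with one record per (miRNA, target) pair
#'   having at least one site; `evidence_tag` lists `type:position`
#'   (1-based start on the target) for every site found.
#' @export
predict_seed_matches <- function(mirna_seqs, target_seqs,
                                 target_class = "lncRNA",
                                 site_types = c("6mer", "7mer-m8",
                                                "7mer-A1", "8mer")) {
  site_types <- match.arg(site_types, several.ok = TRUE)
  clean <- function(seqs, what) {
    seqs <- toupper(seqs)
    seqs <- chartr("T", "U", seqs)
    ok <- grepl("^[ACGU]+$", seqs)
    if (!all(ok)) {
      stop("invalid characters in ", what, " sequence(s): ",
           paste(names(seqs)[!ok], collapse = ", "))
    }
    seqs
  }
  mirna_seqs <- clean(mirna_seqs, "miRNA")
  target_seqs <- clean(target_seqs, "target")
  if (any(nchar(mirna_seqs) < 8L)) {
    stop("miRNA sequences must be at least 8 nt: ",
         paste(names(mirna_seqs)[nchar(mirna_seqs) < 8L], collapse = ", "))
  }

  site_seq <- function(mir, type) {
    switch(type,
      "6mer"    = revcomp_rna(substr(mir, 2L, 7L)),
      "7mer-m8" = revcomp_rna(substr(mir, 2L, 8L)),
      "7mer-A1" = paste0(revcomp_rna(substr(mir, 2L, 7L)), "A"),
      "8mer"    = paste0(revcomp_rna(substr(mir, 2L, 8L)), "A"))
  }

  out <- list()
  for (mi in names(mirna_seqs)) {
    for (ti in names(target_seqs)) {
      tags <- character(0)
      for (type in site_types) {
        pat <- site_seq(mirna_seqs[[mi]], type)
        hits <- gregexpr(pat, target_seqs[[ti]], fixed = TRUE)[[1L]]
        if (hits[1L] != -1L) {
          tags <- c(tags, paste0(type, ":", hits))
        }
      }
      if (length(tags)) {
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = mi, target_id = ti, target_class = target_class,
          evidence_tag = paste(tags, collapse = ";"))
      }
    }
  }
  if (!length(out)) {
    return(interaction_table(data.frame(
      mirna_id = character(0), target_id = character(0),
      target_class = character(0), evidence_tag = character(0))))
  }
  interaction_table(do.call(rbind, out))
}

#' Intersect two interaction tables on (miRNA, target) pairs
#'
#' Used to keep only predicted interactions that also carry experimental
#' (e.g. CLIP-seq) support. Evidence tags from both tables are merged.
#'
#' @param predicted,supported [interaction_table()]s.
#' @return [interaction_table()] restricted to shared pairs.
#' @export
intersect_interactions <- function(predicted, supported) {
  kp <- paste(predicted$mirna_id, predicted$target_id, sep = "\r")
  ks <- paste(supported$mirna_id, supported$target_id, sep = "\r")
  keep <- kp %in% ks
  out <- as.data.frame(predicted)[keep, , drop = FALSE]
  if (nrow(out)) {
    m <- match(paste(out$mirna_id, out$target_id, sep = "\r"), ks)
    out$evidence_tag <- paste(out$evidence_tag, supported$evidence_tag[m],
                              sep = ";")
  }
  interaction_table(out)
}

#' Keep interactions whose endpoints are dysregulated in opposite directions
#'
#' The activity rule of the ceRNA model: a miRNA-target pair is considered
#' active only when both molecules are members of the dysregulated set and
#' their expression moved in opposite directions in resistant cells
#' (miRNA down with target up, or vice versa). Applied to candidate
#' miRNA-lncRNA and miRNA-mRNA tables alike.
#'
#' @param candidates [interaction_table()].
#' @param dys dysregulated set from [intersect_consistent()].
#' @return data frame of active interactions with columns `mirna_id`,
#'   `target_id`, `target_class`, `mirna_direction`, `target_direction`,
#'   `evidence_tag`.
#' @export
filter_active_interactions <- function(candidates, dys) {
  dir <- stats::setNames(dys$direction, dys$molecule_id)
  md <- dir[candidates$mirna_id]
  td <- dir[candidates$target_id]
  keep <- !is.na(md) & !is.na(td) & md != td
  out <- data.frame(
    mirna_id = candidates$mirna_id[keep],
    target_id = candidates$target_id[keep],
    target_class = candidates$target_class[keep],
    mirna_direction = unname(md[keep]),
    target_direction = unname(td[keep]),
    evidence_tag = candidates$evidence_tag[keep])
  rownames(out) <- NULL
  out
}
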