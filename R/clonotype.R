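# Clonotype computation and the subclonal-variant definitions: a clonotype
# is a unique nucleotide rearrangement; the top clonotype is the main
# variant; subclonal variants share the main's V gene and CDR3 length and
# differ by at most two amino acids; switched variants are the same
# rearrangement under a gamma/alpha isotype.

#' Compute clonotypes for one sample and isotype
#'
#' One clonotype per unique nucleotide rearrangement among the productive
#' reads; frequency is read count over the sample's total productive
#' reads. Sorted by count (descending), ties by sequence.
#'
#' @param annot annotation table from [annotate_sequences()].
#' @return data.frame with `clonotype_id`, `sequence`, `read_count`,
#'   `frequency`, `v_call`, `d_call`, `j_call`, `cdr3_aa`, `cdr3`,
#'   `cdr3_regions`, `germline_cdr3`, `v_identity`, `sample_id`,
#'   `isotype`; empty input gives an empty table.
#' @export
compute_clonotypes <- function(annot) {
  p <- annot[annot$productive, , drop = FALSE]
  if (!nrow(p)) {
    out <- p[, c("sequence", "v_call", "d_call", "j_call", "cdr3_aa",
                 "cdr3", "cdr3_regions", "germline_cdr3", "v_identity",
                 "sample_id", "isotype")]
    out$clonotype_id <- character(0)
    out$read_count <- integer(0)
    out$frequency <- numeric(0)
    return(out[, c("clonotype_id", "sequence", "read_count", "frequency",
                   "v_call", "d_call", "j_call", "cdr3_aa", "cdr3",
                   "cdr3_regions", "germline_cdr3", "v_identity",
                   "sample_id", "isotype")])
  }
  agg <- tapply(p$duplicate_count, p$sequence, sum)
  first <- p[match(names(agg), p$sequence), , drop = FALSE]
  total <- sum(p$duplicate_count)
  out <- data.frame(
    sequence = names(agg), read_count = as.integer(agg),
    frequency = as.numeric(agg) / total,
    v_call = first$v_call, d_call = first$d_call, j_call = first$j_call,
    cdr3_aa = first$cdr3_aa, cdr3 = first$cdr3,
    cdr3_regions = first$cdr3_regions, germline_cdr3 = first$germline_cdr3,
    v_identity = first$v_identity,
    sample_id = first$sample_id, isotype = first$isotype,
    stringsAsFactors = FALSE)
  out <- out[order(-out$read_count, out$sequence), , drop = FALSE]
  out$clonotype_id <- sprintf("%s_%s_CT%04d", out$sample_id[1],
                              out$isotype[1], seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("clonotype_id", "sequence", "read_count", "frequency",
          "v_call", "d_call", "j_call", "cdr3_aa", "cdr3", "cdr3_regions",
          "germline_cdr3", "v_identity", "sample_id", "isotype")]
}

#' Identify the main variant
#'
#' The clonotype with the highest read count; an exact tie is resolved to
#' the lexicographically smallest sequence and logged as a warning.
#'
#' @param clonotypes table from [compute_clonotypes()].
#' @return the main clonotype as a one-row data.frame.
#' @export
identify_main_variant <- function(clonotypes) {
  if (!nrow(clonotypes)) stop("empty clonotype table: no main variant")
  top <- clonotypes[clonotypes$read_count == max(clonotypes$read_count), ,
                    drop = FALSE]
  if (nrow(top) > 1) {
    warning("read-count tie for the main variant; picking the ",
            "lexicographically smallest sequence")
    top <- top[order(top$sequence), , drop = FALSE]
  }
  top[1, , drop = FALSE]
}

# Hamming distance between two equal-length amino-acid strings
.aa_hamming <- function(a, b) {
  sum(.chars(a) != .chars(b))
}

#' Assign main / subclonal / background roles
#'
#' A clonotype is subclonal iff it uses the main variant's V gene, has a
#' CDR3 amino-acid sequence of the same length, and differs from the
#' main's CDR3 by at most `max_aa_distance` amino acids (zero differences
#' are allowed: synonymous nucleotide variants). Everything else is
#' background.
#'
#' @param clonotypes table from [compute_clonotypes()].
#' @param main main variant row (default: [identify_main_variant()]).
#' @param max_aa_distance maximum amino-acid difference (default 2).
#' @return the table with `role` and `aa_distance_to_main` columns.
#' @export
find_subclonal_variants <- function(clonotypes, main = NULL,
                                    max_aa_distance = 2) {
  if (is.null(main)) main <- identify_main_variant(clonotypes)
  ct <- clonotypes
  ct$aa_distance_to_main <- NA_integer_
  ct$role <- "background"
  ok <- !is.na(ct$cdr3_aa) & !is.na(ct$v_call) &
    ct$v_call == main$v_call & nchar(ct$cdr3_aa) == nchar(main$cdr3_aa)
  ct$aa_distance_to_main[ok] <- vapply(ct$cdr3_aa[ok], .aa_hamming,
                                       integer(1), b = main$cdr3_aa)
  ct$role[ok & ct$aa_distance_to_main <= max_aa_distance] <- "subclonal"
  ct$role[ct$sequence == main$sequence] <- "main"
  ct
}

#' Apply the read-count cutoff
#'
#' Keeps clonotypes with at least `min_reads` reads (inclusive). With
#' `allow_germline_exception`, a below-cutoff clonotype is retained (and
#' flagged) when every amino acid at which it differs from the main
#' variant restores the germline residue — mirroring the reporting of a
#' 33-read germline-revertant variant below the 66-read cutoff.
#'
#' @param clonotypes table (any columns from the clonotype stage).
#' @param min_reads inclusive cutoff (default 66, the coverage limit for a
#'   2.4% sequencing error).
#' @param allow_germline_exception retain germline-revertant variants.
#' @param main main variant row; required for the exception.
#' @param germline_cdr3_aa germline CDR3 amino-acid reference; defaults to
#'   the translation of the main variant's `germline_cdr3`.
#' @return list with `table` (kept rows, plus a `cutoff_exception`
#'   column) and `discarded` (the dropped rows).
#' @export
apply_read_cutoff <- function(clonotypes, min_reads = 66,
                              allow_germline_exception = FALSE,
                              main = NULL, germline_cdr3_aa = NULL) {
  keep <- clonotypes$read_count >= min_reads
  exception <- rep(FALSE, nrow(clonotypes))
  if (allow_germline_exception && any(!keep)) {
    if (is.null(main)) main <- identify_main_variant(clonotypes)
    if (is.null(germline_cdr3_aa))
      germline_cdr3_aa <- translate_nt(main$germline_cdr3)
    g <- .chars(germline_cdr3_aa)
    m <- .chars(main$cdr3_aa)
    for (i in which(!keep)) {
      v <- clonotypes$cdr3_aa[i]
      if (is.na(v) || nchar(v) != length(m)) next
      vv <- .chars(v)
      diffs <- which(vv != m)
      if (length(diffs) && all(vv[diffs] == g[diffs])) {
        keep[i] <- TRUE
        exception[i] <- TRUE
      }
    }
  }
  out <- clonotypes[keep, , drop = FALSE]
  out$cutoff_exception <- exception[keep]
  list(table = out, discarded = clonotypes[!keep, , drop = FALSE])
}

#' Keep truly unmutated clonotypes
#'
#' Retains clonotypes whose V gene is 100% identical to the germline
#' across FR1-FR3 (mutations within the CDR3 do not count).
#'
#' @param clonotypes clonotype table with a `v_identity` column.
#' @return the truly unmutated subset.
#' @export
filter_truly_unmutated <- function(clonotypes) {
  clonotypes[!is.na(clonotypes$v_identity) & clonotypes$v_identity == 100, ,
             drop = FALSE]
}

#' Link switched (gamma/alpha) variants to the mu repertoire
#'
#' For each mu clonotype, reports switched clonotypes with the identical
#' nucleotide rearrangement (`switched_main` when the mu clonotype is the
#' main variant, else `identical_nt`) and switched clonotypes sharing the
#' same CDR3 amino-acid sequence through different nucleotides
#' (`shared_aa_change`).
#'
#' @param mu_clonotypes mu-isotype clonotype table (with roles).
#' @param switched named list of switched clonotype tables, e.g.
#'   `list(IGG = ..., IGA = ...)`.
#' @return data.frame with `mu_clonotype_id`, `isotype`,
#'   `linked_sequence_id`, `relation`; zero rows when nothing links.
#' @export
link_switched_variants <- function(mu_clonotypes, switched) {
  out <- list()
  main_seq <- if ("role" %in% names(mu_clonotypes))
    mu_clonotypes$sequence[mu_clonotypes$role == "main"][1] else NA_character_
  for (iso in names(switched)) {
    sw <- switched[[iso]]
    if (is.null(sw) || !nrow(sw)) next
    for (i in seq_len(nrow(mu_clonotypes))) {
      mu <- mu_clonotypes[i, ]
      ident <- sw$clonotype_id[sw$sequence == mu$sequence]
      for (id in ident)
        out[[length(out) + 1L]] <- data.frame(
          mu_clonotype_id = mu$clonotype_id, isotype = iso,
          linked_sequence_id = id,
          relation = if (!is.na(main_seq) && mu$sequence == main_seq)
            "switched_main" else "identical_nt",
          stringsAsFactors = FALSE)
      shared <- sw$clonotype_id[!is.na(sw$cdr3_aa) &
                                  sw$cdr3_aa == mu$cdr3_aa &
                                  sw$sequence != mu$sequence]
      for (id in shared)
        out[[length(out) + 1L]] <- data.frame(
          mu_clonotype_id = mu$clonotype_id, isotype = iso,
          linked_sequence_id = id, relation = "shared_aa_change",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(mu_clonotype_id = character(0), isotype = character(0),
                      linked_sequence_id = character(0),
                      relation = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
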