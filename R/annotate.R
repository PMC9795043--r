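# Simplified V(D)J annotation: gap-free V and J assignment, exact-substring
# D assignment, FR1-FR3 germline identity, and CDR3 extraction with
# per-codon region provenance. The aligner is gap-free by design: the
# analysis concerns substitutions only, and length-aberrant variants are
# excluded downstream by the same-CDR3-length rule.

#' Align the best V segment (gap-free)
#'
#' Scores every placement of each V segment inside the read (match +1,
#' mismatch -2, no gaps) and returns the highest-scoring segment; ties are
#' broken by lexicographic segment name. Scores below `min_score_frac`
#' times the segment length yield an unassigned result.
#'
#' @param sequence one nucleotide string.
#' @param db an `ig_germline_db`.
#' @param min_score_frac score floor as a fraction of segment length.
#' @return list with `call` (NA if unassigned), `offset` (0-based read
#'   offset of the segment start), `score`, `n_mismatch`,
#'   `mismatch_ref_pos` (0-based, segment coordinates), `span`, `partial`
#'   and `end` (0-based exclusive read position of the segment end).
#' @export
align_v <- function(sequence, db, min_score_frac = 0.5) {
  .align_best(sequence, db, "V", min_score_frac, from = 0L)
}

#' Align the best J segment (gap-free)
#'
#' Same contract as [align_v()], searched in the read 3' of `from`
#' (normally the V segment end).
#'
#' @inheritParams align_v
#' @param from 0-based read position where the search starts.
#' @export
align_j <- function(sequence, db, from = 0L, min_score_frac = 0.5) {
  .align_best(sequence, db, "J", min_score_frac, from = as.integer(from))
}

.align_best <- function(sequence, db, class, min_score_frac, from = 0L) {
  segs <- db[vapply(db, `[[`, character(1), "segment_class") == class]
  if (!length(segs)) stop("no ", class, " segments in db")
  segs <- segs[order(names(segs))]
  tail_seq <- if (from > 0) substr(sequence, from + 1, nchar(sequence)) else sequence
  best <- NULL
  for (seg in segs) {
    a <- .align_gapfree_cpp(tail_seq, seg$sequence)
    if (is.null(best) || a$score > best$score) {
      best <- a; best$call <- seg$name; best$segment <- seg
    }
  }
  if (best$score < min_score_frac * nchar(best$segment$sequence))
    return(list(call = NA_character_, score = best$score))
  list(call = best$call, offset = from + best$offset, score = best$score,
       n_mismatch = best$n_mismatch,
       mismatch_ref_pos = as.integer(best$mismatch_ref_pos),
       span = best$span, partial = best$partial,
       end = from + best$offset + best$span, segment = best$segment)
}

#' Assign the D segment by longest exact match
#'
#' Finds the longest exact substring shared between the junction (or the
#' `search_start`/`search_end` window of it, normally the stretch between
#' the V end and the J start) and any D segment, requiring at least
#' `min_match` nt. Ties go to the longest match, then the 5'-most match in
#' the junction, then the lexicographically smallest segment name. The D
#' reading frame is derived from the phase of the match within the
#' junction's codon frame. Absence of a D match is a legal outcome
#' (`call = NA`).
#'
#' @param junction_nt in-frame CDR3 nucleotide string.
#' @param db an `ig_germline_db`.
#' @param min_match minimum exact-match length (default 5).
#' @param search_start,search_end 0-based half-open window of the junction
#'   to search (defaults: the whole junction).
#' @return list with `call`, `reading_frame` (1-3), `junction_start`,
#'   `junction_end` (0-based half-open, junction coordinates), `d_start`
#'   (0-based, segment coordinates) and `length`.
#' @export
assign_d <- function(junction_nt, db, min_match = 5,
                     search_start = 0L, search_end = nchar(junction_nt)) {
  segs <- db[vapply(db, `[[`, character(1), "segment_class") == "D"]
  segs <- segs[order(names(segs))]
  window <- substr(junction_nt, search_start + 1, search_end)
  best <- NULL
  for (seg in segs) {
    r <- .lcs_cpp(window, seg$sequence)
    if (r[1] < min_match) next
    cand <- list(length = r[1], junction_start = search_start + r[2],
                 d_start = r[3], call = seg$name)
    if (is.null(best) ||
        cand$length > best$length ||
        (cand$length == best$length && cand$junction_start < best$junction_start))
      best <- cand
  }
  if (is.null(best))
    return(list(call = NA_character_, reading_frame = NA_integer_,
                junction_start = NA_integer_, junction_end = NA_integer_,
                d_start = NA_integer_, length = 0L))
  frame <- ((best$d_start - best$junction_start) %% 3L) + 1L
  list(call = best$call, reading_frame = frame,
       junction_start = best$junction_start,
       junction_end = best$junction_start + best$length,
       d_start = best$d_start, length = best$length)
}

#' Germline identity over FR1-FR3
#'
#' Percent identity of the aligned V counting only positions inside the
#' segment's FR1..FR3 bounds; mismatches 3' of FR3 (the junction tail)
#' never reduce it. Alignments that do not reach the FR3 end are flagged
#' incomplete (identity `NA`) and are excluded downstream.
#'
#' @param v_aln result of [align_v()].
#' @return list with `identity` (percent, `NA` if incomplete) and
#'   `complete`.
#' @export
compute_v_identity <- function(v_aln) {
  if (is.na(v_aln$call)) return(list(identity = NA_real_, complete = FALSE))
  seg <- v_aln$segment
  fr1_start <- seg$regions$fr1[1]
  fr3_end <- seg$regions$fr3[2]
  if (v_aln$span < fr3_end)
    return(list(identity = NA_real_, complete = FALSE))
  counted <- fr3_end - fr1_start
  mm <- sum(v_aln$mismatch_ref_pos >= fr1_start &
              v_aln$mismatch_ref_pos < fr3_end)
  list(identity = 100 * (counted - mm) / counted, complete = TRUE)
}

#' Extract the CDR3 with per-codon region provenance
#'
#' Delimits the CDR3 from the codon after the conserved FR3 cysteine to
#' the codon before the J tryptophan, labels every CDR3 nucleotide with
#' its origin (V tail, N1, D, N2, J), assigns each codon an encoding
#' region by nucleotide majority (ties to the 5'-most contributing
#' region), and reconstructs the germline CDR3 reference: germline bases
#' at V/D/J-covered positions, the observed bases at N positions (no
#' germline exists there). Junctions whose length is not divisible by 3
#' are retained with `productive = FALSE`.
#'
#' @param sequence the read.
#' @param v_aln,j_aln results of [align_v()] / [align_j()].
#' @param db an `ig_germline_db` (for D assignment).
#' @param min_d_match minimum D match length, see [assign_d()].
#' @return list with `cdr3_nt`, `cdr3_aa`, `junction_nt` (C104..W118
#'   inclusive), `productive`, `regions` (per 1-based CDR3 codon, one of
#'   V/N1/D/N2/J), `nt_regions`, `germline_cdr3_nt`, `germline_cdr3_aa`,
#'   `d` (the [assign_d()] result), `cdr3_start`/`cdr3_end` (0-based read
#'   coordinates).
#' @export
extract_cdr3 <- function(sequence, v_aln, j_aln, db, min_d_match = 5) {
  if (is.na(v_aln$call) || is.na(j_aln$call))
    stop("V and J must both be assigned before CDR3 extraction")
  vseg <- v_aln$segment; jseg <- j_aln$segment
  fr3_end <- vseg$regions$fr3[2]
  cdr3_start <- v_aln$offset + fr3_end
  cdr3_end <- j_aln$offset + jseg$fr4_start
  len <- cdr3_end - cdr3_start
  if (len <= 0) stop("J aligned 5' of the V FR3 end; no CDR3 window")
  cdr3_nt <- substr(sequence, cdr3_start + 1, cdr3_end)
  in_frame <- len %% 3L == 0L
  cdr3_aa <- if (in_frame) translate_nt(cdr3_nt) else NA_character_
  productive <- in_frame && !grepl("*", cdr3_aa, fixed = TRUE)

  v_cov <- max(0L, min(v_aln$end, cdr3_end) - cdr3_start)   # V tail inside CDR3
  j_cov <- max(0L, cdr3_end - max(j_aln$offset, cdr3_start))
  mid_start <- v_cov                       # junction coords, 0-based
  mid_end <- len - j_cov
  d <- assign_d(cdr3_nt, db, min_match = min_d_match,
                search_start = mid_start, search_end = mid_end)

  nt_regions <- rep("N1", len)
  if (v_cov > 0) nt_regions[seq_len(v_cov)] <- "V"
  if (j_cov > 0) nt_regions[(len - j_cov + 1):len] <- "J"
  if (!is.na(d$call)) {
    nt_regions[(d$junction_start + 1):d$junction_end] <- "D"
    if (d$junction_end < mid_end)
      nt_regions[(d$junction_end + 1):mid_end] <- "N2"
  }

  germ <- .chars(cdr3_nt)
  if (v_cov > 0)
    germ[seq_len(v_cov)] <- .chars(substr(vseg$sequence, fr3_end + 1,
                                          fr3_end + v_cov))
  if (j_cov > 0)
    germ[(len - j_cov + 1):len] <-
      .chars(substr(jseg$sequence, jseg$fr4_start - j_cov + 1,
                    jseg$fr4_start))
  germline_cdr3_nt <- paste(germ, collapse = "")

  regions <- if (in_frame) {
    vapply(seq_len(len / 3L), function(i)
      .codon_region(nt_regions[(3L * i - 2L):(3L * i)]), character(1))
  } else character(0)

  junction_nt <- substr(sequence, cdr3_start - 3 + 1, cdr3_end + 3)
  list(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa, junction_nt = junction_nt,
       productive = productive, regions = regions, nt_regions = nt_regions,
       germline_cdr3_nt = germline_cdr3_nt,
       germline_cdr3_aa = if (in_frame) translate_nt(germline_cdr3_nt) else NA_character_,
       d = d, cdr3_start = cdr3_start, cdr3_end = cdr3_end)
}

#' Annotate a set of (merged) sequences
#'
#' Runs V alignment, FR1-FR3 identity, J alignment, D assignment and CDR3
#' extraction on each unique sequence and returns an AIRR-style
#' rearrangement table. Reads whose V or J cannot be assigned, or whose V
#' alignment does not reach the FR3 end, are reported with
#' `productive = FALSE` and `v_call`/`j_call` of `NA`.
#'
#' @param sequences character vector of nucleotide sequences.
#' @param db an `ig_germline_db`.
#' @param counts optional read multiplicities (default 1 each); duplicate
#'   sequences are collapsed and their counts summed.
#' @param sample_id,isotype labels carried into the table.
#' @param min_d_match,min_score_frac see [assign_d()], [align_v()].
#' @return data.frame with one row per unique sequence: `sequence_id`,
#'   `sequence`, `duplicate_count`, `v_call`, `d_call`, `j_call`,
#'   `d_frame`, `v_identity`, `v_complete`, `junction`, `cdr3`,
#'   `cdr3_aa`, `cdr3_regions` (comma-separated per-codon labels),
#'   `germline_cdr3`, `productive`, `sample_id`, `isotype`.
#' @export
annotate_sequences <- function(sequences, db, counts = NULL,
                               sample_id = "S1", isotype = "IGM",
                               min_d_match = 5, min_score_frac = 0.5) {
  if (is.null(counts)) counts <- rep(1L, length(sequences))
  stopifnot(length(counts) == length(sequences))
  uniq <- unique(sequences)
  cnt <- vapply(split(counts, factor(sequences, levels = uniq)), sum,
                numeric(1))
  n <- length(uniq)
  v_call <- d_call <- j_call <- junction <- cdr3 <- cdr3_aa <-
    cdr3_regions <- germline_cdr3 <- rep(NA_character_, n)
  d_frame <- rep(NA_integer_, n)
  v_identity <- rep(NA_real_, n)
  v_complete <- productive <- rep(FALSE, n)
  for (i in seq_len(n)) {
    s <- uniq[i]
    v <- align_v(s, db, min_score_frac)
    if (is.na(v$call)) next
    idy <- compute_v_identity(v)
    v_call[i] <- v$call
    v_identity[i] <- idy$identity
    v_complete[i] <- idy$complete
    if (!idy$complete) next
    j <- align_j(s, db, from = v$end, min_score_frac = min_score_frac)
    if (is.na(j$call)) next
    j_call[i] <- j$call
    cd <- extract_cdr3(s, v, j, db, min_d_match)
    d_call[i] <- cd$d$call
    d_frame[i] <- cd$d$reading_frame
    junction[i] <- cd$junction_nt
    cdr3[i] <- cd$cdr3_nt
    cdr3_aa[i] <- cd$cdr3_aa
    cdr3_regions[i] <- paste(cd$regions, collapse = ",")
    germline_cdr3[i] <- cd$germline_cdr3_nt
    productive[i] <- cd$productive
  }
  data.frame(
    sequence_id = sprintf("%s_seq%05d", sample_id, seq_len(n)),
    sequence = uniq, duplicate_count = as.integer(cnt),
    v_call = v_call, d_call = d_call, j_call = j_call, d_frame = d_frame,
    v_identity = v_identity, v_complete = v_complete, junction = junction,
    cdr3 = cdr3, cdr3_aa = cdr3_aa, cdr3_regions = cdr3_regions,
    germline_cdr3 = germline_cdr3, productive = productive,
    sample_id = sample_id, isotype = isotype, stringsAsFactors = FALSE)
}

#' Write an AIRR-style rearrangement TSV
#'
#' @param annot table from [annotate_sequences()].
#' @param path output path.
#' @export
write_airr <- function(annot, path) {
  .write_tsv(annot, path)
}
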