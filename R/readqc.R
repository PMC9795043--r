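# Read-level quality control: length/mean-quality filters, paired-end
# merging, and the CDR3-window filter anchored on the FR4 G-X-G motif.

#' Merge paired-end reads
#'
#' For each pair, reverse-complements read 2 and scans every placement with
#' overlap >= `min_overlap`; among placements whose overlap mismatch
#' fraction is <= `max_mismatch_frac` the one with the fewest mismatches
#' wins (ties: longer overlap, then 5'-most placement). Disagreeing overlap
#' bases resolve to the higher-quality call (read 1 wins equal-quality
#' ties) and the merged quality is the per-base maximum. Pairs with no
#' valid placement are rejected, not errors.
#'
#' @param r1,q1 read-1 sequences and Phred+33 quality strings.
#' @param r2,q2 read-2 (reverse-strand) sequences and qualities.
#' @param min_overlap minimum overlap length (default 30).
#' @param max_mismatch_frac maximum mismatch fraction in the overlap.
#' @return data.frame with `merged` (logical), `sequence`, `quality`,
#'   `overlap` (NA for rejected pairs).
#' @export
merge_pairs <- function(r1, q1, r2, q2, min_overlap = 30,
                        max_mismatch_frac = 0.1) {
  stopifnot(length(r1) == length(r2), length(r1) == length(q1),
            length(r2) == length(q2))
  out <- .merge_pairs_cpp(r1, q1, r2, q2, as.integer(min_overlap),
                          max_mismatch_frac)
  data.frame(merged = out$merged, sequence = out$sequence,
             quality = out$quality, overlap = out$overlap,
             stringsAsFactors = FALSE)
}

#' Length and mean-quality filters
#'
#' @param sequence,quality sequences and Phred+33 quality strings.
#' @param min_len,max_len inclusive length bounds.
#' @param min_mean_q inclusive minimum mean Phred score.
#' @return data.frame with `pass` and `reason` (`"pass"`, `"too_short"`,
#'   `"too_long"` or `"low_mean_q"`; the first failing reason is reported).
#' @export
basic_filters <- function(sequence, quality, min_len = 200, max_len = 350,
                          min_mean_q = 25) {
  len <- nchar(sequence)
  meanq <- .mean_phred_cpp(quality)
  reason <- rep("pass", length(sequence))
  reason[meanq < min_mean_q] <- "low_mean_q"
  reason[len > max_len] <- "too_long"
  reason[len < min_len] <- "too_short"
  data.frame(pass = reason == "pass", reason = reason,
             stringsAsFactors = FALSE)
}

# locate the FR4 anchor: the W-G-x-G amino-acid motif, searched in all
# three frames; returns the 1-based nt position of the first base of the
# motif's first G codon (the codon after the W), rightmost hit wins
.gxg_anchor <- function(sequence) {
  n <- length(sequence)
  best <- rep(NA_integer_, n)
  for (frame in 0:2) {
    L <- nchar(sequence)
    keep <- L - frame >= 12L
    aa <- rep(NA_character_, n)
    if (any(keep)) {
      sub <- substr(sequence[keep], frame + 1L,
                    frame + ((nchar(sequence[keep]) - frame) %/% 3L) * 3L)
      aa[keep] <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(sub), if.fuzzy.codon = "X"))
    }
    # rightmost W-G-x-G occurrence in this frame
    hits <- gregexpr("(?=WG.G)", aa, perl = TRUE)
    pos <- vapply(hits, function(h) {
      h <- as.integer(h)
      if (length(h) == 0 || h[1] == -1) NA_integer_ else h[length(h)]
    }, integer(1))
    nt <- frame + (pos - 1L) * 3L + 3L + 1L  # first base of the G after W
    upd <- !is.na(nt) & (is.na(best) | nt > best)
    best[upd] <- nt[upd]
  }
  best
}

#' CDR3-window quality filter
#'
#' Locates the FR4 G-X-G anchor (the last three residues of the conserved
#' W-G-x-G motif, searched across all three frames; rightmost hit) and
#' requires every base in a window upstream of the anchor to reach
#' `min_q`. The default reading treats "the 30-45 nucleotide stretch ahead
#' of the motif" as the closed offset interval \[-45, -30\] relative to
#' the first base of the motif's first G codon (`mode = "interval"`);
#' `mode = "stretch"` instead checks the whole contiguous stretch
#' \[-45, -1\]. Reads without the anchor fail with reason `"no_anchor"`.
#'
#' @param sequence,quality merged sequences and Phred+33 qualities.
#' @param window_near,window_far window bounds in nt upstream of the
#'   anchor (defaults 30 and 45).
#' @param min_q inclusive minimum Phred score inside the window.
#' @param mode `"interval"` (default) or `"stretch"`; see above.
#' @return data.frame with `pass`, `reason` (`"pass"`, `"low_q_window"`,
#'   `"no_anchor"`) and `anchor` (1-based nt position or NA).
#' @export
cdr3_window_filter <- function(sequence, quality, window_near = 30,
                               window_far = 45, min_q = 30,
                               mode = c("interval", "stretch")) {
  mode <- match.arg(mode)
  anchor <- .gxg_anchor(sequence)
  from <- if (mode == "interval") anchor - window_far else anchor - window_far
  to <- if (mode == "interval") anchor - window_near else anchor - 1L
  from <- pmax(from, 1L)
  minq <- .min_phred_cpp(quality, ifelse(is.na(anchor), 1L, from),
                         ifelse(is.na(anchor), 1L, to))
  reason <- rep("pass", length(sequence))
  reason[!is.na(anchor) & minq < min_q] <- "low_q_window"
  reason[is.na(anchor)] <- "no_anchor"
  data.frame(pass = reason == "pass", reason = reason, anchor = anchor,
             stringsAsFactors = FALSE)
}

#' Run the full read-QC stage on one sample
#'
#' Applies, in order: per-mate length/mean-quality filters, paired-end
#' merging, merged-read length/quality filters, and the CDR3-window
#' filter. Returns the surviving merged reads plus a per-stage accounting
#' in which every input pair appears in exactly one outcome tally.
#'
#' @param sim an `ig_simulation`, or a list with `r1`, `q1`, `r2`, `q2`.
#' @param raw_min_len,raw_max_len,raw_min_mean_q pre-merge filters.
#' @param merged_min_len,merged_max_len,merged_min_mean_q post-merge
#'   filters.
#' @param min_overlap,max_mismatch_frac merging parameters.
#' @param window_near,window_far,window_min_q,window_mode CDR3-window
#'   filter parameters (see [cdr3_window_filter()]).
#' @return list with `reads` (data.frame `sequence`, `quality`) and
#'   `report` (data.frame `stage`, `outcome`, `n`).
#' @export
qc_sample <- function(sim,
                      raw_min_len = 200, raw_max_len = 350,
                      raw_min_mean_q = 25,
                      min_overlap = 30, max_mismatch_frac = 0.1,
                      merged_min_len = 250, merged_max_len = 450,
                      merged_min_mean_q = 25,
                      window_near = 30, window_far = 45,
                      window_min_q = 30, window_mode = "interval") {
  n0 <- length(sim$r1)
  f1 <- basic_filters(sim$r1, sim$q1, raw_min_len, raw_max_len, raw_min_mean_q)
  f2 <- basic_filters(sim$r2, sim$q2, raw_min_len, raw_max_len, raw_min_mean_q)
  raw_ok <- f1$pass & f2$pass
  report <- data.frame(stage = "raw_filter",
                       outcome = c("pass", "fail"),
                       n = c(sum(raw_ok), sum(!raw_ok)))

  # dereplicate identical pairs before the expensive merge
  key <- paste(sim$r1, sim$q1, sim$r2, sim$q2, sep = "\r")[raw_ok]
  uk <- unique(key)
  ki <- match(key, uk)
  first <- match(seq_along(uk), ki)
  idx <- which(raw_ok)[first]
  m <- merge_pairs(sim$r1[idx], sim$q1[idx], sim$r2[idx], sim$q2[idx],
                   min_overlap, max_mismatch_frac)
  merged_ok <- m$merged[ki]
  report <- rbind(report, data.frame(
    stage = "merge", outcome = c("merged", "rejected"),
    n = c(sum(merged_ok), sum(!merged_ok))))

  seqs <- m$sequence[ki]; quals <- m$quality[ki]
  alive <- which(merged_ok)
  f3 <- basic_filters(seqs[alive], quals[alive], merged_min_len,
                      merged_max_len, merged_min_mean_q)
  f4 <- cdr3_window_filter(seqs[alive], quals[alive], window_near,
                           window_far, window_min_q, window_mode)
  keep <- f3$pass & f4$pass
  report <- rbind(report, data.frame(
    stage = "merged_filter",
    outcome = c("pass", "fail_basic", "fail_window"),
    n = c(sum(keep), sum(!f3$pass), sum(f3$pass & !f4$pass))))

  list(reads = data.frame(sequence = seqs[alive][keep],
                          quality = quals[alive][keep],
                          stringsAsFactors = FALSE),
       report = report)
}
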