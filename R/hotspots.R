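# AID hotspot scanning (WRC / GYW / overlapping WGCW) and topological
# classification of mutations relative to hotspots, including hotspots
# created at region junctions. IUPAC semantics: W = A/T, R = A/G, Y = C/T.
# GYW is the reverse-strand presentation of WRC; both are scanned on the
# sense strand, with the deaminated site at the C (WRC) or the G (GYW,
# reflecting the minus-strand C). The both-strand overlapping motif
# (e.g. AGCT) is the canonical WGCW instance.

.hotspot_empty <- function() {
  data.frame(motif_class = character(0), start = integer(0),
             end = integer(0), strand = character(0),
             deaminated_site = integer(0), stringsAsFactors = FALSE)
}

#' Scan a sequence for AID hotspot motifs
#'
#' Reports all occurrences of WRC (plus strand), GYW (the minus-strand
#' WRC seen on the sense strand) and the 4-nt overlapping WGCW motif.
#' Overlapping hits are all reported. Intervals are 0-based half-open.
#'
#' @param sequence nucleotide string over A/C/G/T.
#' @return data.frame with `motif_class`, `start`, `end`, `strand`
#'   (`+`, `-` or `both`), `deaminated_site` (0-based position of the
#'   deaminated C, or of the G mirroring the minus-strand C), sorted by
#'   `start`.
#' @export
scan_hotspots <- function(sequence) {
  .check_acgt(sequence)
  b <- .chars(toupper(sequence))
  n <- length(b)
  if (n < 3) return(.hotspot_empty())
  W <- b %in% c("A", "T"); R <- b %in% c("A", "G")
  Y <- b %in% c("C", "T"); C <- b == "C"; G <- b == "G"
  i <- seq_len(n - 2)
  wrc <- which(W[i] & R[i + 1] & C[i + 2])
  gyw <- which(G[i] & Y[i + 1] & W[i + 2])
  out <- rbind(
    if (length(wrc)) data.frame(motif_class = "WRC", start = wrc - 1L,
                                end = wrc + 2L, strand = "+",
                                deaminated_site = wrc + 1L,
                                stringsAsFactors = FALSE),
    if (length(gyw)) data.frame(motif_class = "GYW", start = gyw - 1L,
                                end = gyw + 2L, strand = "-",
                                deaminated_site = gyw - 1L,
                                stringsAsFactors = FALSE))
  if (n >= 4) {
    j <- seq_len(n - 3)
    wgcw <- which(W[j] & G[j + 1] & C[j + 2] & W[j + 3])
    out <- rbind(out,
      if (length(wgcw)) data.frame(motif_class = "WGCW", start = wgcw - 1L,
                                   end = wgcw + 3L, strand = "both",
                                   deaminated_site = wgcw + 1L,
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out)) return(.hotspot_empty())
  out <- out[order(out$start, out$motif_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a mutation's topology relative to AID hotspots
#'
#' `canonical_AID` when the mutated base is the deaminated site of a hit
#' (the C of a WRC, the G of a GYW, or either central base of a WGCW);
#' otherwise `adjacent_AT_noncanonical` when the mutated (germline) base
#' is an A or T within `proximity` nt of a hit interval (the signature of
#' non-canonical, mismatch-repair-driven SHM); otherwise `unassociated`.
#' The nearest hit and its distance (0 = inside) are always reported.
#'
#' @param nt_position 0-based position of the mutated base on `sequence`.
#' @param ref_base the germline base at that position.
#' @param sequence the germline sequence context to scan.
#' @param hits optional pre-computed [scan_hotspots()] table.
#' @param proximity adjacency threshold in nt (default 2).
#' @return list with `mechanism_class`, `distance` (NA when no hit
#'   exists), `nearest_motif`, `nearest_start`.
#' @export
classify_mutation_topology <- function(nt_position, ref_base, sequence,
                                       hits = NULL, proximity = 2) {
  if (is.null(hits)) hits <- scan_hotspots(sequence)
  if (!nrow(hits))
    return(list(mechanism_class = "unassociated", distance = NA_real_,
                nearest_motif = NA_character_, nearest_start = NA_integer_))
  d <- pmax(0, hits$start - nt_position, nt_position - (hits$end - 1L))
  # deaminated sites of a WGCW: both central bases
  dea <- nt_position == hits$deaminated_site |
    (hits$motif_class == "WGCW" & nt_position == hits$deaminated_site - 1L)
  nearest <- which.min(d)
  cls <- if (any(dea)) "canonical_AID"
  else if (toupper(ref_base) %in% c("A", "T") && min(d) <= proximity)
    "adjacent_AT_noncanonical"
  else "unassociated"
  if (cls == "canonical_AID") nearest <- which(dea)[1]
  list(mechanism_class = cls, distance = d[nearest],
       nearest_motif = hits$motif_class[nearest],
       nearest_start = hits$start[nearest])
}

#' Detect junction-created hotspots
#'
#' Reports hotspot hits whose interval spans at least two regions of the
#' rearrangement (e.g. the N1/D boundary) and whose motif sequence is
#' absent from the direct concatenation of the germline-encoded regions
#' (the sequence the rearrangement would have without non-templated
#' nucleotides and without mutations) — i.e. motifs that exist only
#' because of the junction. Motifs fully inside one germline region are
#' germline-encoded and never flagged.
#'
#' @param sequence the (possibly mutated) rearrangement window to scan.
#' @param nt_regions per-nucleotide region labels of `sequence` (e.g.
#'   V/N1/D/N2/J).
#' @param germline_regions named list of the germline-encoded regions'
#'   sequences, in 5'-to-3' order (e.g. `list(V = ..., D = ..., J =
#'   ...)`); their direct concatenation is the pure-germline comparator.
#' @return the [scan_hotspots()] table subset to junction-created hits,
#'   with a `junction` column naming the spanned regions.
#' @export
detect_junction_created_hotspots <- function(sequence, nt_regions,
                                             germline_regions) {
  stopifnot(nchar(sequence) == length(nt_regions))
  hits <- scan_hotspots(sequence)
  if (!nrow(hits)) {
    hits$junction <- character(0)
    return(hits)
  }
  germ <- paste(unlist(germline_regions), collapse = "")
  spans <- vapply(seq_len(nrow(hits)), function(i) {
    regs <- unique(nt_regions[(hits$start[i] + 1):hits$end[i]])
    paste(regs, collapse = "-")
  }, character(1))
  motif_seq <- substring(sequence, hits$start + 1, hits$end)
  created <- grepl("-", spans, fixed = TRUE) &
    !vapply(motif_seq, grepl, logical(1), x = germ, fixed = TRUE)
  out <- hits[created, , drop = FALSE]
  out$junction <- spans[created]
  rownames(out) <- NULL
  out
}

#' Cohort-level topology summary
#'
#' Per recurrent substitution: the fraction of samples carrying it,
#' whether it is clonal or subclonal, and the associated hotspot
#' mechanism — the node table of a topology graph.
#'
#' @param calls event table from [profile_substitutions()] (pooled across
#'   samples) augmented with `mechanism_class`, `nearest_motif` columns
#'   (see [classify_mutation_topology()]).
#' @param cohort_size number of samples.
#' @return data.frame with `cdr3_position`, `ref_aa`, `obs_aa`,
#'   `fraction`, `clonal`, `mechanism_class`, `nearest_motif`.
#' @export
topology_summary <- function(calls, cohort_size) {
  calls <- calls[!calls$synonymous, , drop = FALSE]
  if (!nrow(calls))
    return(data.frame(cdr3_position = integer(0), ref_aa = character(0),
                      obs_aa = character(0), fraction = numeric(0),
                      clonal = logical(0), mechanism_class = character(0),
                      nearest_motif = character(0), stringsAsFactors = FALSE))
  key <- paste(calls$cdr3_position, calls$ref_aa, calls$obs_aa, sep = "|")
  out <- do.call(rbind, lapply(split(calls, key), function(g) {
    data.frame(cdr3_position = g$cdr3_position[1], ref_aa = g$ref_aa[1],
               obs_aa = g$obs_aa[1],
               fraction = length(unique(g$sample_id)) / cohort_size,
               clonal = any(g$clonal),
               mechanism_class = names(sort(table(g$mechanism_class),
                                            decreasing = TRUE))[1],
               nearest_motif = names(sort(table(g$nearest_motif),
                                          decreasing = TRUE))[1],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$cdr3_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
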