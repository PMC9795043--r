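# Germline segment model, region coordinate conventions and the two
# stereotyped archetypes every other stage consumes.
#
# Conventions: nucleotide intervals are 0-based half-open; the CDR3 runs
# from the codon after the conserved FR3 cysteine to the codon before the
# J-region conserved tryptophan, and CDR3 amino-acid positions are 1-based.

#' Construct a germline gene segment
#'
#' A V, D or J germline segment with the coordinate metadata the annotator
#' needs: V segments carry half-open FR1/CDR1/FR2/CDR2/FR3 intervals (the
#' sequence 3' of FR3 is the junction-contributing tail), D segments carry
#' their usable reading frames, J segments the offset of the conserved FR4
#' tryptophan codon.
#'
#' @param name segment label.
#' @param sequence nucleotide string over A/C/G/T (uppercased).
#' @param segment_class one of `"V"`, `"D"`, `"J"`.
#' @param regions for V: named list with elements `fr1`, `cdr1`, `fr2`,
#'   `cdr2`, `fr3`, each a length-2 integer vector `c(start, end)`
#'   (0-based, half-open, ordered and disjoint).
#' @param frames for D: integer vector of usable reading frames (1-3).
#' @param fr4_start for J: 0-based offset of the FR4 tryptophan codon.
#' @return an object of class `ig_segment`.
#' @export
ig_segment <- function(name, sequence, segment_class,
                       regions = NULL, frames = NULL, fr4_start = NULL) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("segment '", name, "': empty sequence")
  .check_acgt(sequence, paste0("segment '", name, "'"))
  segment_class <- match.arg(segment_class, c("V", "D", "J"))
  seg <- structure(
    list(name = name, sequence = sequence, segment_class = segment_class,
         regions = regions, frames = frames, fr4_start = fr4_start),
    class = "ig_segment")
  if (segment_class == "V") {
    need <- c("fr1", "cdr1", "fr2", "cdr2", "fr3")
    if (is.null(regions) || !all(need %in% names(regions)))
      stop("V segment '", name, "' lacks region bounds (fr1..fr3)")
    iv <- do.call(rbind, lapply(regions[need], as.integer))
    if (any(iv < 0) || any(iv[, 2] <= iv[, 1]))
      stop("V segment '", name, "': malformed region intervals")
    if (any(diff(as.vector(t(iv))) < 0))
      stop("V segment '", name, "': region intervals out of order or overlapping")
    if (iv["fr3", 2] > nchar(sequence))
      stop("V segment '", name, "': FR3 end exceeds sequence length")
    if (nchar(sequence) - iv["fr3", 2] < 3L)
      stop("V segment '", name, "': fewer than 3 junction-contributing nucleotides after FR3")
    seg$regions <- lapply(regions[need], as.integer)
  }
  if (segment_class == "D") {
    if (is.null(frames) || !all(frames %in% 1:3))
      stop("D segment '", name, "': reading frames must be within 1..3")
    seg$frames <- as.integer(frames)
  }
  if (segment_class == "J") {
    if (is.null(fr4_start) || fr4_start < 0 || fr4_start + 3 > nchar(sequence))
      stop("J segment '", name, "': invalid fr4_start")
    if (substr(sequence, fr4_start + 1, fr4_start + 3) != "TGG")
      stop("J segment '", name, "': fr4_start does not address a TGG (W) codon")
    seg$fr4_start <- as.integer(fr4_start)
  }
  seg
}

#' @export
print.ig_segment <- function(x, ...) {
  cat(sprintf("<ig_segment %s [%s], %d nt>\n", x$name, x$segment_class,
              nchar(x$sequence)))
  invisible(x)
}

#' Load a germline segment database
#'
#' Reads a multi-FASTA of germline V/D/J segments together with a YAML
#' boundary sidecar (segment name -> class and named intervals/offsets) and
#' returns a validated collection. Every V record must have a boundary
#' entry; sequences with non-ACGT characters are rejected.
#'
#' @param fasta_path path to the germline FASTA.
#' @param bounds_path path to the YAML boundary sidecar.
#' @return a named list of [ig_segment] objects, class `ig_germline_db`.
#' @seealso [default_germline_db()] for the packaged synthetic database.
#' @export
read_germline_db <- function(fasta_path, bounds_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  bounds <- yaml::read_yaml(bounds_path)
  segs <- lapply(names(seqs), function(nm) {
    b <- bounds[[nm]]
    if (is.null(b) || is.null(b$class))
      stop("no boundary entry (or class) for segment '", nm, "'")
    cls <- toupper(b$class)
    regions <- if (cls == "V") b[c("fr1", "cdr1", "fr2", "cdr2", "fr3")] else NULL
    if (cls == "V" && any(vapply(regions, is.null, logical(1))))
      stop("missing region boundary entry for V segment '", nm, "'")
    ig_segment(nm, as.character(seqs[[nm]]), cls,
               regions = regions, frames = b$frames, fr4_start = b$fr4_start)
  })
  names(segs) <- names(seqs)
  structure(segs, class = "ig_germline_db")
}

#' @export
print.ig_germline_db <- function(x, ...) {
  cls <- vapply(x, `[[`, character(1), "segment_class")
  cat(sprintf("<ig_germline_db: %d segments (%d V, %d D, %d J)>\n",
              length(x), sum(cls == "V"), sum(cls == "D"), sum(cls == "J")))
  invisible(x)
}

#' Packaged synthetic germline database
#'
#' Loads the synthetic germline segments shipped with the package: a clan
#' I-like V / IGHD6-19-like D / IGHJ4-like J trio for the subset #1
#' archetype and an IGHV1-69-like V / IGHD3-16-like D / IGHJ3-like J trio
#' for subset #6. The sequences are constraint-driven stand-ins, not IMGT
#' alleles; only the stereotype constraints (CDR3 lengths, motif positions,
#' encoding regions) are guaranteed.
#'
#' @return an `ig_germline_db`.
#' @export
default_germline_db <- function() {
  read_germline_db(
    system.file("extdata", "germline_synthetic.fasta", package = "cdr3shm"),
    system.file("extdata", "germline_synthetic_bounds.yaml", package = "cdr3shm"))
}

#' Stereotyped archetype specification
#'
#' Describes how a stereotyped rearrangement is assembled from germline
#' segments: the segment trio, the D reading frame, the non-templated N1/N2
#' insertions and the constraint set the assembled CDR3 must satisfy. The
#' two built-in subsets mirror the major CLL stereotypes: subset #1 (13-aa
#' CDR3, D-encoded QWL at positions 4-6) and subset #6 (21-aa CDR3,
#' D-encoded valine at position 9, J-encoded FDI tail).
#'
#' @param subset `"subset1"` or `"subset6"` for the built-ins, or `"custom"`
#'   with all remaining arguments supplied.
#' @param v_name,d_name,j_name segment labels present in the database.
#' @param d_reading_frame D reading frame (1-3); the archetype uses the D
#'   suffix starting at that frame's first in-frame base.
#' @param n1,n2 non-templated insertions (possibly empty strings).
#' @param cdr3_aa_length expected CDR3 amino-acid length.
#' @param constraints data.frame with columns `position` (1-based CDR3
#'   position), `aa` (expected residue) and `region` (expected encoding
#'   region, one of V/N1/D/N2/J).
#' @return an object of class `ig_archetype_spec`.
#' @export
archetype_spec <- function(subset = c("subset1", "subset6", "custom"),
                           v_name = NULL, d_name = NULL, j_name = NULL,
                           d_reading_frame = 1L, n1 = "", n2 = "",
                           cdr3_aa_length = NULL, constraints = NULL) {
  subset <- match.arg(subset)
  if (subset == "subset1") {
    v_name <- "IGHV1-S1"; d_name <- "IGHD6-19S"; j_name <- "IGHJ4S"
    d_reading_frame <- 1L; n1 <- "GA"; n2 <- "TCTGGTAGTTAT"
    cdr3_aa_length <- 13L
    constraints <- data.frame(
      position = c(2L, 4L, 5L, 6L, 12L),
      aa = c("R", "Q", "W", "L", "D"),
      region = c("V", "D", "D", "D", "J"))
  } else if (subset == "subset6") {
    v_name <- "IGHV1-69S"; d_name <- "IGHD3-16S"; j_name <- "IGHJ3S"
    d_reading_frame <- 2L; n1 <- "TGGC"; n2 <- "CCTCTCTCCGGT"
    cdr3_aa_length <- 21L
    constraints <- data.frame(
      position = c(2L, 9L, 19L, 20L, 21L),
      aa = c("R", "V", "F", "D", "I"),
      region = c("V", "D", "J", "J", "J"))
  } else {
    if (is.null(v_name) || is.null(d_name) || is.null(j_name) ||
        is.null(cdr3_aa_length))
      stop("custom archetype_spec needs v/d/j names and cdr3_aa_length")
    if (is.null(constraints))
      constraints <- data.frame(position = integer(), aa = character(),
                                region = character())
  }
  if (nzchar(n1)) .check_acgt(n1, "n1")
  if (nzchar(n2)) .check_acgt(n2, "n2")
  structure(
    list(subset_id = subset, v_name = v_name, d_name = d_name,
         j_name = j_name, d_reading_frame = as.integer(d_reading_frame),
         n1 = n1, n2 = n2, cdr3_aa_length = as.integer(cdr3_aa_length),
         constraints = constraints),
    class = "ig_archetype_spec")
}

# majority region of one CDR3 codon; ties go to the 5'-most contributing
# region among the tied ones (all-distinct labels tie at 1 each, so the
# first nucleotide's region wins)
.codon_region <- function(labels3) {
  if (labels3[1] == labels3[2] || labels3[1] == labels3[3]) return(labels3[1])
  if (labels3[2] == labels3[3]) return(labels3[2])
  labels3[1]
}

#' Assemble a stereotyped archetype rearrangement
#'
#' Concatenates V (full length, ending in its junction-contributing tail),
#' N1, the D suffix in the requested reading frame, N2 and the full J into
#' one nucleotide rearrangement, labels every nucleotide with its region of
#' origin, delimits the CDR3 (post-cysteine codon to pre-tryptophan codon),
#' assigns each CDR3 codon an encoding region by nucleotide majority
#' (5'-most contributing region on ties) and checks the spec's constraint
#' set. The junction must be in-frame and stop-free.
#'
#' @param spec an [archetype_spec()].
#' @param db an `ig_germline_db` containing the referenced segments.
#' @return an object of class `ig_archetype` with elements `sequence`,
#'   `nt_region` (per-nucleotide label), `cdr3_start` (0-based), `cdr3_nt`,
#'   `cdr3_aa`, `cdr3_region` (per 1-based CDR3 position, one of
#'   V/N1/D/N2/J), `fr4_w_start` and the segment names.
#' @export
build_archetype <- function(spec, db) {
  for (nm in c(spec$v_name, spec$d_name, spec$j_name))
    if (is.null(db[[nm]])) stop("segment '", nm, "' not found in germline db")
  v <- db[[spec$v_name]]; d <- db[[spec$d_name]]; j <- db[[spec$j_name]]
  stopifnot(v$segment_class == "V", d$segment_class == "D",
            j$segment_class == "J")
  if (!spec$d_reading_frame %in% d$frames)
    stop("D segment '", d$name, "' does not allow reading frame ",
         spec$d_reading_frame)

  fr3_end <- v$regions$fr3[2]
  v_tail <- substr(v$sequence, fr3_end + 1, nchar(v$sequence))
  d_used <- substr(d$sequence, spec$d_reading_frame, nchar(d$sequence))
  j_cdr3 <- substr(j$sequence, 1, j$fr4_start)
  cdr3_nt <- paste0(v_tail, spec$n1, d_used, spec$n2, j_cdr3)
  if (nchar(cdr3_nt) %% 3L != 0L)
    stop("assembled junction is out of frame (", nchar(cdr3_nt),
         " nt); revise the archetype spec (N1/N2 lengths or D frame)")
  cdr3_aa <- translate_nt(cdr3_nt)
  if (grepl("*", cdr3_aa, fixed = TRUE))
    stop("assembled junction contains a stop codon; revise the archetype spec")
  if (nchar(cdr3_aa) != spec$cdr3_aa_length)
    stop("assembled CDR3 length ", nchar(cdr3_aa), " != expected ",
         spec$cdr3_aa_length, "; revise the archetype spec")

  sequence <- paste0(v$sequence, spec$n1, d_used, spec$n2, j$sequence)
  vreg <- v$regions
  nt_region <- c(
    rep("FR1", diff(vreg$fr1)), rep("CDR1", diff(vreg$cdr1)),
    rep("FR2", diff(vreg$fr2)), rep("CDR2", diff(vreg$cdr2)),
    rep("FR3", diff(vreg$fr3)),
    rep("V", nchar(v_tail)), rep("N1", nchar(spec$n1)),
    rep("D", nchar(d_used)), rep("N2", nchar(spec$n2)),
    rep("J", j$fr4_start), rep("FR4", nchar(j$sequence) - j$fr4_start))
  stopifnot(length(nt_region) == nchar(sequence))

  cdr3_labels <- nt_region[(fr3_end + 1):(fr3_end + nchar(cdr3_nt))]
  cdr3_region <- vapply(seq_len(nchar(cdr3_nt) / 3L), function(i) {
    .codon_region(cdr3_labels[(3L * i - 2L):(3L * i)])
  }, character(1))

  cons <- spec$constraints
  if (nrow(cons)) {
    aa <- .chars(cdr3_aa)
    for (k in seq_len(nrow(cons))) {
      p <- cons$position[k]
      if (aa[p] != cons$aa[k] || cdr3_region[p] != cons$region[k])
        stop(sprintf(
          "constraint violated at CDR3 position %d: expected %s/%s, got %s/%s; revise the archetype spec",
          p, cons$aa[k], cons$region[k], aa[p], cdr3_region[p]))
    }
  }

  structure(
    list(subset_id = spec$subset_id, sequence = sequence,
         nt_region = nt_region, cdr3_start = fr3_end,
         cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa, cdr3_region = cdr3_region,
         fr4_w_start = nchar(sequence) - (nchar(j$sequence) - j$fr4_start),
         v_name = v$name, d_name = d$name, j_name = j$name,
         d_reading_frame = spec$d_reading_frame, spec = spec),
    class = "ig_archetype")
}

#' @export
print.ig_archetype <- function(x, ...) {
  cat(sprintf("<ig_archetype %s: %s/%s/%s, %d nt>\n", x$subset_id,
              x$v_name, x$d_name, x$j_name, nchar(x$sequence)))
  cat("  CDR3:", x$cdr3_aa, sprintf("(%d aa)\n", nchar(x$cdr3_aa)))
  cat("  region:", paste(x$cdr3_region, collapse = " "), "\n")
  invisible(x)
}
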