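# Paired-end amplicon repertoire simulator with a truth ledger. The
# generator emulates the study conditions: one dominant stereotyped
# clonotype, low-frequency single-nucleotide CDR3 variants, isotype tags,
# uniform per-base substitution error (no indels) and a two-component
# quality model (high-quality baseline with a small fraction of low-quality
# bases).

#' Specify a subclonal variant to inject
#'
#' Addresses one CDR3 codon base of an archetype and the substitution to
#' place there, plus the target read fraction of the resulting variant.
#'
#' @param cdr3_position 1-based CDR3 amino-acid position.
#' @param codon_offset base within the codon, 0-2.
#' @param germline_nt expected germline base at that position (guards
#'   drift between the injection spec and the archetype).
#' @param mutant_nt replacement base.
#' @param target_frequency fraction of reads the variant should receive,
#'   in (0, 1).
#' @param isotypes isotypes carrying the variant (informational tag).
#' @return an object of class `ig_injection_spec`.
#' @export
injection_spec <- function(cdr3_position, codon_offset, germline_nt,
                           mutant_nt, target_frequency,
                           isotypes = "IGM") {
  germline_nt <- toupper(germline_nt); mutant_nt <- toupper(mutant_nt)
  stopifnot(codon_offset %in% 0:2, cdr3_position >= 1,
            germline_nt %in% c("A", "C", "G", "T"),
            mutant_nt %in% c("A", "C", "G", "T"))
  if (mutant_nt == germline_nt) stop("mutant_nt equals germline_nt")
  if (!(target_frequency > 0 && target_frequency < 1))
    stop("target_frequency must be in (0, 1)")
  structure(
    list(cdr3_position = as.integer(cdr3_position),
         codon_offset = as.integer(codon_offset),
         germline_nt = germline_nt, mutant_nt = mutant_nt,
         target_frequency = target_frequency, isotypes = isotypes),
    class = "ig_injection_spec")
}

#' Inject a single-nucleotide variant into an archetype
#'
#' Substitutes exactly one base of the archetype's CDR3 and reports the
#' induced amino-acid change by translating the affected codon. Errors if
#' the addressed base does not match the spec's expected germline base or
#' if the position lies outside the CDR3.
#'
#' @param archetype an `ig_archetype`.
#' @param spec an [injection_spec()].
#' @return list with `sequence` (full variant rearrangement), `nt_index`
#'   (0-based position of the change), `ref_nt`, `alt_nt`, `aa_from`,
#'   `aa_to`, `cdr3_position`, `codon_offset`, `region` and `change_class`.
#' @export
inject_variant <- function(archetype, spec) {
  if (spec$cdr3_position > nchar(archetype$cdr3_aa))
    stop("cdr3_position ", spec$cdr3_position, " outside the ",
         nchar(archetype$cdr3_aa), "-aa CDR3")
  idx0 <- archetype$cdr3_start + (spec$cdr3_position - 1L) * 3L +
    spec$codon_offset
  have <- substr(archetype$sequence, idx0 + 1, idx0 + 1)
  if (have != spec$germline_nt)
    stop("germline base mismatch at CDR3 position ", spec$cdr3_position,
         " offset ", spec$codon_offset, ": archetype has ", have,
         ", spec expects ", spec$germline_nt)
  seq <- archetype$sequence
  substr(seq, idx0 + 1, idx0 + 1) <- spec$mutant_nt
  cstart <- archetype$cdr3_start + (spec$cdr3_position - 1L) * 3L
  codon_from <- substr(archetype$sequence, cstart + 1, cstart + 3)
  codon_to <- substr(seq, cstart + 1, cstart + 3)
  list(sequence = seq, nt_index = idx0,
       ref_nt = spec$germline_nt, alt_nt = spec$mutant_nt,
       aa_from = translate_nt(codon_from), aa_to = translate_nt(codon_to),
       cdr3_position = spec$cdr3_position, codon_offset = spec$codon_offset,
       region = archetype$cdr3_region[spec$cdr3_position],
       change_class = classify_nt_change(spec$germline_nt, spec$mutant_nt))
}

# place per-base substitution errors on a block of reads; operates on the
# concatenated raw bytes for speed
.mutate_reads <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  L <- nchar(reads)
  r <- charToRaw(paste(reads, collapse = ""))
  hit <- which(runif(length(r)) < rate)
  if (length(hit)) {
    bases <- charToRaw("ACGT")
    cur <- match(r[hit], bases)
    r[hit] <- bases[((cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
  }
  ends <- cumsum(L)
  substring(rawToChar(r), ends - L + 1L, ends)
}

.quality_strings <- function(n, L, high_q, low_q, low_q_frac) {
  base <- strrep(intToUtf8(high_q + 33L), L)
  if (low_q_frac <= 0 || n == 0) return(rep(base, n))
  r <- rep(charToRaw(intToUtf8(high_q + 33L)), n * L)
  hit <- which(runif(length(r)) < low_q_frac)
  r[hit] <- charToRaw(intToUtf8(low_q + 33L))
  ends <- seq_len(n) * L
  substring(rawToChar(r), ends - L + 1L, ends)
}

#' Simulate a paired-end amplicon repertoire
#'
#' Draws reads from the archetype and any injected variants by a
#' multinomial at the target frequencies, emits a 2 x `read_length`
#' paired-end run over the full rearrangement (read 1 from the 5' end,
#' read 2 reverse-complemented from the 3' end), applies independent
#' per-base substitution errors at `error_rate` and a two-component Phred
#' quality model, and returns the reads together with a truth ledger.
#' Deterministic under a fixed seed.
#'
#' @param archetype an `ig_archetype`.
#' @param injections list of [injection_spec()] objects.
#' @param n_reads number of read pairs.
#' @param error_rate per-base substitution probability (default 0.024, the
#'   PhiX-calibrated error regime the pipeline's read cutoff is tuned for).
#' @param read_length length of each mate (default 250; 2x250/2x300
#'   chemistry covers the ~320 nt amplicons with ample overlap).
#' @param high_q,low_q,low_q_frac quality model: baseline Phred `high_q`
#'   with a fraction `low_q_frac` of bases at `low_q`.
#' @param background_frac fraction of reads drawn from an unrelated
#'   (scrambled) rearrangement, default 0.
#' @param isotype isotype tag for the sample (`"IGM"`, `"IGG"`, `"IGA"`).
#' @param sample_id sample label carried into downstream tables.
#' @param seed integer seed; the global RNG state is restored on exit.
#' @return an object of class `ig_simulation`: `r1`, `q1`, `r2`, `q2`
#'   (character vectors), `truth` (per-variant ledger with realized
#'   counts), and the generating parameters.
#' @export
simulate_repertoire <- function(archetype, injections = list(),
                                n_reads = 1e5, error_rate = 0.024,
                                read_length = 250, high_q = 37,
                                low_q = 20, low_q_frac = 0.02,
                                background_frac = 0,
                                isotype = "IGM", sample_id = "S1",
                                seed = 1) {
  stopifnot(n_reads > 0, error_rate >= 0, error_rate < 1)
  amp_len <- nchar(archetype$sequence)
  if (2L * read_length < amp_len + 30L)
    stop("read_length ", read_length, " too short: mates cannot overlap ",
         "across the ", amp_len, " nt rearrangement")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  variants <- lapply(injections, inject_variant, archetype = archetype)
  templates <- c(archetype$sequence, vapply(variants, `[[`, character(1), "sequence"))
  freqs <- vapply(injections, `[[`, numeric(1), "target_frequency")
  ids <- c("main", if (length(variants)) sprintf("inj%d", seq_along(variants)))
  probs <- c(1 - sum(freqs) - background_frac, freqs)
  if (background_frac > 0) {
    scram <- paste(sample(.chars(archetype$sequence)), collapse = "")
    templates <- c(templates, scram)
    ids <- c(ids, "background")
    probs <- c(probs, background_frac)
  }
  if (probs[1] <= 0) stop("injected frequencies sum to >= 1")
  counts <- as.vector(rmultinom(1, n_reads, probs))
  assign_idx <- sample(rep.int(seq_along(templates), counts))

  r1_t <- substr(templates, 1, read_length)
  r2_t <- .revcomp(substr(templates, nchar(templates) - read_length + 1,
                          nchar(templates)))
  r1 <- .mutate_reads(r1_t[assign_idx], error_rate)
  r2 <- .mutate_reads(r2_t[assign_idx], error_rate)
  q1 <- .quality_strings(n_reads, read_length, high_q, low_q, low_q_frac)
  q2 <- .quality_strings(n_reads, read_length, high_q, low_q, low_q_frac)

  truth <- data.frame(
    variant_id = ids,
    nt_change = c(NA_character_, vapply(variants, function(v)
      sprintf("%s>%s@%d", tolower(v$ref_nt), tolower(v$alt_nt), v$nt_index),
      character(1)), if (background_frac > 0) NA_character_),
    aa_change = c(NA_character_, vapply(variants, function(v)
      sprintf("%s>%s@CDR3:%d", v$aa_from, v$aa_to, v$cdr3_position),
      character(1)), if (background_frac > 0) NA_character_),
    cdr3_position = c(NA_integer_, vapply(variants, `[[`, integer(1),
                                          "cdr3_position"),
                      if (background_frac > 0) NA_integer_),
    target_frequency = c(probs[1], freqs, if (background_frac > 0) background_frac),
    realized_count = counts,
    realized_frequency = counts / n_reads,
    stringsAsFactors = FALSE)

  structure(
    list(r1 = r1, q1 = q1, r2 = r2, q2 = q2,
         truth = truth, variants = variants,
         n_reads = n_reads, error_rate = error_rate,
         read_length = read_length, seed = seed,
         isotype = isotype, sample_id = sample_id,
         archetype = archetype),
    class = "ig_simulation")
}

#' @export
print.ig_simulation <- function(x, ...) {
  cat(sprintf("<ig_simulation %s [%s]: %d read pairs, error %.3g, seed %d>\n",
              x$sample_id, x$isotype, x$n_reads, x$error_rate, x$seed))
  print(x$truth[, c("variant_id", "aa_change", "target_frequency",
                    "realized_count")])
  invisible(x)
}

#' Write simulated reads as gzipped FASTQ
#'
#' @param sim an `ig_simulation`.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths (R1, R2).
#' @export
write_fastq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("%s:%06d", sim$sample_id, seq_along(sim$r1))
  paths <- file.path(dir, sprintf("%s_%s_R%d.fastq.gz", sim$sample_id,
                                  sim$isotype, 1:2))
  for (i in 1:2) {
    s <- Biostrings::DNAStringSet(if (i == 1) sim$r1 else sim$r2)
    names(s) <- ids
    q <- Biostrings::PhredQuality(if (i == 1) sim$q1 else sim$q2)
    x <- Biostrings::QualityScaledDNAStringSet(s, q)
    Biostrings::writeQualityScaledXStringSet(x, paths[i], compress = TRUE)
  }
  invisible(paths)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (optionally gzipped, Phred+33).
#' @return data.frame with `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x), sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Simulate a multi-sample cohort
#'
#' Generates one repertoire per sample with per-sample RNG streams derived
#' from a single master seed. `carriers` controls which samples carry each
#' injection (default: all samples).
#'
#' @param archetype an `ig_archetype`.
#' @param injections list of [injection_spec()] objects.
#' @param n_samples number of samples; ids are `S01`, `S02`, ...
#' @param carriers optional list (one element per injection) of sample
#'   indices carrying that injection.
#' @param seed master seed.
#' @param ... passed to [simulate_repertoire()].
#' @return list of `ig_simulation` objects.
#' @export
simulate_cohort <- function(archetype, injections = list(), n_samples = 12,
                            carriers = NULL, seed = 1, ...) {
  lapply(seq_len(n_samples), function(i) {
    inj <- injections
    if (!is.null(carriers))
      inj <- injections[vapply(carriers, function(cc) i %in% cc, logical(1))]
    simulate_repertoire(archetype, inj, seed = .derive_seed(seed, i),
                        sample_id = sprintf("S%02d", i), ...)
  })
}
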