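# Shared low-level helpers. Coordinates are 0-based half-open internally;
# every user-facing CDR3 amino-acid position is 1-based.

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' Translate a nucleotide string in frame 1
#'
#' Standard-code translation of an in-frame nucleotide string. Incomplete
#' trailing codons are an error; stop codons translate to `*`.
#'
#' @param nt nucleotide string over A/C/G/T, length divisible by 3.
#' @return single amino-acid string.
#' @keywords internal
translate_nt <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3: ", n)
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  tab <- .codon_table()
  aa <- tab[codons]
  if (anyNA(aa)) stop("untranslatable codon in: ", nt)
  paste(aa, collapse = "")
}

.check_acgt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) stop(what, " contains non-ACGT characters")
  invisible(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.phred_string <- function(scores) {
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}

.phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

# split a string into single characters
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# deterministic per-sample RNG stream derived from one master seed
.derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}

.is_purine <- function(b) b %in% c("A", "G")

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
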