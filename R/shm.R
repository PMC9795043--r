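# Per-position CDR3 substitution profiling, nucleotide-change
# classification, cross-sample recurrence, and the rank-based statistics:
# Kruskal-Wallis omnibus across positions, Wilcoxon rank-sum post-hocs,
# Holm-Bonferroni adjustment, and an exact Mann-Whitney U for small
# between-subset comparisons.

#' Classify a nucleotide change
#'
#' Transition iff both bases are purines or both pyrimidines; otherwise a
#' transversion. Identical bases are an error.
#'
#' @param ref_nt,alt_nt single bases (A/C/G/T, case-insensitive).
#' @return `"transition"` or `"transversion"` (vectorised).
#' @export
classify_nt_change <- function(ref_nt, alt_nt) {
  ref_nt <- toupper(ref_nt); alt_nt <- toupper(alt_nt)
  stopifnot(all(ref_nt %in% c("A", "C", "G", "T")),
            all(alt_nt %in% c("A", "C", "G", "T")))
  if (any(ref_nt == alt_nt)) stop("ref and alt nucleotides are identical")
  ifelse(.is_purine(ref_nt) == .is_purine(alt_nt),
         "transition", "transversion")
}

.empty_events <- function() {
  data.frame(sample_id = character(0), isotype = character(0),
             clonotype_id = character(0),
             cdr3_position = integer(0), codon_offset = integer(0),
             region = character(0), ref_aa = character(0),
             obs_aa = character(0), ref_nt = character(0),
             obs_nt = character(0), change_class = character(0),
             synonymous = logical(0), frequency = numeric(0),
             clonal = logical(0), stringsAsFactors = FALSE)
}

# diff one variant CDR3 against the reference; returns event rows
.diff_cdr3 <- function(ref_nt, ref_aa, var_nt, var_aa, regions, row,
                       clonal = FALSE) {
  rn <- .chars(ref_nt); vn <- .chars(var_nt)
  ra <- .chars(ref_aa); va <- .chars(var_aa)
  d <- which(rn != vn)
  if (!length(d)) return(NULL)
  pos <- ((d - 1L) %/% 3L) + 1L
  data.frame(
    sample_id = row$sample_id, isotype = row$isotype,
    clonotype_id = row$clonotype_id,
    cdr3_position = pos, codon_offset = (d - 1L) %% 3L,
    region = regions[pos],
    ref_aa = ra[pos], obs_aa = va[pos],
    ref_nt = rn[d], obs_nt = vn[d],
    change_class = classify_nt_change(rn[d], vn[d]),
    synonymous = ra[pos] == va[pos],
    frequency = row$frequency, clonal = clonal,
    stringsAsFactors = FALSE)
}

#' Profile CDR3 substitutions of subclonal variants
#'
#' Calls every nucleotide (and induced amino-acid) difference between each
#' subclonal variant's CDR3 and the germline-encoded CDR3 reference. The
#' reference carries germline bases at V/D/J-encoded positions and the
#' main variant's bases at N positions (no germline exists there), so
#' substitutions are only ever called against germline-encoded sequence.
#' With `include_clonal`, differences between the main variant itself and
#' the reference are reported as clonal events. Events from the same
#' variant share its frequency; synonymous nucleotide-only differences
#' are recorded with `synonymous = TRUE`.
#'
#' @param clonotypes role-annotated clonotype table (see
#'   [find_subclonal_variants()]); the main variant's `germline_cdr3` and
#'   `cdr3_regions` define the reference.
#' @param include_clonal also diff the main variant against the germline
#'   reference.
#' @return data.frame of substitution events: `sample_id`, `isotype`,
#'   `clonotype_id`, `cdr3_position` (1-based), `codon_offset`, `region`,
#'   `ref_aa`, `obs_aa`, `ref_nt`, `obs_nt`, `change_class`,
#'   `synonymous`, `frequency`, `clonal`.
#' @export
profile_substitutions <- function(clonotypes, include_clonal = TRUE) {
  main <- clonotypes[clonotypes$role == "main", , drop = FALSE]
  if (nrow(main) != 1) stop("expected exactly one main variant")
  ref_nt <- main$germline_cdr3
  ref_aa <- translate_nt(ref_nt)
  regions <- strsplit(main$cdr3_regions, ",", fixed = TRUE)[[1]]
  subs <- clonotypes[clonotypes$role == "subclonal", , drop = FALSE]
  ev <- list()
  if (include_clonal)
    ev[[1]] <- .diff_cdr3(ref_nt, ref_aa, main$cdr3, main$cdr3_aa, regions,
                          main, clonal = TRUE)
  for (i in seq_len(nrow(subs))) {
    v <- subs[i, ]
    if (nchar(v$cdr3) != nchar(ref_nt))
      stop("variant/main CDR3 length mismatch for ", v$clonotype_id,
           " (subclonal variants must share the main CDR3 length)")
    ev[[length(ev) + 1L]] <- .diff_cdr3(ref_nt, ref_aa, v$cdr3, v$cdr3_aa,
                                        regions, v, clonal = FALSE)
  }
  ev <- ev[!vapply(ev, is.null, logical(1))]
  if (!length(ev)) return(.empty_events())
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Cross-sample recurrence of substitutions
#'
#' Groups non-synonymous subclonal events by (CDR3 position, amino-acid
#' change) and reports, per group, the number and fraction of samples
#' carrying it and the median and range of the variant frequencies.
#'
#' @param events event table from [profile_substitutions()] pooled across
#'   samples.
#' @param cohort_size number of samples in the cohort (denominator of the
#'   fraction).
#' @param min_samples report groups present in at least this many samples.
#' @return data.frame with `cdr3_position`, `ref_aa`, `obs_aa`, `region`,
#'   `n_samples`, `fraction`, `median_frequency`, `min_frequency`,
#'   `max_frequency`.
#' @export
recurrence_report <- function(events, cohort_size, min_samples = 2) {
  ev <- events[!events$synonymous & !events$clonal, , drop = FALSE]
  if (!nrow(ev))
    return(data.frame(cdr3_position = integer(0), ref_aa = character(0),
                      obs_aa = character(0), region = character(0),
                      n_samples = integer(0), fraction = numeric(0),
                      median_frequency = numeric(0),
                      min_frequency = numeric(0), max_frequency = numeric(0)))
  key <- paste(ev$cdr3_position, ev$ref_aa, ev$obs_aa, sep = "|")
  groups <- split(ev, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(cdr3_position = g$cdr3_position[1], ref_aa = g$ref_aa[1],
               obs_aa = g$obs_aa[1], region = g$region[1],
               n_samples = length(unique(g$sample_id)),
               fraction = length(unique(g$sample_id)) / cohort_size,
               median_frequency = stats::median(g$frequency),
               min_frequency = min(g$frequency),
               max_frequency = max(g$frequency),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n_samples >= min_samples, , drop = FALSE]
  out <- out[order(out$cdr3_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down Holm adjustment with monotonicity enforcement, capped at 1.
#' Output order matches input order.
#'
#' @param pvals numeric vector of p-values.
#' @return adjusted p-values.
#' @export
holm_bonferroni <- function(pvals) {
  n <- length(pvals)
  if (!n) return(numeric(0))
  o <- order(pvals)
  adj <- pmin(1, cummax((n - seq_len(n) + 1L) * pvals[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Positional-targeting test across CDR3 positions
#'
#' Kruskal-Wallis omnibus test for differences in per-sample mutation
#' frequencies across CDR3 positions; if the omnibus is significant at
#' `alpha`, each position is compared against the pooled remaining
#' positions with a Wilcoxon rank-sum post-hoc (one-sided "greater" by
#' default: the question is preferential targeting) and the post-hoc
#' family is Holm-Bonferroni adjusted.
#'
#' @param freq numeric matrix of mutation frequencies, samples in rows,
#'   CDR3 positions in columns (column names label positions).
#' @param alpha significance level (default 0.05).
#' @param alternative post-hoc alternative, default `"greater"`.
#' @return list with `omnibus_p`, `posthoc` (data.frame `position`, `p`,
#'   `p_adj`, `flagged`; empty when the omnibus is not significant) and
#'   `alpha`. All-zero input returns `omnibus_p = 1` by convention.
#' @export
positional_targeting_test <- function(freq, alpha = 0.05,
                                      alternative = "greater") {
  freq <- as.matrix(freq)
  if (nrow(freq) < 2 || ncol(freq) < 2)
    stop("need at least 2 samples and 2 positions")
  positions <- colnames(freq)
  if (is.null(positions)) positions <- as.character(seq_len(ncol(freq)))
  empty <- data.frame(position = character(0), p = numeric(0),
                      p_adj = numeric(0), flagged = logical(0))
  if (all(freq == 0))
    return(list(omnibus_p = 1, posthoc = empty, alpha = alpha))
  kw <- stats::kruskal.test(split(as.vector(freq), col(freq)))
  if (is.na(kw$p.value) || kw$p.value >= alpha)
    return(list(omnibus_p = kw$p.value, posthoc = empty, alpha = alpha))
  p <- vapply(seq_len(ncol(freq)), function(j) {
    suppressWarnings(stats::wilcox.test(freq[, j], as.vector(freq[, -j]),
                                        alternative = alternative,
                                        exact = FALSE)$p.value)
  }, numeric(1))
  p_adj <- holm_bonferroni(p)
  list(omnibus_p = kw$p.value,
       posthoc = data.frame(position = positions, p = p, p_adj = p_adj,
                            flagged = p_adj < alpha,
                            stringsAsFactors = FALSE),
       alpha = alpha)
}

#' Mann-Whitney U comparison of subclonal heterogeneity
#'
#' Two-sided Mann-Whitney U test comparing two groups (e.g. subclonal
#' variant counts of two stereotyped subsets). Uses exact enumeration of
#' all group assignments when both groups have at most `exact_limit`
#' observations (ties handled through midranks), and the normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param x,y numeric vectors.
#' @param exact_limit enumerate exactly when `length(x)` and `length(y)`
#'   are both at most this (default 8).
#' @return list with `U` (statistic of the first group), `p` (two-sided)
#'   and `method`.
#' @export
compare_heterogeneity <- function(x, y, exact_limit = 8) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  comb <- c(x, y)
  r <- rank(comb)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_limit && n2 <= exact_limit) {
    idx <- utils::combn(n1 + n2, n1)
    Us <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps)))
    return(list(U = U, p = p, method = "exact enumeration"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(comb)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "normal approximation with tie correction")
}

#' Read-weighted position frequency matrix
#'
#' Per-position amino-acid frequency matrix of the main variant and its
#' subclonal variants, weighted by read count; each position (row) sums
#' to 1. The input to a CDR3 sequence logo.
#'
#' @param clonotypes role-annotated clonotype table; rows with role
#'   `main` or `subclonal` contribute.
#' @return numeric matrix, rows = 1-based CDR3 positions, columns = amino
#'   acids observed.
#' @export
position_frequency_matrix <- function(clonotypes) {
  ct <- clonotypes[clonotypes$role %in% c("main", "subclonal"), ,
                   drop = FALSE]
  if (!nrow(ct)) stop("no main/subclonal clonotypes")
  len <- nchar(ct$cdr3_aa[ct$role == "main"][1])
  aa_mat <- do.call(rbind, strsplit(ct$cdr3_aa, "", fixed = TRUE))
  letters_seen <- sort(unique(as.vector(aa_mat)))
  pfm <- matrix(0, nrow = len, ncol = length(letters_seen),
                dimnames = list(seq_len(len), letters_seen))
  for (i in seq_len(nrow(ct)))
    for (p in seq_len(len))
      pfm[p, aa_mat[i, p]] <- pfm[p, aa_mat[i, p]] + ct$read_count[i]
  sweep(pfm, 1, rowSums(pfm), "/")
}
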