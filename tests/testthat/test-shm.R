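# helper: a role-annotated clonotype table around the subset #1 archetype
shm_table <- function(variant_cdr3s, freqs, counts = NULL) {
  n <- length(variant_cdr3s)
  if (is.null(counts)) counts <- round(freqs * 1e5)
  data.frame(
    clonotype_id = c("MAIN", sprintf("VAR%02d", seq_len(n))),
    sequence = c(fix_a1$sequence, sprintf("VARSEQ%02d", seq_len(n))),
    read_count = as.integer(c(round((1 - sum(freqs)) * 1e5), counts)),
    frequency = c(1 - sum(freqs), freqs),
    v_call = "IGHV1-S1",
    cdr3_aa = vapply(c(fix_a1$cdr3_nt, variant_cdr3s), translate_nt, ""),
    cdr3 = c(fix_a1$cdr3_nt, variant_cdr3s),
    cdr3_regions = paste(fix_a1$cdr3_region, collapse = ","),
    germline_cdr3 = fix_a1$cdr3_nt,
    sample_id = "S1", isotype = "IGM",
    role = c("main", rep("subclonal", n)),
    stringsAsFactors = FALSE)
}

mutate_cdr3 <- function(pos, offset, to, nt = fix_a1$cdr3_nt) {
  i <- (pos - 1) * 3 + offset + 1
  substr(nt, i, i) <- to
  nt
}

test_that("transition/transversion classification partitions all 12 pairs", {
  expect_equal(classify_nt_change("A", "G"), "transition")
  expect_equal(classify_nt_change("T", "G"), "transversion")
  pairs <- expand.grid(ref = c("A", "C", "G", "T"),
                       alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_nt_change(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "transition"), 4L)
  expect_equal(sum(cls == "transversion"), 8L)
  expect_error(classify_nt_change("A", "A"), "identical")
})

test_that("substitution profiling recovers position, change and region", {
  ct <- shm_table(c(mutate_cdr3(2, 0, "G"),     # R>G, V-encoded
                    mutate_cdr3(4, 1, "G"),     # Q>R, D-encoded
                    mutate_cdr3(12, 1, "G")),   # D>G, J-encoded
                  freqs = c(0.0012, 0.0010, 0.0011))
  ev <- profile_substitutions(ct)
  ev <- ev[order(ev$cdr3_position), ]
  expect_equal(ev$cdr3_position, c(2L, 4L, 12L))
  expect_equal(paste0(ev$ref_aa, ">", ev$obs_aa), c("R>G", "Q>R", "D>G"))
  expect_equal(ev$region, c("V", "D", "J"))
  expect_equal(unique(ev$change_class), "transition")
  expect_false(any(ev$synonymous))
  expect_false(any(ev$clonal))
  expect_equal(ev$frequency, c(0.0012, 0.0010, 0.0011))
})

test_that("synonymous and multi-aa variants are profiled correctly", {
  # CTG -> CTC at position 6 is synonymous
  ct <- shm_table(mutate_cdr3(6, 2, "C"), freqs = 0.001)
  ev <- profile_substitutions(ct)
  expect_equal(nrow(ev), 1)
  expect_true(ev$synonymous)
  expect_equal(ev$obs_aa, ev$ref_aa)

  # a two-aa variant yields two events sharing one frequency
  ct2 <- shm_table(mutate_cdr3(12, 1, "G", mutate_cdr3(2, 0, "G")),
                   freqs = 0.002)
  ev2 <- profile_substitutions(ct2)
  expect_equal(nrow(ev2), 2)
  expect_equal(sort(ev2$cdr3_position), c(2L, 12L))
  expect_equal(unique(ev2$frequency), 0.002)

  # a clonal change in the main variant is flagged clonal
  ct3 <- shm_table(character(0), numeric(0))
  ct3$cdr3[1] <- mutate_cdr3(2, 0, "G")
  ct3$cdr3_aa[1] <- translate_nt(ct3$cdr3[1])
  ev3 <- profile_substitutions(ct3)
  expect_true(all(ev3$clonal))
  expect_equal(ev3$cdr3_position, 2L)

  # CDR3 length mismatch is a hard error
  ct4 <- shm_table(substr(fix_a1$cdr3_nt, 1, 36), freqs = 0.001)
  expect_error(profile_substitutions(ct4), "length mismatch")
})

test_that("recurrence aggregates events across samples", {
  one <- function(sid) {
    ev <- profile_substitutions(shm_table(mutate_cdr3(2, 0, "G"), 0.001))
    ev$sample_id <- sid
    ev
  }
  ev <- do.call(rbind, lapply(sprintf("P%02d", 1:12), one))
  rec <- recurrence_report(ev, cohort_size = 12)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$n_samples, 12L)
  expect_equal(rec$fraction, 1)
  expect_equal(rec$median_frequency, 0.001)

  # events in a single sample fall below min_samples
  rec2 <- recurrence_report(one("P1"), cohort_size = 12, min_samples = 2)
  expect_equal(nrow(rec2), 0)

  # 8 of 12 carriers
  ev3 <- do.call(rbind, lapply(sprintf("P%02d", 1:8), one))
  rec3 <- recurrence_report(ev3, cohort_size = 12)
  expect_equal(round(rec3$fraction, 3), 0.667)
})

test_that("Holm-Bonferroni matches the step-down definition and p.adjust", {
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_bonferroni(0.03), 0.03)
  x <- holm_bonferroni(c(0.6, 0.7, 0.8))
  expect_true(all(x <= 1))
  expect_true(all(diff(sort(x)) >= 0))
  set.seed(61)
  for (k in 1:50) {
    p <- runif(sample(1:12, 1))
    expect_equal(holm_bonferroni(p), p.adjust(p, method = "holm"))
  }
  # invariant under permutation of the input order
  p <- runif(8)
  o <- sample(8)
  expect_equal(holm_bonferroni(p)[o], holm_bonferroni(p[o]))
})

test_that("Mann-Whitney comparison is exact for small groups", {
  r <- compare_heterogeneity(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact enumeration")
  # identical multisets give p = 1
  expect_equal(compare_heterogeneity(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # agrees with the independent pair-counting enumeration oracle
  set.seed(62)
  for (k in 1:15) {
    x <- sample(0:6, sample(3:5, 1), TRUE)
    y <- sample(0:6, sample(3:5, 1), TRUE)
    got <- compare_heterogeneity(x, y)
    want <- oracle_mw(x, y)
    expect_equal(got$U, want$U, info = paste("case", k))
    expect_equal(got$p, want$p, info = paste("case", k))
  }
  # the large-sample path matches wilcox.test's corrected normal approximation
  set.seed(63)
  x <- rpois(20, 22); y <- rpois(15, 7)
  got <- compare_heterogeneity(x, y)
  want <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(got$U, unname(want$statistic))
  expect_equal(got$p, want$p.value, tolerance = 1e-10)
})

test_that("positional targeting flags elevated positions only", {
  expect_error(positional_targeting_test(matrix(1, 1, 13)), "at least 2")
  z <- positional_targeting_test(matrix(0, 12, 13))
  expect_equal(z$omnibus_p, 1)
  expect_equal(nrow(z$posthoc), 0)

  set.seed(64)
  freq <- matrix(rlnorm(12 * 13, log(0.001), 0.5), 12, 13,
                 dimnames = list(NULL, 1:13))
  freq[, c(2, 4, 12)] <- freq[, c(2, 4, 12)] * 10
  res <- positional_targeting_test(freq)
  expect_lt(res$omnibus_p, 0.05)
  expect_equal(res$posthoc$position[res$posthoc$flagged],
               c("2", "4", "12"))
})

test_that("the position frequency matrix is read-weighted and normalised", {
  ct <- shm_table(character(0), numeric(0))
  pfm <- position_frequency_matrix(ct)
  expect_true(all(apply(pfm, 1, max) == 1))   # one-hot on main only
  expect_equal(unname(rowSums(pfm)), rep(1, 13))

  ct2 <- shm_table(mutate_cdr3(2, 0, "G"), freqs = 0.001)
  pfm2 <- position_frequency_matrix(ct2)
  expect_equal(unname(pfm2["2", "G"]), 0.001, tolerance = 1e-12)
  expect_equal(unname(rowSums(pfm2)), rep(1, 13))
})
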