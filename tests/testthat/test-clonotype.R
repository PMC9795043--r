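# build a role-ready clonotype table directly (bypassing alignment) for
# definition-level tests
make_ct <- function(cdr3_aas, counts, v_call = "IGHV1-S1",
                    seqs = NULL, cdr3s = NULL) {
  n <- length(cdr3_aas)
  if (is.null(seqs)) seqs <- sprintf("SEQ%03d_%s", seq_len(n), cdr3_aas)
  data.frame(clonotype_id = sprintf("CT%03d", seq_len(n)), sequence = seqs,
             read_count = as.integer(counts),
             frequency = counts / sum(counts),
             v_call = rep(v_call, length.out = n),
             cdr3_aa = cdr3_aas,
             cdr3 = if (is.null(cdr3s)) cdr3_aas else cdr3s,
             stringsAsFactors = FALSE)
}

test_that("clonotypes are unique nucleotide rearrangements", {
  # 100 identical reads -> one clonotype at frequency 1
  ann <- annotate_sequences(rep(fix_a1$sequence, 100), fix_db)
  ct <- compute_clonotypes(ann)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$read_count, 100L)
  expect_equal(ct$frequency, 1)

  # 99 archetype + 1 single-nt variant -> 0.99 / 0.01
  v <- inject_variant(fix_a1, injection_spec(2, 0, "A", "G", 0.01))
  ann <- annotate_sequences(c(rep(fix_a1$sequence, 99), v$sequence), fix_db)
  ct <- compute_clonotypes(ann)
  expect_equal(ct$frequency, c(0.99, 0.01))

  # synonymous nucleotide variants are distinct clonotypes
  syn <- fix_a1$sequence
  # CTG (L, CDR3 pos 6) -> CTC (still L): third base of codon 6
  p <- fix_a1$cdr3_start + 5 * 3 + 2
  expect_equal(substr(syn, p + 1, p + 1), "G")
  substr(syn, p + 1, p + 1) <- "C"
  ann <- annotate_sequences(c(fix_a1$sequence, syn), fix_db)
  ct <- compute_clonotypes(ann)
  expect_equal(nrow(ct), 2)
  expect_equal(unique(ct$cdr3_aa), fix_a1$cdr3_aa)

  expect_equal(nrow(compute_clonotypes(ann[0, ])), 0)
})

test_that("the main variant is the top clonotype, ties warned and resolved", {
  ct <- make_ct(c("AAA", "AAB", "AAC"), c(50, 30, 20))
  expect_equal(identify_main_variant(ct)$cdr3_aa, "AAA")
  ct2 <- make_ct(c("AAB", "AAA"), c(30, 30),
                 seqs = c("TTT", "AAA"))
  expect_warning(m <- identify_main_variant(ct2), "tie")
  expect_equal(m$sequence, "AAA")
  expect_error(identify_main_variant(make_ct(character(0), integer(0))),
               "empty")
})

test_that("subclonal variants share V gene and CDR3 length within 2 aa", {
  ct <- make_ct(
    c("ARGQWLSGSYNDY",    # main
      "ARGRWLSGSYNDY",    # 1 aa
      "GRGRWLSGSYNDY",    # 2 aa
      "GRGRWLSGSYNDG",    # 3 aa -> background
      "ARGQWLSGSYND",     # shorter -> background
      "ARGQWLSGSYNDY"),   # same aa, different nt -> subclonal (distance 0)
    c(1000, 60, 50, 40, 30, 20))
  ct$v_call[3] <- "IGHV1-S1"
  roles <- find_subclonal_variants(ct)
  expect_equal(roles$role,
               c("main", "subclonal", "subclonal", "background",
                 "background", "subclonal"))
  expect_equal(roles$aa_distance_to_main,
               c(0L, 1L, 2L, 3L, NA, 0L))
  # a different V gene is background even with the same CDR3
  ct2 <- make_ct(c("AAAA", "AAAB"), c(10, 5))
  ct2$v_call[2] <- "IGHV1-69S"
  expect_equal(find_subclonal_variants(ct2)$role, c("main", "background"))
})

test_that("role assignment agrees with the pairwise brute-force oracle", {
  set.seed(51)
  for (rep in 1:5) {
    n <- 120
    aas <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "R", "G"), sample(12:14, 1), TRUE), collapse = ""),
      character(1))
    ct <- make_ct(aas, counts = sample(1:500, n, TRUE),
                  v_call = sample(c("V1", "V2"), n, TRUE),
                  seqs = sprintf("S%04d", seq_len(n)))
    main <- identify_main_variant(ct)
    got <- find_subclonal_variants(ct, main)$role
    expect_equal(got, oracle_roles(ct, main))
  }
})

test_that("the read cutoff is inclusive and supports the germline exception", {
  ct <- make_ct(c("AAA", "AAB", "AAC"), c(100, 66, 65))
  cut <- apply_read_cutoff(ct, 66)
  expect_equal(cut$table$read_count, c(100L, 66L))
  expect_equal(cut$discarded$read_count, 65L)

  expect_equal(nrow(apply_read_cutoff(make_ct("AAA", 10), 66)$table), 0)

  # a 33-read variant restoring the germline residue is retained + flagged
  # main carries a clonal V>I at position 2; germline says V
  ct <- make_ct(c("AIA", "AVA"), c(1000, 33),
                cdr3s = c("GCTATTGCT", "GCTGTTGCT"))
  ct$germline_cdr3 <- "GCTGTTGCT"
  cut <- apply_read_cutoff(ct, 66, allow_germline_exception = TRUE)
  expect_equal(nrow(cut$table), 2)
  expect_true(cut$table$cutoff_exception[cut$table$cdr3_aa == "AVA"])
  # without the flag it is discarded
  expect_equal(nrow(apply_read_cutoff(ct, 66)$table), 1)
  # a below-cutoff variant NOT restoring germline is still discarded
  ct2 <- make_ct(c("AIA", "AGA"), c(1000, 33),
                 cdr3s = c("GCTATTGCT", "GCTGGTGCT"))
  ct2$germline_cdr3 <- "GCTGTTGCT"
  expect_equal(nrow(apply_read_cutoff(ct2, 66,
                                      allow_germline_exception = TRUE)$table), 1)
})

test_that("the truly-unmutated filter requires exactly 100% FR1-FR3 identity", {
  ct <- make_ct(c("AAA", "AAB", "AAC"), c(10, 5, 2))
  ct$v_identity <- c(100, 99.6, NA)
  out <- filter_truly_unmutated(ct)
  expect_equal(out$cdr3_aa, "AAA")
})

test_that("clonotype read counts conserve the productive input reads", {
  sim <- simulate_repertoire(fix_a1,
                             list(injection_spec(4, 1, "A", "G", 0.03)),
                             n_reads = 500, error_rate = 0.01, seed = 13)
  qc <- qc_sample(sim)
  ann <- annotate_sequences(qc$reads$sequence, fix_db)
  ct <- compute_clonotypes(ann)
  expect_equal(sum(ct$read_count),
               sum(ann$duplicate_count[ann$productive]))
})

test_that("switched variants link by identical rearrangement or shared change", {
  mu <- make_ct(c("ARG", "ARW"), c(100, 70), seqs = c("AAAA", "CCCC"))
  mu <- find_subclonal_variants(mu, mu[1, ])
  # gamma holds the mu main's exact nt -> switched_main; a synonymous copy
  # of the mu variant -> shared_aa_change
  gamma <- make_ct(c("ARG", "ARW"), c(40, 10), seqs = c("AAAA", "GGGG"))
  link <- link_switched_variants(mu, list(IGG = gamma))
  expect_equal(sort(unique(link$relation)),
               c("shared_aa_change", "switched_main"))
  expect_equal(link$isotype[1], "IGG")
  # identical non-main nt links as identical_nt
  gamma2 <- make_ct("ARW", 10, seqs = "CCCC")
  link2 <- link_switched_variants(mu, list(IGA = gamma2))
  expect_true("identical_nt" %in% link2$relation)
  # empty switched table -> zero links
  expect_equal(nrow(link_switched_variants(mu, list(IGG = gamma[0, ]))), 0)
})
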