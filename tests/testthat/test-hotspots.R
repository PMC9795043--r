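test_that("hotspot scanning handles the canonical examples", {
  h <- scan_hotspots("TGC")
  expect_equal(nrow(h), 1)
  expect_equal(h$motif_class, "WRC")
  expect_equal(c(h$start, h$end, h$deaminated_site), c(0L, 3L, 2L))

  # AGCT decomposes into WRC (AGC), GYW (GCT) and the overlapping WGCW
  h <- scan_hotspots("AGCT")
  expect_setequal(h$motif_class, c("WRC", "GYW", "WGCW"))
  expect_equal(h$start[h$motif_class == "WRC"], 0L)
  expect_equal(h$end[h$motif_class == "WRC"], 3L)
  expect_equal(h$start[h$motif_class == "GYW"], 1L)
  expect_equal(h$end[h$motif_class == "GYW"], 4L)
  expect_equal(h$start[h$motif_class == "WGCW"], 0L)
  expect_equal(h$end[h$motif_class == "WGCW"], 4L)

  expect_equal(nrow(scan_hotspots("AAAA")), 0)
  expect_error(scan_hotspots("ACGN"), "non-ACGT")
})

test_that("the scanner agrees with the sliding-window oracle", {
  set.seed(71)
  for (k in 1:200) {
    s <- rand_dna(sample(3:120, 1))
    got <- scan_hotspots(s)
    want <- oracle_scan(s)
    expect_equal(got[, c("motif_class", "start", "end", "deaminated_site")],
                 want[, c("motif_class", "start", "end", "deaminated_site")],
                 ignore_attr = TRUE, info = paste("case", k, s))
  }
})

test_that("hits are strand-symmetric under reverse complement", {
  set.seed(72)
  for (k in 1:40) {
    s <- rand_dna(80)
    n <- nchar(s)
    fwd <- scan_hotspots(s)
    rev <- scan_hotspots(revcomp(s))
    # mirror the reverse hits back onto forward coordinates
    mirror <- data.frame(
      motif_class = c(WRC = "GYW", GYW = "WRC",
                      WGCW = "WGCW")[rev$motif_class],
      start = n - rev$end, end = n - rev$start,
      stringsAsFactors = FALSE)
    key <- function(d) sort(paste(d$motif_class, d$start, d$end))
    expect_equal(key(fwd), key(mirror))
  }
})

test_that("mutation topology classifies canonical, adjacent and unassociated", {
  # g>a at the G inside an AGCT overlapping motif: canonical AID
  ctx <- "TTTTAGCTTTTT"
  r <- classify_mutation_topology(5, "G", ctx)
  expect_equal(r$mechanism_class, "canonical_AID")
  expect_equal(r$distance, 0)

  # an a/t base 1 nt from a WRC deaminated C: adjacent, non-canonical
  ctx2 <- "GGTGCGAGGGGG"
  #        0123456789  TGC at 2-5, C at 4; A at 6
  r2 <- classify_mutation_topology(6, "A", ctx2)
  expect_equal(r2$mechanism_class, "adjacent_AT_noncanonical")
  expect_true(r2$distance <= 2)

  # far from every hit: unassociated
  ctx3 <- "TGCGGGGGGGGGGGGGGGGGGGGGA"
  r3 <- classify_mutation_topology(24, "A", ctx3)
  expect_equal(r3$mechanism_class, "unassociated")
  expect_gt(r3$distance, 2)

  # a non-a/t base near a hit is not "adjacent"
  r4 <- classify_mutation_topology(6, "G", ctx2)
  expect_equal(r4$mechanism_class, "unassociated")

  # no hits at all
  r5 <- classify_mutation_topology(1, "A", "AAAAAA")
  expect_equal(r5$mechanism_class, "unassociated")
  expect_true(is.na(r5$distance))
})

test_that("the subset archetype mutations land on the expected hotspots", {
  # subset #1: the pos-2 a>g and pos-12 a>g sit at a/t bases adjacent to
  # the TGC (V) and AAC (J) hotspots; the archetype sequence is its own
  # germline context
  for (spec in list(injection_spec(2, 0, "A", "G", 0.01),
                    injection_spec(12, 1, "A", "G", 0.01))) {
    v <- inject_variant(fix_a1, spec)
    r <- classify_mutation_topology(v$nt_index, v$ref_nt, fix_a1$sequence)
    expect_equal(r$mechanism_class, "adjacent_AT_noncanonical")
  }
  # subset #6: the clonal g>a at codon 9 is the deaminated G of a GYW
  v <- inject_variant(fix_a6, injection_spec(9, 0, "G", "A", 0.01))
  r <- classify_mutation_topology(v$nt_index, v$ref_nt, fix_a6$sequence)
  expect_equal(r$mechanism_class, "canonical_AID")
})

test_that("junction-created hotspots span regions and are germline-absent", {
  # N1 ending ...A + D starting GCA... forms AGCA (WGCW/WRC) at the boundary
  seq <- paste0("TTT", "A", "GCATTT")          # V=TTT, N1=A, D=GCATTT
  regions <- c("V", "V", "V", "N1", rep("D", 6))
  hits <- detect_junction_created_hotspots(seq, regions,
                                           list(V = "TTT", D = "GCATTT"))
  expect_true(nrow(hits) >= 1)
  expect_true(any(hits$motif_class == "WGCW"))
  expect_true(all(grepl("-", hits$junction)))

  # the same motif fully inside germline D is never flagged
  seq2 <- paste0("TTT", "G", "AGCATT")         # AGCA inside D
  regions2 <- c("V", "V", "V", "N1", rep("D", 6))
  hits2 <- detect_junction_created_hotspots(seq2, regions2,
                                            list(V = "TTT", D = "AGCATT"))
  expect_false(any(vapply(seq_len(nrow(hits2)), function(i)
    all(regions2[(hits2$start[i] + 1):hits2$end[i]] == "D"), logical(1))))

  # an empty-junction archetype with no boundary motifs yields nothing
  db <- tiny_db()
  a <- build_archetype(archetype_spec("custom", v_name = "Vt", d_name = "Dt",
                                      j_name = "Jt", d_reading_frame = 1L,
                                      n1 = "", n2 = "", cdr3_aa_length = 6L),
                       db)
  cdr3_regions_nt <- a$nt_region[(a$cdr3_start + 1):
                                   (a$cdr3_start + nchar(a$cdr3_nt))]
  h <- detect_junction_created_hotspots(
    a$cdr3_nt, cdr3_regions_nt,
    list(V = db$Vt$sequence, D = db$Dt$sequence, J = db$Jt$sequence))
  expect_equal(nrow(h), 0)
})

test_that("topology summaries aggregate by substitution", {
  ev <- do.call(rbind, lapply(sprintf("P%02d", 1:12), function(sid) {
    data.frame(sample_id = sid, isotype = "IGM", clonotype_id = "V1",
               cdr3_position = 2L, codon_offset = 0L, region = "V",
               ref_aa = "R", obs_aa = "G", ref_nt = "A", obs_nt = "G",
               change_class = "transition", synonymous = FALSE,
               frequency = 0.001, clonal = FALSE,
               mechanism_class = "adjacent_AT_noncanonical",
               nearest_motif = "WRC", stringsAsFactors = FALSE)
  }))
  ts <- topology_summary(ev, cohort_size = 12)
  expect_equal(nrow(ts), 1)
  expect_equal(ts$fraction, 1)
  expect_false(ts$clonal)
  expect_equal(ts$mechanism_class, "adjacent_AT_noncanonical")

  one <- topology_summary(ev[1, ], cohort_size = 1)
  expect_equal(one$fraction, 1)
  expect_equal(nrow(topology_summary(ev[0, ], cohort_size = 12)), 0)
})
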