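# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as plain loops, independent of the package's
# vectorised / compiled implementations they check.

fix_db <- default_germline_db()
fix_a1 <- build_archetype(archetype_spec("subset1"), fix_db)
fix_a6 <- build_archetype(archetype_spec("subset6"), fix_db)

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# exhaustive-offset oracle for paired-end merging, same contract as
# merge_pairs(): minimum mismatches, ties to longer overlap then 5'-most
# placement; overlap bases resolved to the higher-quality call (read 1 on
# ties), quality = max
oracle_merge <- function(s1, q1, s2, q2, min_overlap = 30,
                         max_mismatch_frac = 0.1) {
  s2rc <- revcomp(s2)
  q2r <- paste(rev(strsplit(q2, "")[[1]]), collapse = "")
  l1 <- nchar(s1); l2 <- nchar(s2)
  best <- NULL
  for (s in 0:(l1 - min_overlap)) {
    ov <- min(l1 - s, l2)
    if (ov < min_overlap) next
    a <- strsplit(substr(s1, s + 1, s + ov), "")[[1]]
    b <- strsplit(substr(s2rc, 1, ov), "")[[1]]
    mm <- sum(a != b)
    if (mm > floor(max_mismatch_frac * ov)) next
    if (is.null(best) || mm < best$mm ||
        (mm == best$mm && ov > best$ov)) best <- list(s = s, ov = ov, mm = mm)
  }
  if (is.null(best)) return(list(merged = FALSE))
  s <- best$s; ov <- best$ov
  c1 <- strsplit(s1, "")[[1]]; cq1 <- strsplit(q1, "")[[1]]
  c2 <- strsplit(s2rc, "")[[1]]; cq2 <- strsplit(q2r, "")[[1]]
  seq <- character(s + l2); qual <- character(s + l2)
  for (i in seq_len(s)) { seq[i] <- c1[i]; qual[i] <- cq1[i] }
  for (i in seq_len(ov)) {
    b1 <- c1[s + i]; b2 <- c2[i]
    hi <- utf8ToInt(cq2[i]) > utf8ToInt(cq1[s + i])
    seq[s + i] <- if (b1 == b2 || !hi) b1 else b2
    qual[s + i] <- if (hi) cq2[i] else cq1[s + i]
  }
  if (ov < l2) for (i in (ov + 1):l2) { seq[s + i] <- c2[i]; qual[s + i] <- cq2[i] }
  list(merged = TRUE, sequence = paste(seq, collapse = ""),
       quality = paste(qual, collapse = ""), overlap = ov)
}

# brute-force sliding-window IUPAC matcher for the hotspot scanner
oracle_scan <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  inw <- function(x) x == "A" || x == "T"
  inr <- function(x) x == "A" || x == "G"
  iny <- function(x) x == "C" || x == "T"
  out <- list()
  for (i in seq_len(max(0, length(b) - 2))) {
    if (inw(b[i]) && inr(b[i + 1]) && b[i + 2] == "C")
      out[[length(out) + 1]] <- c("WRC", i - 1, i + 2, i + 1)
    if (b[i] == "G" && iny(b[i + 1]) && inw(b[i + 2]))
      out[[length(out) + 1]] <- c("GYW", i - 1, i + 2, i - 1)
  }
  for (i in seq_len(max(0, length(b) - 3)))
    if (inw(b[i]) && b[i + 1] == "G" && b[i + 2] == "C" && inw(b[i + 3]))
      out[[length(out) + 1]] <- c("WGCW", i - 1, i + 3, i + 1)
  if (!length(out))
    return(data.frame(motif_class = character(0), start = integer(0),
                      end = integer(0), deaminated_site = integer(0)))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("motif_class", "start", "end", "deaminated_site")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$deaminated_site <- as.integer(df$deaminated_site)
  df[order(df$start, df$motif_class), ]
}

# brute-force longest-common-substring oracle with assign_d's tie rules
oracle_lcs <- function(junction, d_seq) {
  best <- list(len = 0L, js = NA_integer_, ds = NA_integer_)
  nj <- nchar(junction); nd <- nchar(d_seq)
  for (len in seq_len(min(nj, nd))) {
    for (js in 0:(nj - len)) {
      sub <- substr(junction, js + 1, js + len)
      ds <- regexpr(sub, d_seq, fixed = TRUE)[1]
      if (ds > 0) {
        cand <- list(len = len, js = js, ds = ds - 1L)
        if (cand$len > best$len ||
            (cand$len == best$len &&
             (cand$js < best$js ||
              (cand$js == best$js && cand$ds < best$ds))))
          best <- cand
      }
    }
  }
  best
}

# pairwise brute-force subclonal-variant oracle
oracle_roles <- function(tab, main, max_aa = 2) {
  roles <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (tab$sequence[i] == main$sequence) { roles[i] <- "main"; next }
    if (is.na(tab$cdr3_aa[i]) || is.na(tab$v_call[i]) ||
        tab$v_call[i] != main$v_call ||
        nchar(tab$cdr3_aa[i]) != nchar(main$cdr3_aa)) {
      roles[i] <- "background"; next
    }
    a <- strsplit(tab$cdr3_aa[i], "")[[1]]
    b <- strsplit(main$cdr3_aa, "")[[1]]
    roles[i] <- if (sum(a != b) <= max_aa) "subclonal" else "background"
  }
  roles
}

# full-enumeration Mann-Whitney oracle: counts pairs (x_i > y_j) + half
# ties per assignment; a computation route distinct from the rank-sum one
oracle_mw <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  comb <- c(x, y)
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) for (bj in b) u <- u + (ai > bj) + 0.5 * (ai == bj)
    u
  }
  U <- u_of(x, y)
  idx <- utils::combn(n1 + n2, n1)
  Us <- apply(idx, 2, function(i) u_of(comb[i], comb[-i]))
  eps <- 1e-9
  list(U = U, p = min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps))))
}

# a tiny custom germline db with empty-junction-compatible segments
tiny_db <- function() {
  v <- ig_segment("Vt", paste0("CACTGTAGGTCCTTTAGG", "GCGAGA"), "V",
                  regions = list(fr1 = c(0, 6), cdr1 = c(6, 9),
                                 fr2 = c(9, 12), cdr2 = c(12, 15),
                                 fr3 = c(15, 18)))
  d <- ig_segment("Dt", "TGGCTG", "D", frames = 1L)
  j <- ig_segment("Jt", "GACTACTGGGGTCAAGGA", "J", fr4_start = 6L)
  structure(list(Vt = v, Dt = d, Jt = j), class = "ig_germline_db")
}
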