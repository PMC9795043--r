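# Pipeline orchestration: simulate (optional) -> QC -> annotate ->
# clonotype -> SHM profile -> hotspot topology -> cohort reports. The
# configuration surfaces every analysis constant as a named key with the
# study defaults (read cutoff 66, CDR3 window Q30 over [-45, -30], <= 2 aa
# subclonal distance, 100% FR1-FR3 identity, alpha = 0.05).

.default_params <- function() {
  list(read_cutoff = 66, max_aa_distance = 2,
       raw_min_len = 200, raw_max_len = 350, raw_min_mean_q = 25,
       merged_min_len = 250, merged_max_len = 450, merged_min_mean_q = 25,
       min_overlap = 30, max_mismatch_frac = 0.1,
       window_near = 30, window_far = 45, window_min_q = 30,
       window_mode = "interval",
       alpha = 0.05, proximity = 2, min_recurrence_samples = 2,
       allow_germline_exception = FALSE,
       frequency_denominator = "productive")
}

#' Assemble (or load) a pipeline configuration
#'
#' @param path YAML file to read, or `NULL` to build from the arguments.
#' @param simulate simulation block (list): `subset`, `n_samples`,
#'   `n_reads`, `error_rate`, `low_q_frac`, `isotypes`, `injections` (list
#'   of lists with `cdr3_position`, `codon_offset`, `germline_nt`,
#'   `mutant_nt`, `target_frequency`), optional `carriers`.
#' @param samples alternatively, a list of FASTQ sample entries
#'   (`sample_id`, `isotype`, `r1`, `r2`).
#' @param germline list with `fasta` and `bounds` paths (`NULL` = the
#'   packaged synthetic database).
#' @param params analysis parameters; unset keys take the study defaults.
#' @param seed master seed.
#' @return a `cdr3shm_config` list.
#' @export
pipeline_config <- function(path = NULL, simulate = NULL, samples = NULL,
                            germline = NULL, params = list(), seed = 1) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path)
  else list(simulate = simulate, samples = samples, germline = germline,
            params = params, seed = seed)
  p <- .default_params()
  p[names(cfg$params)] <- cfg$params
  cfg$params <- p
  if (is.null(cfg$seed)) cfg$seed <- 1
  structure(cfg, class = "cdr3shm_config")
}

.pipeline_db <- function(cfg) {
  g <- cfg$germline
  if (is.null(g) || is.null(g$fasta)) default_germline_db()
  else read_germline_db(g$fasta, g$bounds)
}

# per-sample analysis on QC-surviving merged reads
.process_sample <- function(reads, db, params, sample_id, isotype) {
  annot <- annotate_sequences(reads$sequence, db, sample_id = sample_id,
                              isotype = isotype)
  ct <- compute_clonotypes(annot)
  tu <- filter_truly_unmutated(ct)
  if (identical(params$frequency_denominator, "truly_unmutated") && nrow(tu))
    tu$frequency <- tu$read_count / sum(tu$read_count)
  if (!nrow(tu))
    return(list(annot = annot, clonotypes = tu, events = NULL))
  main <- identify_main_variant(tu)
  cut <- apply_read_cutoff(
    tu, params$read_cutoff,
    allow_germline_exception = isTRUE(params$allow_germline_exception),
    main = main)
  kept <- cut$table
  if (!nrow(kept) || !main$sequence %in% kept$sequence)
    return(list(annot = annot, clonotypes = kept, discarded = cut$discarded,
                events = NULL))
  roles <- find_subclonal_variants(kept, main, params$max_aa_distance)
  events <- profile_substitutions(roles)
  if (nrow(events)) {
    ctx <- .germline_context(main, db)
    hits <- scan_hotspots(ctx$sequence)
    topo <- lapply(seq_len(nrow(events)), function(k) {
      pos0 <- ctx$cdr3_offset + (events$cdr3_position[k] - 1L) * 3L +
        events$codon_offset[k]
      classify_mutation_topology(pos0, events$ref_nt[k], ctx$sequence,
                                 hits = hits, proximity = params$proximity)
    })
    events$mechanism_class <- vapply(topo, `[[`, character(1), "mechanism_class")
    events$hotspot_distance <- vapply(topo, `[[`, numeric(1), "distance")
    events$nearest_motif <- vapply(topo, `[[`, character(1), "nearest_motif")
  }
  list(annot = annot, clonotypes = roles, discarded = cut$discarded,
       events = events)
}

# germline rearrangement context of a main clonotype: germline V + the
# main's germline CDR3 reference (germline at V/D/J, main at N) + germline
# J from the FR4 tryptophan on
.germline_context <- function(main, db) {
  v <- db[[main$v_call]]
  j <- db[[main$j_call]]
  fr3_end <- v$regions$fr3[2]
  seq <- paste0(substr(v$sequence, 1, fr3_end), main$germline_cdr3,
                substr(j$sequence, j$fr4_start + 1, nchar(j$sequence)))
  list(sequence = seq, cdr3_offset = fr3_end)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when configured) -> read QC -> annotation ->
#' clonotype analysis -> substitution profiling -> hotspot topology ->
#' cohort summaries, writing per-stage TSVs, a per-filter read accounting
#' and a JSON summary under `outdir`.
#'
#' @param config a `cdr3shm_config` (or YAML path, or plain list).
#' @param outdir output directory; `NULL` suppresses file output.
#' @return (invisibly) list with per-sample results (`samples`), the QC
#'   accounting (`qc`), pooled `events`, `recurrence`, `positional`
#'   (targeting test, when >= 2 mu samples), `topology`, `linkage`
#'   (switched-variant links) and `summary`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- pipeline_config(path = config)
  if (!inherits(config, "cdr3shm_config"))
    config <- pipeline_config(simulate = config$simulate,
                              samples = config$samples,
                              germline = config$germline,
                              params = if (is.null(config$params)) list() else config$params,
                              seed = config$seed)
  params <- config$params
  db <- .pipeline_db(config)

  inputs <- list()   # list of (sample_id, isotype, reads-like object)
  if (!is.null(config$simulate)) {
    sm <- config$simulate
    spec <- archetype_spec(sm$subset)
    arch <- build_archetype(spec, db)
    inj <- lapply(sm$injections, function(x)
      injection_spec(x$cdr3_position, x$codon_offset, x$germline_nt,
                     x$mutant_nt, x$target_frequency))
    isotypes <- if (is.null(sm$isotypes)) "IGM" else sm$isotypes
    n_samples <- if (is.null(sm$n_samples)) 1L else sm$n_samples
    for (iso_i in seq_along(isotypes)) {
      sims <- simulate_cohort(
        arch, inj, n_samples = n_samples, carriers = sm$carriers,
        seed = .derive_seed(config$seed, 7919L * iso_i),
        n_reads = sm$n_reads,
        error_rate = if (is.null(sm$error_rate)) 0.024 else sm$error_rate,
        low_q_frac = if (is.null(sm$low_q_frac)) 0.02 else sm$low_q_frac,
        isotype = isotypes[iso_i])
      inputs <- c(inputs, sims)
    }
  } else if (!is.null(config$samples)) {
    for (s in config$samples) {
      for (f in c(s$r1, s$r2))
        if (!file.exists(f))
          stop("sample ", s$sample_id, ": FASTQ not found: ", f)
      r1 <- read_fastq(s$r1); r2 <- read_fastq(s$r2)
      inputs[[length(inputs) + 1L]] <-
        list(r1 = r1$sequence, q1 = r1$quality,
             r2 = r2$sequence, q2 = r2$quality,
             sample_id = s$sample_id, isotype = s$isotype)
    }
  } else stop("config needs either a 'simulate' or a 'samples' block")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(outdir, "airr"), showWarnings = FALSE)
    dir.create(file.path(outdir, "clonotypes"), showWarnings = FALSE)
  }

  results <- list(); qc_all <- list(); events_all <- list()
  for (inp in inputs) {
    sid <- inp$sample_id; iso <- inp$isotype
    tag <- paste(sid, iso, sep = "_")
    message("[cdr3shm] ", tag, ": QC")
    qc <- tryCatch(
      qc_sample(inp,
                raw_min_len = params$raw_min_len,
                raw_max_len = params$raw_max_len,
                raw_min_mean_q = params$raw_min_mean_q,
                min_overlap = params$min_overlap,
                max_mismatch_frac = params$max_mismatch_frac,
                merged_min_len = params$merged_min_len,
                merged_max_len = params$merged_max_len,
                merged_min_mean_q = params$merged_min_mean_q,
                window_near = params$window_near,
                window_far = params$window_far,
                window_min_q = params$window_min_q,
                window_mode = params$window_mode),
      error = function(e) stop("stage qc failed for sample ", tag, ": ",
                               conditionMessage(e)))
    qc$report$sample_id <- sid; qc$report$isotype <- iso
    qc_all[[tag]] <- qc$report
    message("[cdr3shm] ", tag, ": annotate + clonotypes (",
            nrow(qc$reads), " reads)")
    res <- tryCatch(
      .process_sample(qc$reads, db, params, sid, iso),
      error = function(e) stop("stage analysis failed for sample ", tag,
                               ": ", conditionMessage(e)))
    res$qc_report <- qc$report
    results[[tag]] <- res
    if (!is.null(res$events) && nrow(res$events))
      events_all[[tag]] <- res$events
    if (!is.null(outdir)) {
      write_airr(res$annot, file.path(outdir, "airr", paste0(tag, ".tsv")))
      .write_tsv(res$clonotypes,
                 file.path(outdir, "clonotypes", paste0(tag, ".tsv")))
    }
  }

  events <- if (length(events_all)) do.call(rbind, events_all) else
    .empty_events()
  rownames(events) <- NULL

  # cohort reports over mu samples
  mu_tags <- names(results)[vapply(results, function(r)
    any(r$clonotypes$isotype == "IGM"), logical(1))]
  mu_samples <- unique(vapply(mu_tags, function(t)
    results[[t]]$clonotypes$sample_id[1], character(1)))
  n_mu <- length(mu_samples)
  mu_events <- events[events$isotype == "IGM", , drop = FALSE]
  recurrence <- recurrence_report(mu_events, cohort_size = max(n_mu, 1L),
                                  min_samples = params$min_recurrence_samples)
  positional <- NULL
  if (n_mu >= 2 && nrow(mu_events)) {
    len <- max(mu_events$cdr3_position)
    sub_ev <- mu_events[!mu_events$clonal & !mu_events$synonymous, ,
                        drop = FALSE]
    freq <- matrix(0, nrow = n_mu, ncol = len,
                   dimnames = list(mu_samples, seq_len(len)))
    for (k in seq_len(nrow(sub_ev))) {
      s <- sub_ev$sample_id[k]; p <- sub_ev$cdr3_position[k]
      freq[s, p] <- freq[s, p] + sub_ev$frequency[k]
    }
    positional <- positional_targeting_test(freq, alpha = params$alpha)
    positional$frequencies <- freq
  }
  topology <- if (nrow(events) && "mechanism_class" %in% names(events))
    topology_summary(events[events$isotype == "IGM", , drop = FALSE],
                     cohort_size = max(n_mu, 1L)) else NULL

  # switched-variant linkage per sample
  linkage <- list()
  for (sid in mu_samples) {
    mu_tag <- names(results)[vapply(results, function(r)
      nrow(r$clonotypes) > 0 && r$clonotypes$sample_id[1] == sid &&
        r$clonotypes$isotype[1] == "IGM", logical(1))]
    sw_tags <- names(results)[vapply(results, function(r)
      nrow(r$clonotypes) > 0 && r$clonotypes$sample_id[1] == sid &&
        r$clonotypes$isotype[1] %in% c("IGG", "IGA"), logical(1))]
    if (length(mu_tag) && length(sw_tags)) {
      sw <- lapply(sw_tags, function(t) results[[t]]$clonotypes)
      names(sw) <- vapply(sw_tags, function(t)
        results[[t]]$clonotypes$isotype[1], character(1))
      linkage[[sid]] <- link_switched_variants(
        results[[mu_tag]]$clonotypes, sw)
    }
  }
  linkage <- if (length(linkage)) do.call(rbind, linkage) else NULL

  qc <- do.call(rbind, qc_all); rownames(qc) <- NULL
  summary <- list(
    n_samples = length(inputs), n_mu_samples = n_mu,
    reads_in = sum(qc$n[qc$stage == "raw_filter"]),
    reads_merged = sum(qc$n[qc$stage == "merge" & qc$outcome == "merged"]),
    reads_qc_pass = sum(qc$n[qc$stage == "merged_filter" &
                               qc$outcome == "pass"]),
    n_events = nrow(events), n_recurrent = nrow(recurrence),
    omnibus_p = if (!is.null(positional)) positional$omnibus_p else NULL)

  if (!is.null(outdir)) {
    .write_tsv(qc, file.path(outdir, "qc_report.tsv"))
    .write_tsv(events, file.path(outdir, "events.tsv"))
    .write_tsv(recurrence, file.path(outdir, "recurrence.tsv"))
    if (!is.null(topology))
      .write_tsv(topology, file.path(outdir, "topology.tsv"))
    if (!is.null(linkage))
      .write_tsv(linkage, file.path(outdir, "linkage.tsv"))
    if (!is.null(positional))
      jsonlite::write_json(
        list(omnibus_p = positional$omnibus_p,
             posthoc = positional$posthoc),
        file.path(outdir, "stats.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(samples = results, qc = qc, events = events,
                 recurrence = recurrence, positional = positional,
                 topology = topology, linkage = linkage,
                 summary = summary))
}
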