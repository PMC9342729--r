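# Full-study orchestration: stats -> regions -> repeats -> compare ->
# igs-scan -> markers, with deterministic TSV/JSON report twins and a run
# manifest.

#' Pipeline configuration
#'
#' Parameter blocks default to the common published settings: SSR
#' thresholds "1-10 2-6 3-5 4-5 5-5 6-5", tandem weights "2 7 7 80 10 50
#' 500", dispersed scan "-l 30 -h 3", anchor k 21, alignment gap
#' open/extend 10/2, top 5 loci over threshold 5.
#'
#' @param genomes Character vector of GenBank paths, or a (named) list of
#'   [plastome] records. The first genome is the reference.
#' @param out_dir Output directory for reports.
#' @param ssr,tandem,dispersed Parameter objects for the repeat scans.
#' @param k Anchor length for genome comparison.
#' @param window Flank-repeat search window.
#' @param gap_open,gap_extend Alignment penalties for the IGS scan.
#' @param top_n,threshold Hypervariable ranking controls.
#' @param min_ir_len Minimum IR length for partition detection.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genomes, out_dir = tempfile("plastocomp"),
                            ssr = ssr_params(), tandem = tandem_params(),
                            dispersed = dispersed_params(), k = 21,
                            window = 500, gap_open = 10, gap_extend = 2,
                            top_n = 5, threshold = 5, min_ir_len = 1000,
                            seed = 1L) {
  if (is.character(genomes)) {
    missing <- genomes[!file.exists(genomes)]
    if (length(missing) > 0) {
      abort(sprintf("genome file(s) not found: %s",
                    paste(missing, collapse = ", ")))
    }
  } else if (!is.list(genomes) || length(genomes) == 0) {
    abort("genomes must be file paths or a non-empty list of plastome records")
  }
  structure(list(genomes = genomes, out_dir = out_dir, ssr = ssr,
                 tandem = tandem, dispersed = dispersed, k = k,
                 window = window, gap_open = gap_open,
                 gap_extend = gap_extend, top_n = top_n,
                 threshold = threshold, min_ir_len = min_ir_len,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full comparative-plastome pipeline
#'
#' Stages: per-genome summary statistics, quadripartite regions and
#' junction report, the three repeat scans, pairwise structural comparison
#' against the reference (with at least two genomes), the IGS divergence
#' scan and hypervariable ranking, and diagnostic-site calls on the
#' top-ranked locus. Comparative stages are skipped (with a message) when
#' only one genome is given. Each stage writes a TSV and a JSON twin into
#' `out_dir`; a manifest records parameters and input checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-stage results and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  recs <- if (is.character(config$genomes)) {
    loaded <- lapply(config$genomes, read_genbank)
    setNames(loaded, vapply(loaded, function(r) r$id, ""))
  } else config$genomes
  if (is.null(names(recs))) names(recs) <- vapply(recs, function(r) r$id, "")
  n_gen <- length(recs)
  log_stage <- function(stage, msg) {
    message(sprintf("[plastocomp:%s] %s", stage, msg))
  }
  emit <- function(stage, df) {
    tsv <- file.path(config$out_dir, paste0(stage, ".tsv"))
    json <- file.path(config$out_dir, paste0(stage, ".json"))
    df_out <- df
    for (cl in names(df_out)) if (is.list(df_out[[cl]])) df_out[[cl]] <- NULL
    write.table(df_out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(df_out, json, auto_unbox = TRUE, digits = NA,
                         na = "null")
    c(tsv = tsv, json = json)
  }
  results <- list(); paths <- list()

  # partitions first: every downstream stage uses them
  for (id in names(recs)) {
    if (is.null(recs[[id]]$partition)) {
      recs[[id]]$partition <- tryCatch(
        detect_inverted_repeat(recs[[id]], min_ir_len = config$min_ir_len),
        error = function(e) { log_stage("regions", conditionMessage(e)); NULL })
    }
  }

  log_stage("stats", sprintf("summarizing %d genome(s)", n_gen))
  stats_tbl <- bind_rows(lapply(names(recs), function(id) {
    r <- recs[[id]]
    if (is.null(r$partition)) return(tibble(genome = id))
    s <- summarize_genome(r)
    tibble(genome = id, total_len = s$total_len,
           lsc = s$region_lens[["LSC"]], ssc = s$region_lens[["SSC"]],
           ir = s$region_lens[["IRa"]], gc_overall = s$gc_overall,
           gc_lsc = s$gc_by_region[["LSC"]], gc_ssc = s$gc_by_region[["SSC"]],
           gc_ir = s$gc_by_region[["IR"]],
           genes_total = s$gene_counts[["total"]],
           genes_cds = s$gene_counts[["protein_coding"]],
           genes_trna = s$gene_counts[["tRNA"]],
           genes_rrna = s$gene_counts[["rRNA"]])
  }))
  results$stats <- stats_tbl; paths$stats <- emit("stats", stats_tbl)

  log_stage("regions", "junction reports")
  regions_tbl <- bind_rows(lapply(names(recs), function(id) {
    r <- recs[[id]]
    if (is.null(r$partition)) return(NULL)
    mutate(junction_report(r), genome = id, .before = 1)
  }))
  results$regions <- regions_tbl; paths$regions <- emit("regions", regions_tbl)

  log_stage("repeats", "SSR / tandem / dispersed scans on the reference")
  ref <- recs[[1]]
  irb_mask <- NULL
  if (!is.null(ref$partition)) {
    irb <- ref$partition$regions[ref$partition$regions$region == "IRb", ]
    irb_mask <- cbind(start = irb$start + 1L, end = irb$end)
  }
  rep_out <- list(
    ssr = find_ssrs(ref, config$ssr),
    tandem = find_tandem_repeats(ref, config$tandem),
    dispersed = find_dispersed_repeats(ref, config$dispersed, mask = irb_mask))
  results$repeats <- rep_out
  paths$repeats_ssr <- emit("repeats_ssr", rep_out$ssr)
  paths$repeats_tandem <- emit("repeats_tandem", rep_out$tandem)
  paths$repeats_dispersed <- emit("repeats_dispersed", rep_out$dispersed)

  if (n_gen >= 2) {
    log_stage("compare", sprintf("structural comparison vs %s", names(recs)[1]))
    cmp <- bind_rows(lapply(names(recs)[-1], function(id) {
      cv <- call_inversions(ref, recs[[id]], k = config$k,
                            window = config$window)
      if (nrow(cv$inversions) == 0) return(NULL)
      mutate(cv$inversions, query = id, .before = 1)
    }))
    results$compare <- cmp
    paths$compare <- emit("compare", cmp %||% tibble())

    log_stage("igs_scan", "spacer divergence scan")
    div <- scan_igs_divergence(recs, gap_open = config$gap_open,
                               gap_extend = config$gap_extend)
    ranked <- rank_hypervariable(div, top_n = config$top_n,
                                 threshold = config$threshold)
    results$igs <- ranked
    paths$igs <- emit("igs_scan",
                      select(ranked, "locus", "aln_length", "statistic",
                             "summary_max", "summary_mean", "rank"))

    if (nrow(ranked) > 0) {
      log_stage("markers", sprintf("diagnostic sites in %s", ranked$locus[1]))
      sites <- call_diagnostic_sites(ranked$alignment[[1]])
      rep_m <- minimal_discriminating_set(sites, taxa = names(recs))
      results$markers <- rep_m
      marker_tbl <- tibble(column = sites$column, kind = sites$kind,
                           in_minimal_set = sites$column %in% rep_m$minimal_set)
      paths$markers <- emit("markers", marker_tbl)
    } else {
      log_stage("markers", "no locus above threshold; stage skipped")
    }
  } else {
    log_stage("compare", "single genome: comparative stages skipped")
  }

  manifest <- list(
    package = "plastocomp",
    version = as.character(utils::packageVersion("plastocomp")),
    seed = config$seed,
    parameters = list(
      ssr = config$ssr$min_repeats,
      tandem = unclass(config$tandem)[c("match", "mismatch", "min_score",
                                        "max_period", "report_min_unit",
                                        "report_min_identity")],
      dispersed = unclass(config$dispersed)[c("min_len", "max_hamming")],
      k = config$k, window = config$window, gap_open = config$gap_open,
      gap_extend = config$gap_extend, top_n = config$top_n,
      threshold = config$threshold, min_ir_len = config$min_ir_len),
    inputs = if (is.character(config$genomes)) {
      as.list(tools::md5sum(config$genomes))
    } else {
      lapply(recs, function(r) unname(tools::md5sum(
        write_fasta(r, tempfile(fileext = ".fa")))))
    })
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  invisible(c(results, list(paths = paths)))
}
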