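# Genome summary statistics: region lengths, GC by class and region, gene
# inventory, codon usage, intron/cis-trans splicing classification.

#' Summarize a plastome
#'
#' Computes total and per-region lengths, GC content overall / per region /
#' per feature class, feature-class lengths as genome fractions, and gene
#' counts. Gene counting follows `count_policy`: `"unique"` counts each
#' (gene name, class) once regardless of IR duplication (a multiplicity
#' table is attached either way), `"all"` counts every annotated copy.
#'
#' @param rec A [plastome] record.
#' @param partition A quadripartite partition; defaults to `rec$partition`.
#' @param count_policy `"unique"` (default) or `"all"`.
#' @return A list of class `genome_summary` with elements `total_len`,
#'   `region_lens`, `gc_overall`, `gc_by_region`, `gc_by_class`,
#'   `class_lens`, `gene_counts` and `gene_multiplicity`.
#' @export
summarize_genome <- function(rec, partition = NULL,
                             count_policy = c("unique", "all")) {
  count_policy <- match.arg(count_policy)
  partition <- partition %||% rec$partition
  if (is.null(partition)) {
    abort("no quadripartite partition: run detect_inverted_repeat() first")
  }
  n <- nchar(rec$seq)
  regions <- partition$regions
  region_seq <- setNames(
    lapply(seq_len(nrow(regions)),
           function(i) seq_slice(rec$seq, regions$start[i], regions$end[i])),
    regions$region)
  region_lens <- setNames(regions$length, regions$region)
  stopifnot(sum(region_lens) == n)

  gc_by_region <- vapply(region_seq, gc_content, 0)
  gc_by_region[["IR"]] <- gc_content(paste0(region_seq[["IRa"]], region_seq[["IRb"]]))

  classes <- c(protein_coding = "CDS", tRNA = "tRNA", rRNA = "rRNA")
  cls <- lapply(classes, function(k) class_sequences(rec, k, count_policy))
  gc_by_class <- vapply(cls, function(s) {
    if (length(s) == 0) NA_real_ else gc_content(s)
  }, 0)
  class_bp <- vapply(cls, function(s) sum(nchar(s)), 0)
  class_lens <- tibble(class = names(classes), bp = unname(class_bp),
                       pct_of_genome = round_half_up(100 * unname(class_bp) / n, 2))

  spans <- feature_spans(rec, kinds = unname(classes))
  mult <- spans |>
    group_by(.data$gene, .data$kind) |>
    summarise(copies = dplyr::n(), .groups = "drop")
  counts <- if (count_policy == "unique") {
    c(protein_coding = sum(mult$kind == "CDS"),
      tRNA = sum(mult$kind == "tRNA"),
      rRNA = sum(mult$kind == "rRNA"))
  } else {
    c(protein_coding = sum(spans$kind == "CDS"),
      tRNA = sum(spans$kind == "tRNA"),
      rRNA = sum(spans$kind == "rRNA"))
  }
  counts <- c(counts, total = sum(counts))

  structure(list(
    id = rec$id,
    total_len = n,
    region_lens = region_lens,
    gc_overall = gc_content(rec$seq),
    gc_by_region = gc_by_region,
    gc_by_class = gc_by_class,
    class_lens = class_lens,
    gene_counts = counts,
    gene_multiplicity = mult,
    count_policy = count_policy), class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf("<genome_summary> %s: %s bp, GC %.2f%%\n", x$id,
              format(x$total_len, big.mark = ","), x$gc_overall))
  cat("  regions:", paste(sprintf("%s=%d", names(x$region_lens),
                                  x$region_lens), collapse = " "), "\n")
  cat("  genes:", paste(sprintf("%s=%d", names(x$gene_counts),
                                x$gene_counts), collapse = " "),
      sprintf("(%s policy)\n", x$count_policy))
  invisible(x)
}

# spliced sequences of one feature class, optionally de-duplicated by name
class_sequences <- function(rec, kind, count_policy) {
  f <- rec$features[rec$features$kind == kind, , drop = FALSE]
  if (nrow(f) == 0) return(character())
  ids <- unique(f$feature_id)
  if (count_policy == "unique") {
    first <- f |>
      distinct(.data$feature_id, .data$gene) |>
      distinct(.data$gene, .keep_all = TRUE)
    ids <- first$feature_id
  }
  vapply(ids, function(fid) {
    extract_feature_sequence(rec, f[f$feature_id == fid, ])
  }, "")
}

#' Codon usage over annotated CDS features
#'
#' Counts codons over concatenated CDS transcripts under the bacterial /
#' plastid genetic code (translation table 11). By default every annotated
#' CDS copy is counted (IR duplicates included); `dedup = TRUE` counts each
#' gene name once. CDS whose spliced length is not divisible by three are
#' reported in the `notes` attribute and their trailing partial codon is
#' dropped; internal stop codons are counted as stops and noted, not fatal.
#'
#' @param rec A [plastome] record.
#' @param dedup Count each gene name once?
#' @return A list of class `codon_usage` with `counts` (tibble: codon,
#'   amino_acid, count), `by_amino_acid`, and `total_codons`.
#' @export
codon_usage <- function(rec, dedup = FALSE) {
  seqs <- class_sequences(rec, "CDS", if (dedup) "unique" else "all")
  if (length(seqs) == 0) abort("no CDS features annotated")
  notes <- character()
  code <- Biostrings::getGeneticCode("11")
  all_codons <- names(code)
  tab <- setNames(integer(length(all_codons)), all_codons)
  total_checked_len <- 0L
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    extra <- nchar(s) %% 3
    if (extra != 0) {
      notes <- c(notes, sprintf("CDS %d length %d not divisible by 3; trailing %d base(s) dropped",
                                i, nchar(s), extra))
      s <- substr(s, 1, nchar(s) - extra)
    }
    total_checked_len <- total_checked_len + nchar(s)
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    cods <- cods[!grepl("N", cods)]
    t1 <- table(cods)
    tab[names(t1)] <- tab[names(t1)] + as.integer(t1)
    aa <- code[cods]
    internal_stops <- sum(aa[-length(aa)] == "*")
    if (internal_stops > 0) {
      notes <- c(notes, sprintf("CDS %d has %d internal stop codon(s)", i, internal_stops))
    }
  }
  counts <- tibble(codon = all_codons, amino_acid = unname(code[all_codons]),
                   count = unname(tab))
  by_aa <- counts |>
    group_by(amino_acid = ifelse(.data$amino_acid == "*", "stop", .data$amino_acid)) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(desc(.data$count))
  structure(list(counts = counts, by_amino_acid = by_aa,
                 total_codons = sum(tab), notes = notes,
                 cds_length_used = total_checked_len),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  aa <- x$by_amino_acid[x$by_amino_acid$amino_acid != "stop", ]
  cat(sprintf("<codon_usage> %s codons; most abundant %s (%d), least %s (%d)\n",
              format(x$total_codons, big.mark = ","),
              aa$amino_acid[1], aa$count[1],
              aa$amino_acid[nrow(aa)], aa$count[nrow(aa)]))
  invisible(x)
}

#' Classify intron content and cis/trans splicing
#'
#' A multi-part feature is cis-spliced when its parts all lie on one strand
#' and follow transcript order along the genome (ascending for `+`,
#' descending for `-`); it is trans-spliced otherwise (mixed strands or
#' non-collinear part order, as for plastid rps12). Intron count is
#' `parts - 1` per annotated copy.
#'
#' @param rec A [plastome] record.
#' @param kinds Feature kinds to classify.
#' @return Tibble: gene, kind, copy, n_parts, introns, splicing
#'   (`"none"`, `"cis"`, `"trans"`).
#' @export
classify_splicing <- function(rec, kinds = c("CDS", "tRNA", "rRNA")) {
  f <- rec$features[rec$features$kind %in% kinds, , drop = FALSE]
  if (nrow(f) == 0) {
    return(tibble(gene = character(), kind = character(), copy = integer(),
                  n_parts = integer(), introns = integer(),
                  splicing = character()))
  }
  f |>
    group_by(.data$feature_id, .data$gene, .data$kind, .data$copy) |>
    summarise(n_parts = dplyr::n(),
              splicing = {
                if (dplyr::n() == 1) "none"
                else {
                  st <- .data$strand[order(.data$part)]
                  starts <- .data$start[order(.data$part)]
                  one_strand <- length(unique(st)) == 1
                  collinear <- if (!one_strand) FALSE
                  else if (st[1] == "+") !is.unsorted(starts)
                  else !is.unsorted(rev(starts))
                  if (one_strand && collinear) "cis" else "trans"
                }
              }, .groups = "drop") |>
    mutate(introns = .data$n_parts - 1L) |>
    select("gene", "kind", "copy", "n_parts", "introns", "splicing")
}
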