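# Hypervariable-region scan: extract intergenic spacers (IGS) from
# annotations, align each locus across genomes, compute pairwise Kimura
# two-parameter distances, and rank loci by divergence.

#' Extract intergenic spacer (IGS) loci
#'
#' One locus per pair of genomically adjacent genes with a gap of at least
#' `min_len` bp, on the linearized deposited orientation (including the
#' origin-wrapping pair for circular genomes). Loci spanning any of the
#' four quadripartite junctions are dropped, as are loci intersecting
#' `exclude` (e.g. an inversion region). IR-duplicated loci are collapsed
#' to one representative: loci fully inside IRb are dropped.
#'
#' @param rec A [plastome] record.
#' @param part A quadripartite partition; defaults to `rec$partition`
#'   (junction/IR filters are skipped when no partition is available).
#' @param exclude Optional 1-based inclusive interval(s) to exclude
#'   (two-column matrix/data frame or length-2 vector).
#' @param min_len Minimum spacer length (default 1).
#' @return Tibble: locus (`"geneA-geneB"`), gene5, gene3, start, end
#'   (1-based inclusive), length, sequence.
#' @export
extract_igs <- function(rec, part = NULL, exclude = NULL, min_len = 1) {
  part <- part %||% rec$partition
  spans <- feature_spans(rec, kinds = c("CDS", "tRNA", "rRNA"))
  if (nrow(spans) == 0) abort("no annotated features to derive spacers from")
  n <- nchar(rec$seq)
  # merge book-ended/overlapping gene copies into occupied blocks, keeping
  # the last gene name of each block as the upstream label
  spans <- arrange(spans, .data$start, .data$end)
  loci <- list()
  n_sp <- nrow(spans)
  for (i in seq_len(n_sp)) {
    j <- if (i == n_sp) 1L else i + 1L
    gap_start <- spans$end[i]
    gap_end <- if (i == n_sp) spans$start[j] + n else spans$start[j]
    if (gap_end - gap_start < min_len) next
    if (gap_start >= gap_end) next
    loci[[length(loci) + 1]] <- tibble(
      gene5 = spans$gene[i], gene3 = spans$gene[j],
      start0 = gap_start, end0 = gap_end)
  }
  if (length(loci) == 0) abort("no spacers found")
  out <- bind_rows(loci)
  # a gene nested inside another creates a negative/contained gap: drop dups
  out <- out[!duplicated(out[, c("start0", "end0")]), , drop = FALSE]
  if (!is.null(part)) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      s <- out$start0[i]; e <- out$end0[i]
      !any(vapply(part$junctions, function(jc) {
        off <- (jc - s) %% n
        off > 0 && off < (e - s)
      }, TRUE))
    }, TRUE)
    out <- out[keep, , drop = FALSE]
    irb <- part$regions[part$regions$region == "IRb", ]
    inside_irb <- out$start0 >= irb$start & out$end0 <= irb$end
    out <- out[!inside_irb, , drop = FALSE]
  }
  if (!is.null(exclude)) {
    if (is.null(dim(exclude))) exclude <- matrix(exclude, ncol = 2, byrow = TRUE)
    exclude <- as.matrix(as.data.frame(exclude))
    hit <- vapply(seq_len(nrow(out)), function(i) {
      any(intervals_overlap(out$start0[i], out$end0[i],
                            exclude[, 1] - 1L, exclude[, 2]))
    }, TRUE)
    out <- out[!hit, , drop = FALSE]
  }
  out |>
    mutate(locus = paste0(.data$gene5, "-", .data$gene3),
           start = .data$start0 %% n + 1L,
           end = ((.data$end0 - 1L) %% n) + 1L,
           length = .data$end0 - .data$start0,
           sequence = vapply(seq_len(dplyr::n()), function(i) {
             seq_slice(rec$seq, .data$start0[i], .data$end0[i], rec$circular)
           }, "")) |>
    select("locus", "gene5", "gene3", "start", "end", "length", "sequence")
}

#' Align the sequences of one locus
#'
#' Global alignment with affine gaps (match +1, mismatch -1; a gap of
#' length g costs `gap_open + g * gap_extend`). More than two sequences
#' are aligned progressively along a shared-k-mer guide tree with
#' profile-profile alignment. Input residues are preserved in the columns.
#'
#' @param seqs Named character vector of >= 2 DNA sequences (each >= 1 bp).
#' @param gap_open,gap_extend Affine gap penalties (defaults 10 and 2).
#' @param match,mismatch Substitution scores (defaults +1 / -1).
#' @return A character matrix (rows = sequences, columns = alignment
#'   positions, entries single residues or `"-"`), with the pairwise DP
#'   score in attribute `score` for two-sequence alignments.
#' @export
align_locus <- function(seqs, gap_open = 10, gap_extend = 2,
                        match = 1, mismatch = -1) {
  if (length(seqs) < 2) abort("need at least two sequences")
  if (any(nchar(seqs) == 0)) abort("empty sequence in locus")
  seqs <- vapply(seqs, normalize_residues, "", warn_ambiguous = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))

  aln_of <- function(rows) do.call(rbind, lapply(rows, function(s) {
    strsplit(s, "")[[1]]
  }))
  profile_of <- function(mat) {
    L <- ncol(mat)
    pr <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (b in rownames(pr)) pr[b, ] <- colMeans(mat == b)
    pr
  }
  merge_two <- function(matA, matB) {
    res <- cpp_align_profiles(profile_of(matA), profile_of(matB),
                              match, mismatch, gap_open, gap_extend)
    ops <- res$ops
    L <- length(ops)
    out <- matrix("-", nrow(matA) + nrow(matB), L)
    rownames(out) <- c(rownames(matA), rownames(matB))
    ia <- 0L; ib <- 0L
    colA <- integer(L); colB <- integer(L)
    for (t in seq_len(L)) {
      if (ops[t] != 2L) ia <- ia + 1L
      if (ops[t] != 1L) ib <- ib + 1L
      colA[t] <- if (ops[t] != 2L) ia else 0L
      colB[t] <- if (ops[t] != 1L) ib else 0L
    }
    out[seq_len(nrow(matA)), colA > 0] <- matA[, colA[colA > 0], drop = FALSE]
    out[nrow(matA) + seq_len(nrow(matB)), colB > 0] <-
      matB[, colB[colB > 0], drop = FALSE]
    attr(out, "score") <- res$score
    out
  }

  if (length(seqs) == 2) {
    a1 <- aln_of(seqs[1]); rownames(a1) <- names(seqs)[1]
    a2 <- aln_of(seqs[2]); rownames(a2) <- names(seqs)[2]
    return(merge_two(a1, a2))
  }
  # guide tree from shared 4-mer dissimilarity
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < 4) return(character())
    unique(substring(s, 1:(L - 3), 4:L))
  })
  ns <- length(seqs)
  d <- matrix(0, ns, ns)
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    u <- length(union(km[[i]], km[[j]]))
    d[i, j] <- d[j, i] <- if (u == 0) 1 else 1 - length(intersect(km[[i]], km[[j]])) / u
  }
  hc <- hclust(as.dist(d), method = "average")
  nodes <- vector("list", ns + nrow(hc$merge))
  for (i in seq_len(ns)) {
    nodes[[i]] <- aln_of(seqs[i])
    rownames(nodes[[i]]) <- names(seqs)[i]
  }
  for (m in seq_len(nrow(hc$merge))) {
    pick <- function(v) if (v < 0) nodes[[-v]] else nodes[[ns + v]]
    nodes[[ns + m]] <- merge_two(pick(hc$merge[m, 1]), pick(hc$merge[m, 2]))
  }
  out <- nodes[[ns + nrow(hc$merge)]]
  out[names(seqs), , drop = FALSE]
}

#' Kimura two-parameter distance between two aligned rows
#'
#' Columns with a gap or N in either row are excluded (pairwise deletion).
#' With transition proportion P and transversion proportion Q over the
#' compared sites, d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q), reported in
#' substitutions per 100 sites. When a log argument is <= 0 the distance
#' is saturated: `d` is `NA` and `saturated` is `TRUE`.
#'
#' @param a,b Aligned sequences: equal-length character strings or
#'   character vectors of single residues.
#' @return A one-row tibble: P, Q, n_sites, d, saturated.
#' @export
k2p_distance <- function(a, b) {
  if (length(a) == 1) a <- strsplit(toupper(a), "")[[1]]
  if (length(b) == 1) b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) abort("aligned rows differ in length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) abort("no comparable (non-gap, non-N) sites")
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  saturated <- arg1 <= 0 || arg2 <= 0
  d <- if (saturated) NA_real_ else 100 * (-0.5 * log(arg1) - 0.25 * log(arg2))
  tibble(P = P, Q = Q, n_sites = n, d = d, saturated = saturated)
}

#' Scan intergenic spacers for divergence across genomes
#'
#' Extracts IGS loci from every genome, keeps loci present (by name) in all
#' genomes, aligns each locus, and computes all pairwise K2p distances.
#' The per-locus summaries are the maximum and mean finite pairwise
#' distance.
#'
#' @param records Named list of [plastome] records (>= 2). The first is the
#'   reference.
#' @param exclude Optional interval(s) on each genome to exclude, as for
#'   [extract_igs()]; either a single interval set applied to the reference
#'   only, or a named list per genome id.
#' @param gap_open,gap_extend Alignment penalties (see [align_locus()]).
#' @param min_len Minimum spacer length.
#' @return A tibble of class `locus_divergence`: locus, n_genomes,
#'   aln_length, summary_max, summary_mean, pairwise (list column of
#'   per-pair K2p tibbles), alignment (list column of character matrices).
#' @export
scan_igs_divergence <- function(records, exclude = NULL, gap_open = 10,
                                gap_extend = 2, min_len = 1) {
  if (length(records) < 2) abort("need at least two genomes")
  ids <- names(records) %||% vapply(records, function(r) r$id, "")
  names(records) <- ids
  per_genome <- lapply(ids, function(id) {
    rec <- records[[id]]
    part <- rec$partition %||% tryCatch(detect_inverted_repeat(rec),
                                        error = function(e) NULL)
    ex <- if (is.list(exclude) && !is.null(names(exclude))) exclude[[id]]
    else if (id == ids[1]) exclude else NULL
    extract_igs(rec, part = part, exclude = ex, min_len = min_len)
  })
  names(per_genome) <- ids
  common <- Reduce(intersect, lapply(per_genome, function(x) x$locus))
  if (length(common) == 0) abort("no spacer locus shared by all genomes")
  rows <- lapply(common, function(lc) {
    seqs <- vapply(ids, function(id) {
      g <- per_genome[[id]]
      g$sequence[match(lc, g$locus)]
    }, "")
    aln <- align_locus(seqs, gap_open = gap_open, gap_extend = gap_extend)
    prs <- combn(ids, 2, simplify = FALSE)
    pw <- bind_rows(lapply(prs, function(p) {
      k2 <- k2p_distance(aln[p[1], ], aln[p[2], ])
      mutate(k2, genome1 = p[1], genome2 = p[2], .before = 1)
    }))
    dfin <- pw$d[!pw$saturated]
    tibble(locus = lc, n_genomes = length(ids), aln_length = ncol(aln),
           summary_max = if (length(dfin)) max(dfin) else NA_real_,
           summary_mean = if (length(dfin)) mean(dfin) else NA_real_,
           pairwise = list(pw), alignment = list(aln))
  })
  out <- bind_rows(rows)
  class(out) <- c("locus_divergence", class(out))
  out
}

#' Rank hypervariable spacer loci
#'
#' Orders loci by the chosen per-locus summary statistic (maximum pairwise
#' K2p by default; both max and mean are always carried) and reports the
#' `top_n` loci whose statistic exceeds `threshold`.
#'
#' @param div A [scan_igs_divergence()] result.
#' @param top_n Number of loci to report (default 5).
#' @param threshold Minimum summary statistic, per 100 sites (default 5).
#' @param statistic `"max"` (default) or `"mean"`.
#' @return The ranked subset of `div` with a `rank` column.
#' @export
rank_hypervariable <- function(div, top_n = 5, threshold = 5,
                               statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  if (nrow(div) == 0) abort("no loci to rank")
  stat <- if (statistic == "max") div$summary_max else div$summary_mean
  div$statistic <- stat
  out <- div |>
    filter(!is.na(.data$statistic), .data$statistic > threshold) |>
    arrange(desc(.data$statistic)) |>
    head(top_n)
  out$rank <- seq_len(nrow(out))
  class(out) <- unique(c("locus_divergence", class(out)))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a locus-divergence scan into one row per locus pair
#'
#' @param x A `locus_divergence` object.
#' @param ... Unused.
#' @return Tibble: locus, genome1, genome2, P, Q, n_sites, d, saturated.
#' @export
tidy.locus_divergence <- function(x, ...) {
  x |>
    select("locus", "pairwise") |>
    tidyr::unnest("pairwise")
}

#' One-row summary of a locus-divergence scan
#'
#' @param x A `locus_divergence` object.
#' @param ... Unused.
#' @return Tibble: n_loci, n_genomes, top_locus, max_d, mean_d.
#' @export
glance.locus_divergence <- function(x, ...) {
  top <- x$locus[which.max(x$summary_max)]
  tibble(n_loci = nrow(x), n_genomes = x$n_genomes[1] %||% NA_integer_,
         top_locus = top %||% NA_character_,
         max_d = suppressWarnings(max(x$summary_max, na.rm = TRUE)),
         mean_d = mean(x$summary_mean, na.rm = TRUE))
}
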