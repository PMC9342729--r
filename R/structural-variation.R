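# Pairwise whole-plastome synteny through unique-k-mer anchors, inversion
# calling by orientation-consistent chaining, and association of inversions
# with flanking palindromic repeats.

#' Build a unique-anchor map between two genomes
#'
#' Anchors are placed at k-mers occurring exactly once in each genome,
#' counting a k-mer and its reverse complement as one strand-equivalence
#' class; strand-palindromic k-mers are skipped. The orientation records
#' whether the two genomes hold the same strand of the class.
#'
#' @param ref,query [plastome] records or DNA strings.
#' @param k Anchor length (default 21; must be >= 15).
#' @param ref_mask,query_mask Optional 1-based inclusive interval sets
#'   excluded from seeding (e.g. the IR regions, which are near-identical
#'   across species and would create ambiguous anchors).
#' @param min_anchors Warn when fewer anchors are found.
#' @return Tibble of class `anchor_map`: ref_pos, query_pos (1-based k-mer
#'   starts), k, orientation (`"same"`/`"inverted"`).
#' @export
build_anchor_map <- function(ref, query, k = 21, ref_mask = NULL,
                             query_mask = NULL, min_anchors = 50) {
  if (k < 15) abort("k must be >= 15 for unique anchoring")
  to_mask <- function(m) {
    if (is.null(m)) return(list(s = integer(), e = integer()))
    m <- as.matrix(as.data.frame(m))
    list(s = as.integer(m[, 1] - 1L), e = as.integer(m[, 2]))
  }
  rm <- to_mask(ref_mask); qm <- to_mask(query_mask)
  a <- as_tibble(cpp_anchor_map(as_dna_string(ref), as_dna_string(query),
                                as.integer(k), rm$s, rm$e, qm$s, qm$e))
  if (nrow(a) < min_anchors) {
    warn(sprintf("only %d anchors found (< %d): genomes may be too repetitive",
                 nrow(a), min_anchors))
  }
  out <- a |>
    mutate(ref_pos = .data$ref_pos0 + 1L, query_pos = .data$query_pos0 + 1L,
           k = as.integer(k),
           orientation = ifelse(.data$orientation == 1, "same", "inverted")) |>
    select("ref_pos", "query_pos", "k", "orientation") |>
    arrange(.data$ref_pos)
  class(out) <- c("anchor_map", class(out))
  out
}

# chain anchors (sorted by ref) into orientation-consistent collinear blocks
chain_anchor_blocks <- function(anchors, max_gap = 5000) {
  if (nrow(anchors) == 0) return(tibble())
  a <- arrange(anchors, .data$ref_pos)
  n <- nrow(a)
  block <- integer(n); block[1] <- 1L
  for (i in seq_len(n)[-1]) {
    same_orient <- a$orientation[i] == a$orientation[i - 1]
    dr <- a$ref_pos[i] - a$ref_pos[i - 1]
    dq <- a$query_pos[i] - a$query_pos[i - 1]
    ok <- same_orient && dr <= max_gap &&
      ((a$orientation[i] == "same" && dq > 0 && dq <= max_gap) ||
         (a$orientation[i] == "inverted" && dq < 0 && -dq <= max_gap))
    block[i] <- if (ok) block[i - 1] else block[i - 1] + 1L
  }
  a$block <- block
  a |>
    group_by(.data$block) |>
    summarise(orientation = .data$orientation[1],
              ref_start = min(.data$ref_pos),
              ref_end = max(.data$ref_pos) + .data$k[1] - 1L,
              query_start = min(.data$query_pos),
              query_end = max(.data$query_pos) + .data$k[1] - 1L,
              n_anchors = dplyr::n(), .groups = "drop")
}

#' Call inversions from an anchor map
#'
#' Anchors are chained into maximal orientation-consistent collinear
#' blocks; an inverted block bounded by same-orientation blocks is emitted
#' as an inversion call. The reported endpoints are the outermost anchor
#' positions of the inverted block (1-based inclusive); `outer_start` /
#' `outer_end` bound the true breakpoints from the flanking same-oriented
#' blocks, and [find_flanking_inverted_repeat()] can snap the endpoints to
#' a flanking palindromic repeat pair.
#'
#' @param anchors An [build_anchor_map()] result.
#' @param min_block Minimum block span in bp (default 1000).
#' @param max_gap Maximum anchor-to-anchor gap within a block.
#' @return Tibble of class `inversion_calls`: ref_start, ref_end,
#'   query_start, query_end, n_anchors, outer_start, outer_end.
#' @export
detect_inversions <- function(anchors, min_block = 1000, max_gap = 5000) {
  empty <- tibble(ref_start = integer(), ref_end = integer(),
                  query_start = integer(), query_end = integer(),
                  n_anchors = integer(), outer_start = integer(),
                  outer_end = integer())
  blocks <- chain_anchor_blocks(anchors, max_gap)
  if (nrow(blocks) == 0) return(empty)
  blocks <- blocks |>
    filter(.data$ref_end - .data$ref_start + 1 >= min_block) |>
    arrange(.data$ref_start)
  if (nrow(blocks) < 1) return(empty)
  calls <- list()
  for (i in seq_len(nrow(blocks))) {
    if (blocks$orientation[i] != "inverted") next
    left_ok <- i == 1 || blocks$orientation[i - 1] == "same"
    right_ok <- i == nrow(blocks) || blocks$orientation[i + 1] == "same"
    has_neighbor <- i > 1 || i < nrow(blocks)
    if (!(left_ok && right_ok && has_neighbor)) next
    calls[[length(calls) + 1]] <- tibble(
      ref_start = blocks$ref_start[i], ref_end = blocks$ref_end[i],
      query_start = blocks$query_start[i], query_end = blocks$query_end[i],
      n_anchors = blocks$n_anchors[i],
      outer_start = if (i > 1) blocks$ref_end[i - 1] + 1L else 1L,
      outer_end = if (i < nrow(blocks)) blocks$ref_start[i + 1] - 1L else NA_integer_)
  }
  out <- if (length(calls)) bind_rows(calls) else empty
  class(out) <- c("inversion_calls", class(out))
  out
}

#' Find a palindromic repeat pair flanking an inversion and snap endpoints
#'
#' Searches the windows immediately outside the provisional inversion
#' endpoints for a maximal inverted-repeat pair (length >= `min_len`,
#' mismatches <= `max_hamming`) and, when found, re-snaps the inversion so
#' the repeat copies lie exactly outside it (5' copy end + 1 ==
#' inversion start; inversion end + 1 == 3' copy start).
#'
#' @param x The genome carrying the inversion ([plastome] or DNA string).
#' @param inversion One row of a [detect_inversions()] result (or a list
#'   with `ref_start`, `ref_end`, optionally `outer_start`/`outer_end`).
#' @param window Search window outside each endpoint (default 500 bp).
#' @param params A [dispersed_params()] object (length/Hamming budget).
#' @return `NULL` when no flanking repeat is found; otherwise a list with
#'   `repeat5` (start, end), `repeat3` (start, end), `length`,
#'   `mismatches`, and the snapped `ref_start`, `ref_end` (all 1-based
#'   inclusive).
#' @export
find_flanking_inverted_repeat <- function(x, inversion, window = 500,
                                          params = dispersed_params()) {
  seq <- as_dna_string(x)
  n <- nchar(seq)
  s0 <- inversion$ref_start[1]; e0 <- inversion$ref_end[1]
  # uncertainty of the provisional endpoints, bounded by the flanking blocks
  pad_l <- if (!is.null(inversion$outer_start) && !is.na(inversion$outer_start[1])) {
    max(0L, s0 - inversion$outer_start[1])
  } else 200L
  pad_r <- if (!is.null(inversion$outer_end) && !is.na(inversion$outer_end[1])) {
    max(0L, inversion$outer_end[1] - e0)
  } else 200L
  left_lo <- max(1L, s0 - window - pad_l); left_hi <- min(n, s0 + pad_l)
  right_lo <- max(1L, e0 - pad_r); right_hi <- min(n, e0 + window + pad_r)
  left <- substr(seq, left_lo, left_hi)
  right <- substr(seq, right_lo, right_hi)
  spacer <- strrep("N", 20)
  combo <- paste0(left, spacer, right)
  off_r <- nchar(left) + nchar(spacer)      # 0-based offset of right segment
  hits <- find_dispersed_repeats(combo,
                                 dispersed_params(min_len = params$min_len,
                                                  max_hamming = params$max_hamming,
                                                  kinds = "palindromic"))
  if (nrow(hits) > 0) {
    hits <- hits |>
      filter(.data$end1 <= nchar(left), .data$start2 > off_r) |>
      arrange(desc(.data$length))
  }
  if (nrow(hits) == 0) return(NULL)
  h <- hits[1, ]
  rep5 <- c(start = left_lo + h$start1 - 1L, end = left_lo + h$end1 - 1L)
  rep3 <- c(start = right_lo + (h$start2 - off_r) - 1L,
            end = right_lo + (h$end2 - off_r) - 1L)
  list(repeat5 = rep5, repeat3 = rep3, length = h$length,
       mismatches = h$mismatches,
       ref_start = unname(rep5["end"] + 1L), ref_end = unname(rep3["start"] - 1L))
}

#' Compare two genomes end to end: anchors, inversions, flank snapping
#'
#' Convenience orchestrator: builds the anchor map (masking each genome's
#' IRs when partitions are available or detectable), calls inversions, and
#' snaps each call to a flanking palindromic repeat when one is found.
#'
#' @inheritParams build_anchor_map
#' @inheritParams detect_inversions
#' @param window Flank search window (see [find_flanking_inverted_repeat()]).
#' @param mask_ir Mask IR regions during anchor seeding?
#' @return List with `anchors`, `inversions` (with snapped coordinates and
#'   flank columns when found).
#' @export
call_inversions <- function(ref, query, k = 21, min_block = 1000,
                            max_gap = 5000, window = 500, mask_ir = TRUE) {
  ir_mask <- function(g) {
    if (!mask_ir || !inherits(g, "plastome")) return(NULL)
    part <- g$partition %||% tryCatch(detect_inverted_repeat(g),
                                      error = function(e) NULL)
    if (is.null(part)) return(NULL)
    r <- part$regions[part$regions$region %in% c("IRa", "IRb"), ]
    n <- nchar(g$seq)
    cbind(start = r$start %% n + 1L, end = pmin(r$end, n))
  }
  anchors <- build_anchor_map(ref, query, k = k, ref_mask = ir_mask(ref),
                              query_mask = ir_mask(query))
  inv <- detect_inversions(anchors, min_block = min_block, max_gap = max_gap)
  if (nrow(inv) > 0) {
    inv$flank_length <- NA_integer_
    inv$flank_mismatches <- NA_integer_
    inv$flank5_start <- NA_integer_; inv$flank5_end <- NA_integer_
    inv$flank3_start <- NA_integer_; inv$flank3_end <- NA_integer_
    for (i in seq_len(nrow(inv))) {
      fl <- find_flanking_inverted_repeat(ref, inv[i, ], window = window)
      if (is.null(fl)) next
      inv$ref_start[i] <- fl$ref_start; inv$ref_end[i] <- fl$ref_end
      inv$flank_length[i] <- fl$length
      inv$flank_mismatches[i] <- fl$mismatches
      inv$flank5_start[i] <- fl$repeat5[["start"]]
      inv$flank5_end[i] <- fl$repeat5[["end"]]
      inv$flank3_start[i] <- fl$repeat3[["start"]]
      inv$flank3_end[i] <- fl$repeat3[["end"]]
    }
  }
  list(anchors = anchors, inversions = inv)
}

#' Search for the best local hit of a repeat unit in another genome
#'
#' Local alignment of the unit (both strands) against the genome under
#' match +1 / mismatch -2 / gap open -5 / gap extend -2 scoring.
#'
#' @param unit DNA string (>= 20 bp).
#' @param genome A [plastome] record or DNA string.
#' @param min_score Minimum local alignment score (default 20).
#' @return `NULL` if no hit scores above `min_score`; otherwise a tibble
#'   with start, end (1-based, forward genome coordinates), strand,
#'   aligned_length, identity, score.
#' @export
search_repeat_homolog <- function(unit, genome, min_score = 20) {
  unit <- as_dna_string(unit)
  if (nchar(unit) < 20) abort("repeat unit must be at least 20 bp")
  gseq <- as_dna_string(genome)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                      baseOnly = FALSE)
  best <- NULL
  for (strand in c("+", "-")) {
    u <- if (strand == "+") unit else dna_revcomp(unit)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(u), Biostrings::DNAString(gseq),
      type = "local", substitutionMatrix = sub_mat,
      gapOpening = 5, gapExtension = 2)
    sc <- Biostrings::score(aln)
    if (is.null(best) || sc > best$score) {
      rng <- aln@subject@range
      best <- list(score = sc, strand = strand,
                   start = BiocGenerics::start(rng), end = BiocGenerics::end(rng),
                   aligned_length = Biostrings::nchar(aln),
                   identity = Biostrings::pid(aln))
    }
  }
  if (best$score < min_score) return(NULL)
  tibble(start = best$start, end = best$end, strand = best$strand,
         aligned_length = best$aligned_length,
         identity = round_half_up(best$identity, 2), score = best$score)
}
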