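# Repeat surveys: MISA-style SSRs, a simplified tandem-repeat detector, and
# maximal dispersed (forward/palindromic) repeats under a Hamming budget.

#' SSR search parameters (MISA-style)
#'
#' Minimum repeat counts per motif length 1-6; the default is the common
#' plastome setting "1-10 2-6 3-5 4-5 5-5 6-5".
#'
#' @param min_repeats Integer vector of length 6 (motif sizes 1..6).
#' @return A list of class `ssr_params`.
#' @export
ssr_params <- function(min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  stopifnot(length(min_repeats) == 6, all(min_repeats >= 2))
  structure(list(min_repeats = as.integer(min_repeats)), class = "ssr_params")
}

#' Find simple sequence repeats (microsatellites)
#'
#' Reports every maximal run of a primitive 1-6 bp motif meeting the
#' per-unit-size minimum repeat count; a trailing partial motif copy is not
#' counted. Runs contained in (or overlapping) a reported run of a larger
#' unit size are suppressed. The canonical class is the lexicographic
#' minimum over all rotations of the motif and of its reverse complement,
#' reported as a `"fwd/rc"` pair (e.g. `"A/T"`, `"AT/AT"`, `"AGG/CCT"`).
#'
#' @param x A [plastome] record or DNA string.
#' @param params An [ssr_params()] object.
#' @return Tibble: start, end (1-based inclusive), motif, unit, n_repeats,
#'   canonical_class.
#' @export
find_ssrs <- function(x, params = ssr_params()) {
  seq <- as_dna_string(x)
  hits <- as_tibble(cpp_find_ssrs(seq, params$min_repeats))
  if (nrow(hits) == 0) {
    return(tibble(start = integer(), end = integer(), motif = character(),
                  unit = integer(), n_repeats = integer(),
                  canonical_class = character()))
  }
  hits <- hits |>
    mutate(start = .data$start0 + 1L,
           end = .data$start0 + .data$unit * .data$n_repeats) |>
    select(-"start0")
  # suppress shorter-unit runs overlapping a longer-unit run
  keep <- rep(TRUE, nrow(hits))
  ord <- order(-hits$unit)
  for (i in seq_along(ord)) {
    a <- ord[i]
    if (!keep[a]) next
    ov <- hits$start <= hits$end[a] & hits$end >= hits$start[a] &
      hits$unit < hits$unit[a]
    keep[ov] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]
  hits$canonical_class <- unname(vapply(hits$motif, canonical_ssr_class, ""))
  hits |>
    select("start", "end", "motif", "unit", "n_repeats", "canonical_class") |>
    arrange(.data$start)
}

canonical_ssr_class <- function(motif) {
  rots <- function(m) {
    k <- nchar(m)
    vapply(seq_len(k), function(i) {
      paste0(substr(m, i, k), substr(m, 1, i - 1))
    }, "")
  }
  cand <- c(rots(motif), rots(dna_revcomp(motif)))
  fwd <- sort(cand)[1]
  paste0(fwd, "/", dna_revcomp(fwd))
}

#' Tandem-repeat search parameters
#'
#' Alignment weights follow the common "2 7 7 80 10 50 500" convention
#' (match +2, mismatch and indel -7, minimum score 50, maximum period 500);
#' reported hits additionally require a unit of at least `report_min_unit`
#' bp and at least `report_min_identity` percent identity between adjacent
#' copies.
#'
#' @param match,mismatch,indel Alignment weights (indels are not modelled
#'   by the simplified detector but kept for interface compatibility).
#' @param min_score Minimum tract alignment score.
#' @param min_period,max_period Repeat-unit size bounds.
#' @param report_min_unit,report_min_identity Reporting filters.
#' @return A list of class `tandem_params`.
#' @export
tandem_params <- function(match = 2, mismatch = 7, indel = 7, min_score = 50,
                          min_period = 7, max_period = 500,
                          report_min_unit = 30, report_min_identity = 90) {
  stopifnot(match > 0, mismatch > 0, min_score > 0, max_period >= min_period)
  structure(list(match = match, mismatch = mismatch, indel = indel,
                 min_score = min_score, min_period = min_period,
                 max_period = max_period, report_min_unit = report_min_unit,
                 report_min_identity = report_min_identity),
            class = "tandem_params")
}

#' Find tandem repeats (simplified detector)
#'
#' A deliberately simplified, deterministic stand-in for probabilistic
#' tandem-repeat finders: candidate periods are seeded by exact self-matches
#' on the period diagonal and extended with an X-drop rule under
#' match/mismatch weights, without indels. Identity is the match fraction
#' between adjacent copies of the tract.
#'
#' @param x A [plastome] record or DNA string.
#' @param params A [tandem_params()] object.
#' @param report_all Return all scoring tracts, ignoring the unit-size and
#'   identity reporting filters?
#' @return Tibble: start, end (1-based inclusive), period, n_copies, score,
#'   identity, unit.
#' @export
find_tandem_repeats <- function(x, params = tandem_params(), report_all = FALSE) {
  seq <- as_dna_string(x)
  hits <- as_tibble(cpp_find_tandem(
    seq, as.integer(params$min_period), as.integer(params$max_period),
    as.integer(params$match), -as.integer(params$mismatch),
    as.integer(params$min_score), as.integer(3 * params$mismatch)))
  if (nrow(hits) == 0) {
    return(tibble(start = integer(), end = integer(), period = integer(),
                  n_copies = numeric(), score = integer(),
                  identity = numeric(), unit = character()))
  }
  hits <- hits |>
    mutate(identity = 100 * .data$matches / (.data$end0 - .data$start0 - .data$period),
           n_copies = (.data$end0 - .data$start0) / .data$period,
           start = .data$start0 + 1L, end = .data$end0,
           unit = substr(rep(seq, dplyr::n()), .data$start0 + 1,
                         .data$start0 + .data$period)) |>
    select("start", "end", "period", "n_copies", "score", "identity", "unit") |>
    arrange(.data$start)
  if (!report_all) {
    hits <- hits |>
      filter(.data$period >= params$report_min_unit,
             .data$identity >= params$report_min_identity)
  }
  hits
}

#' Dispersed-repeat search parameters
#'
#' @param min_len Minimum copy length (default 30 bp).
#' @param max_hamming Maximum Hamming distance between copies (default 3).
#' @param kinds Orientations to search: `"forward"`, `"palindromic"`.
#' @return A list of class `dispersed_params`.
#' @export
dispersed_params <- function(min_len = 30, max_hamming = 3,
                             kinds = c("forward", "palindromic")) {
  stopifnot(min_len >= 8, max_hamming >= 0)
  kinds <- match.arg(kinds, several.ok = TRUE)
  structure(list(min_len = as.integer(min_len),
                 max_hamming = as.integer(max_hamming), kinds = kinds),
            class = "dispersed_params")
}

#' Find maximal dispersed repeats (forward and palindromic)
#'
#' Reports every maximal repeated pair of length >= `min_len` with at most
#' `max_hamming` mismatches, in forward and reverse-complement
#' ("palindromic") orientation. Maximality is per comparison diagonal:
#' extending the window in either direction would exceed the mismatch
#' budget; window ends are trimmed to matching bases. The two copies must
#' be disjoint and are canonicalized so `start1 < start2`. Hits with a copy
#' fully inside `mask` (e.g. one IR) are suppressed and masked positions do
#' not seed the search.
#'
#' @param x A [plastome] record or DNA string.
#' @param params A [dispersed_params()] object.
#' @param mask Optional interval set: two-column matrix or data frame of
#'   1-based inclusive start/end positions to mask.
#' @return Tibble: kind, start1, end1, start2, end2 (1-based inclusive),
#'   length, mismatches.
#' @export
find_dispersed_repeats <- function(x, params = dispersed_params(), mask = NULL) {
  seq <- as_dna_string(x)
  if (is.null(mask)) {
    ms <- integer(); me <- integer()
  } else {
    mask <- as.matrix(as.data.frame(mask))
    ms <- as.integer(mask[, 1] - 1L); me <- as.integer(mask[, 2])
  }
  hits <- as_tibble(cpp_find_dispersed(
    seq, params$min_len, params$max_hamming,
    "forward" %in% params$kinds, "palindromic" %in% params$kinds, ms, me))
  if (nrow(hits) == 0) {
    return(tibble(kind = character(), start1 = integer(), end1 = integer(),
                  start2 = integer(), end2 = integer(), length = integer(),
                  mismatches = integer()))
  }
  hits |>
    mutate(start1 = .data$start1_0 + 1L, end1 = .data$start1_0 + .data$length,
           start2 = .data$start2_0 + 1L, end2 = .data$start2_0 + .data$length) |>
    select("kind", "start1", "end1", "start2", "end2", "length", "mismatches") |>
    arrange(.data$start1, .data$start2)
}
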