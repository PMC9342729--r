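# Diagnostic marker-site evaluation: SNP/indel site discovery in per-locus
# alignments and minimal discriminating site sets for species assignment.

#' Call diagnostic SNP/indel sites in an alignment
#'
#' Every alignment column at which taxa carry different residues is
#' classified as a SNP (substitution only) or an indel (any gap among the
#' taxon residues), with the set of taxon pairs it distinguishes. When
#' several individuals share a taxon label they must agree at a column for
#' it to be called; intra-taxon polymorphic columns are skipped and listed
#' in the `skipped` attribute.
#'
#' @param aln Character matrix (rows = sequences, columns = positions) as
#'   returned by [align_locus()].
#' @param taxa Taxon label per row; defaults to row names.
#' @return Tibble of class `site_calls`: column, kind (`"SNP"`/`"indel"`),
#'   residues (named character of per-taxon residues, list column),
#'   distinguishes (list column of `"taxonA|taxonB"` pairs).
#' @export
call_diagnostic_sites <- function(aln, taxa = rownames(aln)) {
  if (is.null(taxa) || length(taxa) != nrow(aln)) {
    abort("need one taxon label per alignment row")
  }
  utaxa <- unique(taxa)
  if (length(utaxa) < 2) abort("need at least two taxa")
  skipped <- integer()
  rows <- list()
  for (j in seq_len(ncol(aln))) {
    col <- toupper(aln[, j])
    per_taxon <- vapply(utaxa, function(tx) {
      r <- unique(col[taxa == tx])
      if (length(r) > 1) NA_character_ else r
    }, "")
    if (anyNA(per_taxon)) { skipped <- c(skipped, j); next }
    if (length(unique(per_taxon)) == 1) next
    pairs <- combn(utaxa, 2, simplify = FALSE)
    dis <- vapply(pairs, function(p) {
      if (per_taxon[[p[1]]] != per_taxon[[p[2]]]) paste(p, collapse = "|")
      else NA_character_
    }, "")
    rows[[length(rows) + 1]] <- tibble(
      column = j,
      kind = if (any(per_taxon == "-")) "indel" else "SNP",
      residues = list(per_taxon),
      distinguishes = list(dis[!is.na(dis)]))
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(column = integer(), kind = character(),
           residues = list(), distinguishes = list())
  attr(out, "skipped") <- skipped
  class(out) <- c("site_calls", class(out))
  out
}

#' Minimal discriminating site set
#'
#' Finds a smallest set of diagnostic columns that together distinguish
#' every distinguishable taxon pair: greedy set cover followed by an
#' exhaustive minimality check whenever at most 20 sites are involved.
#'
#' @param sites A [call_diagnostic_sites()] result.
#' @param taxa Character vector of all taxon labels (defaults to the taxa
#'   appearing in `sites`).
#' @return A list of class `discrimination_report`: `sites`,
#'   `pairs_covered`, `pairs_uncovered`, `minimal_set` (columns),
#'   `fully_discriminating`.
#' @export
minimal_discriminating_set <- function(sites, taxa = NULL) {
  if (is.null(taxa)) {
    taxa <- unique(unlist(strsplit(unlist(sites$distinguishes), "\\|")))
  }
  all_pairs <- if (length(taxa) >= 2) {
    vapply(combn(sort(taxa), 2, simplify = FALSE),
           paste, "", collapse = "|")
  } else character()
  canon <- function(p) {
    vapply(strsplit(p, "\\|"),
           function(x) paste(sort(x), collapse = "|"), "")
  }
  site_pairs <- lapply(sites$distinguishes, canon)
  coverable <- unique(unlist(site_pairs))
  uncovered_always <- setdiff(all_pairs, coverable)

  # greedy cover over the coverable universe
  remaining <- coverable
  chosen <- integer()
  avail <- seq_along(site_pairs)
  while (length(remaining) > 0 && length(avail) > 0) {
    gain <- vapply(avail, function(i) length(intersect(site_pairs[[i]], remaining)), 0L)
    best <- avail[which.max(gain)]
    if (max(gain) == 0) break
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, site_pairs[[best]])
    avail <- setdiff(avail, best)
  }
  # exhaustive minimality verification for small site sets
  if (nrow(sites) <= 20 && length(chosen) > 1) {
    for (sz in seq_len(length(chosen) - 1)) {
      combos <- combn(seq_along(site_pairs), sz, simplify = FALSE)
      for (cb in combos) {
        if (setequal(intersect(unique(unlist(site_pairs[cb])), coverable), coverable)) {
          chosen <- cb
          break
        }
      }
      if (length(chosen) == sz) break
    }
  }
  structure(list(
    sites = sites,
    pairs_covered = coverable,
    pairs_uncovered = uncovered_always,
    minimal_set = sort(sites$column[chosen]),
    fully_discriminating = length(uncovered_always) == 0 &&
      length(coverable) == length(all_pairs)),
    class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("<discrimination_report> %d diagnostic sites; minimal set {%s}\n",
              nrow(x$sites), paste(x$minimal_set, collapse = ", ")))
  cat(sprintf("  covers %d taxon pair(s)%s\n", length(x$pairs_covered),
              if (x$fully_discriminating) ", fully discriminating"
              else sprintf("; uncovered: %s",
                           paste(x$pairs_uncovered, collapse = ", "))))
  invisible(x)
}
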