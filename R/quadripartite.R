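# Quadripartite structure: detect the LSC/IRb/SSC/IRa partition from the
# sequence alone (longest pair of disjoint, exactly matching inverted
# segments) and report the genes flanking the four junctions.

#' Detect the inverted-repeat pair and quadripartite partition
#'
#' Finds the longest pair of disjoint, exactly matching inverted segments
#' (maximal by construction: no longer pair exists), names the longer
#' intervening single-copy region LSC, and derives the four junctions
#' JLB (LSC/IRb), JSB (IRb/SSC), JSA (SSC/IRa) and JLA (IRa/LSC). The IR
#' following the LSC in genome order is IRb. Ties are broken by leftmost
#' start. Detection is exact-match: plastome IRs are identical by
#' definition here; near-identical IRs with SNPs are out of scope.
#'
#' @param x A [plastome] record or DNA string.
#' @param min_ir_len Minimum acceptable IR length (default 1000 bp).
#' @return An object of class `quadripartite_partition`: list with
#'   `regions` (tibble region/start/end/length, 0-based half-open, `end`
#'   may exceed the genome length for the origin-wrapping region) and
#'   `junctions` (named vector of boundary coordinates: the 0-based index
#'   of the first base of the downstream region).
#' @export
detect_inverted_repeat <- function(x, min_ir_len = 1000) {
  seq <- as_dna_string(x)
  n <- nchar(seq)
  hit <- cpp_longest_inverted_pair(seq, as.integer(min_ir_len))
  if (!isTRUE(hit$found)) {
    abort(sprintf("no quadripartite structure: no inverted repeat >= %d bp",
                  min_ir_len))
  }
  p1 <- hit$start1_0; p2 <- hit$start2_0; L <- hit$length
  ir1 <- c(p1, p1 + L); ir2 <- c(p2, p2 + L)
  lenA <- p2 - (p1 + L)              # between the two IR copies
  lenB <- n - L - L - lenA           # wrapping region
  if (lenA >= lenB) {
    # order (circular): B, ir1, A?? -- LSC is A, the in-between region
    lsc <- c(p1 + L, p2); ssc_start <- (p2 + L) %% n
    regions <- tibble(
      region = c("LSC", "IRb", "SSC", "IRa"),
      start = c(lsc[1], p2, ssc_start, p1),
      length = c(lenA, L, lenB, L))
  } else {
    lsc_start <- (p2 + L) %% n
    regions <- tibble(
      region = c("LSC", "IRb", "SSC", "IRa"),
      start = c(lsc_start, p1, p1 + L, p2),
      length = c(lenB, L, lenA, L))
  }
  regions$end <- regions$start + regions$length
  regions <- regions[, c("region", "start", "end", "length")]

  ira <- regions[regions$region == "IRa", ]
  irb <- regions[regions$region == "IRb", ]
  sa <- seq_slice(seq, ira$start, ira$end)
  sb <- seq_slice(seq, irb$start, irb$end)
  stopifnot(identical(sa, dna_revcomp(sb)))

  junctions <- c(
    JLB = irb$start %% n,
    JSB = regions$start[regions$region == "SSC"] %% n,
    JSA = ira$start %% n,
    JLA = regions$start[regions$region == "LSC"] %% n)
  structure(list(regions = regions, junctions = junctions, genome_length = n),
            class = "quadripartite_partition")
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat("<quadripartite_partition>\n")
  r <- x$regions
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-3s %9d..%d (%d bp)\n", r$region[i], r$start[i] + 1,
                r$end[i], r$length[i]))
  }
  cat("  junctions:",
      paste(sprintf("%s=%d", names(x$junctions), x$junctions), collapse = " "),
      "\n")
  invisible(x)
}

#' Junction report: genes flanking the four quadripartite boundaries
#'
#' For each junction, reports the nearest annotated gene on each side with
#' its distance to the boundary; a gene straddling the junction is reported
#' once with its split lengths (bp falling in the region on each side of
#' the boundary). Distances and splits are computed on half-open intervals:
#' a gene ending exactly at a junction has distance 0 and no split.
#'
#' @param rec A [plastome] record.
#' @param part A quadripartite partition; defaults to `rec$partition`.
#' @param kinds Feature kinds whose spans are considered.
#' @return A tibble of class `junction_report`: junction, coordinate
#'   (1-based index of the last base before the boundary), gene, copy,
#'   side (`"upstream"`, `"downstream"`, `"spanning"`), distance,
#'   split_upstream, split_downstream.
#' @export
junction_report <- function(rec, part = NULL, kinds = c("CDS", "tRNA", "rRNA")) {
  part <- part %||% rec$partition
  if (is.null(part)) abort("no partition: run detect_inverted_repeat() first")
  spans <- feature_spans(rec, kinds)
  n <- nchar(rec$seq)
  rows <- list()
  for (jn in names(part$junctions)) {
    j <- part$junctions[[jn]]
    if (nrow(spans) == 0) next
    # circular offset of the boundary within each gene interval
    len <- spans$end - spans$start
    off <- (j - spans$start) %% n              # bp of the gene before j
    spanning <- off > 0 & off < len
    up_d <- (j - spans$end) %% n               # gap upstream side
    down_d <- (spans$start - j) %% n
    cand <- list()
    if (any(spanning)) {
      for (i in which(spanning)) {
        cand[[length(cand) + 1]] <- tibble(
          junction = jn, coordinate = j, gene = spans$gene[i],
          copy = spans$copy[i], side = "spanning", distance = 0L,
          split_upstream = as.integer(off[i]),
          split_downstream = as.integer(len[i] - off[i]))
      }
    }
    nonspan <- which(!spanning)
    if (length(nonspan) > 0) {
      iu <- nonspan[which.min(up_d[nonspan])]
      id <- nonspan[which.min(down_d[nonspan])]
      cand[[length(cand) + 1]] <- tibble(
        junction = jn, coordinate = j, gene = spans$gene[iu],
        copy = spans$copy[iu], side = "upstream",
        distance = as.integer(up_d[iu]),
        split_upstream = NA_integer_, split_downstream = NA_integer_)
      cand[[length(cand) + 1]] <- tibble(
        junction = jn, coordinate = j, gene = spans$gene[id],
        copy = spans$copy[id], side = "downstream",
        distance = as.integer(down_d[id]),
        split_upstream = NA_integer_, split_downstream = NA_integer_)
    }
    rows <- c(rows, cand)
  }
  out <- bind_rows(rows)
  class(out) <- c("junction_report", class(out))
  out
}
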