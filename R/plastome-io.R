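# Plastome records: sequence + feature table (+ optional quadripartite
# partition). Feature coordinates are 0-based half-open internally; GenBank
# I/O converts 1-based inclusive locations at the boundary.

#' Construct a plastome record
#'
#' @param seq DNA string (character scalar).
#' @param features Feature table: one row per exon/part with columns
#'   `feature_id`, `gene`, `kind` (gene/CDS/tRNA/rRNA), `part` (1-based
#'   transcript order), `start`, `end` (0-based half-open), `strand`
#'   (`"+"`/`"-"`), `copy` (copy index distinguishing IR duplicates).
#' @param id Accession-like identifier.
#' @param circular Is the genome circular?
#' @param partition Optional quadripartite partition
#'   (see [detect_inverted_repeat()]).
#' @return An object of class `plastome`.
#' @export
plastome <- function(seq, features = empty_features(), id = "plastome",
                     circular = TRUE, partition = NULL) {
  seq <- normalize_residues(seq)
  features <- as_tibble(features)
  if (nrow(features) > 0) {
    stopifnot(all(c("feature_id", "gene", "kind", "part", "start", "end",
                    "strand", "copy") %in% names(features)))
    n <- nchar(seq)
    bad <- features$start < 0 | features$start >= n | features$end <= features$start
    if (any(bad)) abort("feature parts outside [0, genome length) or empty")
  }
  structure(list(id = id, seq = seq, circular = circular,
                 features = features, partition = partition),
            class = "plastome")
}

empty_features <- function() {
  tibble(feature_id = integer(), gene = character(), kind = character(),
         part = integer(), start = integer(), end = integer(),
         strand = character(), copy = integer())
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %s bp, %s, %d features (%d gene copies)\n",
              x$id, format(nchar(x$seq), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features), length(unique(x$features$feature_id))))
  if (!is.null(x$partition)) {
    cat("  partition:",
        paste(sprintf("%s=%d", x$partition$regions$region,
                      x$partition$regions$length), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
length.plastome <- function(x) nchar(x$seq)

as_dna_string <- function(x) {
  if (inherits(x, "plastome")) x$seq
  else if (is.character(x) && length(x) == 1) normalize_residues(x, warn_ambiguous = FALSE)
  else abort("expected a plastome record or a single DNA string")
}

# --------------------------------------------------------------------------
# GenBank flat-file reader
# --------------------------------------------------------------------------

#' Read an annotated genome from a GenBank flat file
#'
#' Captures gene, CDS, tRNA and rRNA features, including `join(...)` and
#' `complement(...)` locations, and converts coordinates from GenBank's
#' 1-based inclusive convention to the internal 0-based half-open one.
#' The circular flag is taken from the LOCUS line. Features whose location
#' cannot be parsed are skipped with a warning and recorded in the
#' `load_report` attribute.
#'
#' @param path Path to a GenBank flat file.
#' @return A [plastome] record.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) abort("not a GenBank flat file: no LOCUS line")
  id <- strsplit(trimws(sub("^LOCUS\\s+", "", locus[1])), "\\s+")[[1]][1]
  circular <- grepl("circular", locus[1], ignore.case = TRUE)

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0) abort("GenBank record has no sequence (ORIGIN missing)")
  end_rec <- grep("^//", lines)
  end_rec <- if (length(end_rec)) end_rec[end_rec > ori[1]][1] else length(lines) + 1
  seq_lines <- lines[(ori[1] + 1):(end_rec - 1)]
  seq <- paste(gsub("[^A-Za-z]", "", seq_lines), collapse = "")
  if (nchar(seq) == 0) abort("GenBank record has an empty sequence")
  seq <- normalize_residues(seq)

  feat_start <- grep("^FEATURES", lines)
  features <- empty_features()
  skipped <- character()
  if (length(feat_start) > 0) {
    block <- lines[(feat_start[1] + 1):(ori[1] - 1)]
    # split into individual features: header lines have a key in column 6-20
    is_head <- grepl("^ {5}\\S", block)
    idx <- cumsum(is_head)
    rows <- list()
    fid <- 0L
    for (g in split(block[idx > 0], idx[idx > 0])) {
      head_line <- g[1]
      key <- strsplit(trimws(head_line), "\\s+")[[1]][1]
      if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
      qual_start <- grep("^\\s+/", g)[1]
      loc_lines <- if (is.na(qual_start)) g else g[seq_len(qual_start - 1)]
      loc <- paste(c(sub("^\\s*\\S+\\s*", "", loc_lines[1]),
                     trimws(loc_lines[-1])), collapse = "")
      qual <- paste(g[-1], collapse = " ")
      name <- genbank_qualifier(qual, "gene") %||%
        genbank_qualifier(qual, "locus_tag") %||%
        genbank_qualifier(qual, "product")
      parts <- tryCatch(parse_genbank_location(loc), error = function(e) NULL)
      if (is.null(parts)) {
        skipped <- c(skipped, sprintf("%s %s: unparsable location '%s'",
                                      key, name %||% "?", loc))
        next
      }
      fid <- fid + 1L
      name <- name %||% sprintf("feature_%d", fid)
      rows[[length(rows) + 1]] <- tibble(
        feature_id = fid, gene = name, kind = key,
        part = seq_len(nrow(parts)),
        start = parts$start, end = parts$end, strand = parts$strand)
    }
    if (length(rows) > 0) {
      features <- bind_rows(rows)
      features <- features |>
        group_by(.data$gene, .data$kind) |>
        mutate(copy = match(.data$feature_id, unique(.data$feature_id))) |>
        ungroup()
    }
  }
  if (length(skipped) > 0) {
    warn(sprintf("skipped %d feature(s) with unparsable locations", length(skipped)))
  }
  rec <- plastome(seq, features, id = id, circular = circular)
  attr(rec, "load_report") <- skipped
  rec
}

genbank_qualifier <- function(qual, key) {
  m <- regmatches(qual, regexpr(sprintf('/%s="[^"]*"', key), qual))
  if (length(m) == 0) return(NULL)
  sub('"$', "", sub(sprintf('^/%s="', key), "", m))
}

# Parse a GenBank location string into a tibble (start, end, strand) of
# 0-based half-open parts in transcript order.
parse_genbank_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  parse_one <- function(s, minus = FALSE) {
    if (grepl("^complement\\(", s)) {
      inner <- sub("\\)$", "", sub("^complement\\(", "", s))
      parts <- parse_one(inner, minus = !minus)
      return(parts[rev(seq_len(nrow(parts))), , drop = FALSE])
    }
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("\\)$", "", sub("^(join|order)\\(", "", s))
      pieces <- split_top_level(inner)
      return(bind_rows(lapply(pieces, parse_one, minus = minus)))
    }
    s <- gsub("[<>]", "", s)
    if (grepl("^\\d+\\.\\.\\d+$", s)) {
      ab <- as.integer(strsplit(s, "\\.\\.")[[1]])
    } else if (grepl("^\\d+$", s)) {
      ab <- c(as.integer(s), as.integer(s))
    } else {
      abort(sprintf("unsupported location element '%s'", s))
    }
    tibble(start = ab[1] - 1L, end = ab[2],
           strand = if (minus) "-" else "+")
  }
  out <- parse_one(loc)
  if (nrow(out) == 0) abort("empty location")
  out
}

split_top_level <- function(s) {
  depth <- 0L
  chars <- strsplit(s, "")[[1]]
  cuts <- integer()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts),
         function(j) paste(chars[starts[j]:ends[j]], collapse = ""), "")
}

# --------------------------------------------------------------------------
# GenBank writer (used by the synthetic generator)
# --------------------------------------------------------------------------

#' Write a plastome record as a GenBank flat file
#'
#' @param rec A [plastome] record.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(rec, path) {
  stopifnot(inherits(rec, "plastome"))
  n <- nchar(rec$seq)
  lines <- c(sprintf("LOCUS       %-16s %10d bp    DNA     %-8s PLN 01-JAN-2024",
                     rec$id, n, if (rec$circular) "circular" else "linear"),
             sprintf("DEFINITION  %s synthetic plastome.", rec$id),
             sprintf("ACCESSION   %s", rec$id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", n))
  if (nrow(rec$features) > 0) {
    for (fid in unique(rec$features$feature_id)) {
      f <- rec$features[rec$features$feature_id == fid, , drop = FALSE]
      f <- f[order(f$part), , drop = FALSE]
      loc <- format_genbank_location(f)
      lines <- c(lines,
                 sprintf("     %-16s%s", f$kind[1], loc),
                 sprintf('                     /gene="%s"', f$gene[1]))
    }
  }
  lines <- c(lines, "ORIGIN")
  starts <- seq(1, n, by = 60)
  for (s in starts) {
    chunk <- substr(rec$seq, s, min(s + 59, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, tolower(paste(groups, collapse = " "))))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

format_genbank_location <- function(parts) {
  iv <- sprintf("%d..%d", parts$start + 1L, parts$end)
  if (all(parts$strand == "+")) {
    if (nrow(parts) == 1) return(iv)
    return(sprintf("join(%s)", paste(iv, collapse = ",")))
  }
  if (all(parts$strand == "-")) {
    iv_rev <- rev(iv)  # complement(join()) lists parts in genome order
    if (nrow(parts) == 1) return(sprintf("complement(%s)", iv))
    return(sprintf("complement(join(%s))", paste(iv_rev, collapse = ",")))
  }
  # mixed strands (trans-spliced): per-part complement, transcript order
  el <- ifelse(parts$strand == "-", sprintf("complement(%s)", iv), iv)
  sprintf("join(%s)", paste(el, collapse = ","))
}

# --------------------------------------------------------------------------
# FASTA I/O (via Biostrings)
# --------------------------------------------------------------------------

#' Write sequences to FASTA (60-column wrapping)
#'
#' @param x A named character vector of sequences, a [plastome] record, or a
#'   list of records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "plastome")) x <- setNames(x$seq, x$id)
  if (is.list(x)) x <- setNames(vapply(x, function(r) r$seq, ""),
                                vapply(x, function(r) r$id, ""))
  if (length(x) == 0) abort("no records to write")
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort("every record needs a non-empty id")
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = 60)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

# --------------------------------------------------------------------------
# Feature sequence extraction
# --------------------------------------------------------------------------

#' Extract the (spliced) sequence of an annotated feature
#'
#' Concatenates the feature's parts in transcript order, reverse
#' complementing minus-strand parts; origin-spanning parts of circular
#' genomes are handled by modular slicing.
#'
#' @param rec A [plastome] record.
#' @param feature Either a feature table subset (rows of `rec$features`
#'   belonging to one feature) or a gene name; with a gene name, `copy` and
#'   `kind` select among duplicates.
#' @param copy,kind Used when `feature` is a gene name.
#' @return A DNA string.
#' @export
extract_feature_sequence <- function(rec, feature, copy = 1L, kind = NULL) {
  if (is.character(feature) && length(feature) == 1) {
    f <- rec$features[rec$features$gene == feature & rec$features$copy == copy, ]
    if (!is.null(kind)) f <- f[f$kind == kind, ]
    if (nrow(f) == 0) abort(sprintf("no feature named '%s'", feature))
    if (length(unique(f$feature_id)) > 1) f <- f[f$feature_id == f$feature_id[1], ]
  } else {
    f <- as_tibble(feature)
  }
  if (nrow(f) == 0) abort("feature has no parts")
  f <- f[order(f$part), , drop = FALSE]
  pieces <- vapply(seq_len(nrow(f)), function(i) {
    s <- seq_slice(rec$seq, f$start[i], f$end[i], rec$circular)
    if (f$strand[i] == "-") dna_revcomp(s) else s
  }, "")
  paste(pieces, collapse = "")
}

# per-copy gene spans (0-based half-open), one row per feature_id
feature_spans <- function(rec, kinds = c("gene", "CDS", "tRNA", "rRNA")) {
  f <- rec$features[rec$features$kind %in% kinds, , drop = FALSE]
  if (nrow(f) == 0) return(tibble(feature_id = integer(), gene = character(),
                                  kind = character(), copy = integer(),
                                  start = integer(), end = integer(),
                                  strand = character()))
  f |>
    group_by(.data$feature_id, .data$gene, .data$kind, .data$copy) |>
    summarise(start = min(.data$start), end = max(.data$end),
              strand = .data$strand[1], .groups = "drop") |>
    arrange(.data$start)
}
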