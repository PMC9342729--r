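# Synthetic annotated plastomes with machine-readable ground truth:
# quadripartite layout with identical IRs, annotated genes (multi-exon,
# both strands, IR-duplicated, optionally trans-spliced), planted SSRs,
# tandem and dispersed repeats, a plantable LSC inversion flanked by a
# palindromic pair, and divergence under a two-parameter substitution
# model with per-locus rate heterogeneity and indels.

#' Specification for a synthetic plastome
#'
#' Defaults emulate a typical large plastome: an ~86 kb LSC, ~7.7 kb SSC
#' and two identical ~38.5 kb IRs (~170 kb total, GC 0.38), and a repeat
#' complement of 19 mononucleotide, 8 dinucleotide and 3 trinucleotide
#' SSRs plus a handful of tandem and dispersed repeats.
#'
#' @param lsc_len,ssc_len,ir_len Region lengths in bp.
#' @param gc Background GC fraction.
#' @param n_genes Named integer vector: genes laid out in LSC, SSC and IRb
#'   (IRb genes are mirrored into IRa).
#' @param trans_spliced Plant one trans-spliced two-part gene in the LSC?
#' @param planted_ssrs Tibble with columns motif, n_repeats (positions are
#'   assigned at generation time).
#' @param planted_tandems Tibble with columns unit_len, n_copies, mismatches.
#' @param planted_dispersed Tibble with columns kind ("forward" /
#'   "palindromic"), length, mismatches.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `plastome_spec`.
#' @export
plastome_spec <- function(lsc_len = 86108, ssc_len = 7654, ir_len = 38455,
                          gc = 0.38,
                          n_genes = c(LSC = 40L, SSC = 4L, IR = 8L),
                          trans_spliced = TRUE,
                          planted_ssrs = default_planted_ssrs(),
                          planted_tandems = default_planted_tandems(),
                          planted_dispersed = default_planted_dispersed(),
                          seed = 1L) {
  stopifnot(lsc_len > ssc_len, ir_len >= 1000, gc > 0, gc < 1)
  structure(list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len), gc = gc,
                 n_genes = n_genes, trans_spliced = trans_spliced,
                 planted_ssrs = as_tibble(planted_ssrs),
                 planted_tandems = as_tibble(planted_tandems),
                 planted_dispersed = as_tibble(planted_dispersed),
                 seed = as.integer(seed)),
            class = "plastome_spec")
}

default_planted_ssrs <- function() {
  tibble(motif = c(rep("A", 10), rep("T", 9), rep("AT", 8),
                   "AGG", "AGG", "AAG"),
         n_repeats = c(rep(10:11, 5), 11, rep(10, 8), rep(6:7, 4), 5, 5, 5))
}

default_planted_tandems <- function() {
  tibble(unit_len = c(35L, 48L), n_copies = c(2L, 3L), mismatches = c(0L, 1L))
}

default_planted_dispersed <- function() {
  tibble(kind = c("forward", "forward", "palindromic", "palindromic"),
         length = c(32L, 45L, 38L, 60L), mismatches = c(0L, 1L, 0L, 2L))
}

random_dna <- function(n, gc = 0.38) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chars <- function(v) unname(COMP[rev(v)])

#' Generate a synthetic annotated plastome with ground truth
#'
#' IRa is the exact reverse complement of IRb; genes are written so the
#' annotated transcript of every CDS starts with ATG and ends with a stop
#' codon; planted repeats are embedded verbatim with their flanks hardened
#' (forced mismatches) so every planted hit is maximal; chance SSRs are
#' removed by rejection resampling so closed-loop detector tests can assert
#' exact equality. Deterministic for a fixed spec (including its seed).
#'
#' @param spec A [plastome_spec()].
#' @return List with `record` (a [plastome] with its partition attached)
#'   and `truth` (list of tibbles: regions, junctions, genes, ssrs,
#'   tandems, dispersed).
#' @export
generate_plastome <- function(spec = plastome_spec()) {
  stopifnot(inherits(spec, "plastome_spec"))
  withr::with_seed(spec$seed, generate_plastome_impl(spec))
}

generate_plastome_impl <- function(spec) {
  L <- spec$lsc_len; S <- spec$ssc_len; IR <- spec$ir_len
  total <- L + 2L * IR + S
  lsc0 <- 0L; irb0 <- L; ssc0 <- L + IR; ira0 <- L + IR + S
  g <- random_dna(total, spec$gc)

  feats <- list(); fid <- 0L
  occupied <- list()  # 0-based half-open intervals reserved (genes + margins)
  reserve <- function(s, e) occupied[[length(occupied) + 1]] <<- c(s, e)
  is_free <- function(s, e) {
    !any(vapply(occupied, function(iv) intervals_overlap(s, e, iv[1], iv[2]), TRUE))
  }

  code <- Biostrings::getGeneticCode("11")
  sense_codons <- names(code)[code != "*"]
  make_cds <- function(n_codons) {
    paste0("ATG", paste(sample(sense_codons, n_codons - 2, replace = TRUE),
                        collapse = ""), "TAA")
  }
  write_piece <- function(start0, piece_chars, minus = FALSE) {
    if (minus) piece_chars <- revcomp_chars(piece_chars)
    g[(start0 + 1):(start0 + length(piece_chars))] <<- piece_chars
  }
  add_feature <- function(name, kind, parts, copy = 1L) {
    fid <<- fid + 1L
    feats[[length(feats) + 1]] <<- tibble(
      feature_id = fid, gene = name, kind = kind,
      part = seq_along(parts),
      start = vapply(parts, function(p) as.integer(p$start), 0L),
      end = vapply(parts, function(p) as.integer(p$end), 0L),
      strand = vapply(parts, function(p) p$strand, ""),
      copy = copy)
  }

  # ---- gene layout ---------------------------------------------------------
  lay_genes <- function(region0, region_len, n, prefix) {
    if (n == 0) return(invisible())
    slot <- region_len %/% n
    for (i in seq_len(n)) {
      s0 <- region0 + (i - 1L) * slot
      margin <- max(30L, slot %/% 5)
      area <- c(s0 + margin, s0 + slot - margin)
      kind <- if (i %% 5 == 0) "tRNA" else if (prefix == "ir" && i %% 4 == 0) "rRNA" else "CDS"
      minus <- i %% 3 == 2
      name <- sprintf("%s%s%02d", prefix,
                      c(CDS = "G", tRNA = "T", rRNA = "R")[[kind]], i)
      if (kind == "tRNA") {
        glen <- 75L
        piece <- random_dna(glen, 0.5)
        start0 <- area[1]
        write_piece(start0, piece, minus)
        add_feature(name, "tRNA",
                    list(list(start = start0, end = start0 + glen,
                              strand = if (minus) "-" else "+")))
        reserve(start0 - 5L, start0 + glen + 5L)
      } else if (kind == "rRNA") {
        glen <- min(1500L, (area[2] - area[1]) - 10L)
        piece <- random_dna(glen, 0.52)
        start0 <- area[1]
        write_piece(start0, piece, minus)
        add_feature(name, "rRNA",
                    list(list(start = start0, end = start0 + glen,
                              strand = if (minus) "-" else "+")))
        reserve(start0 - 5L, start0 + glen + 5L)
      } else {
        n_exons <- if (i %% 7 == 3) 2L else if (i %% 11 == 5) 3L else 1L
        intron <- 80L
        avail <- (area[2] - area[1]) - (n_exons - 1L) * intron - 10L
        n_codons <- max(20L, min(300L, avail %/% 3L))
        cds <- strsplit(make_cds(n_codons), "")[[1]]
        exon_len <- rep(length(cds) %/% n_exons, n_exons)
        exon_len[n_exons] <- length(cds) - sum(exon_len[-n_exons])
        # genome-order exon starts; transcript order follows strand
        starts0 <- area[1] + cumsum(c(0L, head(exon_len, -1) + intron))
        pieces <- split(cds, rep(seq_len(n_exons), exon_len))
        parts <- vector("list", n_exons)
        for (e in seq_len(n_exons)) {
          te <- if (minus) n_exons - e + 1L else e  # genome slot for exon e
          write_piece(starts0[te], pieces[[e]], minus)
          parts[[e]] <- list(start = as.integer(starts0[te]),
                             end = as.integer(starts0[te] + exon_len[e]),
                             strand = if (minus) "-" else "+")
        }
        add_feature(name, "CDS", parts)
        reserve(area[1] - 5L, starts0[n_exons] + max(exon_len) + 5L)
      }
    }
  }
  lay_genes(lsc0, L, spec$n_genes[["LSC"]], "ls")
  lay_genes(ssc0, S, spec$n_genes[["SSC"]], "ss")
  lay_genes(irb0, IR, spec$n_genes[["IR"]], "ir")

  if (isTRUE(spec$trans_spliced)) {
    # two-part gene with mixed strands and non-collinear order
    cds <- strsplit(make_cds(40L), "")[[1]]
    p1 <- cds[1:60]; p2 <- cds[61:length(cds)]
    base0 <- lsc0 + L %/% 2L + 11L
    while (!is_free(base0 - 10L, base0 + 500L)) base0 <- base0 + 97L
    write_piece(base0, p1, minus = TRUE)
    write_piece(base0 + 200L, p2, minus = FALSE)
    add_feature("tsp1", "CDS", list(
      list(start = base0, end = base0 + length(p1), strand = "-"),
      list(start = base0 + 200L, end = base0 + 200L + length(p2), strand = "+")))
    reserve(base0 - 10L, base0 + 200L + length(p2) + 10L)
  }

  # ---- plant repeats in free LSC space ------------------------------------
  pick_slot <- function(width) {
    for (try in 1:500) {
      s <- sample.int(L - width - 20L, 1) + 10L
      if (is_free(s - 8L, s + width + 8L)) return(s)
    }
    abort("could not place a planted repeat: region too crowded")
  }
  force_differ <- function(i0, from_chars) {
    # set g[i0+1] (0-based i0) to a base different from every char in from_chars
    cand <- setdiff(c("A", "C", "G", "T"), from_chars)
    g[i0 + 1] <<- sample(cand, 1)
  }

  ssr_truth <- list()
  for (r in seq_len(nrow(spec$planted_ssrs))) {
    motif <- strsplit(spec$planted_ssrs$motif[r], "")[[1]]
    u <- length(motif); nrep <- spec$planted_ssrs$n_repeats[r]
    width <- u * nrep
    s0 <- pick_slot(width)
    g[(s0 + 1):(s0 + width)] <- rep(motif, nrep)
    # break period-u extension on both flanks
    force_differ(s0 - 1L, g[s0 - 1L + u + 1])
    force_differ(s0 + width, g[s0 + width - u + 1])
    reserve(s0 - 2L, s0 + width + 2L)
    ssr_truth[[r]] <- tibble(start = as.integer(s0 + 1L),
                             end = as.integer(s0 + width),
                             motif = spec$planted_ssrs$motif[r],
                             unit = as.integer(u),
                             n_repeats = as.integer(nrep))
  }

  screen_unit <- function(n_chars, gc = 0.45) {
    # a planted unit must not itself contain an SSR or a self-repeat
    for (try in 1:200) {
      u <- random_dna(n_chars, gc)
      if (nrow(find_ssrs(paste(u, collapse = "")))) next
      return(u)
    }
    abort("could not draw a repeat unit free of chance SSRs")
  }

  tandem_truth <- list()
  for (r in seq_len(nrow(spec$planted_tandems))) {
    p <- spec$planted_tandems$unit_len[r]; nc <- spec$planted_tandems$n_copies[r]
    mm <- spec$planted_tandems$mismatches[r]
    unit <- screen_unit(p)
    tract <- rep(unit, nc)
    if (mm > 0) {
      # mutate interior positions of the final copy
      pos <- (nc - 1L) * p + sample(2:(p - 1L), mm)
      for (q in pos) tract[q] <- sample(setdiff(c("A", "C", "G", "T"), tract[q]), 1)
    }
    s0 <- pick_slot(length(tract))
    g[(s0 + 1):(s0 + length(tract))] <- tract
    force_differ(s0 - 1L, g[s0 - 1L + p + 1])
    force_differ(s0 + length(tract), g[s0 + length(tract) - p + 1])
    reserve(s0 - 2L, s0 + length(tract) + 2L)
    tandem_truth[[r]] <- tibble(start = as.integer(s0 + 1L),
                                end = as.integer(s0 + length(tract)),
                                period = as.integer(p),
                                n_copies = as.numeric(nc),
                                mismatches = as.integer(mm))
  }

  disp_truth <- list()
  for (r in seq_len(nrow(spec$planted_dispersed))) {
    len <- spec$planted_dispersed$length[r]
    mm <- spec$planted_dispersed$mismatches[r]
    kindr <- spec$planted_dispersed$kind[r]
    unit <- screen_unit(len)
    copy2 <- if (kindr == "palindromic") revcomp_chars(unit) else unit
    if (mm > 0) {
      pos <- sample(3:(len - 2L), mm)
      for (q in pos) copy2[q] <- sample(setdiff(c("A", "C", "G", "T"), copy2[q]), 1)
    }
    a0 <- pick_slot(len)
    reserve(a0 - 8L, a0 + len + 8L)
    b0 <- pick_slot(len)
    reserve(b0 - 8L, b0 + len + 8L)
    if (b0 < a0) { tmp <- a0; a0 <- b0; b0 <- tmp }
    g[(a0 + 1):(a0 + len)] <- unit
    g[(b0 + 1):(b0 + len)] <- copy2
    # harden 4 positions beyond each end so the planted pair is maximal
    for (i in 0:3) {
      if (kindr == "forward") {
        force_differ(a0 - 1L - i, g[b0 - 1L - i + 1])
        force_differ(a0 + len + i, g[b0 + len + i + 1])
      } else {
        force_differ(a0 - 1L - i, COMP[[g[b0 + len + i + 1]]])
        force_differ(a0 + len + i, COMP[[g[b0 - 1L - i + 1]]])
      }
    }
    disp_truth[[r]] <- tibble(kind = kindr,
                              start1 = as.integer(a0 + 1L),
                              end1 = as.integer(a0 + len),
                              start2 = as.integer(b0 + 1L),
                              end2 = as.integer(b0 + len),
                              length = as.integer(len),
                              mismatches = as.integer(mm))
  }

  # ---- mirror IRb into IRa -------------------------------------------------
  mirror_ira <- function(gv) {
    irb_chars <- gv[(irb0 + 1):(irb0 + IR)]
    gv[(ira0 + 1):(ira0 + IR)] <- revcomp_chars(irb_chars)
    gv
  }
  g <- mirror_ira(g)
  # harden the IRb/SSC boundary: the first SSC base must not pair with the
  # last SSC base under reverse complement, or the detected IR would extend
  # one base inward past the planted boundary
  force_differ(ssc0, COMP[[g[ssc0 + S]]])

  # IRa copies of IRb features
  irb_feats <- bind_rows(feats)
  irb_rows <- irb_feats[irb_feats$start >= irb0 & irb_feats$end <= irb0 + IR, ]
  if (nrow(irb_rows) > 0) {
    for (f in unique(irb_rows$feature_id)) {
      fr <- irb_rows[irb_rows$feature_id == f, ]
      fr <- fr[order(fr$part), ]
      irb_end <- irb0 + IR
      # the mirror map reverses genome order by itself; keeping the part
      # index preserves transcript order (exon 1 maps to the IRa interval
      # read first on the flipped strand)
      parts <- lapply(seq_len(nrow(fr)), function(e) {
        list(start = as.integer(ira0 + (irb_end - fr$end[e])),
             end = as.integer(ira0 + (irb_end - fr$start[e])),
             strand = if (fr$strand[e] == "+") "-" else "+")
      })
      add_feature(fr$gene[1], fr$kind[1], parts, copy = 2L)
    }
  }

  truth_ssrs <- bind_rows(ssr_truth)
  truth_tandems <- bind_rows(tandem_truth)
  truth_disp <- bind_rows(disp_truth)

  # ---- rejection pass: remove chance SSRs ---------------------------------
  planted_iv <- rbind(
    if (nrow(truth_ssrs)) cbind(truth_ssrs$start, truth_ssrs$end),
    if (nrow(truth_tandems)) cbind(truth_tandems$start, truth_tandems$end),
    if (nrow(truth_disp)) cbind(truth_disp$start1, truth_disp$end1),
    if (nrow(truth_disp)) cbind(truth_disp$start2, truth_disp$end2))
  for (iter in 1:80) {
    seq_now <- paste(g, collapse = "")
    hits <- find_ssrs(seq_now)
    extra <- hits
    if (nrow(truth_ssrs) > 0 && nrow(hits) > 0) {
      extra <- hits[!(hits$start %in% truth_ssrs$start &
                        hits$end %in% truth_ssrs$end), , drop = FALSE]
    }
    if (nrow(extra) == 0) break
    for (e in seq_len(nrow(extra))) {
      run <- extra$start[e]:extra$end[e]
      if (!is.null(planted_iv)) {
        inside <- vapply(run, function(p) {
          any(p >= planted_iv[, 1] & p <= planted_iv[, 2])
        }, TRUE)
        run <- run[!inside]
      }
      if (length(run) == 0) next
      p1 <- run[ceiling(length(run) / 2)]          # 1-based
      u <- extra$unit[e]
      avoid <- c(g[p1], g[max(1, p1 - u)], g[min(total, p1 + u)])
      force_differ(p1 - 1L, avoid)
      if (p1 > irb0 && p1 <= irb0 + IR) g <- mirror_ira(g)
      if (p1 > ira0) {
        # mutate the IRb twin instead, then re-mirror
        p_irb0 <- irb0 + ((ira0 + IR) - p1)        # 0-based twin in IRb
        force_differ(p_irb0, COMP[[g[p1]]])
        g <- mirror_ira(g)
      }
    }
  }
  seq_final <- paste(g, collapse = "")

  features <- bind_rows(feats)
  regions <- tibble(region = c("LSC", "IRb", "SSC", "IRa"),
                    start = c(lsc0, irb0, ssc0, ira0),
                    end = c(irb0, ssc0, ira0, total),
                    length = c(L, IR, S, IR))
  junctions <- c(JLB = irb0, JSB = ssc0, JSA = ira0, JLA = 0L)
  partition <- structure(list(regions = regions, junctions = junctions,
                              genome_length = total),
                         class = "quadripartite_partition")
  rec <- plastome(seq_final, features, id = sprintf("synth%04d", spec$seed),
                  circular = TRUE, partition = partition)
  truth <- list(regions = regions, junctions = junctions,
                genes = feature_spans(rec),
                ssrs = truth_ssrs, tandems = truth_tandems,
                dispersed = truth_disp, spec = spec)
  list(record = rec, truth = truth)
}

#' Plant a repeat-flanked inversion into a plastome
#'
#' Writes a palindromic repeat pair of `flank_len` bp (with
#' `flank_mismatches` mismatches between the copies) immediately outside
#' `interval`, then reverse complements the interval, flipping the
#' coordinates and strands of any features inside it. Bases adjacent to
#' the planted flank copies are hardened (forced mismatches) so the pair
#' is maximal and recoverable exactly.
#'
#' @param rec A [plastome] record with a partition (generator output).
#' @param interval 1-based inclusive `c(start, end)` inside the LSC, or
#'   `NULL` to choose a random gene-free-endpoint interval.
#' @param flank_len Flank repeat length (default 164 bp).
#' @param flank_mismatches Mismatches between the flank copies.
#' @param seed Optional seed (deterministic when given).
#' @return List with `record` (inverted genome) and `truth` (inversion and
#'   flank coordinates, 1-based inclusive).
#' @export
plant_inversion <- function(rec, interval = NULL, flank_len = 164,
                            flank_mismatches = 0, seed = NULL) {
  run <- function() plant_inversion_impl(rec, interval, flank_len, flank_mismatches)
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

plant_inversion_impl <- function(rec, interval, flank_len, flank_mismatches) {
  part <- rec$partition
  if (is.null(part)) abort("record needs a quadripartite partition")
  lsc <- part$regions[part$regions$region == "LSC", ]
  spans <- feature_spans(rec)
  g <- strsplit(rec$seq, "")[[1]]
  n <- length(g)
  pad <- flank_len + 4L

  free_at <- function(p0, w) {     # 0-based half-open window free of genes
    !any(intervals_overlap(p0, p0 + w, spans$start, spans$end))
  }
  if (is.null(interval)) {
    ok <- FALSE
    for (try in 1:500) {
      a0 <- lsc$start + pad + sample.int(lsc$length %/% 4L, 1)
      b0 <- lsc$end - pad - sample.int(lsc$length %/% 4L, 1)
      if (b0 - a0 < 2000) next
      if (free_at(a0 - pad, pad + 8L) && free_at(b0 - 4L, pad + 8L)) {
        ok <- TRUE; break
      }
    }
    if (!ok) abort("could not place an inversion with gene-free endpoints")
  } else {
    a0 <- interval[1] - 1L; b0 <- interval[2]
    if (a0 < lsc$start + pad || b0 > lsc$end - pad) {
      abort("inversion interval (plus flanks) must lie inside the LSC")
    }
    if (!free_at(a0 - pad, pad + 8L) || !free_at(b0 - 4L, pad + 8L)) {
      abort("inversion endpoints or flank windows overlap annotated genes")
    }
  }
  # interval to invert: 0-based [a0, b0)
  flank <- random_dna(flank_len, 0.45)
  copy3 <- revcomp_chars(flank)
  if (flank_mismatches > 0) {
    pos <- sample(3:(flank_len - 2L), flank_mismatches)
    for (q in pos) copy3[q] <- sample(setdiff(c("A", "C", "G", "T"), copy3[q]), 1)
  }
  g[(a0 - flank_len + 1):a0] <- flank          # 5' copy: [a0-flank_len, a0)
  g[(b0 + 1):(b0 + flank_len)] <- copy3        # 3' copy: [b0, b0+flank_len)
  force_diff <- function(i0, avoid) {
    g[i0 + 1] <<- sample(setdiff(c("A", "C", "G", "T"), avoid), 1)
  }
  # harden outer extensions: left of 5' copy vs right of 3' copy
  for (i in 0:3) {
    force_diff(a0 - flank_len - 1L - i, COMP[[g[b0 + flank_len + i + 1]]])
  }
  # harden inner extensions: after inversion, position a0+i pairs with b0-1-i
  for (i in 0:3) {
    force_diff(a0 + i, COMP[[g[b0 - i]]])
  }
  # invert
  g[(a0 + 1):b0] <- revcomp_chars(g[(a0 + 1):b0])
  # flip features contained in the interval
  f <- rec$features
  inside <- f$start >= a0 & f$end <= b0
  if (any(f$start < b0 & f$end > a0 & !inside)) {
    abort("a feature straddles the inversion boundary")
  }
  if (any(inside)) {
    ns <- a0 + b0 - f$end[inside]
    ne <- a0 + b0 - f$start[inside]
    f$start[inside] <- as.integer(ns); f$end[inside] <- as.integer(ne)
    f$strand[inside] <- ifelse(f$strand[inside] == "+", "-", "+")
    # transcript order is preserved; genome order of parts reverses with it
  }
  out <- plastome(paste(g, collapse = ""), f, id = paste0(rec$id, "_inv"),
                  circular = rec$circular, partition = rec$partition)
  truth <- list(
    inversion = c(start = a0 + 1L, end = b0),
    flank5 = c(start = a0 - flank_len + 1L, end = a0),
    flank3 = c(start = b0 + 1L, end = b0 + flank_len),
    flank_length = flank_len, flank_mismatches = flank_mismatches)
  list(record = out, truth = truth)
}

#' Specification for genome divergence
#'
#' @param n_genomes Number of derived genomes (star topology around the
#'   base genome; each branch has the same expected length).
#' @param rate Expected substitutions per site from base to each derived
#'   genome.
#' @param kappa Transition/transversion rate ratio (alpha/beta).
#' @param indel_rate Expected indels per intergenic site.
#' @param per_locus_multiplier Optional named numeric vector of rate
#'   multipliers keyed by IGS locus name.
#' @param seed Integer seed.
#' @return A list of class `divergence_spec`.
#' @export
divergence_spec <- function(n_genomes = 3L, rate = 0.02, kappa = 2,
                            indel_rate = 0, per_locus_multiplier = NULL,
                            seed = 1L) {
  if (kappa <= 0) abort("kappa must be positive")
  stopifnot(rate >= 0, indel_rate >= 0, n_genomes >= 1)
  structure(list(n_genomes = as.integer(n_genomes), rate = rate,
                 kappa = kappa, indel_rate = indel_rate,
                 per_locus_multiplier = per_locus_multiplier,
                 seed = as.integer(seed)),
            class = "divergence_spec")
}

# K80 substitution probabilities at distance d (expected subs/site)
k80_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.5 - 0.5 * exp(-4 * bt)     # total over both transversion targets
  c(ts = p_ts, tv = p_tv)
}

#' Evolve derived genomes from a base plastome
#'
#' Substitutions are drawn site-wise from the Kimura two-parameter
#' transition matrix at the branch's expected distance, with per-locus
#' rate multipliers applied to intergenic spacers. The two IRs evolve in
#' concert: substitutions are applied to LSC/IRb/SSC and IRb is mirrored
#' into IRa, so derived genomes keep an exact quadripartite structure.
#' Indels (length 1 + geometric) are placed outside annotated genes and
#' feature coordinates are lifted through them.
#'
#' @param rec Base [plastome] record with a partition.
#' @param dspec A [divergence_spec()].
#' @return List with `records` (named list: base first, then derived
#'   genomes) and `truth` (tibbles `expected` — per locus and genome pair
#'   expected distance per 100 sites — and `realized` substitution counts).
#' @export
diverge_genomes <- function(rec, dspec = divergence_spec()) {
  stopifnot(inherits(dspec, "divergence_spec"))
  withr::with_seed(dspec$seed, diverge_genomes_impl(rec, dspec))
}

diverge_genomes_impl <- function(rec, dspec) {
  part <- rec$partition %||% detect_inverted_repeat(rec)
  n <- nchar(rec$seq)
  base <- strsplit(rec$seq, "")[[1]]
  loci <- extract_igs(rec, part = part)
  site_mult <- rep(1, n)
  if (!is.null(dspec$per_locus_multiplier)) {
    for (lc in names(dspec$per_locus_multiplier)) {
      i <- match(lc, loci$locus)
      if (is.na(i)) abort(sprintf("unknown locus '%s' in per_locus_multiplier", lc))
      site_mult[loci$start[i]:loci$end[i]] <- dspec$per_locus_multiplier[[lc]]
    }
  }
  # substitutions are applied to LSC + IRb + SSC; IRa is then mirrored from
  # IRb (concerted IR evolution). Indels are confined to LSC intergenic
  # positions so the IR correspondence and downstream coordinates stay
  # simple to lift.
  reg <- part$regions
  ira <- reg[reg$region == "IRa", ]
  irb <- reg[reg$region == "IRb", ]
  lsc <- reg[reg$region == "LSC", ]
  mut_ok <- rep(TRUE, n)
  mut_ok[(ira$start %% n + 1L):(((ira$end - 1L) %% n) + 1L)] <- FALSE
  spans <- feature_spans(rec)
  in_gene <- rep(FALSE, n)
  for (i in seq_len(nrow(spans))) in_gene[(spans$start[i] + 1L):spans$end[i]] <- TRUE

  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv_map2 <- c(A = "T", G = "T", C = "G", T = "G")

  d_site <- dspec$rate * site_mult
  pr_ts <- numeric(n); pr_tv <- numeric(n)
  for (dv in unique(d_site)) {
    p <- k80_probs(dv, dspec$kappa)
    sel <- d_site == dv
    pr_ts[sel] <- p[["ts"]]; pr_tv[sel] <- p[["tv"]]
  }

  records <- list()
  records[[rec$id]] <- rec
  realized <- list()
  for (gidx in seq_len(dspec$n_genomes)) {
    gv <- base
    u <- runif(n)
    known <- gv %in% names(ts_map)
    do_ts <- u < pr_ts & mut_ok & known
    do_tv <- !do_ts & u < (pr_ts + pr_tv) & mut_ok & known
    gv[do_ts] <- ts_map[gv[do_ts]]
    pick2 <- runif(sum(do_tv)) < 0.5
    gv[do_tv] <- ifelse(pick2, tv_map1[gv[do_tv]], tv_map2[gv[do_tv]])
    realized[[length(realized) + 1]] <- tibble(
      genome = paste0(rec$id, "_d", gidx),
      transitions = sum(do_ts), transversions = sum(do_tv))

    # mirror IRa from IRb before any indels (coordinates still original)
    gv[(ira$start + 1L):ira$end] <-
      revcomp_chars(gv[(irb$start + 1L):irb$end])

    feats <- rec$features
    if (dspec$indel_rate > 0) {
      cand <- which(!in_gene & seq_len(n) > lsc$start & seq_len(n) <= lsc$end)
      k <- stats::rbinom(1, length(cand), dspec$indel_rate)
      if (k > 0) {
        pos <- sort(sample(cand, k), decreasing = TRUE)
        for (p0 in pos) {
          len <- 1L + stats::rgeom(1, 0.5)
          if (runif(1) < 0.5) {                    # insertion after p0
            gv <- append(gv, random_dna(len, 0.38), after = p0)
            shift <- feats$start >= p0
            feats$start[shift] <- feats$start[shift] + len
            shift <- feats$end > p0
            feats$end[shift] <- feats$end[shift] + len
          } else {                                  # deletion [p0, p0+len)
            len <- min(len, lsc$end - p0)
            if (len < 1) next
            gv <- gv[-(p0:(p0 + len - 1L))]
            feats$start <- as.integer(ifelse(feats$start >= p0 + len, feats$start - len,
                                  ifelse(feats$start >= p0, p0 - 1L, feats$start)))
            feats$end <- as.integer(ifelse(feats$end >= p0 + len, feats$end - len,
                                ifelse(feats$end >= p0, p0 - 1L, feats$end)))
          }
        }
      }
    }
    records[[paste0(rec$id, "_d", gidx)]] <-
      plastome(paste(gv, collapse = ""), feats,
               id = paste0(rec$id, "_d", gidx), circular = rec$circular)
  }
  pair_rows <- list()
  ids <- names(records)
  for (i in seq_len(nrow(loci))) {
    mult <- site_mult[loci$start[i]]
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (a >= b) next
      branches <- sum(c(a, b) != 1)      # base has index 1
      pair_rows[[length(pair_rows) + 1]] <- tibble(
        locus = loci$locus[i], genome1 = ids[a], genome2 = ids[b],
        expected_d = 100 * branches * dspec$rate * mult)
    }
  }
  list(records = records,
       truth = list(expected = bind_rows(pair_rows),
                    realized = bind_rows(realized)))
}
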