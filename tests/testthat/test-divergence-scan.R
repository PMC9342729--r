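make_rec <- function(seq, genes) {
  # genes: tibble gene,start,end (0-based half-open), strand
  feats <- dplyr::bind_rows(lapply(seq_len(nrow(genes)), function(i) {
    tibble::tibble(feature_id = i, gene = genes$gene[i], kind = "CDS",
                   part = 1L, start = genes$start[i], end = genes$end[i],
                   strand = genes$strand %||% "+", copy = 1L)
  }))
  plastome(seq, feats, id = "toy")
}

test_that("IGS adjacency: spaced genes give loci, abutting genes do not", {
  withr::with_seed(601, {
    seq <- rand_dna_str(1000)
    genes <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
                            start = c(0L, 200L, 500L, 800L),
                            end = c(100L, 300L, 600L, 900L), strand = "+")
    rec <- make_rec(seq, genes)
    loci <- extract_igs(rec)
    expect_equal(nrow(loci), 4)            # includes the circular wrap locus
    expect_setequal(loci$locus, c("g1-g2", "g2-g3", "g3-g4", "g4-g1"))
    expect_equal(loci$length[loci$locus == "g1-g2"], 100)
    # abut g1 and g2: locus disappears
    genes2 <- genes; genes2$end[1] <- 200L
    loci2 <- extract_igs(make_rec(seq, genes2))
    expect_equal(nrow(loci2), 3)
    expect_false("g1-g2" %in% loci2$locus)
  })
})

test_that("loci spanning junctions or the excluded interval are dropped", {
  gp <- generate_plastome(small_spec(602))
  loci <- extract_igs(gp$record)
  n <- nchar(gp$record$seq)
  for (j in gp$record$partition$junctions) {
    off <- (j - (loci$start - 1L)) %% n
    expect_false(any(off > 0 & off < loci$length))
  }
  # excluding an interval removes the loci intersecting it
  mid <- loci[3, ]
  loci_ex <- extract_igs(gp$record, exclude = c(mid$start, mid$end))
  expect_false(mid$locus %in% loci_ex$locus)
  expect_lt(nrow(loci_ex), nrow(loci))
  # IR-duplicated loci are collapsed: none lies fully inside IRb
  irb <- gp$record$partition$regions[
    gp$record$partition$regions$region == "IRb", ]
  expect_false(any(loci$start - 1L >= irb$start & loci$end <= irb$end))
})

test_that("pairwise alignment equals the full-DP oracle and Biostrings", {
  a <- align_locus(c(x = "ACGT", y = "AGT"))
  expect_equal(dim(a), c(2L, 4L))
  expect_equal(sum(a == "-"), 1)
  expect_equal(attr(a, "score"), oracle_nw_score("ACGT", "AGT"))
  for (s in 1:40) {
    withr::with_seed(610 + s, {
      la <- sample(3:10, 1); lb <- sample(3:10, 1)
      x <- rand_dna_str(la); y <- rand_dna_str(lb)
      got <- attr(align_locus(c(a = x, b = y)), "score")
      expect_equal(got, oracle_nw_score(x, y))
    })
  }
  # independent route: Biostrings pairwiseAlignment, same scoring scheme
  withr::with_seed(651, {
    x <- rand_dna_str(40); y <- evolve_k80(x, 0.15)
    sm <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      x, y, type = "global", substitutionMatrix = sm,
      gapOpening = 10, gapExtension = 2))
    expect_equal(attr(align_locus(c(a = x, b = y)), "score"), ref)
  })
  expect_error(align_locus(c(a = "ACGT")), "at least two")
  expect_error(align_locus(c(a = "ACGT", b = "")), "empty")
})

test_that("identical sequences align without gaps", {
  withr::with_seed(603, {
    x <- rand_dna_str(120)
    a <- align_locus(c(p = x, q = x))
    expect_equal(ncol(a), 120)
    expect_false(any(a == "-"))
  })
})

test_that("progressive alignment of related sequences preserves column homology", {
  withr::with_seed(604, {
    x <- rand_dna_str(300)
    seqs <- c(a = x, b = evolve_k80(x, 0.05), c = evolve_k80(x, 0.05),
              d = evolve_k80(x, 0.1))
    a <- align_locus(seqs)
    # equal-length, substitution-only inputs must align gap-free, so every
    # planted substitution stays in its own column
    expect_equal(ncol(a), 300)
    expect_false(any(a == "-"))
    expect_equal(paste(a["a", ], collapse = ""), x)
  })
})

test_that("K2p distance: closed form, symmetry, zero iff identical, saturation", {
  same <- k2p_distance("ACGTACGT", "ACGTACGT")
  expect_equal(same$d, 0)
  expect_equal(same$P + same$Q, 0)
  # 100 sites, 10 transitions, 5 transversions -> 17.02 per 100 sites
  a <- paste(c(rep("A", 85), rep("A", 10), rep("A", 5)), collapse = "")
  b <- paste(c(rep("A", 85), rep("G", 10), rep("C", 5)), collapse = "")
  k <- k2p_distance(a, b)
  expect_equal(k$P, 0.10)
  expect_equal(k$Q, 0.05)
  expect_equal(round(k$d, 2), 17.02)
  # symmetric
  expect_equal(k2p_distance(b, a)$d, k$d)
  # gaps and N excluded pairwise
  kg <- k2p_distance("AC-GTN", "ACTGTA")
  expect_equal(kg$n_sites, 4)
  # saturation flag instead of NaN
  sat <- k2p_distance(strrep("A", 20), strrep("G", 20))
  expect_true(sat$saturated)
  expect_true(is.na(sat$d))
  expect_error(k2p_distance("---", "AAA"), "no comparable")
})

test_that("K2p agrees with ape::dist.dna on diverged pairs", {
  for (s in 1:5) {
    withr::with_seed(620 + s, {
      x <- rand_dna_str(800)
      y <- evolve_k80(x, 0.12, kappa = 3)
      mine <- k2p_distance(x, y)$d
      m <- ape::as.DNAbin(t(sapply(list(x, y), function(z) {
        tolower(strsplit(z, "")[[1]])
      })))
      ref <- 100 * as.numeric(ape::dist.dna(m, model = "K80"))
      expect_equal(mine, ref, tolerance = 1e-8)
    })
  }
})

test_that("scan + ranking surfaces the hot locus and honours the threshold", {
  gp <- generate_plastome(small_spec(605))
  loci <- extract_igs(gp$record)
  hot <- loci$locus[which.max(loci$length)]
  dv <- diverge_genomes(gp$record, divergence_spec(
    n_genomes = 3, rate = 0.01, kappa = 2, seed = 6051,
    per_locus_multiplier = setNames(10, hot)))
  sc <- scan_igs_divergence(dv$records)
  rk <- rank_hypervariable(sc, top_n = 5, threshold = 0)
  expect_equal(rk$locus[1], hot)
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(rk$summary_max >= rk$summary_mean - 1e-12))
  # identical genomes: nothing exceeds the threshold
  sc0 <- scan_igs_divergence(list(a = gp$record, b = gp$record))
  expect_equal(nrow(rank_hypervariable(sc0, threshold = 5)), 0)
  # tidy/glance interfaces
  td <- generics::tidy(sc)
  expect_true(all(c("locus", "genome1", "genome2", "P", "Q", "d") %in% names(td)))
  gl <- generics::glance(sc)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_genomes, 4L)
})
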