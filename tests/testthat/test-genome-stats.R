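test_that("gc_content handles the definitional cases", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATGCNNNN"), 50)   # N excluded from both sides
  expect_error(gc_content("NNNN"), "no unambiguous")
})

test_that("region GC values combine length-weighted to the overall GC", {
  gp <- generate_plastome(small_spec(201))
  s <- summarize_genome(gp$record)
  w <- s$region_lens / s$total_len
  combined <- sum(w * s$gc_by_region[names(s$region_lens)])
  expect_lt(abs(combined - s$gc_overall), 0.011)
})

test_that("summarize_genome reproduces the generator spec exactly", {
  sp <- small_spec(202)
  gp <- generate_plastome(sp)
  s <- summarize_genome(gp$record)
  expect_equal(s$total_len, sp$lsc_len + sp$ssc_len + 2 * sp$ir_len)
  expect_equal(unname(s$region_lens[c("LSC", "SSC", "IRa", "IRb")]),
               c(sp$lsc_len, sp$ssc_len, sp$ir_len, sp$ir_len))
  truth <- gp$truth$genes
  uniq <- dplyr::distinct(truth, gene, kind)
  expect_equal(unname(s$gene_counts[["protein_coding"]]),
               sum(uniq$kind == "CDS"))
  expect_equal(unname(s$gene_counts[["tRNA"]]), sum(uniq$kind == "tRNA"))
  expect_equal(unname(s$gene_counts[["total"]]), nrow(uniq))
  # the "all copies" policy counts IR duplicates twice
  s2 <- summarize_genome(gp$record, count_policy = "all")
  expect_equal(unname(s2$gene_counts[["total"]]), nrow(truth))
  expect_gt(s2$gene_counts[["total"]], s$gene_counts[["total"]])
  # multiplicity table flags exactly the IR-duplicated genes
  dup <- s$gene_multiplicity[s$gene_multiplicity$copies > 1, ]
  expect_setequal(dup$gene, truth$gene[duplicated(truth$gene)])
})

test_that("summarize_genome demands a partition", {
  rec <- plastome(rand_dna_str(2000), id = "nopart")
  expect_error(summarize_genome(rec), "detect_inverted_repeat")
})

test_that("codon usage counts follow translation table 11", {
  seq <- paste0(rand_dna_str(10), "ATGTTATAA", rand_dna_str(10))
  feats <- tibble::tibble(feature_id = 1L, gene = "m1", kind = "CDS",
                          part = 1L, start = 10L, end = 19L, strand = "+",
                          copy = 1L)
  rec <- plastome(seq, feats)
  cu <- codon_usage(rec)
  expect_equal(cu$total_codons, 3)
  aa <- setNames(cu$by_amino_acid$count, cu$by_amino_acid$amino_acid)
  expect_equal(unname(aa[["L"]]), 1)
  expect_equal(unname(aa[["M"]]), 1)
  expect_equal(unname(aa[["stop"]]), 1)
  expect_equal(cu$total_codons * 3, cu$cds_length_used)
})

test_that("codon usage dedup OFF doubles two identical annotated copies", {
  cds <- "ATGGGTTCATAA"
  seq <- paste0(rand_dna_str(5), cds, rand_dna_str(7), cds, rand_dna_str(5))
  feats <- dplyr::bind_rows(
    tibble::tibble(feature_id = 1L, gene = "dup", kind = "CDS", part = 1L,
                   start = 5L, end = 17L, strand = "+", copy = 1L),
    tibble::tibble(feature_id = 2L, gene = "dup", kind = "CDS", part = 1L,
                   start = 24L, end = 36L, strand = "+", copy = 2L))
  rec <- plastome(seq, feats)
  on <- codon_usage(rec, dedup = TRUE)
  off <- codon_usage(rec, dedup = FALSE)
  expect_equal(off$total_codons, 2 * on$total_codons)
  expect_error(codon_usage(plastome(rand_dna_str(50))), "no CDS")
})

test_that("codon-table total times three equals the CDS length used", {
  gp <- generate_plastome(small_spec(203))
  cu <- codon_usage(gp$record)
  expect_equal(cu$total_codons * 3, cu$cds_length_used)
})

test_that("splicing classification separates none, cis and trans", {
  seq <- rand_dna_str(600)
  feats <- dplyr::bind_rows(
    # contiguous 2-exon plus-strand gene: cis, 1 intron
    tibble::tibble(feature_id = 1L, gene = "cis2", kind = "CDS",
                   part = 1:2, start = c(10L, 100L), end = c(40L, 130L),
                   strand = "+", copy = 1L),
    # 3-exon gene: 2 introns
    tibble::tibble(feature_id = 2L, gene = "cis3", kind = "CDS",
                   part = 1:3, start = c(200L, 260L, 320L),
                   end = c(230L, 290L, 350L), strand = "+", copy = 1L),
    # rps12-style: distant parts on mixed strands -> trans
    tibble::tibble(feature_id = 3L, gene = "tra", kind = "CDS",
                   part = 1:2, start = c(480L, 400L), end = c(510L, 430L),
                   strand = c("-", "+"), copy = 1L),
    # single exon
    tibble::tibble(feature_id = 4L, gene = "plain", kind = "CDS",
                   part = 1L, start = 550L, end = 580L, strand = "+",
                   copy = 1L))
  rec <- plastome(seq, feats)
  cs <- classify_splicing(rec)
  got <- setNames(cs$splicing, cs$gene)
  expect_equal(unname(got[c("cis2", "cis3", "tra", "plain")]),
               c("cis", "cis", "trans", "none"))
  expect_equal(setNames(cs$introns, cs$gene)[c("cis2", "cis3", "plain")],
               c(cis2 = 1L, cis3 = 2L, plain = 0L))
})

test_that("generator splicing ground truth: only the planted gene is trans", {
  gp <- generate_plastome(small_spec(204))
  cs <- classify_splicing(gp$record)
  expect_equal(cs$gene[cs$splicing == "trans"], "tsp1")
  expect_gt(sum(cs$splicing == "cis"), 0)
})
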