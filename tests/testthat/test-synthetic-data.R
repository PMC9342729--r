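test_that("generation is deterministic: same seed gives byte-identical GenBank", {
  sp <- small_spec(801)
  f1 <- withr::local_tempfile(fileext = ".gb")
  f2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(generate_plastome(sp)$record, f1)
  write_genbank(generate_plastome(sp)$record, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generator output validates against its own ground truth", {
  sp <- small_spec(802, planted_tandems = no_tandem())
  gp <- generate_plastome(sp)
  rec <- gp$record
  # IRs
  part <- detect_inverted_repeat(rec)
  expect_equal(part$regions$start, gp$truth$regions$start)
  # SSRs: detected exactly as planted
  hits <- find_ssrs(rec)
  tr <- dplyr::arrange(gp$truth$ssrs, start)
  expect_equal(hits$start, tr$start)
  expect_equal(hits$end, tr$end)
  expect_equal(hits$n_repeats, tr$n_repeats)
  # dispersed: exactly as planted once IRb is masked
  irb <- gp$truth$regions[gp$truth$regions$region == "IRb", ]
  disp <- find_dispersed_repeats(rec, mask = cbind(irb$start + 1, irb$end))
  td <- dplyr::arrange(gp$truth$dispersed, start1, start2)
  expect_equal(disp$start1, td$start1)
  expect_equal(disp$end2, td$end2)
  expect_equal(disp$kind, td$kind)
  expect_equal(disp$mismatches, td$mismatches)
})

test_that("planted tandem tracts are detected with their planted identity", {
  gp <- generate_plastome(small_spec(803))
  hits <- find_tandem_repeats(gp$record)
  tr <- dplyr::arrange(gp$truth$tandems, start)
  expect_equal(hits$start, tr$start)
  expect_equal(hits$end, tr$end)
  expect_equal(hits$period, tr$period)
})

test_that("zero-rate divergence returns identical genomes", {
  gp <- generate_plastome(small_spec(804))
  dv <- diverge_genomes(gp$record, divergence_spec(n_genomes = 2, rate = 0,
                                                   seed = 8041))
  for (r in dv$records[-1]) expect_identical(r$seq, gp$record$seq)
})

test_that("realized transition:transversion ratio obeys the kappa model", {
  gp <- generate_plastome(small_spec(805))
  dv <- diverge_genomes(gp$record, divergence_spec(n_genomes = 4, rate = 0.05,
                                                   kappa = 2, seed = 8051))
  rl <- dv$truth$realized
  p <- plastocomp:::k80_probs(0.05, 2)
  frac_exp <- p[["ts"]] / (p[["ts"]] + p[["tv"]])
  for (i in seq_len(nrow(rl))) {
    tot <- rl$transitions[i] + rl$transversions[i]
    ci <- stats::qbinom(c(0.005, 0.995), tot, frac_exp)
    expect_gte(rl$transitions[i], ci[1])
    expect_lte(rl$transitions[i], ci[2])
  }
})

test_that("derived genomes keep an exact quadripartite structure (concerted IRs)", {
  gp <- generate_plastome(small_spec(806))
  dv <- diverge_genomes(gp$record, divergence_spec(n_genomes = 2, rate = 0.03,
                                                   seed = 8061))
  for (r in dv$records[-1]) {
    part <- detect_inverted_repeat(r)
    expect_equal(part$regions$length, gp$truth$regions$length)
  }
})

test_that("indels shift coordinates but annotations stay extractable", {
  gp <- generate_plastome(small_spec(807))
  dv <- diverge_genomes(gp$record, divergence_spec(n_genomes = 1, rate = 0.01,
                                                   indel_rate = 0.002,
                                                   seed = 8071))
  der <- dv$records[[2]]
  expect_false(nchar(der$seq) == nchar(gp$record$seq))
  # every CDS still starts with a start codon modulo substitutions: check
  # lengths only (substitutions do not change part lengths)
  l0 <- gp$record$features$end - gp$record$features$start
  l1 <- der$features$end - der$features$start
  expect_equal(l1, l0)
  # sanity: extraction works at the lifted coordinates
  g1 <- der$features$gene[1]
  expect_silent(extract_feature_sequence(der, g1))
})

test_that("invalid specs are rejected", {
  expect_error(divergence_spec(kappa = 0), "kappa")
  expect_error(plastome_spec(lsc_len = 1000, ssc_len = 2000), "lsc_len")
  gp <- generate_plastome(small_spec(808))
  irb <- gp$truth$regions[gp$truth$regions$region == "IRb", ]
  expect_error(plant_inversion(gp$record,
                               interval = c(irb$start - 100, irb$start + 500),
                               flank_len = 40),
               "LSC")
})
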