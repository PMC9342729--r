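test_that("anchor map of a genome against itself lies on the main diagonal", {
  gp <- generate_plastome(plastome_spec(
    lsc_len = 8000, ssc_len = 2000, ir_len = 2000,
    n_genes = c(LSC = 6L, SSC = 2L, IR = 2L), seed = 501))
  a <- build_anchor_map(gp$record, gp$record)
  expect_gt(nrow(a), 50)
  expect_true(all(a$orientation == "same"))
  expect_true(all(a$ref_pos == a$query_pos))
})

test_that("anchor map against the reverse complement is fully inverted", {
  gp <- generate_plastome(plastome_spec(
    lsc_len = 8000, ssc_len = 2000, ir_len = 2000,
    n_genes = c(LSC = 6L, SSC = 2L, IR = 2L), seed = 502))
  rc <- revcomp_str(gp$record$seq)
  a <- build_anchor_map(gp$record$seq, rc)
  expect_gt(nrow(a), 50)
  expect_true(all(a$orientation == "inverted"))
  # positions mirror: query k-mer start = n - (ref start + k) (0-based)
  n <- nchar(rc)
  expect_true(all(a$query_pos == n - a$ref_pos - a$k + 2))
})

test_that("identical genomes yield zero inversion calls", {
  gp <- generate_plastome(small_spec(503))
  a <- build_anchor_map(gp$record, gp$record)
  expect_equal(nrow(detect_inversions(a)), 0)
})

test_that("a planted inversion is recovered and snapped exactly to truth", {
  gp <- generate_plastome(small_spec(504))
  pl <- plant_inversion(gp$record, flank_len = 164, seed = 5041)
  cv <- call_inversions(pl$record, gp$record, k = 21)
  inv <- cv$inversions
  expect_equal(nrow(inv), 1)
  expect_equal(inv$ref_start, unname(pl$truth$inversion[["start"]]))
  expect_equal(inv$ref_end, unname(pl$truth$inversion[["end"]]))
  expect_equal(inv$flank_length, 164L)
  expect_equal(inv$flank5_start, unname(pl$truth$flank5[["start"]]))
  expect_equal(inv$flank3_end, unname(pl$truth$flank3[["end"]]))
  # snapped endpoints abut the repeat copies
  expect_equal(inv$flank5_end + 1L, inv$ref_start)
  expect_equal(inv$ref_end + 1L, inv$flank3_start)
})

test_that("inversion detection is symmetric between the two genomes", {
  gp <- generate_plastome(small_spec(505))
  pl <- plant_inversion(gp$record, flank_len = 120, seed = 5051)
  fwd <- detect_inversions(build_anchor_map(pl$record, gp$record))
  rev <- detect_inversions(build_anchor_map(gp$record, pl$record))
  expect_equal(nrow(fwd), 1)
  expect_equal(nrow(rev), 1)
  # the call appears at exchanged coordinates, same anchor support
  expect_equal(fwd$ref_start, rev$query_start, tolerance = 0)
  expect_equal(fwd$n_anchors, rev$n_anchors)
})

test_that("snapped endpoints are invariant to the anchor length", {
  gp <- generate_plastome(small_spec(506))
  pl <- plant_inversion(gp$record, flank_len = 164, seed = 5061)
  ends <- vapply(c(17, 21, 25), function(k) {
    inv <- call_inversions(pl$record, gp$record, k = k)$inversions
    c(inv$ref_start, inv$ref_end)
  }, numeric(2))
  expect_equal(ends[1, ], rep(ends[1, 1], 3))
  expect_equal(ends[2, ], rep(ends[2, 1], 3))
})

test_that("an inversion without a flanking repeat returns no flank", {
  gp <- generate_plastome(small_spec(507))
  rec <- gp$record
  # invert a gene-free LSC slice by hand (no planted flanks)
  v <- strsplit(rec$seq, "")[[1]]
  a0 <- 4000L; b0 <- 12000L
  v[(a0 + 1):b0] <- rev(c(A = "T", C = "G", G = "C", T = "A")[v[(a0 + 1):b0]])
  inv_rec <- plastome(paste(v, collapse = ""), empty_features(), id = "manual",
                      partition = rec$partition)
  a <- build_anchor_map(inv_rec$seq, rec$seq)
  inv <- detect_inversions(a)
  expect_equal(nrow(inv), 1)
  expect_null(find_flanking_inverted_repeat(inv_rec$seq, inv[1, ]))
})

test_that("a 40 bp flank palindrome with one mismatch is detected as such", {
  gp <- generate_plastome(small_spec(508))
  pl <- plant_inversion(gp$record, flank_len = 40, flank_mismatches = 1,
                        seed = 5081)
  cv <- call_inversions(pl$record, gp$record, k = 21)
  expect_equal(cv$inversions$flank_length, 40L)
  expect_equal(cv$inversions$flank_mismatches, 1L)
})

test_that("repeat-homolog search: self-hit at identity 100, null on random", {
  gp <- generate_plastome(tiny_spec(509, lsc_len = 4000, ssc_len = 1000,
                                    ir_len = 1000,
                                    n_genes = c(LSC = 3L, SSC = 1L, IR = 1L)))
  unit <- substr(gp$record$seq, 501, 664)
  hit <- search_repeat_homolog(unit, gp$record)
  expect_equal(hit$identity, 100)
  expect_equal(hit$start, 501)
  expect_equal(hit$end, 664)
  expect_equal(hit$aligned_length, 164)
  # empirical null: a random unit rarely hits a random genome
  nulls <- vapply(1:100, function(s) {
    withr::with_seed(50900 + s, {
      u <- rand_dna_str(164)
      g <- rand_dna_str(5000)
      is.null(search_repeat_homolog(u, g))
    })
  }, TRUE)
  expect_gte(mean(nulls), 0.95)
})
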