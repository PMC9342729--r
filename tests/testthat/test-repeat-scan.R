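test_that("SSR thresholds and canonical classes follow the MISA convention", {
  withr::with_seed(401, {
    bg <- rand_dna_str(200, prob = c(0.1, 0.4, 0.4, 0.1))
    x10 <- paste0(substr(bg, 1, 80), "C", strrep("A", 10), "G",
                  substr(bg, 81, 160))
    hits <- find_ssrs(x10)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$canonical_class, "A/T")
    expect_equal(hits$n_repeats, 10L)
    x9 <- sub(strrep("A", 10), strrep("A", 9), x10)
    expect_equal(nrow(find_ssrs(x9)), 0)
  })
  expect_equal(plastocomp:::canonical_ssr_class("AGG"), "AGG/CCT")
  expect_equal(plastocomp:::canonical_ssr_class("CCT"), "AGG/CCT")
  expect_equal(plastocomp:::canonical_ssr_class("TA"), "AT/AT")
  expect_equal(plastocomp:::canonical_ssr_class("T"), "A/T")
})

test_that("SSR finder matches the brute-force enumerator on random sequences", {
  for (s in 1:30) {
    withr::with_seed(400 + s, {
      x <- rand_dna_str(400, prob = c(0.35, 0.15, 0.15, 0.35))
      substr(x, 50, 61) <- strrep("A", 12)
      substr(x, 150, 163) <- strrep("AT", 7)
      substr(x, 250, 264) <- strrep("AGG", 5)
      mine <- as.data.frame(find_ssrs(x)[, c("start", "end", "motif",
                                             "unit", "n_repeats")])
      for (cc in names(mine)) if (is.numeric(mine[[cc]])) {
        mine[[cc]] <- as.integer(mine[[cc]])
      }
      rownames(mine) <- NULL
      expect_equal(mine, oracle_ssrs(x), ignore_attr = TRUE)
    })
  }
})

test_that("tandem detector handles exact, mismatched and short tracts", {
  withr::with_seed(402, {
    unit <- rand_dna_str(35, prob = c(0.3, 0.25, 0.25, 0.2))
    while (nrow(find_ssrs(unit)) > 0) unit <- rand_dna_str(35)
    bg1 <- rand_dna_str(150); bg2 <- rand_dna_str(150)
    x <- paste0(bg1, unit, unit, bg2)
    hits <- find_tandem_repeats(x)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$period, 35L)
    expect_equal(hits$identity, 100)
    expect_equal(hits$start, 151L)
    expect_equal(hits$end, 220L)
    # one mismatch in the second copy: identity 34/35
    u2 <- unit
    substr(u2, 17, 17) <- setdiff(DNA4, substr(unit, 17, 17))[1]
    x2 <- paste0(bg1, unit, u2, bg2)
    h2 <- find_tandem_repeats(x2)
    expect_equal(nrow(h2), 1)
    expect_equal(h2$identity, 100 * 34 / 35, tolerance = 1e-9)
    # short-unit tract: detected internally, filtered from the report
    # (unit < 30); four copies so the tract scores above min_score
    u10 <- "ACGGTACGTC"
    x3 <- paste0(bg1, strrep(u10, 4), bg2)
    expect_equal(nrow(find_tandem_repeats(x3)), 0)
    all3 <- find_tandem_repeats(x3, report_all = TRUE)
    expect_true(any(all3$period == 10))
  })
})

test_that("planted palindromic pair is the only dispersed hit in random background", {
  withr::with_seed(403, {
    u <- rand_dna_str(30)
    bg <- rand_dna_str(500)
    # hardened flanks: force mismatching bases around both copies
    # 'AAAA' on every flank: an A pairs with comp(A) = T under the
    # palindromic comparison, so all four extension directions hit four
    # consecutive mismatches and the planted pair is maximal
    x <- paste0(substr(bg, 1, 200), "AAAA", u, "AAAA",
                substr(bg, 201, 300), "AAAA", revcomp_str(u), "AAAA",
                substr(bg, 301, 500))
    hits <- find_dispersed_repeats(x)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$kind, "palindromic")
    expect_equal(hits$length, 30L)
    expect_equal(hits$mismatches, 0L)
    expect_equal(hits$start1, 205L)
  })
})

test_that("dispersed finder matches the brute-force enumerator", {
  for (s in 1:30) {
    withr::with_seed(430 + s, {
      x <- rand_dna_str(250)
      u <- rand_dna_str(18)
      substr(x, 20, 37) <- u
      substr(x, 120, 137) <- u
      substr(x, 170, 187) <- revcomp_str(u)
      mine <- normalize_hits(
        find_dispersed_repeats(x, dispersed_params(min_len = 10,
                                                   max_hamming = 1)))
      expect_equal(mine, oracle_dispersed(x, 10, 1), ignore_attr = TRUE)
    })
  }
})

test_that("every reported dispersed hit re-extracts to its claimed mismatch count", {
  gp <- generate_plastome(small_spec(404, planted_tandems = no_tandem()))
  irb <- gp$truth$regions[gp$truth$regions$region == "IRb", ]
  hits <- find_dispersed_repeats(gp$record,
                                 mask = cbind(irb$start + 1, irb$end))
  expect_gt(nrow(hits), 0)
  for (i in seq_len(nrow(hits))) {
    c1 <- substr(gp$record$seq, hits$start1[i], hits$end1[i])
    c2 <- substr(gp$record$seq, hits$start2[i], hits$end2[i])
    if (hits$kind[i] == "palindromic") c2 <- revcomp_str(c2)
    mm <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    expect_equal(mm, hits$mismatches[i])
  }
})

test_that("masking one IR suppresses the IR pair; unmasked scans report it", {
  gp <- generate_plastome(small_spec(405, planted_tandems = no_tandem()))
  irb <- gp$truth$regions[gp$truth$regions$region == "IRb", ]
  ir_len <- irb$end - irb$start
  unmasked <- find_dispersed_repeats(gp$record)
  expect_true(any(unmasked$length >= ir_len))
  masked <- find_dispersed_repeats(gp$record,
                                   mask = cbind(irb$start + 1, irb$end))
  expect_false(any(masked$length >= ir_len))
})
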