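test_that("GenBank round trip preserves residues and feature coordinates", {
  gp <- generate_plastome(small_spec(101))
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(gp$record, f)
  rec2 <- read_genbank(f)
  expect_identical(rec2$seq, gp$record$seq)
  expect_true(rec2$circular)
  o1 <- dplyr::arrange(gp$record$features, feature_id, part)
  o2 <- dplyr::arrange(rec2$features, feature_id, part)
  expect_equal(o2$start, o1$start)
  expect_equal(o2$end, o1$end)
  expect_equal(o2$strand, o1$strand)
  expect_equal(o2$kind, o1$kind)
  # FASTA round trip on the same record
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(gp$record, fa)
  expect_identical(unname(read_fasta(fa)[1]), gp$record$seq)
})

test_that("complement(join(...)) extraction equals the hand-built transcript", {
  # 0-based: exon1 [10,19), exon2 [30,42) on the minus strand
  seq <- rand_dna_str(60)
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       toy01             60 bp    DNA     circular PLN 01-JAN-2024",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             complement(join(11..19,31..42))",
    '                     /gene="mini"',
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(paste(
      substring(seq, seq(1, 60, 10), seq(10, 60, 10)), collapse = " "))),
    "//"), gb)
  rec <- read_genbank(gb)
  expect_equal(nrow(rec$features), 2)
  expect_true(all(rec$features$strand == "-"))
  got <- extract_feature_sequence(rec, "mini")
  # complement(join(a,b)) reads the concatenation a+b reverse complemented
  manual <- revcomp_str(paste0(substr(seq, 11, 19), substr(seq, 31, 42)))
  expect_identical(got, manual)
  # transcript order: the downstream (second listed) interval comes first
  expect_gt(rec$features$start[1], rec$features$start[2])
})

test_that("trans-spliced mixed-strand parts are joined in transcript order", {
  gp <- generate_plastome(small_spec(102))
  tsp <- gp$record$features[gp$record$features$gene == "tsp1", ]
  expect_setequal(unique(tsp$strand), c("+", "-"))
  transcript <- extract_feature_sequence(gp$record, "tsp1")
  expect_true(startsWith(transcript, "ATG"))
  expect_true(endsWith(transcript, "TAA"))
  # length equals the sum of part lengths
  expect_equal(nchar(transcript), sum(tsp$end - tsp$start))
})

test_that("features spanning the origin of a circular genome extract contiguously", {
  seq <- rand_dna_str(100)
  feats <- tibble::tibble(feature_id = 1L, gene = "wrap", kind = "CDS",
                          part = 1L, start = 90L, end = 110L, strand = "+",
                          copy = 1L)
  rec <- plastome(seq, feats, id = "wrap1")
  got <- extract_feature_sequence(rec, "wrap")
  expect_identical(got, paste0(substr(seq, 91, 100), substr(seq, 1, 10)))
  expect_equal(nchar(got), 20)
})

test_that("FASTA writer wraps at 60 columns and validates ids", {
  x <- setNames(rand_dna_str(1234), "long1")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(x, fa)
  lines <- readLines(fa)
  expect_equal(sum(!startsWith(lines, ">")), ceiling(1234 / 60))
  expect_identical(unname(read_fasta(fa)), unname(x))
  expect_error(write_fasta(setNames("ACGT", ""), fa), "non-empty id")
  expect_error(write_fasta(character(), fa), "no records")
})

test_that("GenBank reader errors on missing sequence, warns on bad locations", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       empty             0 bp    DNA     linear PLN",
               "FEATURES             Location/Qualifiers"), gb)
  expect_error(read_genbank(gb), "ORIGIN")
  writeLines(c(
    "LOCUS       badloc            20 bp    DNA     linear PLN",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(5..qq)",
    '                     /gene="broken"',
    "     tRNA            3..12",
    '                     /gene="fine"',
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt",
    "//"), gb)
  expect_warning(rec <- read_genbank(gb), "unparsable")
  expect_equal(unique(rec$features$gene), "fine")
  expect_length(attr(rec, "load_report"), 1)
})

test_that("parsed features agree with Biopython on a generated record", {
  gp <- generate_plastome(plastome_spec(
    lsc_len = 6000, ssc_len = 1500, ir_len = 1500,
    n_genes = c(LSC = 5L, SSC = 2L, IR = 2L), seed = 103))
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(gp$record, gb)
  py <- sprintf(paste0(
    "from Bio import SeqIO\n",
    "r = SeqIO.read('%s', 'genbank')\n",
    "fs = [f for f in r.features if f.type in ('CDS','tRNA','rRNA')]\n",
    "print(len(r.seq))\n",
    "print(len(fs))\n",
    "for f in fs:\n",
    "    for p in f.location.parts:\n",
    "        print(int(p.start), int(p.end), p.strand)\n"), gb)
  out <- tryCatch(system2("python", "-", input = py, stdout = TRUE),
                  warning = function(w) character())
  expect_gt(length(out), 2)
  expect_equal(as.integer(out[1]), nchar(gp$record$seq))
  expect_equal(as.integer(out[2]),
               length(unique(gp$record$features$feature_id)))
  py_parts <- do.call(rbind, lapply(out[-(1:2)], function(l) {
    as.integer(strsplit(l, " ")[[1]])
  }))
  mine <- gp$record$features
  expect_setequal(paste(py_parts[, 1], py_parts[, 2]),
                  paste(mine$start, mine$end))
})
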