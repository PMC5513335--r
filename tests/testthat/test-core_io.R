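# Sequence I/O, window extraction and call output.

test_that("read_fasta parses, normalizes and validates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1 first read", "ACGT"), f)
  x <- read_fasta(f)
  expect_s3_class(x, "dna_set")
  expect_equal(names(x), "r1")
  expect_equal(unclass(x)[["r1"]], "ACGT")
  expect_equal(attr(x, "desc")[["r1"]], "first read")

  writeLines(c(">r1", "acgu"), f)
  expect_equal(unclass(read_fasta(f))[["r1"]], "ACGT")

  writeLines(c(">r1", "ACRT"), f)
  expect_warning(x <- read_fasta(f), "1 non-ACGTN")
  expect_equal(unclass(x)[["r1"]], "ACNT")

  writeLines(c(">r1", "ACGT", ">r1", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(c("r1", "ACGT"), f)
  expect_error(read_fasta(f), "line 1")

  file.create(f2 <- withr::local_tempfile(fileext = ".fa"))
  expect_error(read_fasta(f2), "empty file")
})

test_that("read_fastq parses Phred+33 and validates structure", {
  f <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), f)
  x <- read_fastq(f)
  expect_equal(attr(x, "qual")[["r1"]], rep(40L, 4))

  writeLines(c("@r1", "ACGT", "+", "III"), f)
  expect_error(read_fastq(f), "line 4")

  writeLines(character(0), f)
  expect_length(read_fastq(f), 0)

  writeLines(c("@r1", "ACGT", "+"), f)
  expect_error(read_fastq(f), "truncated")
})

test_that("FASTA and FASTQ round trips preserve ids, residues and qualities", {
  set.seed(1)
  x <- dna_set(setNames(c(rand_seq(80), rand_seq(33)), c("a", "b")),
               desc = c("alpha", ""),
               qual = list(sample(0:60, 80, TRUE), sample(0:60, 33, TRUE)))
  fa <- withr::local_tempfile(fileext = ".fa")
  fq <- withr::local_tempfile(fileext = ".fq")
  write_fasta(x, fa)
  y <- read_fasta(fa)
  expect_equal(names(y), names(x))
  expect_equal(unname(c(unclass(y))), unname(c(unclass(x))))
  expect_equal(attr(y, "desc")[["a"]], "alpha")
  write_fastq(x, fq)
  z <- read_fastq(fq)
  expect_equal(unname(c(unclass(z))), unname(c(unclass(x))))
  expect_equal(attr(z, "qual"), setNames(attr(x, "qual"), names(x)))
})

test_that("extract_window pads, clips and honours strand", {
  set.seed(2)
  g <- dna_set(setNames(rand_seq(10000), "chr1"))
  w <- extract_window(g, "chr1", 5000, 5001, pad = 1000)
  expect_equal(nchar(unclass(w)[[1]]), 2001L)
  w <- extract_window(g, "chr1", 0, 5, pad = 1000)
  expect_equal(nchar(unclass(w)[[1]]), 1005L)
  w <- extract_window(g, "chr1", 100, 150, pad = 0)
  expect_equal(unclass(w)[[1]], gseq(g, "chr1", 100, 150))
  wm <- extract_window(g, "chr1", 100, 150, pad = 0, strand = "-")
  expect_equal(unclass(wm)[[1]], revcomp(gseq(g, "chr1", 100, 150)))
  expect_error(extract_window(g, "chr9", 0, 5), "unknown chromosome")
  # length identity for assorted pads
  for (p in c(0, 7, 500, 9999)) {
    w <- extract_window(g, "chr1", 9000, 9500, pad = p)
    expect_equal(nchar(unclass(w)[[1]]),
                 min(9500 + p, 10000) - max(9000 - p, 0))
  }
})

test_that("call output converts coordinates and round-trips", {
  calls <- data.frame(call_id = c("teasv_001", "teasv_002"),
                      chrom = c("chr4", "chr1"),
                      start = c(99L, 1234L), end = c(100L, 1300L),
                      position = c(99L, 1267L),
                      te_family = "EVDlike", orientation = c("antisense", "sense"),
                      n_support = c(2L, 1L), support = c("r1,r2", "r3"),
                      support_categories = c("split,split", "full_span"),
                      status = "validated", is_reference_copy = FALSE,
                      stringsAsFactors = FALSE)
  bed <- withr::local_tempfile(fileext = ".bed")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_calls(calls, bed, "BED")
  write_calls(calls, gff, "GFF3")
  bl <- readLines(bed)
  expect_equal(bl[2], "chr4\t99\t100\tteasv_001;EVDlike\t2\t-")
  gl <- read.table(gff, sep = "\t")
  expect_equal(gl$V4, calls$start + 1L)  # gff_start = bed_start + 1
  expect_equal(gl$V5, calls$end)         # gff_end = bed_end
  expect_equal(gl$V3[1], "transposable_element_insertion_site")

  # BED round trip is byte-identical
  back <- read_calls_bed(bed)
  bed2 <- withr::local_tempfile(fileext = ".bed")
  write_calls(back, bed2, "BED")
  expect_identical(readLines(bed), readLines(bed2))

  # empty call set -> header-only files
  write_calls(calls[0, ], bed, "BED")
  expect_equal(readLines(bed), "#chrom\tstart\tend\tname\tscore\tstrand")
  write_calls(calls[0, ], gff, "GFF3")
  expect_equal(readLines(gff), "##gff-version 3")
})

test_that("dna_set enforces id uniqueness and quality lengths", {
  expect_error(dna_set(setNames(c("AC", "GT"), c("x", "x"))), "duplicate")
  expect_error(dna_set(setNames("ACGT", "x"), qual = list(1:3)),
               "quality length")
  expect_error(dna_set(setNames("ACGT", "a b")), "whitespace")
})

test_that("run configuration round-trips losslessly through YAML", {
  cfg <- run_config(scoring = scoring_scheme(min_hsp_score = 60L),
                    thresholds = detection_thresholds(cluster_tolerance = 80L),
                    seed = 42L, log_level = "DEBUG")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back, cfg)
})

test_that("truth records export to BED in both coordinate spaces", {
  truth <- data.frame(chrom = "chr1", pos_ref = 1000L, pos_mut = 6305L,
                      te_family = "fam", orientation = "antisense",
                      tsd_length = 5L, te_length = 5300L,
                      stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".bed")
  truth_to_bed(truth, f, space = "ref")
  b <- read_calls_bed(f)
  expect_equal(b$start, 1000L)
  expect_equal(b$strand, "-")
  truth_to_bed(truth, f, space = "mut")
  expect_equal(read_calls_bed(f)$start, 6305L)
})
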