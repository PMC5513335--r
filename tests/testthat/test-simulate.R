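# Simulator: genomes, insertion planting, read generation.

test_that("simulated genomes are reproducible and GC-faithful", {
  g1 <- simulate_genome(c(60000, 40000), gc = 0.36, seed = 7)
  g2 <- simulate_genome(c(60000, 40000), gc = 0.36, seed = 7)
  expect_identical(unclass(g1), unclass(g2))
  expect_equal(names(g1), c("chr1", "chr2"))
  expect_equal(unname(nchar(g1)), c(60000L, 40000L))
  gc_obs <- sum(nchar(gsub("[AT]", "", g1))) / sum(nchar(g1))
  expect_lt(abs(gc_obs - 0.36), 0.02)
  g5 <- simulate_genome(rep(12000, 5), seed = 1)
  expect_length(g5, 5)
})

test_that("planting inserts TE, TSD and updates coordinates", {
  set.seed(40)
  g <- simulate_genome(1e5, 0.36)
  lib <- synthetic_te(5300, 400)
  fam <- lib$families$family[1]
  res <- plant_insertions(g, lib,
                          insertion_plan("chr1", c(30000L, 60000L), fam,
                                         c("sense", "antisense"),
                                         tsd_length = 5L))
  expect_equal(nchar(unclass(res$genome)[[1]]), 100000L + 2L * 5305L)
  tr <- res$truth
  expect_equal(tr$pos_mut, c(30000L, 60000L + 5305L))
  # junction structure: flank | TE | TSD | flank
  te <- te_seq(lib, fam)
  m <- res$genome
  expect_equal(gseq(m, "chr1", tr$pos_mut[1], tr$pos_mut[1] + 5300), te)
  expect_equal(gseq(m, "chr1", tr$pos_mut[2], tr$pos_mut[2] + 5300),
               revcomp(te))  # antisense plan inserts the reverse complement
  tsd <- gseq(g, "chr1", 30000 - 5, 30000)
  expect_equal(gseq(m, "chr1", tr$pos_mut[1] - 5, tr$pos_mut[1]), tsd)
  expect_equal(gseq(m, "chr1", tr$pos_mut[1] + 5300, tr$pos_mut[1] + 5305), tsd)
  # flanks resume exactly
  expect_equal(gseq(m, "chr1", tr$pos_mut[1] + 5305, tr$pos_mut[1] + 5405),
               gseq(g, "chr1", 30000, 30100))
  # zero plans leave the genome untouched
  res0 <- plant_insertions(g, lib, insertion_plan(character(0), integer(0), fam))
  expect_identical(unclass(res0$genome), unclass(g))
  expect_equal(nrow(res0$truth), 0L)
  # overlapping plans are rejected
  expect_error(plant_insertions(g, lib,
                                insertion_plan("chr1", c(500L, 500L), fam)),
               "overlapping")
})

test_that("cut-paste plans excise their donor", {
  set.seed(41)
  g <- simulate_genome(50000, 0.36)
  lib <- synthetic_te(2000, 300)
  fam <- lib$families$family[1]
  plan <- insertion_plan("chr1", 30000L, fam, mechanism = "cut_paste",
                         donor_chrom = "chr1", donor_start = 10000L,
                         donor_end = 12000L, tsd_length = 3L)
  res <- plant_insertions(g, lib, plan)
  expect_equal(nchar(unclass(res$genome)[[1]]), 50000L - 2000L + 2003L)
  # sequence across the excised donor is joined
  expect_equal(gseq(res$genome, "chr1", 9900, 10100),
               paste0(gseq(g, "chr1", 9900, 10000), gseq(g, "chr1", 12000, 12100)))
  # insertion lands at the shifted position
  expect_equal(gseq(res$genome, "chr1", res$truth$pos_mut,
                    res$truth$pos_mut + 2000), te_seq(lib, fam))
})

test_that("read simulation is seed-deterministic with faithful lengths", {
  set.seed(42)
  g <- simulate_genome(2e5, 0.36)
  model <- read_error_model(median_length = 1000, sdlog_length = 1.2,
                            min_length = 100)
  r1 <- simulate_reads(g, n_reads = 50, model = model, seed = 9)
  r2 <- simulate_reads(g, n_reads = 50, model = model, seed = 9)
  expect_identical(unclass(r1), unclass(r2))
  # median template length within 5% of the configured median (n = 1000)
  rl <- simulate_reads(g, n_reads = 1000, model = model, seed = 10)
  org <- parse_read_origin(names(rl))
  expect_lt(abs(median(org$end - org$start) / 1000 - 1), 0.05)
})

test_that("coverage targets are met by template base count", {
  set.seed(43)
  g <- simulate_genome(1e6, 0.36)
  model <- read_error_model(total_error = 0)
  reads <- simulate_reads(g, coverage = 0.8, model = model, seed = 11)
  org <- parse_read_origin(names(reads))
  total <- sum(org$end - org$start)
  expect_lt(abs(total / 8e5 - 1), 0.10)
  # noiseless reads are exact (reverse-complemented) substrings
  for (i in seq_len(min(10, length(reads)))) {
    tmpl <- gseq(g, org$chrom[i], org$start[i], org$end[i])
    if (org$strand[i] == "-") tmpl <- revcomp(tmpl)
    expect_identical(unclass(reads)[[i]], tmpl)
  }
})

test_that("error model hits the requested identity", {
  set.seed(44)
  g <- simulate_genome(1e5, 0.36)
  model <- read_error_model(total_error = 0.10, median_length = 2000,
                            sdlog_length = 0.3, min_length = 500)
  reads <- simulate_reads(g, n_reads = 40, model = model, seed = 12)
  filt <- filter_genomic_reads(reads, g)
  s <- summarize_reads(filt, 1e5)
  expect_lt(abs(s$mean_identity_pct - 90), 2)
})

test_that("qualifying-read accounting follows the documented rules", {
  truth <- data.frame(chrom = "chr1", pos_ref = 10000L, pos_mut = 10000L,
                      te_family = "fam", orientation = "sense",
                      tsd_length = 5L, te_length = 5300L,
                      stringsAsFactors = FALSE)
  te_end <- 10000 + 5305
  ids <- c(
    sprintf("q1|chr1|%d|%d|+", 10000 - 2000, 10000 + 2000),  # flank 2000 of 4000
    sprintf("q2|chr1|%d|%d|+", 10000 - 450, 10000 + 4050),   # flank 450 of 4500: 10% < 33%
    sprintf("q3|chr1|%d|%d|+", 10000 - 350, 10000 + 350),    # flank 350 < 400
    sprintf("q4|chr1|%d|%d|-", te_end - 2000, te_end + 2000), # right junction
    sprintf("q5|chr1|%d|%d|+", 10000 - 900, te_end + 800),   # full span
    sprintf("q6|chr1|%d|%d|+", 20000, 24000))                # no overlap
  q <- qualifying_junction_reads(ids, truth)
  expect_equal(q$n_qualifying, 3L)
  d <- attr(q, "detail")
  expect_setequal(substr(d$read_id, 1, 2), c("q1", "q4", "q5"))
})

test_that("the benchmark report is internally consistent", {
  rep <- cached_benchmark(genome_length = 2e5, n_insertions = 3,
                          coverage = 5, seed = 11)
  f <- rep$funnel
  expect_true(all(diff(c(f[["n_reads"]], f[["n_kept"]], f[["n_candidates"]],
                         f[["n_te_hit"]], f[["n_validated"]])) <= 0))
  expect_equal(f[["n_calls"]], nrow(rep$calls))
  expect_equal(sum(rep$eval$truth$detected), rep$eval$tp)
  expect_true(all(rep$signatures$pass))
  # JSON serialisation round-trips the headline numbers
  jf <- withr::local_tempfile(fileext = ".json")
  benchmark_report_json(rep, jf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(back$eval$recall, rep$eval$recall)
  expect_equal(back$funnel$n_calls, nrow(rep$calls))
})
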