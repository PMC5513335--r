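# Detection: locus validation, scan filters, clustering, evaluation.

# assemble a signature row for verify_locus_construct without running a scan
manual_sig <- function(w, read_id, read_length, block_start, block_end,
                       strand = "+", full_span = FALSE) {
  data.frame(read_id = read_id, read_length = read_length, chrom = "chr1",
             block_start = block_start, block_end = block_end,
             block_strand = strand, block_span = block_end - block_start,
             block_score = 2L * (block_end - block_start),
             te_family = w$fam, te_q_start = NA_integer_,
             te_q_end = NA_integer_, te_span = NA_integer_,
             te_strand = "+", te_score = NA_integer_,
             junction_side = "right", breakpoint = block_end,
             full_span = full_span, orientation = "sense",
             hsp_sum_locus = NA_integer_, fraction_of_read = NA_real_,
             two_sided_junction = NA, clipped = NA, pass = NA,
             stringsAsFactors = FALSE)
}

test_that("locus concordance applies the HSP-sum and fraction rules", {
  w <- small_world()
  p <- 30000L
  mk <- function(blk, total) paste0(gseq(w$ref, "chr1", p, p + blk),
                                    rand_seq(total - blk))
  set.seed(30)
  # 500 of 1200 genomic: sum > 300 and fraction 0.417 within [0.33, 0.75]
  s1 <- verify_locus_construct(manual_sig(w, "ok", 1200L, p, p + 500L),
                               mk(500, 1200), w$ctx)
  expect_true(s1$pass)
  expect_gt(s1$hsp_sum_locus, 300)
  expect_true(abs(s1$fraction_of_read - 0.42) < 0.03)
  # 290 of 1200: HSP sum below the strict 300 floor
  s2 <- verify_locus_construct(manual_sig(w, "low", 1200L, p, p + 290L),
                               mk(290, 1200), w$ctx)
  expect_false(s2$pass)
  # 1000 of 1200: fraction 0.83 above the 75% ceiling
  s3 <- verify_locus_construct(manual_sig(w, "high", 1200L, p, p + 1000L),
                               mk(1000, 1200), w$ctx)
  expect_false(s3$pass)
  expect_gt(s3$fraction_of_read, 0.75)
})

test_that("two-sided junctions are recognised against the construct", {
  w <- small_world()
  tr <- w$truth[1, ]  # sense insertion at 45000
  # read: 800 bp left flank + first 900 bp of the element, noiseless
  rd <- gseq(w$mut, "chr1", tr$pos_mut - 800, tr$pos_mut + 900)
  sig <- manual_sig(w, "jun", nchar(rd), tr$pos_ref - 800L, tr$pos_ref)
  out <- verify_locus_construct(sig, rd, w$ctx)
  expect_true(out$pass)
  expect_true(out$two_sided_junction)
})

test_that("ab initio scan applies the block and TE-length filters", {
  w <- small_world()
  tr <- w$truth[1, ]
  reads <- dna_set(setNames(c(
    # 90% genomic -> rejected by the 75% block ceiling
    paste0(gseq(w$ref, "chr1", 20000, 20900), rand_seq(100)),
    # 500 genomic + only 150 TE -> rejected at the TE-library step
    paste0(gseq(w$mut, "chr1", tr$pos_mut - 500, tr$pos_mut + 150),
           rand_seq(550)),
    # 1000 genomic + 1000 TE across the junction -> signature
    gseq(w$mut, "chr1", tr$pos_mut - 1000, tr$pos_mut + 1000)),
    c("mostly_genomic", "short_te", "junction")))
  sigs <- ab_initio_scan(reads, w$ctx)
  expect_equal(sigs$read_id, "junction")
  expect_true(sigs$pass)
  expect_lt(abs(sigs$breakpoint - tr$pos_ref), 20)
  expect_equal(sigs$orientation, "sense")
  expect_equal(sigs$junction_side, "right")
  fun <- attr(sigs, "funnel")
  expect_true(all(diff(c(fun[["n_reads"]], fun[["n_candidates"]],
                         fun[["n_te_hit"]], fun[["n_validated"]])) <= 0))
})

test_that("antisense insertions are reported with antisense orientation", {
  w <- small_world()
  tr <- w$truth[2, ]  # antisense insertion at 75000
  rd <- gseq(w$mut, "chr1", tr$pos_mut - 1200, tr$pos_mut + 800)
  sigs <- ab_initio_scan(dna_set(setNames(rd, "anti")), w$ctx)
  expect_equal(nrow(sigs), 1L)
  expect_equal(sigs$orientation, "antisense")
  expect_lt(abs(sigs$breakpoint - tr$pos_ref), 20)
})

test_that("reads spanning the native reference copy produce no call", {
  w <- small_world()
  # native copy junction region of the reference genome itself
  rd <- gseq(w$ref, "chr1", 15000 - 900, 15000 + 1100)
  sigs <- ab_initio_scan(dna_set(setNames(rd, "native")), w$ctx)
  if (nrow(sigs)) {
    calls <- cluster_calls(sigs, w$ctx)
    expect_true(all(calls$is_reference_copy))
  } else {
    succeed()
  }
  # plain genomic read far from any element: never a signature
  rd2 <- gseq(w$ref, "chr1", 90000, 94000)
  expect_equal(nrow(ab_initio_scan(dna_set(setNames(rd2, "plain")), w$ctx)), 0L)
})

test_that("breakpoints cluster by tolerance, family and chromosome", {
  w <- small_world()
  mksig <- function(bp, read_id, fam = w$fam) {
    data.frame(read_id = read_id, read_length = 4000L, chrom = "chr1",
               block_start = bp - 1000L, block_end = bp,
               block_strand = "+", block_span = 1000L, block_score = 2000L,
               te_family = fam, te_q_start = 1000L, te_q_end = 2000L,
               te_span = 1000L, te_strand = "+", te_score = 2000L,
               junction_side = "right", breakpoint = bp, full_span = FALSE,
               orientation = "sense", hsp_sum_locus = 1000L,
               fraction_of_read = 0.5, two_sided_junction = TRUE,
               clipped = FALSE, pass = TRUE, stringsAsFactors = FALSE)
  }
  # eleven signatures at nine loci (two loci doubly supported within 100 bp)
  loci <- c(5000, 12000, 20000, 28000, 36000, 50000, 60000, 70000, 80000)
  bps <- c(loci, 5040, 28090)
  sigs <- do.call(rbind, lapply(seq_along(bps), function(i) {
    mksig(as.integer(bps[i]), sprintf("r%02d", i))
  }))
  calls <- cluster_calls(sigs, w$ctx)
  expect_equal(nrow(calls), 9L)
  expect_equal(sum(calls$n_support == 2), 2L)
  # permutation invariance and idempotence
  set.seed(31)
  calls2 <- cluster_calls(sigs[sample(nrow(sigs)), ], w$ctx)
  expect_equal(calls, calls2)
  # 150 bp apart stays split
  two <- rbind(mksig(40000L, "a"), mksig(40150L, "b"))
  expect_equal(nrow(cluster_calls(two, w$ctx)), 2L)
  # a signature at the native copy is flagged as the reference copy
  ref_sig <- mksig(15002L, "nat")
  expect_true(cluster_calls(ref_sig, w$ctx)$is_reference_copy)
  # orientation consensus: 2 sense vs 1 antisense -> sense; 1v1 -> unknown
  mix <- rbind(mksig(40000L, "a"), mksig(40010L, "b"), mksig(40020L, "c"))
  mix$orientation <- c("sense", "antisense", "sense")
  expect_equal(cluster_calls(mix, w$ctx)$orientation, "sense")
  tie <- mix[1:2, ]
  expect_equal(cluster_calls(tie, w$ctx)$orientation, "unknown")
})

test_that("evaluation matches calls to truth within the window", {
  truth <- data.frame(chrom = "chr1", pos_ref = c(1000L, 5000L),
                      pos_mut = c(1000L, 6305L), te_family = "fam",
                      orientation = "sense", tsd_length = 5L,
                      te_length = 1300L, stringsAsFactors = FALSE)
  calls <- data.frame(call_id = c("c1", "c2"), chrom = "chr1",
                      start = c(1000L, 5004L), end = c(1001L, 5005L),
                      position = c(1000L, 5004L), te_family = "fam",
                      orientation = "sense", n_support = 1L, support = "r",
                      support_categories = "split", status = "validated",
                      is_reference_copy = FALSE, stringsAsFactors = FALSE)
  ev <- evaluate_against_truth(calls, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$mean_abs_offset, 2)
  # empty call set
  ev0 <- evaluate_against_truth(calls[0, ], truth)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 1)
  # reference-copy calls are excluded before scoring
  calls$is_reference_copy <- c(FALSE, TRUE)
  ev2 <- evaluate_against_truth(calls, truth)
  expect_equal(ev2$n_calls, 1L)
  expect_equal(ev2$tp, 1L)
  # a call 200 bp away does not match under the 50 bp window
  far <- calls[1, ]; far$position <- 1200L; far$is_reference_copy <- FALSE
  ev3 <- evaluate_against_truth(far, truth)
  expect_equal(ev3$tp, 0L)
})

test_that("noiseless end-to-end run is sound and complete", {
  w <- small_world()
  model <- read_error_model(total_error = 0, median_length = 3500,
                            sdlog_length = 0, min_length = 500)
  reads <- simulate_reads(w$mut, coverage = 6, model = model, seed = 77)
  filt <- filter_genomic_reads(reads, w$ctx)
  kept <- reads[filt$read_id[filt$kept]]
  sigs <- ab_initio_scan(kept, w$ctx, hsp_cache = attr(filt, "hsps"))
  calls <- cluster_calls(sigs, w$ctx)
  ev <- evaluate_against_truth(calls, w$truth)
  q <- qualifying_junction_reads(reads, w$truth)
  expect_true(all(q$n_qualifying >= 1))   # both junctions received evidence
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_lt(ev$mean_abs_offset, 10)
  # no signature from reads drawn entirely outside TE copies
  org <- parse_read_origin(sigs$read_id)
  for (i in seq_len(nrow(sigs))) {
    tr <- w$truth[w$truth$chrom == org$chrom[i], ]
    ov <- pmin(org$end[i], tr$pos_mut + tr$te_length) - pmax(org$start[i], tr$pos_mut)
    expect_true(any(ov > 0))
  }
})

test_that("targeted and ab initio scans validate the same sites", {
  w <- small_world()
  model <- read_error_model(total_error = 0.13, median_length = 3000,
                            sdlog_length = 0.4, min_length = 500)
  reads <- simulate_reads(w$mut, coverage = 4, model = model, seed = 78)
  filt <- filter_genomic_reads(reads, w$ctx)
  kept <- reads[filt$read_id[filt$kept]]
  cache <- attr(filt, "hsps")
  ab <- cluster_calls(ab_initio_scan(kept, w$ctx, hsp_cache = cache), w$ctx)
  tg <- targeted_scan(kept, w$ctx, hsp_cache = cache)
  tc <- cluster_calls(tg$signatures, w$ctx)
  ab <- ab[!ab$is_reference_copy, ]
  tc <- tc[!tc$is_reference_copy, ]
  expect_equal(nrow(ab), nrow(tc))
  expect_true(all(abs(sort(ab$position) - sort(tc$position)) <= 100))
})

test_that("raising detection thresholds never adds signatures", {
  w <- small_world()
  model <- read_error_model(total_error = 0.13, median_length = 3000,
                            sdlog_length = 0.4, min_length = 500)
  reads <- simulate_reads(w$mut, coverage = 3, model = model, seed = 79)
  filt <- filter_genomic_reads(reads, w$ctx)
  kept <- reads[filt$read_id[filt$kept]]
  cache <- attr(filt, "hsps")
  n_sig <- function(th) {
    ctx <- detection_context(w$ref, w$lib, thresholds = th)
    nrow(ab_initio_scan(kept, ctx, hsp_cache = cache))
  }
  along_block <- vapply(c(300L, 400L, 700L), function(b) {
    n_sig(detection_thresholds(min_block_len = b))
  }, 1L)
  along_te <- vapply(c(150L, 200L, 400L), function(t) {
    n_sig(detection_thresholds(min_te_len = t))
  }, 1L)
  expect_true(all(diff(along_block) <= 0))
  expect_true(all(diff(along_te) <= 0))
  expect_gt(along_block[1], 0)
})
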