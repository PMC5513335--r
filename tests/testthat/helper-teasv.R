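# Shared fixtures: random sequences, a Smith-Waterman oracle, and cached
# benchmark runs (several acceptance properties probe the same simulated
# datasets, so each configuration is computed once per test session).

options(teasv.log_level = "WARN")

rand_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# apply n random edits (substitution / insertion / deletion) to a sequence
mutate_seq <- function(s, n_edits) {
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in seq_len(n_edits)) {
    op <- sample(3L, 1L)
    p <- sample(length(b), 1L)
    if (op == 1L) {
      b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
    } else if (op == 2L) {
      b <- append(b, sample(c("A", "C", "G", "T"), 1L), p)
    } else {
      b <- b[-p]
    }
  }
  paste(b, collapse = "")
}

# independent affine-gap Smith-Waterman oracle (Biostrings implementation)
sw_oracle_score <- function(q, s, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                mismatch = mismatch,
                                                baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    q, s, type = "local", substitutionMatrix = m,
    gapOpening = gap_open, gapExtension = gap_extend))
}

.bench_cache <- new.env(parent = emptyenv())

cached_benchmark <- function(...) {
  cfg <- benchmark_config(...)
  key <- digest_key(cfg)
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- run_benchmark(cfg)
  }
  .bench_cache[[key]]
}

digest_key <- function(cfg) {
  paste(deparse(cfg[setdiff(names(cfg), c("scoring", "thresholds"))]),
        collapse = "")
}

# small noiseless world reused by several detection tests: 100-kb genome
# with a native TE copy and two planted insertions (one antisense)
small_world <- function() {
  if (is.null(.bench_cache$world)) {
    set.seed(424241)
    g <- simulate_genome(1e5, 0.36)
    lib <- synthetic_te(5300, 400, 0.36)
    fam <- lib$families$family[1]
    ref <- plant_insertions(g, lib, insertion_plan("chr1", 15000L, fam))$genome
    mut <- plant_insertions(ref, lib,
                            insertion_plan("chr1", c(45000L, 75000L), fam,
                                           c("sense", "antisense")))
    ctx <- detection_context(ref, lib)
    .bench_cache$world <- list(base = g, ref = ref, mut = mut$genome,
                               truth = mut$truth, lib = lib, fam = fam,
                               ctx = ctx)
  }
  .bench_cache$world
}

# pull a subsequence of a genome (1-based substr wrapper on 0-based coords)
gseq <- function(genome, chrom, start, end) {
  substr(unclass(genome)[[chrom]], start + 1L, end)
}
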