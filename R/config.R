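# Scoring scheme, detection thresholds and run configuration.

#' Alignment scoring scheme
#'
#' BLAST-style nucleotide scoring used throughout the package. Defaults
#' mirror the -r 2 -G 5 -E 2 parameter set used for error-tolerant long-read
#' search, with the companion mismatch penalty of -3; gap costs are expressed
#' as positive costs (a gap of length k costs `gap_open + k * gap_extend`).
#' Significance is controlled by a minimum HSP score and length rather than
#' E-values, which keeps results deterministic and independent of database
#' size.
#'
#' The remaining fields parameterise the seeded aligner: exact `k`-mer seeds
#' are clustered by diagonal (`diag_jump` tolerance, `max_seed_gap` query
#' locality, at least `min_seeds` seeds per cluster, `max_occ` repeat cutoff)
#' and extended by banded affine-gap DP with `band_pad` extra diagonals on
#' each side of the seed envelope. Pairs smaller than `full_dp_limit` cells
#' are aligned exhaustively (band spanning every diagonal), in which case the
#' best HSP score equals the full Smith-Waterman optimum. `chain_max_gap` is
#' the per-axis gap tolerance when joining co-linear HSPs into blocks.
#'
#' @param match_reward match reward (positive).
#' @param mismatch_penalty mismatch cost (positive).
#' @param gap_open gap opening cost (positive).
#' @param gap_extend per-base gap extension cost (positive).
#' @param min_hsp_score minimum reported HSP score.
#' @param min_hsp_length minimum reported HSP length (alignment columns).
#' @param k seed k-mer size.
#' @param band_pad extra diagonals on each side of a seed cluster.
#' @param min_seeds minimum seeds per cluster before extension.
#' @param max_seed_gap maximum query gap between seeds of one cluster.
#' @param diag_jump maximum diagonal step between clustered seeds.
#' @param max_occ k-mers occurring more often than this are skipped.
#' @param chain_max_gap maximum query/subject gap when chaining HSPs.
#' @param full_dp_limit cell-count threshold below which alignment is
#'   exhaustive.
#' @return a list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match_reward = 2L, mismatch_penalty = 3L,
                           gap_open = 5L, gap_extend = 2L,
                           min_hsp_score = 50L, min_hsp_length = 40L,
                           k = 11L, band_pad = 100L, min_seeds = 2L,
                           max_seed_gap = 1000L, diag_jump = 50L,
                           max_occ = 400L, chain_max_gap = 50L,
                           full_dp_limit = 4e6) {
  s <- list(match_reward = as.integer(match_reward),
            mismatch_penalty = as.integer(mismatch_penalty),
            gap_open = as.integer(gap_open),
            gap_extend = as.integer(gap_extend),
            min_hsp_score = as.integer(min_hsp_score),
            min_hsp_length = as.integer(min_hsp_length),
            k = as.integer(k), band_pad = as.integer(band_pad),
            min_seeds = as.integer(min_seeds),
            max_seed_gap = as.integer(max_seed_gap),
            diag_jump = as.integer(diag_jump),
            max_occ = as.integer(max_occ),
            chain_max_gap = as.integer(chain_max_gap),
            full_dp_limit = as.numeric(full_dp_limit))
  stopifnot(s$match_reward > 0, s$mismatch_penalty > 0,
            s$gap_open >= 0, s$gap_extend > 0,
            s$min_hsp_length >= 1, s$k >= 4, s$k <= 15)
  class(s) <- "scoring_scheme"
  s
}

as_cpp_params <- function(scoring) {
  list(match = scoring$match_reward, mismatch = scoring$mismatch_penalty,
       gap_open = scoring$gap_open, gap_extend = scoring$gap_extend,
       min_hsp_score = scoring$min_hsp_score,
       min_hsp_length = scoring$min_hsp_length,
       k = scoring$k, band_pad = scoring$band_pad,
       min_seeds = scoring$min_seeds, max_seed_gap = scoring$max_seed_gap,
       diag_jump = scoring$diag_jump, max_occ = scoring$max_occ,
       full_dp_limit = scoring$full_dp_limit)
}

#' Detection thresholds
#'
#' Numeric rules of the split-read pipeline. A read is a breakpoint candidate
#' when its best genomic block spans at least `min_block_len` bases and at
#' most `max_block_frac` of the read; the remaining portion must align over
#' at least `min_te_len` bases of a library TE; locus validation re-aligns
#' the read against the genomic block padded by `locus_window / 2` (ab
#' initio) or `flank_pad` (targeted) on each side, concatenated with the TE,
#' and requires a locus-side HSP-length sum strictly greater than
#' `min_hsp_sum` comprising between `hsp_sum_frac_low` and
#' `hsp_sum_frac_high` of the read length (bounds inclusive). Breakpoints
#' within `cluster_tolerance` bases merge into one call. `min_genomic_frac`
#' is the read-retention bound of the upstream QC filter.
#'
#' @param min_block_len minimum contiguous genomic block (bp).
#' @param max_block_frac maximum genomic block fraction of read length.
#' @param min_te_len minimum TE-aligned length of the remainder (bp).
#' @param locus_window width of the re-validation locus window (bp).
#' @param min_hsp_sum locus HSP-length sum must exceed this (bp, strict).
#' @param hsp_sum_frac_low,hsp_sum_frac_high inclusive bounds on the locus
#'   HSP sum as a fraction of read length.
#' @param flank_pad flank extracted around a targeted-mode locus (bp).
#' @param cluster_tolerance breakpoint clustering distance (bp).
#' @param min_genomic_frac minimum genomically-aligned fraction for read QC.
#' @return a list of class `detection_thresholds`.
#' @export
detection_thresholds <- function(min_block_len = 400L, max_block_frac = 0.75,
                                 min_te_len = 200L, locus_window = 2000L,
                                 min_hsp_sum = 300L,
                                 hsp_sum_frac_low = 0.33,
                                 hsp_sum_frac_high = 0.75,
                                 flank_pad = 1000L,
                                 cluster_tolerance = 100L,
                                 min_genomic_frac = 0.20) {
  t <- list(min_block_len = as.integer(min_block_len),
            max_block_frac = as.numeric(max_block_frac),
            min_te_len = as.integer(min_te_len),
            locus_window = as.integer(locus_window),
            min_hsp_sum = as.integer(min_hsp_sum),
            hsp_sum_frac_low = as.numeric(hsp_sum_frac_low),
            hsp_sum_frac_high = as.numeric(hsp_sum_frac_high),
            flank_pad = as.integer(flank_pad),
            cluster_tolerance = as.integer(cluster_tolerance),
            min_genomic_frac = as.numeric(min_genomic_frac))
  stopifnot(t$hsp_sum_frac_low > 0,
            t$hsp_sum_frac_low < t$hsp_sum_frac_high,
            t$hsp_sum_frac_high <= 1,
            t$min_block_len > 0, t$min_te_len > 0, t$locus_window > 0,
            t$flank_pad >= 0, t$cluster_tolerance >= 0)
  class(t) <- "detection_thresholds"
  t
}

#' Run configuration
#'
#' Bundles scoring, thresholds, seed and output settings; serializes
#' losslessly to YAML via [write_config()] / [read_config()].
#'
#' @param scoring a [scoring_scheme()].
#' @param thresholds a [detection_thresholds()].
#' @param seed integer random seed.
#' @param out_dir output directory.
#' @param log_level "DEBUG", "INFO" or "WARN".
#' @return a list of class `run_config`.
#' @export
run_config <- function(scoring = scoring_scheme(),
                       thresholds = detection_thresholds(),
                       seed = 1L, out_dir = ".", log_level = "INFO") {
  stopifnot(log_level %in% c("DEBUG", "INFO", "WARN"))
  cfg <- list(scoring = scoring, thresholds = thresholds,
              seed = as.integer(seed), out_dir = out_dir,
              log_level = log_level)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  x <- list(scoring = unclass(cfg$scoring),
            thresholds = unclass(cfg$thresholds),
            seed = cfg$seed, out_dir = cfg$out_dir,
            log_level = cfg$log_level)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(scoring = do.call(scoring_scheme, x$scoring),
             thresholds = do.call(detection_thresholds, x$thresholds),
             seed = x$seed, out_dir = x$out_dir, log_level = x$log_level)
}
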