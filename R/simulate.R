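# Synthetic data: random genomes, TE-insertion planting with ground truth,
# and a nanopore-like noisy long-read simulator.

#' Simulate a random genome
#'
#' I.i.d. bases at the requested GC content. Chromosomes are named
#' `chr1..chrN`. Identical arguments and seed give identical sequences.
#'
#' @param chrom_lengths integer vector of chromosome lengths.
#' @param gc GC fraction in (0, 1).
#' @param seed optional integer seed (set just before drawing).
#' @return a [dna_set()] genome.
#' @export
simulate_genome <- function(chrom_lengths = 1e6, gc = 0.36, seed = NULL) {
  stopifnot(gc > 0, gc < 1, all(chrom_lengths >= 1))
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(chrom_lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
          collapse = "")
  }, "")
  names(seqs) <- paste0("chr", seq_along(seqs))
  dna_set(seqs, normalize = FALSE)
}

#' Generate a synthetic LTR retrotransposon
#'
#' A random element with identical long terminal repeats at both ends,
#' mimicking the structure of an active COPIA-like element (LTR - internal
#' region - LTR). The sequence is random, sharing no ancestry with any real
#' element.
#'
#' @param length total element length (bp).
#' @param ltr_length length of each terminal repeat (bp).
#' @param gc GC fraction.
#' @param family family id.
#' @param seed optional integer seed.
#' @return a single-entry [te_library()].
#' @export
synthetic_te <- function(length = 5300, ltr_length = 400, gc = 0.36,
                         family = "TEsim1", seed = NULL) {
  stopifnot(ltr_length * 2 < length)
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ltr <- paste(sample(c("A", "C", "G", "T"), ltr_length, replace = TRUE,
                      prob = p), collapse = "")
  internal <- paste(sample(c("A", "C", "G", "T"), length - 2 * ltr_length,
                           replace = TRUE, prob = p), collapse = "")
  te_library(setNames(paste0(ltr, internal, ltr), family),
             te_class = "LTR_retrotransposon", ltr_length = ltr_length)
}

#' Build an insertion plan table
#'
#' @param chrom,pos insertion points (0-based, between `pos-1` and `pos`).
#' @param family TE family to insert.
#' @param orientation "sense" or "antisense".
#' @param tsd_length target-site duplication length (bp); defaults to 5 for
#'   LTR retrotransposons and 3 for DNA transposons, the respective family
#'   norms.
#' @param mechanism "copy_paste" (donor untouched) or "cut_paste" (a stated
#'   donor interval is excised; supply `donor_chrom`, `donor_start`,
#'   `donor_end`).
#' @param donor_chrom,donor_start,donor_end donor interval for cut-paste.
#' @return a plan data frame for [plant_insertions()].
#' @export
insertion_plan <- function(chrom, pos, family, orientation = "sense",
                           tsd_length = NULL, mechanism = "copy_paste",
                           donor_chrom = NA, donor_start = NA,
                           donor_end = NA) {
  n <- max(length(chrom), length(pos))
  df <- data.frame(chrom = rep_len(chrom, n), pos = rep_len(as.integer(pos), n),
                   family = rep_len(family, n),
                   orientation = rep_len(orientation, n),
                   tsd_length = rep_len(if (is.null(tsd_length)) NA_integer_
                                        else as.integer(tsd_length), n),
                   mechanism = rep_len(mechanism, n),
                   donor_chrom = rep_len(donor_chrom, n),
                   donor_start = rep_len(as.integer(donor_start), n),
                   donor_end = rep_len(as.integer(donor_end), n),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$orientation %in% c("sense", "antisense")),
            all(df$mechanism %in% c("copy_paste", "cut_paste")))
  df
}

default_tsd <- function(te_class) {
  ifelse(te_class == "LTR_retrotransposon", 5L, 3L)
}

#' Plant TE insertions into a genome
#'
#' At each planned point the element sequence (reverse-complemented for
#' antisense plans) is inserted with the `tsd_length` bases preceding the
#' point duplicated on both flanks, producing the canonical
#' flank-TSD-TE-TSD-flank junction structure. Cut-paste plans additionally
#' excise their stated donor interval (applied before the insertions, in
#' original coordinates). Truth records give the insertion point in both
#' coordinate spaces: `pos_ref` (input-genome coordinates, where a
#' split-read caller mapping against the input genome will place the
#' breakpoint) and `pos_mut` (start of the inserted material in the output
#' genome, used for read-origin bookkeeping).
#'
#' @param genome a [dna_set()] genome.
#' @param lib a [te_library()] providing the planned families.
#' @param plans an [insertion_plan()] data frame, sorted by (chrom, pos),
#'   non-overlapping.
#' @return a list: `genome` (mutated) and `truth` (data frame).
#' @export
plant_insertions <- function(genome, lib, plans) {
  stopifnot(inherits(lib, "te_library"))
  if (nrow(plans) == 0) {
    return(list(genome = genome, truth = empty_truth()))
  }
  o <- order(plans$chrom, plans$pos)
  if (!identical(o, seq_len(nrow(plans)))) {
    stop("plans must be sorted by (chrom, pos)")
  }
  if (any(duplicated(plans[, c("chrom", "pos")]))) {
    stop("overlapping plans: duplicate insertion points")
  }
  tsd <- plans$tsd_length
  cls <- lib$families$te_class[match(plans$family, lib$families$family)]
  tsd[is.na(tsd)] <- default_tsd(cls[is.na(tsd)])
  plans$tsd_length <- tsd

  seqs <- unclass(genome)
  # cut-paste donors first, in original coordinates
  cut <- plans[plans$mechanism == "cut_paste", , drop = FALSE]
  shift_at <- function(chrom, x) {
    # coordinate shift at original position x after donor excisions
    if (!nrow(cut)) return(0L)
    d <- cut[cut$donor_chrom == chrom, , drop = FALSE]
    -sum(pmin(d$donor_end, x) - pmin(d$donor_start, x))
  }
  if (nrow(cut)) {
    for (i in seq_len(nrow(cut))) {
      dc <- cut$donor_chrom[i]
      if (!dc %in% names(seqs)) stop("unknown donor chromosome")
      inside <- plans$chrom == dc & plans$pos > cut$donor_start[i] &
        plans$pos < cut$donor_end[i]
      if (any(inside)) stop("a donor interval overlaps an insertion point")
    }
    for (dc in unique(cut$donor_chrom)) {
      d <- cut[cut$donor_chrom == dc, , drop = FALSE]
      d <- d[order(-d$donor_start), , drop = FALSE]  # excise right to left
      for (i in seq_len(nrow(d))) {
        s <- seqs[[dc]]
        seqs[[dc]] <- paste0(substr(s, 1, d$donor_start[i]),
                             substr(s, d$donor_end[i] + 1L, nchar(s)))
      }
    }
  }

  truth <- list()
  for (chrom in unique(plans$chrom)) {
    if (!chrom %in% names(seqs)) stop(sprintf("unknown chromosome '%s'", chrom))
    p <- plans[plans$chrom == chrom, , drop = FALSE]
    s <- seqs[[chrom]]
    offset <- 0L
    for (i in seq_len(nrow(p))) {
      pos0 <- p$pos[i] + shift_at(chrom, p$pos[i])  # after donor excision
      pos <- pos0 + offset
      if (pos < p$tsd_length[i] || pos > nchar(s)) {
        stop(sprintf("insertion point %d out of bounds on %s", p$pos[i], chrom))
      }
      te <- te_seq(lib, p$family[i])
      if (p$orientation[i] == "antisense") te <- cpp_revcomp(te)
      tsd_seq <- substr(s, pos - p$tsd_length[i] + 1L, pos)
      s <- paste0(substr(s, 1, pos), te, tsd_seq,
                  substr(s, pos + 1L, nchar(s)))
      truth[[length(truth) + 1]] <- data.frame(
        chrom = chrom, pos_ref = p$pos[i], pos_mut = pos,
        te_family = p$family[i], orientation = p$orientation[i],
        tsd_length = p$tsd_length[i], te_length = nchar(te),
        stringsAsFactors = FALSE)
      offset <- offset + nchar(te) + p$tsd_length[i]
    }
    seqs[[chrom]] <- s
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$chrom, truth$pos_ref), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = dna_set(seqs, normalize = FALSE), truth = truth)
}

empty_truth <- function() {
  data.frame(chrom = character(0), pos_ref = integer(0),
             pos_mut = integer(0), te_family = character(0),
             orientation = character(0), tsd_length = integer(0),
             te_length = integer(0), stringsAsFactors = FALSE)
}

#' Write truth records as BED
#' @param truth truth data frame from [plant_insertions()].
#' @param path output path.
#' @param space "ref" (input-genome coordinates) or "mut" (post-insertion).
#' @export
truth_to_bed <- function(truth, path, space = c("ref", "mut")) {
  space <- match.arg(space)
  pos <- if (space == "ref") truth$pos_ref else truth$pos_mut
  df <- data.frame(truth$chrom, pos, pos + 1L,
                   paste0(truth$te_family, ";tsd=", truth$tsd_length),
                   0L, ifelse(truth$orientation == "sense", "+", "-"))
  con <- file(path, "w")
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
  close(con)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Nanopore-like read error model
#'
#' Per-base error process: each template base is substituted, deleted, or
#' followed by an insertion with probabilities `total_error` times the
#' respective share. Read lengths are log-normal, parameterised by median
#' and log-scale spread; the default spread 1.5 puts about 72 percent of
#' reads between 500 and 15000 bases when the median is 4600.
#'
#' @param total_error total per-base error rate between 0 and 0.3.
#' @param mismatch_share,insertion_share,deletion_share error composition
#'   (must sum to 1).
#' @param median_length median read length (bp).
#' @param sdlog_length log-normal spread (sdlog).
#' @param min_length minimum template length (bp).
#' @return a list of class `read_error_model`.
#' @export
read_error_model <- function(total_error = 0.13, mismatch_share = 0.5,
                             insertion_share = 0.25, deletion_share = 0.25,
                             median_length = 4600, sdlog_length = 1.5,
                             min_length = 200) {
  stopifnot(total_error >= 0, total_error <= 0.3,
            abs(mismatch_share + insertion_share + deletion_share - 1) < 1e-9,
            median_length >= min_length, sdlog_length >= 0)
  m <- list(total_error = total_error, mismatch_share = mismatch_share,
            insertion_share = insertion_share,
            deletion_share = deletion_share,
            median_length = median_length, sdlog_length = sdlog_length,
            min_length = as.integer(min_length))
  class(m) <- "read_error_model"
  m
}

BASES <- c("A", "C", "G", "T")
# substitution alternatives per base
ALT <- matrix(c("C", "G", "T",
                "A", "G", "T",
                "A", "C", "T",
                "A", "C", "G"), nrow = 4, byrow = TRUE,
              dimnames = list(BASES, NULL))

apply_read_errors <- function(seq, model) {
  e <- model$total_error
  if (e == 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  u <- runif(n)
  pm <- e * model$mismatch_share
  pd <- e * model$deletion_share
  pi <- e * model$insertion_share
  mis <- which(u < pm & b %in% BASES)
  del <- u >= pm & u < pm + pd
  ins <- u >= pm + pd & u < pm + pd + pi
  if (length(mis)) {
    b[mis] <- ALT[cbind(match(b[mis], BASES),
                        sample.int(3L, length(mis), replace = TRUE))]
  }
  b[del] <- ""
  insb <- character(n)
  n_ins <- sum(ins)
  if (n_ins) insb[ins] <- sample(BASES, n_ins, replace = TRUE)
  paste(paste0(b, insb), collapse = "")
}

#' Simulate noisy long reads
#'
#' Template start positions are uniform over the genome (chromosomes
#' weighted by length), template lengths log-normal (truncated at the
#' chromosome end), strands equiprobable, and errors applied per base
#' according to the model. Read ids encode the true origin as
#' `name|chrom|start|end|strand` (template coordinates on the source
#' genome, 0-based half-open) for downstream evaluation.
#'
#' @param genome the source [dna_set()] genome (typically the mutated one).
#' @param coverage target coverage (total template bases / genome length);
#'   give either this or `n_reads`.
#' @param n_reads exact number of reads to draw.
#' @param model a [read_error_model()].
#' @param seed optional integer seed.
#' @return a [dna_set()] of reads.
#' @export
simulate_reads <- function(genome, coverage = NULL, n_reads = NULL,
                           model = read_error_model(), seed = NULL) {
  stopifnot(xor(is.null(coverage), is.null(n_reads)))
  if (!is.null(seed)) set.seed(seed)
  lens <- nchar(genome)
  G <- sum(lens)
  if (max(lens) < model$min_length) {
    stop("genome shorter than the minimum read length; coverage target unattainable")
  }
  target <- if (!is.null(coverage)) coverage * G else Inf
  max_n <- if (!is.null(n_reads)) n_reads else Inf
  seqs <- character(0); ids <- character(0)
  total <- 0; i <- 0L
  while (total < target && i < max_n) {
    i <- i + 1L
    len <- max(model$min_length,
               as.integer(round(model$median_length *
                                  exp(model$sdlog_length * stats::rnorm(1)))))
    ci <- sample.int(length(lens), 1L, prob = lens)
    chrom <- names(lens)[ci]
    start <- sample.int(lens[[ci]], 1L) - 1L
    end <- min(lens[[ci]], start + len)
    if (end - start < model$min_length) {
      start <- max(0L, end - model$min_length)
    }
    strand <- if (runif(1) < 0.5) "+" else "-"
    tmpl <- substr(unclass(genome)[[chrom]], start + 1L, end)
    if (strand == "-") tmpl <- cpp_revcomp(tmpl)
    seqs <- c(seqs, apply_read_errors(tmpl, model))
    ids <- c(ids, sprintf("r%05d|%s|%d|%d|%s", i, chrom, start, end, strand))
    total <- total + (end - start)
  }
  names(seqs) <- ids
  dna_set(seqs, normalize = FALSE)
}

#' Parse read-origin ids produced by [simulate_reads()]
#' @param ids character vector of read ids.
#' @return a data frame: `read_id`, `chrom`, `start`, `end`, `strand`.
#' @export
parse_read_origin <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 5L
  if (any(bad)) stop("ids do not carry origin information")
  data.frame(read_id = ids,
             chrom = vapply(parts, `[`, "", 2),
             start = as.integer(vapply(parts, `[`, "", 3)),
             end = as.integer(vapply(parts, `[`, "", 4)),
             strand = vapply(parts, `[`, "", 5),
             stringsAsFactors = FALSE)
}

#' Which reads qualify as junction evidence, from origin truth alone
#'
#' Classifies each simulated read against each planted insertion using only
#' its true template interval. Flanks are measured within the genomic run
#' bordering the insertion (they stop at the next planted element, since a
#' genomic block cannot extend across another insertion). A read qualifies
#' as split evidence when it overlaps the inserted element by at least
#' `min_te_len` bases and carries a bordering flank of at least
#' `max(min_block_len, hsp_sum_frac_low * L)` and at most
#' `hsp_sum_frac_high * L` bases; it qualifies as full-span evidence when it
#' covers the whole element with at least 200 bp of flank on both sides and
#' at least one flank within the block bounds. These are the pipeline's
#' documented read-level requirements, so a qualifying read is one the
#' detector is expected to turn into a validated signature.
#'
#' @param reads simulated reads (or their ids) with origin-encoded names.
#' @param truth truth data frame from [plant_insertions()].
#' @param thresholds a [detection_thresholds()].
#' @return `truth` with a `n_qualifying` column counting qualifying reads
#'   per insertion; per-read detail in attribute `"detail"`.
#' @export
qualifying_junction_reads <- function(reads, truth,
                                      thresholds = detection_thresholds()) {
  ids <- if (is.null(names(reads))) reads else names(reads)
  org <- parse_read_origin(ids)
  th <- thresholds
  truth$n_qualifying <- integer(nrow(truth))
  detail <- list()
  for (ti in seq_len(nrow(truth))) {
    a <- truth$pos_mut[ti]
    b <- a + truth$te_length[ti] + truth$tsd_length[ti]
    same <- truth$chrom == truth$chrom[ti]
    ends <- truth$pos_mut[same] + truth$te_length[same] +
      truth$tsd_length[same]
    prev_end <- suppressWarnings(max(ends[ends <= a]))
    if (!is.finite(prev_end)) prev_end <- 0L
    nxt <- suppressWarnings(min(truth$pos_mut[same][truth$pos_mut[same] >= b]))
    if (!is.finite(nxt)) nxt <- .Machine$integer.max
    r <- org[org$chrom == truth$chrom[ti] &
               org$end > a & org$start < b, , drop = FALSE]
    if (!nrow(r)) next
    L <- r$end - r$start
    t_ov <- pmin(r$end, b) - pmax(r$start, a)
    f_left <- pmax(0L, a - pmax(r$start, prev_end))
    f_right <- pmax(0L, pmin(r$end, nxt) - b)
    in_bounds <- function(f) {
      f >= th$min_block_len & f <= th$hsp_sum_frac_high * L
    }
    split_ok <- function(f) {
      t_ov >= th$min_te_len & f >= pmax(th$min_block_len,
                                        ceiling(th$hsp_sum_frac_low * L)) &
        f <= th$hsp_sum_frac_high * L
    }
    fs_ok <- t_ov >= (b - a) & f_left >= 200L & f_right >= 200L &
      (in_bounds(f_left) | in_bounds(f_right))
    q <- split_ok(f_left) | split_ok(f_right) | fs_ok
    truth$n_qualifying[ti] <- sum(q)
    if (any(q)) {
      detail[[length(detail) + 1]] <- data.frame(
        truth_index = ti, read_id = r$read_id[q],
        stringsAsFactors = FALSE)
    }
  }
  attr(truth, "detail") <- if (length(detail)) do.call(rbind, detail)
                           else NULL
  truth
}

#' Benchmark configuration
#'
#' Default values reproduce the study conditions the pipeline targets: a
#' 1-Mb random genome at Arabidopsis-like 36 percent GC carrying one native
#' copy of a synthetic 5.3-kb LTR element, ten planted neo-insertions with
#' 5-bp target-site duplications, and reads with median length 4.6 kb and
#' 13 percent total error.
#'
#' @param genome_length reference length (bp).
#' @param gc GC fraction.
#' @param native_copy plant one native element copy into the reference.
#' @param n_insertions number of planted neo-insertions.
#' @param te_length,ltr_length synthetic element geometry (bp).
#' @param tsd_length target-site duplication (bp).
#' @param coverage read coverage of the mutated genome.
#' @param total_error per-base read error rate.
#' @param median_length,sdlog_length,min_read_length read length model.
#' @param seed integer seed driving every random step.
#' @param scoring a [scoring_scheme()].
#' @param thresholds a [detection_thresholds()].
#' @param targeted also run the targeted mode on the planted family.
#' @return a list of class `benchmark_config`.
#' @export
benchmark_config <- function(genome_length = 1e6, gc = 0.36,
                             native_copy = TRUE, n_insertions = 10,
                             te_length = 5300, ltr_length = 400,
                             tsd_length = 5, coverage = 5,
                             total_error = 0.13, median_length = 4600,
                             sdlog_length = 1.5, min_read_length = 200,
                             seed = 1L, scoring = scoring_scheme(),
                             thresholds = detection_thresholds(),
                             targeted = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "benchmark_config"
  cfg
}

#' Run the planted-insertion benchmark
#'
#' Chains the whole pipeline against known truth: simulate a reference
#' (optionally with a native element copy), plant neo-insertions, simulate
#' noisy reads from the mutated genome, QC-filter them against the
#' reference, run the ab initio scan (and optionally the targeted scan),
#' cluster calls, and score them against the planted truth.
#'
#' @param cfg a [benchmark_config()].
#' @return a list: `config`, `funnel` (per-stage read counts), `qc`
#'   summary, `truth` (with qualifying-read counts), `calls`,
#'   `signatures`, `eval` (precision/recall/offsets) and, if requested,
#'   `targeted` results.
#' @export
run_benchmark <- function(cfg = benchmark_config()) {
  set.seed(cfg$seed)
  base <- simulate_genome(cfg$genome_length, cfg$gc)
  lib <- synthetic_te(cfg$te_length, cfg$ltr_length, cfg$gc)
  fam <- lib$families$family[1]
  sep <- 2L * as.integer(cfg$median_length)
  margin <- sep + as.integer(cfg$te_length)
  n_pos <- cfg$n_insertions + as.integer(cfg$native_copy)
  pos <- spaced_positions(n_pos, margin, cfg$genome_length - margin, sep)

  if (cfg$native_copy) {
    ni <- sample.int(n_pos, 1L)
    native <- pos[ni]
    neo <- pos[-ni]
    planted <- plant_insertions(base, lib,
                                insertion_plan("chr1", native, fam,
                                               tsd_length = cfg$tsd_length))
    reference <- planted$genome
    # neo positions shift by the native insertion upstream of them
    neo <- neo + ifelse(neo > native,
                        cfg$te_length + cfg$tsd_length, 0L)
  } else {
    reference <- base
    neo <- pos
  }
  if (length(neo)) {
    ori <- sample(c("sense", "antisense"), length(neo), replace = TRUE)
    mut <- plant_insertions(reference, lib,
                            insertion_plan("chr1", sort(neo),
                                           fam, ori[order(neo)],
                                           tsd_length = cfg$tsd_length))
  } else {
    mut <- list(genome = reference, truth = empty_truth())
  }
  truth <- mut$truth

  model <- read_error_model(total_error = cfg$total_error,
                            median_length = cfg$median_length,
                            sdlog_length = cfg$sdlog_length,
                            min_length = cfg$min_read_length)
  reads <- simulate_reads(mut$genome, coverage = cfg$coverage, model = model)

  ctx <- detection_context(reference, lib, cfg$scoring, cfg$thresholds)
  filt <- filter_genomic_reads(reads, ctx, cfg$scoring,
                               min_fraction = cfg$thresholds$min_genomic_frac)
  kept_ids <- filt$read_id[filt$kept]
  kept <- reads[kept_ids]
  cache <- attr(filt, "hsps")[kept_ids]
  sigs <- ab_initio_scan(kept, ctx, hsp_cache = cache)
  calls <- cluster_calls(sigs, ctx)
  ev <- evaluate_against_truth(calls, truth, match_window = 50L)
  truth_q <- qualifying_junction_reads(reads, truth, cfg$thresholds)
  fun <- attr(sigs, "funnel")

  out <- list(config = cfg,
              funnel = c(n_reads = length(reads),
                         n_kept = length(kept_ids),
                         n_candidates = unname(fun["n_candidates"]),
                         n_te_hit = unname(fun["n_te_hit"]),
                         n_validated = unname(fun["n_validated"]),
                         n_calls = nrow(calls),
                         n_calls_nonref = sum(!calls$is_reference_copy)),
              qc = summarize_reads(filt, sum(nchar(reference))),
              truth = truth_q, calls = calls, signatures = sigs, eval = ev,
              reference = reference, mutated = mut$genome, reads = reads,
              ctx = ctx, hsp_cache = attr(filt, "hsps"),
              kept_ids = kept_ids)
  if (isTRUE(cfg$targeted)) {
    tg <- targeted_scan(kept, ctx, family = fam, hsp_cache = cache)
    out$targeted <- list(classes = tg$classes,
                         signatures = tg$signatures,
                         calls = cluster_calls(tg$signatures, ctx))
  }
  out
}

# n positions in [lo, hi] pairwise at least sep apart, uniform given the
# constraint (rejection sampling; deterministic under the active seed)
spaced_positions <- function(n, lo, hi, sep) {
  stopifnot(hi - lo >= (n - 1) * sep)
  for (try in 1:1000) {
    p <- sort(sample(lo:hi, n))
    if (n == 1 || min(diff(p)) >= sep) return(p)
  }
  stop("could not place insertions with the requested separation")
}

#' Serialize a benchmark report to JSON
#'
#' Drops the bulky sequence members and writes counts, QC, calls, truth and
#' evaluation results.
#'
#' @param report output of [run_benchmark()].
#' @param path output path.
#' @export
benchmark_report_json <- function(report, path) {
  slim <- list(funnel = as.list(report$funnel),
               qc = unclass(report$qc),
               truth = report$truth,
               calls = report$calls,
               eval = report$eval[c("n_calls", "n_truth", "tp", "fp", "fn",
                                    "precision", "recall",
                                    "mean_abs_offset")])
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
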