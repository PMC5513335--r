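# Read-set characterisation: genomic filtering, identity, coverage, and the
# ddCt relative copy-number utility.

#' Filter reads by genomically aligned fraction
#'
#' A read is kept when the union of its genomic HSP query intervals covers at
#' least `min_fraction` of its length (boundary inclusive). All HSPs count,
#' whatever the strand or chromosome: the criterion concerns overall
#' mappability, not a single best placement.
#'
#' @param reads a [dna_set()] of reads.
#' @param genome a [dna_set()] genome, a [seq_index()], or a
#'   [detection_context()].
#' @param scoring a [scoring_scheme()].
#' @param min_fraction minimum aligned fraction (inclusive).
#' @param hsp_cache optional named list of precomputed per-read HSP data
#'   frames (as produced by this function's `"hsps"` attribute), to avoid
#'   re-aligning.
#' @return a data frame with one row per read (`read_id`, `length`,
#'   `n_hsps`, `aligned_bases`, `aligned_fraction`, `mean_identity_pct`,
#'   `kept`), with the per-read HSP list in attribute `"hsps"`.
#' @export
filter_genomic_reads <- function(reads, genome, scoring = scoring_scheme(),
                                 min_fraction = 0.20, hsp_cache = NULL) {
  stopifnot(length(reads) >= 1)
  index <- resolve_index(genome, scoring)
  ids <- names(reads)
  hsps <- vector("list", length(ids))
  names(hsps) <- ids
  out <- data.frame(read_id = ids, length = unname(nchar(reads)),
                    n_hsps = 0L, aligned_bases = 0L,
                    aligned_fraction = 0, mean_identity_pct = NA_real_,
                    kept = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    h <- if (!is.null(hsp_cache) && !is.null(hsp_cache[[ids[i]]])) {
      hsp_cache[[ids[i]]]
    } else {
      index_search(index, reads[i], scoring, query_id = ids[i])
    }
    hsps[[i]] <- h
    if (nrow(h)) {
      ab <- union_length(h$q_start, h$q_end)
      out$n_hsps[i] <- nrow(h)
      out$aligned_bases[i] <- ab
      out$aligned_fraction[i] <- ab / out$length[i]
      out$mean_identity_pct[i] <- mean(h$identity_pct)
    }
  }
  out$kept <- out$aligned_fraction >= min_fraction
  teasv_log(sprintf("genomic filter: kept %d / %d reads (>= %.0f%% aligned)",
                    sum(out$kept), nrow(out), 100 * min_fraction))
  attr(out, "hsps") <- hsps
  attr(out, "min_fraction") <- min_fraction
  out
}

resolve_index <- function(genome, scoring) {
  if (inherits(genome, "detection_context")) return(genome$index)
  if (inherits(genome, "seq_index")) return(genome)
  seq_index(genome, scoring)
}

# lower median: for even n, the lower of the two central values
median_lower <- function(x) {
  if (length(x) == 0) return(0)
  sort(x)[ceiling(length(x) / 2)]
}

#' Summarise a filtered read set
#'
#' @param filtered output of [filter_genomic_reads()].
#' @param genome_length total genome length in bases (or a [dna_set()]
#'   genome).
#' @return a list of class `read_qc_summary`: read and kept counts, total
#'   kept bases, lower-interpolation median length, fraction of kept reads
#'   between 500 and 15000 bases, unweighted mean HSP identity over all kept
#'   reads' HSPs, and `coverage_x` = kept aligned bases / genome length.
#' @export
summarize_reads <- function(filtered, genome_length) {
  if (!is.numeric(genome_length)) genome_length <- sum(nchar(genome_length))
  stopifnot(genome_length > 0)
  k <- filtered[filtered$kept, , drop = FALSE]
  hsps <- attr(filtered, "hsps")
  ident <- if (nrow(k) && !is.null(hsps)) {
    all_id <- unlist(lapply(hsps[k$read_id], function(h) h$identity_pct))
    if (length(all_id)) mean(all_id) else NA_real_
  } else NA_real_
  out <- list(n_reads = nrow(filtered),
              n_kept = nrow(k),
              total_bases = sum(k$length),
              median_length = median_lower(k$length),
              fraction_in_range = if (nrow(k)) {
                mean(k$length >= 500 & k$length <= 15000)
              } else 0,
              mean_identity_pct = ident,
              coverage_x = sum(k$aligned_bases) / genome_length)
  class(out) <- "read_qc_summary"
  out
}

#' @export
print.read_qc_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "read QC summary\n",
    "  reads: %d (kept %d)\n",
    "  kept bases: %s (median length %s, %.1f%% in [500, 15000])\n",
    "  mean HSP identity: %.1f%%\n",
    "  genome coverage: %.2fX\n"),
    x$n_reads, x$n_kept, format(x$total_bases, big.mark = ","),
    format(x$median_length, big.mark = ","), 100 * x$fraction_in_range,
    x$mean_identity_pct, x$coverage_x))
  invisible(x)
}

#' Check for the presence of unique genes in a read set
#'
#' A gene is called present when at least one read produces an HSP to it
#' passing the scoring scheme's minimum score and length; used as an
#' independent sanity check of a coverage estimate.
#'
#' @param genes a [dna_set()] of unique gene sequences.
#' @param reads a [dna_set()] of (typically QC-kept) reads.
#' @param scoring a [scoring_scheme()].
#' @return a data frame: `gene_id`, `present`, `n_reads`, `support`
#'   (comma-separated supporting read ids).
#' @export
gene_presence_check <- function(genes, reads, scoring = scoring_scheme()) {
  stopifnot(length(genes) >= 1, length(reads) >= 1)
  idx <- seq_index(reads, scoring)
  out <- data.frame(gene_id = names(genes), present = FALSE, n_reads = 0L,
                    support = "", stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    h <- index_search(idx, genes[i], scoring, query_id = names(genes)[i])
    if (nrow(h)) {
      ids <- sort(unique(h$subject_id))
      out$present[i] <- TRUE
      out$n_reads[i] <- length(ids)
      out$support[i] <- paste(ids, collapse = ",")
    }
  }
  out
}

#' Relative copy number by the 2^-ddCt method
#'
#' Computes `calibrator_copies * 2^-ddCt` with
#' `ddCt = (ct_target_sample - ct_reference_sample) -
#' (ct_target_calibrator - ct_reference_calibrator)`. The default
#' calibrator value of 2 corresponds to a diploid single-copy calibrator
#' locus. Only the arithmetic is implemented; amplification-efficiency
#' correction is out of scope.
#'
#' @param ct_target_sample,ct_reference_sample,ct_target_calibrator,ct_reference_calibrator
#'   Ct cycle numbers (finite, positive); vectors recycle.
#' @param calibrator_copies copy number assigned to the calibrator.
#' @return relative copy number(s).
#' @examples
#' ddct_copy_number(20, 18, 20, 18)  # ddCt = 0 -> 2
#' ddct_copy_number(20, 18, 23, 18)  # ddCt = -3 -> 16
#' @export
ddct_copy_number <- function(ct_target_sample, ct_reference_sample,
                             ct_target_calibrator, ct_reference_calibrator,
                             calibrator_copies = 2) {
  ct <- c(ct_target_sample, ct_reference_sample,
          ct_target_calibrator, ct_reference_calibrator)
  if (!all(is.finite(ct)) || any(ct <= 0)) {
    stop("all Ct values must be finite and positive")
  }
  ddct <- (ct_target_sample - ct_reference_sample) -
    (ct_target_calibrator - ct_reference_calibrator)
  calibrator_copies * 2^(-ddct)
}

#' Read a 4- or 5-column Ct table and compute copy numbers
#'
#' Columns: ct_target_sample, ct_reference_sample, ct_target_calibrator,
#' ct_reference_calibrator, and optionally calibrator_copies.
#'
#' @param path TSV path with a header line.
#' @return the table with a `copy_number` column appended.
#' @export
ddct_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  cc <- if ("calibrator_copies" %in% names(df)) df$calibrator_copies else 2
  df$copy_number <- ddct_copy_number(df$ct_target_sample,
                                     df$ct_reference_sample,
                                     df$ct_target_calibrator,
                                     df$ct_reference_calibrator, cc)
  df
}
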