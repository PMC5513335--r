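# Split-read detection of TE insertions: targeted and ab initio modes,
# locus-concordance validation, and clustering of breakpoints into calls.

#' TE library
#'
#' A set of canonical transposable-element sequences used as detection
#' queries (targeted mode) or as the search database for read remainders
#' (ab initio mode).
#'
#' @param seqs named character vector or [dna_set()] of TE sequences
#'   (each at least 100 bp); names are family ids.
#' @param te_class per-family class, "LTR_retrotransposon" or
#'   "DNA_transposon" (recycled).
#' @param ltr_length per-family long-terminal-repeat length (bp, `NA` for
#'   non-LTR families); must not exceed half the element length.
#' @return a list of class `te_library` with a `families` data frame and the
#'   sequences.
#' @export
te_library <- function(seqs, te_class = "LTR_retrotransposon",
                       ltr_length = NA_integer_) {
  seqs <- dna_set(if (inherits(seqs, "dna_set")) unclass(seqs) else seqs)
  stopifnot(all(nchar(seqs) >= 100))
  te_class <- rep_len(te_class, length(seqs))
  ltr_length <- rep_len(as.integer(ltr_length), length(seqs))
  stopifnot(all(te_class %in% c("LTR_retrotransposon", "DNA_transposon")))
  bad <- !is.na(ltr_length) & ltr_length > nchar(seqs) / 2
  if (any(bad)) stop("ltr_length must not exceed half the element length")
  lib <- list(families = data.frame(family = names(seqs),
                                    te_class = te_class,
                                    length = unname(nchar(seqs)),
                                    ltr_length = ltr_length,
                                    stringsAsFactors = FALSE),
              seqs = seqs)
  class(lib) <- "te_library"
  lib
}

te_seq <- function(lib, family) {
  s <- unclass(lib$seqs)[[family]]
  if (is.null(s)) stop(sprintf("family '%s' not in TE library", family))
  s
}

#' Detection context
#'
#' Pre-computes everything the detection passes share: the genome k-mer
#' index and the self-detected reference TE copies (each library element
#' aligned back to the genome; chained matches of at least
#' `thresholds$min_te_len` become annotated reference copies). Reference
#' copies serve two purposes: genomic chains falling mostly inside one are
#' not eligible to define a read's genomic block (they are TE evidence, not
#' locus evidence), and calls at one are flagged `is_reference_copy`.
#'
#' @param genome a [dna_set()] genome.
#' @param lib a [te_library()].
#' @param scoring a [scoring_scheme()].
#' @param thresholds a [detection_thresholds()].
#' @return a list of class `detection_context`.
#' @export
detection_context <- function(genome, lib, scoring = scoring_scheme(),
                              thresholds = detection_thresholds()) {
  stopifnot(inherits(lib, "te_library"))
  genome <- if (inherits(genome, "dna_set")) genome else dna_set(genome)
  index <- seq_index(genome, scoring)
  ref_te <- ref_te_regions(index, lib, scoring, thresholds)
  teasv_log(sprintf("detection context: %d chromosome(s), %d TE famil%s, %d reference TE cop%s",
                    length(genome), nrow(lib$families),
                    if (nrow(lib$families) == 1) "y" else "ies",
                    nrow(ref_te), if (nrow(ref_te) == 1) "y" else "ies"))
  ctx <- list(genome = genome, index = index, te_library = lib,
              scoring = scoring, thresholds = thresholds, ref_te = ref_te)
  class(ctx) <- "detection_context"
  ctx
}

ref_te_regions <- function(index, lib, scoring, thresholds) {
  out <- list()
  for (fam in lib$families$family) {
    h <- index_search(index, setNames(te_seq(lib, fam), fam), scoring,
                      query_id = fam)
    if (!nrow(h)) next
    ch <- chain_blocks(h, max_gap = scoring$chain_max_gap)
    ch <- ch[ch$joined_query_span >= thresholds$min_te_len, , drop = FALSE]
    if (!nrow(ch)) next
    for (chrom in unique(ch$subject_id)) {
      ci <- ch[ch$subject_id == chrom, , drop = FALSE]
      m <- merge_intervals(ci$s_start, ci$s_end,
                           tol = thresholds$cluster_tolerance)
      out[[length(out) + 1]] <- data.frame(chrom = chrom, start = m$start,
                                           end = m$end, family = fam,
                                           stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), family = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# fraction of [s1, s2) covered by reference TE annotation on chrom
ref_te_overlap_frac <- function(ctx, chrom, s1, s2) {
  r <- ctx$ref_te[ctx$ref_te$chrom == chrom, , drop = FALSE]
  if (!nrow(r) || s2 <= s1) return(0)
  ov <- pmin(r$end, s2) - pmax(r$start, s1)
  sum(pmax(ov, 0L)) / (s2 - s1)
}

# chains eligible to define a read's genomic block
eligible_chains <- function(chains, ctx) {
  if (!nrow(chains)) return(chains)
  frac <- vapply(seq_len(nrow(chains)), function(i) {
    ref_te_overlap_frac(ctx, chains$subject_id[i],
                        chains$s_start[i], chains$s_end[i])
  }, 0)
  chains[frac <= 0.5, , drop = FALSE]
}

# reference coordinate of the block end adjacent to the TE side of the read
block_junction <- function(block, te_side) {
  if (block$strand == "+") {
    if (te_side == "right") block$s_end else block$s_start
  } else {
    if (te_side == "right") block$s_start else block$s_end
  }
}

empty_signatures <- function() {
  data.frame(read_id = character(0), read_length = integer(0),
             chrom = character(0), block_start = integer(0),
             block_end = integer(0), block_strand = character(0),
             block_span = integer(0), block_score = integer(0),
             te_family = character(0), te_q_start = integer(0),
             te_q_end = integer(0), te_span = integer(0),
             te_strand = character(0), te_score = integer(0),
             junction_side = character(0), breakpoint = integer(0),
             full_span = logical(0), orientation = character(0),
             hsp_sum_locus = integer(0), fraction_of_read = numeric(0),
             two_sided_junction = logical(0), clipped = logical(0),
             pass = logical(0), stringsAsFactors = FALSE)
}

# all TE-library alignments of a read: chained matches of at least
# min_te_len query bases, one row per (family, read segment)
read_te_chains <- function(rseq, ctx, families = NULL) {
  th <- ctx$thresholds
  if (is.null(families)) families <- ctx$te_library$families$family
  out <- list()
  union_bp <- 0L
  for (fam in families) {
    h <- local_align(rseq, te_seq(ctx$te_library, fam), ctx$scoring,
                     query_id = "read", subject_id = fam)
    if (!nrow(h)) next
    union_bp <- max(union_bp, union_length(h$q_start, h$q_end))
    ch <- chain_blocks(h, max_gap = ctx$scoring$chain_max_gap)
    ch <- ch[ch$joined_query_span >= th$min_te_len, , drop = FALSE]
    if (!nrow(ch)) next
    out[[length(out) + 1]] <- data.frame(
      family = fam, q_start = ch$q_start, q_end = ch$q_end,
      span = ch$joined_query_span, strand = ch$strand, score = ch$score,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(family = character(0), q_start = integer(0),
               q_end = integer(0), span = integer(0),
               strand = character(0), score = integer(0),
               stringsAsFactors = FALSE)
  attr(res, "union_bp") <- union_bp
  res
}

# chains eligible as genomic blocks, and those within the size bounds
candidate_blocks <- function(chains, ctx, L) {
  th <- ctx$thresholds
  elig <- eligible_chains(chains, ctx)
  ok <- if (nrow(elig)) {
    elig$joined_query_span >= th$min_block_len &
      elig$joined_query_span <= th$max_block_frac * L
  } else logical(0)
  list(elig = elig, blocks = elig[ok, , drop = FALSE])
}

# Pair every in-bounds genomic block with a junction-adjacent TE hit.
# Reads spanning more than one insertion (or a full element) legitimately
# carry several junctions; each TE hit supports at most one signature
# (full-span geometry consumes its hit for both flanks). Blocks are taken
# in score order, so ties resolve deterministically.
pair_signatures <- function(read_id, L, elig, blocks, te_hits, ctx) {
  th <- ctx$thresholds
  if (!nrow(blocks) || !nrow(te_hits)) return(NULL)
  consumed <- rep(FALSE, nrow(te_hits))
  sigs <- list()
  for (gi in seq_len(nrow(blocks))) {
    g <- blocks[gi, ]
    for (side in c("right", "left")) {
      gap <- if (side == "right") te_hits$q_start - g$q_end
             else g$q_start - te_hits$q_end
      beyond <- if (side == "right") te_hits$q_end > g$q_end
                else te_hits$q_start < g$q_start
      cand <- which(!consumed & abs(gap) <= 100 & beyond)
      if (!length(cand)) next
      ti <- cand[order(-te_hits$score[cand])[1]]
      t <- as.list(te_hits[ti, ])
      other <- find_other_flank(elig, g, t, side, th)
      sigs[[length(sigs) + 1]] <- make_signature(read_id, L, g, t, side,
                                                 other, ctx)
      consumed[ti] <- TRUE
    }
  }
  if (length(sigs)) do.call(rbind, sigs) else NULL
}

# look for a second eligible flank chain across the TE hit that is
# reference-adjacent to the block (full-span geometry)
find_other_flank <- function(elig, block, te_hit, te_side, th) {
  for (i in seq_len(nrow(elig))) {
    ch2 <- elig[i, ]
    if (ch2$chain_id == block$chain_id) next
    if (ch2$subject_id != block$subject_id || ch2$strand != block$strand) next
    on_far_side <- if (te_side == "right") {
      ch2$q_start >= te_hit$q_end - 50
    } else {
      ch2$q_end <= te_hit$q_start + 50
    }
    if (!on_far_side) next
    gap <- max(ch2$s_start - block$s_end, block$s_start - ch2$s_end)
    if (gap <= th$cluster_tolerance && gap >= -50) return(ch2)
  }
  NULL
}

make_signature <- function(read_id, L, block, te_hit, te_side, other_flank,
                           ctx) {
  full_span <- !is.null(other_flank)
  bp <- block_junction(block, te_side)
  if (full_span) {
    bp2 <- block_junction(other_flank,
                          if (te_side == "right") "left" else "right")
    bp <- as.integer(round((bp + bp2) / 2))
  }
  orientation <- if (te_hit$strand == block$strand) "sense" else "antisense"
  sig <- data.frame(read_id = read_id, read_length = L,
                    chrom = block$subject_id,
                    block_start = block$s_start, block_end = block$s_end,
                    block_strand = block$strand,
                    block_span = block$joined_query_span,
                    block_score = block$score,
                    te_family = te_hit$family,
                    te_q_start = te_hit$q_start, te_q_end = te_hit$q_end,
                    te_span = te_hit$span, te_strand = te_hit$strand,
                    te_score = te_hit$score,
                    junction_side = te_side, breakpoint = bp,
                    full_span = full_span, orientation = orientation,
                    hsp_sum_locus = NA_integer_,
                    fraction_of_read = NA_real_,
                    two_sided_junction = NA, clipped = NA, pass = NA,
                    stringsAsFactors = FALSE)
  if (full_span) {
    sig$block_start <- min(block$s_start, other_flank$s_start)
    sig$block_end <- max(block$s_end, other_flank$s_end)
  }
  sig
}

#' Validate a breakpoint signature against its locus construct
#'
#' Rebuilds the putative insertion locus (the genomic block padded by `pad`
#' bases on each side), concatenates it with the TE sequence, re-aligns the
#' read against the construct, and measures concordance: the locus-side
#' HSP-length sum must exceed `min_hsp_sum` and, for split reads, comprise
#' between `hsp_sum_frac_low` and `hsp_sum_frac_high` of the read length.
#' Full-span reads are instead required to show locus-side alignment
#' adjacent (within 50 bp on the read) to the TE-side alignment at both
#' junctions, since their genomic portion is legitimately small relative to
#' the element. `two_sided_junction` reports whether locus- and TE-side
#' alignments approach within 50 bp on the read, the quantitative
#' equivalent of inspecting a dot-plot of the read against the construct.
#'
#' @param sig one signature row (from the scan functions, pre-validation).
#' @param read_seq the read sequence (character).
#' @param ctx a [detection_context()].
#' @param pad locus flank padding (bp); defaults to half the locus window.
#' @return the signature row with `hsp_sum_locus`, `fraction_of_read`,
#'   `two_sided_junction`, `clipped` and `pass` filled in.
#' @export
verify_locus_construct <- function(sig, read_seq, ctx, pad = NULL) {
  th <- ctx$thresholds
  if (is.null(pad)) pad <- th$locus_window %/% 2L
  chrom_len <- unname(ctx$index$lengths[sig$chrom])
  ls <- sig$block_start - pad
  le <- sig$block_end + pad
  clipped <- ls < 0 || le > chrom_len
  ls <- max(0L, as.integer(ls)); le <- min(chrom_len, as.integer(le))
  locus_seq <- substr(unclass(ctx$genome)[[sig$chrom]], ls + 1L, le)
  locus_len <- nchar(locus_seq)
  construct <- paste0(locus_seq, te_seq(ctx$te_library, sig$te_family))
  h <- local_align(read_seq, construct, ctx$scoring,
                   query_id = sig$read_id, subject_id = "construct")
  mid <- (h$s_start + h$s_end) / 2
  loc <- h[mid < locus_len, , drop = FALSE]
  te <- h[mid >= locus_len, , drop = FALSE]
  if (!is.na(sig$te_q_start)) {
    # a read may carry several copies of the element (one per insertion it
    # spans); junction checks concern only this signature's TE segment
    keep <- te$q_end > sig$te_q_start - 100 & te$q_start < sig$te_q_end + 100
    te <- te[keep, , drop = FALSE]
  }
  hsp_sum <- union_length(loc$q_start, loc$q_end)
  frac <- hsp_sum / sig$read_length
  two_sided <- FALSE
  if (nrow(loc) && nrow(te)) {
    gaps <- outer(seq_len(nrow(loc)), seq_len(nrow(te)),
                  Vectorize(function(i, j) {
                    max(te$q_start[j] - loc$q_end[i],
                        loc$q_start[i] - te$q_end[j], 0L)
                  }))
    two_sided <- min(gaps) <= 50
  }
  if (isTRUE(sig$full_span)) {
    jun_ok <- FALSE
    if (nrow(loc) && nrow(te)) {
      t1 <- min(te$q_start); t2 <- max(te$q_end)
      left_ok <- any(loc$q_end >= t1 - 50 & loc$q_start < t1)
      right_ok <- any(loc$q_start <= t2 + 50 & loc$q_end > t2)
      jun_ok <- left_ok && right_ok
    }
    pass <- hsp_sum > th$min_hsp_sum && jun_ok
  } else {
    pass <- hsp_sum > th$min_hsp_sum &&
      frac >= th$hsp_sum_frac_low && frac <= th$hsp_sum_frac_high
  }
  sig$hsp_sum_locus <- hsp_sum
  sig$fraction_of_read <- frac
  sig$two_sided_junction <- two_sided
  sig$clipped <- clipped
  sig$pass <- pass
  sig
}

#' Ab initio split-read scan
#'
#' Discovers insertion breakpoints of any TE-library member in individual
#' reads. Per read: (1) genomic HSPs are chained into blocks; among chains
#' not masked by reference TE copies, those spanning at least
#' `min_block_len` bases and at most `max_block_frac` of the read qualify
#' as genomic blocks; (2) the rest of the read is aligned against every
#' library element, and each block is paired with a TE alignment of at
#' least `min_te_len` bases adjacent to it on the read (a long read
#' crossing several insertions carries several such junctions, each TE
#' alignment supporting one signature); (3) every resulting breakpoint
#' signature is validated with [verify_locus_construct()]. Only signatures
#' passing validation with a visible two-sided junction (locus- and
#' TE-side alignments adjacent on the read) are returned. When a second
#' unmasked flank chain sits reference-adjacent across the TE hit, the
#' read is recognised as spanning the complete element (full-span).
#'
#' @param reads a [dna_set()] of (QC-kept) reads.
#' @param ctx a [detection_context()].
#' @param hsp_cache optional named list of precomputed genomic HSP data
#'   frames per read (the `"hsps"` attribute of [filter_genomic_reads()]).
#' @return a signature data frame (one row per validated breakpoint
#'   signature), with per-stage funnel counts in attribute `"funnel"`.
#' @export
ab_initio_scan <- function(reads, ctx, hsp_cache = NULL) {
  stopifnot(inherits(ctx, "detection_context"))
  if (nrow(ctx$te_library$families) == 0) stop("TE library is empty")
  th <- ctx$thresholds
  sigs <- list()
  n_candidates <- n_te_hit <- n_validated <- 0L
  for (i in seq_along(reads)) {
    id <- names(reads)[i]
    rseq <- unclass(reads)[[i]]
    L <- nchar(rseq)
    if (L < 1) next
    h <- if (!is.null(hsp_cache) && !is.null(hsp_cache[[id]])) {
      hsp_cache[[id]]
    } else {
      index_search(ctx$index, reads[i], ctx$scoring, query_id = id)
    }
    if (!nrow(h)) next
    chains <- chain_blocks(h, max_gap = ctx$scoring$chain_max_gap)
    cb <- candidate_blocks(chains, ctx, L)
    if (!nrow(cb$blocks)) next
    n_candidates <- n_candidates + 1L
    te_hits <- read_te_chains(rseq, ctx)
    raw <- pair_signatures(id, L, cb$elig, cb$blocks, te_hits, ctx)
    if (is.null(raw)) next
    n_te_hit <- n_te_hit + 1L
    kept_any <- FALSE
    for (si in seq_len(nrow(raw))) {
      sig <- verify_locus_construct(raw[si, ], rseq, ctx,
                                    pad = th$locus_window %/% 2L)
      # the junction itself must be visible: locus- and TE-side alignments
      # adjacent on the read (the automated form of dot-plot inspection)
      if (isTRUE(sig$pass) && isTRUE(sig$two_sided_junction)) {
        kept_any <- TRUE
        sigs[[length(sigs) + 1]] <- sig
      }
    }
    if (kept_any) n_validated <- n_validated + 1L
  }
  out <- if (length(sigs)) do.call(rbind, sigs) else empty_signatures()
  rownames(out) <- NULL
  attr(out, "funnel") <- c(n_reads = length(reads),
                           n_candidates = n_candidates,
                           n_te_hit = n_te_hit, n_validated = n_validated)
  teasv_log(sprintf(
    "ab initio scan: %d reads -> %d breakpoint candidates -> %d TE-hit -> %d validated",
    length(reads), n_candidates, n_te_hit, n_validated))
  out
}

#' Targeted scan for one known TE
#'
#' Aligns the chosen element against every read and classifies TE-hit
#' reads: `full_TE` (at least 95 percent of the read is element sequence),
#' `full_span` (complete element plus both genomic flanks mapping
#' reference-adjacent to one locus), `split` (element plus one genomic
#' flank), or `none`. Split and full-span reads yield breakpoint signatures
#' located by aligning the non-TE portion to the genome; signatures are
#' validated with [verify_locus_construct()] using `flank_pad` padding, and
#' the same block-size bounds as the ab initio mode apply.
#'
#' @param reads a [dna_set()] of (QC-kept) reads.
#' @param ctx a [detection_context()] whose library contains `family`.
#' @param family TE family to scan for (default: first library entry).
#' @param hsp_cache optional precomputed genomic HSPs per read.
#' @return a list with `classes` (read classification data frame) and
#'   `signatures` (validated breakpoint signatures).
#' @export
targeted_scan <- function(reads, ctx, family = NULL, hsp_cache = NULL) {
  stopifnot(inherits(ctx, "detection_context"))
  if (is.null(family)) family <- ctx$te_library$families$family[1]
  th <- ctx$thresholds
  classes <- data.frame(read_id = names(reads),
                        category = "none",
                        te_span = 0L, te_fraction = 0,
                        stringsAsFactors = FALSE)
  sigs <- list()
  for (i in seq_along(reads)) {
    id <- names(reads)[i]
    rseq <- unclass(reads)[[i]]
    L <- nchar(rseq)
    if (L < 1) next
    te_hits <- read_te_chains(rseq, ctx, families = family)
    te_union <- attr(te_hits, "union_bp")
    classes$te_span[i] <- te_union
    classes$te_fraction[i] <- te_union / L
    if (te_union >= 0.95 * L) {
      classes$category[i] <- "full_TE"
      next
    }
    if (!nrow(te_hits)) next
    classes$category[i] <- "split"
    h <- if (!is.null(hsp_cache) && !is.null(hsp_cache[[id]])) {
      hsp_cache[[id]]
    } else {
      index_search(ctx$index, reads[i], ctx$scoring, query_id = id)
    }
    if (!nrow(h)) next
    chains <- chain_blocks(h, max_gap = ctx$scoring$chain_max_gap)
    cb <- candidate_blocks(chains, ctx, L)
    raw <- pair_signatures(id, L, cb$elig, cb$blocks, te_hits, ctx)
    if (is.null(raw)) next
    if (any(raw$full_span)) classes$category[i] <- "full_span"
    for (si in seq_len(nrow(raw))) {
      sig <- verify_locus_construct(raw[si, ], rseq, ctx, pad = th$flank_pad)
      if (isTRUE(sig$pass) && isTRUE(sig$two_sided_junction)) {
        sigs[[length(sigs) + 1]] <- sig
      }
    }
  }
  out <- if (length(sigs)) do.call(rbind, sigs) else empty_signatures()
  rownames(out) <- NULL
  teasv_log(sprintf(
    "targeted scan (%s): %d reads, %d TE-hit, %d validated signatures",
    family, length(reads), sum(classes$category != "none"), nrow(out)))
  list(classes = classes, signatures = out)
}

#' Cluster breakpoint signatures into insertion calls
#'
#' Signatures on the same chromosome with the same TE family whose
#' breakpoints lie within `cluster_tolerance` of each other (single
#' linkage) merge into one call. Orientation is the strand consensus of
#' the supporting signatures (majority, ties reported as "unknown"); calls
#' overlapping or within `cluster_tolerance` of a self-detected reference
#' TE copy are flagged `is_reference_copy`. Output order is (chromosome,
#' position), making the operation deterministic and invariant to input
#' order.
#'
#' @param signatures validated signature data frame.
#' @param ctx a [detection_context()].
#' @return a call data frame: locus interval, `position` (median
#'   breakpoint), family, orientation, support read ids and categories,
#'   `status`, `is_reference_copy`.
#' @export
cluster_calls <- function(signatures, ctx) {
  th <- ctx$thresholds
  if (is.null(signatures) || nrow(signatures) == 0) return(empty_calls())
  s <- signatures[order(signatures$chrom, signatures$te_family,
                        signatures$breakpoint, signatures$read_id), ,
                  drop = FALSE]
  grp <- integer(nrow(s))
  g <- 1L
  grp[1] <- g
  for (i in seq_len(nrow(s))[-1]) {
    same <- s$chrom[i] == s$chrom[i - 1] &&
      s$te_family[i] == s$te_family[i - 1] &&
      (s$breakpoint[i] - s$breakpoint[i - 1]) <= th$cluster_tolerance
    if (!same) g <- g + 1L
    grp[i] <- g
  }
  rows <- lapply(split(seq_len(nrow(s)), grp), function(ii) {
    cl <- s[ii, , drop = FALSE]
    ori <- names(sort(table(cl$orientation), decreasing = TRUE))
    orientation <- if (length(ori) > 1 &&
                       sum(cl$orientation == ori[1]) ==
                       sum(cl$orientation == ori[2])) "unknown" else ori[1]
    pos <- as.integer(round(median_lower(cl$breakpoint)))
    data.frame(chrom = cl$chrom[1],
               start = min(cl$breakpoint),
               end = max(cl$breakpoint) + 1L,
               position = pos,
               te_family = cl$te_family[1],
               orientation = orientation,
               n_support = nrow(cl),
               support = paste(sort(cl$read_id), collapse = ","),
               support_categories = paste(
                 ifelse(cl$full_span[order(cl$read_id)], "full_span",
                        "split"), collapse = ","),
               status = "validated",
               is_reference_copy = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (i in seq_len(nrow(out))) {
    r <- ctx$ref_te[ctx$ref_te$chrom == out$chrom[i], , drop = FALSE]
    if (nrow(r)) {
      near <- out$end[i] + th$cluster_tolerance > r$start &
        out$start[i] - th$cluster_tolerance < r$end
      out$is_reference_copy[i] <- any(near)
    }
  }
  out <- out[order(out$chrom, out$position), , drop = FALSE]
  out$call_id <- sprintf("teasv_%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("call_id", setdiff(names(out), "call_id"))]
}

empty_calls <- function() {
  data.frame(call_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), position = integer(0),
             te_family = character(0), orientation = character(0),
             n_support = integer(0), support = character(0),
             support_categories = character(0), status = character(0),
             is_reference_copy = logical(0), stringsAsFactors = FALSE)
}

#' Compare insertion calls against planted truth
#'
#' A call is a true positive when a truth record on the same chromosome
#' with the same family lies within `match_window` bases of the call
#' position (reference coordinates); each truth record matches at most one
#' call (nearest first). Calls flagged `is_reference_copy` describe known
#' reference features and are excluded before scoring. Precision of an
#' empty call set is reported as 1.
#'
#' @param calls a call data frame from [cluster_calls()].
#' @param truth a truth data frame from [plant_insertions()] (columns
#'   `chrom`, `pos_ref`, `te_family`).
#' @param match_window maximum breakpoint offset (bp).
#' @return a list: counts, `precision`, `recall`, `mean_abs_offset`, the
#'   matched pairs, and per-truth detection flags.
#' @export
evaluate_against_truth <- function(calls, truth, match_window = 50L) {
  nr <- calls[!calls$is_reference_copy, , drop = FALSE]
  truth$detected <- logical(nrow(truth))
  truth$offset <- rep(NA_integer_, nrow(truth))
  matched_call <- rep(FALSE, nrow(nr))
  if (nrow(nr) && nrow(truth)) {
    cand <- do.call(rbind, lapply(seq_len(nrow(nr)), function(i) {
      j <- which(truth$chrom == nr$chrom[i] &
                   truth$te_family == nr$te_family[i] &
                   abs(truth$pos_ref - nr$position[i]) <= match_window)
      if (!length(j)) return(NULL)
      data.frame(call = i, truth = j,
                 dist = abs(truth$pos_ref[j] - nr$position[i]))
    }))
    if (!is.null(cand)) {
      cand <- cand[order(cand$dist, cand$call, cand$truth), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        ci <- cand$call[r]; ti <- cand$truth[r]
        if (matched_call[ci] || truth$detected[ti]) next
        matched_call[ci] <- TRUE
        truth$detected[ti] <- TRUE
        truth$offset[ti] <- nr$position[ci] - truth$pos_ref[ti]
      }
    }
  }
  tp <- sum(matched_call)
  list(n_calls = nrow(nr), n_truth = nrow(truth),
       tp = tp, fp = nrow(nr) - tp, fn = nrow(truth) - tp,
       precision = if (nrow(nr)) tp / nrow(nr) else 1,
       recall = if (nrow(truth)) tp / nrow(truth) else 1,
       mean_abs_offset = if (tp) mean(abs(truth$offset), na.rm = TRUE)
                         else NA_real_,
       truth = truth)
}
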