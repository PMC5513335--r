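# Local alignment (HSPs), k-mer indexing and block chaining.
#
# HSP data frames carry 0-based half-open intervals on the forward query and
# forward subject; strand "-" means the reverse complement of the query was
# aligned. identity_pct = 100 * matches / aligned_cols.

hsp_columns <- c("query_id", "subject_id", "strand", "q_start", "q_end",
                 "s_start", "s_end", "score", "aligned_cols", "matches",
                 "gaps", "identity_pct")

empty_hsps <- function() {
  df <- data.frame(query_id = character(0), subject_id = character(0),
                   strand = character(0), q_start = integer(0),
                   q_end = integer(0), s_start = integer(0),
                   s_end = integer(0), score = integer(0),
                   aligned_cols = integer(0), matches = integer(0),
                   gaps = integer(0), identity_pct = numeric(0),
                   stringsAsFactors = FALSE)
  df
}

finish_hsps <- function(raw, query_id, subject_names) {
  if (nrow(raw) == 0) return(empty_hsps())
  data.frame(query_id = query_id,
             subject_id = subject_names[raw$subject],
             strand = raw$strand,
             q_start = raw$q_start, q_end = raw$q_end,
             s_start = raw$s_start, s_end = raw$s_end,
             score = raw$score, aligned_cols = raw$aligned_cols,
             matches = raw$matches, gaps = raw$gaps,
             identity_pct = 100 * raw$matches / raw$aligned_cols,
             stringsAsFactors = FALSE)
}

seq1 <- function(x) {
  # single sequence as plain character, whatever the container
  if (methods::is(x, "DNAStringSet")) x <- as.character(x)
  x <- unclass(x)
  if (length(x) != 1) stop("expected a single sequence")
  unname(x[[1]])
}

#' Local alignment of two sequences
#'
#' Returns every high-scoring segment pair (HSP) between `query` and
#' `subject` on both strands, with score at least `min_hsp_score` and at
#' least `min_hsp_length` alignment columns, sorted by descending score.
#' Small problems (fewer than `full_dp_limit` cells) are solved by
#' exhaustive affine-gap Smith-Waterman, so the best HSP score equals the
#' full optimum; larger problems use seeded banded extension.
#'
#' @param query,subject single sequences (character, or one-record
#'   [dna_set()]).
#' @param scoring a [scoring_scheme()].
#' @param query_id,subject_id ids used in the output (default from names).
#' @return an HSP data frame (see package docs for the column contract);
#'   zero rows when nothing aligns.
#' @export
local_align <- function(query, subject, scoring = scoring_scheme(),
                        query_id = NULL, subject_id = NULL) {
  if (is.null(query_id)) query_id <- names(query)[1] %||% "query"
  if (is.null(subject_id)) subject_id <- names(subject)[1] %||% "subject"
  q <- seq1(query); s <- seq1(subject)
  if (nchar(q) == 0 || nchar(s) == 0) stop("sequences must be non-empty")
  raw <- cpp_align_pair(q, s, as_cpp_params(scoring))
  finish_hsps(raw, query_id, subject_id)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Build a k-mer index over a sequence set
#'
#' @param subjects a [dna_set()] (e.g. a genome, or a read database).
#' @param scoring a [scoring_scheme()] (supplies `k` and `max_occ`).
#' @return an opaque index of class `seq_index`.
#' @export
seq_index <- function(subjects, scoring = scoring_scheme()) {
  stopifnot(length(subjects) >= 1)
  ptr <- cpp_index_build(names(subjects), unname(unclass(subjects)),
                         scoring$k, scoring$max_occ)
  idx <- list(ptr = ptr, names = names(subjects),
              lengths = setNames(nchar(subjects), names(subjects)),
              k = scoring$k)
  class(idx) <- "seq_index"
  idx
}

#' @export
print.seq_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat(sprintf("seq_index: %d sequence(s), %s %d-mers\n",
              length(x$names), format(info$n_kmers, big.mark = ","), x$k))
  invisible(x)
}

#' Search a query against an index
#'
#' @param index a [seq_index()].
#' @param query a single sequence.
#' @param scoring a [scoring_scheme()]; its `k` must match the index.
#' @param query_id id used in the output.
#' @return an HSP data frame over all indexed subjects, both strands.
#' @export
index_search <- function(index, query, scoring = scoring_scheme(),
                         query_id = NULL) {
  stopifnot(inherits(index, "seq_index"))
  if (scoring$k != index$k) stop("scoring$k does not match index k")
  if (is.null(query_id)) query_id <- names(query)[1] %||% "query"
  raw <- cpp_index_search(index$ptr, seq1(query), as_cpp_params(scoring))
  finish_hsps(raw, query_id, index$names)
}

#' Mean alignment identity over HSPs
#'
#' Unweighted arithmetic mean of per-HSP identity by default; set
#' `weighted = TRUE` for a length (alignment-column) weighted mean.
#'
#' @param hsps an HSP data frame.
#' @param weighted weight by alignment columns.
#' @return mean identity in percent.
#' @export
mean_identity <- function(hsps, weighted = FALSE) {
  if (is.null(hsps) || nrow(hsps) == 0) stop("mean_identity of empty HSP set")
  if (weighted) {
    sum(hsps$identity_pct * hsps$aligned_cols) / sum(hsps$aligned_cols)
  } else {
    mean(hsps$identity_pct)
  }
}

# total length of the union of 0-based half-open intervals
union_length <- function(start, end) {
  if (length(start) == 0) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0L; cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce) {
      ce <- max(ce, end[i])
    } else {
      tot <- tot + (ce - cs); cs <- start[i]; ce <- end[i]
    }
  }
  tot + (ce - cs)
}

# merge 0-based half-open intervals, joining gaps <= tol
merge_intervals <- function(start, end, tol = 0L) {
  if (length(start) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- cs <- start[1]; ce <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce + tol) {
      ce <- max(ce, end[i])
    } else {
      out_s <- c(out_s, cs); out_e <- c(out_e, ce)
      cs <- start[i]; ce <- end[i]
    }
  }
  data.frame(start = c(out_s, cs), end = c(out_e, ce))
}

#' Chain co-linear HSPs into blocks
#'
#' Greedy score-ordered chaining: HSPs are taken in order of descending
#' score (ties to the leftmost query start) and attached to the first
#' existing chain with the same subject and strand that they extend
#' co-linearly with query and subject gaps no larger than `max_gap`
#' (small overlaps up to `overlap_tol` are allowed, since banded extension
#' can duplicate a few edge columns). Every HSP ends up in exactly one
#' chain. The chain's `joined_query_span` is the union length of its member
#' query intervals, the operational meaning of "contiguously aligned" for
#' indel-rich reads.
#'
#' @param hsps an HSP data frame sharing one query id.
#' @param max_gap maximum per-axis gap between chained HSPs (bp).
#' @param overlap_tol tolerated per-axis overlap between chained HSPs (bp);
#'   generous by default because banded extensions of one alignment started
#'   from different seed clusters can overlap substantially at their edges.
#' @return a data frame with one row per chain: envelope coordinates, summed
#'   score, `joined_query_span`, `n_hsps`, and a `members` list column of
#'   row indices into `hsps`.
#' @export
chain_blocks <- function(hsps, max_gap = 50L, overlap_tol = 200L) {
  if (is.null(hsps) || nrow(hsps) == 0) return(empty_chains())
  if (length(unique(hsps$query_id)) != 1) {
    stop("chain_blocks expects HSPs of a single query")
  }
  o <- order(-hsps$score, hsps$q_start, hsps$s_start)
  chains <- list()
  for (ri in o) {
    h <- hsps[ri, ]
    placed <- FALSE
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      if (ch$subject_id != h$subject_id || ch$strand != h$strand) next
      if (fits_chain(ch, h, max_gap, overlap_tol)) {
        ch$members <- c(ch$members, ri)
        ch$q_start <- min(ch$q_start, h$q_start)
        ch$q_end <- max(ch$q_end, h$q_end)
        ch$s_start <- min(ch$s_start, h$s_start)
        ch$s_end <- max(ch$s_end, h$s_end)
        ch$score <- ch$score + h$score
        chains[[ci]] <- ch
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      chains[[length(chains) + 1]] <- list(
        query_id = h$query_id, subject_id = h$subject_id, strand = h$strand,
        q_start = h$q_start, q_end = h$q_end,
        s_start = h$s_start, s_end = h$s_end,
        score = h$score, members = ri)
    }
  }
  out <- do.call(rbind, lapply(chains, function(ch) {
    data.frame(query_id = ch$query_id, subject_id = ch$subject_id,
               strand = ch$strand, q_start = ch$q_start, q_end = ch$q_end,
               s_start = ch$s_start, s_end = ch$s_end, score = ch$score,
               n_hsps = length(ch$members),
               joined_query_span = union_length(hsps$q_start[ch$members],
                                               hsps$q_end[ch$members]),
               stringsAsFactors = FALSE)
  }))
  out$members <- I(lapply(chains, function(ch) sort(ch$members)))
  o2 <- order(-out$score, out$q_start, out$subject_id)
  out <- out[o2, , drop = FALSE]
  out$chain_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

empty_chains <- function() {
  out <- data.frame(query_id = character(0), subject_id = character(0),
                    strand = character(0), q_start = integer(0),
                    q_end = integer(0), s_start = integer(0),
                    s_end = integer(0), score = integer(0),
                    n_hsps = integer(0), joined_query_span = integer(0),
                    stringsAsFactors = FALSE)
  out$members <- I(list())
  out$chain_id <- integer(0)
  out
}

# can HSP h extend chain ch co-linearly (before or after it)?
fits_chain <- function(ch, h, max_gap, overlap_tol) {
  after_q <- (h$q_start - ch$q_end) <= max_gap &&
    (h$q_start - ch$q_end) >= -overlap_tol
  before_q <- (ch$q_start - h$q_end) <= max_gap &&
    (ch$q_start - h$q_end) >= -overlap_tol
  if (ch$strand == "+") {
    after_s <- (h$s_start - ch$s_end) <= max_gap &&
      (h$s_start - ch$s_end) >= -overlap_tol
    before_s <- (ch$s_start - h$s_end) <= max_gap &&
      (ch$s_start - h$s_end) >= -overlap_tol
    (after_q && after_s) || (before_q && before_s)
  } else {
    # reverse strand: query ascends while subject descends
    after_s <- (ch$s_start - h$s_end) <= max_gap &&
      (ch$s_start - h$s_end) >= -overlap_tol
    before_s <- (h$s_start - ch$s_end) <= max_gap &&
      (h$s_start - ch$s_end) >= -overlap_tol
    (after_q && after_s) || (before_q && before_s)
  }
}

#' Write HSPs as a 12-column tabular report
#'
#' Layout matches the widespread tabular similarity-search output: query,
#' subject, percent identity, alignment length, mismatches, gap columns,
#' query start/end, subject start/end (1-based, subject reversed on the
#' minus strand), score twice (in place of E-value and bit score, which the
#' deterministic score model does not define).
#'
#' @param hsps an HSP data frame.
#' @param path output path.
#' @export
write_hsps_tsv <- function(hsps, path) {
  df <- data.frame(
    query = hsps$query_id, subject = hsps$subject_id,
    identity = sprintf("%.2f", hsps$identity_pct),
    length = hsps$aligned_cols,
    mismatches = hsps$aligned_cols - hsps$matches - hsps$gaps,
    gaps = hsps$gaps,
    q_start = hsps$q_start + 1L, q_end = hsps$q_end,
    s_start = ifelse(hsps$strand == "+", hsps$s_start + 1L, hsps$s_end),
    s_end = ifelse(hsps$strand == "+", hsps$s_end, hsps$s_start + 1L),
    score1 = hsps$score, score2 = hsps$score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' ASCII dot plot of two sequences
#'
#' Coarse k-mer match matrix for eye-balling a read against a locus
#' construct, in the spirit of classic dotter inspection. Purely a review
#' aid: it never influences calling.
#'
#' @param a,b sequences (rows and columns respectively).
#' @param width plot width in characters; height scales with length ratio.
#' @param k word size per character cell.
#' @return invisibly, the character matrix; printed to the console.
#' @export
ascii_dotplot <- function(a, b, width = 72L, k = 12L) {
  a <- seq1(a); b <- seq1(b)
  nc <- min(width, nchar(b))
  nr <- max(5L, min(width, as.integer(ceiling(nc * nchar(a) / nchar(b)))))
  astep <- nchar(a) / nr
  bstep <- nchar(b) / nc
  words <- function(s, step, n, k) {
    vapply(seq_len(n), function(i) {
      p <- as.integer(round((i - 1) * step)) + 1L
      substr(s, p, min(nchar(s), p + k - 1L))
    }, "")
  }
  wa <- words(a, astep, nr, k)
  m <- matrix(" ", nr, nc)
  for (j in seq_len(nc)) {
    p <- as.integer(round((j - 1) * bstep)) + 1L
    win <- substr(b, max(1L, p - as.integer(bstep)),
                  min(nchar(b), p + as.integer(bstep) + k))
    rwin <- cpp_revcomp(win)
    hit_f <- vapply(wa, function(w) grepl(w, win, fixed = TRUE), NA)
    hit_r <- vapply(wa, function(w) grepl(w, rwin, fixed = TRUE), NA)
    m[hit_r, j] <- "\\"
    m[hit_f, j] <- "."
  }
  apply(m, 1, function(r) cat(paste(r, collapse = ""), "\n"))
  invisible(m)
}
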