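# Sequence containers and FASTA/FASTQ I/O.
#
# A sequence set ("dna_set") is a named character vector of uppercase
# DNA strings over {A,C,G,T,N}, with optional attributes:
#   desc - named character vector of free-text descriptions
#   qual - named list of integer Phred quality vectors (FASTQ input)
# A reference genome is simply a dna_set whose elements are chromosomes.

#' Construct a sequence set
#'
#' @param seqs named character vector of DNA sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param desc optional character vector of descriptions.
#' @param qual optional list of integer per-base quality vectors.
#' @param normalize uppercase, map U to T and non-ACGTN to N (with a warning
#'   giving the replaced-base count).
#' @return a named character vector of class `dna_set`.
#' @export
dna_set <- function(seqs, desc = NULL, qual = NULL, normalize = TRUE) {
  if (methods::is(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  if (!is.character(seqs)) stop("seqs must be a character vector or DNAStringSet")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("every sequence must be named")
  }
  if (anyDuplicated(names(seqs))) {
    dup <- names(seqs)[duplicated(names(seqs))][1]
    stop(sprintf("duplicate sequence id '%s'", dup))
  }
  if (grepl("\\s", paste(names(seqs), collapse = ""))) {
    stop("sequence ids must not contain whitespace")
  }
  if (normalize) seqs <- normalize_residues(seqs)
  if (!is.null(qual)) {
    if (length(qual) != length(seqs)) stop("qual must match seqs in length")
    names(qual) <- names(seqs)
    bad <- which(vapply(qual, length, 1L) != nchar(seqs))
    if (length(bad)) {
      stop(sprintf("quality length does not match sequence length for '%s'",
                   names(seqs)[bad[1]]))
    }
    attr(seqs, "qual") <- qual
  }
  if (!is.null(desc)) {
    names(desc) <- names(seqs)
    attr(seqs, "desc") <- desc
  }
  class(seqs) <- "dna_set"
  seqs
}

normalize_residues <- function(seqs) {
  at <- attributes(seqs)
  seqs <- chartr("u", "t", seqs)
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  n_bad <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  if (n_bad > 0) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    warning(sprintf("%d non-ACGTN residues replaced by N", n_bad))
  }
  attributes(seqs) <- at
  seqs
}

#' @export
print.dna_set <- function(x, ...) {
  cat(sprintf("dna_set with %d sequence(s), %s bases total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %-20s %9d bp  %s%s\n", names(x)[i], nchar(s),
                substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' @export
`[.dna_set` <- function(x, i) {
  qual <- attr(x, "qual"); desc <- attr(x, "desc")
  y <- unclass(x)[i]
  dna_set(y,
          desc = if (!is.null(desc)) desc[names(y)] else NULL,
          qual = if (!is.null(qual)) qual[names(y)] else NULL,
          normalize = FALSE)
}

#' Reverse complement
#' @param x a DNA string (or character vector of them).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- vapply(unclass(x), cpp_revcomp, "", USE.NAMES = FALSE)
  names(out) <- names(x)
  out
}

first_token <- function(x) sub("\\s.*$", "", x)
rest_tokens <- function(x) ifelse(grepl("\\s", x), sub("^\\S+\\s+", "", x), "")

#' Read a FASTA file
#'
#' Residues are uppercased, U is mapped to T, and any other non-ACGTN
#' character becomes N (a warning reports the count). Record ids (the first
#' whitespace-delimited header token) must be unique.
#'
#' @param path path to a FASTA file.
#' @return a [dna_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (file.size(path) == 0) stop(sprintf("%s: empty file (line 1)", path))
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">")) {
    stop(sprintf("%s: malformed FASTA header at line 1 (expected '>')", path))
  }
  # BStringSet: keep raw residues so that U and ambiguity codes reach our
  # own normalization instead of the DNA-alphabet coercion
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) {
                  stop(sprintf("%s: FASTA format error: %s", path,
                               conditionMessage(e)), call. = FALSE)
                })
  if (length(x) == 0) stop(sprintf("%s: empty file (line 1)", path))
  hdr <- names(x)
  seqs <- as.character(x)
  names(seqs) <- first_token(hdr)
  dna_set(seqs, desc = rest_tokens(hdr))
}

#' Read a FASTQ file (Phred+33)
#'
#' Structure is validated record by record (errors name the offending line);
#' qualities are returned as integer Phred scores. An empty file yields an
#' empty sequence set.
#'
#' @param path path to a FASTQ file.
#' @return a [dna_set()] with a `qual` attribute.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  while (length(lines) && lines[length(lines)] == "") lines <- lines[-length(lines)]
  if (length(lines) == 0) {
    return(dna_set(setNames(character(0), character(0)), normalize = FALSE))
  }
  if (length(lines) %% 4 != 0) {
    stop(sprintf("%s: truncated FASTQ record at line %d", path,
                 4L * (length(lines) %/% 4L) + 1L))
  }
  n <- length(lines) %/% 4L
  hdr_i <- 4L * (seq_len(n) - 1L) + 1L
  bad_hdr <- which(!startsWith(lines[hdr_i], "@"))
  if (length(bad_hdr)) {
    stop(sprintf("%s: malformed FASTQ header at line %d (expected '@')",
                 path, hdr_i[bad_hdr[1]]))
  }
  seqs <- lines[hdr_i + 1L]
  quals <- lines[hdr_i + 3L]
  mism <- which(nchar(seqs) != nchar(quals))
  if (length(mism)) {
    stop(sprintf("%s: quality length differs from sequence length at line %d",
                 path, hdr_i[mism[1]] + 3L))
  }
  hdr <- substring(lines[hdr_i], 2L)
  qv <- lapply(quals, function(q) utf8ToInt(q) - 33L)
  if (length(qv) && (min(unlist(qv), Inf) < 0 || max(unlist(qv), -Inf) > 93)) {
    stop(sprintf("%s: quality characters outside Phred+33 range", path))
  }
  names(seqs) <- first_token(hdr)
  dna_set(seqs, desc = rest_tokens(hdr), qual = qv)
}

#' Write sequences as FASTA
#' @param x a [dna_set()] or named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(x, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(unname(c(x))))
  names(ss) <- names(x)
  desc <- attr(x, "desc")
  if (!is.null(desc) && any(nzchar(desc))) {
    names(ss) <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
  }
  Biostrings::writeXStringSet(ss, path, format = "fasta", width = width)
  invisible(path)
}

#' Write sequences as FASTQ (Phred+33)
#'
#' Sequences lacking stored qualities get a flat quality of 40.
#' @inheritParams write_fasta
#' @export
write_fastq <- function(x, path) {
  qual <- attr(x, "qual")
  desc <- attr(x, "desc")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    id <- names(x)[i]
    s <- unclass(x)[[i]]
    q <- if (!is.null(qual) && !is.null(qual[[id]])) qual[[id]] else rep(40L, nchar(s))
    hdr <- if (!is.null(desc) && nzchar(desc[[id]])) paste(id, desc[[id]]) else id
    writeLines(c(paste0("@", hdr), s, "+", intToUtf8(q + 33L)), con)
  }
  invisible(path)
}

#' Extract a padded genomic window
#'
#' Returns the subsequence of `[max(0, start-pad), min(chrom_len, end+pad))`
#' on the requested strand (reverse strand returns the reverse complement).
#' Coordinates are 0-based half-open; the record id encodes the clipped
#' source coordinates as `chrom:start-end(strand)`.
#'
#' @param genome a [dna_set()] of chromosomes.
#' @param chrom chromosome id.
#' @param start,end 0-based half-open interval on the chromosome.
#' @param pad bases of flank added on each side (clipped at the ends).
#' @param strand "+" or "-".
#' @return a single-record [dna_set()].
#' @export
extract_window <- function(genome, chrom, start, end, pad = 0L, strand = "+") {
  if (!chrom %in% names(genome)) stop(sprintf("unknown chromosome '%s'", chrom))
  if (end <= start) stop("end must be greater than start")
  L <- nchar(unclass(genome)[[chrom]])
  s0 <- max(0L, as.integer(start) - as.integer(pad))
  e0 <- min(L, as.integer(end) + as.integer(pad))
  seq <- substr(unclass(genome)[[chrom]], s0 + 1L, e0)
  if (strand == "-") seq <- cpp_revcomp(seq)
  out <- setNames(seq, sprintf("%s:%d-%d(%s)", chrom, s0, e0, strand))
  dna_set(out, normalize = FALSE)
}
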