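# Insertion-call output: BED6, GFF3 and TSV, plus BED read-back.
# Internal coordinates are 0-based half-open; GFF3 output converts to
# 1-based inclusive (gff_start = bed_start + 1, gff_end = bed_end).

call_strand <- function(orientation) {
  ifelse(orientation == "sense", "+",
         ifelse(orientation == "antisense", "-", "."))
}

#' Write insertion calls
#'
#' BED6 body columns: chrom, start, end (0-based half-open), name
#' (`call_id;family`), score (supporting-read count), strand (element
#' orientation). GFF3 uses 1-based inclusive coordinates, type
#' `transposable_element_insertion_site`, with family, support and status
#' in the attributes. TSV dumps the full call table. Writing an empty call
#' set produces a header-only file; a BED round trip through
#' [read_calls_bed()] reproduces the body byte for byte.
#'
#' @param calls a call data frame ([cluster_calls()] output, or the
#'   BED-like frame returned by [read_calls_bed()]).
#' @param path output path.
#' @param format "BED", "GFF3" or "TSV".
#' @export
write_calls <- function(calls, path, format = c("BED", "GFF3", "TSV")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "BED") {
    writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
    if (nrow(calls)) {
      nm <- if ("name" %in% names(calls)) calls$name else
        paste0(calls$call_id, ";", calls$te_family)
      sc <- if ("score" %in% names(calls)) calls$score else calls$n_support
      st <- if ("strand" %in% names(calls)) calls$strand else
        call_strand(calls$orientation)
      writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", calls$chrom,
                         calls$start, calls$end, nm, sc, st), con)
    }
  } else if (format == "GFF3") {
    writeLines("##gff-version 3", con)
    if (nrow(calls)) {
      attrs <- sprintf(
        "ID=%s;family=%s;n_support=%d;support=%s;status=%s;reference_copy=%s",
        calls$call_id, calls$te_family, calls$n_support,
        gsub(",", "|", calls$support), calls$status,
        ifelse(calls$is_reference_copy, "true", "false"))
      writeLines(sprintf(
        "%s\tteasv\ttransposable_element_insertion_site\t%d\t%d\t%d\t%s\t.\t%s",
        calls$chrom, calls$start + 1L, calls$end, calls$n_support,
        call_strand(calls$orientation), attrs), con)
    }
  } else {
    writeLines(paste(names(calls), collapse = "\t"), con)
    if (nrow(calls)) {
      write.table(calls, con, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read calls back from BED6
#'
#' @param path a BED file written by [write_calls()] (or any BED6 with
#'   optional `#` header lines).
#' @return a data frame: `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`; re-writable with [write_calls()] byte-identically.
#' @export
read_calls_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop(sprintf("%s: expected BED6 (6 columns)", path))
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  df[, 1:6]
}
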