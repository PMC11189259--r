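#' Read sequences from FASTA or FASTQ
#'
#' Loads a (possibly gzipped) FASTA or FASTQ file into a tibble, preserving
#' record order. Sequences are upper-cased on input; the full header line is
#' kept as `read_id`.
#'
#' @param path Path to the file.
#' @param format `"auto"` (detect from the first byte: `>` FASTA, `@` FASTQ),
#'   `"fasta"`, or `"fastq"`.
#' @return A tibble with columns `read_id`, `seq` and, for FASTQ, `qual`.
#'   An empty file yields a zero-row tibble.
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    first <- readLines(con, n = 1L)
    if (length(first) == 0L) {
      return(tibble(read_id = character(), seq = character()))
    }
    ch <- substr(trimws(first), 1, 1)
    format <- switch(ch,
      ">" = "fasta",
      "@" = "fastq",
      abort(paste0("cannot detect format of ", path,
                   ": first record starts with '", ch, "'"))
    )
  }
  if (format == "fastq") validate_fastq(path)
  parsed <- tryCatch(
    if (format == "fasta") {
      Biostrings::readDNAStringSet(path, format = "fasta")
    } else {
      Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    },
    error = function(e) {
      abort(paste0("malformed ", format, " file ", path, ": ",
                   conditionMessage(e)))
    }
  )
  out <- tibble(
    read_id = names(parsed),
    seq = unname(toupper(as.character(parsed)))
  )
  if (format == "fastq") {
    out$qual <- unname(as.character(S4Vectors::mcols(parsed)$qualities))
  }
  out
}

# The flexible multi-line FASTQ parsers are lenient about truncated quality
# strings, so record structure is checked against the 4-line layout first.
validate_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0) return(invisible(TRUE))
  if (length(lines) %% 4 != 0) {
    abort(paste0("malformed fastq file ", path,
                 ": line count is not a multiple of 4"))
  }
  n_rec <- length(lines) / 4
  heads <- lines[seq(1, by = 4, length.out = n_rec)]
  seps <- lines[seq(3, by = 4, length.out = n_rec)]
  seqs <- lines[seq(2, by = 4, length.out = n_rec)]
  quals <- lines[seq(4, by = 4, length.out = n_rec)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad) > 0) {
    abort(paste0("malformed fastq record ", bad[1], " in ", path))
  }
  invisible(TRUE)
}

#' Write sequences to FASTA or FASTQ
#'
#' Round-trips with [read_seqs()] on `read_id` and `seq`. When writing FASTA
#' from records that carry qualities, the qualities are silently dropped;
#' when writing FASTQ from records without qualities, a uniform placeholder
#' quality (`"I"`, Q40) is used.
#'
#' @param records Tibble with `read_id` and `seq` (optionally `qual`), or a
#'   named character vector of sequences.
#' @param path Output path. A `.gz` suffix writes gzip-compressed output.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_seqs <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  records <- as_seq_tbl(records, "records")
  compress <- grepl("\\.gz$", path)
  if (nrow(records) == 0) {
    con <- if (compress) gzfile(path, "wt") else file(path, "wt")
    close(con)
    return(invisible(path))
  }
  set <- Biostrings::DNAStringSet(records$seq)
  names(set) <- records$read_id
  if (format == "fasta") {
    Biostrings::writeXStringSet(set, path, format = "fasta",
                                compress = compress)
  } else {
    qual <- records[["qual"]]
    if (is.null(qual)) {
      qual <- vapply(nchar(records$seq),
                     function(n) strrep("I", n), character(1))
    }
    Biostrings::writeXStringSet(
      set, path, format = "fastq", compress = compress,
      qualities = Biostrings::BStringSet(qual)
    )
  }
  invisible(path)
}

#' Filter long reads by length
#'
#' Keeps reads whose length is within `[min_len, max_len]`, bounds included.
#' The default window of 1 kb to 100 kb is the standard nanopore input filter
#' for chromosome-quotient binning. Input order is preserved and a summary of
#' kept/dropped counts is emitted as a message.
#'
#' @param reads Tibble with a `seq` column (see [read_seqs()]) or character
#'   vector of sequences.
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return The subset of `reads` passing the filter, order preserved.
#' @examples
#' reads <- tibble::tibble(
#'   read_id = c("a", "b"),
#'   seq = c(strrep("A", 500), strrep("A", 1500))
#' )
#' filter_long_reads(reads, min_len = 1000)
#' @export
filter_long_reads <- function(reads, min_len = 1000, max_len = 100000) {
  if (!(min_len > 0 && min_len < max_len)) {
    abort("need 0 < min_len < max_len")
  }
  reads <- as_seq_tbl(reads, "reads")
  len <- nchar(reads$seq)
  keep <- len >= min_len & len <= max_len
  inform(sprintf("filter_long_reads: kept %d, dropped %d of %d reads",
                 sum(keep), sum(!keep), length(keep)))
  reads[keep, , drop = FALSE]
}
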