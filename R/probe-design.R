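#' Anchor Y-bin reads on a target k-mer
#'
#' Collects every Y-bin long read containing the target k-mer as an exact
#' match on either strand (the 100%-match sub-bin) and cuts an oriented
#' window around the first (leftmost) occurrence in each read: reads whose
#' match lies on the minus strand are reverse-complemented so that the
#' target appears in plus orientation at a fixed column. Windows span
#' `flank` bases on each side of the target and are padded with `-` where
#' the read ends inside the window; pad symbols never vote in the consensus.
#'
#' @param target_kmer Target sequence (the 25-bp k-mer).
#' @param y_bin_reads Tibble of Y-bin long reads (`read_id`, `seq`) or
#'   character vector.
#' @param flank Bases kept on each side of the target (default 60, i.e.
#'   145-bp windows for a 25-bp target).
#' @return An `anchored_subbin`: list with `target`, `flank`, `members`
#'   (tibble `read_id`, `offset` — 1-based leftmost match position in the
#'   original read — and `strand`) and `windows` (equal-length oriented
#'   character vector).
#' @export
build_subbin <- function(target_kmer, y_bin_reads, flank = 60) {
  y_bin_reads <- as_seq_tbl(y_bin_reads, "y_bin_reads")
  if (nrow(y_bin_reads) == 0) abort("y_bin_reads must be non-empty")
  target_kmer <- toupper(target_kmer)
  k <- nchar(target_kmer)
  if (flank < 0) abort("flank must be >= 0")
  m <- cpp_first_match(y_bin_reads$seq, target_kmer)
  keep <- which(m$offset >= 0)
  if (length(keep) == 0) {
    abort("empty sub-bin: no Y-bin read contains the target k-mer")
  }
  windows <- character(length(keep))
  for (i in seq_along(keep)) {
    idx <- keep[i]
    seq <- toupper(y_bin_reads$seq[idx])
    off <- m$offset[idx] # 0-based
    if (m$strand[idx] == "-") {
      n <- nchar(seq)
      seq <- cpp_revcomp(seq)
      off <- n - (off + k)
    }
    n <- nchar(seq)
    lo <- off - flank # 0-based window start
    hi <- off + k + flank # 0-based exclusive end
    core <- substr(seq, max(0, lo) + 1, min(n, hi))
    windows[i] <- paste0(strrep("-", max(0, -lo)), core,
                         strrep("-", max(0, hi - n)))
  }
  structure(list(
    target = target_kmer,
    flank = flank,
    members = tibble(read_id = y_bin_reads$read_id[keep],
                     offset = m$offset[keep] + 1L,
                     strand = m$strand[keep]),
    windows = windows
  ), class = "anchored_subbin")
}

#' @export
print.anchored_subbin <- function(x, ...) {
  cat(sprintf("<anchored_subbin> target %s, %d member reads, %d-bp windows\n",
              x$target, length(x$windows), nchar(x$windows[1])))
  invisible(x)
}

#' Column-wise consensus of an anchored sub-bin
#'
#' Because every window carries the target at the same columns, a gap-free
#' column-wise consensus is exact in the anchor's neighbourhood: per column,
#' the consensus base is the modal base among non-pad symbols provided its
#' frequency (the column support) reaches `support_threshold`, otherwise
#' `N`. Modal ties are broken alphabetically (A < C < G < T). Columns with
#' no voting base (all pads) are `N` with support 0.
#'
#' @param subbin An [build_subbin()] result.
#' @param support_threshold Minimum modal-base frequency for a called base
#'   (default 0.5).
#' @return A `probe_consensus`: list with `consensus` (string), `support`
#'   (per-column numeric), `n_windows`, `target`, and `target_col` (column
#'   of the target's first base).
#' @export
consensus_from_subbin <- function(subbin, support_threshold = 0.5) {
  if (length(subbin$windows) < 1) abort("sub-bin has no windows")
  mat <- do.call(rbind, strsplit(subbin$windows, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  ncol_w <- ncol(mat)
  cons <- character(ncol_w)
  supp <- numeric(ncol_w)
  for (j in seq_len(ncol_w)) {
    col <- mat[, j]
    counts <- c(sum(col == "A"), sum(col == "C"),
                sum(col == "G"), sum(col == "T"))
    voting <- sum(counts)
    if (voting == 0) {
      cons[j] <- "N"
      supp[j] <- 0
      next
    }
    best <- which.max(counts) # first max: alphabetical tie-break
    supp[j] <- counts[best] / voting
    cons[j] <- if (supp[j] >= support_threshold) bases[best] else "N"
  }
  structure(list(
    consensus = paste(cons, collapse = ""),
    support = supp,
    n_windows = length(subbin$windows),
    target = subbin$target,
    target_col = subbin$flank + 1L
  ), class = "probe_consensus")
}

#' @export
print.probe_consensus <- function(x, ...) {
  cat(sprintf("<probe_consensus> %d bp from %d windows (min support %.2f)\n",
              nchar(x$consensus), x$n_windows, min(x$support)))
  invisible(x)
}

#' @describeIn consensus_from_subbin Per-column tibble of the consensus.
#' @param x A `probe_consensus`.
#' @param ... Unused.
#' @export
tidy.probe_consensus <- function(x, ...) {
  tibble(column = seq_len(nchar(x$consensus)),
         base = strsplit(x$consensus, "", fixed = TRUE)[[1]],
         support = x$support)
}

#' Select a FISH probe from a consensus
#'
#' Among all `probe_len`-bp windows of the consensus that contain the full
#' target k-mer, returns the window maximizing mean column support (ties:
#' smallest start offset). Windows containing more than `max_n` uncalled
#' (`N`) positions are rejected; an error is raised if no admissible window
#' remains. The default 44-bp probe extends the 25-bp target with flanking
#' satellite sequence so the oligo hybridizes robustly.
#'
#' @param consensus A `probe_consensus` from [consensus_from_subbin()], or a
#'   plain consensus string (then `support` must be supplied).
#' @param target_kmer The target that the probe must contain.
#' @param probe_len Probe length in bp (default 44; must be >= the target
#'   length).
#' @param max_n Maximum tolerated `N` positions inside the probe (default 0).
#' @param support Per-column support, only when `consensus` is a string.
#' @return A `probe_design`: list with `probe`, `probe_start` (1-based
#'   column in the consensus), `support_min` and `support_mean` inside the
#'   probe, `target`, and `probe_len`.
#' @export
design_probe <- function(consensus, target_kmer, probe_len = 44, max_n = 0,
                         support = NULL) {
  if (inherits(consensus, "probe_consensus")) {
    support <- consensus$support
    cons <- consensus$consensus
    if (missing(target_kmer)) target_kmer <- consensus$target
  } else {
    cons <- consensus
    if (is.null(support)) support <- rep(1, nchar(cons))
  }
  target_kmer <- toupper(target_kmer)
  k <- nchar(target_kmer)
  if (probe_len < k) abort("probe_len must be >= the target length")
  L <- nchar(cons)
  if (L < probe_len) abort("consensus shorter than probe_len")
  occ <- gregexpr(target_kmer, cons, fixed = TRUE)[[1]]
  if (occ[1] == -1) abort("target k-mer absent from the consensus")
  starts <- integer(0)
  for (o in as.integer(occ)) {
    lo <- max(1L, o + k - probe_len)
    hi <- min(o, L - probe_len + 1L)
    if (lo <= hi) starts <- c(starts, lo:hi)
  }
  starts <- sort(unique(starts))
  if (length(starts) == 0) abort("no probe window can contain the target")
  cons_chars <- strsplit(cons, "", fixed = TRUE)[[1]]
  best_start <- NA_integer_
  best_score <- -Inf
  for (s in starts) {
    idx <- s:(s + probe_len - 1)
    if (sum(cons_chars[idx] == "N") > max_n) next
    score <- mean(support[idx])
    if (score > best_score + 1e-12) {
      best_score <- score
      best_start <- s
    }
  }
  if (is.na(best_start)) {
    abort("every admissible probe window exceeds the N limit")
  }
  idx <- best_start:(best_start + probe_len - 1)
  structure(list(
    probe = substr(cons, best_start, best_start + probe_len - 1),
    probe_start = best_start,
    probe_len = probe_len,
    target = target_kmer,
    support_min = min(support[idx]),
    support_mean = mean(support[idx])
  ), class = "probe_design")
}

#' @export
print.probe_design <- function(x, ...) {
  cat(sprintf("<probe_design> %d bp at consensus column %d (min support %.2f)\n",
              x$probe_len, x$probe_start, x$support_min))
  cat(" ", x$probe, "\n")
  invisible(x)
}

#' Design a FISH probe for a target k-mer in one call
#'
#' Convenience wrapper: builds the 100%-match sub-bin of the Y-bin reads,
#' forms the anchored consensus, and selects the best probe window.
#'
#' @inheritParams build_subbin
#' @inheritParams consensus_from_subbin
#' @inheritParams design_probe
#' @return A `probe_design` (see [design_probe()]).
#' @export
design_fish_probe <- function(target_kmer, y_bin_reads, flank = 60,
                              support_threshold = 0.5, probe_len = 44,
                              max_n = 0) {
  if (flank < probe_len - nchar(target_kmer)) {
    abort("flank too small to cut a probe_len window around the target")
  }
  subbin <- build_subbin(target_kmer, y_bin_reads, flank = flank)
  cons <- consensus_from_subbin(subbin, support_threshold = support_threshold)
  design_probe(cons, target_kmer, probe_len = probe_len, max_n = max_n)
}
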