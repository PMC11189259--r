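#' Chromosome-Quotient bin thresholds
#'
#' The standard thresholds assign a long read to the Y bin when its CQ is at
#' most `ymax`, to the autosomal bin between `ymax` and `xmin`, and to the X
#' bin between `xmin` and `xmax` (inclusive); reads with CQ above `xmax`, or
#' with too few male hits for a defined CQ, are excluded.
#'
#' @param xmin,xmax Bounds of the X bin (defaults 1.5 and 2.5).
#' @param ymax Upper bound of the Y bin (default 0.3).
#' @return A validated `bin_thresholds` list.
#' @export
bin_thresholds <- function(xmin = 1.5, xmax = 2.5, ymax = 0.3) {
  if (!(ymax > 0 && ymax < xmin && xmin < xmax)) {
    abort("need 0 < ymax < xmin < xmax")
  }
  structure(list(xmin = xmin, xmax = xmax, ymax = ymax),
            class = "bin_thresholds")
}

#' Count sex-separated short-read hits on long reads
#'
#' For each long read, counts how many female and how many male short reads
#' pseudo-align to it. By default (`seed_len = NULL`) a short read hits a
#' long read when it occurs as an exact substring on either strand — the
#' natural definition for error-free reads. With a numeric `seed_len`, a hit
#' instead requires at least `min_shared` exact canonical seed k-mers of
#' that length shared between the two reads, which tolerates substitution
#' errors. A short read hitting several long reads is counted once per long
#' read. Externally computed hit tables with the same columns can be
#' substituted anywhere this one is accepted.
#'
#' @param long_reads Tibble with `read_id` and `seq`, or character vector.
#' @param female_reads,male_reads Short-read tibbles or character vectors.
#' @param seed_len `NULL` for exact containment, or an integer seed k-mer
#'   length (15–32).
#' @param min_shared Minimum number of shared seed k-mers for a hit (seed
#'   mode only).
#' @return Tibble with `read_id`, `female_hits`, `male_hits`, one row per
#'   long read in input order.
#' @export
count_short_read_hits <- function(long_reads, female_reads, male_reads,
                                  seed_len = NULL, min_shared = 1) {
  long_reads <- as_seq_tbl(long_reads, "long_reads")
  female_reads <- as_seq_tbl(female_reads, "female_reads")
  male_reads <- as_seq_tbl(male_reads, "male_reads")
  if (nrow(long_reads) == 0) abort("long_reads must be non-empty")
  if (nrow(female_reads) == 0 || nrow(male_reads) == 0) {
    abort("short-read sets must be non-empty")
  }
  if (is.null(seed_len)) {
    fh <- cpp_containment_hits(long_reads$seq, female_reads$seq)
    mh <- cpp_containment_hits(long_reads$seq, male_reads$seq)
  } else {
    if (seed_len < 15) abort("seed_len must be >= 15")
    min_short <- min(nchar(female_reads$seq), nchar(male_reads$seq))
    if (seed_len > min_short) {
      abort("seed_len exceeds the short-read length")
    }
    fh <- cpp_seed_hits(long_reads$seq, female_reads$seq, seed_len, min_shared)
    mh <- cpp_seed_hits(long_reads$seq, male_reads$seq, seed_len, min_shared)
  }
  tibble(read_id = long_reads$read_id, female_hits = fh, male_hits = mh)
}

#' Compute the Chromosome Quotient
#'
#' CQ is the ratio of female to male short-read coverage after per-library
#' normalization: hits are scaled to hits per million reads of each sex's
#' library before taking the ratio, which makes CQ invariant to unequal
#' sequencing depth. Sequences with fewer than `m_min` male hits get an
#' undefined CQ (`NA`) and are excluded downstream, rather than producing
#' unstable or infinite ratios. Y-linked sequences have CQ near 0, autosomal
#' near 1, X-linked near 2.
#'
#' @param hits Tibble with `female_hits` and `male_hits` (see
#'   [count_short_read_hits()]).
#' @param female_total,male_total Library sizes: total numbers of female and
#'   male short reads (> 0).
#' @param m_min Minimum male hits for a defined CQ (default 10).
#' @return `hits` with added columns `female_norm`, `male_norm`, `cq`.
#' @examples
#' compute_cq(tibble::tibble(female_hits = 20, male_hits = 10),
#'            female_total = 1e6, male_total = 1e6, m_min = 1)
#' @export
compute_cq <- function(hits, female_total, male_total, m_min = 10) {
  if (female_total <= 0 || male_total <= 0) {
    abort("read totals must be > 0")
  }
  hits %>%
    mutate(
      female_norm = .data$female_hits * 1e6 / female_total,
      male_norm = .data$male_hits * 1e6 / male_total,
      cq = ifelse(.data$male_hits >= m_min,
                  .data$female_norm / .data$male_norm, NA_real_)
    )
}

#' Assign a chromosomal bin from a CQ value
#'
#' @param cq Numeric vector of CQ values (`NA` = undefined).
#' @param thresholds A [bin_thresholds()].
#' @return Character vector over `{"Y", "autosomal", "X", "excluded"}`.
#'   Boundaries are inclusive toward their bins: `cq == ymax` is Y and
#'   `cq == xmin` or `cq == xmax` is X; `cq > xmax` or undefined CQ is
#'   excluded.
#' @examples
#' assign_bin(c(0.1, 0.3, 1, 2, 3.7, NA), bin_thresholds())
#' @export
assign_bin <- function(cq, thresholds = bin_thresholds()) {
  out <- rep("excluded", length(cq))
  def <- !is.na(cq)
  out[def & cq <= thresholds$ymax] <- "Y"
  out[def & cq > thresholds$ymax & cq < thresholds$xmin] <- "autosomal"
  out[def & cq >= thresholds$xmin & cq <= thresholds$xmax] <- "X"
  out
}

#' Bin long reads by Chromosome Quotient
#'
#' End-to-end binning stage: counts sex-separated short-read hits on each
#' long read, computes CQ, and assigns each read to the Y, autosomal, X or
#' excluded bin. Output rows are in input order.
#'
#' @inheritParams count_short_read_hits
#' @inheritParams compute_cq
#' @param thresholds A [bin_thresholds()].
#' @return Tibble: the long reads with `female_hits`, `male_hits`,
#'   `female_norm`, `male_norm`, `cq` and `bin` columns appended.
#' @seealso [bin_summary()] for per-bin counts and base totals.
#' @export
bin_reads <- function(long_reads, female_reads, male_reads,
                      thresholds = bin_thresholds(), m_min = 10,
                      seed_len = NULL, min_shared = 1) {
  long_reads <- as_seq_tbl(long_reads, "long_reads")
  female_reads <- as_seq_tbl(female_reads, "female_reads")
  male_reads <- as_seq_tbl(male_reads, "male_reads")
  hits <- count_short_read_hits(long_reads, female_reads, male_reads,
                                seed_len = seed_len, min_shared = min_shared)
  cov <- compute_cq(hits, nrow(female_reads), nrow(male_reads), m_min = m_min)
  out <- long_reads
  out$female_hits <- cov$female_hits
  out$male_hits <- cov$male_hits
  out$female_norm <- cov$female_norm
  out$male_norm <- cov$male_norm
  out$cq <- cov$cq
  out$bin <- assign_bin(cov$cq, thresholds)
  out
}

#' Per-bin read counts and base totals
#'
#' @param binned Output of [bin_reads()].
#' @return Tibble with one row per bin: `bin`, `n_reads`, `total_bases`.
#' @export
bin_summary <- function(binned) {
  binned %>%
    mutate(bases = nchar(.data$seq)) %>%
    group_by(.data$bin) %>%
    summarise(n_reads = n(), total_bases = sum(.data$bases),
              .groups = "drop") %>%
    arrange(factor(.data$bin, levels = c("Y", "autosomal", "X", "excluded")))
}
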