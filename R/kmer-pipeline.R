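#' Extract canonical k-mers from reads
#'
#' Every length-`k` window consisting solely of A/C/G/T contributes one count
#' to its canonical form (the lexicographic minimum of the window and its
#' reverse complement); windows containing N or other IUPAC codes are
#' skipped. The sum of counts therefore equals the number of valid windows.
#'
#' @param reads Tibble with a `seq` column or character vector of sequences.
#' @param k K-mer length, 1–32 (default 25).
#' @return Tibble with `kmer` (canonical, lexicographically sorted) and
#'   `count`.
#' @export
extract_kmers <- function(reads, k = 25) {
  reads <- as_seq_tbl(reads, "reads")
  as_tibble(cpp_kmer_counts(reads$seq, as.integer(k)))
}

#' Sex-specific abundance profile of k-mers
#'
#' Joins male and female canonical k-mer counts and computes the k-mer-level
#' Chromosome Quotient with the same per-million normalization and `m_min`
#' policy as the read-level CQ (see [compute_cq()]): counts are scaled per
#' million reads of each library and the female/male ratio is undefined
#' (`NA`) below `m_min` male occurrences. K-mers seen only in females thus
#' never become Y candidates.
#'
#' @param male_kmers,female_kmers K-mer count tibbles from [extract_kmers()].
#' @param male_total,female_total Library sizes (numbers of short reads).
#' @param m_min Minimum male count for a defined k-mer CQ.
#' @return Tibble with `kmer`, `male_count`, `female_count`, `kmer_cq`.
#' @export
kmer_sex_profile <- function(male_kmers, female_kmers,
                             male_total, female_total, m_min = 10) {
  if (male_total <= 0 || female_total <= 0) abort("read totals must be > 0")
  prof <- full_join(
    rename(male_kmers, male_count = "count"),
    rename(female_kmers, female_count = "count"),
    by = "kmer"
  ) %>%
    mutate(
      male_count = ifelse(is.na(.data$male_count), 0, .data$male_count),
      female_count = ifelse(is.na(.data$female_count), 0, .data$female_count),
      kmer_cq = ifelse(
        .data$male_count >= m_min,
        (.data$female_count / female_total) / (.data$male_count / male_total),
        NA_real_
      )
    ) %>%
    arrange(.data$kmer)
  prof
}

#' Allocate k-mers to long-read chromosomal bins
#'
#' A long read contains a k-mer when the k-mer or its reverse complement
#' occurs in it as an exact substring. For each k-mer the columns `y_hits`,
#' `a_hits` and `x_hits` count the long reads of the corresponding bin
#' containing it (distinct reads by default; set `occurrences = TRUE` to
#' count every occurrence instead, which inflates counts inside tandem
#' arrays). Excluded-bin reads are ignored.
#'
#' @param kmers Tibble with a canonical `kmer` column (e.g. from
#'   [kmer_sex_profile()]).
#' @param binned_reads Output of [bin_reads()].
#' @param occurrences Count occurrences instead of distinct reads.
#' @return `kmers` with `y_hits`, `a_hits`, `x_hits` appended.
#' @export
map_kmers_to_bins <- function(kmers, binned_reads, occurrences = FALSE) {
  if (nrow(binned_reads) == 0) abort("binned_reads must be non-empty")
  k <- unique(nchar(kmers$kmer))
  if (length(k) != 1) abort("all k-mers must have the same length")
  bin_code <- c(Y = 1L, autosomal = 2L, X = 3L, excluded = 0L)
  hits <- cpp_bin_hits(kmers$kmer, binned_reads$seq,
                       bin_code[binned_reads$bin], as.integer(k),
                       occurrences)
  kmers$y_hits <- hits[, 1]
  kmers$a_hits <- hits[, 2]
  kmers$x_hits <- hits[, 3]
  kmers
}

#' Select Y-candidate k-mers
#'
#' A k-mer is a Y candidate when its k-mer CQ is defined and at most
#' `kmer_cq_max` (sex specificity), its male count reaches `min_abundance`
#' (repetitiveness/abundance), and it is found in at least `min_y_hits`
#' Y-bin long reads. The result is sorted by descending male count, then
#' k-mer, and flagged `y_candidate`.
#'
#' @param records Tibble from [map_kmers_to_bins()].
#' @param kmer_cq_max Maximum k-mer CQ (default 0.3, the Y-bin threshold).
#' @param min_abundance Minimum male short-read count (default 10).
#' @param min_y_hits Minimum number of Y-bin long-read hits (default 2).
#' @return The candidate subset with a `y_candidate` flag column.
#' @export
select_y_candidates <- function(records, kmer_cq_max = 0.3,
                                min_abundance = 10, min_y_hits = 2) {
  records %>%
    filter(!is.na(.data$kmer_cq),
           .data$kmer_cq <= kmer_cq_max,
           .data$male_count >= min_abundance,
           .data$y_hits >= min_y_hits) %>%
    mutate(y_candidate = TRUE) %>%
    arrange(desc(.data$male_count), .data$kmer)
}

#' Remove k-mers with off-targets in the autosomal or X bins
#'
#' Keeps exactly the candidates with zero hits in both the autosomal and the
#' X long-read bins (exact-match policy): any exact occurrence outside the Y
#' bin disqualifies a k-mer as a Y-shredding target.
#'
#' @param candidates Output of [select_y_candidates()].
#' @return The off-target-free subset with an `offtarget_free` flag column.
#' @export
filter_offtargets <- function(candidates) {
  candidates %>%
    filter(.data$x_hits == 0, .data$a_hits == 0) %>%
    mutate(offtarget_free = TRUE)
}

#' Run the full Y-specific k-mer screen
#'
#' End-to-end discovery pipeline: filters long reads by length, bins them by
#' Chromosome Quotient, profiles canonical k-mers of the male short reads
#' against the female library, allocates k-mers to bins, and applies the
#' Y-candidate, off-target and PAM filters in sequence (each stage keeps a
#' subset of the previous one).
#'
#' @inheritParams bin_reads
#' @param k K-mer length (default 25).
#' @param kmer_cq_max,min_abundance,min_y_hits See [select_y_candidates()].
#' @param min_protospacer,pam See [scan_pam()].
#' @param min_len,max_len Long-read length filter bounds (bp).
#' @return A `ykmer_screen` object: list with `binned` (binned long reads),
#'   `kmers` (full k-mer profile with bin hits), `candidates`,
#'   `offtarget_free`, `final` (PAM-bearing records), `guides` (one row per
#'   guide placement), and `params`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
screen_y_kmers <- function(long_reads, female_reads, male_reads,
                           thresholds = bin_thresholds(), k = 25,
                           m_min = 10, kmer_cq_max = thresholds$ymax,
                           min_abundance = 10, min_y_hits = 2,
                           min_protospacer = 20, pam = "NGG",
                           seed_len = NULL, min_shared = 1,
                           min_len = 1000, max_len = 100000) {
  long_reads <- filter_long_reads(as_seq_tbl(long_reads, "long_reads"),
                                  min_len = min_len, max_len = max_len)
  female_reads <- as_seq_tbl(female_reads, "female_reads")
  male_reads <- as_seq_tbl(male_reads, "male_reads")
  binned <- bin_reads(long_reads, female_reads, male_reads,
                      thresholds = thresholds, m_min = m_min,
                      seed_len = seed_len, min_shared = min_shared)
  profile <- kmer_sex_profile(
    extract_kmers(male_reads, k = k),
    extract_kmers(female_reads, k = k),
    male_total = nrow(male_reads), female_total = nrow(female_reads),
    m_min = m_min
  )
  kmers <- map_kmers_to_bins(profile, binned)
  candidates <- select_y_candidates(kmers, kmer_cq_max = kmer_cq_max,
                                    min_abundance = min_abundance,
                                    min_y_hits = min_y_hits)
  offtarget_free <- filter_offtargets(candidates)
  final <- select_guides(offtarget_free, min_protospacer = min_protospacer,
                         pam = pam)
  guides <- if (nrow(final) > 0) scan_pam(final$kmer, min_protospacer, pam)
            else scan_pam(character(), min_protospacer, pam)
  structure(list(
    binned = binned,
    kmers = kmers,
    candidates = candidates,
    offtarget_free = offtarget_free,
    final = final,
    guides = guides,
    params = list(thresholds = thresholds, k = k, m_min = m_min,
                  kmer_cq_max = kmer_cq_max, min_abundance = min_abundance,
                  min_y_hits = min_y_hits, min_protospacer = min_protospacer,
                  pam = pam, min_len = min_len, max_len = max_len)
  ), class = "ykmer_screen")
}

#' @export
print.ykmer_screen <- function(x, ...) {
  g <- glance(x)
  cat("<ykmer_screen>\n")
  cat(sprintf("  long reads binned: %d (Y=%d, autosomal=%d, X=%d, excluded=%d)\n",
              g$n_long_reads, g$n_y_bin, g$n_a_bin, g$n_x_bin, g$n_excluded))
  cat(sprintf("  k-mer funnel: %d profiled -> %d Y candidates -> %d off-target-free -> %d PAM-bearing\n",
              g$n_kmers, g$n_candidates, g$n_offtarget_free, g$n_final))
  invisible(x)
}

#' @describeIn screen_y_kmers K-mer table with candidacy flags, one row per
#'   profiled k-mer.
#' @param x A `ykmer_screen` object.
#' @param ... Unused.
#' @export
tidy.ykmer_screen <- function(x, ...) {
  x$kmers %>%
    mutate(
      y_candidate = .data$kmer %in% x$candidates$kmer,
      offtarget_free = .data$kmer %in% x$offtarget_free$kmer,
      pam_ok = .data$kmer %in% x$final$kmer
    )
}

#' @describeIn screen_y_kmers One-row summary with bin sizes and funnel
#'   counts.
#' @export
glance.ykmer_screen <- function(x, ...) {
  bins <- table(factor(x$binned$bin,
                       levels = c("Y", "autosomal", "X", "excluded")))
  tibble(
    n_long_reads = nrow(x$binned),
    n_y_bin = as.integer(bins[["Y"]]),
    n_a_bin = as.integer(bins[["autosomal"]]),
    n_x_bin = as.integer(bins[["X"]]),
    n_excluded = as.integer(bins[["excluded"]]),
    n_kmers = nrow(x$kmers),
    n_candidates = nrow(x$candidates),
    n_offtarget_free = nrow(x$offtarget_free),
    n_final = nrow(x$final),
    n_guides = nrow(x$guides)
  )
}

#' Write a k-mer screen to TSV
#'
#' Writes the flagged k-mer table of [tidy.ykmer_screen()] as
#' tab-separated values with a deterministic row order.
#'
#' @param x A `ykmer_screen`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
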