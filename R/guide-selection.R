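pam_to_regex <- function(pam) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T",
             R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
             K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
             H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(pam), "", fixed = TRUE)[[1]]
  if (!all(chars %in% names(iupac))) abort("invalid PAM pattern")
  paste(iupac[chars], collapse = "")
}

#' Scan a k-mer for SpCas9 protospacer/PAM placements
#'
#' Finds every placement of a PAM (default NGG) at either end of a k-mer
#' that leaves at least `min_protospacer` bases of protospacer immediately
#' 5' of it: on the plus strand an NGG in the 3'-terminal region with >=
#' `min_protospacer` bases before it, and on the minus strand a CCN in the
#' 5'-terminal region (an NGG on the reverse strand) with >=
#' `min_protospacer` bases after it. Protospacers are reported 5'->3' in
#' their own orientation and consist of all k-mer bases 5' of the PAM on
#' that strand. Placements are deduplicated and ordered plus strand first,
#' then minus, each left to right along the written k-mer.
#'
#' @param kmers Character vector of k-mers (A/C/G/T only).
#' @param min_protospacer Minimum protospacer length (default 20).
#' @param pam PAM pattern over the IUPAC alphabet (default `"NGG"`).
#' @return Tibble with `source_kmer`, `protospacer`, `pam`, `strand`
#'   (`"+"`/`"-"` relative to the k-mer as written), and `pam_end`
#'   (`"3'"`/`"5'"`: which end of the written k-mer holds the PAM).
#' @examples
#' scan_pam(paste0(strrep("A", 20), "TGGCC"))
#' @export
scan_pam <- function(kmers, min_protospacer = 20, pam = "NGG") {
  plen <- nchar(pam)
  pam_re <- pam_to_regex(pam)
  rc_re <- pam_to_regex(cpp_revcomp(pam))
  out <- vector("list", length(kmers))
  for (i in seq_along(kmers)) {
    kmer <- toupper(kmers[i])
    if (grepl("[^ACGT]", kmer)) {
      abort(paste0("k-mer contains a non-ACGT character: ", kmer))
    }
    n <- nchar(kmer)
    if (n < min_protospacer + plen) {
      abort("k-mer shorter than min_protospacer + PAM length")
    }
    rows <- list()
    # plus strand: PAM at positions p..p+plen-1 with >= min_protospacer
    # bases 5' of it
    for (p in seq_len(n - plen + 1)) {
      if (p - 1 < min_protospacer) next
      pam_seq <- substr(kmer, p, p + plen - 1)
      if (!grepl(paste0("^", pam_re, "$"), pam_seq)) next
      rows[[length(rows) + 1]] <- tibble(
        source_kmer = kmer,
        protospacer = substr(kmer, 1, p - 1),
        pam = pam_seq, strand = "+", pam_end = "3'"
      )
    }
    # minus strand: reverse-complement PAM (CCN for NGG) at the 5' end of
    # the written k-mer, protospacer 3' of it
    for (p in seq_len(n - plen + 1)) {
      if (n - (p + plen - 1) < min_protospacer) next
      site <- substr(kmer, p, p + plen - 1)
      if (!grepl(paste0("^", rc_re, "$"), site)) next
      rows[[length(rows) + 1]] <- tibble(
        source_kmer = kmer,
        protospacer = cpp_revcomp(substr(kmer, p + plen, n)),
        pam = cpp_revcomp(site), strand = "-", pam_end = "5'"
      )
    }
    out[[i]] <- if (length(rows)) bind_rows(rows) else NULL
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(source_kmer = character(), protospacer = character(),
                  pam = character(), strand = character(),
                  pam_end = character()))
  }
  dplyr::distinct(res)
}

#' Keep k-mers usable as SpCas9 guide targets
#'
#' Retains exactly the off-target-free k-mers with at least one
#' protospacer/PAM placement (see [scan_pam()]) and flags them `pam_ok`.
#' This is the final stage of the discovery funnel.
#'
#' @param offtarget_free Tibble from [filter_offtargets()] with a `kmer`
#'   column.
#' @inheritParams scan_pam
#' @return The PAM-bearing subset with `pam_ok` and `n_guides` columns.
#' @export
select_guides <- function(offtarget_free, min_protospacer = 20, pam = "NGG") {
  if (nrow(offtarget_free) == 0) {
    return(mutate(offtarget_free, pam_ok = logical(0), n_guides = integer(0)))
  }
  placements <- scan_pam(offtarget_free$kmer, min_protospacer, pam)
  counts <- placements %>%
    group_by(.data$source_kmer) %>%
    summarise(n_guides = n(), .groups = "drop")
  offtarget_free %>%
    left_join(counts, by = c(kmer = "source_kmer")) %>%
    filter(!is.na(.data$n_guides)) %>%
    mutate(pam_ok = TRUE)
}
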