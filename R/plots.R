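#' Abundance versus Chromosome Quotient of k-mers
#'
#' Scatter of log10 male short-read abundance ("sum") against k-mer CQ, the
#' standard diagnostic for a Y-specificity screen: Y-candidate k-mers sit in
#' the high-abundance, near-zero-CQ corner.
#'
#' @param kmers Flagged k-mer tibble (e.g. [tidy.ykmer_screen()] output).
#' @param cq_max Horizontal guide line at the candidate CQ threshold; `NULL`
#'   omits it.
#' @return A ggplot object.
#' @export
plot_kmer_cq <- function(kmers, cq_max = 0.3) {
  d <- kmers %>% filter(!is.na(.data$kmer_cq), .data$male_count > 0)
  flagged <- "y_candidate" %in% names(d)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$male_count),
                                       y = .data$kmer_cq)) +
    (if (flagged) {
      ggplot2::geom_point(ggplot2::aes(colour = .data$y_candidate),
                          alpha = 0.5, size = 0.8)
    } else {
      ggplot2::geom_point(alpha = 0.5, size = 0.8)
    }) +
    ggplot2::labs(x = "log10(sum) [male short-read count]",
                  y = "Chromosome Quotient (CQ)") +
    ggplot2::theme_bw()
  if (!is.null(cq_max)) {
    p <- p + ggplot2::geom_hline(yintercept = cq_max, linetype = "dashed")
  }
  p
}

#' Short-read abundance versus Y-bin long-read hits
#'
#' Scatter of log10 male abundance ("sum") against log10 Y-bin long-read
#' hits ("hits_sum") for candidate k-mers; PAM-bearing, off-target-free
#' k-mers are circled when flags are present.
#'
#' @param kmers Flagged k-mer tibble with `y_hits` (zero-hit k-mers are
#'   dropped).
#' @return A ggplot object.
#' @export
plot_kmer_hits <- function(kmers) {
  d <- kmers %>% filter(.data$y_hits > 0, .data$male_count > 0)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$male_count),
                                       y = log10(.data$y_hits))) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "log10(sum) [male short-read count]",
                  y = "log10(hits_sum) [Y-bin long-read hits]") +
    ggplot2::theme_bw()
  if (all(c("offtarget_free", "pam_ok") %in% names(d))) {
    sel <- d %>% filter(.data$offtarget_free, .data$pam_ok)
    if (nrow(sel) > 0) {
      p <- p + ggplot2::geom_point(data = sel, shape = 21, size = 2.5,
                                   colour = "red", fill = NA)
    }
  }
  p
}

#' CQ distribution of binned long reads
#'
#' Histogram of defined CQ values with the bin thresholds marked.
#'
#' @param binned Output of [bin_reads()].
#' @param thresholds A [bin_thresholds()].
#' @return A ggplot object.
#' @export
plot_cq_distribution <- function(binned, thresholds = bin_thresholds()) {
  d <- binned %>% filter(!is.na(.data$cq))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cq)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(
      xintercept = c(thresholds$ymax, thresholds$xmin, thresholds$xmax),
      linetype = "dashed"
    ) +
    ggplot2::labs(x = "Chromosome Quotient (CQ)", y = "long reads") +
    ggplot2::theme_bw()
}

#' @describeIn screen_y_kmers Diagnostic plots: `type = "cq"` for abundance
#'   vs CQ, `"hits"` for abundance vs Y-bin hits, `"bins"` for the read CQ
#'   histogram.
#' @param object A `ykmer_screen`.
#' @param type Plot type.
#' @export
autoplot.ykmer_screen <- function(object, type = c("cq", "hits", "bins"),
                                  ...) {
  type <- match.arg(type)
  switch(type,
    cq = plot_kmer_cq(tidy(object), cq_max = object$params$kmer_cq_max),
    hits = plot_kmer_hits(tidy(object)),
    bins = plot_cq_distribution(object$binned, object$params$thresholds)
  )
}

#' Sperm category proportions per group
#'
#' Bar plot of per-category median proportions with interquartile-range
#' error bars and the per-individual points overlaid.
#'
#' @param x A `sperm_summary` from [sperm_proportions()].
#' @return A ggplot object.
#' @export
plot_sperm_proportions <- function(x) {
  s <- x$summary %>%
    mutate(category = factor(.data$category, levels = sperm_categories))
  pts <- x$proportions %>%
    mutate(category = factor(.data$category, levels = sperm_categories))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$category, y = .data$median)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$iqr_low,
                                        ymax = .data$iqr_high), width = 0.25) +
    ggplot2::geom_jitter(data = pts,
                         ggplot2::aes(x = .data$category, y = .data$prop),
                         width = 0.1, size = 1, alpha = 0.7) +
    ggplot2::labs(x = "sperm category", y = "proportion per individual") +
    ggplot2::theme_bw()
}

#' @export
autoplot.sperm_summary <- function(object, ...) {
  plot_sperm_proportions(object)
}
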