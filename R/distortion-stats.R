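#' Hatching rate with insemination-based inclusion rules
#'
#' Scores each female's hatching rate (HR) as larvae hatched over eggs laid,
#' with the standard inclusion rules for individually ovipositing females:
#' a female that laid no eggs but was inseminated scores HR = 0; a female
#' whose eggs all failed to hatch and whose spermathecae held no sperm is
#' excluded (the failure is attributed to lack of insemination, not to the
#' male genotype), as is a female that neither laid nor was inseminated.
#'
#' @param data Tibble with columns `eggs_laid`, `larvae_hatched` and logical
#'   `inseminated` (one row per female).
#' @return `data` with columns `hr` (fraction in `[0, 1]`, `NA` when the
#'   female is excluded) and `hr_included` (logical) appended.
#' @examples
#' hatching_rate(tibble::tibble(
#'   eggs_laid = c(80, 0, 50), larvae_hatched = c(60, 0, 0),
#'   inseminated = c(TRUE, TRUE, FALSE)
#' ))
#' @export
hatching_rate <- function(data) {
  if (any(data$larvae_hatched > data$eggs_laid)) {
    abort("larvae_hatched cannot exceed eggs_laid")
  }
  if (any(data$eggs_laid < 0 | data$larvae_hatched < 0)) {
    abort("counts must be non-negative")
  }
  eggs <- data$eggs_laid
  larvae <- data$larvae_hatched
  insem <- data$inseminated
  hr <- rep(NA_real_, nrow(data))
  hr[eggs > 0] <- larvae[eggs > 0] / eggs[eggs > 0]
  hr[eggs == 0 & insem] <- 0
  # exclusions: laid non-hatching eggs without insemination; or neither
  hr[eggs > 0 & larvae == 0 & !insem] <- NA_real_
  hr[eggs == 0 & !insem] <- NA_real_
  data$hr <- hr
  data$hr_included <- !is.na(hr)
  data
}

#' Percentage of females among sexed progeny
#'
#' @param data Tibble with columns `progeny_females` and `progeny_males`.
#' @return `data` with a `pct_female` column: `100 * females / (females +
#'   males)`, `NA` (excluded from summaries) when no progeny were sexed.
#' @export
sex_ratio <- function(data) {
  tot <- data$progeny_females + data$progeny_males
  data$pct_female <- ifelse(tot > 0, 100 * data$progeny_females / tot,
                            NA_real_)
  data
}

sperm_categories <- c("X", "Y", "XY", "nSC")

#' Per-individual sperm genotype proportions and group summaries
#'
#' Sperm are FISH-scored into four sex-chromosome categories: X-bearing,
#' Y-bearing, both (X-Y non-disjunction) and neither (nSC). For a chosen
#' group and organ this computes each individual's category proportions and
#' summarises them across individuals (median, interquartile range, and SD —
#' published figures mix the two spreads, so both are reported), together
#' with the pooled per-category totals.
#'
#' @param data Tibble with columns `individual_id`, `organ`, `group` and the
#'   four count columns `X`, `Y`, `XY`, `nSC`.
#' @param group,organ Values selecting the rows to summarise; `NULL` keeps
#'   all rows.
#' @return A `sperm_summary`: list with `proportions` (long tibble:
#'   `individual_id`, `category`, `count`, `prop`), `summary` (per category:
#'   `median`, `iqr_low`, `iqr_high`, `sd`, `pooled_count`, `pooled_prop`),
#'   `n_individuals` and `total` (pooled grand total). Individuals with
#'   all-zero counts are dropped with a warning.
#' @export
sperm_proportions <- function(data, group = NULL, organ = NULL) {
  if (!all(sperm_categories %in% names(data))) {
    abort("data must have count columns X, Y, XY, nSC")
  }
  if (!is.null(group)) data <- data[data$group == group, , drop = FALSE]
  if (!is.null(organ)) data <- data[data$organ == organ, , drop = FALSE]
  if (nrow(data) == 0) abort("no individuals in the selected group/organ")
  counts <- as.matrix(data[, sperm_categories])
  if (any(counts < 0)) abort("sperm counts must be non-negative")
  rowtot <- rowSums(counts)
  if (any(rowtot == 0)) {
    warn(sprintf("dropping %d individual(s) with all-zero counts",
                 sum(rowtot == 0)))
    data <- data[rowtot > 0, , drop = FALSE]
    counts <- counts[rowtot > 0, , drop = FALSE]
    rowtot <- rowtot[rowtot > 0]
    if (nrow(data) == 0) abort("all individuals had zero counts")
  }
  props <- counts / rowtot
  proportions <- tibble(
    individual_id = rep(data$individual_id, times = length(sperm_categories)),
    category = rep(sperm_categories, each = nrow(data)),
    count = as.vector(counts),
    prop = as.vector(props)
  )
  summary <- tibble(
    category = sperm_categories,
    median = unname(apply(props, 2, median)),
    iqr_low = unname(apply(props, 2, quantile, probs = 0.25, names = FALSE)),
    iqr_high = unname(apply(props, 2, quantile, probs = 0.75, names = FALSE)),
    sd = unname(apply(props, 2,
                      function(v) if (length(v) > 1) sd(v) else NA_real_)),
    pooled_count = unname(colSums(counts)),
    pooled_prop = unname(colSums(counts) / sum(counts))
  )
  structure(list(
    proportions = proportions,
    summary = summary,
    n_individuals = nrow(data),
    total = sum(counts)
  ), class = "sperm_summary")
}

#' @export
print.sperm_summary <- function(x, ...) {
  cat(sprintf("<sperm_summary> %d individuals, %d sperm\n",
              x$n_individuals, x$total))
  print(x$summary)
  invisible(x)
}

#' @describeIn sperm_proportions Per-category summary tibble.
#' @param x A `sperm_summary`.
#' @param ... Unused.
#' @export
tidy.sperm_summary <- function(x, ...) x$summary

#' @describeIn sperm_proportions One-row overview (individuals, pooled
#'   total).
#' @export
glance.sperm_summary <- function(x, ...) {
  tibble(n_individuals = x$n_individuals, total_sperm = x$total)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. With both group sizes at most
#' `exact_max_n` the null distribution of U is enumerated exhaustively over
#' all assignments of the pooled observations (exact even with ties) and the
#' two-sided p-value is twice the smaller tail, capped at 1; for larger
#' groups the tie-corrected normal approximation (without continuity
#' correction) is used.
#'
#' @param x,y Numeric samples.
#' @param exact_max_n Enumerate exactly when `max(n1, n2) <= exact_max_n`
#'   (default 8).
#' @return An `mw_test`: list with `statistic` (U for sample `x`), `n1`,
#'   `n2`, `p_value`, `method`. Has [tidy()] and [glance()] methods.
#' @export
mann_whitney <- function(x, y, exact_max_n = 8) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both samples must be non-empty")
  u_stat <- function(a, b) {
    sum(vapply(a, function(v) sum(v > b) + 0.5 * sum(v == b), numeric(1)))
  }
  u <- u_stat(x, y)
  if (max(n1, n2) <= exact_max_n) {
    pooled <- c(x, y)
    combos <- utils::combn(n1 + n2, n1)
    us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
    p <- min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
    method <- "exact"
  } else {
    pooled <- c(x, y)
    N <- n1 + n2
    ties <- table(pooled)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal approximation (tie-corrected)"
  }
  structure(list(statistic = u, n1 = n1, n2 = n2, p_value = p,
                 method = method), class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$statistic, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' @describeIn mann_whitney One-row tibble of the test result.
#' @param x An `mw_test`.
#' @param ... Unused.
#' @export
tidy.mw_test <- function(x, ...) {
  tibble(statistic = x$statistic, n1 = x$n1, n2 = x$n2,
         p_value = x$p_value, method = x$method)
}

#' @describeIn mann_whitney Alias of [tidy.mw_test()].
#' @export
glance.mw_test <- function(x, ...) tidy(x)

#' Compare a sperm category between testes and spermathecae
#'
#' Tests whether the per-individual proportion of one sperm category differs
#' between the two organs within a group, by a two-sided Mann-Whitney test
#' on the per-individual proportions (exact for the small group sizes
#' typical of these experiments).
#'
#' @inheritParams sperm_proportions
#' @param group Group label to compare within.
#' @param category One of `"X"`, `"Y"`, `"XY"`, `"nSC"`.
#' @param organs Length-2 character vector naming the organ levels to
#'   compare (first vs second).
#' @inheritParams mann_whitney
#' @return An `mw_test` (see [mann_whitney()]).
#' @export
compare_organs <- function(data, group, category,
                           organs = c("testis", "spermatheca"),
                           exact_max_n = 8) {
  if (!category %in% sperm_categories) {
    abort("category must be one of X, Y, XY, nSC")
  }
  prop_of <- function(organ) {
    s <- sperm_proportions(data, group = group, organ = organ)
    s$proportions$prop[s$proportions$category == category]
  }
  mann_whitney(prop_of(organs[1]), prop_of(organs[2]),
               exact_max_n = exact_max_n)
}

#' Read a phenotype table
#'
#' Reads a TSV of per-female phenotype records with columns `female_id`,
#' `group`, `eggs_laid`, `larvae_hatched`, `inseminated`,
#' `progeny_females`, `progeny_males`.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_phenotype_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a sperm count table
#'
#' Reads a TSV of per-individual sperm counts with columns `individual_id`,
#' `organ`, `group`, `X`, `Y`, `XY`, `nSC`.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_sperm_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
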