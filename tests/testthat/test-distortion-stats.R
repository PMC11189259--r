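test_that("hatching rate applies the insemination-based inclusion rules", {
  d <- tibble::tibble(
    eggs_laid = c(80, 0, 50, 0, 40),
    larvae_hatched = c(60, 0, 0, 0, 0),
    inseminated = c(TRUE, TRUE, FALSE, FALSE, TRUE)
  )
  out <- hatching_rate(d)
  expect_equal(out$hr, c(0.75, 0, NA, NA, 0))
  expect_identical(out$hr_included, c(TRUE, TRUE, FALSE, FALSE, TRUE))

  # scale invariance of the scored rate
  scaled <- hatching_rate(tibble::tibble(eggs_laid = 800,
                                         larvae_hatched = 600,
                                         inseminated = TRUE))
  expect_equal(scaled$hr, 0.75)

  expect_error(hatching_rate(tibble::tibble(eggs_laid = 10,
                                            larvae_hatched = 11,
                                            inseminated = TRUE)),
               "exceed")
})

test_that("progeny sex ratio is the percentage of females among sexed pupae", {
  d <- tibble::tibble(progeny_females = c(50, 99, 0),
                      progeny_males = c(50, 1, 0))
  out <- sex_ratio(d)
  expect_equal(out$pct_female, c(50, 99, NA))
})

test_that("sperm summaries conserve counts and reproduce published totals", {
  path <- system.file("extdata", "sperm_counts_pooled.tsv", package = "ykmer")
  pooled <- read_sperm_counts(path)
  pooled$individual_id <- paste(pooled$group, pooled$organ)

  wt_te <- sperm_proportions(pooled, group = "WT", organ = "testis")
  expect_equal(wt_te$total, 1457)
  expect_equal(sum(wt_te$summary$pooled_count), 1457)
  expect_equal(wt_te$summary$pooled_prop[wt_te$summary$category == "X"],
               760 / 1457)
  wt_sp <- sperm_proportions(pooled, group = "WT", organ = "spermatheca")
  expect_equal(wt_sp$total, 804)

  # single individual: median equals that individual's proportions
  expect_equal(wt_te$summary$median, wt_te$summary$pooled_prop)

  # per-individual proportions sum to 1; pooled totals are column sums
  withr::with_seed(83, {
    many <- tibble::tibble(
      individual_id = sprintf("i%d", 1:6),
      organ = rep(c("testis", "spermatheca"), each = 3),
      group = "G",
      X = rpois(6, 50), Y = rpois(6, 40), XY = rpois(6, 5),
      nSC = rpois(6, 3)
    )
  })
  s <- sperm_proportions(many, group = "G", organ = "testis")
  sums <- tapply(s$proportions$prop, s$proportions$individual_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(unname(s$summary$pooled_count),
               unname(colSums(as.matrix(many[many$organ == "testis",
                                             c("X", "Y", "XY", "nSC")]))))

  zero <- dplyr::bind_rows(many, tibble::tibble(
    individual_id = "z", organ = "testis", group = "G",
    X = 0, Y = 0, XY = 0, nSC = 0
  ))
  expect_warning(sperm_proportions(zero, group = "G", organ = "testis"),
                 "all-zero")
  expect_error(sperm_proportions(many, group = "absent"), "no individuals")
})

test_that("exact Mann-Whitney matches enumeration and known results", {
  # complete separation at n1 = n2 = 3: two-sided exact p = 2/20
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_identical(res$method, "exact")

  # identical samples: no separation, p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # enumeration oracle for all n1, n2 <= 5, with and without ties
  withr::with_seed(89, {
    for (n1 in 1:5) {
      for (n2 in 1:5) {
        x <- sample(1:6, n1, replace = TRUE) # discrete: ties likely
        y <- sample(1:6, n2, replace = TRUE)
        expect_equal(mann_whitney(x, y)$p_value, oracle_mw_p(x, y),
                     info = sprintf("n1=%d n2=%d", n1, n2))
        xc <- rnorm(n1) # continuous: cross-check wilcox.test exact path
        yc <- rnorm(n2)
        expect_equal(mann_whitney(xc, yc)$p_value,
                     wilcox.test(xc, yc, exact = TRUE)$p.value,
                     tolerance = 1e-12)
      }
    }
  })

  # large samples: tie-corrected normal approximation
  withr::with_seed(97, {
    x <- round(rnorm(20, 0, 2), 1)
    y <- round(rnorm(25, 1, 2), 1)
  })
  res <- mann_whitney(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  expect_match(res$method, "normal")
})

test_that("organ comparison tests per-individual category proportions", {
  d <- tibble::tibble(
    individual_id = sprintf("i%d", 1:6),
    organ = rep(c("testis", "spermatheca"), each = 3),
    group = "G",
    X = c(10, 12, 11, 40, 42, 45),
    Y = c(10, 9, 12, 40, 45, 41),
    XY = c(75, 80, 70, 15, 10, 12),
    nSC = c(5, 4, 6, 5, 3, 2)
  )
  res <- compare_organs(d, group = "G", category = "XY")
  # complete separation of XY proportions across organs at 3 vs 3
  expect_equal(res$p_value, 0.1)
  expect_equal(tidy(res)$n1, 3)
  expect_error(compare_organs(d, group = "G", category = "Z"), "category")
  expect_error(compare_organs(d, group = "H", category = "X"),
               "no individuals")
})
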