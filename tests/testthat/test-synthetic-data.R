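test_that("zero divergence plants an exact tandem array on Y", {
  cfg <- sim_config(
    chrom_lengths = c(A1 = 4000, A2 = 4000, X = 3000, Y = 8000),
    satellites = tibble::tibble(family = "satY", monomer_len = 53,
                                copies = 100, divergence = 0),
    shared_repeat_fraction = 0, junction_len = 0, seed = 3
  )
  g <- build_genome(cfg)
  ann <- dplyr::filter(g$repeats, family == "satY")
  expect_equal(ann$end - ann$start + 1, 53 * 100)
  y_seq <- g$chromosomes$seq[g$chromosomes$chrom == "Y"]
  array <- substr(y_seq, ann$start, ann$end)
  expect_identical(array, strrep(ann$monomer, 100))
})

test_that("genome construction is deterministic and validates sizing", {
  cfg <- sim_config(chrom_lengths = c(A1 = 3000, A2 = 3000, X = 2500,
                                      Y = 2000),
                    satellites = tibble::tibble(family = "satY",
                      monomer_len = 53, copies = 10, divergence = 0.02),
                    junction_len = 30, seed = 11)
  g1 <- build_genome(cfg)
  g2 <- build_genome(cfg)
  expect_identical(g1$chromosomes$seq, g2$chromosomes$seq)
  expect_identical(g1$repeats, g2$repeats)

  too_small <- sim_config(chrom_lengths = c(A1 = 3000, A2 = 3000, X = 2500,
                                            Y = 400),
                          satellites = tibble::tibble(family = "satY",
                            monomer_len = 53, copies = 10, divergence = 0),
                          junction_len = 0, seed = 1)
  expect_error(build_genome(too_small), "cannot hold")
})

test_that("the junction element is a verbatim Y-satellite substring on X", {
  cfg <- sim_config(chrom_lengths = c(A1 = 3000, A2 = 3000, X = 2500,
                                      Y = 2000),
                    satellites = tibble::tibble(family = "satY",
                      monomer_len = 53, copies = 10, divergence = 0),
                    junction_len = 30, seed = 5)
  g <- build_genome(cfg)
  jx <- dplyr::filter(g$repeats, family == "junction")
  expect_equal(nrow(jx), 1)
  x_seq <- g$chromosomes$seq[g$chromosomes$chrom == "X"]
  y_seq <- g$chromosomes$seq[g$chromosomes$chrom == "Y"]
  junction <- substr(x_seq, jx$start, jx$end)
  expect_equal(nchar(junction), 30)
  # with zero divergence a 30-bp array slice lies within the monomer region
  expect_true(grepl(junction, y_seq, fixed = TRUE))
})

test_that("truth_y_kmers matches brute-force enumeration and edge cases", {
  # toy chromosomes: poly-T Y against an unrelated autosome
  toy <- structure(list(chromosomes = tibble::tibble(
    chrom = c("A1", "A2", "X", "Y"),
    seq = c("ACGTACGTACGT", "ACGTACGTACGT", "ACGTACGTACGT", "TTTTTTTT"),
    length = c(12L, 12L, 12L, 8L)
  )), class = "genome_model")
  truth <- truth_y_kmers(toy, k = 4)
  expect_true(oracle_canonical("TTTT") %in% truth)

  # Y identical to an autosome: nothing is Y-private
  dup <- toy
  dup$chromosomes$seq[4] <- dup$chromosomes$seq[1]
  dup$chromosomes$length[4] <- dup$chromosomes$length[1]
  expect_length(truth_y_kmers(dup, k = 4), 0)

  # brute-force oracle on a generated genome; junction k-mers excluded
  sim <- tiny_simulation(seed = 17)
  g <- sim$genome
  k <- 13
  y_seq <- g$chromosomes$seq[g$chromosomes$chrom == "Y"]
  other <- g$chromosomes$seq[g$chromosomes$chrom != "Y"]
  expected <- sort(setdiff(oracle_kmer_counts(y_seq, k)$kmer,
                           oracle_kmer_counts(other, k)$kmer))
  expect_identical(truth_y_kmers(g, k = k), expected)

  jx <- dplyr::filter(g$repeats, family == "junction")
  x_seq <- g$chromosomes$seq[g$chromosomes$chrom == "X"]
  junction <- substr(x_seq, jx$start, jx$end)
  junction_kmers <- oracle_kmer_counts(junction, k)$kmer
  expect_length(intersect(junction_kmers, truth_y_kmers(g, k = k)), 0)
})

test_that("long-read simulation respects sex, determinism and preconditions", {
  sim <- tiny_simulation(seed = 23)
  expect_error(simulate_long_reads(sim$genome, "male", 0, sim$cfg),
               "n_reads")
  expect_error(simulate_long_reads(sim$genome, "hermaphrodite", 5, sim$cfg),
               "ploidy")

  female <- simulate_long_reads(sim$genome, "female", 200, sim$cfg)
  expect_false(any(female$chrom == "Y"))

  again <- simulate_long_reads(sim$genome, "male", 40, sim$cfg)
  expect_identical(sim$long, again)

  # error-free reads are substrings of their chromosome (either strand)
  chroms <- setNames(sim$genome$chromosomes$seq, sim$genome$chromosomes$chrom)
  ok <- vapply(seq_len(nrow(sim$long)), function(i) {
    s <- sim$long$seq[i]
    grepl(s, chroms[[sim$long$chrom[i]]], fixed = TRUE) ||
      grepl(oracle_revcomp(s), chroms[[sim$long$chrom[i]]], fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
})

test_that("short-read simulation hits the requested depth and dosage", {
  sim <- tiny_simulation(seed = 29, depth = 20)
  cfg <- sim$cfg
  g <- sim$genome
  L <- cfg$short_read_len
  for (sex in c("male", "female")) {
    ploidy <- g$ploidy[[sex]]
    G <- sum(ploidy[g$chromosomes$chrom] * g$chromosomes$length)
    reads <- simulate_short_reads(g, sex, depth = 20, config = cfg)
    expect_lt(abs(nrow(reads) - 20 * G / L), 0.1 * 20 * G / L)
    expect_true(all(nchar(reads$seq) == L))
  }
  m <- simulate_short_reads(g, "male", depth = 20, config = cfg)
  f <- simulate_short_reads(g, "female", depth = 20, config = cfg)
  # ploidy dosage at equal depth: X 2:1 female:male, autosomes 1:1, Y absent
  expect_equal(sum(f$chrom == "X") / sum(m$chrom == "X"), 2, tolerance = 0.1)
  expect_equal(sum(f$chrom %in% c("A1", "A2")) /
                 sum(m$chrom %in% c("A1", "A2")), 1, tolerance = 0.1)
  expect_equal(sum(f$chrom == "Y"), 0)

  expect_identical(m, simulate_short_reads(g, "male", depth = 20,
                                           config = cfg))
  long_read_cfg <- cfg
  long_read_cfg$short_read_len <- 5000
  expect_error(simulate_short_reads(g, "male", depth = 5,
                                    config = long_read_cfg),
               "shortest chromosome")
})
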