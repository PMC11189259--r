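test_that("k-mer extraction counts canonical windows and skips non-ACGT", {
  expect_equal(nrow(extract_kmers(tibble::tibble(read_id = "r", seq = "ACG"),
                                  k = 4)), 0)
  counts <- extract_kmers("ACGTNACGT", k = 4)
  expect_identical(counts$kmer, "ACGT")
  expect_equal(counts$count, 2) # windows spanning the N are skipped

  # conservation: total counts equal the number of valid windows
  withr::with_seed(311, reads <- vapply(rep(200, 20), random_dna,
                                        character(1)))
  counts <- extract_kmers(reads, k = 25)
  expect_equal(sum(counts$count), 20 * (200 - 25 + 1))

  # brute-force sliding-window oracle
  expect_equal(as.data.frame(counts),
               as.data.frame(oracle_kmer_counts(reads, 25)))
})

test_that("canonicalization is an involution under reverse complement", {
  withr::with_seed(313, kmers <- vapply(rep(25, 200), random_dna,
                                        character(1)))
  expect_identical(canonical_kmer(revcomp(kmers)), canonical_kmer(kmers))
  expect_identical(canonical_kmer(kmers), oracle_canonical(kmers))
})

test_that("sex profiles reproduce hand-computed CQ ratios", {
  male <- tibble::tibble(kmer = c("AAAA", "AACC", "ACAC", "AGGG", "ATAT"),
                         count = c(100, 40, 20, 5, 0))
  female <- tibble::tibble(kmer = c("AAAA", "AACC", "ACAC", "AGGG", "CCCC"),
                           count = c(0, 80, 20, 50, 30))
  prof <- kmer_sex_profile(male, female, male_total = 1000,
                           female_total = 2000, m_min = 10)
  prof <- tibble::deframe(prof[, c("kmer", "kmer_cq")])
  expect_equal(prof[["AAAA"]], 0) # the Y signature
  expect_equal(prof[["AACC"]], (80 / 2000) / (40 / 1000)) # = 1
  expect_equal(prof[["ACAC"]], (20 / 2000) / (20 / 1000)) # = 0.5
  expect_true(is.na(prof[["AGGG"]])) # below m_min
  expect_true(is.na(prof[["CCCC"]])) # absent from males
})

test_that("bin allocation counts distinct long reads on both strands", {
  y_kmer <- canonical_kmer("ACGTTGCAGGTCAATGCCTAGGTAC")
  reads <- tibble::tibble(
    read_id = c("y1", "y2", "a1", "x1"),
    seq = c(paste0(random_dna(40), y_kmer, random_dna(30), y_kmer),
            paste0(random_dna(10), oracle_revcomp(y_kmer), random_dna(10)),
            random_dna(120),
            random_dna(120)),
    bin = c("Y", "Y", "autosomal", "X")
  )
  km <- tibble::tibble(kmer = y_kmer)
  hits <- map_kmers_to_bins(km, reads)
  expect_equal(hits$y_hits, 2) # distinct reads, not the 3 occurrences
  expect_equal(hits$a_hits, 0)
  expect_equal(hits$x_hits, 0)
  occ <- map_kmers_to_bins(km, reads, occurrences = TRUE)
  expect_equal(occ$y_hits, 3)

  # brute-force substring oracle over a 10-read toy set
  withr::with_seed(317, {
    toy <- tibble::tibble(
      read_id = sprintf("r%d", 1:10),
      seq = vapply(rep(120, 10), random_dna, character(1)),
      bin = rep(c("Y", "autosomal", "X", "excluded", "Y"), 2)
    )
    kmers <- tibble::tibble(kmer = unique(canonical_kmer(
      c(vapply(rep(15, 5), random_dna, character(1)),
        substr(toy$seq[1], 11, 25), substr(toy$seq[3], 50, 64))
    )))
  })
  got <- map_kmers_to_bins(kmers, toy)
  rc <- oracle_revcomp(kmers$kmer)
  for (i in seq_len(nrow(kmers))) {
    contains <- grepl(kmers$kmer[i], toy$seq, fixed = TRUE) |
      grepl(rc[i], toy$seq, fixed = TRUE)
    expect_equal(got$y_hits[i], sum(contains & toy$bin == "Y"))
    expect_equal(got$a_hits[i], sum(contains & toy$bin == "autosomal"))
    expect_equal(got$x_hits[i], sum(contains & toy$bin == "X"))
  }
})

test_that("candidate selection and off-target filtering apply the stated rules", {
  records <- tibble::tibble(
    kmer = c("AAAA", "CCCC", "GGAA", "TTAA", "ACGT"),
    male_count = c(50, 40, 30, 5, 20),
    female_count = c(0, 0, 0, 0, 40),
    kmer_cq = c(0, 0, 0.1, 0, 2),
    y_hits = c(5, 1, 3, 4, 2),
    a_hits = c(0, 0, 1, 0, 0),
    x_hits = c(0, 0, 0, 0, 3)
  )
  cand <- select_y_candidates(records, kmer_cq_max = 0.3,
                              min_abundance = 10, min_y_hits = 2)
  # CCCC fails min_y_hits, TTAA fails abundance, ACGT fails CQ
  expect_identical(cand$kmer, c("AAAA", "GGAA")) # sorted by male_count
  expect_true(all(cand$y_candidate))

  off <- filter_offtargets(cand)
  expect_identical(off$kmer, "AAAA") # GGAA has an autosomal off-target
  expect_true(all(off$offtarget_free))

  expect_equal(nrow(select_y_candidates(records, min_abundance = 1000)), 0)
})

test_that("the screen recovers planted Y k-mers on a small genome", {
  sim <- tiny_simulation(seed = 401, depth = 20, n_long = 120)
  scr <- suppressMessages(screen_y_kmers(
    sim$long, sim$short_f, sim$short_m,
    k = 21, m_min = 5, min_abundance = 8, min_y_hits = 2,
    min_protospacer = 15, min_len = 300
  ))
  truth <- truth_y_kmers(sim$genome, k = 21)
  truth_ab <- intersect(truth,
                        scr$kmers$kmer[scr$kmers$male_count >= 8])
  got <- scr$offtarget_free$kmer
  expect_true(all(got %in% truth_ab)) # precision 1
  expect_gte(mean(truth_ab %in% got), 0.99)

  # funnel monotonicity and flag consistency
  expect_true(all(scr$offtarget_free$kmer %in% scr$candidates$kmer))
  expect_true(all(scr$final$kmer %in% scr$offtarget_free$kmer))
  flags <- tidy(scr)
  expect_true(all(flags$pam_ok <= flags$offtarget_free))
  expect_true(all(flags$offtarget_free <= flags$y_candidate))
  g <- glance(scr)
  expect_lte(g$n_final, g$n_offtarget_free)
  expect_lte(g$n_offtarget_free, g$n_candidates)
})
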