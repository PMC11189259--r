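# Brute-force reference implementations, deliberately independent of the
# package's kernels: string handling goes through Biostrings and base R.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

oracle_canonical <- function(x) {
  rc <- oracle_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# sliding-window canonical k-mer counts over a set of reads
oracle_kmer_counts <- function(seqs, k) {
  wins <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  wins <- wins[!grepl("[^ACGT]", wins)]
  if (length(wins) == 0) {
    return(tibble::tibble(kmer = character(), count = numeric()))
  }
  tab <- table(oracle_canonical(wins))
  tibble::tibble(kmer = names(tab), count = as.numeric(tab)) |>
    dplyr::arrange(kmer)
}

# per-long-read substring-containment hit counts (either strand)
oracle_containment_hits <- function(long_seqs, short_seqs) {
  rc <- oracle_revcomp(short_seqs)
  vapply(long_seqs, function(L) {
    sum(vapply(seq_along(short_seqs), function(i) {
      grepl(short_seqs[i], L, fixed = TRUE) || grepl(rc[i], L, fixed = TRUE)
    }, logical(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

# all protospacer/PAM placements of NGG at either terminus, via regex search
oracle_pam_scan <- function(kmer, min_proto = 20) {
  n <- nchar(kmer)
  rows <- list()
  gg <- gregexpr("(?=GG)", kmer, perl = TRUE)[[1]]
  if (gg[1] != -1) {
    for (q in as.integer(gg)) { # GG at q..q+1, PAM = (q-1)..(q+1)
      p <- q - 1
      if (p >= 1 && p - 1 >= min_proto) {
        rows[[length(rows) + 1]] <- data.frame(
          protospacer = substr(kmer, 1, p - 1),
          pam = substr(kmer, p, p + 2), strand = "+", pam_end = "3'"
        )
      }
    }
  }
  cc <- gregexpr("(?=CC)", kmer, perl = TRUE)[[1]]
  if (cc[1] != -1) {
    for (q in as.integer(cc)) { # CCN at q..q+2
      if (q + 2 <= n && n - (q + 2) >= min_proto) {
        rows[[length(rows) + 1]] <- data.frame(
          protospacer = oracle_revcomp(substr(kmer, q + 3, n)),
          pam = oracle_revcomp(substr(kmer, q, q + 2)),
          strand = "-", pam_end = "5'"
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(protospacer = character(), pam = character(),
                      strand = character(), pam_end = character()))
  }
  unique(do.call(rbind, rows))
}

# exact two-sided Mann-Whitney p-value via the rank-sum formula, enumerating
# all assignments of pooled ranks
oracle_mw_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# small genome + read sets for fast pipeline-level tests
tiny_simulation <- function(seed, depth = 10, n_long = 40) {
  cfg <- sim_config(
    chrom_lengths = c(A1 = 2500, A2 = 2500, X = 2000, Y = 1500),
    satellites = tibble::tibble(family = "satY", monomer_len = 53,
                                copies = 10, divergence = 0.02),
    shared_repeat_fraction = 0.02,
    junction_len = 30,
    long_read_range = c(300, 3000),
    short_read_len = 60,
    depth = depth,
    seed = seed
  )
  genome <- build_genome(cfg)
  list(
    cfg = cfg,
    genome = genome,
    long = simulate_long_reads(genome, "male", n_long, cfg),
    short_m = simulate_short_reads(genome, "male", config = cfg),
    short_f = simulate_short_reads(genome, "female", config = cfg)
  )
}
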