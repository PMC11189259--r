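#' Simulation settings for synthetic sex-chromosome genomes
#'
#' Bundles the parameters of the synthetic genome and read generator. The
#' defaults describe a compact mosquito-like test genome: two autosomes, an
#' X, and a Y carrying a private tandem satellite family (53-bp monomer,
#' 500 copies, 2% per-copy divergence, in the style of the AgY53 satellite
#' families), transposon-like repeats shared by the autosomes and the X, and
#' a short "junction" element copied verbatim from the Y satellite array
#' onto the X — the decoy that the off-target filter must reject. Short-read
#' depth defaults to 20x per sex, the minimum coverage the binning statistic
#' is designed for.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp;
#'   names must be `A1`, `A2`, `X`, `Y`.
#' @param satellites Data frame of Y-private satellite families with columns
#'   `family`, `monomer_len` (bp), `copies`, `divergence` (per-base
#'   substitution rate applied independently to each monomer copy).
#' @param shared_repeat_fraction Fraction of each non-Y chromosome occupied
#'   by a shared transposon-like repeat (500-bp element, copies diverged at
#'   `shared_repeat_divergence`).
#' @param shared_repeat_divergence Per-copy substitution rate of the shared
#'   repeat.
#' @param junction_len Length in bp of the Y-satellite-derived element
#'   copied verbatim onto X (0 disables it).
#' @param long_read_range Two-element vector: long-read lengths are drawn
#'   log-uniformly over this range (bp) before truncation at chromosome
#'   ends.
#' @param long_error,short_error Per-base substitution error rates of the
#'   simulated long and short reads.
#' @param short_read_len Short-read length in bp.
#' @param depth Target short-read depth per sex (fold coverage of the
#'   ploidy-weighted genome).
#' @param seed Integer seed; all generator functions are deterministic given
#'   the config.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(chrom_lengths = c(A1 = 150000, A2 = 150000,
                                         X = 120000, Y = 60000),
                       satellites = tibble(
                         family = "satY",
                         monomer_len = 53,
                         copies = 500,
                         divergence = 0.02
                       ),
                       shared_repeat_fraction = 0.02,
                       shared_repeat_divergence = 0.02,
                       junction_len = 120,
                       long_read_range = c(1000, 100000),
                       long_error = 0,
                       short_error = 0,
                       short_read_len = 100,
                       depth = 20,
                       seed = 1L) {
  cfg <- list(
    chrom_lengths = chrom_lengths,
    satellites = as_tibble(satellites),
    shared_repeat_fraction = shared_repeat_fraction,
    shared_repeat_divergence = shared_repeat_divergence,
    junction_len = junction_len,
    long_read_range = long_read_range,
    long_error = long_error,
    short_error = short_error,
    short_read_len = short_read_len,
    depth = depth,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  req <- c("A1", "A2", "X", "Y")
  if (!all(req %in% names(cfg$chrom_lengths))) {
    abort("chrom_lengths must name A1, A2, X and Y")
  }
  if (any(cfg$chrom_lengths <= 0)) abort("chromosome lengths must be positive")
  if (cfg$depth <= 0) abort("depth must be > 0")
  if (cfg$long_error < 0 || cfg$long_error >= 1 ||
      cfg$short_error < 0 || cfg$short_error >= 1) {
    abort("error rates must lie in [0, 1)")
  }
  if (cfg$long_read_range[1] >= cfg$long_read_range[2]) {
    abort("long_read_range must satisfy min_len < max_len")
  }
  if (any(cfg$satellites$divergence < 0 | cfg$satellites$divergence > 1)) {
    abort("satellite divergence must lie in [0, 1]")
  }
  invisible(cfg)
}

random_seq <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent per-base substitutions at the given rate; each mutated base is
# replaced by one of the three other bases uniformly.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  n_mut <- rbinom(1, n, rate)
  if (n_mut == 0) return(seq)
  pos <- sample.int(n, n_mut)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

apply_read_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, mutate_seq, character(1), rate = rate, USE.NAMES = FALSE)
}

# Lay `elements` (in order) along a chromosome of total length `len`,
# separated by random-sequence gaps. Returns the sequence and the 1-based
# inclusive start/end of each element.
assemble_chromosome <- function(len, elements) {
  planted <- sum(nchar(unlist(elements)))
  if (planted > len) {
    abort(sprintf("chromosome of %d bp cannot hold %d bp of planted repeats",
                  len, planted))
  }
  k <- length(elements) + 1
  gaps <- as.vector(stats::rmultinom(1, len - planted, rep(1 / k, k)))
  pieces <- character(2 * length(elements) + 1)
  starts <- ends <- integer(length(elements))
  pos <- 0L
  j <- 1L
  for (i in seq_along(elements)) {
    g <- random_seq(gaps[i])
    pieces[j] <- g
    pos <- pos + gaps[i]
    starts[i] <- pos + 1L
    pieces[j + 1] <- elements[[i]]
    pos <- pos + nchar(elements[[i]])
    ends[i] <- pos
    j <- j + 2L
  }
  pieces[j] <- random_seq(gaps[k])
  list(seq = paste(pieces, collapse = ""), starts = starts, ends = ends)
}

#' Build a synthetic genome with planted sex-linked repeats
#'
#' Constructs chromosomes A1, A2, X and Y. Each configured satellite family
#' is planted on Y as a head-to-tail tandem array whose copies are mutated
#' independently at the family's divergence rate. A shared transposon-like
#' repeat is planted on A1, A2 and X, and a junction element — a verbatim
#' slice of the planted Y satellite array — is copied onto X, so that k-mers
#' spanning it are present on both sex chromosomes. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `genome_model`: list with `chromosomes` (tibble `chrom`, `seq`,
#'   `length`), `repeats` (tibble `family`, `chrom`, `start`, `end`,
#'   `monomer`, `copies`; coordinates 1-based inclusive), and `ploidy`
#'   (named copy-number vectors for `male` and `female`).
#' @examples
#' cfg <- sim_config(chrom_lengths = c(A1 = 5000, A2 = 5000, X = 4000, Y = 3000),
#'                   satellites = tibble::tibble(family = "satY",
#'                     monomer_len = 53, copies = 20, divergence = 0),
#'                   junction_len = 30, seed = 7)
#' g <- build_genome(cfg)
#' g$repeats
#' @export
build_genome <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    lens <- config$chrom_lengths
    reps <- list()

    # Y: one tandem array per satellite family
    arrays <- list()
    monomers <- character(nrow(config$satellites))
    for (i in seq_len(nrow(config$satellites))) {
      fam <- config$satellites[i, ]
      monomers[i] <- random_seq(fam$monomer_len)
      copies <- vapply(seq_len(fam$copies), function(j) {
        mutate_seq(monomers[i], fam$divergence)
      }, character(1))
      arrays[[i]] <- paste(copies, collapse = "")
    }
    y <- assemble_chromosome(lens[["Y"]], arrays)
    for (i in seq_len(nrow(config$satellites))) {
      reps[[length(reps) + 1]] <- tibble(
        family = config$satellites$family[i], chrom = "Y",
        start = y$starts[i], end = y$ends[i],
        monomer = monomers[i], copies = config$satellites$copies[i]
      )
    }

    # junction element: verbatim slice of the first Y satellite array
    junction <- NULL
    if (config$junction_len > 0) {
      if (length(arrays) == 0 || nchar(arrays[[1]]) < config$junction_len) {
        abort("junction_len exceeds the planted Y satellite array")
      }
      junction <- substr(y$seq, y$starts[1], y$starts[1] + config$junction_len - 1)
    }

    # shared transposon-like repeat on A1, A2 and X
    te_len <- 500L
    te_monomer <- if (config$shared_repeat_fraction > 0) random_seq(te_len) else NULL
    shared <- list()
    for (chrom in c("A1", "A2", "X")) {
      elements <- list()
      fams <- character()
      if (!is.null(te_monomer)) {
        n_copies <- max(1L, round(config$shared_repeat_fraction *
                                    lens[[chrom]] / te_len))
        for (j in seq_len(n_copies)) {
          elements[[length(elements) + 1]] <-
            mutate_seq(te_monomer, config$shared_repeat_divergence)
          fams <- c(fams, "sharedTE")
        }
      }
      if (chrom == "X" && !is.null(junction)) {
        elements[[length(elements) + 1]] <- junction
        fams <- c(fams, "junction")
      }
      asm <- assemble_chromosome(lens[[chrom]], elements)
      shared[[chrom]] <- asm$seq
      if (length(elements) > 0) {
        monomer_of <- ifelse(fams == "junction", junction, te_monomer)
        reps[[length(reps) + 1]] <- tibble(
          family = fams, chrom = chrom,
          start = asm$starts, end = asm$ends,
          monomer = monomer_of, copies = 1L
        )
      }
    }

    chromosomes <- tibble(
      chrom = c("A1", "A2", "X", "Y"),
      seq = c(shared[["A1"]], shared[["A2"]], shared[["X"]], y$seq)
    )
    chromosomes$length <- nchar(chromosomes$seq)

    structure(list(
      chromosomes = chromosomes,
      repeats = bind_rows(reps),
      ploidy = list(
        male = c(A1 = 2, A2 = 2, X = 1, Y = 1),
        female = c(A1 = 2, A2 = 2, X = 2, Y = 0)
      ),
      config = config
    ), class = "genome_model")
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model>\n")
  cat(sprintf("  chromosomes: %s (total %d bp)\n",
              paste(sprintf("%s=%d", x$chromosomes$chrom,
                            x$chromosomes$length), collapse = ", "),
              sum(x$chromosomes$length)))
  cat(sprintf("  planted repeats: %d intervals (%s)\n", nrow(x$repeats),
              paste(unique(x$repeats$family), collapse = ", ")))
  invisible(x)
}

#' Ground-truth Y-private k-mers
#'
#' Enumerates every canonical k-mer present on the Y chromosome and absent,
#' on both strands, from all other chromosomes. Junction-element k-mers
#' (shared with X by construction) are therefore excluded. This is the truth
#' set that a Y-specificity screen should recover.
#'
#' @param genome A `genome_model` from [build_genome()].
#' @param k K-mer length (default 25).
#' @return Character vector of canonical k-mers, sorted.
#' @export
truth_y_kmers <- function(genome, k = 25) {
  if (k < 1) abort("k must be >= 1")
  chroms <- genome$chromosomes
  y_seq <- chroms$seq[chroms$chrom == "Y"]
  other <- chroms$seq[chroms$chrom != "Y"]
  y_kmers <- cpp_kmer_counts(y_seq, k)$kmer
  other_kmers <- cpp_kmer_counts(other, k)$kmer
  sort(setdiff(y_kmers, other_kmers))
}

sex_weights <- function(genome, sex) {
  if (!sex %in% names(genome$ploidy)) {
    abort(paste0("no ploidy entry for sex '", sex, "'"))
  }
  ploidy <- genome$ploidy[[sex]]
  chroms <- genome$chromosomes
  w <- ploidy[chroms$chrom] * chroms$length
  names(w) <- chroms$chrom
  w
}

#' Simulate long reads from a synthetic genome
#'
#' Reads are drawn from the sex's ploidy-weighted chromosomes with uniform
#' start positions, lengths log-uniform over `config$long_read_range`
#' (truncated at the chromosome ends), a random strand, and independent
#' per-base substitution errors at `config$long_error`. Raw start positions
#' may overhang the 5' end of the chromosome (the read is truncated to the
#' chromosome), so that coverage near both chromosome ends matches interior
#' coverage — on a miniature test chromosome, anchoring every start inside
#' the sequence would leave its first kilobase almost uncovered, an artefact
#' real chromosome-scale data does not show. The true chromosome of origin
#' is recorded in the `chrom` column and echoed in the read id after a
#' reserved `|truth=` tag; the discovery pipeline never reads it.
#'
#' @param genome A `genome_model`.
#' @param sex `"male"` or `"female"`.
#' @param n_reads Number of reads (> 0).
#' @param config The [sim_config()] used to build the genome.
#' @return Tibble with `read_id`, `seq`, `chrom`, `strand`, `start`,
#'   `length`.
#' @export
simulate_long_reads <- function(genome, sex, n_reads, config) {
  if (n_reads <= 0) abort("n_reads must be > 0")
  w <- sex_weights(genome, sex)
  chroms <- genome$chromosomes
  seed_offset <- if (sex == "male") 101L else 102L
  withr::with_seed(config$seed + seed_offset, {
    idx <- sample.int(nrow(chroms), n_reads, replace = TRUE,
                      prob = w[chroms$chrom])
    len_raw <- round(exp(runif(n_reads, log(config$long_read_range[1]),
                               log(config$long_read_range[2]))))
    clen <- chroms$length[idx]
    raw_start <- floor(runif(n_reads, 2 - len_raw, clen + 1))
    start <- pmax(1, raw_start)
    end <- pmin(raw_start + len_raw - 1, clen)
    seqs <- substr(chroms$seq[idx], start, end)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs[strand == "-"] <- cpp_revcomp(seqs[strand == "-"])
    seqs <- apply_read_errors(seqs, config$long_error)
    tibble(
      read_id = sprintf("lr_%s_%05d|truth=%s", sex, seq_len(n_reads),
                        chroms$chrom[idx]),
      seq = seqs,
      chrom = chroms$chrom[idx],
      strand = strand,
      start = start,
      length = nchar(seqs)
    )
  })
}

#' Simulate short reads from a synthetic genome
#'
#' Fixed-length reads sampled to the requested fold coverage of the sex's
#' ploidy-weighted genome (so X is sampled twice as often per genome copy in
#' females as in males, and Y only in males), with a random strand and
#' independent substitution errors at `config$short_error`. The read count is
#' `round(depth * G / L)` where `G` is the ploidy-weighted genome size and
#' `L` the read length.
#'
#' @inheritParams simulate_long_reads
#' @param depth Target fold coverage (> 0); defaults to `config$depth`.
#' @return Tibble with `read_id`, `seq`, `chrom`, `strand`, `start`.
#' @export
simulate_short_reads <- function(genome, sex, depth = config$depth, config) {
  if (depth <= 0) abort("depth must be > 0")
  w <- sex_weights(genome, sex)
  chroms <- genome$chromosomes
  L <- config$short_read_len
  present <- chroms$length[w[chroms$chrom] > 0]
  if (L > min(present)) {
    abort("short_read_len exceeds the shortest chromosome present in this sex")
  }
  n_reads <- round(depth * sum(w) / L)
  seed_offset <- if (sex == "male") 201L else 202L
  withr::with_seed(config$seed + seed_offset, {
    idx <- sample.int(nrow(chroms), n_reads, replace = TRUE,
                      prob = w[chroms$chrom])
    start <- floor(runif(n_reads, 1, chroms$length[idx] - L + 2))
    seqs <- substr(chroms$seq[idx], start, start + L - 1)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs[strand == "-"] <- cpp_revcomp(seqs[strand == "-"])
    seqs <- apply_read_errors(seqs, config$short_error)
    tibble(
      read_id = sprintf("sr_%s_%07d|truth=%s", sex, seq_len(n_reads),
                        chroms$chrom[idx]),
      seq = seqs,
      chrom = chroms$chrom[idx],
      strand = strand,
      start = start
    )
  })
}
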