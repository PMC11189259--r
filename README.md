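# ykmer

Assembly-free discovery of Y-chromosome-specific, highly repetitive
CRISPR/Cas9 target sites from male and female whole-genome sequencing —
plus FISH probe design for the chosen target and the count statistics used
to score sex-ratio distortion phenotypes.

## Who this is for

Building a synthetic sex-ratio distorter (a "Y-shredder") in a species
like *Anopheles gambiae* requires endonuclease targets that are private to
the Y chromosome and repeated hundreds of times — but the *An. gambiae* Y
is unassembled heterochromatin, so targets cannot be taken from a
reference. `ykmer` is for researchers who have sex-separated short-read
libraries and long reads and want to find such targets without any
assembly, validate them cytologically, and score the downstream phenotype.

## The method

Sex linkage is inferred from the **Chromosome Quotient**: for a sequence
hit by `h_f` female and `h_m` male short reads from libraries of `N_f` and
`N_m` reads,

    CQ = (h_f / N_f) / (h_m / N_m)

so autosomal sequence has CQ ≈ 1, X-linked ≈ 2, Y-linked ≈ 0. Long reads
are binned with the standard thresholds (Ymax = 0.3, Xmin = 1.5,
Xmax = 2.5; undefined CQ below `m_min` male hits → excluded). Canonical
25-mers of the male short reads are then profiled with the same statistic
and funnelled:

1. **Y candidates** — k-mer CQ ≤ 0.3, abundant in males, present in ≥ 2
   Y-bin long reads;
2. **off-target-free** — zero exact hits in the autosomal and X bins;
3. **guide-bearing** — an NGG PAM at either end of the 25-mer leaving a
   ≥ 20-nt protospacer (both strands).

A 44-bp FISH probe for any surviving target is cut from an anchored
column-wise consensus of the Y-bin reads that contain the target at 100%
identity. Phenotypes are scored with the field's rules (hatching rate with
insemination-based inclusion, percent-female progeny) and sperm
sex-chromosome genotypes (X / Y / XY non-disjunction / no-sex-chromosome)
are summarised per individual and compared between testes and spermathecae
with an exact Mann–Whitney test.

A synthetic genome generator with planted ground truth (Y-private
satellite, shared repeats, and a Y-satellite slice copied onto X as an
off-target decoy) makes the whole pipeline testable end to end.

## Worked example

```r
library(ykmer)
library(dplyr)

cfg <- sim_config(seed = 1)            # 480-kb genome, satY 53 bp x 500, 20x
genome <- build_genome(cfg)
long <- simulate_long_reads(genome, "male", 1200, cfg)
scr <- screen_y_kmers(long,
                      simulate_short_reads(genome, "female", config = cfg),
                      simulate_short_reads(genome, "male", config = cfg))
scr
#> <ykmer_screen>
#>   long reads binned: 1184 (Y=84, autosomal=928, X=172, excluded=0)
#>   k-mer funnel: 454879 profiled -> 37394 Y candidates -> 37341 off-target-free -> 11248 PAM-bearing

head(scr$final[, c("kmer", "male_count", "kmer_cq", "y_hits", "x_hits", "a_hits", "n_guides")], 3)
#> # A tibble: 3 x 7
#>   kmer                      male_count kmer_cq y_hits x_hits a_hits n_guides
#> 1 CCCCGTTTCTAGCATATGACAGGTC        111       0     42      0      0        4
#> 2 ACCTGTCATATGCTAGAAACGGGGC        109       0     42      0      0        3
#> 3 CCCGTTTCTAGCATATGACAGGTCG         94       0     41      0      0        2
```

Reading the funnel: of 454,879 distinct 25-mers, 37,394 look Y-linked and
repetitive; 53 of them are the planted X-junction decoys and are removed by
the off-target filter (37,341 remain — every one a true Y-private k-mer);
11,248 carry a usable PAM. The top survivors are satellite-monomer k-mers
seen ~110 times in the male library (CQ = 0, 42 distinct Y-bin reads, no
off-target hits).

Design the FISH probe for the best target from the Y-bin reads themselves:

```r
y_bin <- filter(scr$binned, bin == "Y")
design_fish_probe(scr$final$kmer[1], y_bin)
#> <probe_design> 44 bp at consensus column 42 (min support 0.81)
#>   GAGAAAACAACCCATGATGCCCCGTTTCTAGCATATGACAGGTC
```

The probe contains the full 25-bp target plus satellite flank; minimum
per-column support 0.81 over 84 anchored reads. `autoplot(scr, type =
"cq")` and `autoplot(scr, type = "hits")` draw the abundance-vs-CQ and
abundance-vs-Y-hits diagnostics.

Sperm genotype tables are summarised the same way:

```r
pooled <- read_sperm_counts(system.file("extdata",
  "sperm_counts_pooled.tsv", package = "ykmer"))
pooled$individual_id <- paste(pooled$group, pooled$organ)
sperm_proportions(pooled, group = "WT", organ = "testis")$total
#> [1] 1457
```

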