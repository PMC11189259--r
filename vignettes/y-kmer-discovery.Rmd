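---
title: "Assembly-free discovery of Y-specific repetitive CRISPR targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-free discovery of Y-specific repetitive CRISPR targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ykmer)
library(dplyr)
```

## The problem

Synthetic sex-ratio distorters for mosquito control need endonuclease
target sites that are (i) private to one sex chromosome and (ii) repeated
often enough that cutting them shreds the chromosome. In *Anopheles
gambiae* the Y chromosome is almost entirely heterochromatic satellite DNA
with no complete assembly, so targets cannot be read off a reference
genome. `ykmer` implements an assembly-free route: sex-linked sequence is
recognised purely from the differential coverage of male and female
whole-genome sequencing libraries, and targets are short k-mers rather
than annotated loci.

## The Chromosome Quotient model

For any sequence, let $h_f$ and $h_m$ be the numbers of female and male
short reads that pseudo-align to it, and $N_f$, $N_m$ the library sizes.
The Chromosome Quotient is the depth-normalized coverage ratio

$$\mathrm{CQ} = \frac{h_f / N_f}{h_m / N_m}.$$

Under equal per-copy sampling, autosomal sequence (two copies in both
sexes) has CQ ≈ 1, X-linked sequence (two copies in females, one in
males) CQ ≈ 2, and Y-linked sequence (absent from females) CQ ≈ 0.
Long nanopore reads are assigned to bins with the standard thresholds
$Y_{max} = 0.3$ (CQ ≤ 0.3 → Y), $X_{min} = 1.5$ and $X_{max} = 2.5$
(1.5 ≤ CQ ≤ 2.5 → X), autosomal in between, and excluded above $X_{max}$
or when fewer than `m_min` male reads hit (an undefined CQ; this avoids
division-by-near-zero artefacts inflating the X bin). Boundaries are
inclusive toward their bins — the thresholds themselves carry no
open/closed convention, so we fix one and boundary-test it.

The same statistic is computed per canonical 25-mer of the male short
reads, with the same per-million normalization and the same `m_min`
policy. The discovery funnel is then:

1. **Y candidates**: k-mer CQ ≤ 0.3, male count ≥ `min_abundance`
   (repetitiveness), and presence in ≥ `min_y_hits` Y-bin long reads;
2. **off-target-free**: zero exact hits in the autosomal and X long-read
   bins;
3. **guide-bearing**: at least one SpCas9 protospacer/PAM placement — an
   NGG at either terminus of the 25-mer leaving ≥ 20 protospacer bases
   (both strands are scanned; the minus-strand placement appears as CCN at
   the written 5' end).

On real 20× data this funnel is the 1,795 → 866 → 175 candidate
progression; those counts depend on the original sequencing accessions and
on thresholds that were never published, so this package validates the
method on synthetic genomes with planted ground truth instead (below).

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `min_len`, `max_len` | 1,000 / 100,000 bp | nanopore input length filter, inclusive |
| `xmin`, `xmax`, `ymax` | 1.5 / 2.5 / 0.3 | CQ bin thresholds |
| `m_min` | 10 | male hits below which CQ is undefined |
| `k` | 25 bp | k-mer length |
| `min_abundance` | 10 | minimum male count of a candidate (≈ 0.5× the 20× depth) |
| `min_y_hits` | 2 | minimum Y-bin long reads containing the k-mer |
| `min_protospacer` | 20 nt | protospacer length required next to the PAM |
| `probe_len` | 44 bp | FISH probe length (25-bp target + satellite flank) |

`min_abundance` and `min_y_hits` have no published values; the defaults
are what a practitioner would use at 20× coverage — half the expected
depth for abundance, and two independent long reads so a single chimeric
or mis-binned read cannot carry a candidate. Both are arguments
everywhere they matter. Hit counting defaults to exact substring
containment (either strand), the natural definition for the error-free
validation data; a seed-k-mer mode (`seed_len`, `min_shared`) tolerates
substitution errors, and externally computed hit tables can be supplied
in place of either.

Two deliberate counting choices: a k-mer's bin hits count *distinct* long
reads, not occurrences, so tandem arrays do not inflate a single read
into apparent repetitiveness (occurrence counting is available via
`occurrences = TRUE`); and the off-target rule is strict equality to zero
exact 25-mer matches — one autosomal or X hit disqualifies.

## What the simulator emulates — and what it does not

`sim_config()` + `build_genome()` construct a miniature karyotype (two
autosomes, X, Y; 480 kb total by default) with the features the method
must discriminate:

* a Y-private tandem satellite (53-bp monomer × 500 copies, each copy
  independently mutated at 2% — satellite arrays are homogeneous but not
  identical);
* a transposon-like repeat shared by A1, A2 and X (sequence present in
  both sexes, CQ ≈ 1–2, never a candidate);
* a **junction element**: a 120-bp verbatim slice of the Y satellite
  array copied onto X. Its k-mers are abundant and female-depleted
  (CQ ≤ 0.3), so they pass the candidate filter and can only be removed
  by the X-bin off-target check — the planted decoy that makes precision
  = 1.0 a meaningful assertion.

Reads are sampled with ploidy weighting (X twice per genome copy in
females, Y only in males), log-uniform long-read lengths over 1–100 kb so
the length filter is exercised from both sides, and substitution-only
errors (0 by default). Long-read start positions may overhang the 5' end
of a chromosome before truncation: on a 60-kb miniature chromosome,
anchoring every start inside the sequence would leave the first kilobase
almost uncovered — an artefact of miniaturization, not a property of
chromosome-scale data — and edge k-mers would spuriously fail
`min_y_hits`.

The simulator does **not** model realistic nanopore error profiles,
indels, structural variation, quality scores, or heterozygosity. Passing
the planted-truth tests therefore shows the *logic* of the funnel is
exact under its own assumptions; it does not certify performance on real
error-prone libraries, where the seed-based hit mode and the published
thresholds take over.

Problem sizes used in the packaged validation runs — a 480-kb genome,
20× short reads per sex (~324,000 × 100 bp), and 1,200 long reads (~16 Mb)
— were chosen as the smallest configuration that keeps every genomic
feature (500-copy satellite, shared repeats, junction) at realistic copy
number while binning with comfortable margins.

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 1)
genome <- build_genome(cfg)
long <- simulate_long_reads(genome, "male", 1200, cfg)
scr <- screen_y_kmers(long,
                      simulate_short_reads(genome, "female", config = cfg),
                      simulate_short_reads(genome, "male", config = cfg))
glance(scr)
autoplot(scr, type = "cq")
```

## Probe design

To validate a chosen target cytologically, a FISH oligo is designed from
the Y-bin reads themselves: all reads containing the target at 100%
identity form a sub-bin; each is cut to a window around the (leftmost)
match and oriented so the target is on the plus strand at a fixed column.
Because every window shares that exact 25-bp anchor, a gap-free
column-wise consensus is exact in the anchor's neighbourhood — no
general-purpose multiple alignment is needed, the result is deterministic,
and per-column support is directly interpretable (windows can be exported
for an external MSA if desired; its consensus can be fed straight into
`design_probe()`). Per column the modal base is called when its frequency
among non-pad symbols reaches `support_threshold` (default 0.5; ties
break alphabetically), else `N`. The probe is the 44-bp window of the
consensus containing the full target that maximizes mean support, ties
going to the leftmost window, with at most `max_n = 0` uncalled positions.
Support-maximization is our positioning rule — published work states only
that a 44-bp region including the target was selected.

```{r probe, eval = FALSE}
y_bin <- dplyr::filter(scr$binned, bin == "Y")
design_fish_probe(scr$final$kmer[1], y_bin, flank = 60, probe_len = 44)
```

The default 60-bp flank gives 145-bp windows, enough for any 44-bp
placement around the 25-mer; truncated windows are pad-filled and pads
never vote, avoiding edge bias.

## Phenotype and sperm-genotype scoring

The distortion statistics operate on plain tables. `hatching_rate()`
applies the insemination-based inclusion rules exactly: eggs > 0 → HR =
larvae/eggs; no eggs but inseminated → HR = 0; non-hatching clutches from
non-inseminated females, and females that neither laid nor were
inseminated, are excluded. `sex_ratio()` is the percentage of females
among sexed progeny. `sperm_proportions()` converts per-individual FISH
counts of the four sperm categories (X, Y, XY non-disjunction, nSC = no
sex chromosome) into proportions and reports medians with both IQR and SD
(published figures mix the two), plus pooled totals. `compare_organs()`
tests a category's per-individual proportions between testes and
spermathecae with a Mann–Whitney test that is *exact* (full enumeration,
valid under ties) whenever both groups have ≤ 8 individuals — the group
sizes in these experiments are 3–6, where the normal approximation is
poor — and tie-corrected normal otherwise. Two-sided p-values double the
smaller tail, capped at 1. Only the pairwise rank-sum test is
implemented; multi-group procedures (Kruskal–Wallis, Dunn) are standard
library territory and out of scope.

```{r sperm, eval = TRUE}
pooled <- read_sperm_counts(system.file("extdata",
  "sperm_counts_pooled.tsv", package = "ykmer"))
pooled$individual_id <- paste(pooled$group, pooled$organ)
sperm_proportions(pooled, group = "WT", organ = "testis")$total
```

The bundled `sperm_counts_pooled.tsv` holds the published pooled category
totals per strain and organ; per-individual counts (needed for the organ
comparisons) are supplied by the user in the same format, one row per
individual.

## Numerical and design notes

* **Canonical form** is the lexicographic minimum of a k-mer and its
  reverse complement; canonicalization is involutive under reverse
  complement and all counting is strand-symmetric.
* **Determinism**: every generator takes its randomness from
  `sim_config(seed = )` (with fixed per-function offsets), and all
  pipeline outputs are deterministically ordered (candidates by
  descending male count, then k-mer), so runs are byte-reproducible.
* **Normalization invariance**: scaling both library sizes by a common
  factor leaves every CQ unchanged; CQ is monotone in each hit count.
* **Degenerate inputs**: empty read sets and empty sub-bins raise
  errors; IUPAC codes other than A/C/G/T are preserved in storage but
  excluded at k-mer extraction (windows containing them are skipped), a
  single central alphabet policy.
* **Coordinates** are 1-based inclusive in all user-facing tables.
* The published construct's cloned spacer is 18 nt although selection
  required ≥ 20 bp of homology; `min_protospacer` stays configurable and
  defaults to 20.

## Limitations

The funnel counts from the original 20×
accessions (1,795/866/175) are not reproducible without those accessions
and the unpublished thresholds, and are not asserted anywhere. Hit
counting is substitution-tolerant only in seed mode; indels are not
modelled. The anchored consensus assumes the satellite's period is
longer than sequencing error spacing at the anchor — for highly diverged
families an external MSA may be preferable, and the interchange path
exists for that.
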