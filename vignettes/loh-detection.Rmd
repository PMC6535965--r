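---
title: "Detecting somatic loss of heterozygosity in paired bud-sport genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic loss of heterozygosity in paired bud-sport genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohsport)
```

## The problem

A bud sport is a somatic mutant branch of a perennial plant: part of a
tree whose fruit (or leaves, or habit) differs heritably from the rest
of the same individual. When the phenotypic switch is caused by loss of
heterozygosity (LOH) — a chromosomal region changing from heterozygous
to homozygous in the mutant lineage — the signature is visible in a
paired whole-genome comparison of the wild-type and sport tissues: a
contiguous run of SNPs that are heterozygous in the wild type but
homozygous in the sport, starting at a breakpoint and typically running
to the telomere.

`lohsport` implements that comparison as a reusable pipeline:

1. read a paired callset from VCF and apply a stringent hard-filter
   thread (`read_pair_vcf()`, `apply_hard_filters()`);
2. code genotypes 0/1/2 and summarize per-scaffold genotype discordance
   and SNP density (`code_genotype()`, `discordance_table()`);
3. call LOH segments as interruption-tolerant runs of discordant sites
   and bracket the transition breakpoint (`find_loh_segments()`,
   `locate_transition()`);
4. decide copy-neutral LOH versus hemizygous deletion from read-depth
   ratios (`depth_ratio_report()`);
5. trace which parental haplotype was duplicated from phased genotypes,
   and test a marker SNP against a dominance model
   (`haplotype_identity_matrix()`, `call_origin()`,
   `dominance_consistency()`);
6. generate synthetic paired callsets with a planted event so that every
   stage is testable without sequencing data (`simulate_pair()`).

The running example throughout is a flat peach whose sport bears round
fruit: flat is dominant, controlled by a locus at the distal end of
scaffold Pp06, and the sport lost the haplotype carrying the dominant
allele.

## Genotype coding and discordance statistics

Genotypes at biallelic SNPs are coded 0 (homozygous reference), 1
(heterozygous), 2 (homozygous variant); missing calls are a sentinel,
never 0. Two discordance definitions are exposed. `any_mismatch` counts
any difference between the two samples' codes and is what a genome-wide
error audit uses; `loh_only` counts only the LOH direction (wild type 1,
sport 0 or 2) and is what the segment scanner uses. Rates are computed
over scaffold length in bp — not over called SNPs — and printed in
3-significant-figure scientific notation (`format_sci()`), because that
is how per-scaffold discordance tables are conventionally reported.
SNP densities are additionally phrased as an average marker spacing
("1 SNP/480 bp"), with the spacing rounded to two significant figures.

A useful control is a *double haploid* re-sequenced and compared against
its own reference assembly: every heterozygous call is then a false
positive of the calling pipeline and every homozygous-variant call a
putative assembly error. `control_stats()` summarizes such a
self-comparison; with the published counts (58 het, 397 hom over a
225.7 Mb genome) it reproduces the error floor of 2.57E-7 per bp for
het miscalls.

## Hard filtering

`hard_filter_thresholds()` encodes a deliberately stringent post-calling
filter thread: QD < 10, MQ outside [59.9, 60.1], FS > 15,
|MQRankSum| > 0.04, ReadPosRankSum < −1.5, SOR > 2,
|ClippingRankSum| > 0.3, any GQ < 20, any missing genotype. Three
numerical choices deserve comment:

* the rank-sum windows are symmetric absolute-value bounds, as printed;
* the ReadPosRankSum bound is one-sided by default (only the lower tail
  is printed in the source thread); a symmetric upper bound can be
  switched on with `rprs_one_sided = FALSE`;
* a missing INFO metric never fires its rule (the convention of the
  calling toolchain for annotations undefined at a site); the count of
  such lenient evaluations is reported so the user can see how often it
  happened.

Failing sites are attributed to the *first* failing rule in the order
above, so the per-rule counts partition the removed sites and filtering
is idempotent.

## The LOH segment scanner

The scanner is a run test, not a CNV segmenter. Per scaffold, in one
left-to-right pass:

1. mark each site discordant iff wild = 1 and sport ∈ {0, 2};
2. cluster maximal discordant runs: two adjacent runs merge when the gap
   of non-discordant sites between them is at most `max_gap_sites`
   (default 5) long and contains no reverse-discordant site (sport
   heterozygous, wild homozygous);
3. keep a cluster only if it contains at least `min_run` (default 5)
   *consecutive* discordant sites.

The two defaults implement one rule each: `min_run` protects against
isolated genotyping errors seeding fake events (five consecutive
discordant calls are vanishingly unlikely from independent errors at the
measured error floor), while `max_gap_sites` protects a *real* event
from being fragmented by its own false negatives — a megabase-scale LOH
tract contains dozens of sites where the caller still reports a
heterozygote in the sport, and a literal "consecutive" rule would split
one somatic event into dozens of reported segments. Setting
`max_gap_sites = 0` recovers the fragmented view; every fragment is then
contained in some merged segment (a tested invariant). The "at least 5"
reading of the seed rule is the default; `strict = TRUE` gives the
"more than 5" reading.

Each segment reports its site composition and a **consistency**
fraction: the share of segment sites that do not contradict LOH
(everything except sites heterozygous in both samples). On the default
event-scaffold preset this is (10,515 − 36)/10,515 = 99.66%.

Breakpoints are *bracketed*, never guessed: the true transition lies
between the last upstream concordant-heterozygous site and the first
discordant site (`locate_transition()`). With ~1 SNP/kb spacing the
bracket is a few kb wide; reporting a single base would be false
precision. The scanner's exactness is checked against a brute-force
connected-components oracle on all inputs up to 50 sites.

## Copy-neutral versus deletion

Both copy-neutral LOH and a hemizygous deletion produce the same
genotype signature; they differ in read depth. `depth_ratio_report()`
computes per-site sport/wild depth ratios inside the candidate region
and outside it, and takes the **ratio of medians**
(region median / genome median) as the decision statistic. Medians
resist depth outliers, and the normalization cancels global library-size
differences exactly — a sample sequenced at 26× versus 28× cannot fake a
deletion. The verdict thresholds (deletion below 0.75, copy-neutral
above 0.85, ambiguous between) are package choices placed between the
expected values of 0.5 (one copy lost) and 1.0 (copy number preserved),
with a buffer where no call is safer than a wrong call; the source study
states no numeric threshold. Regions with fewer than 50 usable sites are
always ambiguous.

## Haplotype tracing and the dominance rule

Given phased haplotypes for both samples over the event region (phasing
is consumed, e.g. from a population phasing run — never computed here),
`haplotype_identity_matrix()` tabulates the fraction of sites at which
each sport haplotype matches each wild haplotype. Under copy-neutral LOH
both sport haplotypes are copies of the *same* wild haplotype: both rows
of the matrix peak in the same column. `call_origin()` requires each row
to prefer that column by a margin (`min_margin = 0.05`, a package
choice — "derived from" has no numeric criterion in the source) before
declaring the origin haplotype duplicated and the other lost.

`dominance_consistency()` tests a marker SNP against the model "the
dominant allele implies the dominant phenotype". For the built-in
fruit-shape panels (`fruit_shape_marker_table()`): in the association
panel 11 of 12 flat accessions carry a T (91.7%) and all 93 round
accessions are A/A; in the validation panel all 22 flat accessions are
A/T and all 236 round accessions A/A. Violations are listed in both
directions (flat without T, round with T), since either falsifies the
dominance model.

## What the generator emulates — and what it does not

`simulate_pair()` draws a diploid genome of eight scaffolds with the
observed per-scaffold SNP counts and lengths, places SNPs uniformly per
scaffold, and plants:

* a somatic event distal to a breakpoint (default Pp06-like at
  22,195,188 bp): 10,515 distal SNPs of which 8,537 are wild-het; all
  but 36 "dropout" sites convert to homozygous for the retained
  haplotype's allele, and 1,978 are concordant homozygous-variant;
* per-scaffold genotype-call errors outside the event, as *exact planted
  counts* (defaults: the observed 7/54/6/10/4/14/7/0) rather than
  per-site Bernoulli draws, so downstream tests are deterministic in
  expectation and non-flaky;
* negative-binomial depths at 28×/26× with `size = 20`
  (variance/mean ≈ 2.2 at these depths, a typical whole-genome
  overdispersion), halved distally in the sport under
  `hemizygous_deletion`;
* QC metrics drawn inside the nominal pass window of the default filter
  thread.

The non-discordant event sites are interleaved so that no interior gap
run exceeds `gap_cap` (default 5) and the region's first and last sites
are discordant; the planted event is therefore recoverable as exactly
one segment under the default scanner, which is the regime the
acceptance checks probe. The `mechanism` parameter implements the two
break-induced-replication models: under G1 every sampled cell carries
the event; under G2 the lesion yields two daughter lineages
(`simulate_cell_lineage()`), and `mosaic_fraction < 1` renders distal
sites heterozygous again with probability 1 − `mosaic_fraction`, a
deliberately simple linear stand-in for allele-balance-dependent
recalling in a cell mixture.

Known non-features, hence what passing tests do *not* show about real
data:

* SNP positions are uniform; real SNP density is locally clustered.
* Depths are independent across sites and samples; real depth has shared
  site-level structure (GC, mappability), which is why real per-site
  depth-ratio distributions are tighter (>95% within [0.5, 1.5] in the
  motivating dataset) than the generator's (~80% at `size = 20`). The
  verdict statistic is a median of thousands of sites and is unaffected.
* No read-level error model, no mapping artifacts, no structural
  variants; genotype errors are planted at the *measured* error rates,
  not mechanistically generated.

## Problem sizes and reproducibility

Everything is seeded, and identical seeds give byte-identical VCF
output. The shipped checks run the event-scaffold preset (35,486 sites)
for 100 seeds for segment recovery and breakpoint bracketing, 100
simulations for the deletion/copy-neutral discrimination, 1,000
random ≤50-site inputs against the exhaustive scanner oracle, and
1,000-daughter lineage draws; `scripts/acceptance.R` recomputes the
headline numbers at 50/50/1,000 in under a minute.

## Worked example

```{r example, eval = FALSE}
library(lohsport)

sim <- simulate_pair(sim_config(seed = 1, preset = "pp06"))
write_pair_vcf(sim, "pair.vcf")

sites <- read_pair_vcf("pair.vcf", c("wild", "sport"))
sites <- apply_hard_filters(sites)$sites
sites$code_wild <- code_genotype(sites$gt_wild)
sites$code_sport <- code_genotype(sites$gt_sport)

segs <- find_loh_segments(sites)
locate_transition(sites, segs[1, ])
depth_ratio_report(sites, list(scaffold = "Pp06",
                               start = segs$start[1],
                               end = segs$end[1]))
call_origin(haplotype_identity_matrix(emit_phased_truth(sim)))
```

The same flow is available from a shell via the installed
`exec/lohsport` script (`simulate`, `filter`, `discordance`, `scan`,
`depth`, `haplotrace`, `report` subcommands).
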