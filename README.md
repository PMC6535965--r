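# lohsport

Paired-sample detection of somatic **loss of heterozygosity (LOH)** for
bud-sport genomics.

A bud sport is a somatic mutant branch of a perennial plant — the same
individual, but one lineage of meristem cells carries a new mutation.
When the mutation is an LOH event, a chromosomal region that is
heterozygous in the wild-type tissue becomes homozygous in the sport,
usually from a breakpoint to the telomere. `lohsport` detects and
characterizes such events from a pair of whole-genome variant callsets
(wild type vs sport), and ships a synthetic-callset generator so the
whole pipeline is testable without any sequencing data. The motivating
system is a flat peach whose bud sport bears round fruit: an ~8.6 Mb
copy-neutral LOH at the distal end of scaffold Pp06 removed the
haplotype carrying the dominant flat-shape allele.

## What it computes

With genotypes coded 0/1/2 (hom-ref / het / hom-alt), for each site
carrying codes $c_w$ (wild) and $c_s$ (sport):

* **Discordance statistics** — per scaffold, the discordance count
  $D = \#\{c_w \ne c_s\}$, called SNPs $N$, discordance rate $D/L$ and
  SNP density $N/L$ over the scaffold length $L$, printed in
  3-significant-figure scientific notation (e.g. `4.52E-7`), plus
  "1 SNP/X bp" spacing phrases.
* **LOH segments** — runs of sites with $c_w = 1$, $c_s \in \{0, 2\}$:
  maximal discordant runs are clustered across interruption gaps of at
  most `max_gap_sites` (default 5) non-discordant sites, and a cluster
  qualifies if it contains ≥ `min_run` (default 5) consecutive
  discordant sites. Each segment carries a consistency fraction
  $(n - n_{het})/n$ and a breakpoint *bracket* (last concordant-het
  site, first discordant site).
* **Copy-neutral vs deletion** — per-site depth ratios
  $r_i = d_{s,i}/d_{w,i}$; the verdict compares the region median to the
  genome median: $\tilde r_{region}/\tilde r_{genome} < 0.75$ calls a
  hemizygous deletion, $> 0.85$ copy-neutral LOH, else ambiguous.
* **Haplotype origin** — from phased genotypes, a 2×2 identity matrix
  between the two sport and two wild haplotypes; if both sport
  haplotypes match the same wild haplotype with margin ≥ 0.05, that
  haplotype was duplicated and the other lost.
* **Dominance rule** — a genotype–phenotype table checked against
  "dominant allele ⇒ dominant phenotype" (built-in fruit-shape panels:
  91.7% of flat accessions carry T, all round accessions are A/A).
* **Mechanism models** — G1 vs G2 break-induced replication: one
  daughter genotype class under G1, two (het-distal / hom-distal, each
  ~1/2) under G2, with a mosaic-tissue mode for the generator.

## Worked example

Simulate the default event-scaffold preset (35,486 SNPs on a Pp06-like
scaffold, copy-neutral LOH distal to 22,195,188 bp) and run the
pipeline:

```r
library(lohsport)

sim  <- simulate_pair(sim_config(seed = 1, preset = "pp06"))
segs <- find_loh_segments(sim$sites)
segs
#  scaffold    start      end n_sites n_discordant n_interrupting_het
#      Pp06 22195586 30766105   10515         8501                 36
#  n_concordant_hom consistency
#              1978   0.9965763
```

One segment: 10,515 sites from 22.2 Mb to the scaffold end, 8,501
discordant in the LOH direction, 36 residual heterozygous calls
(genotyping false negatives), consistency 99.66%.

```r
locate_transition(sim$sites, segs[1, ])$bracket
# [1] 22195025 22195586          # brackets the planted 22,195,188

depth_ratio_report(sim$sites, list(scaffold = "Pp06",
                                   start = segs$start[1],
                                   end = segs$end[1]))
#   region median ratio : 0.931 (10515 sites)
#   genome median ratio : 0.923 (24971 sites)
#   normalized ratio    : 1.009
#   verdict             : copy_neutral

call_origin(haplotype_identity_matrix(emit_phased_truth(sim)))$origin
# [1] "wild_h1"                  # the duplicated (retained) haplotype
```

The normalized depth ratio near 1 rules out a hemizygous deletion (which
would sit near 0.5); the identity matrix shows both sport haplotypes are
copies of wild haplotype 1, so haplotype 2 — the one carrying the
dominant allele — was lost. The same steps are available from a shell
via the installed `exec/lohsport` script:

```sh
lohsport simulate --preset pp06 --seed 1 -o run/
lohsport scan -i run/pair.vcf -o run/
lohsport depth -i run/pair.vcf --region Pp06:22195189-30767194 -o run/
lohsport report -d run/
```

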