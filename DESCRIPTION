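Package: lohsport
Title: Paired-Sample Loss-of-Heterozygosity Detection for Bud-Sport Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects somatic loss-of-heterozygosity (LOH) events from paired
    wild-type / bud-sport variant callsets. Reads paired-sample VCFs, applies
    GATK-style hard filters and genotype-quality gates, computes per-scaffold
    genotype discordance and SNP-density statistics, calls LOH segments as
    interruption-tolerant runs of heterozygous-to-homozygous transitions,
    localizes the transition breakpoint, discriminates copy-neutral LOH from
    hemizygous deletion by read-depth ratios, and traces which parental
    haplotype was duplicated from phased genotypes. A synthetic paired-callset
    generator emulating a diploid eight-scaffold genome, including G1/G2
    break-induced-replication mechanism models, makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    optparse,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    rtracklayer,
    GenomicRanges,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
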