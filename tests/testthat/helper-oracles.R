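# Independent oracles and small fixture builders shared across tests.

# Brute-force LOH segment oracle: connected components of discordant
# sites, linked when at most max_gap non-discordant sites separate them
# and none of the separating sites is reverse-discordant; a component
# qualifies if it contains min_run site-consecutive discordant sites.
# Deliberately a different formulation from the scanner's rle pass.
oracle_loh_segments <- function(pos, cw, cs, min_run = 5,
                                max_gap = 5, strict = FALSE) {
  disc <- which(cw == 1 & cs %in% c(0, 2))
  rev_disc <- cs == 1 & cw %in% c(0, 2)
  if (length(disc) == 0) return(NULL)
  comp <- cumsum(c(1, vapply(seq_along(disc)[-1], function(k) {
    i <- disc[k - 1]; j <- disc[k]
    gap <- j - i - 1
    blocked <- gap > max_gap ||
      (gap > 0 && any(rev_disc[(i + 1):(j - 1)]))
    as.integer(blocked)
  }, integer(1))))
  out <- NULL
  for (g in unique(comp)) {
    idx <- disc[comp == g]
    # longest stretch of site-consecutive discordant indices:
    # k consecutive sites show k - 1 unit differences
    stretch <- if (length(idx) == 1) 1 else {
      r <- rle(diff(idx) == 1)
      max(c(0, r$lengths[r$values])) + 1
    }
    qual <- if (strict) stretch > min_run else stretch >= min_run
    if (qual)
      out <- rbind(out, data.frame(start = pos[min(idx)],
                                   end = pos[max(idx)],
                                   n_discordant = length(idx)))
  }
  out
}

# Per-site re-evaluation of every hard-filter condition, independent of
# the vectorized implementation.
oracle_filter_pass <- function(site, thr) {
  bad <- function(x, f) !is.na(x) && f(x)
  fails <- c(
    bad(site$QD, function(x) x < thr$qd_min),
    bad(site$MQ, function(x) x < thr$mq_low),
    bad(site$MQ, function(x) x > thr$mq_high),
    bad(site$FS, function(x) x > thr$fs_max),
    bad(site$MQRankSum, function(x) abs(x) > thr$mqranksum_abs_max),
    bad(site$ReadPosRankSum, function(x) x < thr$readposranksum_min),
    if (thr$rprs_one_sided) FALSE else
      bad(site$ReadPosRankSum, function(x) x > -thr$readposranksum_min),
    bad(site$SOR, function(x) x > thr$sor_max),
    bad(site$ClippingRankSum,
        function(x) abs(x) > thr$clippingranksum_abs_max),
    bad(site$gq_wild, function(x) x < thr$gq_min),
    bad(site$gq_sport, function(x) x < thr$gq_min),
    thr$require_complete &&
      (is.na(site$gt_wild) || is.na(site$gt_sport) ||
         site$gt_wild %in% c("./.", ".") || site$gt_sport %in% c("./.", "."))
  )
  !any(fails)
}

# A down-scaled event configuration: one 100 kb scaffold, 200 SNPs,
# breakpoint mid-scaffold, 100 distal SNPs of which 80 wild-het with 5
# dropouts.
small_config <- function(seed, event = "loh_copy_neutral", ...) {
  sim_config(
    seed = seed, event = event,
    scaffolds = tibble::tibble(scaffold = "Pp06", length_bp = 100000L,
                               called_snp = 200L),
    breakpoint_bp = 50000, distal_snp = 100L, distal_het = 80L,
    distal_dropout = 5L, error_counts = c(Pp06 = 2L), ...)
}

# Random coded-site table for property tests.
random_sites <- function(n, p_disc = 0.5, scaffold = "chr1") {
  cw <- sample(0:2, n, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  cs <- ifelse(stats::runif(n) < p_disc & cw == 1,
               sample(c(0L, 2L), n, replace = TRUE), cw)
  tibble::tibble(scaffold = scaffold, pos = sort(sample.int(n * 100, n)),
                 code_wild = as.integer(cw), code_sport = as.integer(cs))
}

# Minimal hand-written VCF text for reader tests.
toy_vcf_lines <- function(body, samples = c("wild", "sport")) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    body)
}
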