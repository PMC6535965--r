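INFO_METRICS <- c("QD", "MQ", "FS", "MQRankSum", "ReadPosRankSum",
                  "SOR", "ClippingRankSum")

#' Hard-filter thresholds for site-level quality control
#'
#' Threshold set of the GATK-style hard-filter thread applied after
#' variant calling. A site is removed when any condition fires:
#' `QD < qd_min`, `MQ < mq_low`, `MQ > mq_high`, `FS > fs_max`,
#' `|MQRankSum| > mqranksum_abs_max`,
#' `ReadPosRankSum < readposranksum_min` (and symmetrically above
#' `-readposranksum_min` unless `rprs_one_sided`), `SOR > sor_max`,
#' `|ClippingRankSum| > clippingranksum_abs_max`, any genotype quality
#' below `gq_min`, or (with `require_complete`) any missing genotype.
#' Defaults reproduce the stringent thread used for the paired peach
#' callset; the printed thread bounds `ReadPosRankSum` from below only,
#' so the default is one-sided.
#'
#' @param qd_min,mq_low,mq_high,fs_max,mqranksum_abs_max Numeric bounds.
#' @param readposranksum_min,sor_max,clippingranksum_abs_max Numeric
#'   bounds.
#' @param gq_min Minimum genotype quality for both samples (phred).
#' @param require_complete Drop sites with any missing genotype.
#' @param rprs_one_sided Only apply the lower `ReadPosRankSum` bound.
#' @return List of class `hard_filter_thresholds`.
#' @export
hard_filter_thresholds <- function(qd_min = 10.0,
                                   mq_low = 59.9, mq_high = 60.1,
                                   fs_max = 15.0,
                                   mqranksum_abs_max = 0.04,
                                   readposranksum_min = -1.5,
                                   sor_max = 2.0,
                                   clippingranksum_abs_max = 0.3,
                                   gq_min = 20,
                                   require_complete = TRUE,
                                   rprs_one_sided = TRUE) {
  stopifnot(mq_low < mq_high,
            all(is.finite(c(qd_min, mq_low, mq_high, fs_max,
                            mqranksum_abs_max, readposranksum_min,
                            sor_max, clippingranksum_abs_max, gq_min))))
  structure(list(qd_min = qd_min, mq_low = mq_low, mq_high = mq_high,
                 fs_max = fs_max, mqranksum_abs_max = mqranksum_abs_max,
                 readposranksum_min = readposranksum_min,
                 sor_max = sor_max,
                 clippingranksum_abs_max = clippingranksum_abs_max,
                 gq_min = gq_min,
                 require_complete = isTRUE(require_complete),
                 rprs_one_sided = isTRUE(rprs_one_sided)),
            class = "hard_filter_thresholds")
}

vcf_to_site_table <- function(v, samples) {
  avail <- colnames(v@gt)[-1]
  missing <- setdiff(samples, avail)
  if (length(missing) > 0)
    stop("sample(s) not in VCF: ", paste(missing, collapse = ", "),
         "; available samples: ", paste(avail, collapse = ", "),
         call. = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  multi <- grepl(",", alt, fixed = TRUE)
  snp <- !multi & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  indel <- !multi & !snp
  keep <- snp

  # sortedness within scaffold (scaffold blocks in file order)
  for (sc in unique(chrom)) {
    p <- pos[chrom == sc]
    if (is.unsorted(p))
      stop("VCF not sorted on ", sc, "; first offending position: ",
           p[which(diff(p) < 0)[1] + 1L], call. = FALSE)
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, "GQ", as.numeric = TRUE))
  col <- function(mat, s) if (is.null(mat)) rep(NA_real_, sum(keep))
                          else mat[keep, s]
  info <- lapply(INFO_METRICS, function(k)
    suppressWarnings(vcfR::extract.info(v, k, as.numeric = TRUE))[keep])
  names(info) <- INFO_METRICS

  out <- tibble::tibble(
    scaffold = chrom[keep], pos = pos[keep],
    ref = ref[keep], alt = alt[keep],
    gt_wild = unname(gt[keep, samples[1]]),
    gt_sport = unname(gt[keep, samples[2]]),
    dp_wild = unname(col(dp, samples[1])),
    dp_sport = unname(col(dp, samples[2])),
    gq_wild = unname(col(gq, samples[1])),
    gq_sport = unname(col(gq, samples[2]))
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(info))
  attr(out, "skip_summary") <- c(indel = sum(indel),
                                 multiallelic = sum(multi))
  out
}

#' Read a paired-sample callset from VCF
#'
#' Reads the wild-type and sport genotypes either from one two-sample VCF
#' or from two single-sample VCFs. Only biallelic SNPs are kept; indels
#' and multiallelic records are skipped and counted in the
#' `"skip_summary"` attribute. With two files, sites are matched on
#' (scaffold, pos, ref, alt); positions private to one file or with
#' mismatched alleles are dropped and counted.
#'
#' @param path VCF file (two-sample mode) or the wild-type VCF.
#' @param samples Length-2 character vector naming the wild-type and
#'   sport samples. In two-file mode each name must occur in its own
#'   file.
#' @param sport_path Optional second VCF holding the sport sample.
#' @return Tibble of sites sorted by (scaffold, pos) with columns
#'   `scaffold`, `pos`, `ref`, `alt`, `gt_wild`, `gt_sport`, `dp_*`,
#'   `gq_*`, and the site-level INFO metrics QD, MQ, FS, MQRankSum,
#'   ReadPosRankSum, SOR, ClippingRankSum (`NA` when absent). The
#'   attribute `skip_summary` is a named count vector.
#' @export
read_pair_vcf <- function(path, samples, sport_path = NULL) {
  stopifnot(length(samples) == 2)
  if (is.null(sport_path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    out <- vcf_to_site_table(v, samples)
  } else {
    w <- vcf_to_site_table(vcfR::read.vcfR(path, verbose = FALSE),
                           rep(samples[1], 2))
    s <- vcf_to_site_table(vcfR::read.vcfR(sport_path, verbose = FALSE),
                           rep(samples[2], 2))
    key_w <- paste(w$scaffold, w$pos, w$ref, w$alt)
    key_s <- paste(s$scaffold, s$pos, s$ref, s$alt)
    pos_w <- paste(w$scaffold, w$pos)
    pos_s <- paste(s$scaffold, s$pos)
    shared <- intersect(key_w, key_s)
    allele_mismatch <- length(intersect(pos_w, pos_s)) - length(shared)
    i <- match(shared, key_w)
    j <- match(shared, key_s)
    out <- w[i, ]
    out$gt_sport <- s$gt_wild[j]
    out$dp_sport <- s$dp_wild[j]
    out$gq_sport <- s$gq_wild[j]
    attr(out, "skip_summary") <- c(
      attr(w, "skip_summary") + attr(s, "skip_summary"),
      private = (nrow(w) - length(shared)) + (nrow(s) - length(shared)) -
        2L * allele_mismatch,
      allele_mismatch = allele_mismatch)
  }
  skip <- attr(out, "skip_summary")
  out <- out[order(out$scaffold, out$pos), ]
  attr(out, "skip_summary") <- skip
  out
}

#' Apply the hard-filter thread to a site table
#'
#' Evaluates every filter condition of [hard_filter_thresholds()] on each
#' site. A site passes iff no condition fires; failing sites are
#' attributed to the first firing rule in the documented order, so the
#' per-rule fail counts sum to the number of removed sites. A missing
#' INFO metric never fires its rule (calling-pipeline convention for
#' annotations that are undefined at a site); the count of such
#' leniently-passed evaluations is reported.
#'
#' @param sites Site table from [read_pair_vcf()] (or the generator).
#' @param thr A [hard_filter_thresholds()] object.
#' @return List with `sites` (passing subset), `fail_counts` (named
#'   integer vector in attribution order), `n_input`, `n_pass`,
#'   `n_missing_metric` (rule evaluations skipped for lack of the
#'   metric).
#' @export
apply_hard_filters <- function(sites, thr = hard_filter_thresholds()) {
  stopifnot(inherits(thr, "hard_filter_thresholds"))
  n <- nrow(sites)
  fire <- function(x) !is.na(x) & x   # absent metric: rule does not fire
  g <- function(nm) if (nm %in% names(sites)) sites[[nm]]
                    else rep(NA_real_, n)
  missing_gt <- is.na(sites$gt_wild) | is.na(sites$gt_sport) |
    sites$gt_wild %in% c("./.", ".", ".|.") |
    sites$gt_sport %in% c("./.", ".", ".|.")
  rules <- list(
    QD = fire(g("QD") < thr$qd_min),
    MQ_low = fire(g("MQ") < thr$mq_low),
    MQ_high = fire(g("MQ") > thr$mq_high),
    FS = fire(g("FS") > thr$fs_max),
    MQRankSum = fire(abs(g("MQRankSum")) > thr$mqranksum_abs_max),
    ReadPosRankSum_low = fire(g("ReadPosRankSum") < thr$readposranksum_min),
    ReadPosRankSum_high = if (thr$rprs_one_sided) rep(FALSE, n)
      else fire(g("ReadPosRankSum") > -thr$readposranksum_min),
    SOR = fire(g("SOR") > thr$sor_max),
    ClippingRankSum = fire(abs(g("ClippingRankSum")) >
                             thr$clippingranksum_abs_max),
    GQ = fire(g("gq_wild") < thr$gq_min) | fire(g("gq_sport") < thr$gq_min),
    missing_gt = if (thr$require_complete) missing_gt else rep(FALSE, n)
  )
  fail_mat <- do.call(cbind, rules)
  any_fail <- rowSums(fail_mat) > 0
  first <- apply(fail_mat, 1, function(r) which(r)[1])  # NA when passing
  fail_counts <- vapply(seq_along(rules), function(k)
    sum(first == k, na.rm = TRUE), integer(1))
  names(fail_counts) <- names(rules)
  metrics_present <- intersect(INFO_METRICS, names(sites))
  n_missing_metric <- sum(vapply(metrics_present,
                                 function(k) sum(is.na(sites[[k]])),
                                 integer(1)))
  list(sites = sites[!any_fail, ],
       fail_counts = fail_counts,
       n_input = n, n_pass = sum(!any_fail),
       n_missing_metric = n_missing_metric)
}

#' Write LOH segments as BED
#'
#' Converts 1-based inclusive segment coordinates to the BED convention
#' (0-based, half-open): `start - 1`, `end`. The name column encodes the
#' segment type (a `type` column when present, otherwise `"LOH"`) and
#' the discordant-site count. Output is sorted by (scaffold, start).
#'
#' @param segments Tibble with `scaffold`, `start`, `end`, optionally
#'   `type` and `n_discordant`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_segments_bed <- function(segments, path) {
  if (nrow(segments) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  segments <- segments[order(segments$scaffold, segments$start), ]
  for (sc in unique(segments$scaffold)) {
    s <- segments[segments$scaffold == sc, ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments on ", sc,
           ": merge before writing BED", call. = FALSE)
  }
  type <- if ("type" %in% names(segments)) segments$type
          else rep("LOH", nrow(segments))
  name <- if ("n_discordant" %in% names(segments))
    sprintf("%s_n%d", type, segments$n_discordant) else type
  writeLines(sprintf("%s\t%d\t%d\t%s", segments$scaffold,
                     as.integer(segments$start) - 1L,
                     as.integer(segments$end), name), path)
  invisible(path)
}

#' Read a segment BED back to 1-based coordinates
#'
#' Inverse of [write_segments_bed()] for round-trip checks and report
#' collation.
#'
#' @param path BED file.
#' @return Tibble with `scaffold`, `start`, `end` (1-based inclusive),
#'   `name`.
#' @export
read_segments_bed <- function(path) {
  if (file.size(path) == 0)
    return(tibble::tibble(scaffold = character(), start = double(),
                          end = double(), name = character()))
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  tibble::tibble(scaffold = x[[1]], start = x[[2]] + 1, end = x[[3]],
                 name = if (ncol(x) >= 4) x[[4]] else NA_character_)
}
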