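#' Copy-neutral LOH versus hemizygous deletion by depth ratios
#'
#' A region that lost heterozygosity by deletion of one chromosome copy
#' shows roughly half the read depth of the rest of the genome in the
#' mutant sample; a copy-neutral event (break-induced replication /
#' mitotic recombination) leaves depth unchanged. This report computes the
#' per-site depth ratio sport/wild inside the candidate region and
#' genome-wide (all provided sites outside the region), and compares the
#' region median to the genome median. The normalized ratio
#' (region median / genome median) is invariant to global library-size
#' differences between the two samples, so a verdict cannot be created by
#' unequal sequencing effort alone.
#'
#' @param sites Tibble with columns `scaffold`, `pos`, `dp_wild`,
#'   `dp_sport`.
#' @param region List or one-row tibble with `scaffold`, `start`, `end`
#'   (1-based inclusive).
#' @param deletion_max Normalized ratio below which the verdict is
#'   `"deletion"` (default 0.75 — midway-ish between the 0.5 expected for
#'   a hemizygous deletion and 1 for copy-neutral, with an ambiguity
#'   buffer).
#' @param neutral_min Normalized ratio above which the verdict is
#'   `"copy_neutral"` (default 0.85). Between the two bounds the verdict
#'   is `"ambiguous"`.
#' @param invert Use wild/sport ratios instead of sport/wild. The verdict
#'   is orientation-independent because it is based on the normalized
#'   ratio.
#' @param min_region_sites Below this many usable region sites the verdict
#'   is forced to `"ambiguous"` with a warning (default 50).
#' @return List of class `depth_ratio_report`: `region_median`,
#'   `genome_median`, `normalized_ratio`, `fraction_in_band` (region sites
#'   with ratio in `[0.5, 1.5]`), `fraction_below_1`, `verdict`,
#'   `n_region`, `n_genome`, `n_zero_excluded`, and the per-site region
#'   `ratios`.
#' @export
depth_ratio_report <- function(sites, region,
                               deletion_max = 0.75, neutral_min = 0.85,
                               invert = FALSE, min_region_sites = 50L) {
  stopifnot(deletion_max < neutral_min)
  usable <- sites$dp_wild > 0 & sites$dp_sport > 0
  n_zero <- sum(!usable)
  s <- sites[usable, ]
  r <- if (invert) s$dp_wild / s$dp_sport else s$dp_sport / s$dp_wild
  in_region <- s$scaffold == region$scaffold &
    s$pos >= region$start & s$pos <= region$end
  if (!any(in_region)) stop("region contains no usable sites",
                            call. = FALSE)
  r_reg <- r[in_region]
  r_gen <- r[!in_region]
  if (length(r_gen) == 0)
    stop("no sites outside the region to form a genome-wide baseline",
         call. = FALSE)
  region_median <- stats::median(r_reg)
  genome_median <- stats::median(r_gen)
  nr <- region_median / genome_median
  verdict <- if (nr < deletion_max) "deletion"
             else if (nr > neutral_min) "copy_neutral"
             else "ambiguous"
  if (length(r_reg) < min_region_sites) {
    warning("fewer than ", min_region_sites,
            " usable region sites; verdict forced to ambiguous")
    verdict <- "ambiguous"
  }
  structure(list(
    region = region,
    region_median = region_median,
    genome_median = genome_median,
    normalized_ratio = nr,
    fraction_in_band = mean(r_reg >= 0.5 & r_reg <= 1.5),
    fraction_below_1 = mean(r_reg < 1),
    verdict = verdict,
    n_region = length(r_reg),
    n_genome = length(r_gen),
    n_zero_excluded = n_zero,
    ratios = tibble::tibble(scaffold = s$scaffold[in_region],
                            pos = s$pos[in_region], ratio = r_reg)
  ), class = "depth_ratio_report")
}

#' @export
print.depth_ratio_report <- function(x, ...) {
  cat("Depth-ratio report for", x$region$scaffold,
      sprintf("%s-%s", format(x$region$start, big.mark = ","),
              format(x$region$end, big.mark = ",")), "\n")
  cat(sprintf("  region median ratio : %.3f (%d sites)\n",
              x$region_median, x$n_region))
  cat(sprintf("  genome median ratio : %.3f (%d sites)\n",
              x$genome_median, x$n_genome))
  cat(sprintf("  normalized ratio    : %.3f\n", x$normalized_ratio))
  cat(sprintf("  in [0.5, 1.5]       : %.1f%%\n",
              100 * x$fraction_in_band))
  cat(sprintf("  below 1             : %.1f%%\n",
              100 * x$fraction_below_1))
  cat("  verdict             :", x$verdict, "\n")
  invisible(x)
}
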