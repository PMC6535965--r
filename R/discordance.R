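#' Code a genotype call numerically
#'
#' Maps biallelic genotype calls onto the 0/1/2 coding used throughout the
#' pipeline: 0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' variant. The coding is symmetric in allele order (`"0/1"` and `"1/0"`
#' both give 1) and accepts phased separators. Missing calls (`"./."`,
#' `"."`, `NA`) become `NA`, never 0.
#'
#' @param gt Character vector of VCF-style genotype strings (`"0/1"`,
#'   `"1|1"`, `"./."`, ...).
#' @return Integer vector of codes in \{0, 1, 2\} with `NA` for missing.
#' @examples
#' code_genotype(c("0/0", "0/1", "1|0", "1/1", "./."))
#' @export
code_genotype <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2L || any(al == "."))
      return(NA_integer_)
    al <- suppressWarnings(as.integer(al))
    if (any(is.na(al)))
      stop("malformed genotype string: '", g, "'", call. = FALSE)
    if (any(al > 1L))
      stop("allele index > 1 in genotype '", g,
           "': multiallelic site leaked past input filtering", call. = FALSE)
    sum(al)
  }, integer(1), USE.NAMES = FALSE)
}

#' Is a site discordant in the LOH direction?
#'
#' A site supports loss of heterozygosity when the wild type is
#' heterozygous (code 1) and the sport is homozygous (code 0 or 2).
#'
#' @param code_wild,code_sport Integer genotype codes.
#' @return Logical vector.
#' @export
is_loh_discordant <- function(code_wild, code_sport) {
  code_wild == 1L & code_sport %in% c(0L, 2L)
}

#' Discordance, rate and density summary from raw counts
#'
#' Pure arithmetic shared by all summary tables: given a discordance count
#' D, a called-SNP count N and a region size L (bp), computes the
#' discordance rate D/L and SNP density N/L, with the 3-significant-figure
#' strings used in printed reports.
#'
#' @param discordance,called_snp Counts (D, N).
#' @param scaffold_size Region length L in bp; `NA` allowed (unplaced
#'   scaffolds), giving `NA` rates.
#' @return Tibble with columns `discordance`, `called_snp`,
#'   `scaffold_size`, `discordance_rate`, `snp_density`, `rate_str`,
#'   `density_str`.
#' @examples
#' rate_summary(102, 237476, 225694811)
#' @export
rate_summary <- function(discordance, called_snp, scaffold_size) {
  stopifnot(all(discordance >= 0), all(called_snp >= 0))
  if (any(!is.na(scaffold_size) & scaffold_size <= 0))
    stop("scaffold_size must be positive", call. = FALSE)
  rate <- discordance / scaffold_size
  dens <- called_snp / scaffold_size
  tibble::tibble(
    discordance = as.integer(discordance),
    called_snp = as.integer(called_snp),
    scaffold_size = scaffold_size,
    discordance_rate = rate,
    snp_density = dens,
    rate_str = format_sci(rate),
    density_str = format_sci(dens)
  )
}

#' Per-scaffold discordance statistics
#'
#' Counts genotype discordances between the two samples on one scaffold
#' and expresses them per base pair. Two discordance definitions are
#' available: `any_mismatch` (any difference between the codes, the
#' definition behind whole-genome inconsistency tables) and `loh_only`
#' (wild-type heterozygous, sport homozygous — the definition used for
#' LOH scanning).
#'
#' @param code_wild,code_sport Integer genotype codes for the sites of one
#'   scaffold (no missing values).
#' @param scaffold_size Scaffold length in bp (> 0).
#' @param discordance_def `"any_mismatch"` or `"loh_only"`.
#' @param scaffold Optional scaffold label for the output row.
#' @return One-row tibble as in [rate_summary()], prefixed by `scaffold`.
#' @export
scaffold_stats <- function(code_wild, code_sport, scaffold_size,
                           discordance_def = c("any_mismatch", "loh_only"),
                           scaffold = NA_character_) {
  discordance_def <- match.arg(discordance_def)
  stopifnot(length(code_wild) == length(code_sport))
  if (anyNA(code_wild) || anyNA(code_sport))
    stop("missing genotype codes: filter incomplete sites first",
         call. = FALSE)
  d <- if (discordance_def == "any_mismatch") {
    sum(code_wild != code_sport)
  } else {
    sum(is_loh_discordant(code_wild, code_sport))
  }
  out <- rate_summary(d, length(code_wild), scaffold_size)
  tibble::tibble(scaffold = scaffold, out)
}

#' Genome-wide discordance table
#'
#' Builds the per-scaffold discordance/density table for a paired callset,
#' with a `Total` row summing counts over scaffolds present in the
#' scaffold table. Sites on scaffolds absent from the table (unplaced
#' contigs) are reported as a `Remaining` row without rates.
#'
#' @param sites Tibble with columns `scaffold`, `code_wild`, `code_sport`.
#' @param scaffold_table Tibble with columns `scaffold`, `length_bp`
#'   (default [peach_scaffold_table()]).
#' @param discordance_def Passed to [scaffold_stats()].
#' @return Tibble, one row per scaffold plus optional `Remaining` and a
#'   `Total` row.
#' @export
discordance_table <- function(sites,
                              scaffold_table = peach_scaffold_table(),
                              discordance_def = c("any_mismatch",
                                                  "loh_only")) {
  discordance_def <- match.arg(discordance_def)
  rows <- lapply(seq_len(nrow(scaffold_table)), function(i) {
    sc <- scaffold_table$scaffold[i]
    sub <- sites[sites$scaffold == sc, ]
    scaffold_stats(sub$code_wild, sub$code_sport,
                   scaffold_table$length_bp[i],
                   discordance_def, scaffold = sc)
  })
  out <- dplyr::bind_rows(rows)
  rem <- sites[!sites$scaffold %in% scaffold_table$scaffold, ]
  if (nrow(rem) > 0) {
    d <- if (discordance_def == "any_mismatch") {
      sum(rem$code_wild != rem$code_sport)
    } else {
      sum(is_loh_discordant(rem$code_wild, rem$code_sport))
    }
    out <- dplyr::bind_rows(out, tibble::tibble(
      scaffold = "Remaining", discordance = as.integer(d),
      called_snp = nrow(rem), scaffold_size = NA_real_,
      discordance_rate = NA_real_, snp_density = NA_real_,
      rate_str = "NA", density_str = "NA"))
  }
  total <- rate_summary(sum(out$discordance),
                        sum(out$called_snp),
                        sum(scaffold_table$length_bp))
  dplyr::bind_rows(out, tibble::tibble(scaffold = "Total", total))
}

#' Self-comparison statistics for a homozygous control
#'
#' Summarizes SNP calls made when re-sequencing reads of the (double
#' haploid) reference genotype are compared with the reference itself —
#' the empirical error floor of the calling pipeline. Every heterozygous
#' call (code 1) is a putative false positive; homozygous-variant calls
#' (code 2) are putative assembly errors.
#'
#' @param codes Integer genotype codes of the control sample against the
#'   reference.
#' @param genome_size Total reference length in bp.
#' @return Tibble with rows `Het`, `Hom`, `Total`: counts and per-bp rates
#'   (with formatted strings).
#' @export
control_stats <- function(codes, genome_size) {
  stopifnot(genome_size > 0)
  het <- sum(codes == 1L, na.rm = TRUE)
  hom <- sum(codes == 2L, na.rm = TRUE)
  n <- c(het, hom, het + hom)
  tibble::tibble(
    state = c("Het", "Hom", "Total"),
    discordance = as.integer(n),
    size_bp = genome_size,
    discordance_rate = n / genome_size,
    rate_str = format_sci(n / genome_size)
  )
}

#' Rank scaffolds by SNP density
#'
#' Reports the average marker spacing of each scaffold as a "1 SNP/X bp"
#' phrase (spacing rounded to 2 significant figures) and ranks scaffolds
#' from densest to sparsest. Scaffolds with no called SNPs get `"NA"` and
#' are excluded from the ranking.
#'
#' @param stats Tibble with columns `scaffold`, `called_snp`,
#'   `scaffold_size` (e.g. rows of [discordance_table()]).
#' @return Tibble with `scaffold`, `called_snp`, `scaffold_size`,
#'   `spacing_bp`, `spacing_label`, `density_rank` (1 = densest; `NA` when
#'   unranked).
#' @export
density_report <- function(stats) {
  spacing <- ifelse(stats$called_snp > 0,
                    signif(stats$scaffold_size / stats$called_snp, 2),
                    NA_real_)
  out <- tibble::tibble(
    scaffold = stats$scaffold,
    called_snp = stats$called_snp,
    scaffold_size = stats$scaffold_size,
    spacing_bp = spacing,
    spacing_label = snp_spacing_label(stats$called_snp,
                                      stats$scaffold_size)
  )
  dens <- stats$called_snp / stats$scaffold_size
  rankable <- !is.na(dens) & stats$called_snp > 0
  rk <- rep(NA_integer_, nrow(out))
  rk[rankable] <- as.integer(rank(-dens[rankable], ties.method = "min"))
  out$density_rank <- rk
  out[order(is.na(out$density_rank), out$density_rank), ]
}
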