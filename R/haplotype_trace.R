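#' A phased four-haplotype region
#'
#' Container for the phased haplotypes of the two compared samples over
#' one genomic interval: two wild-type haplotypes and two sport
#' haplotypes, as allele vectors over the same ordered site positions.
#' Phasing is consumed, not computed, by this package.
#'
#' @param pos Strictly increasing 1-based site positions.
#' @param wild_h1,wild_h2,sport_h1,sport_h2 Allele vectors (any atomic
#'   type, e.g. bases or 0/1 indices), all the same length as `pos`.
#' @return A list of class `phased_region`.
#' @export
phased_region <- function(pos, wild_h1, wild_h2, sport_h1, sport_h2) {
  n <- length(pos)
  if (!all(lengths(list(wild_h1, wild_h2, sport_h1, sport_h2)) == n))
    stop("all four haplotype vectors must match the number of sites",
         call. = FALSE)
  if (n > 1 && any(diff(pos) <= 0))
    stop("site positions must be strictly increasing", call. = FALSE)
  structure(list(pos = pos, wild_h1 = wild_h1, wild_h2 = wild_h2,
                 sport_h1 = sport_h1, sport_h2 = sport_h2),
            class = "phased_region")
}

#' Read a phased region from a VCF
#'
#' Extracts the four haplotypes of two samples over an interval from a
#' VCF with phased genotypes (`|` separator). Unphased or missing
#' genotypes in the interval are dropped with a message.
#'
#' @param path VCF file.
#' @param samples Length-2 character vector: wild-type sample name, sport
#'   sample name.
#' @param scaffold,start,end Interval to extract (1-based inclusive);
#'   `start`/`end` default to the whole scaffold.
#' @return A [phased_region()] with alleles as bases.
#' @export
read_phased_region <- function(path, samples, scaffold,
                               start = 1, end = Inf) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  avail <- colnames(v@gt)[-1]
  missing <- setdiff(samples, avail)
  if (length(missing) > 0)
    stop("sample(s) not in VCF: ", paste(missing, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "), call. = FALSE)
  fix <- vcfR::getFIX(v)
  pos <- as.numeric(fix[, "POS"])
  keep <- fix[, "CHROM"] == scaffold & pos >= start & pos <= end
  gt <- vcfR::extract.gt(v, element = "GT")[keep, samples, drop = FALSE]
  pos <- pos[keep]
  ref <- fix[keep, "REF"]
  alt <- fix[keep, "ALT"]
  phased <- grepl("^[01]\\|[01]$", gt[, 1]) & grepl("^[01]\\|[01]$", gt[, 2])
  if (any(!phased))
    message(sum(!phased), " unphased or missing sites dropped")
  gt <- gt[phased, , drop = FALSE]
  base <- function(idx, i) ifelse(idx == "0", ref[phased][i], alt[phased][i])
  hap <- function(col, field) {
    parts <- do.call(rbind, strsplit(unname(gt[, col]), "|",
                                     fixed = TRUE))
    base(parts[, field], seq_len(nrow(parts)))
  }
  phased_region(pos[phased],
                wild_h1 = hap(1, 1), wild_h2 = hap(1, 2),
                sport_h1 = hap(2, 1), sport_h2 = hap(2, 2))
}

#' Haplotype identity matrix
#'
#' Fraction of sites at which each sport haplotype carries the same
#' allele as each wild-type haplotype. Under a copy-neutral LOH that
#' duplicated one wild haplotype, both rows have their maximum in the
#' same column.
#'
#' @param region A [phased_region()].
#' @return 2x2 numeric matrix; rows `sport_h1`, `sport_h2`, columns
#'   `wild_h1`, `wild_h2`.
#' @export
haplotype_identity_matrix <- function(region) {
  stopifnot(inherits(region, "phased_region"))
  if (length(region$pos) < 1) stop("region has no sites", call. = FALSE)
  m <- matrix(c(mean(region$sport_h1 == region$wild_h1),
                mean(region$sport_h1 == region$wild_h2),
                mean(region$sport_h2 == region$wild_h1),
                mean(region$sport_h2 == region$wild_h2)),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("sport_h1", "sport_h2"),
                              c("wild_h1", "wild_h2")))
  m
}

#' Call the origin of a duplicated haplotype
#'
#' Decides, from a haplotype identity matrix, whether both sport
#' haplotypes derive from the same wild-type haplotype (the copy-neutral
#' LOH signature: one haplotype duplicated, the other lost) or whether
#' transmission looks biparental.
#'
#' @param m 2x2 matrix from [haplotype_identity_matrix()].
#' @param min_margin Minimum identity margin each sport haplotype must
#'   show for its best-matching wild haplotype over the alternative
#'   (default 0.05).
#' @return List with `origin` (`"wild_h1"`, `"wild_h2"` or
#'   `"undetermined"`), `lost` (the complementary haplotype or
#'   `"undetermined"`), `duplicated` (logical), and `margins`.
#' @export
call_origin <- function(m, min_margin = 0.05) {
  stopifnot(is.matrix(m), all(dim(m) == c(2, 2)))
  best <- apply(m, 1, which.max)
  margin <- abs(m[, 1] - m[, 2])
  if (best[1] == best[2] && all(margin >= min_margin)) {
    j <- best[1]
    list(origin = colnames(m)[j], lost = colnames(m)[3 - j],
         duplicated = TRUE, margins = unname(margin))
  } else {
    list(origin = "undetermined", lost = "undetermined",
         duplicated = FALSE, margins = unname(margin))
  }
}

#' Dominance consistency of a marker SNP
#'
#' Tests a genotype-phenotype table against the dominance model "the
#' dominant allele implies the dominant phenotype": here, accessions
#' carrying at least one copy of the dominant allele (default `T`) should
#' be flat-fruited, and round accessions should all be homozygous for the
#' alternative allele.
#'
#' @param table Tibble with columns `accession`, `phenotype` (`"flat"` /
#'   `"round"`), `genotype` (strings like `"A/A"`, `"A/T"`, `"T/T"`).
#' @param dominant_allele Single base, default `"T"`.
#' @return List: `flat_with_T` (fraction of flat accessions carrying the
#'   dominant allele; `NA` when there are no flat accessions),
#'   `flat_with_T_pct` (rounded to 1 decimal), `round_all_AA` (logical:
#'   no round accession carries the dominant allele), `violations`
#'   (tibble of accessions inconsistent with the model: flat without the
#'   allele or round with it), `n_flat`, `n_round`.
#' @examples
#' dominance_consistency(fruit_shape_marker_table("gwas"))
#' @export
dominance_consistency <- function(table, dominant_allele = "T") {
  if (nrow(table) == 0) stop("empty genotype-phenotype table",
                             call. = FALSE)
  ok_ph <- table$phenotype %in% c("flat", "round")
  if (any(!ok_ph))
    stop("unknown phenotype in row ", which(!ok_ph)[1], " (accession ",
         table$accession[which(!ok_ph)[1]], "): '",
         table$phenotype[which(!ok_ph)[1]], "'", call. = FALSE)
  ok_gt <- grepl("^[ACGT]/[ACGT]$", table$genotype)
  if (any(!ok_gt))
    stop("unknown genotype string in row ", which(!ok_gt)[1],
         " (accession ", table$accession[which(!ok_gt)[1]], "): '",
         table$genotype[which(!ok_gt)[1]], "'", call. = FALSE)
  carries <- vapply(strsplit(table$genotype, "/", fixed = TRUE),
                    function(a) dominant_allele %in% a, logical(1))
  flat <- table$phenotype == "flat"
  frac <- if (any(flat)) mean(carries[flat]) else NA_real_
  list(
    flat_with_T = frac,
    flat_with_T_pct = if (is.na(frac)) NA_real_ else round(100 * frac, 1),
    round_all_AA = !any(carries[!flat]),
    violations = table[(flat & !carries) | (!flat & carries), ],
    n_flat = sum(flat),
    n_round = sum(!flat)
  )
}
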