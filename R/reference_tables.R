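#' Scaffold summary of the flat-peach / bud-sport callset
#'
#' The eight chromosome-scale scaffolds of the peach reference (Pp01-Pp08)
#' with their lengths, the number of high-quality biallelic SNPs called in
#' the wild-type/bud-sport pair on each, and the number of genotype
#' discordances observed outside the somatic event region. These values
#' parameterize the synthetic-callset generator defaults and the worked
#' examples; `pair_discordance` for Pp06 is the proximal (non-event) count.
#'
#' @return A tibble with columns `scaffold`, `length_bp`, `called_snp`,
#'   `pair_discordance`.
#' @examples
#' peach_scaffold_table()
#' @export
peach_scaffold_table <- function() {
  tibble::tibble(
    scaffold = sprintf("Pp%02d", 1:8),
    length_bp = c(47851208L, 30405870L, 27368013L, 25843236L,
                  18496696L, 30767194L, 22388614L, 22573980L),
    called_snp = c(35297L, 63329L, 23281L, 21835L,
                   24476L, 35486L, 26451L, 7101L),
    pair_discordance = c(7L, 54L, 6L, 10L, 4L, 14L, 7L, 0L)
  )
}

#' Default parameters of the distal-Pp06 LOH event
#'
#' Composition of the somatic event region used as generator defaults: the
#' heterozygous-to-homozygous transition breakpoint on Pp06, the SNP count
#' of the distal interval, how many of those SNPs are heterozygous in the
#' wild type, and how many heterozygous calls survive in the sport sample
#' (false-negative "dropouts" of the event).
#'
#' @return A named list with `scaffold`, `breakpoint_bp`, `distal_snp`,
#'   `distal_het`, `distal_dropout`.
#' @keywords internal
pp06_event_defaults <- function() {
  list(
    scaffold = "Pp06",
    breakpoint_bp = 22195188L,
    distal_snp = 10515L,
    distal_het = 8537L,     # 8,501 convert to homozygous + 36 dropouts
    distal_dropout = 36L
  )
}

#' Genotype-phenotype table at the fruit-shape marker SNP
#'
#' Accession counts at the A/T marker SNP on distal Pp06 associated with
#' flat versus round fruit, expanded to one row per accession. Two panels
#' are available: the association-mapping panel (12 flat: 10 A/T, 1 T/T,
#' 1 A/A; 93 round: all A/A) and the independent validation panel (22 flat
#' A/T; 236 round A/A).
#'
#' @param panel `"gwas"` or `"validation"`.
#' @return A tibble with columns `accession`, `phenotype` (`"flat"` /
#'   `"round"`), `genotype` (`"A/A"`, `"A/T"`, `"T/T"`).
#' @examples
#' dominance_consistency(fruit_shape_marker_table("gwas"))
#' @export
fruit_shape_marker_table <- function(panel = c("gwas", "validation")) {
  panel <- match.arg(panel)
  counts <- switch(panel,
    gwas = list(flat = c("A/T" = 10L, "T/T" = 1L, "A/A" = 1L),
                round = c("A/A" = 93L)),
    validation = list(flat = c("A/T" = 22L),
                      round = c("A/A" = 236L))
  )
  rows <- lapply(names(counts), function(ph) {
    gt <- rep(names(counts[[ph]]), counts[[ph]])
    tibble::tibble(phenotype = ph, genotype = gt)
  })
  out <- dplyr::bind_rows(rows)
  out$accession <- sprintf("%s_%s_%03d", panel, out$phenotype,
                           stats::ave(seq_len(nrow(out)), out$phenotype,
                                      FUN = seq_along))
  out[, c("accession", "phenotype", "genotype")]
}
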