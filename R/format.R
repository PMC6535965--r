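#' Format a rate in 3-significant-figure scientific notation
#'
#' Formats rates and densities the way per-scaffold discordance tables are
#' conventionally printed: three significant figures, an uppercase `E`, and
#' no zero-padding of the exponent (`4.52E-7`, `1.05E-3`). Zero is printed
#' as `"0"` and missing values as `"NA"`.
#'
#' @param x Numeric vector of rates (typically counts per base pair).
#' @return Character vector, same length as `x`.
#' @examples
#' format_sci(102 / 225694811)  # "4.52E-7"
#' format_sci(0)                # "0"
#' @export
format_sci <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == 0) return("0")
    e <- floor(log10(abs(v)))
    m <- round(v / 10^e, 2)
    if (abs(m) >= 10) {      # rounding rolled the mantissa over
      e <- e + 1
      m <- round(v / 10^e, 2)
    }
    sprintf("%.2fE%d", m, e)
  }, character(1))
}

#' Express a SNP density as an average marker spacing
#'
#' Converts a (called SNPs, region length) pair into the conventional
#' "1 SNP/X bp" phrasing, with the spacing rounded to two significant
#' figures and switched to kilobases at or above 1,000 bp.
#'
#' @param called_snp Number of called SNPs in the region.
#' @param length_bp Region length in base pairs.
#' @return Character scalar such as `"1 SNP/950 bp"` or `"1 SNP/3.2 kb"`;
#'   `"NA"` when `called_snp` is zero.
#' @examples
#' snp_spacing_label(237476, 225694811)  # "1 SNP/950 bp"
#' snp_spacing_label(7101, 22573980)     # "1 SNP/3.2 kb"
#' @export
snp_spacing_label <- function(called_snp, length_bp) {
  mapply(function(n, l) {
    if (is.na(n) || is.na(l) || n == 0) return("NA")
    x <- signif(l / n, 2)
    if (x >= 1000) {
      sprintf("1 SNP/%s kb", format(x / 1000, trim = TRUE))
    } else {
      sprintf("1 SNP/%s bp", format(x, trim = TRUE, scientific = FALSE))
    }
  }, called_snp, length_bp, USE.NAMES = FALSE)
}
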