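#' Parameters of the LOH run scanner
#'
#' @param min_run Minimum number of consecutive discordant SNPs
#'   (wild-type heterozygous, sport homozygous) required to seed a
#'   segment. Default 5; seeds of exactly `min_run` sites qualify unless
#'   `strict = TRUE`, which requires strictly more.
#' @param max_gap_sites Maximum length of a run of consecutive
#'   non-discordant sites tolerated between two seeds that are merged
#'   into one event. Genotyping false negatives interrupt real events, so
#'   a pure "consecutive" rule would fragment them; merging across short
#'   interruptions keeps one somatic event as one segment. Set to 0 for
#'   the fragmented view.
#' @param extend_to_end Report the terminal segment of a scaffold as
#'   running to the telomere (requires `scaffold_length` at scan time).
#'   Default `FALSE`: segments are bounded by their first/last discordant
#'   SNP.
#' @param strict Require seeds longer than (not at least) `min_run`.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(min_run = 5L, max_gap_sites = 5L,
                        extend_to_end = FALSE, strict = FALSE) {
  stopifnot(min_run >= 1, max_gap_sites >= 0)
  structure(list(min_run = as.integer(min_run),
                 max_gap_sites = as.integer(max_gap_sites),
                 extend_to_end = isTRUE(extend_to_end),
                 strict = isTRUE(strict)),
            class = "scan_params")
}

#' Detect LOH segments as runs of discordant sites
#'
#' Scans the coded sites of one scaffold for loss-of-heterozygosity
#' segments in a single left-to-right pass: (1) each site is marked
#' discordant iff the wild type is heterozygous (code 1) and the sport is
#' homozygous (0 or 2); (2) maximal runs of consecutive discordant sites
#' are clustered: adjacent runs merge when the non-discordant gap between
#' them is at most `max_gap_sites` sites long and contains no site
#' discordant in the reverse direction (sport heterozygous, wild type
#' homozygous); (3) a cluster qualifies as a segment only if it contains
#' at least one seed run of `min_run` or more consecutive discordant
#' sites, so isolated short runs of genotyping errors never become
#' events; (4) qualifying segments are emitted
#' with their site composition and a consistency fraction — the share of
#' segment sites not contradicting LOH (everything except sites
#' heterozygous in both samples).
#'
#' @param sites Tibble with columns `pos` (sorted, 1-based), `code_wild`,
#'   `code_sport` (no missing codes), and optionally `scaffold`.
#' @param params A [scan_params()] object.
#' @param scaffold_length Optional scaffold length in bp, used only when
#'   `params$extend_to_end` is `TRUE`.
#' @return Tibble of segments with columns `scaffold`, `start`, `end`
#'   (1-based inclusive), `n_sites`, `n_discordant`, `n_interrupting_het`,
#'   `n_concordant_hom`, `consistency`.
#' @export
find_loh_segments <- function(sites, params = scan_params(),
                              scaffold_length = NULL) {
  stopifnot(inherits(params, "scan_params"))
  if (is.unsorted(sites$pos))
    stop("sites must be sorted by position; first offending position: ",
         sites$pos[which(diff(sites$pos) < 0)[1] + 1L], call. = FALSE)
  if (anyNA(sites$code_wild) || anyNA(sites$code_sport))
    stop("missing genotype codes", call. = FALSE)
  scaffold <- if ("scaffold" %in% names(sites) && nrow(sites) > 0)
    sites$scaffold[1] else NA_character_

  empty <- tibble::tibble(scaffold = character(), start = double(),
                          end = double(), n_sites = integer(),
                          n_discordant = integer(),
                          n_interrupting_het = integer(),
                          n_concordant_hom = integer(),
                          consistency = double())
  n <- nrow(sites)
  if (n == 0) return(empty)

  disc <- is_loh_discordant(sites$code_wild, sites$code_sport)
  rev_disc <- is_loh_discordant(sites$code_sport, sites$code_wild)

  r <- rle(disc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values]
  run_end <- ends[r$values]
  run_len <- r$lengths[r$values]
  if (length(run_start) == 0) return(empty)
  is_seed <- if (params$strict) run_len > params$min_run
             else run_len >= params$min_run
  if (!any(is_seed)) return(empty)

  # cluster discordant runs across tolerated interruption gaps
  grp <- integer(length(run_start))
  grp[1] <- 1L
  if (length(run_start) > 1) {
    for (k in 2:length(run_start)) {
      between <- (run_end[k - 1L] + 1L):(run_start[k] - 1L)
      ok <- length(between) <= params$max_gap_sites &&
        !any(rev_disc[between])
      grp[k] <- if (ok) grp[k - 1L] else grp[k - 1L] + 1L
    }
  }

  # a cluster qualifies only if it contains at least one seed run
  keep <- split(seq_along(run_start), grp)
  keep <- keep[vapply(keep, function(ix) any(is_seed[ix]), logical(1))]
  segs <- lapply(keep, function(ix) {
    i1 <- run_start[ix[1]]
    i2 <- run_end[ix[length(ix)]]
    cw <- sites$code_wild[i1:i2]
    cs <- sites$code_sport[i1:i2]
    total <- i2 - i1 + 1L
    n_het <- sum(cw == 1L & cs == 1L)
    tibble::tibble(
      scaffold = scaffold,
      start = sites$pos[i1],
      end = sites$pos[i2],
      n_sites = total,
      n_discordant = sum(is_loh_discordant(cw, cs)),
      n_interrupting_het = n_het,
      n_concordant_hom = sum(cw %in% c(0L, 2L) & cw == cs),
      consistency = (total - n_het) / total
    )
  })
  out <- dplyr::bind_rows(segs)
  if (params$extend_to_end && !is.null(scaffold_length)) {
    last <- which.max(out$end)
    i2 <- max(which(disc))
    if (i2 == n || !any(rev_disc[(i2 + 1L):n]))
      out$end[last] <- scaffold_length
  }
  out[order(out$start), ]
}

#' Bracket the heterozygous-to-homozygous transition breakpoint
#'
#' The physical breakpoint of an LOH event lies between the last upstream
#' site that is heterozygous in both samples and the first discordant site
#' of the segment. Only this bracket is identifiable from genotypes; a
#' single-base breakpoint is never guessed, though the bracket midpoint is
#' reported as a point summary.
#'
#' @param sites The coded sites the segment was scanned from.
#' @param segment One row of [find_loh_segments()] output.
#' @return List with `upstream_het_pos` (`NA` with
#'   `upstream_label = "scaffold start"` when the segment starts at the
#'   first site without any upstream concordant-het site),
#'   `first_discordant_pos`, `midpoint`, and `bracket` (length-2 vector).
#' @export
locate_transition <- function(sites, segment) {
  first_disc <- segment$start
  upstream <- sites$pos < first_disc &
    sites$code_wild == 1L & sites$code_sport == 1L
  if (any(upstream)) {
    u <- max(sites$pos[upstream])
    label <- "upstream concordant het"
  } else {
    u <- NA_real_
    label <- "scaffold start"
  }
  lo <- if (is.na(u)) 1 else u
  list(
    upstream_het_pos = u,
    upstream_label = label,
    first_discordant_pos = first_disc,
    midpoint = floor((lo + first_disc) / 2),
    bracket = c(lo, first_disc)
  )
}

#' Apparent false-negative rate of heterozygous calls inside an event
#'
#' Sites still called heterozygous in both samples inside a true LOH
#' segment are genotyping false negatives; their count over the segment
#' span estimates the per-bp het false-negative rate of the pipeline.
#'
#' @param segment One row of [find_loh_segments()] output.
#' @param span_bp Physical span used as denominator (bp, > 0).
#' @return Numeric rate (use [format_sci()] for the printed form).
#' @examples
#' seg <- tibble::tibble(n_interrupting_het = 36)
#' format_sci(false_negative_rate(seg, 8.6e6))  # "4.19E-6"
#' @export
false_negative_rate <- function(segment, span_bp) {
  stopifnot(span_bp > 0)
  segment$n_interrupting_het / span_bp
}

#' Per-site discordance track
#'
#' A plotting-friendly per-site table (position, both codes, LOH-direction
#' discordance flag) for genotype-pattern figures along a scaffold.
#'
#' @param sites Coded sites of one scaffold.
#' @return Tibble with `scaffold`, `pos`, `code_wild`, `code_sport`,
#'   `discordant`.
#' @export
discordance_track <- function(sites) {
  tibble::tibble(
    scaffold = if ("scaffold" %in% names(sites)) sites$scaffold
               else NA_character_,
    pos = sites$pos,
    code_wild = sites$code_wild,
    code_sport = sites$code_sport,
    discordant = is_loh_discordant(sites$code_wild, sites$code_sport)
  )
}
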