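#' Configuration of the synthetic paired-callset generator
#'
#' Parameterizes a simulated diploid genome and a configurable somatic
#' event, emulating the statistical structure of the flat-peach /
#' bud-sport comparison: eight chromosome-scale scaffolds with realistic
#' per-scaffold SNP counts, a mostly-heterozygous event region at the
#' distal end of one scaffold, a small planted set of genotype
#' discordances elsewhere (the calling error floor), and overdispersed
#' sequencing depths around 28x / 26x.
#'
#' @param seed Integer seed; all output is reproducible from it.
#' @param preset `"genome"` (all eight scaffolds) or `"pp06"` (the event
#'   scaffold only — the composition of the candidate region plus its
#'   proximal background, convenient for simulation studies).
#' @param event `"loh_copy_neutral"` (one wild haplotype duplicated
#'   distal to the breakpoint, depth unchanged), `"hemizygous_deletion"`
#'   (one copy lost: same genotype conversion, sport depth halved
#'   distally), or `"none"`.
#' @param mechanism `"G1"` or `"G2"` break-induced replication. Under G1
#'   all sampled cells carry the event; under G2 the lesion produces two
#'   daughter lineages and the sampled tissue may be a mosaic.
#' @param mosaic_fraction Share of sampled cells from the mutant lineage
#'   (used when `mechanism = "G2"`; 1 = pure mutant tissue). Distal
#'   wild-het sites are rendered heterozygous in the sport sample with
#'   probability `1 - mosaic_fraction`.
#' @param event_scaffold,breakpoint_bp Location of the somatic event;
#'   sites strictly beyond the breakpoint are distal. Defaults: Pp06 at
#'   22,195,188 bp.
#' @param distal_snp,distal_het,distal_dropout Composition of the event
#'   region: total SNPs, wild-heterozygous SNPs among them, and how many
#'   of those escape conversion in the sport calls (het false-negative
#'   "dropouts", planted as an exact count so tests are not flaky).
#' @param het_fraction Wild-type heterozygous fraction outside the event
#'   region (default 0.6).
#' @param error_counts Named integer vector of planted genotype-call
#'   discordances per scaffold outside the event region; default: the
#'   observed per-scaffold pair discordances of
#'   [peach_scaffold_table()].
#' @param gap_cap Largest run of non-discordant sites planted inside the
#'   event region (default 5, matching the default scanner merge
#'   tolerance: the planted event is one merged segment by
#'   construction).
#' @param depth_mean_wild,depth_mean_sport,depth_dispersion Negative
#'   binomial depth model (means in x coverage; `size` dispersion).
#' @param scaffolds Optional replacement scaffold table (`scaffold`,
#'   `length_bp`, `called_snp`).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       preset = c("genome", "pp06"),
                       event = c("loh_copy_neutral",
                                 "hemizygous_deletion", "none"),
                       mechanism = c("G1", "G2"),
                       mosaic_fraction = 1,
                       event_scaffold = "Pp06",
                       breakpoint_bp = 22195188,
                       distal_snp = 10515L,
                       distal_het = 8537L,
                       distal_dropout = 36L,
                       het_fraction = 0.6,
                       error_counts = NULL,
                       gap_cap = 5L,
                       depth_mean_wild = 28,
                       depth_mean_sport = 26,
                       depth_dispersion = 20,
                       scaffolds = NULL) {
  preset <- match.arg(preset)
  event <- match.arg(event)
  mechanism <- match.arg(mechanism)
  if (is.null(scaffolds)) {
    scaffolds <- peach_scaffold_table()
    if (preset == "pp06")
      scaffolds <- scaffolds[scaffolds$scaffold == event_scaffold, ]
  }
  if (event != "none") {
    if (!event_scaffold %in% scaffolds$scaffold)
      stop("event scaffold '", event_scaffold,
           "' not in scaffold table", call. = FALSE)
    len <- scaffolds$length_bp[scaffolds$scaffold == event_scaffold]
    if (breakpoint_bp <= 0 || breakpoint_bp >= len)
      stop("breakpoint must lie within the event scaffold", call. = FALSE)
    n_ev <- scaffolds$called_snp[scaffolds$scaffold == event_scaffold]
    stopifnot(distal_snp <= n_ev, distal_het <= distal_snp,
              distal_dropout <= distal_het)
  }
  stopifnot(mosaic_fraction >= 0, mosaic_fraction <= 1,
            het_fraction >= 0, het_fraction <= 1, gap_cap >= 0,
            depth_mean_wild > 0, depth_mean_sport > 0,
            depth_dispersion > 0)
  if (is.null(error_counts)) {
    tab <- peach_scaffold_table()
    error_counts <- stats::setNames(tab$pair_discordance, tab$scaffold)
  }
  structure(list(
    seed = as.integer(seed), preset = preset, event = event,
    mechanism = mechanism, mosaic_fraction = mosaic_fraction,
    event_scaffold = event_scaffold, breakpoint_bp = breakpoint_bp,
    distal_snp = as.integer(distal_snp),
    distal_het = as.integer(distal_het),
    distal_dropout = as.integer(distal_dropout),
    het_fraction = het_fraction, error_counts = error_counts,
    gap_cap = as.integer(gap_cap),
    depth_mean_wild = depth_mean_wild,
    depth_mean_sport = depth_mean_sport,
    depth_dispersion = depth_dispersion,
    scaffolds = scaffolds), class = "sim_config")
}

# Arrange n_d discordant and n_nd non-discordant sites so that no run of
# non-discordant sites inside the event exceeds gap_cap, boundaries are
# discordant, and the arrangement is otherwise uniform (rejection
# sampling over interior gap slots).
plant_event_order <- function(n_d, n_nd, gap_cap) {
  if (n_nd == 0) return(rep(TRUE, n_d))
  if (n_d < 2) stop("event region needs at least 2 discordant sites",
                    call. = FALSE)
  if (gap_cap == 0)
    stop("cannot interleave interruptions with gap_cap = 0", call. = FALSE)
  if (n_nd > (n_d - 1) * gap_cap)
    stop("too many interruptions for the gap cap", call. = FALSE)
  for (i in 1:10000) {
    slot <- sample.int(n_d - 1L, n_nd, replace = TRUE)
    if (max(tabulate(slot, n_d - 1L)) <= gap_cap) break
  }
  counts <- tabulate(slot, n_d - 1L)
  is_disc <- logical(n_d + n_nd)
  k <- 1L
  for (i in seq_len(n_d - 1L)) {
    is_disc[k] <- TRUE
    k <- k + 1L + counts[i]
  }
  is_disc[k] <- TRUE
  is_disc
}

#' Simulate a paired wild-type / bud-sport callset
#'
#' Generates one realization of the synthetic genome described by a
#' [sim_config()]: SNP positions uniform per scaffold, wild-type
#' genotypes heterozygous or homozygous-variant, sport genotypes equal to
#' the wild type everywhere except (a) the planted per-scaffold
#' genotype-call errors and (b) the somatic event region, where wild-het
#' sites are converted to homozygous for the retained haplotype's allele
#' (minus the planted dropouts). Under a hemizygous deletion the expected
#' sport depth is additionally halved distally; under a G2 mosaic the
#' conversion is incomplete. Depths are negative binomial; site QC
#' metrics are drawn in the nominal pass range of the default hard
#' filters.
#'
#' @param config A [sim_config()].
#' @return List of class `loh_sim` with elements `sites` (a site table as
#'   returned by [read_pair_vcf()], plus `code_wild`/`code_sport`
#'   columns), `truth` (event scaffold, breakpoint, retained haplotype,
#'   dropout and planted-error positions, mechanism, per-site phase of
#'   the event region), and `config`.
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  retained <- if (config$event == "none") NA_character_
              else sample(c("h1", "h2"), 1)
  per_scaffold <- list()
  truth_err <- list()
  dropout_pos <- numeric(0)
  g2_het_pos <- numeric(0)
  phase <- NULL

  for (i in seq_len(nrow(config$scaffolds))) {
    sc <- config$scaffolds$scaffold[i]
    len <- config$scaffolds$length_bp[i]
    n <- config$scaffolds$called_snp[i]
    is_event_sc <- config$event != "none" && sc == config$event_scaffold

    if (is_event_sc) {
      b <- config$breakpoint_bp
      n_dist <- config$distal_snp
      n_prox <- n - n_dist
      pos <- c(sort(sample.int(b, n_prox)),
               b + sort(sample.int(len - b, n_dist)))
      distal <- c(rep(FALSE, n_prox), rep(TRUE, n_dist))
    } else {
      pos <- sort(sample.int(len, n))
      distal <- rep(FALSE, n)
    }
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                  character(1), USE.NAMES = FALSE)

    # wild genotype codes
    code_w <- ifelse(stats::runif(n) < config$het_fraction, 1L, 2L)
    if (is_event_sc) {
      n_d <- config$distal_het - config$distal_dropout
      n_nd <- config$distal_snp - n_d
      is_disc <- plant_event_order(n_d, n_nd, config$gap_cap)
      nd_idx <- which(!is_disc)
      drop_local <- sort(sample(nd_idx, config$distal_dropout))
      code_dist <- integer(config$distal_snp)
      code_dist[is_disc] <- 1L                     # converting het
      code_dist[drop_local] <- 1L                  # dropout het
      code_dist[setdiff(nd_idx, drop_local)] <- 2L # concordant hom-alt
      code_w[distal] <- code_dist
    }

    # phase of het sites: which wild haplotype carries the alt allele
    h1_alt <- stats::runif(n) < 0.5

    # sport codes: start identical, then apply the event
    code_s <- code_w
    if (is_event_sc) {
      d_idx <- which(distal)
      het_d <- d_idx[code_w[d_idx] == 1L]
      drop_global <- d_idx[drop_local]
      convert <- setdiff(het_d, drop_global)
      retained_alt <- if (retained == "h1") h1_alt[convert]
                      else !h1_alt[convert]
      code_s[convert] <- ifelse(retained_alt, 2L, 0L)
      if (config$mechanism == "G2" && config$mosaic_fraction < 1) {
        back <- convert[stats::runif(length(convert)) <
                          (1 - config$mosaic_fraction)]
        code_s[back] <- 1L
        g2_het_pos <- pos[back]
      }
      dropout_pos <- pos[drop_global]
      phase <- tibble::tibble(
        scaffold = sc, pos = pos[d_idx],
        ref = ref[d_idx], alt = alt[d_idx],
        wild_h1_alt = ifelse(code_w[d_idx] == 2L, TRUE, h1_alt[d_idx]),
        wild_h2_alt = ifelse(code_w[d_idx] == 2L, TRUE, !h1_alt[d_idx]))
    }

    # planted genotype-call errors outside the event region
    n_err <- if (sc %in% names(config$error_counts))
      config$error_counts[[sc]] else 0L
    if (n_err > 0) {
      pool <- which(!distal)
      err <- sort(sample(pool, min(n_err, length(pool))))
      code_s[err] <- vapply(code_w[err], function(cw)
        sample(setdiff(0:2, cw), 1), integer(1))
      truth_err[[sc]] <- pos[err]
    }

    # depths and QC metrics
    mu_s <- rep(config$depth_mean_sport, n)
    if (is_event_sc && config$event == "hemizygous_deletion")
      mu_s[distal] <- mu_s[distal] / 2
    per_scaffold[[sc]] <- tibble::tibble(
      scaffold = sc, pos = pos, ref = ref, alt = alt,
      gt_wild = c("0/0", "0/1", "1/1")[code_w + 1L],
      gt_sport = c("0/0", "0/1", "1/1")[code_s + 1L],
      dp_wild = stats::rnbinom(n, mu = config$depth_mean_wild,
                               size = config$depth_dispersion),
      dp_sport = stats::rnbinom(n, mu = mu_s,
                                size = config$depth_dispersion),
      gq_wild = sample(20:99, n, replace = TRUE),
      gq_sport = sample(20:99, n, replace = TRUE),
      QD = round(stats::runif(n, 15, 35), 2),
      MQ = 60.0,
      FS = round(stats::runif(n, 0, 5), 3),
      MQRankSum = round(stats::runif(n, -0.03, 0.03), 3),
      ReadPosRankSum = round(stats::runif(n, -1.2, 1.2), 3),
      SOR = round(stats::runif(n, 0.5, 1.5), 3),
      ClippingRankSum = round(stats::runif(n, -0.25, 0.25), 3),
      code_wild = code_w, code_sport = code_s)
  }
  sites <- dplyr::bind_rows(per_scaffold)
  structure(list(
    sites = sites,
    truth = list(
      event = config$event,
      event_scaffold = if (config$event == "none") NA_character_
                       else config$event_scaffold,
      breakpoint_bp = if (config$event == "none") NA_real_
                      else config$breakpoint_bp,
      retained_hap = retained,
      dropout_pos = dropout_pos,
      g2_het_pos = g2_het_pos,
      error_pos = truth_err,
      mechanism = config$mechanism,
      mosaic_fraction = config$mosaic_fraction,
      phase = phase),
    config = config), class = "loh_sim")
}

#' Phased truth haplotypes of the simulated event region
#'
#' Returns the four true haplotypes over the event region of a
#' simulation: the two wild-type haplotypes (differing at every planted
#' heterozygous site) and the two sport haplotypes, both copies of the
#' retained wild haplotype under copy-neutral LOH. Under a hemizygous
#' deletion the sport carries one physical copy; it is emitted as the
#' retained haplotype duplicated, with `hemizygous = TRUE` recorded. The
#' truth haplotypes reflect the somatic event only — planted genotype
#' errors (dropouts) in the emitted calls deviate from them by design.
#'
#' @param sim A [simulate_pair()] result with `event != "none"`.
#' @return A [phased_region()] with allele bases; attribute
#'   `hemizygous` flags the deletion case.
#' @export
emit_phased_truth <- function(sim) {
  stopifnot(inherits(sim, "loh_sim"))
  ph <- sim$truth$phase
  if (is.null(ph))
    stop("no event region: simulation was run with event = 'none'",
         call. = FALSE)
  allele <- function(is_alt) ifelse(is_alt, ph$alt, ph$ref)
  w1 <- allele(ph$wild_h1_alt)
  w2 <- allele(ph$wild_h2_alt)
  sp <- if (sim$truth$retained_hap == "h1") w1 else w2
  out <- phased_region(ph$pos, wild_h1 = w1, wild_h2 = w2,
                       sport_h1 = sp, sport_h2 = sp)
  attr(out, "hemizygous") <- sim$truth$event == "hemizygous_deletion"
  out
}

#' Daughter-cell genotype classes under G1 vs G2 break-induced replication
#'
#' Models the cell-lineage consequence of the repair timing of a
#' one-ended break repaired from the homologous chromosome. A break in
#' G1 is replicated before repair resolution, so every daughter cell is
#' homozygous distal to the break: one genotype class. A break repaired
#' in G2 produces two daughter lineages at the first division — one
#' heterozygous-distal, one homozygous-distal — and subsequent daughters
#' descend from either lineage with equal probability: two classes at
#' expected frequency 1/2 each.
#'
#' @param mechanism `"G1"` or `"G2"`.
#' @param n_daughters Number of daughter cells (>= 2).
#' @return Character vector of length `n_daughters` with values
#'   `"homozygous_distal"` / `"heterozygous_distal"`.
#' @examples
#' table(simulate_cell_lineage("G2", 100))
#' @export
simulate_cell_lineage <- function(mechanism = c("G1", "G2"),
                                  n_daughters = 2L) {
  mechanism <- match.arg(mechanism)
  stopifnot(n_daughters >= 2)
  if (mechanism == "G1") return(rep("homozygous_distal", n_daughters))
  first <- c("heterozygous_distal", "homozygous_distal")
  c(first, sample(first, n_daughters - 2L, replace = TRUE))
}

#' Write a simulated pair as VCF
#'
#' Emits the simulated callset as VCF 4.2, either one two-sample file or
#' two single-sample files, with GT:DP:GQ genotype fields and the
#' site-level QC metrics in INFO. Output is deterministic: identical
#' simulations produce byte-identical files.
#'
#' @param sim A [simulate_pair()] result.
#' @param path Output VCF path (two-sample mode), or the wild-type path.
#' @param sport_path When given, write two single-sample files instead.
#' @param samples Sample names, default `c("wild", "sport")`.
#' @return Invisibly, the path(s) written.
#' @export
write_pair_vcf <- function(sim, path, sport_path = NULL,
                           samples = c("wild", "sport")) {
  stopifnot(inherits(sim, "loh_sim"))
  s <- sim$sites
  info <- sprintf(
    "QD=%.2f;MQ=%.2f;FS=%.3f;MQRankSum=%.3f;ReadPosRankSum=%.3f;SOR=%.3f;ClippingRankSum=%.3f",
    s$QD, s$MQ, s$FS, s$MQRankSum, s$ReadPosRankSum, s$SOR,
    s$ClippingRankSum)
  header <- function(sample_cols) c(
    "##fileformat=VCFv4.2",
    "##source=lohsport-simulate",
    sprintf("##contig=<ID=%s,length=%d>", sim$config$scaffolds$scaffold,
            sim$config$scaffolds$length_bp),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            INFO_METRICS, INFO_METRICS),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sample_cols), collapse = "\t"))
  fmt <- function(gt, dp, gq) sprintf("%s:%d:%d", gt, dp, gq)
  fixed <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s\tGT:DP:GQ",
                   s$scaffold, as.integer(s$pos), s$ref, s$alt, info)
  if (is.null(sport_path)) {
    writeLines(c(header(samples),
                 paste(fixed, fmt(s$gt_wild, s$dp_wild, s$gq_wild),
                       fmt(s$gt_sport, s$dp_sport, s$gq_sport),
                       sep = "\t")), path)
    invisible(path)
  } else {
    writeLines(c(header(samples[1]),
                 paste(fixed, fmt(s$gt_wild, s$dp_wild, s$gq_wild),
                       sep = "\t")), path)
    writeLines(c(header(samples[2]),
                 paste(fixed, fmt(s$gt_sport, s$dp_sport, s$gq_sport),
                       sep = "\t")), sport_path)
    invisible(c(path, sport_path))
  }
}
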