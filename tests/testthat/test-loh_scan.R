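sites_from_codes <- function(cw, cs, pos = seq_along(cw) * 100) {
  tibble::tibble(scaffold = "chrT", pos = pos,
                 code_wild = as.integer(cw), code_sport = as.integer(cs))
}

test_that("minimal runs seed segments and short runs do not", {
  s <- sites_from_codes(rep(1, 6), c(0, 2, 0, 0, 2, 0))
  seg <- find_loh_segments(s)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 100)
  expect_equal(seg$end, 600)
  expect_equal(seg$n_discordant, 6L)
  expect_equal(seg$consistency, 1)
  # concordant het everywhere: nothing to report
  expect_equal(nrow(find_loh_segments(sites_from_codes(rep(1, 10),
                                                       rep(1, 10)))), 0)
  # four consecutive discordant sites stay below the seed threshold
  expect_equal(nrow(find_loh_segments(sites_from_codes(rep(1, 4),
                                                       rep(0, 4)))), 0)
  # exactly five qualifies by default but not under the strict reading
  five <- sites_from_codes(rep(1, 5), rep(2, 5))
  expect_equal(nrow(find_loh_segments(five)), 1)
  expect_equal(nrow(find_loh_segments(five,
                                      scan_params(strict = TRUE))), 0)
})

test_that("interruptions are tolerated per gap run and counted", {
  # 6 discordant, an interior concordant-het, 6 discordant
  cw <- rep(1, 13)
  cs <- c(rep(0, 6), 1, rep(2, 6))
  seg <- find_loh_segments(sites_from_codes(cw, cs))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_discordant, 12L)
  expect_equal(seg$n_interrupting_het, 1L)
  expect_equal(seg$consistency, 12 / 13)
  # a reverse-discordant site blocks the merge
  cw2 <- c(rep(1, 6), 0, rep(1, 6))
  cs2 <- c(rep(0, 6), 1, rep(2, 6))
  expect_equal(nrow(find_loh_segments(sites_from_codes(cw2, cs2))), 2)
  # a gap longer than max_gap_sites splits the event
  cw3 <- c(rep(1, 6), rep(1, 6), rep(1, 6))
  cs3 <- c(rep(0, 6), rep(1, 6), rep(0, 6))
  expect_equal(nrow(find_loh_segments(sites_from_codes(cw3, cs3))), 2)
  expect_equal(nrow(find_loh_segments(sites_from_codes(cw3, cs3),
                                      scan_params(max_gap_sites = 6))), 1)
})

test_that("unsorted input is rejected", {
  s <- sites_from_codes(rep(1, 5), rep(0, 5), pos = c(1, 2, 3, 10, 4))
  expect_error(find_loh_segments(s), "sorted")
})

test_that("scanner matches the exhaustive oracle on random small inputs", {
  set.seed(101)
  for (trial in 1:200) {
    n <- sample(1:50, 1)
    s <- random_sites(n, p_disc = stats::runif(1, 0.2, 0.9))
    min_run <- sample(1:6, 1)
    max_gap <- sample(0:6, 1)
    got <- find_loh_segments(s, scan_params(min_run, max_gap))
    want <- oracle_loh_segments(s$pos, s$code_wild, s$code_sport,
                                min_run, max_gap)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_discordant, want$n_discordant)
    }
  }
})

test_that("raising min_run never increases the number of segments", {
  set.seed(102)
  for (trial in 1:40) {
    s <- random_sites(80, p_disc = 0.7)
    counts <- vapply(1:8, function(m)
      nrow(find_loh_segments(s, scan_params(min_run = m))), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("fragmented segments are contained in merged ones", {
  set.seed(103)
  for (trial in 1:20) {
    s <- random_sites(100, p_disc = 0.8)
    merged <- find_loh_segments(s, scan_params(max_gap_sites = 5))
    frag <- find_loh_segments(s, scan_params(max_gap_sites = 0))
    if (nrow(frag) == 0) next
    contained <- vapply(seq_len(nrow(frag)), function(i)
      any(merged$start <= frag$start[i] & frag$end[i] <= merged$end),
      logical(1))
    expect_true(all(contained))
    # segments are disjoint and sorted
    if (nrow(merged) > 1) {
      expect_true(all(diff(merged$start) > 0))
      expect_true(all(merged$start[-1] > merged$end[-nrow(merged)]))
    }
  }
})

test_that("transition bracket covers the planted breakpoint", {
  hits <- 0
  for (seed in 1:25) {
    sim <- simulate_pair(small_config(seed))
    segs <- find_loh_segments(sim$sites)
    seg <- segs[which.max(segs$n_discordant), ]
    tr <- locate_transition(sim$sites, seg)
    b <- sim$truth$breakpoint_bp
    expect_lt(tr$upstream_het_pos, tr$first_discordant_pos)
    if (tr$bracket[1] <= b && b <= tr$bracket[2]) hits <- hits + 1
  }
  expect_gte(hits, 24)
})

test_that("a segment at the scaffold start reports no upstream flank", {
  s <- sites_from_codes(rep(1, 6), rep(0, 6))
  seg <- find_loh_segments(s)
  tr <- locate_transition(s, seg)
  expect_true(is.na(tr$upstream_het_pos))
  expect_equal(tr$upstream_label, "scaffold start")
  expect_equal(tr$first_discordant_pos, 100)
})

test_that("false-negative rate is interruptions over span", {
  seg <- tibble::tibble(n_interrupting_het = 36L)
  expect_equal(format_sci(false_negative_rate(seg, 8.6e6)), "4.19E-6")
  seg0 <- tibble::tibble(n_interrupting_het = 0L)
  expect_equal(false_negative_rate(seg0, 1e6), 0)
  for (k in c(1, 7, 19)) {
    segk <- tibble::tibble(n_interrupting_het = k)
    expect_equal(false_negative_rate(segk, 5e5), k / 5e5)
  }
})

test_that("terminal segments optionally extend to the telomere", {
  s <- sites_from_codes(c(1, 1, rep(1, 6)), c(1, 1, rep(0, 6)))
  seg <- find_loh_segments(s, scan_params(extend_to_end = TRUE),
                           scaffold_length = 5000)
  expect_equal(seg$end, 5000)
  expect_equal(seg$start, 300)
  seg2 <- find_loh_segments(s)
  expect_equal(seg2$end, 800)
})
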