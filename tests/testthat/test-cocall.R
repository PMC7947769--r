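# small builder for a single-chromosome genotype matrix
geno <- function(pos, ..., chrom = "chr1") {
  spores <- list(...)
  out <- tibble::tibble(marker = paste0("m", seq_along(pos)), chrom = chrom,
                        pos = pos)
  for (s in 1:4) out[[paste0("spore_", s)]] <- as.integer(spores[[s]])
  out
}

test_that("marker filtering keeps the expected segregation configurations", {
  g <- geno(c(1e4, 2e4, 3e4),
            c(1, 1, 1), c(1, 1, 1), c(0, 1, 0), c(0, 0, 0))
  # totals: 2 (kept), 3 (dropped), 2 (kept)
  kept <- select_informative_markers(g, "disomic")
  expect_equal(kept$marker, c("m1", "m3"))
  expect_equal(attr(kept, "retention"), 2 / 3)
  # tetrasomic: totals 2 and 6 of 8 kept, others dropped
  gt <- geno(c(1e4, 2e4, 3e4),
             c(1, 2, 2), c(1, 2, 2), c(0, 1, 2), c(0, 1, 1))
  keptt <- select_informative_markers(gt, "tetrasomic")
  expect_equal(keptt$marker, c("m1", "m2"))
  # filtering is idempotent and never alters dosages
  twice <- select_informative_markers(kept, "disomic")
  expect_equal(attr(twice, "retention"), 1)     # nothing further to drop
  attr(twice, "retention") <- attr(kept, "retention") <- NULL
  expect_equal(twice, kept)
  # empty result warns rather than errors
  g3 <- geno(c(1e4, 2e4), c(1, 1), c(1, 1), c(1, 1), c(0, 0))
  expect_warning(select_informative_markers(g3, "disomic"), "no informative")
})

test_that("reciprocal two-spore exchanges are called at the right interval", {
  g <- geno(c(1e4, 2e4, 3e4, 6e4, 8e4),
            c(1, 1, 1, 1, 1), c(1, 1, 1, 0, 0),
            c(0, 0, 0, 1, 1), c(0, 0, 0, 0, 0))
  calls <- call_crossovers(g, "disomic")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 3e4)
  expect_equal(calls$end, 6e4)
  expect_equal(sort(c(calls$spore_up, calls$spore_down)), c(2, 3))
  # constant matrix: no calls
  g0 <- geno(c(1e4, 2e4), c(1, 1), c(1, 1), c(0, 0), c(0, 0))
  expect_equal(nrow(call_crossovers(g0, "disomic")), 0)
})

test_that("non-reciprocal dosage changes are logged and skipped", {
  # three spores change: not a clean reciprocal pair
  g <- geno(c(1e4, 2e4), c(1, 0), c(1, 0), c(0, 1), c(0, 0))
  expect_silent(calls <- call_crossovers(g, "disomic"))
  expect_equal(nrow(calls), 0)
  an <- attr(calls, "anomalies")
  expect_equal(nrow(an), 1)
  expect_equal(an$start, 1e4)
})

test_that("close adjacent calls merge below the 10 kb threshold", {
  mk <- function(gap_bp) {
    pos <- c(0, 2000, 2000 + gap_bp, 4000 + gap_bp)
    geno(pos, c(1, 0, 0, 1), c(0, 1, 1, 0), c(1, 1, 1, 1), c(0, 0, 0, 0))
  }
  near <- call_crossovers(mk(5000), "disomic")
  expect_equal(sum(near$status == "observed"), 1)
  expect_equal(sum(near$status == "merged-away"), 1)
  far <- call_crossovers(mk(15000), "disomic")
  expect_equal(sum(far$status == "observed"), 2)
  # threshold is strict: exactly 10 kb apart stays two calls
  at <- call_crossovers(mk(10000), "disomic")
  expect_equal(sum(at$status == "observed"), 2)
})

test_that("run collapsing yields direction-independent surviving counts", {
  # runs of k close calls must survive as ceiling(k/2) either way
  build_run <- function(k, gap = 6000) {
    pos <- seq(0, by = gap, length.out = k + 1)
    # alternate a reciprocal switch between spores 1 and 2 at every interval
    s1 <- rep(c(1L, 0L), length.out = k + 1)
    s2 <- 1L - s1
    geno(pos, s1, s2, rep(1L, k + 1), rep(0L, k + 1))
  }
  for (k in c(2, 3, 5, 6)) {
    calls <- call_crossovers(build_run(k), "disomic")
    expect_equal(sum(calls$status == "observed"), ceiling(k / 2))
    # right-to-left collapse of the same run gives the same surviving count
    rev_calls <- calls[nrow(calls):1, ]
    mid <- rev((calls$start + calls$end) / 2)
    runs <- cumsum(c(TRUE, abs(diff(mid)) >= 10000))
    surv <- sum(ceiling(table(runs) / 2))
    expect_equal(sum(calls$status == "observed"), unname(surv))
  }
})

test_that("noise-free recall is perfect for well-separated crossovers", {
  sc <- sim_scenario("disomic", r = 0.015, n = 40, seed = 71)
  fx <- make_genotype_matrices(sc, n_markers = 50, chrom_length_bp = 2e6)
  calls <- purrr::imap_dfr(fx$matrices, function(m, i) {
    call_crossovers(select_informative_markers(m, "disomic"), "disomic",
                    tetrad = i)
  })
  # truth intervals, with midpoint separation within each tetrad
  truth <- fx$truth |>
    dplyr::group_by(.data$tetrad) |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2,
                  sep = pmin(abs(.data$mid - dplyr::lag(.data$mid, default = -Inf)),
                             abs(dplyr::lead(.data$mid, default = Inf) - .data$mid))) |>
    dplyr::ungroup()
  well_sep <- truth[truth$sep >= 10000, ]
  # every well-separated true crossover is recovered (as observed or the
  # survivor of its merged pair)
  hit <- purrr::pmap_lgl(well_sep, function(tetrad, start, end, ...) {
    any(calls$tetrad == tetrad & calls$start == start & calls$end == end)
  })
  expect_true(all(hit))
  # and no false calls: every call corresponds to a true crossover
  false_call <- purrr::pmap_lgl(calls, function(tetrad, start, end, ...) {
    !any(fx$truth$tetrad == tetrad & fx$truth$start == start &
           fx$truth$end == end)
  })
  expect_equal(sum(false_call), 0)
})

test_that("tetrasomic bundles are called through visible reciprocal changes", {
  sc <- sim_scenario("tetrasomic", r = 0.02, n = 30, seed = 81)
  fx <- make_genotype_matrices(sc, n_markers = 40, chrom_length_bp = 2e6)
  calls <- purrr::imap_dfr(fx$matrices, function(m, i) {
    call_crossovers(select_informative_markers(m, "tetrasomic"), "tetrasomic",
                    tetrad = i)
  })
  vis <- fx$truth[fx$truth$visible, ]
  expect_equal(nrow(calls), nrow(vis))
  expect_equal(calls$start, vis$start)
})

test_that("crossover summaries average per meiosis and keep expected separate", {
  calls <- tibble::tibble(
    tetrad = rep(1:5, times = c(2, 3, 1, 2, 2)),
    chrom = "chr1",
    status = "observed")
  s <- summarize_crossovers(calls, n_tetrads = 5)
  expect_equal(s$co_observed_mean, 2)
  expect_equal(nrow(summarize_crossovers(calls[0, ])), 0)
  exp_tbl <- tibble::tibble(chrom = "chr1", co_expected = 0.44)
  s2 <- summarize_crossovers(calls, n_tetrads = 5, expected = exp_tbl)
  expect_equal(s2$co_expected, 0.44)
  expect_false("co_combined" %in% names(s2))
  s3 <- summarize_crossovers(calls, n_tetrads = 5, expected = exp_tbl,
                             combine = TRUE)
  expect_equal(s3$co_combined, 2.44)
})
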