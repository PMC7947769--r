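#' Run an end-to-end analysis pipeline
#'
#' Dispatches one of the package's analyses from a configuration list (or a
#' YAML file with the same fields) and writes result tables plus a
#' reproducibility manifest to an output directory. Supported `kind`
#' values:
#'
#' * `"simulate"` — simulate a two-marker segregating population
#'   (`ploidy`, `r`, `alpha`, `coincidence`, `n`) and write its tetrad
#'   class-count table.
#' * `"estimate-tetrad"` — read a tetrad count table (`input`) and write
#'   double-reduction and recombination-fraction estimates.
#' * `"estimate-co"` — read a five-class count table and write per-interval
#'   crossover-probability estimates and per-chromosome expected totals.
#' * `"interference"` — read a three-marker count table and write
#'   coincidence coefficients with simulation-based p-values
#'   (`n_sim`, `ploidy`, `n`, `r` for the null scenario default to values
#'   extracted from the data).
#' * `"call-co"` — read one or more genotype matrix TSVs (`input` may be a
#'   vector), filter markers, call crossovers (`min_spacing_bp`), and write
#'   a BED-like call table plus a per-chromosome summary.
#' * `"pipeline"` — simulate-then-estimate round trip (tetrad analysis).
#'
#' All stochastic stages honour `config$seed`; rerunning with the same
#' configuration yields byte-identical tables.
#'
#' @param config A named list, or path to a YAML file. Common fields:
#'   `kind`, `out_dir`, `seed`; see above for per-kind fields.
#' @return Invisibly, a named list of written file paths.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' run_pipeline(list(kind = "simulate", out_dir = dir, ploidy = "tetrasomic",
#'                   r = 0.2, alpha = 0.1, n = 500, seed = 7))
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$kind)) stop("config must name an analysis `kind`.",
                                 call. = FALSE)
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)

  paths <- switch(
    config$kind,
    "simulate" = stage_simulate(config, out_dir),
    "estimate-tetrad" = stage_estimate_tetrad(config, out_dir),
    "estimate-co" = stage_estimate_co(config, out_dir),
    "interference" = stage_interference(config, out_dir),
    "call-co" = stage_call_co(config, out_dir),
    "pipeline" = {
      cfg1 <- config; cfg1$kind <- "simulate"
      p1 <- stage_simulate(cfg1, out_dir)
      cfg2 <- config; cfg2$kind <- "estimate-tetrad"
      cfg2$input <- p1$counts
      p2 <- stage_estimate_tetrad(cfg2, out_dir)
      c(p1, p2)
    },
    stop(sprintf("unknown analysis kind: '%s'", config$kind), call. = FALSE)
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  write_manifest(paths$manifest, config, seed)
  invisible(paths)
}

# simulate a two-marker population and write tetrad class counts
stage_simulate <- function(config, out_dir) {
  ploidy <- config$ploidy %||% "tetrasomic"
  sc <- sim_scenario(ploidy, r = config$r %||% 0.2,
                     alpha = config$alpha %||% 0,
                     coincidence = config$coincidence %||% 1,
                     n = config$n %||% 1000)
  counts <- simulate_tetrad_counts(sc)
  path <- file.path(out_dir, "tetrad_counts.tsv")
  readr::write_tsv(counts, path, progress = FALSE)
  list(counts = path)
}

#' Simulate a two-marker population and tabulate its tetrad class counts
#'
#' Convenience wrapper joining the gametogenesis samplers to the four
#' fluorescent phenotype classes: spores are classified Y (both dominant
#' alleles), G (proximal only), R (distal only) or B (neither).
#'
#' @param scenario A one-interval [sim_scenario()]; `n` counts spores
#'   (disomic tetrads contribute 4 each; `n` is rounded up accordingly).
#' @return A one-row tibble with columns `population`, `n_y`, `n_g`,
#'   `n_r`, `n_b`.
#' @examples
#' simulate_tetrad_counts(sim_scenario("tetrasomic", r = 0.2, alpha = 0.1,
#'                                     n = 400, seed = 2))
#' @export
simulate_tetrad_counts <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (length(scenario$r) != 1) {
    stop("tetrad class counts need a single marker interval.", call. = FALSE)
  }
  if (scenario$ploidy == "disomic") {
    sc <- scenario
    sc$n <- ceiling(scenario$n / 4)
    sim <- sim_diploid_tetrads(sc)
    car1 <- sim$spores$L1 > 0
    car2 <- sim$spores$L2 > 0
  } else {
    g <- sim_tetraploid_gametes(scenario)
    car1 <- g$L1 > 0
    car2 <- g$L2 > 0
  }
  tibble::tibble(
    population = "sim",
    n_y = sum(car1 & car2), n_g = sum(car1 & !car2),
    n_r = sum(!car1 & car2), n_b = sum(!car1 & !car2)
  )
}

stage_estimate_tetrad <- function(config, out_dir) {
  counts <- read_count_table(config$input, "tetrad")
  ploidy <- config$ploidy %||% "tetrasomic"
  est <- est_recombination(counts, ploidy = ploidy)
  if (ploidy == "tetrasomic") {
    est <- dplyr::bind_cols(
      est,
      test_segregation_neutrality(counts, "tetrasomic")[
        c("carrier_frac", "statistic", "p_value")])
  }
  path <- file.path(out_dir, "estimates.tsv")
  readr::write_tsv(est, path, progress = FALSE)
  list(estimates = path)
}

stage_estimate_co <- function(config, out_dir) {
  counts <- read_count_table(config$input, "co")
  est <- est_co_probability(counts)
  p1 <- file.path(out_dir, "co_probabilities.tsv")
  readr::write_tsv(est, p1, progress = FALSE)
  tot <- expected_crossovers(dplyr::rename(est, p_se = "p_se"))
  p2 <- file.path(out_dir, "co_expected.tsv")
  readr::write_tsv(tot, p2, progress = FALSE)
  list(co_probabilities = p1, co_expected = p2)
}

stage_interference <- function(config, out_dir) {
  counts <- read_count_table(config$input, "three_marker")
  ploidy <- config$ploidy %||% "disomic"
  n <- sum(counts$count)
  if (ploidy == "disomic") {
    obs <- cc_haploid(counts)
    r1 <- obs$r_ab; r2 <- obs$r_bc; alpha <- 0
  } else {
    obs <- cc_tetraploid(counts)
    r1 <- obs$r1_hat; r2 <- obs$r2_hat; alpha <- obs$alpha_hat
  }
  sc <- sim_scenario(ploidy, r = c(min(r1, 0.749), min(r2, 0.749)),
                     alpha = alpha, n = n)
  test <- cc_null_test(obs, sc, n_sim = config$n_sim %||% 1000,
                       seed = config$seed %||% 1L)
  path <- file.path(out_dir, "interference.tsv")
  readr::write_tsv(tibble::as_tibble(test), path, progress = FALSE)
  list(interference = path)
}

stage_call_co <- function(config, out_dir) {
  ploidy <- config$ploidy %||% "disomic"
  spacing <- config$min_spacing_bp %||% 10000
  inputs <- config$input
  calls <- purrr::imap_dfr(inputs, function(p, i) {
    g <- read_genotype_matrix(p)
    g <- select_informative_markers(g, ploidy)
    call_crossovers(g, ploidy, min_spacing_bp = spacing, tetrad = i)
  })
  p1 <- file.path(out_dir, "co_calls.bed.tsv")
  write_co_calls(calls, p1)
  p2 <- file.path(out_dir, "co_summary.tsv")
  readr::write_tsv(summarize_crossovers(calls, n_tetrads = length(inputs)),
                   p2, progress = FALSE)
  list(co_calls = p1, co_summary = p2)
}
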