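#' Filter a genotype matrix to informative markers
#'
#' Keeps markers whose summed allele dosage across the four spores of a
#' tetrad matches the expected segregation configuration: 2 of 4 for
#' disomic tetrads (haploid spores, 2:2 allele configuration), 2 or 6 of 8
#' for tetrasomic tetrads (diploid spores, 2:6 or 6:2 configuration).
#' Markers deviating from these totals (genotyping errors, gene-conversion
#' tracts, structural artefacts) are dropped before crossover calling.
#' Filtering never alters dosages and is idempotent.
#'
#' @param geno A genotype matrix tibble with columns `marker`, `chrom`,
#'   `pos`, `spore_1` ... `spore_4` (e.g. from [make_genotype_matrices()]).
#' @param ploidy `"disomic"` (0/1 dosages) or `"tetrasomic"` (0-2 dosages).
#' @return The filtered tibble, with attribute `retention` (fraction of
#'   markers kept). An empty result triggers a warning, not an error.
#' @examples
#' g <- tibble::tibble(marker = "m1", chrom = "chr1", pos = 100L,
#'                     spore_1 = 1L, spore_2 = 1L, spore_3 = 0L, spore_4 = 0L)
#' select_informative_markers(g, "disomic")
#' @export
select_informative_markers <- function(geno,
                                       ploidy = c("disomic", "tetrasomic")) {
  ploidy <- match.arg(ploidy)
  geno <- check_geno(geno, ploidy)
  tot <- geno$spore_1 + geno$spore_2 + geno$spore_3 + geno$spore_4
  keep <- if (ploidy == "disomic") tot == 2L else tot %in% c(2L, 6L)
  out <- geno[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no informative markers retained.", call. = FALSE)
  }
  attr(out, "retention") <- if (nrow(geno)) mean(keep) else NA_real_
  out
}

check_geno <- function(geno, ploidy) {
  geno <- tibble::as_tibble(geno)
  need <- c("marker", "chrom", "pos", paste0("spore_", 1:4))
  if (!all(need %in% names(geno))) {
    stop("genotype matrix must have columns ",
         paste(setdiff(need, names(geno)), collapse = ", "), ".",
         call. = FALSE)
  }
  dmax <- if (ploidy == "disomic") 1L else 2L
  dos <- as.matrix(geno[paste0("spore_", 1:4)])
  if (any(dos < 0 | dos > dmax)) {
    stop(sprintf("dosages must lie in [0, %d] for %s spores.", dmax, ploidy),
         call. = FALSE)
  }
  bad <- geno |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(bad$ok)) {
    stop("marker positions must be strictly increasing within a chromosome.",
         call. = FALSE)
  }
  geno
}

#' Call crossovers from a filtered tetrad genotype matrix
#'
#' Scans adjacent informative markers of one tetrad for reciprocal
#' exchanges. A crossover is called in an interval where exactly two spores
#' change dosage in complementary directions (one +1, one -1) while the
#' other two are unchanged — for disomic tetrads this is the classic
#' two-spore reciprocal switch; for tetrasomic tetrads it is the
#' phase-inferable case. Dosage-change patterns that are not a clean
#' reciprocal pair are skipped and logged as anomalies (attribute
#' `anomalies`), never raised as errors. Adjacent calls on the same
#' chromosome whose interval midpoints are closer than `min_spacing_bp` are
#' then collapsed: calls are grouped into runs of close neighbours and each
#' run is merged pairwise left to right, the leftmost call of each pair
#' surviving (`status = "observed"`) and the other marked
#' `"merged-away"` — a determinisation whose surviving count is the same
#' whether runs are collapsed from the left or from the right.
#'
#' @param geno A genotype matrix tibble for one tetrad, normally already
#'   passed through [select_informative_markers()]. At least 2 markers per
#'   chromosome.
#' @param ploidy `"disomic"` or `"tetrasomic"`.
#' @param min_spacing_bp Merge threshold in bp (default 10000): adjacent
#'   calls separated by less than this are collapsed.
#' @param tetrad Optional tetrad identifier carried into the output.
#' @return A tibble of calls sorted by position: `chrom`, `start`, `end`
#'   (0-based half-open flanking-marker interval), `tetrad`, `spore_up`
#'   (dosage gain), `spore_down` (dosage loss), `status`
#'   (`"observed"`/`"merged-away"`). Attribute `anomalies` lists skipped
#'   non-reciprocal intervals.
#' @examples
#' sc <- sim_scenario("disomic", r = 0.05, n = 1, seed = 4)
#' fx <- make_genotype_matrices(sc, n_markers = 30, chrom_length_bp = 3e5)
#' call_crossovers(fx$matrices[[1]], "disomic")
#' @export
call_crossovers <- function(geno, ploidy = c("disomic", "tetrasomic"),
                            min_spacing_bp = 10000, tetrad = 1L) {
  ploidy <- match.arg(ploidy)
  geno <- check_geno(geno, ploidy)
  empty <- tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), tetrad = integer(0),
                          spore_up = integer(0), spore_down = integer(0),
                          status = character(0))
  anomalies <- list()
  calls <- list()
  for (ch in unique(geno$chrom)) {
    g <- geno[geno$chrom == ch, ]
    if (nrow(g) < 2) {
      stop(sprintf("chromosome %s has fewer than 2 markers.", ch),
           call. = FALSE)
    }
    dos <- as.matrix(g[paste0("spore_", 1:4)])
    d <- diff(dos)                                # intervals x 4
    for (k in seq_len(nrow(d))) {
      dk <- d[k, ]
      if (all(dk == 0L)) next
      up <- unname(which(dk == 1L)); down <- unname(which(dk == -1L))
      if (length(up) == 1 && length(down) == 1 && sum(dk != 0L) == 2) {
        calls[[length(calls) + 1]] <- tibble::tibble(
          chrom = ch, start = g$pos[k], end = g$pos[k + 1],
          tetrad = tetrad, spore_up = up, spore_down = down)
      } else {
        anomalies[[length(anomalies) + 1]] <- tibble::tibble(
          chrom = ch, start = g$pos[k], end = g$pos[k + 1], tetrad = tetrad,
          pattern = paste(dk, collapse = "/"))
      }
    }
  }
  out <- if (length(calls)) dplyr::bind_rows(calls) else empty
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out <- merge_close_calls(out, min_spacing_bp)
  attr(out, "anomalies") <- if (length(anomalies)) {
    dplyr::bind_rows(anomalies)
  } else NULL
  out
}

# collapse runs of close calls pairwise left-to-right (midpoint gaps)
merge_close_calls <- function(calls, min_spacing_bp) {
  if (nrow(calls) == 0) {
    calls$status <- character(0)
    return(calls)
  }
  calls$status <- "observed"
  for (ch in unique(calls$chrom)) {
    i <- which(calls$chrom == ch)
    if (length(i) < 2) next
    mid <- (calls$start[i] + calls$end[i]) / 2
    close <- diff(mid) < min_spacing_bp
    run_id <- cumsum(c(TRUE, !close))
    for (rid in unique(run_id)) {
      members <- i[run_id == rid]
      if (length(members) < 2) next
      drop <- members[seq_along(members) %% 2 == 0]  # 2nd, 4th, ... of run
      calls$status[drop] <- "merged-away"
    }
  }
  calls
}

#' Summarise crossover calls per chromosome
#'
#' Computes the mean number of observed (surviving) crossovers per meiosis
#' per chromosome across tetrads. If per-interval expected crossover
#' contributions are supplied (from [est_co_probability()] /
#' [expected_crossovers()], covering phase-ambiguous regions that direct
#' calling cannot see), observed and estimated totals are reported in
#' separate columns and only summed into a `co_combined` column when
#' `combine = TRUE`.
#'
#' @param calls A tibble of crossover calls (rows of [call_crossovers()]
#'   output across tetrads, with `tetrad`, `chrom` and `status` columns).
#' @param n_tetrads Number of tetrads assayed (tetrads with zero calls are
#'   invisible in `calls`); defaults to the number of distinct `tetrad`
#'   values.
#' @param expected Optional tibble with `chrom` and `co_expected` columns.
#' @param combine If `TRUE`, adds `co_combined = co_observed_mean +
#'   co_expected`.
#' @return A tibble with one row per chromosome: `chrom`, `n_tetrads`,
#'   `co_observed_mean`, and when supplied `co_expected` (and
#'   `co_combined`).
#' @examples
#' calls <- tibble::tibble(tetrad = 1:5, chrom = "chr1", status = "observed")
#' summarize_crossovers(calls)
#' @export
summarize_crossovers <- function(calls, n_tetrads = NULL, expected = NULL,
                                 combine = FALSE) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) {
    out <- tibble::tibble(chrom = character(0), n_tetrads = integer(0),
                          co_observed_mean = numeric(0))
    return(out)
  }
  n_tetrads <- n_tetrads %||% dplyr::n_distinct(calls$tetrad)
  out <- calls |>
    dplyr::filter(.data$status == "observed") |>
    dplyr::count(.data$chrom, name = "n_obs") |>
    dplyr::mutate(n_tetrads = n_tetrads,
                  co_observed_mean = .data$n_obs / n_tetrads) |>
    dplyr::select("chrom", "n_tetrads", "co_observed_mean")
  if (!is.null(expected)) {
    out <- dplyr::left_join(out, tibble::as_tibble(expected)[c("chrom", "co_expected")],
                            by = "chrom")
    if (combine) {
      out$co_combined <- out$co_observed_mean + out$co_expected
    }
  }
  out
}
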