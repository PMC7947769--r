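#' Fabricate tetrad genotype matrices with a known crossover registry
#'
#' Simulates spore-by-marker allele-dosage matrices for crossover-calling
#' experiments, together with the ground-truth registry of placed
#' crossovers. Disomic tetrads use the four-strand model of
#' [sim_diploid_tetrads()] (haploid spores, 0/1 dosages, 2:2 segregation at
#' every marker). Tetrasomic tetrads use a mechanistic eight-chromatid
#' bundle: per interval a crossover occurs with probability \eqn{2 r_k}
#' between one chromatid currently carrying the dosage-1 haplotype and one
#' carrying the alternative, the four homolog centromeres then disjoin two
#' by two at meiosis I and sister chromatids separate at meiosis II, so
#' every tetrad satisfies the 2:6 (simplex) or 6:2 (triplex) total-dosage
#' configuration and double reduction at distal markers is emergent (at
#' most 1/6) rather than dialled in.
#'
#' @param scenario A [sim_scenario()]; `scenario$n` is the number of
#'   tetrads. `scenario$r` gives per-interval recombination fractions: a
#'   scalar is recycled to all `n_markers - 1` intervals, otherwise the
#'   length must be `n_markers - 1`.
#' @param n_markers Number of marker sites (at least 2).
#' @param chrom_length_bp Chromosome length in bp; marker positions are
#'   drawn uniformly (sorted, deduplicated) unless `scenario$positions`
#'   supplies them.
#' @param noise Per-marker, per-spore symmetric genotyping error rate:
#'   dosages are perturbed by ±1 within ploidy bounds with this
#'   probability.
#' @param parent_config Tetrasomic only: `"simplex"` (one carrier homolog,
#'   2:6 totals) or `"triplex"` (three carrier homologs, 6:2 totals).
#' @param chrom Chromosome label used in outputs.
#' @return A list with `matrices` (list of per-tetrad genotype tibbles with
#'   columns `marker`, `chrom`, `pos`, `spore_1` ... `spore_4`) and `truth`
#'   (BED-like tibble of placed crossovers: `chrom`, `start`, `end`
#'   (0-based half-open flanking-marker interval), `tetrad`, `spore_a`,
#'   `spore_b`, `visible` — `FALSE` when both exchanged chromatids landed
#'   in the same spore and the exchange cannot show in dosages).
#' @examples
#' sc <- sim_scenario("disomic", r = 0.01, n = 2, seed = 1)
#' fx <- make_genotype_matrices(sc, n_markers = 20, chrom_length_bp = 2e5)
#' @export
make_genotype_matrices <- function(scenario, n_markers, chrom_length_bp,
                                   noise = 0,
                                   parent_config = c("simplex", "triplex"),
                                   chrom = "chr1") {
  stopifnot(inherits(scenario, "sim_scenario"))
  parent_config <- match.arg(parent_config)
  if (n_markers < 2) stop("`n_markers` must be at least 2.", call. = FALSE)
  check_range(noise, "noise", 0, 1)
  if (!is.null(scenario$seed)) set.seed(scenario$seed)

  pos <- scenario$positions
  if (is.null(pos)) {
    pos <- sort(unique(round(stats::runif(n_markers, 1, chrom_length_bp))))
    while (length(pos) < n_markers) {
      pos <- sort(unique(c(pos, round(stats::runif(
        n_markers - length(pos), 1, chrom_length_bp)))))
    }
  }
  if (any(diff(pos) <= 0)) {
    stop("marker positions must be strictly increasing.", call. = FALSE)
  }
  K <- n_markers - 1
  r <- scenario$r
  if (length(r) == 1) r <- rep(r, K)
  if (length(r) != K) {
    stop("`scenario$r` must be scalar or have one entry per marker interval.",
         call. = FALSE)
  }

  if (scenario$ploidy == "disomic") {
    sim <- sim_disomic_bundle(scenario$n, r, scenario$coincidence)
  } else {
    sim <- sim_tetrasomic_bundle(scenario$n, r, parent_config)
  }

  dmax <- if (scenario$ploidy == "disomic") 1L else 2L
  matrices <- lapply(seq_len(scenario$n), function(t) {
    dos <- sim$dosage[[t]]                    # markers x 4
    if (noise > 0) {
      flip <- matrix(stats::runif(length(dos)) < noise, nrow(dos), 4)
      dir <- matrix(sample(c(-1L, 1L), length(dos), replace = TRUE),
                    nrow(dos), 4)
      prop <- dos + flip * dir
      oob <- prop < 0L | prop > dmax          # reflect at the dosage bounds
      prop[oob] <- dos[oob] - (flip * dir)[oob]
      dos <- prop
    }
    out <- tibble::tibble(marker = paste0("m", seq_len(n_markers)),
                          chrom = chrom, pos = pos)
    for (s in 1:4) out[[paste0("spore_", s)]] <- as.integer(dos[, s])
    out
  })
  truth <- sim$truth
  if (nrow(truth)) {
    truth$chrom <- chrom
    truth$start <- pos[truth$interval]
    truth$end <- pos[truth$interval + 1]
  } else {
    truth$chrom <- character(0); truth$start <- truth$end <- integer(0)
  }
  truth <- truth[, c("chrom", "start", "end", "tetrad", "spore_a", "spore_b",
                     "visible")]
  list(matrices = matrices, truth = truth)
}

# four-strand disomic bundle reusing the tetrad sampler
sim_disomic_bundle <- function(n, r, coincidence) {
  sc <- sim_scenario("disomic", r = r, coincidence = coincidence, n = n)
  sim <- sim_diploid_tetrads(sc)
  L <- length(r) + 1
  cols <- paste0("L", seq_len(L))
  dosage <- lapply(seq_len(n), function(t) {
    sp <- sim$spores[sim$spores$tetrad == t, cols]
    t(as.matrix(sp))                      # markers x 4
  })
  truth <- sim$crossovers
  truth$visible <- TRUE
  list(dosage = dosage, truth = truth)
}

# mechanistic eight-chromatid tetrasomic bundle
sim_tetrasomic_bundle <- function(n, r, parent_config) {
  K <- length(r)
  L <- K + 1
  if (any(2 * r > 1)) {
    stop("single-crossover bundle model requires r <= 0.5 per interval.",
         call. = FALSE)
  }
  n_car <- if (parent_config == "simplex") 2L else 6L
  dosage <- vector("list", n)
  reg <- list()
  for (t in seq_len(n)) {
    # chromatid c belongs to homolog ceiling(c/2); homolog 1 (and for
    # triplex also 2, 3) carries the focal allele
    car0 <- if (parent_config == "simplex") c(1L, 1L, rep(0L, 6)) else
      c(rep(1L, 6), 0L, 0L)
    A <- matrix(0L, 8, L)
    A[, 1] <- car0
    cur <- car0
    for (k in seq_len(K)) {
      if (stats::runif(1) < 2 * r[k]) {
        i <- sample(which(cur == 1L), 1)
        j <- sample(which(cur == 0L), 1)
        cur[c(i, j)] <- cur[c(j, i)]
        reg[[length(reg) + 1]] <- list(tetrad = t, interval = k,
                                       chrom_a = i, chrom_b = j)
      }
      A[, k + 1] <- cur
    }
    # meiosis I: homolog centromeres disjoin 2|2; meiosis II: sisters split
    cfg <- sample(1:3, 1)
    poles <- switch(cfg, list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                    list(c(1, 4), c(2, 3)))
    spore_of <- integer(8)
    s <- 1L
    for (pole in poles) {
      # each pole: 2 homologs x 2 chromatids; each spore takes one
      # chromatid of each homolog
      h1 <- (pole[1] - 1) * 2 + 1:2
      h2 <- (pole[2] - 1) * 2 + 1:2
      o1 <- sample(h1); o2 <- sample(h2)
      spore_of[c(o1[1], o2[1])] <- s
      spore_of[c(o1[2], o2[2])] <- s + 1L
      s <- s + 2L
    }
    dos <- matrix(0L, L, 4)
    for (sp in 1:4) {
      dos[, sp] <- colSums(A[spore_of == sp, , drop = FALSE])
    }
    dosage[[t]] <- dos
    # visibility: exchange shows in dosages iff the two chromatids went to
    # different spores
    for (ii in seq_along(reg)) {
      if (reg[[ii]]$tetrad == t && is.null(reg[[ii]]$visible)) {
        reg[[ii]]$visible <-
          spore_of[reg[[ii]]$chrom_a] != spore_of[reg[[ii]]$chrom_b]
        reg[[ii]]$spore_a <- min(spore_of[reg[[ii]]$chrom_a],
                                 spore_of[reg[[ii]]$chrom_b])
        reg[[ii]]$spore_b <- max(spore_of[reg[[ii]]$chrom_a],
                                 spore_of[reg[[ii]]$chrom_b])
      }
    }
  }
  truth <- if (length(reg)) {
    tibble::tibble(
      tetrad = purrr::map_int(reg, ~ as.integer(.x$tetrad)),
      interval = purrr::map_int(reg, ~ as.integer(.x$interval)),
      spore_a = purrr::map_int(reg, ~ as.integer(.x$spore_a)),
      spore_b = purrr::map_int(reg, ~ as.integer(.x$spore_b)),
      visible = purrr::map_lgl(reg, "visible")
    )
  } else {
    tibble::tibble(tetrad = integer(0), interval = integer(0),
                   spore_a = integer(0), spore_b = integer(0),
                   visible = logical(0))
  }
  list(dosage = dosage, truth = truth)
}
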