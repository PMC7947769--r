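#' Define a gametogenesis simulation scenario
#'
#' Bundles the parameters of one simulated cross: ploidy, meiotic pairing
#' mode, per-interval recombination fractions, double reduction,
#' interference level, and population size. The scenario object is consumed
#' by [sim_diploid_tetrads()], [sim_tetraploid_gametes()],
#' [sim_segregant_counts()] and [make_genotype_matrices()].
#'
#' @param ploidy `"disomic"` (diploid parent, haploid gametes) or
#'   `"tetrasomic"` (autotetraploid parent, diploid gametes).
#' @param r Numeric vector of recombination fractions, one per marker
#'   interval (so `length(r) + 1` loci). Admissible range \[0, 0.5\]
#'   disomic, \[0, 0.75\] tetrasomic.
#' @param alpha Coefficient of double reduction at the proximal locus
#'   (tetrasomic quadrivalent pairing only; must be 0 otherwise). The
#'   simulator treats `alpha` as a calibrated input dial so that estimator
#'   validation has exact target parameters; mechanistic chromatid-level
#'   simulation with emergent double reduction is available through
#'   [make_genotype_matrices()].
#' @param coincidence Scale on simultaneous recombination in adjacent
#'   intervals (1 = independence). Applied between each pair of adjacent
#'   intervals.
#' @param pairing `"quadrivalent"`, `"bivalent"`, or a numeric weight in
#'   \[0, 1\] giving the per-meiosis probability of quadrivalent pairing
#'   (tetrasomic only).
#' @param n Population size (tetrads or gametes, depending on the sampler).
#' @param positions Optional strictly increasing physical positions (bp) of
#'   the loci.
#' @param seed Optional RNG seed recorded in the scenario; samplers call
#'   `set.seed(seed)` when it is non-`NULL`.
#' @return An object of class `sim_scenario` (a named list).
#' @examples
#' sim_scenario("tetrasomic", r = 0.2, alpha = 0.1, n = 1000, seed = 1)
#' @export
sim_scenario <- function(ploidy = c("disomic", "tetrasomic"),
                         r, alpha = 0, coincidence = 1,
                         pairing = "quadrivalent",
                         n = 1000, positions = NULL, seed = NULL) {
  ploidy <- match.arg(ploidy)
  r_max <- if (ploidy == "disomic") 0.5 else 0.75
  check_range(r, "r", 0, r_max)
  check_range(alpha, "alpha", 0, 1)
  if (is.numeric(pairing)) check_range(pairing, "pairing", 0, 1)
  else pairing <- match.arg(pairing, c("quadrivalent", "bivalent"))
  if (!is.numeric(coincidence) || coincidence < 0) {
    stop("`coincidence` must be non-negative.", call. = FALSE)
  }
  if (n < 1) stop("`n` must be at least 1.", call. = FALSE)
  if (ploidy == "disomic" && alpha != 0) {
    stop("`alpha` must be 0 for a disomic scenario.", call. = FALSE)
  }
  if (identical(pairing, "bivalent") && alpha != 0) {
    stop("double reduction requires quadrivalent pairing: `alpha` must be 0 ",
         "under bivalent pairing.", call. = FALSE)
  }
  if (!is.null(positions)) {
    if (length(positions) != length(r) + 1 || any(diff(positions) <= 0)) {
      stop("`positions` must be strictly increasing with one entry per locus.",
           call. = FALSE)
    }
  }
  structure(list(ploidy = ploidy, r = r, alpha = alpha,
                 coincidence = coincidence, pairing = pairing, n = n,
                 positions = positions, seed = seed),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario> ", x$ploidy,
      if (x$ploidy == "tetrasomic") paste0(" (", x$pairing, " pairing)"), "\n",
      "  loci: ", length(x$r) + 1,
      ", r = ", paste(signif(x$r, 4), collapse = ", "),
      ", alpha = ", x$alpha,
      ", coincidence = ", x$coincidence,
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Sample multinomial class counts
#'
#' Reproducible multinomial sampler behind all parameter-recovery
#' experiments: draws `n_rep` populations of size `n` from a probability
#' vector over phenotype classes.
#'
#' @param probs Probability vector (must sum to 1 within 1e-8); names, if
#'   present, become class labels.
#' @param n Population size per draw.
#' @param n_rep Number of independent draws.
#' @param seed Optional seed (`set.seed` is called when non-`NULL`).
#' @return A tibble with columns `rep`, `class`, `count`.
#' @examples
#' sim_class_counts(c(Y = 0.39, G = 0.085, R = 0.0677, B = 0.4573), n = 100, seed = 1)
#' @export
sim_class_counts <- function(probs, n, n_rep = 1, seed = NULL) {
  if (!is.numeric(probs) || any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop("`probs` must be non-negative and sum to 1.", call. = FALSE)
  }
  if (n < 1) stop("`n` must be at least 1.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- stats::rmultinom(n_rep, size = n, prob = probs)
  labels <- names(probs) %||% as.character(seq_along(probs))
  tibble::tibble(
    rep = rep(seq_len(n_rep), each = length(probs)),
    class = rep(labels, times = n_rep),
    count = as.integer(m)
  )
}

# Markov chain over per-interval event indicators with adjacent-pair
# coupling: P(E_k) = m[k], P(E_k & E_{k+1}) = coincidence * m[k] * m[k+1].
# Returns an n x K 0/1 matrix. Used for crossover indicators (disomic,
# m = 2r) and chromatid switch indicators (tetrasomic, m = r).
coupled_event_chain <- function(n, m, coincidence) {
  K <- length(m)
  E <- matrix(0L, n, K)
  E[, 1] <- as.integer(stats::runif(n) < m[1])
  if (K > 1) for (k in 2:K) {
    p_given1 <- if (m[k - 1] > 0) coincidence * m[k] else m[k]
    p_given0 <- if (m[k - 1] < 1) {
      m[k] * (1 - coincidence * m[k - 1]) / (1 - m[k - 1])
    } else m[k]
    if (p_given1 > 1 + 1e-12 || p_given0 > 1 + 1e-12 || p_given0 < -1e-12) {
      stop("infeasible coincidence for the given recombination fractions.",
           call. = FALSE)
    }
    p <- ifelse(E[, k - 1] == 1L, p_given1, p_given0)
    E[, k] <- as.integer(stats::runif(n) < p)
  }
  E
}

#' Simulate diploid tetrads through a four-strand meiosis model
#'
#' Simulates tetrads of a heterozygous diploid (`ABC.../abc...` coupling
#' parent) with a four-strand bundle per meiosis: in each marker interval a
#' single crossover occurs with probability \eqn{2r_k} (so that the
#' recombinant-spore fraction equals \eqn{r_k}) and exchanges material
#' between one chromatid of each current allelic origin, making every
#' registered crossover a genotype-visible reciprocal exchange. Crossover
#' occurrence in adjacent intervals is coupled so that the spore-level
#' double-recombination rate equals `coincidence * r_k * r_{k+1}`.
#'
#' @param scenario A disomic [sim_scenario()]; `scenario$n` is the number
#'   of tetrads.
#' @return A list with `spores` (tibble: `tetrad`, `spore`, one 0/1 allele
#'   column `L1`, `L2`, ... per locus) and `crossovers` (tibble: `tetrad`,
#'   `interval`, `spore_a`, `spore_b`), the registry of placed crossovers.
#' @examples
#' sim_diploid_tetrads(sim_scenario("disomic", r = 0.2, n = 50, seed = 1))
#' @export
sim_diploid_tetrads <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$ploidy != "disomic") {
    stop("`scenario` must be disomic.", call. = FALSE)
  }
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$n
  K <- length(scenario$r)
  if (any(2 * scenario$r > 1)) {
    stop("single-crossover model requires r <= 0.5 per interval.", call. = FALSE)
  }
  CO <- coupled_event_chain(n, 2 * scenario$r, scenario$coincidence)

  # origins: chromatids 1,2 carry haplotype 1 (dominant), 3,4 haplotype 0
  O <- matrix(rep(c(1L, 1L, 0L, 0L), each = n), n, 4)
  alleles <- array(0L, dim = c(n, 4, K + 1))
  alleles[, , 1] <- O
  reg_t <- reg_k <- reg_a <- reg_b <- integer(0)

  for (k in seq_len(K)) {
    hit <- which(CO[, k] == 1L)
    if (length(hit)) {
      Oh <- O[hit, , drop = FALSE]
      # pick one chromatid of current origin 1 and one of origin 0
      pick <- function(mat, val) {
        is_v <- mat == val
        rk <- t(apply(is_v, 1, cumsum))
        u <- sample(1:2, nrow(mat), replace = TRUE)
        sel <- is_v & rk == u
        max.col(sel, ties.method = "first")
      }
      a <- pick(Oh, 1L)
      b <- pick(Oh, 0L)
      # reciprocal exchange: the two involved chromatids swap origins
      idx_a <- cbind(seq_along(hit), a)
      idx_b <- cbind(seq_along(hit), b)
      tmp <- Oh[idx_a]
      Oh[idx_a] <- Oh[idx_b]
      Oh[idx_b] <- tmp
      O[hit, ] <- Oh
      reg_t <- c(reg_t, hit)
      reg_k <- c(reg_k, rep(k, length(hit)))
      reg_a <- c(reg_a, pmin(a, b))
      reg_b <- c(reg_b, pmax(a, b))
    }
    alleles[, , k + 1] <- O
  }

  spores <- tibble::tibble(
    tetrad = rep(seq_len(n), each = 4),
    spore = rep(1:4, times = n)
  )
  for (l in seq_len(K + 1)) {
    spores[[paste0("L", l)]] <- as.integer(t(alleles[, , l]))
  }
  crossovers <- tibble::tibble(tetrad = reg_t, interval = reg_k,
                               spore_a = reg_a, spore_b = reg_b) |>
    dplyr::arrange(.data$tetrad, .data$interval)
  list(spores = spores, crossovers = crossovers)
}

#' Simulate diploid gametes of an autotetraploid
#'
#' Samples diploid gametes from the chromatid-level tetrasomic model behind
#' [three_locus_probs()]: each gamete is a pair of chromatids formed at the
#' proximal locus by the double-reduction mixture (sister-derived pair with
#' probability `alpha`, otherwise two distinct homologs uniformly), after
#' which each chromatid's homolog origin switches across interval `k` with
#' probability \eqn{r_k} (destination uniform among the other three
#' homologs), switches in adjacent intervals being coupled by
#' `coincidence`. Under quadrivalent pairing the two-locus phenotype class
#' frequencies converge to [tetrad_class_probs()] at the matching
#' \eqn{(\alpha, r)}; the simplex carrier frequency at the proximal locus
#' is \eqn{(2-\alpha)/4}. Under bivalent pairing homologs pair two by two
#' (uniformly re-drawn each meiosis), recombination only exchanges origins
#' within a bivalent, and double reduction cannot occur. A numeric
#' `pairing` weight mixes the two modes per meiosis.
#'
#' @param scenario A tetrasomic [sim_scenario()]; `scenario$n` is the
#'   number of gametes.
#' @param tetrads If `TRUE`, gametes are grouped four-by-four into tetrads
#'   (a `tetrad` column is added and `n` is rounded up to a multiple of 4).
#'   In this calibrated mode tetrad membership carries no within-tetrad
#'   constraint beyond the class frequencies.
#' @return A tibble with one row per gamete: `gamete`, optionally `tetrad`,
#'   and one dosage column `L1`, `L2`, ... per locus counting chromatids
#'   carrying the dominant (homolog-1) haplotype at that locus (0, 1, 2).
#' @examples
#' g <- sim_tetraploid_gametes(
#'   sim_scenario("tetrasomic", r = 0.2, alpha = 0.1, n = 500, seed = 1))
#' mean(g$L1 > 0) # about (2 - 0.1)/4... times... carrier frequency 0.475
#' @export
sim_tetraploid_gametes <- function(scenario, tetrads = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$ploidy != "tetrasomic") {
    stop("`scenario` must be tetrasomic.", call. = FALSE)
  }
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$n
  if (tetrads) n <- 4 * ceiling(n / 4)
  r <- scenario$r
  K <- length(r)

  w_quad <- if (identical(scenario$pairing, "quadrivalent")) 1
  else if (identical(scenario$pairing, "bivalent")) 0
  else scenario$pairing
  quad <- stats::runif(n) < w_quad

  # chromatid origins at the proximal locus; for bivalent meioses each
  # lineage carries the two homologs of its bivalent (switches toggle
  # between them), for quadrivalent meioses switches go to a uniform other
  # homolog
  o1 <- integer(n); o2 <- integer(n)
  biv1 <- matrix(NA_integer_, n, 2)       # bivalent of lineage 1
  biv2 <- matrix(NA_integer_, n, 2)       # bivalent of lineage 2
  if (any(quad)) {
    nq <- sum(quad)
    dr <- stats::runif(nq) < scenario$alpha
    a <- sample.int(4, nq, replace = TRUE)
    shift <- sample.int(3, nq, replace = TRUE)
    b <- ifelse(dr, a, ((a - 1 + shift) %% 4) + 1)  # uniform over the others
    o1[quad] <- a; o2[quad] <- b
  }
  if (any(!quad)) {
    # random pairing {(1, p), (q1, q2)}; gamete takes one chromatid lineage
    # from each bivalent
    nb <- sum(!quad)
    others <- rbind(c(3L, 4L), c(2L, 4L), c(2L, 3L))
    p <- sample.int(3, nb, replace = TRUE) + 1L     # partner of homolog 1
    oth <- others[p - 1L, , drop = FALSE]
    a <- ifelse(stats::runif(nb) < 0.5, 1L, p)
    b <- oth[cbind(seq_len(nb), sample(1:2, nb, replace = TRUE))]
    idx <- which(!quad)
    o1[idx] <- a; o2[idx] <- b
    biv1[idx, ] <- cbind(1L, p)
    biv2[idx, ] <- oth
  }

  dos <- matrix(0L, n, K + 1)
  dos[, 1] <- (o1 == 1L) + (o2 == 1L)
  if (K > 0) {
    s1 <- coupled_event_chain(n, r, scenario$coincidence)
    s2 <- coupled_event_chain(n, r, scenario$coincidence)
    for (k in seq_len(K)) {
      o1 <- switch_origin(o1, s1[, k] == 1L, quad, biv1)
      o2 <- switch_origin(o2, s2[, k] == 1L, quad, biv2)
      dos[, k + 1] <- (o1 == 1L) + (o2 == 1L)
    }
  }

  out <- tibble::tibble(gamete = seq_len(n))
  if (tetrads) out$tetrad <- rep(seq_len(n / 4), each = 4)
  for (l in seq_len(K + 1)) out[[paste0("L", l)]] <- dos[, l]
  out
}

# apply origin switches: quadrivalent lineages move to a uniform other
# homolog, bivalent lineages toggle to the other homolog of their bivalent
switch_origin <- function(o, s, quad, biv) {
  if (!any(s)) return(o)
  iq <- which(s & quad)
  if (length(iq)) {
    shift <- sample.int(3, length(iq), replace = TRUE)
    o[iq] <- ((o[iq] - 1 + shift) %% 4) + 1
  }
  ib <- which(s & !quad)
  if (length(ib)) {
    o[ib] <- biv[ib, 1] + biv[ib, 2] - o[ib]
  }
  o
}

#' Simulate three-marker segregant class counts
#'
#' Draws phenotype-class counts of a three-coupled-simplex-marker segregant
#' population directly from the exact gamete-class distribution
#' ([three_locus_probs()]); one multinomial draw per replicate. This is the
#' fast path used by the interference null-distribution machinery.
#'
#' @param scenario A [sim_scenario()] with two intervals (`length(r) == 2`).
#' @param n_rep Number of replicate populations.
#' @return A tibble with columns `rep`, `class` (canonical three-locus
#'   order), `count`.
#' @examples
#' sim_segregant_counts(sim_scenario("disomic", r = c(0.2, 0.1), n = 200, seed = 1))
#' @export
sim_segregant_counts <- function(scenario, n_rep = 1) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (length(scenario$r) != 2) {
    stop("three-marker simulation needs exactly two intervals.", call. = FALSE)
  }
  probs <- three_locus_probs(scenario$r[1], scenario$r[2],
                             coincidence = scenario$coincidence,
                             ploidy = scenario$ploidy,
                             alpha = scenario$alpha)
  sim_class_counts(stats::setNames(probs$prob, probs$class),
                   n = scenario$n, n_rep = n_rep, seed = scenario$seed)
}
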