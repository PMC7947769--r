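#' Estimate the coefficient of double reduction from tetrad class counts
#'
#' Closed-form maximum-likelihood estimator of the coefficient of double
#' reduction from the four fluorescent phenotype-class counts of a
#' tetraploid-derived spore population. For the proximal (green) locus the
#' MLE is \eqn{\hat\alpha = 2(n_r + n_b - n_y - n_g)/n}; the distal (red)
#' locus variant regroups the classes as
#' \eqn{\hat\beta = 2(n_g + n_b - n_y - n_r)/n}. Negative estimates are
#' truncated at 0 and flagged. The asymptotic standard error is
#' \eqn{\sqrt{16\, g_1 g_2 / n^3}} where \eqn{g_1, g_2} are the two pooled
#' class counts; at expected counts this equals the single-locus binomial
#' value \eqn{\sqrt{(4-\alpha^2)/n}}.
#'
#' @param counts A data frame with integer columns `n_y`, `n_g`, `n_r`,
#'   `n_b` (spore counts of the yellow, green, red, black classes), one row
#'   per population. Other columns are carried through.
#' @param locus `"proximal"` (green locus, nearer the centromere) or
#'   `"distal"` (red locus).
#' @return The input tibble with columns `alpha_hat`, `alpha_se`,
#'   `alpha_truncated` appended (named `beta_*` for `locus = "distal"`).
#' @examples
#' est_double_reduction(tibble::tibble(n_y = 3510, n_g = 765, n_r = 609, n_b = 4116))
#' @export
est_double_reduction <- function(counts, locus = c("proximal", "distal")) {
  locus <- match.arg(locus)
  cc <- as_tetrad_counts(counts)
  res <- unname(purrr::pmap(cc, function(n_y, n_g, n_r, n_b) {
    est_alpha_tetrad_one(c(n_y, n_g, n_r, n_b), locus)
  }))
  pre <- if (locus == "proximal") "alpha" else "beta"
  out <- tibble::as_tibble(counts)
  out[[paste0(pre, "_hat")]] <- purrr::map_dbl(res, "value")
  out[[paste0(pre, "_se")]] <- purrr::map_dbl(res, "se")
  out[[paste0(pre, "_truncated")]] <- purrr::map_lgl(res, "truncated")
  out
}

est_alpha_tetrad_one <- function(n, locus) {
  n <- unname(as.numeric(n))
  check_counts(n, "counts")
  if (sum(n) == 0) stop("empty input: all class counts are zero.", call. = FALSE)
  ntot <- sum(n)
  g1 <- if (locus == "proximal") n[1] + n[2] else n[1] + n[3]
  g2 <- ntot - g1
  raw <- 2 * (g2 - g1) / ntot
  value <- min(max(raw, 0), 1)
  list(value = value,
       se = sqrt(16 * g1 * g2 / ntot^3),
       truncated = raw < 0 || raw > 1,
       raw = raw)
}

#' Estimate double reduction from single-locus gamete counts
#'
#' For a simplex marker `ABBB` in an autotetraploid, carrier (`AB`) and
#' non-carrier (`BB`) gametes occur with probabilities \eqn{(2-\alpha)/4}
#' and \eqn{(2+\alpha)/4}. The MLE is
#' \eqn{\hat\alpha = 2(n_2 - n_1)/(n_1 + n_2)} (truncated at 0) with
#' sampling variance
#' \eqn{(4-\alpha^2)^2 / [(2+\alpha)^2 n_1 + (2-\alpha)^2 n_2]}, evaluated
#' at the unclipped estimate.
#'
#' @param counts A data frame with columns `n_carrier` (gametes showing the
#'   dominant allele) and `n_noncarrier`; one row per marker/population.
#' @return The input tibble with `alpha_hat`, `alpha_se`, `alpha_truncated`
#'   appended.
#' @examples
#' est_double_reduction_gamete(tibble::tibble(n_carrier = 450, n_noncarrier = 550))
#' @export
est_double_reduction_gamete <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("n_carrier", "n_noncarrier")
  if (!all(need %in% names(counts))) {
    stop("`counts` must have columns n_carrier and n_noncarrier.", call. = FALSE)
  }
  res <- unname(purrr::map2(counts$n_carrier, counts$n_noncarrier, function(n1, n2) {
    check_counts(c(n1, n2), "counts")
    if (n1 + n2 == 0) stop("empty input: n_carrier + n_noncarrier is zero.",
                           call. = FALSE)
    raw <- 2 * (n2 - n1) / (n1 + n2)
    a <- raw
    se <- sqrt((4 - a^2)^2 / ((2 + a)^2 * n1 + (2 - a)^2 * n2))
    list(value = min(max(raw, 0), 1), se = se, truncated = raw < 0 || raw > 1)
  }))
  counts$alpha_hat <- purrr::map_dbl(res, "value")
  counts$alpha_se <- purrr::map_dbl(res, "se")
  counts$alpha_truncated <- purrr::map_lgl(res, "truncated")
  counts
}

#' Fit the recombination fraction to one tetrad class-count population
#'
#' Fits the four-class phenotype model to a single population of spore
#' counts. Under tetrasomic inheritance the fit follows a two-step profile:
#' the double-reduction coefficient \eqn{\hat\alpha} is first obtained in
#' closed form (information at the proximal locus alone suffices, so the
#' likelihood is profiled at `r = 0`), and the recombination fraction is
#' then the maximiser of the multinomial log-likelihood
#' \eqn{L(\hat\alpha, r) = \sum_i n_i \log f_i(\hat\alpha, r)} over
#' \eqn{r \in [0, 0.75]}. The score equation in `r` is a degree-5
#' polynomial, so the search combines a dense grid with local refinement to
#' avoid spurious roots. The standard error is
#' \eqn{\sqrt{-1/\partial^2 L/\partial r^2}} at the optimum, from the exact
#' polynomial derivatives of the class probabilities. `method = "joint"`
#' instead maximises jointly over \eqn{(\alpha, r)} as a cross-check.
#' Under disomic inheritance the estimate is the recombinant-spore fraction
#' \eqn{(n_g + n_r)/n}, clipped to \[0, 0.5\], with binomial standard error.
#'
#' @param n_y,n_g,n_r,n_b Spore counts of the four phenotype classes.
#' @param ploidy `"tetrasomic"` (default) or `"disomic"`.
#' @param method `"profile"` (two-step, default) or `"joint"` (simultaneous
#'   maximisation over \eqn{\alpha} and `r`); tetrasomic only.
#' @return An object of class `tetrad_fit` with components `r`, `alpha`,
#'   `beta` (each a list with `value`, `se`, `truncated`), `loglik`,
#'   `counts`, `ploidy`, `method`, and a likelihood `profile` tibble.
#'   Use [generics::tidy()], [generics::glance()], or
#'   [ggplot2::autoplot()] on the result.
#' @examples
#' fit <- fit_tetrad_mrf(3510, 765, 609, 4116)
#' generics::tidy(fit)
#' @export
fit_tetrad_mrf <- function(n_y, n_g, n_r, n_b,
                           ploidy = c("tetrasomic", "disomic"),
                           method = c("profile", "joint")) {
  ploidy <- match.arg(ploidy)
  method <- match.arg(method)
  n <- unname(as.numeric(c(n_y, n_g, n_r, n_b)))
  check_counts(n, "counts")
  ntot <- sum(n)
  if (ntot == 0) stop("empty input: all class counts are zero.", call. = FALSE)

  if (ploidy == "disomic") {
    raw <- (n[2] + n[3]) / ntot
    r_hat <- min(raw, 0.5)
    fit <- list(
      r = list(value = r_hat, se = sqrt(r_hat * (1 - r_hat) / ntot),
               truncated = raw > 0.5),
      alpha = list(value = 0, se = NA_real_, truncated = FALSE),
      beta = list(value = 0, se = NA_real_, truncated = FALSE),
      loglik = disomic_loglik(n, r_hat),
      counts = stats::setNames(n, TETRAD_CLASSES),
      ploidy = ploidy, method = "closed-form", profile = NULL
    )
    return(structure(fit, class = "tetrad_fit"))
  }

  a_fit <- est_alpha_tetrad_one(n, "proximal")
  b_fit <- est_alpha_tetrad_one(n, "distal")
  if (sum(n > 0) < 2) {
    warning("degenerate counts (single class observed); ",
            "recombination estimate set at the boundary.", call. = FALSE)
    r0 <- if (n[1] > 0 || n[4] > 0) 0 else 0.75
    fit <- list(
      r = list(value = r0, se = NA_real_, truncated = TRUE),
      alpha = a_fit[c("value", "se", "truncated")],
      beta = b_fit[c("value", "se", "truncated")],
      loglik = tetra_loglik(n, a_fit$value, r0),
      counts = stats::setNames(n, TETRAD_CLASSES),
      ploidy = ploidy, method = method, profile = NULL
    )
    return(structure(fit, class = "tetrad_fit"))
  }

  if (method == "profile") {
    alpha_use <- a_fit$value
    r_fit <- maximize_r(n, alpha_use)
  } else {
    r_fit <- maximize_joint(n, a_fit$value)
    alpha_use <- r_fit$alpha
    a_fit$value <- alpha_use
    a_fit$truncated <- r_fit$alpha_truncated
  }

  grid <- seq(0.001, 0.749, by = 0.004)
  prof <- tibble::tibble(r = grid, loglik = tetra_loglik(n, alpha_use, grid))

  fit <- list(
    r = r_fit[c("value", "se", "truncated")],
    alpha = a_fit[c("value", "se", "truncated")],
    beta = b_fit[c("value", "se", "truncated")],
    loglik = tetra_loglik(n, alpha_use, r_fit$value),
    counts = stats::setNames(n, TETRAD_CLASSES),
    ploidy = ploidy, method = method, profile = prof
  )
  structure(fit, class = "tetrad_fit")
}

# multinomial log-likelihood at fixed alpha; vectorised over r
tetra_loglik <- function(n, alpha, r) {
  p <- tetrad_probs_vec(alpha, r)
  lp <- log(p)
  lp[, n == 0] <- 0                      # 0 * log(0) = 0 convention
  lp[!is.finite(lp)] <- -Inf
  drop(lp %*% ifelse(n == 0, 0, n))
}

disomic_loglik <- function(n, r) {
  p <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
  sum(ifelse(n == 0, 0, n * log(pmax(p, .Machine$double.xmin))))
}

# dense grid + local refinement of the profile likelihood in r
maximize_r <- function(n, alpha, lower = 0, upper = 0.75) {
  grid <- seq(lower + 1e-6, upper - 1e-6, by = 0.01)
  ll <- tetra_loglik(n, alpha, grid)
  i <- which.max(ll)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(function(r) tetra_loglik(n, alpha, r),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-10)
  r_hat <- opt$maximum
  # boundary handling: compare against the interval ends
  cand <- c(r_hat, lower, upper)
  llc <- tetra_loglik(n, alpha, cand)
  r_hat <- cand[which.max(llc)]
  truncated <- r_hat %in% c(lower, upper)
  list(value = r_hat, se = r_se(n, alpha, r_hat), truncated = truncated)
}

# exact observed-information standard error for r at fixed alpha
r_se <- function(n, alpha, r) {
  if (r <= 0 || r >= 0.75) return(NA_real_)
  p <- drop(tetrad_probs_vec(alpha, r))
  d1 <- drop(tetrad_probs_dr(alpha, r))
  d2 <- drop(tetrad_probs_d2r(alpha, r))
  keep <- n > 0
  info <- -sum(n[keep] * (d2[keep] / p[keep] - (d1[keep] / p[keep])^2))
  if (!is.finite(info) || info <= 0) return(NA_real_)
  sqrt(1 / info)
}

maximize_joint <- function(n, alpha_start) {
  nll <- function(th) -tetra_loglik(n, th[1], th[2])
  r_start <- maximize_r(n, alpha_start)$value
  opt <- stats::optim(c(max(alpha_start, 1e-4), min(max(r_start, 1e-4), 0.7499)),
                      nll, method = "L-BFGS-B",
                      lower = c(0, 1e-6), upper = c(1, 0.75 - 1e-6))
  a <- opt$par[1]; r <- opt$par[2]
  list(value = r, se = r_se(n, a, r),
       truncated = r < 1e-5 || r > 0.75 - 1e-5,
       alpha = a, alpha_truncated = a < 1e-8 || a > 1 - 1e-8)
}

#' Estimate recombination fractions for populations of tetrad class counts
#'
#' Data-frame interface to [fit_tetrad_mrf()]: one fit per row, results
#' appended as columns in a layout mirroring a per-chromosome estimate
#' table (double-reduction coefficients at both loci with standard errors,
#' then the recombination fraction with its standard error).
#'
#' @inheritParams est_double_reduction
#' @param ploidy `"tetrasomic"` or `"disomic"` (recycled across rows).
#' @param method Passed to [fit_tetrad_mrf()].
#' @return The input tibble with columns `alpha_hat`, `alpha_se`,
#'   `beta_hat`, `beta_se`, `r_hat`, `r_se`, `r_truncated`, `loglik`
#'   appended.
#' @examples
#' est_recombination(tibble::tibble(n_y = 366, n_g = 84, n_r = 58, n_b = 392))
#' @export
est_recombination <- function(counts, ploidy = c("tetrasomic", "disomic"),
                              method = c("profile", "joint")) {
  ploidy <- match.arg(ploidy)
  method <- match.arg(method)
  cc <- as_tetrad_counts(counts)
  fits <- unname(purrr::pmap(cc, function(n_y, n_g, n_r, n_b) {
    fit_tetrad_mrf(n_y, n_g, n_r, n_b, ploidy = ploidy, method = method)
  }))
  out <- tibble::as_tibble(counts)
  out$alpha_hat <- purrr::map_dbl(fits, c("alpha", "value"))
  out$alpha_se <- purrr::map_dbl(fits, c("alpha", "se"))
  out$beta_hat <- purrr::map_dbl(fits, c("beta", "value"))
  out$beta_se <- purrr::map_dbl(fits, c("beta", "se"))
  out$r_hat <- purrr::map_dbl(fits, c("r", "value"))
  out$r_se <- purrr::map_dbl(fits, c("r", "se"))
  out$r_truncated <- purrr::map_lgl(fits, c("r", "truncated"))
  out$loglik <- purrr::map_dbl(fits, "loglik")
  out
}

#' Estimate the per-interval crossover probability from five-class counts
#'
#' Maximum-likelihood estimation of the probability `p` of one crossover in
#' a marker interval from the five tetrad marker-phenotype classes of an
#' `AB/ab/ab/ab` autotetraploid (see [co_class_probs()]). The
#' double-reduction coefficient separates in the likelihood and has MLE
#' \eqn{\hat\alpha = (n_1+n_3)/n}. The profile score in `p` is a quadratic,
#' \eqn{5np^2 - (22n - 10n_1 - 12n_2)p + 24(n - n_1 - n_2) = 0}, giving
#' \eqn{\hat p = (11n - 5n_1 - 6n_2 \pm \Delta)/(5n)} with
#' \eqn{\Delta = \sqrt{n^2 + 2n(5n_1 - 6n_2) + (5n_1 + 6n_2)^2}}; the root
#' lying in \[0, 1\] is taken (when both qualify, the one with the higher
#' likelihood). The standard error comes from the observed information of
#' the five-class likelihood at the optimum.
#'
#' @param counts A data frame with integer columns `n1` ... `n5`, one row
#'   per marker interval. Other columns (e.g. a `chromosome` id) are
#'   carried through.
#' @return The input tibble with columns `alpha_hat`, `p_hat`, `p_se`,
#'   `root` (`"minus"`/`"plus"`), `loglik` appended.
#' @examples
#' est_co_probability(tibble::tibble(n1 = 540, n2 = 550, n3 = 60, n4 = 10, n5 = 40))
#' @export
est_co_probability <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- CO_CLASSES
  if (!all(need %in% names(counts))) {
    stop("`counts` must have columns ", paste(need, collapse = ", "), ".",
         call. = FALSE)
  }
  res <- unname(purrr::pmap(counts[need], function(n1, n2, n3, n4, n5) {
    est_p_co_one(c(n1, n2, n3, n4, n5))
  }))
  counts$alpha_hat <- purrr::map_dbl(res, "alpha")
  counts$p_hat <- purrr::map_dbl(res, "value")
  counts$p_se <- purrr::map_dbl(res, "se")
  counts$root <- purrr::map_chr(res, "root")
  counts$loglik <- purrr::map_dbl(res, "loglik")
  counts
}

est_p_co_one <- function(n) {
  n <- unname(as.numeric(n))
  check_counts(n, "counts")
  ntot <- sum(n)
  if (ntot == 0) stop("empty input: all class counts are zero.", call. = FALSE)
  n1 <- n[1]; n2 <- n[2]
  alpha <- (n[1] + n[3]) / ntot
  delta <- sqrt(ntot^2 + 2 * ntot * (5 * n1 - 6 * n2) + (5 * n1 + 6 * n2)^2)
  roots <- (11 * ntot - 5 * n1 - 6 * n2 + c(-1, 1) * delta) / (5 * ntot)
  names(roots) <- c("minus", "plus")
  tol <- 1e-9
  ok <- roots >= -tol & roots <= 1 + tol
  if (!any(ok)) {
    if (min(roots) > 1) {
      # the score is positive throughout (0, 1): boundary MLE at p = 1
      return(list(value = 1, se = p_co_se(n, 1), alpha = alpha,
                  root = "boundary", loglik = co_loglik(n, alpha, 1)))
    }
    stop(sprintf(
      "numerical inconsistency: neither root of the score equation lies in [0, 1] (roots %.6f, %.6f)",
      roots[1], roots[2]), call. = FALSE)
  }
  cand <- pmin(pmax(roots[ok], 0), 1)
  ll <- vapply(cand, function(p) co_loglik(n, alpha, p), numeric(1))
  pick <- which.max(ll)
  p_hat <- unname(cand[pick])
  list(value = p_hat, se = p_co_se(n, p_hat), alpha = alpha,
       root = names(cand)[pick], loglik = ll[[pick]])
}

co_loglik <- function(n, alpha, p) {
  f <- drop(co_probs_vec(alpha, p))
  sum(ifelse(n == 0, 0, n * log(pmax(f, .Machine$double.xmin))))
}

p_co_se <- function(n, p) {
  m <- n[3] + n[4] + n[5]
  info <- n[1] / 4 / (1 - p / 2)^2 + n[2] * 25 / 144 / (1 - 5 * p / 12)^2 +
    (if (m > 0) m / p^2 else 0)
  if (!is.finite(info) || info <= 0) return(NA_real_)
  sqrt(1 / info)
}

#' Expected number of crossovers per chromosome
#'
#' Sums per-interval crossover probability estimates over the marker
#' intervals of a chromosome to give the expected number of crossovers per
#' meiosis per chromosome; the standard error is the quadrature sum of the
#' interval standard errors (intervals treated as independent).
#'
#' @param intervals A data frame with a `p_hat` column (per-interval
#'   crossover probability, e.g. from [est_co_probability()]), optionally a
#'   `p_se` column, and optionally a `chromosome` column to sum within.
#' @return A tibble with one row (or one row per chromosome): `n_intervals`,
#'   `co_expected`, `co_se`.
#' @examples
#' expected_crossovers(tibble::tibble(p_hat = c(0.2, 0.24, 0), p_se = c(0.01, 0.01, 0.005)))
#' @export
expected_crossovers <- function(intervals) {
  intervals <- tibble::as_tibble(intervals)
  if (nrow(intervals) == 0) stop("empty input: no interval estimates.", call. = FALSE)
  if (!"p_hat" %in% names(intervals)) {
    stop("`intervals` must have a p_hat column.", call. = FALSE)
  }
  check_range(intervals$p_hat, "p_hat", 0, 1)
  if (!"p_se" %in% names(intervals)) intervals$p_se <- NA_real_
  g <- if ("chromosome" %in% names(intervals)) "chromosome" else character()
  intervals |>
    dplyr::group_by(dplyr::across(dplyr::all_of(g))) |>
    dplyr::summarise(
      n_intervals = dplyr::n(),
      co_expected = sum(.data$p_hat),
      co_se = sqrt(sum(.data$p_se^2)),
      .groups = "drop"
    )
}

#' Test tetrad class counts for deviation from neutral segregation
#'
#' Tests whether the carrier fraction at the proximal marker locus deviates
#' from its neutral expectation. Under disomic inheritance the carrier
#' fraction \eqn{(n_y+n_g)/n} is compared with 1/2 by a 1-df chi-squared
#' (binomial score) test. Under tetrasomic inheritance neutrality allows
#' any double-reduction coefficient, so the carrier fraction is compared
#' with the model value \eqn{(2-\alpha)/4} by a 1-df likelihood-ratio test
#' with \eqn{\alpha} profiled over \[0, 1/6\] (the mechanistically
#' attainable range); the carrier marginal is free of the recombination
#' fraction, which makes it the natural testable quantity.
#'
#' @inheritParams est_double_reduction
#' @param ploidy `"disomic"` or `"tetrasomic"` (recycled across rows).
#' @return The input tibble with `carrier_frac`, `statistic`, `p_value`
#'   appended.
#' @examples
#' test_segregation_neutrality(
#'   tibble::tibble(n_y = 300, n_g = 300, n_r = 200, n_b = 200), "disomic")
#' @export
test_segregation_neutrality <- function(counts,
                                        ploidy = c("disomic", "tetrasomic")) {
  ploidy <- match.arg(ploidy)
  cc <- as_tetrad_counts(counts)
  res <- unname(purrr::pmap(cc, function(n_y, n_g, n_r, n_b) {
    n <- unname(as.numeric(c(n_y, n_g, n_r, n_b)))
    check_counts(n, "counts")
    ntot <- sum(n)
    if (ntot == 0) stop("empty input: all class counts are zero.", call. = FALSE)
    k <- n_y + n_g
    q <- k / ntot
    if (ploidy == "disomic") {
      stat <- (k - ntot / 2)^2 / (ntot / 4)           # score test vs 1/2
    } else {
      lo <- (2 - 1 / 6) / 4                           # alpha = 1/6
      hi <- 0.5                                       # alpha = 0
      q0 <- min(max(q, lo), hi)
      stat <- 2 * (binom_ll(k, ntot, q) - binom_ll(k, ntot, q0))
    }
    list(q = q, stat = stat,
         p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }))
  out <- tibble::as_tibble(counts)
  out$carrier_frac <- purrr::map_dbl(res, "q")
  out$statistic <- purrr::map_dbl(res, "stat")
  out$p_value <- purrr::map_dbl(res, "p")
  out
}

binom_ll <- function(k, n, q) {
  t1 <- if (k == 0) 0 else k * log(q)
  t2 <- if (k == n) 0 else (n - k) * log(1 - q)
  t1 + t2
}

#' Map density in centimorgan per megabase
#'
#' Converts a recombination fraction to map distance in centimorgan
#' (multiplying by 100) and normalises by the physical length of the
#' interval in megabases.
#'
#' @param r Recombination fraction(s).
#' @param physical_length_mb Physical length(s) of the interval in Mb;
#'   must be positive.
#' @return Numeric vector of map densities (cM/Mb).
#' @examples
#' cm_per_mb(0.2, 0.05) # 400
#' @export
cm_per_mb <- function(r, physical_length_mb) {
  if (!is.numeric(physical_length_mb) || any(physical_length_mb <= 0)) {
    stop("`physical_length_mb` must be positive.", call. = FALSE)
  }
  100 * r / physical_length_mb
}

# coerce/validate the four tetrad-count columns
as_tetrad_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("n_y", "n_g", "n_r", "n_b")
  if (!all(need %in% names(counts))) {
    stop("`counts` must have columns ", paste(need, collapse = ", "), ".",
         call. = FALSE)
  }
  counts[need]
}
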