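#' Tetrad spore phenotype-class probabilities under tetrasomic inheritance
#'
#' Probability of the four fluorescent phenotype classes (yellow, green, red,
#' black) of diploid spores produced by an autotetraploid parent of genotype
#' `GBBB/RCCC`, i.e. two simplex dominant markers in coupling on the same
#' homolog. The yellow class carries both fluorescent alleles, green and red
#' carry one each, and black carries neither. The distribution depends on the
#' coefficient of double reduction `alpha` at the proximal (green) locus and
#' the recombination fraction `r` between the loci:
#'
#' \deqn{f_y = \frac{1}{12}[2(3-3r+r^2) - \alpha(3-6r+5r^2)]}
#' \deqn{f_g = \frac{r}{12}[6-2r-\alpha(6-5r)]}
#' \deqn{f_r = \frac{1}{36}(2+\alpha)r(6-r)}
#' \deqn{f_b = \frac{1}{36}(2+\alpha)(3-r)^2}
#'
#' The four probabilities sum to one, and the carrier marginal at the
#' proximal locus is \eqn{f_y + f_g = (2-\alpha)/4} for every `r`.
#'
#' @param alpha Coefficient of double reduction at the proximal locus, in
#'   \[0, 1\]. Vectorised.
#' @param r Recombination fraction between the two marker loci, in
#'   \[0, 0.75\] (tetrasomic admissible range). Vectorised.
#' @return A tibble with columns `alpha`, `r`, `f_y`, `f_g`, `f_r`, `f_b`,
#'   one row per parameter combination (inputs are recycled).
#' @examples
#' tetrad_class_probs(alpha = 0.1, r = 0.2)
#' @export
tetrad_class_probs <- function(alpha, r) {
  check_range(alpha, "alpha", 0, 1)
  check_range(r, "r", 0, 0.75)
  d <- vctrs_recycle2(alpha, r)
  p <- tetrad_probs_vec(d[[1]], d[[2]])
  tibble::tibble(alpha = d[[1]], r = d[[2]],
                 f_y = p[, 1], f_g = p[, 2], f_r = p[, 3], f_b = p[, 4])
}

# Bare matrix version (rows = parameter combos, cols = Y,G,R,B); no checks.
tetrad_probs_vec <- function(alpha, r) {
  f_y <- (2 * (3 - 3 * r + r^2) - alpha * (3 - 6 * r + 5 * r^2)) / 12
  f_g <- r * (6 - 2 * r - alpha * (6 - 5 * r)) / 12
  f_r <- (2 + alpha) * r * (6 - r) / 36
  f_b <- (2 + alpha) * (3 - r)^2 / 36
  cbind(f_y, f_g, f_r, f_b)
}

# First and second derivatives of the class probabilities w.r.t. r, used by
# the profile likelihood machinery (exact polynomials, no finite differences).
tetrad_probs_dr <- function(alpha, r) {
  cbind(
    (2 * (-3 + 2 * r) - alpha * (-6 + 10 * r)) / 12,
    (6 - 4 * r - alpha * (6 - 10 * r)) / 12,
    (2 + alpha) * (6 - 2 * r) / 36,
    -2 * (2 + alpha) * (3 - r) / 36
  )
}

tetrad_probs_d2r <- function(alpha, r) {
  cbind(
    rep((4 - 10 * alpha) / 12, length(r)),
    rep((-4 + 10 * alpha) / 12, length(r)),
    rep(-2 * (2 + alpha) / 36, length(r)),
    rep(2 * (2 + alpha) / 36, length(r))
  )
}

#' Single-locus gamete probabilities for a simplex marker in an autotetraploid
#'
#' An autotetraploid of genotype `ABBB` (dominant allele A in simplex dose)
#' produces carrier (`AB`) and non-carrier (`BB`) diploid gametes with
#' probabilities \eqn{(2-\alpha)/4} and \eqn{(2+\alpha)/4}, where
#' \eqn{\alpha} is the coefficient of double reduction at the locus. Double
#' reduction inflates the non-carrier class because both sister-derived
#' copies of a non-carrier homolog can enter the same gamete.
#'
#' @param alpha Coefficient of double reduction, in \[0, 1\]. Vectorised.
#' @return A tibble with columns `alpha`, `p_carrier`, `p_noncarrier`.
#' @examples
#' gamete_carrier_probs(alpha = c(0, 0.2, 1))
#' @export
gamete_carrier_probs <- function(alpha) {
  check_range(alpha, "alpha", 0, 1)
  tibble::tibble(alpha = alpha,
                 p_carrier = (2 - alpha) / 4,
                 p_noncarrier = (2 + alpha) / 4)
}

#' Five-class tetrad phenotype probabilities for crossover-number prediction
#'
#' For one marker interval of an autotetraploid with genotype `AB/ab/ab/ab`,
#' the tetrads fall into five distinguishable marker-phenotype classes whose
#' probabilities are, in terms of the double-reduction coefficient
#' \eqn{\alpha} at the proximal flanking locus and the probability `p` of a
#' single crossover in the interval:
#'
#' \deqn{f_1 = \alpha(1-p/2), \quad f_2 = (1-\alpha)(1-5p/12), \quad
#'   f_3 = \alpha p/2, \quad f_4 = (1-\alpha)p/12, \quad
#'   f_5 = (1-\alpha)p/3}
#'
#' The five probabilities sum to one; classes 1 and 3 carry all the
#' double-reduction mass (\eqn{f_1+f_3=\alpha}).
#'
#' @param alpha Coefficient of double reduction at the proximal flanking
#'   locus, in \[0, 1\]. Vectorised.
#' @param p Probability of one crossover in the marker interval, in \[0, 1\].
#'   Vectorised.
#' @return A tibble with columns `alpha`, `p`, `f1` ... `f5`.
#' @examples
#' co_class_probs(alpha = 0.5, p = 0.2)
#' @export
co_class_probs <- function(alpha, p) {
  check_range(alpha, "alpha", 0, 1)
  check_range(p, "p", 0, 1)
  d <- vctrs_recycle2(alpha, p)
  m <- co_probs_vec(d[[1]], d[[2]])
  out <- tibble::tibble(alpha = d[[1]], p = d[[2]])
  out$f1 <- m[, 1]; out$f2 <- m[, 2]; out$f3 <- m[, 3]
  out$f4 <- m[, 4]; out$f5 <- m[, 5]
  out
}

co_probs_vec <- function(alpha, p) {
  cbind(
    alpha * (1 - p / 2),
    (1 - alpha) * (1 - 5 * p / 12),
    alpha * p / 2,
    (1 - alpha) * p / 12,
    (1 - alpha) * p / 3
  )
}

# minimal length-recycling for two vectors (scalar against vector)
vctrs_recycle2 <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) != n) {
    if (length(a) != 1) stop("incompatible lengths", call. = FALSE)
    a <- rep(a, n)
  }
  if (length(b) != n) {
    if (length(b) != 1) stop("incompatible lengths", call. = FALSE)
    b <- rep(b, n)
  }
  list(a, b)
}
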