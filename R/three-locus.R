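#' Three-locus phenotype-class probabilities for coupled simplex markers
#'
#' Joint distribution of observable presence/absence phenotypes at three
#' dominant markers in coupling (all on the same homolog), for segregants of
#' either a diploid (`ABC/abc`, haploid gametes, 8 phase-resolved classes) or
#' an autotetraploid (`ABC/abc/abc/abc`, diploid gametes, 8 dominant
#' phenotype classes). The `coincidence` parameter scales the probability of
#' simultaneous recombination in the two adjacent intervals relative to
#' independence; `coincidence = 1` means no interference.
#'
#' For the disomic model the 8 haploid classes have
#' \eqn{P(\text{double recombinant}) = c\, r_1 r_2} with single-interval
#' marginals preserved. The tetrasomic model is an exact enumeration of a
#' chromatid-level gamete model: a diploid gamete is a pair of chromatids
#' that, with probability `alpha`, are sister-derived copies of one homolog
#' (double reduction at the proximal locus) and otherwise come from two
#' distinct homologs chosen uniformly; each chromatid's homolog origin then
#' switches across an interval with probability \eqn{r_k} (destination
#' uniform among the other three homologs), and the two interval switches of
#' a chromatid are coupled so that \eqn{P(\text{both}) = c\, r_1 r_2}. The
#' two-locus margins of this model reproduce [tetrad_class_probs()] exactly,
#' which is the model's correctness contract.
#'
#' @param r1,r2 Recombination fractions of the two adjacent intervals;
#'   admissible range \[0, 0.5\] for `ploidy = "disomic"`, \[0, 0.75\] for
#'   `"tetrasomic"`.
#' @param coincidence Non-negative scale on double recombination;
#'   `coincidence * r1 * r2` must not exceed `min(r1, r2)` and the implied
#'   no-recombination class must stay non-negative.
#' @param ploidy `"disomic"` or `"tetrasomic"`.
#' @param alpha Coefficient of double reduction at the proximal locus
#'   (tetrasomic only; must be 0 for disomic). Double reduction at the two
#'   distal loci is emergent, see [emergent_dr()].
#' @return A tibble with columns `class` (canonical order: `"ABC"` first,
#'   then lexicographic; upper case = dominant allele present) and `prob`.
#' @examples
#' three_locus_probs(0.2, 0.1, coincidence = 1, ploidy = "disomic")
#' @export
three_locus_probs <- function(r1, r2, coincidence = 1,
                              ploidy = c("disomic", "tetrasomic"),
                              alpha = 0) {
  ploidy <- match.arg(ploidy)
  r_max <- if (ploidy == "disomic") 0.5 else 0.75
  check_range(r1, "r1", 0, r_max)
  check_range(r2, "r2", 0, r_max)
  check_range(alpha, "alpha", 0, 1)
  if (!is.numeric(coincidence) || length(coincidence) != 1 || coincidence < 0) {
    stop("`coincidence` must be a single non-negative number.", call. = FALSE)
  }
  if (ploidy == "disomic" && alpha != 0) {
    stop("`alpha` must be 0 under disomic inheritance.", call. = FALSE)
  }
  p <- if (ploidy == "disomic") {
    disomic_three_locus_vec(r1, r2, coincidence)
  } else {
    tetra_three_locus_vec(r1, r2, coincidence, alpha)
  }
  tibble::tibble(class = THREE_LOCUS_CLASSES, prob = unname(p))
}

# Joint distribution of the two per-interval switch/recombination indicators
# of one strand, with coincidence scaling. Errors if infeasible.
switch_joint <- function(r1, r2, coincidence) {
  q11 <- coincidence * r1 * r2
  q10 <- r1 - q11
  q01 <- r2 - q11
  q00 <- 1 - r1 - r2 + q11
  q <- c(q00 = q00, q01 = q01, q10 = q10, q11 = q11)
  if (any(q < -1e-12)) {
    stop(sprintf(
      "infeasible coincidence: class probability %s = %.4g is negative",
      names(q)[which.min(q)], min(q)), call. = FALSE)
  }
  pmax(q, 0)
}

# Haploid 8-class vector in THREE_LOCUS_CLASSES order.
disomic_three_locus_vec <- function(r1, r2, coincidence) {
  q <- switch_joint(r1, r2, coincidence)
  # gamete = parental phase (1/2 each) with per-interval flips (rec1, rec2)
  c(ABC = q[["q00"]], ABc = q[["q01"]], AbC = q[["q11"]], Abc = q[["q10"]],
    aBC = q[["q10"]], aBc = q[["q11"]], abC = q[["q01"]], abc = q[["q00"]]) / 2
}

# Per-chromatid carrier-bit pattern distribution. The 4-homolog origin chain
# is lumpable to a 2-state carrier/non-carrier chain: from the carrier
# homolog a switch always leaves (3 non-carrier destinations), from a
# non-carrier homolog a switch hits the carrier with probability 1/3.
# Returns a 2 x 8 matrix: rows = starting bit (carrier, non-carrier),
# columns = THREE_LOCUS_CLASSES patterns of (bit1, bit2, bit3).
chromatid_pattern_probs <- function(r1, r2, coincidence) {
  q <- switch_joint(r1, r2, coincidence)
  step <- function(bit, s) {
    # returns c(P(next = 1), P(next = 0))
    if (s == 0) c(bit, 1 - bit)
    else if (bit == 1) c(0, 1) else c(1 / 3, 2 / 3)
  }
  out <- matrix(0, 2, 8, dimnames = list(c("carrier", "non"), THREE_LOCUS_CLASSES))
  for (v0 in c(1, 0)) {
    for (s1 in 0:1) for (s2 in 0:1) {
      w <- q[[paste0("q", s1, s2)]]
      if (w == 0) next
      p2 <- step(v0, s1)               # over bit2 = 1, 0
      for (b2 in c(1, 0)) {
        p3 <- step(b2, s2)             # over bit3 = 1, 0
        for (b3 in c(1, 0)) {
          k <- (1 - v0) * 4 + (1 - b2) * 2 + (1 - b3) + 1
          out[2 - v0, k] <- out[2 - v0, k] +
            w * p2[2 - b2] * p3[2 - b3]
        }
      }
    }
  }
  out
}

# 64 -> 8 collapse map: which phenotype class the OR of two chromatid
# patterns falls in (built once at load time)
or_class_index <- local({
  pat <- rbind(
    c(1, 1, 1), c(1, 1, 0), c(1, 0, 1), c(1, 0, 0),
    c(0, 1, 1), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)
  )
  idx <- matrix(0L, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    orpat <- pmax(pat[i, ], pat[j, ])
    idx[i, j] <- which(colSums(abs(t(pat) - orpat)) == 0)
  }
  idx
})

# Tetrasomic 8-class dominant-phenotype vector in THREE_LOCUS_CLASSES order.
tetra_three_locus_vec <- function(r1, r2, coincidence, alpha) {
  M <- chromatid_pattern_probs(r1, r2, coincidence)
  # starting-bit pair distribution of the two chromatids of one gamete:
  # double reduction (prob alpha): both from homolog i (i = carrier w.p. 1/4);
  # otherwise two distinct homologs, uniform over the 12 ordered pairs.
  p11 <- alpha / 4
  p10 <- (1 - alpha) / 4
  p00 <- 3 * alpha / 4 + (1 - alpha) / 2
  G <- p11 * outer(M[1, ], M[1, ]) +
    p10 * (outer(M[1, ], M[2, ]) + outer(M[2, ], M[1, ])) +
    p00 * outer(M[2, ], M[2, ])
  # phenotype = locus-wise OR of the two chromatid patterns
  out <- as.vector(tapply(G, or_class_index, sum))
  stats::setNames(out, THREE_LOCUS_CLASSES)
}

#' Emergent double-reduction coefficient at a distal locus
#'
#' In the chromatid-level tetrasomic gamete model (see
#' [three_locus_probs()]), double reduction at a locus distal to the locus
#' where the chromatid pair is formed arises from recombination: two
#' chromatids from distinct homologs can both switch onto the same homolog.
#' This returns the effective coefficient \eqn{\beta} such that the
#' non-carrier frequency of a simplex marker at the distal locus equals
#' \eqn{(2+\beta)/4}, given the proximal coefficient `alpha` and the
#' recombination fraction `r` between the loci. At `r = 0` it reduces to
#' `alpha`; it is the quantity estimated by the distal variant of
#' [est_double_reduction()].
#'
#' @param alpha Proximal double-reduction coefficient, in \[0, 1\].
#' @param r Recombination fraction, in \[0, 0.75\]. Vectorised with `alpha`.
#' @return Numeric vector of distal coefficients.
#' @examples
#' emergent_dr(0.1, 0.2) # 0.169333...
#' @export
emergent_dr <- function(alpha, r) {
  check_range(alpha, "alpha", 0, 1)
  check_range(r, "r", 0, 0.75)
  s <- (3 - r) / 3
  p_non <- alpha * (r^2 / 4 + 3 * s^2 / 4) + (1 - alpha) * (s / 2) * (r + s)
  4 * p_non - 2
}
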