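#' Reference recombination and double-reduction estimates for yeast
#'
#' Point estimates (with sampling standard deviations) of the coefficient
#' of double reduction at the proximal (\eqn{\hat\alpha}) and distal
#' (\eqn{\hat\beta}) fluorescent marker loci and of the recombination
#' fraction \eqn{\hat r} between the markers, for segregating populations
#' on the 16 chromosomes of autotetraploid and diploid
#' *Saccharomyces cerevisiae* (chromosome 7 carries two marked intervals).
#' These serve as realistic generating truths for the package's
#' simulation-based validation experiments: tetrasomic recovery runs use
#' the tetraploid \eqn{(\hat\alpha, \hat r)} pair of a chromosome as the
#' simulation parameters and the printed standard deviations as the
#' comparison scale.
#'
#' @return A tibble with columns `chromosome`, `alpha_hat`, `alpha_se`,
#'   `beta_hat`, `beta_se`, `r_tetraploid`, `r_tetraploid_se`,
#'   `r_diploid`, `r_diploid_se`.
#' @examples
#' yeast_marker_estimates()
#' @export
yeast_marker_estimates <- function() {
  tibble::tribble(
    ~chromosome, ~alpha_hat, ~alpha_se, ~beta_hat, ~beta_se,
    ~r_tetraploid, ~r_tetraploid_se, ~r_diploid, ~r_diploid_se,
    "1",   0.0305, 0.0336, 0.0361, 0.0335, 0.2245, 0.0086, 0.2126, 0.0081,
    "2",   0.0466, 0.0394, 0.0435, 0.0393, 0.1640, 0.0088, 0.1165, 0.0065,
    "3",   0.0060, 0.0347, 0.0229, 0.0347, 0.1617, 0.0076, 0.1035, 0.0056,
    "4",   0.0659, 0.0382, 0.0629, 0.0382, 0.1071, 0.0069, 0.0797, 0.0054,
    "5",   0.0431, 0.0392, 0.0446, 0.0392, 0.1404, 0.0081, 0.1004, 0.0061,
    "6",   0.0147, 0.0383, 0.0368, 0.0383, 0.4392, 0.0139, 0.2776, 0.0088,
    "7-1", 0.0618, 0.0233, 0.0678, 0.0234, 0.2322, 0.0062, 0.1599, 0.0062,
    "7-2", 0.0629, 0.0216, 0.0672, 0.0217, 0.2445, 0.0059, 0.1755, 0.0063,
    "8",   0.0000, 0.0383, 0.0063, 0.0398, 0.3460, 0.0128, 0.2571, 0.0087,
    "9",   0.0252, 0.0385, 0.0312, 0.0385, 0.2389, 0.0103, 0.1918, 0.0080,
    "10",  0.0338, 0.0392, 0.0510, 0.0392, 0.2295, 0.0103, 0.1765, 0.0076,
    "11",  0.0404, 0.0387, 0.0510, 0.0387, 0.1682, 0.0087, 0.1645, 0.0074,
    "12",  0.0495, 0.0361, 0.0326, 0.0361, 0.1085, 0.0065, 0.0642, 0.0046,
    "13",  0.0786, 0.0377, 0.0814, 0.0378, 0.2110, 0.0095, 0.1884, 0.0078,
    "14",  0.0637, 0.0308, 0.0751, 0.0308, 0.6143, 0.0133, 0.4681, 0.0083,
    "15",  0.0000, 0.0403, 0.0098, 0.0403, 0.0650, 0.0056, 0.0332, 0.0036,
    "16",  0.0000, 0.0384, 0.0217, 0.0394, 0.2644, 0.0110, 0.1999, 0.0080
  )
}
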