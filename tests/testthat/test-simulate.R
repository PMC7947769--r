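test_that("multinomial class sampler is exact, calibrated, and reproducible", {
  one <- sim_class_counts(c(1, 0, 0, 0), n = 100, seed = 1)
  expect_equal(one$count, c(100L, 0L, 0L, 0L))
  # class-1 mean frequency over many draws obeys the binomial CLT
  p <- 0.37
  d <- sim_class_counts(c(p, 1 - p), n = 1000, n_rep = 1000, seed = 2)
  f1 <- mean(d$count[d$class == "1"]) / 1000
  expect_lt(abs(f1 - p), 3 * sqrt(p * (1 - p) / 1e6))
  # determinism
  a <- sim_class_counts(c(0.3, 0.7), n = 500, n_rep = 5, seed = 9)
  b <- sim_class_counts(c(0.3, 0.7), n = 500, n_rep = 5, seed = 9)
  expect_identical(a, b)
  expect_error(sim_class_counts(c(0.5, 0.4), 10), "sum to 1")
})

test_that("scenario constructor enforces model domains", {
  expect_error(sim_scenario("disomic", r = 0.6), "r")
  expect_error(sim_scenario("disomic", r = 0.2, alpha = 0.1), "alpha")
  expect_error(sim_scenario("tetrasomic", r = 0.2, alpha = 0.1,
                            pairing = "bivalent"), "quadrivalent")
  expect_error(sim_scenario("tetrasomic", r = 0.8), "r")
  expect_s3_class(sim_scenario("tetrasomic", r = 0.6, alpha = 0.1),
                  "sim_scenario")
})

test_that("diploid four-strand tetrads reproduce per-interval recombination", {
  # r = 0 everywhere: all spores parental, empty registry
  s0 <- sim_diploid_tetrads(sim_scenario("disomic", r = c(0, 0), n = 200,
                                         seed = 3))
  expect_equal(nrow(s0$crossovers), 0)
  expect_true(all(s0$spores$L1 == s0$spores$L2 & s0$spores$L2 == s0$spores$L3))
  # single interval: recombinant-spore fraction within binomial error
  n_t <- 10000
  s <- sim_diploid_tetrads(sim_scenario("disomic", r = 0.2, n = n_t, seed = 4))
  frac <- mean(s$spores$L1 != s$spores$L2)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / (4 * n_t)))
  # every crossover is a reciprocal two-spore exchange
  expect_true(all(s$crossovers$spore_a != s$crossovers$spore_b))
  # spore-level double recombination matches coincidence * r1 * r2
  s2 <- sim_diploid_tetrads(sim_scenario("disomic", r = c(0.2, 0.1),
                                         coincidence = 1, n = 20000, seed = 5))
  dbl <- mean(s2$spores$L1 != s2$spores$L2 & s2$spores$L2 != s2$spores$L3)
  expect_lt(abs(dbl - 0.02), 3 * sqrt(0.02 * 0.98 / (4 * 20000)))
})

test_that("pooled spores of two-interval tetrads show no spurious interference", {
  s <- sim_diploid_tetrads(sim_scenario("disomic", r = c(0.2, 0.1),
                                        coincidence = 1, n = 25000, seed = 6))
  rec1 <- s$spores$L1 != s$spores$L2
  rec2 <- s$spores$L2 != s$spores$L3
  cnt <- tibble::tibble(n_none = sum(!rec1 & !rec2),
                        n_ab_only = sum(rec1 & !rec2),
                        n_bc_only = sum(!rec1 & rec2),
                        n_double = sum(rec1 & rec2))
  cc <- cc_haploid(cnt)
  expect_lt(abs(cc$c_joint - 1), 0.15)
})

test_that("tetraploid gamete frequencies obey the single- and two-locus contracts", {
  # R1/R2: class frequencies converge to the four-class model on a grid
  for (a in c(0, 0.05, 0.15)) {
    for (r in c(0.05, 0.2, 0.45)) {
      n <- 40000
      g <- sim_tetraploid_gametes(
        sim_scenario("tetrasomic", r = r, alpha = a, n = n,
                     seed = round(1000 * (a + r))))
      obs <- c(mean(g$L1 > 0 & g$L2 > 0), mean(g$L1 > 0 & g$L2 == 0),
               mean(g$L1 == 0 & g$L2 > 0), mean(g$L1 == 0 & g$L2 == 0))
      th <- unlist(tetrad_class_probs(a, r)[c("f_y", "f_g", "f_r", "f_b")])
      mc <- 3 * sqrt(th * (1 - th) / n)
      expect_true(all(abs(obs - th) < pmax(mc, 0.004)))
    }
  }
})

test_that("recombination is independent across intervals at coincidence 1", {
  # R3: chromatid switches in adjacent intervals are uncorrelated
  g <- sim_tetraploid_gametes(
    sim_scenario("tetrasomic", r = c(0.2, 0.2), alpha = 0, n = 60000,
                 seed = 13))
  pr <- three_locus_probs(0.2, 0.2, 1, "tetrasomic", alpha = 0)
  lab <- paste0(ifelse(g$L1 > 0, "A", "a"), ifelse(g$L2 > 0, "B", "b"),
                ifelse(g$L3 > 0, "C", "c"))
  obs <- as.vector(table(factor(lab, levels = pr$class))) / nrow(g)
  mc <- 3 * sqrt(pr$prob * (1 - pr$prob) / nrow(g))
  expect_true(all(abs(obs - pr$prob) < pmax(mc, 0.004)))
})

test_that("bivalent pairing gives 1/2 carrier frequency and no double reduction", {
  g <- sim_tetraploid_gametes(
    sim_scenario("tetrasomic", r = 0.2, alpha = 0, pairing = "bivalent",
                 n = 50000, seed = 21))
  for (l in c("L1", "L2")) {
    expect_lt(abs(mean(g[[l]] > 0) - 0.5), 3 * sqrt(0.25 / nrow(g)))
  }
})

test_that("estimates recover simulator inputs in a round trip", {
  g <- sim_tetraploid_gametes(
    sim_scenario("tetrasomic", r = 0.2, alpha = 0.1, n = 50000, seed = 31))
  cnt <- tc(sum(g$L1 > 0 & g$L2 > 0), sum(g$L1 > 0 & g$L2 == 0),
            sum(g$L1 == 0 & g$L2 > 0), sum(g$L1 == 0 & g$L2 == 0))
  est <- est_recombination(cnt)
  expect_lt(abs(est$r_hat - 0.2), 3 * est$r_se)
  expect_lt(abs(est$alpha_hat - 0.1), 3 * est$alpha_se)
})

test_that("samplers are deterministic under a fixed seed", {
  sc <- sim_scenario("tetrasomic", r = c(0.2, 0.1), alpha = 0.05, n = 500,
                     seed = 77)
  expect_identical(sim_tetraploid_gametes(sc), sim_tetraploid_gametes(sc))
  scd <- sim_scenario("disomic", r = 0.3, n = 100, seed = 78)
  expect_identical(sim_diploid_tetrads(scd), sim_diploid_tetrads(scd))
})

test_that("genotype matrices are consistent with their crossover registry", {
  # zero recombination, zero noise: constant spores
  sc0 <- sim_scenario("disomic", r = 0, n = 3, seed = 41)
  fx0 <- make_genotype_matrices(sc0, n_markers = 25, chrom_length_bp = 1e5)
  for (m in fx0$matrices) {
    dos <- as.matrix(m[paste0("spore_", 1:4)])
    expect_true(all(apply(dos, 2, function(x) length(unique(x)) == 1)))
  }
  expect_equal(nrow(fx0$truth), 0)
  # a placed crossover flips exactly two spores complementarily
  sc1 <- sim_scenario("disomic", r = 0.05, n = 10, seed = 42)
  fx1 <- make_genotype_matrices(sc1, n_markers = 40, chrom_length_bp = 4e5)
  m1 <- fx1$matrices[[fx1$truth$tetrad[1]]]
  dos <- as.matrix(m1[paste0("spore_", 1:4)])
  k <- which(m1$pos == fx1$truth$start[1])
  d <- dos[k + 1, ] - dos[k, ]
  expect_equal(unname(sort(d)), c(-1L, 0L, 0L, 1L))
  # marker positions strictly increasing; 2:2 segregation everywhere
  expect_true(all(diff(m1$pos) > 0))
  expect_true(all(rowSums(dos) == 2))
})

test_that("mechanistic tetraploid bundles keep dosage bookkeeping and emergent DR", {
  sc <- sim_scenario("tetrasomic", r = 0.05, n = 60, seed = 51)
  fx <- make_genotype_matrices(sc, n_markers = 30, chrom_length_bp = 6e5)
  # simplex parent: total dosage 2 of 8 at every marker
  tots <- sapply(fx$matrices, function(m)
    unique(rowSums(as.matrix(m[paste0("spore_", 1:4)]))))
  expect_true(all(unlist(tots) == 2))
  # emergent double reduction: fraction of spores with dosage 2 at the last
  # marker stays within the mechanistic bound alpha <= 1/6 (allowing MC noise)
  last <- sapply(fx$matrices, function(m) {
    dos <- as.matrix(m[paste0("spore_", 1:4)])
    dos[nrow(dos), ]
  })
  p_dr <- mean(last == 2)                   # P(gamete has both copies)
  # P(dosage 2) = alpha/4 under the calibrated model; 1/24 at the maximum
  expect_lt(p_dr, 1 / 24 + 3 * sqrt((1 / 24) / length(last)))
  # triplex parent: totals of 6
  fx6 <- make_genotype_matrices(sim_scenario("tetrasomic", r = 0.05, n = 10,
                                             seed = 52),
                                n_markers = 10, chrom_length_bp = 1e5,
                                parent_config = "triplex")
  tot6 <- unlist(sapply(fx6$matrices, function(m)
    unique(rowSums(as.matrix(m[paste0("spore_", 1:4)])))))
  expect_true(all(tot6 == 6))
})

test_that("genotyping noise perturbs dosages at the requested rate", {
  sc <- sim_scenario("disomic", r = 0, n = 5, seed = 61)
  fx <- make_genotype_matrices(sc, n_markers = 200, chrom_length_bp = 1e6,
                               noise = 0.1)
  dos <- do.call(rbind, lapply(fx$matrices, function(m)
    as.matrix(m[paste0("spore_", 1:4)])))
  # without noise every column is constant; flips show as within-column changes
  flip_rate <- mean(apply(dos, 2, function(x) x != as.integer(mean(x) > 0.5)))
  expect_lt(abs(flip_rate - 0.1), 0.03)
})
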