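# Shared fixtures: exact expected counts and small builders.

# expected tetrad class counts under the four-class tetrasomic model
expected_tetrad_counts <- function(alpha, r, n) {
  p <- tetrad_class_probs(alpha, r)
  tibble::tibble(n_y = p$f_y * n, n_g = p$f_g * n,
                 n_r = p$f_r * n, n_b = p$f_b * n)
}

# expected five-class crossover-phenotype counts
expected_co_counts <- function(alpha, p, n) {
  f <- co_class_probs(alpha, p)
  tibble::tibble(n1 = f$f1 * n, n2 = f$f2 * n, n3 = f$f3 * n,
                 n4 = f$f4 * n, n5 = f$f5 * n)
}

# independent grid maximizer of the four-class log-likelihood in r
grid_argmax_r <- function(counts, alpha, step = 1e-4) {
  r <- seq(step, 0.75 - step, by = step)
  f_y <- (2 * (3 - 3 * r + r^2) - alpha * (3 - 6 * r + 5 * r^2)) / 12
  f_g <- r * (6 - 2 * r - alpha * (6 - 5 * r)) / 12
  f_r <- (2 + alpha) * r * (6 - r) / 36
  f_b <- (2 + alpha) * (3 - r)^2 / 36
  ll <- counts[1] * log(f_y) + counts[2] * log(f_g) +
    counts[3] * log(f_r) + counts[4] * log(f_b)
  r[which.max(ll)]
}

# independent grid maximizer of the five-class log-likelihood in p
grid_argmax_p <- function(counts, step = 1e-5) {
  p <- seq(step, 1, by = step)
  alpha <- (counts[1] + counts[3]) / sum(counts)
  ll <- rep(0, length(p))
  f <- list(alpha * (1 - p / 2), (1 - alpha) * (1 - 5 * p / 12),
            alpha * p / 2, (1 - alpha) * p / 12, (1 - alpha) * p / 3)
  for (i in 1:5) {
    if (counts[i] > 0) ll <- ll + counts[i] * log(f[[i]])
  }
  p[which.max(ll)]
}

# tetrad-count tibble shorthand
tc <- function(n_y, n_g, n_r, n_b) {
  tibble::tibble(n_y = n_y, n_g = n_g, n_r = n_r, n_b = n_b)
}
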