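#' Coincidence coefficients from haploid three-marker segregant counts
#'
#' For haploid segregants of a diploid `ABC/abc` parent (three dominant
#' markers in coupling), recombination events in the two adjacent intervals
#' are directly countable and the coincidence coefficients are exact
#' ratios. With \eqn{r_{AB\cap BC}} the frequency of simultaneous
#' recombination in both intervals:
#' \deqn{c_{AB-BC} = \frac{r_{AB\cap BC}}{r_{AB}\, r_{BC}}, \quad
#'   c_{AB/BC} = \frac{r_{AB|BC}}{r_{AB|\overline{BC}}}, \quad
#'   c_{BC/AB} = \frac{r_{BC|AB}}{r_{BC|\overline{AB}}}}
#' All three equal 1 when recombination is independent between the
#' intervals; values below 1 indicate positive crossover interference.
#'
#' @param counts Either a long tibble with columns `class` (the 8
#'   phase-resolved gamete classes, canonical order `"ABC"` ... `"abc"`)
#'   and `count`, or a tibble with recombination-event class columns
#'   `n_none`, `n_ab_only`, `n_bc_only`, `n_double`.
#' @return A one-row tibble: `n`, `r_ab`, `r_bc`, `c_joint`,
#'   `c_ab_given_bc`, `c_bc_given_ab`.
#' @examples
#' cc_haploid(tibble::tibble(n_none = 710, n_ab_only = 190,
#'                           n_bc_only = 90, n_double = 10))
#' @export
cc_haploid <- function(counts) {
  ev <- as_event_counts(counts)
  n <- sum(ev)
  if (n == 0) stop("empty input: all counts are zero.", call. = FALSE)
  n_ab <- ev[["n_ab_only"]] + ev[["n_double"]]
  n_bc <- ev[["n_bc_only"]] + ev[["n_double"]]
  if (n_ab == 0) stop("undefined coefficient: no recombinants in interval AB.",
                      call. = FALSE)
  if (n_bc == 0) stop("undefined coefficient: no recombinants in interval BC.",
                      call. = FALSE)
  r_ab <- n_ab / n
  r_bc <- n_bc / n
  c_joint <- (ev[["n_double"]] / n) / (r_ab * r_bc)
  c_ab_given_bc <- (ev[["n_double"]] / n_bc) /
    (ev[["n_ab_only"]] / (n - n_bc))
  c_bc_given_ab <- (ev[["n_double"]] / n_ab) /
    (ev[["n_bc_only"]] / (n - n_ab))
  tibble::tibble(n = n, r_ab = r_ab, r_bc = r_bc, c_joint = c_joint,
                 c_ab_given_bc = c_ab_given_bc, c_bc_given_ab = c_bc_given_ab)
}

# collapse 8 phase-resolved classes (or accept event classes directly)
as_event_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  ev_cols <- c("n_none", "n_ab_only", "n_bc_only", "n_double")
  if (all(ev_cols %in% names(counts))) {
    v <- vapply(counts[ev_cols], sum, numeric(1))
    check_counts(v, "counts")
    return(v)
  }
  if (!all(c("class", "count") %in% names(counts))) {
    stop("`counts` must have either class/count columns or ",
         paste(ev_cols, collapse = ", "), ".", call. = FALSE)
  }
  bad <- setdiff(counts$class, THREE_LOCUS_CLASSES)
  if (length(bad)) {
    stop("unknown phenotype class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  check_counts(counts$count, "count")
  pat <- three_locus_patterns()[counts$class, , drop = FALSE]
  rec1 <- pat[, 1] != pat[, 2]
  rec2 <- pat[, 2] != pat[, 3]
  c(n_none = sum(counts$count[!rec1 & !rec2]),
    n_ab_only = sum(counts$count[rec1 & !rec2]),
    n_bc_only = sum(counts$count[!rec1 & rec2]),
    n_double = sum(counts$count[rec1 & rec2]))
}

#' Coincidence coefficients from tetraploid three-marker segregant counts
#'
#' Diploid segregants of an `ABC/abc/abc/abc` autotetraploid show only
#' dominant presence/absence phenotypes, which do not identify double
#' recombination by direct counting. The coefficients are therefore
#' obtained by maximum likelihood over the enumerated tetrasomic
#' three-locus gamete model (see [three_locus_probs()]): the parameters
#' \eqn{(r_1, r_2, c, \alpha)} are fitted to the 8 phenotype-class counts,
#' `c_joint` is the fitted chromatid-level coincidence, and the conditional
#' coefficients follow from the fitted joint switch distribution as
#' \eqn{c_{AB/BC} = c(1-r_2)/(1-c\,r_2)} and
#' \eqn{c_{BC/AB} = c(1-r_1)/(1-c\,r_1)}. This model-based reconstruction
#' is an interpretation: dominant data carry less information than
#' phase-resolved haploid counts.
#'
#' @param counts A long tibble with columns `class` (8 dominant phenotype
#'   classes, canonical order) and `count`.
#' @param starts Number of extra random multistarts for the box-constrained
#'   optimiser (the score surface of the enumeration model can be
#'   multimodal for small samples).
#' @return An object of class `cc_fit`: a list with `par` (named fitted
#'   parameters `r1`, `r2`, `coincidence`, `alpha`), `coefficients`
#'   (one-row tibble as in [cc_haploid()] minus the exact-ratio columns),
#'   `loglik`, `counts`, `convergence`, `boundary`. `tidy()` and
#'   `glance()` methods are provided.
#' @examples
#' pr <- three_locus_probs(0.2, 0.15, 1, "tetrasomic", alpha = 0.05)
#' cts <- tibble::tibble(class = pr$class, count = round(pr$prob * 4000))
#' fit_cc_tetraploid(cts)
#' @export
fit_cc_tetraploid <- function(counts, starts = 3) {
  counts <- tibble::as_tibble(counts)
  if (!all(c("class", "count") %in% names(counts))) {
    stop("`counts` must have class and count columns.", call. = FALSE)
  }
  check_counts(counts$count, "count")
  n <- counts$count[match(THREE_LOCUS_CLASSES, counts$class)]
  if (anyNA(n)) stop("`counts` must cover all 8 phenotype classes.",
                     call. = FALSE)
  if (sum(n) == 0) stop("empty input: all counts are zero.", call. = FALSE)

  nll <- function(th) {
    r1 <- th[1]; r2 <- th[2]; u <- th[3]; alpha <- th[4]
    lo <- max(0, r1 + r2 - 1); hi <- min(r1, r2)
    q11 <- lo + u * (hi - lo)
    cc <- q11 / (r1 * r2)
    p <- tetra_three_locus_vec(r1, r2, cc, alpha)
    -sum(ifelse(n == 0, 0, n * log(pmax(p, 1e-300))))
  }

  # moment-style starting values from the two-locus margins
  m12 <- collapse_margin(n, 1:2)
  f12 <- fit_tetrad_mrf(m12[1], m12[2], m12[3], m12[4])
  m23 <- collapse_margin(n, 2:3)
  f23 <- fit_tetrad_mrf(m23[1], m23[2], m23[3], m23[4])
  r1s <- min(max(f12$r$value, 0.02), 0.73)
  r2s <- min(max(f23$r$value, 0.02), 0.73)
  as <- min(max(f12$alpha$value, 0.001), 0.49)
  u_indep <- function(r1, r2) {
    lo <- max(0, r1 + r2 - 1); hi <- min(r1, r2)
    if (hi <= lo) 0.5 else min(max((r1 * r2 - lo) / (hi - lo), 0.01), 0.99)
  }
  start_list <- list(c(r1s, r2s, u_indep(r1s, r2s), as))
  for (i in seq_len(starts)) {
    start_list[[i + 1]] <- c(stats::runif(1, 0.05, 0.6),
                             stats::runif(1, 0.05, 0.6),
                             stats::runif(1, 0.1, 0.9),
                             stats::runif(1, 0, 0.3))
  }
  lower <- c(1e-3, 1e-3, 0, 0)
  upper <- c(0.749, 0.749, 1, 0.6)
  best <- NULL
  for (st in start_list) {
    opt <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop("coincidence-coefficient fit failed to converge from any start.",
         call. = FALSE)
  }
  th <- best$par
  r1 <- th[1]; r2 <- th[2]; alpha <- th[4]
  lo <- max(0, r1 + r2 - 1); hi <- min(r1, r2)
  q11 <- lo + th[3] * (hi - lo)
  cc <- q11 / (r1 * r2)
  boundary <- any(abs(th - lower) < 1e-6) || any(abs(th - upper) < 1e-6)
  coefs <- tibble::tibble(
    n = sum(n),
    c_joint = cc,
    c_ab_given_bc = cc * (1 - r2) / (1 - cc * r2),
    c_bc_given_ab = cc * (1 - r1) / (1 - cc * r1)
  )
  structure(list(
    par = c(r1 = r1, r2 = r2, coincidence = cc, alpha = alpha),
    coefficients = coefs,
    loglik = -best$value,
    counts = stats::setNames(n, THREE_LOCUS_CLASSES),
    convergence = best$convergence,
    boundary = boundary
  ), class = "cc_fit")
}

#' @export
print.cc_fit <- function(x, ...) {
  cat("<cc_fit> tetrasomic three-locus ML fit\n")
  print(round(x$par, 4))
  cat("coincidence coefficients:\n")
  print(as.data.frame(round(x$coefficients, 4)), row.names = FALSE)
  if (x$boundary) cat("note: fit at a parameter boundary\n")
  invisible(x)
}

#' @rdname fit_cc_tetraploid
#' @details `cc_tetraploid()` is the data-frame-in, tibble-out wrapper
#'   around `fit_cc_tetraploid()`.
#' @export
cc_tetraploid <- function(counts, starts = 3) {
  fit <- fit_cc_tetraploid(counts, starts = starts)
  out <- fit$coefficients
  out$r1_hat <- fit$par[["r1"]]
  out$r2_hat <- fit$par[["r2"]]
  out$alpha_hat <- fit$par[["alpha"]]
  out$boundary <- fit$boundary
  out
}

#' Simulation-based significance of coincidence-coefficient estimates
#'
#' Tests the deviation of observed coincidence coefficients from their
#' no-interference value of 1 by simulating segregant populations with
#' recombination independent between the two intervals (`coincidence = 1`),
#' recomputing each coefficient per replicate, and reporting two-sided
#' empirical p-values with the add-one estimator
#' \eqn{p = (1 + \#\{|c_{sim}-1| \ge |c_{obs}-1|\})/(n_{sim}+1)}.
#'
#' @param observed A one-row tibble of observed coefficients (output of
#'   [cc_haploid()] or [cc_tetraploid()]), containing `c_joint`,
#'   `c_ab_given_bc`, `c_bc_given_ab`.
#' @param scenario A two-interval [sim_scenario()] carrying the population
#'   size and per-interval recombination fractions extracted from the
#'   observed data; its `coincidence` is forced to 1 under the null.
#' @param n_sim Number of null replicates (at least 100).
#' @param seed Optional RNG seed.
#' @return An object of class `cc_test` (a tibble): one row per
#'   coefficient with `estimate`, `p_value`, `n_sim` (replicates actually
#'   usable). The simulated null draws are kept in attribute `null` for
#'   plotting.
#' @examples
#' obs <- cc_haploid(tibble::tibble(n_none = 710, n_ab_only = 190,
#'                                  n_bc_only = 90, n_double = 10))
#' sc <- sim_scenario("disomic", r = c(0.2, 0.1), n = 1000)
#' cc_null_test(obs, sc, n_sim = 200, seed = 1)
#' @export
cc_null_test <- function(observed, scenario, n_sim = 1000, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (length(scenario$r) != 2) {
    stop("scenario must describe exactly two marker intervals.", call. = FALSE)
  }
  if (n_sim < 100) stop("`n_sim` must be at least 100.", call. = FALSE)
  coef_names <- c("c_joint", "c_ab_given_bc", "c_bc_given_ab")
  observed <- tibble::as_tibble(observed)
  if (!all(coef_names %in% names(observed))) {
    stop("`observed` must contain columns ",
         paste(coef_names, collapse = ", "), ".", call. = FALSE)
  }
  scenario$coincidence <- 1
  scenario$seed <- NULL
  if (!is.null(seed)) set.seed(seed)

  probs <- three_locus_probs(scenario$r[1], scenario$r[2], 1,
                             ploidy = scenario$ploidy, alpha = scenario$alpha)
  draws <- stats::rmultinom(n_sim, size = scenario$n,
                            prob = probs$prob)
  rownames(draws) <- probs$class

  if (scenario$ploidy == "disomic") {
    # fully vectorised counting across replicates
    pat <- three_locus_patterns()[probs$class, ]
    rec1 <- pat[, 1] != pat[, 2]
    rec2 <- pat[, 2] != pat[, 3]
    n_tot <- colSums(draws)
    n_d <- colSums(draws[rec1 & rec2, , drop = FALSE])
    n_ab <- colSums(draws[rec1 & !rec2, , drop = FALSE]) + n_d
    n_bc <- colSums(draws[!rec1 & rec2, , drop = FALSE]) + n_d
    c_joint <- (n_d / n_tot) / ((n_ab / n_tot) * (n_bc / n_tot))
    c_ab <- (n_d / n_bc) / ((n_ab - n_d) / (n_tot - n_bc))
    c_bc <- (n_d / n_ab) / ((n_bc - n_d) / (n_tot - n_ab))
    sims <- rbind(c_joint, c_ab, c_bc)
    sims[!is.finite(sims)] <- NA_real_
  } else {
    sims <- apply(draws, 2, function(cnt) {
      d <- tibble::tibble(class = rownames(draws), count = cnt)
      out <- tryCatch(cc_tetraploid(d, starts = 1), error = function(e) NULL)
      if (is.null(out)) rep(NA_real_, 3) else
        unlist(out[coef_names], use.names = FALSE)
    })
  }
  rownames(sims) <- coef_names

  res <- purrr::map_dfr(coef_names, function(cn) {
    x <- sims[cn, ]
    x <- x[is.finite(x)]
    obs <- observed[[cn]][1]
    tibble::tibble(
      coefficient = cn,
      estimate = obs,
      p_value = (1 + sum(abs(x - 1) >= abs(obs - 1))) / (length(x) + 1),
      n_sim = length(x)
    )
  })
  attr(res, "null") <- sims
  class(res) <- c("cc_test", class(res))
  res
}

# collapse the 8-class three-locus counts to a two-locus 4-class margin
# (Y, G, R, B order: both dominant, first only, second only, neither)
collapse_margin <- function(n, loci) {
  pat <- three_locus_patterns()[, loci, drop = FALSE]
  key <- pat[, 1] * 2 + pat[, 2]
  c(sum(n[key == 3]), sum(n[key == 2]), sum(n[key == 1]), sum(n[key == 0]))
}
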