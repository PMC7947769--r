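#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a tetrad recombination fit
#'
#' @param x A `tetrad_fit` from [fit_tetrad_mrf()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `truncated`.
#' @exportS3Method generics::tidy
tidy.tetrad_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta", "r"),
    estimate = c(x$alpha$value, x$beta$value, x$r$value),
    std.error = c(x$alpha$se, x$beta$se, x$r$se),
    truncated = c(x$alpha$truncated, x$beta$truncated, x$r$truncated)
  )
}

#' @rdname tidy.tetrad_fit
#' @exportS3Method generics::glance
glance.tetrad_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik,
    n = sum(x$counts),
    ploidy = x$ploidy,
    method = x$method
  )
}

#' @export
print.tetrad_fit <- function(x, ...) {
  cat("<tetrad_fit> ", x$ploidy, " (", x$method, ")\n", sep = "")
  print(as.data.frame(tidy.tetrad_fit(x)), row.names = FALSE)
  cat("log-likelihood:", format(x$loglik), " n:", sum(x$counts), "\n")
  invisible(x)
}

#' Profile log-likelihood plot for a tetrad recombination fit
#'
#' @param object A `tetrad_fit` with a likelihood profile (tetrasomic
#'   fits).
#' @param ... Unused.
#' @return A ggplot object: profile log-likelihood in `r` with the MLE
#'   marked.
#' @exportS3Method ggplot2::autoplot
autoplot.tetrad_fit <- function(object, ...) {
  if (is.null(object$profile)) {
    stop("no likelihood profile stored (disomic closed-form fit).",
         call. = FALSE)
  }
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$r, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$r$value, linetype = "dashed") +
    ggplot2::labs(x = "recombination fraction r",
                  y = "profile log-likelihood",
                  title = sprintf("r = %.4f (SE %.4f)", object$r$value,
                                  object$r$se)) +
    ggplot2::theme_minimal()
}

#' @rdname tidy.tetrad_fit
#' @param x A `cc_fit` from [fit_cc_tetraploid()].
#' @exportS3Method generics::tidy
tidy.cc_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname tidy.tetrad_fit
#' @exportS3Method generics::glance
glance.cc_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n = sum(x$counts),
                 convergence = x$convergence, boundary = x$boundary)
}

#' Null-distribution plot for a coincidence-coefficient test
#'
#' @param object A `cc_test` from [cc_null_test()].
#' @param coefficient Which coefficient's null draws to show.
#' @param ... Unused.
#' @return A ggplot object: histogram of the simulated null coefficients
#'   with the observed value marked.
#' @exportS3Method ggplot2::autoplot
autoplot.cc_test <- function(object, coefficient = "c_joint", ...) {
  sims <- attr(object, "null")
  if (is.null(sims) || !coefficient %in% rownames(sims)) {
    stop("no stored null draws for ", coefficient, call. = FALSE)
  }
  df <- tibble::tibble(c_sim = sims[coefficient, ])
  obs <- object$estimate[object$coefficient == coefficient]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$c_sim)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = obs, colour = "red") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = coefficient, y = "null replicates",
                  title = "simulated no-interference null") +
    ggplot2::theme_minimal()
}
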