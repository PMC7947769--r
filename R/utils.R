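# Internal validation helpers shared across modules.

check_range <- function(x, name, lo, hi) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("`%s` must be numeric and non-missing.", name), call. = FALSE)
  }
  if (any(x < lo | x > hi)) {
    stop(sprintf("`%s` must lie in [%g, %g] (got %g).",
                 name, lo, hi, x[which(x < lo | x > hi)[1]]), call. = FALSE)
  }
  invisible(x)
}

# non-negative numeric; fractional values allowed so that exact expected
# counts can be fed to the estimators
check_counts <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must contain non-negative counts.", name),
         call. = FALSE)
  }
  invisible(x)
}

# Canonical class orders; part of the file contract.
TETRAD_CLASSES <- c("Y", "G", "R", "B")
CO_CLASSES <- paste0("n", 1:5)
# Three-locus classes, coupling parent (all dominant alleles) first, then
# lexicographic: upper case = dominant allele present at that locus.
THREE_LOCUS_CLASSES <- c("ABC", "ABc", "AbC", "Abc", "aBC", "aBc", "abC", "abc")

# Presence/absence bit patterns matching THREE_LOCUS_CLASSES (1 = dominant).
three_locus_patterns <- function() {
  m <- rbind(
    c(1, 1, 1), c(1, 1, 0), c(1, 0, 1), c(1, 0, 0),
    c(0, 1, 1), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)
  )
  rownames(m) <- THREE_LOCUS_CLASSES
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
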