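#' Read a phenotype-class count table
#'
#' Reads TSV count tables in the package's canonical layouts, one row per
#' population: tetrad class counts (`n_y`, `n_g`, `n_r`, `n_b`), five-class
#' crossover-phenotype counts (`n1` ... `n5`), or long three-marker counts
#' (`class`, `count`). An optional identifier column (`population`,
#' `chromosome` or `id`) is allowed; any other column is a parse error.
#'
#' @param path Path to a TSV file with a header row.
#' @param kind `"tetrad"`, `"co"`, or `"three_marker"`.
#' @return A validated tibble in canonical column order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines("population\tn_y\tn_g\tn_r\tn_b\npopA\t366\t84\t58\t392", f)
#' read_count_table(f, "tetrad")
#' @export
read_count_table <- function(path, kind = c("tetrad", "co", "three_marker")) {
  kind <- match.arg(kind)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  id_cols <- intersect(c("population", "chromosome", "id"), names(x))
  need <- switch(kind,
                 tetrad = c("n_y", "n_g", "n_r", "n_b"),
                 co = CO_CLASSES,
                 three_marker = c("class", "count"))
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(x), c(need, id_cols))
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(need, "class")
  for (i in seq_len(nrow(x))) {
    v <- unlist(x[i, num_cols])
    if (anyNA(v) || any(v < 0)) {
      stop(sprintf("row %d: negative or missing count.", i), call. = FALSE)
    }
  }
  if (kind %in% c("tetrad", "co")) {
    zero <- rowSums(as.matrix(x[num_cols])) == 0
    if (any(zero)) {
      stop(sprintf("row %d: all-zero counts.", which(zero)[1]), call. = FALSE)
    }
  } else {
    bad <- setdiff(x$class, THREE_LOCUS_CLASSES)
    if (length(bad)) {
      stop("unknown phenotype class: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  x[, c(id_cols, need)]
}

#' Read a genotype matrix TSV
#'
#' Reads a tetrad genotype matrix written by [write_genotype_matrix()]:
#' columns `marker`, `chrom`, `pos` (bp), then one dosage column per spore
#' (`spore_1` ... `spore_4`).
#'
#' @param path Path to the TSV file.
#' @return A genotype matrix tibble.
#' @export
read_genotype_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("marker", "chrom", "pos", paste0("spore_", 1:4))
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x[need]
}

#' @rdname read_genotype_matrix
#' @param geno Genotype matrix tibble to write.
#' @export
write_genotype_matrix <- function(geno, path) {
  readr::write_tsv(geno, path, progress = FALSE)
  invisible(path)
}

#' Write crossover calls as BED-like TSV
#'
#' Emits calls with 0-based half-open intervals: columns `chrom`, `start`,
#' `end`, `tetrad`, `spore_up`, `spore_down`, `status`.
#'
#' @param calls Output of [call_crossovers()] (possibly row-bound across
#'   tetrads).
#' @param path Output path.
#' @export
write_co_calls <- function(calls, path) {
  readr::write_tsv(calls, path, progress = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the seed, package version, and a hash of the configuration so
#' that any result table can be regenerated.
#'
#' @param path Output JSON path.
#' @param config The configuration list used.
#' @param seed The RNG seed used.
#' @export
write_manifest <- function(path, config, seed) {
  manifest <- list(
    package = "tetrarec",
    version = as.character(utils::packageVersion("tetrarec")),
    seed = seed,
    config_hash = rlang::hash(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
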