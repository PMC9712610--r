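# Expression-matrix container: a tibble with a `gene` column, one numeric
# column per sample, and a declared unit. Missing values are explicit NAs,
# never zeros; unit-aware operations reject mismatched inputs.

EM_UNITS <- c("intensity", "ibaq", "copies_per_cell", "fpkm", "fot")

#' Build an expression matrix
#'
#' Construct the gene-by-sample table used throughout the package: a tibble
#' whose first column (`gene`) holds unique gene symbols, whose remaining
#' columns hold one sample each, and which carries a declared measurement
#' unit. Values must be non-negative; missingness (a feature not identified
#' in a sample) is an explicit `NA`, never `0`.
#'
#' @param x A data frame with a `gene` character column and numeric sample
#'   columns, or a numeric matrix with gene rownames.
#' @param unit Measurement unit, one of `"intensity"`, `"ibaq"`,
#'   `"copies_per_cell"`, `"fpkm"`, `"fot"`.
#' @return A tibble of class `expr_mat` with a `unit` attribute.
#' @examples
#' m <- matrix(c(1, 2, NA, 4), 2, 2,
#'             dimnames = list(c("Actb", "Gapdh"), c("s1", "s2")))
#' as_expr_matrix(m, unit = "intensity")
#' @export
as_expr_matrix <- function(x, unit) {
  unit <- match.arg(unit, EM_UNITS)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("matrix input needs gene rownames.")
    x <- tibble(gene = rownames(x), as_tibble(x, .name_repair = "minimal"))
  }
  if (!is.data.frame(x)) abort("`x` must be a data frame or matrix.")
  if (!"gene" %in% names(x)) {
    names(x)[1L] <- "gene"
  }
  x <- as_tibble(x)
  x$gene <- as.character(x$gene)
  validate_expr_parts(x)
  structure(x, unit = unit,
            class = c("expr_mat", class(as_tibble(x))))
}

validate_expr_parts <- function(tbl) {
  dup_g <- tbl$gene[duplicated(tbl$gene)]
  if (length(dup_g)) {
    abort(sprintf("duplicated gene id(s): %s",
                  paste(unique(dup_g), collapse = ", ")))
  }
  smp <- setdiff(names(tbl), "gene")
  if (!length(smp)) abort("expression matrix has no sample columns.")
  dup_s <- smp[duplicated(smp)]
  if (length(dup_s)) {
    abort(sprintf("duplicated sample id(s): %s",
                  paste(unique(dup_s), collapse = ", ")))
  }
  for (s in smp) {
    v <- tbl[[s]]
    if (!is.numeric(v)) abort(sprintf("sample column `%s` is not numeric.", s))
    bad <- which(!is.na(v) & v < 0)
    if (length(bad)) {
      abort(sprintf("negative value at gene `%s`, sample `%s`.",
                    tbl$gene[bad[1L]], s))
    }
  }
  invisible(tbl)
}

#' @rdname as_expr_matrix
#' @export
is_expr_matrix <- function(x) inherits(x, "expr_mat")

#' Expression-matrix accessors
#'
#' `em_unit()` returns the declared unit; `em_genes()` and `em_samples()` the
#' gene and sample identifiers; `em_values()` the numeric gene-by-sample
#' matrix (gene rownames preserved).
#'
#' @param x An `expr_mat`.
#' @return See each function's description.
#' @export
em_unit <- function(x) {
  stopifnot(is_expr_matrix(x))
  attr(x, "unit")
}

#' @rdname em_unit
#' @export
em_genes <- function(x) {
  stopifnot(is_expr_matrix(x))
  x$gene
}

#' @rdname em_unit
#' @export
em_samples <- function(x) {
  stopifnot(is_expr_matrix(x))
  setdiff(names(x), "gene")
}

#' @rdname em_unit
#' @export
em_values <- function(x) {
  stopifnot(is_expr_matrix(x))
  smp <- em_samples(x)
  m <- as.matrix(x[smp])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene
  m
}

# rebuild an expr_mat from a value matrix (internal)
em_replace <- function(m, unit) {
  as_expr_matrix(m, unit = unit)
}

require_unit <- function(x, unit, arg = deparse(substitute(x))) {
  if (!is_expr_matrix(x)) abort(sprintf("`%s` must be an expr_mat.", arg))
  if (!em_unit(x) %in% unit) {
    abort(sprintf("`%s` has unit '%s'; expected %s.", arg, em_unit(x),
                  paste(sprintf("'%s'", unit), collapse = " or ")))
  }
  invisible(x)
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("# Expression matrix: %d genes x %d samples [unit: %s]\n",
              nrow(x), length(em_samples(x)), em_unit(x)))
  NextMethod()
}

#' Replicate-mean expression by population
#'
#' Collapse sample columns to one column per population by averaging
#' replicates, following the design table. Averaging treats undetected
#' replicates as missing (`na.rm = TRUE`); a gene undetected in every
#' replicate of a population stays `NA`. Population order follows the design.
#'
#' @param x An `expr_mat`.
#' @param design A sample design tibble (see [read_sample_design()]).
#' @param min_detected Minimum number of detected replicates for the
#'   population mean to be reported (fewer detections give `NA`). Default 1.
#' @return An `expr_mat` with one column per population, same unit.
#' @export
pool_replicates <- function(x, design, min_detected = 1L) {
  stopifnot(is_expr_matrix(x))
  design <- design[design$sample %in% em_samples(x), , drop = FALSE]
  validate_design(x, design)
  m <- em_values(x)[, design$sample, drop = FALSE]
  pops <- unique(design$population)
  out <- vapply(pops, function(p) {
    cols <- m[, design$sample[design$population == p], drop = FALSE]
    mu <- rowMeans(cols, na.rm = TRUE)
    ndet <- rowSums(!is.na(cols))
    mu[ndet < min_detected] <- NA_real_
    mu[is.nan(mu)] <- NA_real_
    mu
  }, numeric(nrow(m)))
  colnames(out) <- pops
  rownames(out) <- rownames(m)
  em_replace(out, em_unit(x))
}

#' Count detected replicates per gene and population
#'
#' @inheritParams pool_replicates
#' @return A gene-by-population integer matrix of detection counts.
#' @export
detection_counts <- function(x, design) {
  stopifnot(is_expr_matrix(x))
  design <- design[design$sample %in% em_samples(x), , drop = FALSE]
  m <- em_values(x)[, design$sample, drop = FALSE]
  pops <- unique(design$population)
  out <- vapply(pops, function(p) {
    rowSums(!is.na(m[, design$sample[design$population == p], drop = FALSE]))
  }, numeric(nrow(m)))
  colnames(out) <- pops
  storage.mode(out) <- "integer"
  out
}
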