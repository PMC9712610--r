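# Readers and writers for the package's tabular inputs. All tables are
# tab-separated UTF-8 with a header row; empty cells or "NA" denote missing.
# Downstream stages consume only the objects returned here, never files.

read_tsv_quiet <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types, na = c("", "NA"),
                  progress = FALSE, show_col_types = FALSE)
}

#' Read an expression matrix from TSV
#'
#' The file must have a header row of sample identifiers and gene symbols in
#' the first column. Empty cells or `"NA"` denote missing values. Duplicate
#' gene or sample identifiers and negative values are hard errors.
#'
#' @param path Path to a TSV file.
#' @param unit Declared measurement unit (see [as_expr_matrix()]).
#' @return An `expr_mat`.
#' @export
read_expression_matrix <- function(path, unit) {
  # parse numbers via base R's strtod (correctly rounded), so that write
  # followed by read reproduces doubles bit-exactly
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE,
                         show_col_types = FALSE)
  names(tbl)[1L] <- "gene"
  for (s in names(tbl)[-1L]) tbl[[s]] <- as.numeric(tbl[[s]])
  as_expr_matrix(tbl, unit = unit)
}

#' Write an expression matrix to TSV
#'
#' Values round-trip exactly: [read_expression_matrix()] on the written file
#' reproduces the input bit for bit (full double precision is written).
#'
#' @param x An `expr_mat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(is_expr_matrix(x))
  tbl <- as_tibble(x)
  # 17 significant digits guarantee double round-trip exactness
  for (s in setdiff(names(tbl), "gene")) {
    v <- sprintf("%.17g", tbl[[s]])
    v[is.na(tbl[[s]])] <- NA_character_
    tbl[[s]] <- v
  }
  readr::write_tsv(tbl, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' Columns: `sample`, `population`, `replicate` (1..R), `layer`
#' (`"protein"` or `"rna"`), and optionally `tissue`. Population order is
#' taken from the file and preserved by all group-wise operations.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_sample_design <- function(path) {
  tbl <- read_tsv_quiet(path)
  need <- c("sample", "population", "replicate", "layer")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(sprintf("design file lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(tbl$sample)) {
    abort(sprintf("duplicated sample id(s) in design: %s",
                  paste(unique(tbl$sample[duplicated(tbl$sample)]), collapse = ", ")))
  }
  bad <- setdiff(unique(tbl$layer), c("protein", "rna"))
  if (length(bad)) {
    abort(sprintf("unknown layer value(s): %s", paste(bad, collapse = ", ")))
  }
  tbl$replicate <- as.integer(tbl$replicate)
  if (!"tissue" %in% names(tbl)) tbl$tissue <- NA_character_
  tbl
}

#' Read a gene annotation table
#'
#' Columns: `gene`, `molecular_weight` (g/mol), `theoretical_peptides`
#' (integer count of fully tryptic 7-30 aa peptides), and logical flags
#' `is_histone`, `is_ribosomal`, `is_tf`, `is_ligand`, `is_receptor`.
#' Absent flag columns default to `FALSE`.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_gene_annotation <- function(path) {
  tbl <- read_tsv_quiet(path)
  if (!"gene" %in% names(tbl)) names(tbl)[1L] <- "gene"
  if (anyDuplicated(tbl$gene)) {
    abort("duplicated gene id(s) in annotation.")
  }
  for (fl in c("is_histone", "is_ribosomal", "is_tf", "is_ligand", "is_receptor")) {
    if (!fl %in% names(tbl)) tbl[[fl]] <- FALSE
    tbl[[fl]] <- as.logical(tbl[[fl]]) %in% TRUE
  }
  if ("molecular_weight" %in% names(tbl)) {
    bad <- which(!is.na(tbl$molecular_weight) & tbl$molecular_weight <= 0)
    if (length(bad)) {
      abort(sprintf("non-positive molecular weight for gene `%s`.",
                    tbl$gene[bad[1L]]))
    }
  }
  tbl
}

#' Read a TF-to-target regulon table
#'
#' Columns: `tf`, `target`, optional `weight`. Self-edges (TF listed among
#' its own targets) are dropped with a warning.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_regulons <- function(path) {
  tbl <- read_tsv_quiet(path)
  need <- c("tf", "target")
  if (!all(need %in% names(tbl))) {
    names(tbl)[1:2] <- need
  }
  self <- tbl$tf == tbl$target
  if (any(self)) {
    warn(sprintf("dropping %d self-edge(s) from regulon table.", sum(self)))
    tbl <- tbl[!self, , drop = FALSE]
  }
  tbl
}

#' Read a ligand-receptor pair table
#'
#' Columns: `ligand`, `receptor`, optional `source`. Duplicate
#' (ligand, receptor) rows are an error.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_lr_pairs <- function(path) {
  tbl <- read_tsv_quiet(path)
  if (!all(c("ligand", "receptor") %in% names(tbl))) {
    names(tbl)[1:2] <- c("ligand", "receptor")
  }
  key <- paste(tbl$ligand, tbl$receptor, sep = "\r")
  if (anyDuplicated(key)) abort("duplicated (ligand, receptor) pair(s).")
  if (any(!nzchar(tbl$ligand)) || any(!nzchar(tbl$receptor))) {
    abort("empty ligand or receptor symbol.")
  }
  if (!"source" %in% names(tbl)) tbl$source <- NA_character_
  tbl
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, fields `name`, `description`, then
#' tab-separated member genes. Duplicate members within a line are
#' deduplicated with a warning; a line with fewer than three fields is a
#' hard error naming the line.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors with a `descriptions`
#'   attribute; class `gene_sets`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      abort(sprintf("GMT line %d has fewer than 3 fields.", i))
    }
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warn(sprintf("GMT set '%s': %d duplicate member(s) removed.",
                   f[1L], sum(duplicated(members))))
      members <- unique(members)
    }
    if (f[1L] %in% names(sets)) {
      abort(sprintf("duplicated gene-set name '%s'.", f[1L]))
    }
    sets[[f[1L]]] <- members
    descs[[f[1L]]] <- f[2L]
  }
  structure(sets, descriptions = descs, class = c("gene_sets", "list"))
}

#' Write gene sets in GMT format
#'
#' @param sets A named list of character vectors (class `gene_sets` or plain).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Check matrix/design consistency
#'
#' Verifies the bijection between matrix sample columns and design rows, and
#' that the design layer is compatible with the matrix unit (protein layers
#' carry `intensity`/`ibaq`/`copies_per_cell`/`fot`; RNA layers carry
#' `fpkm`/`copies_per_cell`).
#'
#' @param x An `expr_mat`.
#' @param design A sample design tibble.
#' @return Invisibly, `list(matrix = x, design = design)`; errors on any
#'   orphan sample or unit/layer mismatch.
#' @export
validate_design <- function(x, design) {
  stopifnot(is_expr_matrix(x))
  smp <- em_samples(x)
  orphan_m <- setdiff(smp, design$sample)
  orphan_d <- setdiff(design$sample, smp)
  if (length(orphan_m) || length(orphan_d)) {
    abort(sprintf(
      "matrix/design mismatch. In matrix only: %s. In design only: %s.",
      paste(orphan_m, collapse = ", ") %0% "none",
      paste(orphan_d, collapse = ", ") %0% "none"))
  }
  layer_units <- list(
    protein = c("intensity", "ibaq", "copies_per_cell", "fot"),
    rna     = c("fpkm", "copies_per_cell"))
  for (ly in unique(design$layer)) {
    if (!em_unit(x) %in% layer_units[[ly]]) {
      abort(sprintf("layer '%s' is incompatible with matrix unit '%s'.",
                    ly, em_unit(x)))
    }
  }
  invisible(list(matrix = x, design = design))
}

`%0%` <- function(x, fallback) if (nzchar(x)) x else fallback
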