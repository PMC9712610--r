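# Absolute quantification: theoretical tryptic peptide counting, iBAQ, FOT,
# the histone-anchored proteomic ruler (protein copies per cell), and the
# ribosome-anchored RNA ruler (mRNA copies per cell).

#' Count theoretical tryptic peptides
#'
#' Digest a protein sequence in silico with trypsin (cleavage C-terminal to
#' K or R, suppressed before proline - the Keil rule - and zero missed
#' cleavages) and count fragments of length 7 to 30 amino acids. This is the
#' peptide count that normalizes MS intensity to iBAQ.
#'
#' @param sequence Character vector of amino-acid sequences (standard
#'   20-letter alphabet; anything else is an error naming the position).
#' @param min_length,max_length Inclusive fragment-length window (7, 30).
#' @return Integer vector of peptide counts.
#' @examples
#' count_theoretical_peptides("AAAAKAAAAAAR")   # "AAAAK" too short -> 1
#' @export
count_theoretical_peptides <- function(sequence, min_length = 7L,
                                       max_length = 30L) {
  vapply(sequence, function(seq) {
    if (is.na(seq) || !nzchar(seq)) abort("empty protein sequence.")
    seq <- toupper(seq)
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", seq)
    if (bad > 0L) {
      abort(sprintf("non-standard residue '%s' at position %d.",
                    substr(seq, bad, bad), bad))
    }
    frags <- strsplit(seq, "(?<=[KR])(?!P)", perl = TRUE)[[1L]]
    sum(nchar(frags) >= min_length & nchar(frags) <= max_length)
  }, integer(1), USE.NAMES = FALSE)
}

#' Theoretical peptide counts from a protein FASTA
#'
#' Convenience wrapper that reads protein sequences and returns a tibble of
#' per-gene theoretical peptide counts suitable for a gene annotation table.
#'
#' @param path Path to an uncompressed protein FASTA file; record names are
#'   taken as gene symbols (first whitespace-delimited token).
#' @inheritParams count_theoretical_peptides
#' @return A tibble with columns `gene`, `theoretical_peptides`.
#' @export
theoretical_peptides_from_fasta <- function(path, min_length = 7L,
                                            max_length = 30L) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("theoretical_peptides_from_fasta() requires the Biostrings package.")
  }
  aa <- Biostrings::readAAStringSet(path)
  tibble(
    gene = sub("\\s.*$", "", names(aa)),
    theoretical_peptides = count_theoretical_peptides(
      as.character(aa), min_length, max_length))
}

#' iBAQ from raw intensity
#'
#' Divide each protein's MS intensity by its theoretical peptide count so
#' the signal is proportional to molar amount rather than to protein size.
#' Missing values stay missing.
#'
#' @param intensity An `expr_mat` with unit `"intensity"`.
#' @param annotation Gene annotation tibble with `gene` and
#'   `theoretical_peptides`; every quantified gene must have a positive count.
#' @return An `expr_mat` with unit `"ibaq"`.
#' @export
compute_ibaq <- function(intensity, annotation) {
  require_unit(intensity, "intensity")
  m <- em_values(intensity)
  counts <- setNames(annotation$theoretical_peptides, annotation$gene)
  quantified <- rownames(m)[rowSums(!is.na(m)) > 0]
  cnt <- counts[quantified]
  bad <- quantified[is.na(cnt) | cnt <= 0]
  if (length(bad)) {
    abort(sprintf("no positive theoretical peptide count for gene(s): %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  full <- counts[rownames(m)]
  em_replace(m / full, "ibaq")
}

#' Fraction of total (FOT)
#'
#' Normalize each sample column to the fraction of its summed iBAQ, scaled
#' by 1e7: `fot_i = ibaq_i / sum(ibaq_present) * 1e7`. Missing values stay
#' missing; an all-missing column is an error.
#'
#' @param x An `expr_mat` with unit `"ibaq"` (or `"intensity"` for tissue
#'   tables quantified without peptide counts).
#' @param scale Presentation scale, default `1e7`.
#' @return An `expr_mat` with unit `"fot"`.
#' @export
compute_fot <- function(x, scale = 1e7) {
  require_unit(x, c("ibaq", "intensity"))
  m <- em_values(x)
  tot <- colSums(m, na.rm = TRUE)
  empty <- colSums(!is.na(m)) == 0
  if (any(empty)) {
    abort(sprintf("all-missing sample column(s): %s",
                  paste(colnames(m)[empty], collapse = ", ")))
  }
  em_replace(sweep(m, 2, tot, "/") * scale, "fot")
}

#' Ruler calibration parameters
#'
#' Constants for the histone-anchored proteomic ruler and the
#' ribosome-anchored RNA ruler.
#'
#' @param dna_mass_per_cell Total DNA mass per cell in grams; default
#'   `5.5e-12` (diploid mouse genome).
#' @param signal_kind How the MS signal scales with protein amount:
#'   `"mole_proportional"` (iBAQ; the default) or `"mass_proportional"`
#'   (raw intensity).
#' @param rrna_mass_per_ribosome Molar mass of the rRNA complement of one
#'   ribosome (g/mol); default `2.2e6`.
#' @param rrna_fraction_of_total_rna Mass fraction of total RNA that is
#'   rRNA; default `0.80`.
#' @param mrna_mass_fraction_of_total_rna Mass fraction of total RNA that is
#'   mRNA; default `0.04`.
#' @param mean_mrna_molar_mass Mean molar mass of an mRNA molecule (g/mol);
#'   default `340 * 1800` (average nucleotide mass times average length).
#' @return A list of class `ruler_params`.
#' @export
ruler_params <- function(dna_mass_per_cell = 5.5e-12,
                         signal_kind = c("mole_proportional", "mass_proportional"),
                         rrna_mass_per_ribosome = 2.2e6,
                         rrna_fraction_of_total_rna = 0.80,
                         mrna_mass_fraction_of_total_rna = 0.04,
                         mean_mrna_molar_mass = 340 * 1800) {
  signal_kind <- match.arg(signal_kind)
  check_scalar_pos(dna_mass_per_cell, "dna_mass_per_cell")
  check_scalar_pos(rrna_mass_per_ribosome, "rrna_mass_per_ribosome")
  check_scalar_pos(mean_mrna_molar_mass, "mean_mrna_molar_mass")
  for (fr in c(rrna_fraction_of_total_rna, mrna_mass_fraction_of_total_rna)) {
    if (!is.numeric(fr) || fr <= 0 || fr >= 1) {
      abort("RNA mass fractions must lie in (0, 1).")
    }
  }
  structure(list(
    dna_mass_per_cell = dna_mass_per_cell,
    signal_kind = signal_kind,
    rrna_mass_per_ribosome = rrna_mass_per_ribosome,
    rrna_fraction_of_total_rna = rrna_fraction_of_total_rna,
    mrna_mass_fraction_of_total_rna = mrna_mass_fraction_of_total_rna,
    mean_mrna_molar_mass = mean_mrna_molar_mass,
    avogadro = AVOGADRO), class = "ruler_params")
}

#' Histone-anchored proteomic ruler
#'
#' Convert arbitrary-scale MS signal to absolute protein copies per cell,
#' assuming the total histone mass in a cell equals its DNA mass. With
#' mass-proportional signal (raw intensity), each protein's mass is
#' `m_DNA * s_i / sum(s_histones)` and copies follow by dividing by the
#' molecular weight; with mole-proportional signal (iBAQ),
#' `copies_i = m_DNA * N_A * s_i / sum(s_h * MW_h)` over detected histones.
#' Either way the result is invariant to a per-sample global rescaling of
#' the signal.
#'
#' @param signal An `expr_mat` with unit `"intensity"` (mass-proportional)
#'   or `"ibaq"` (mole-proportional); must match `params$signal_kind`.
#' @param annotation Gene annotation with `molecular_weight` and
#'   `is_histone`.
#' @param params A [ruler_params()] object.
#' @return An `expr_mat` with unit `"copies_per_cell"`.
#' @export
proteomic_ruler <- function(signal, annotation, params = ruler_params()) {
  stopifnot(inherits(params, "ruler_params"))
  expected_unit <- switch(params$signal_kind,
                          mole_proportional = "ibaq",
                          mass_proportional = "intensity")
  require_unit(signal, expected_unit)
  m <- em_values(signal)
  mw <- setNames(annotation$molecular_weight, annotation$gene)[rownames(m)]
  quantified <- rowSums(!is.na(m)) > 0
  if (any(quantified & (is.na(mw) | mw <= 0))) {
    abort(sprintf("missing molecular weight for quantified gene(s): %s",
                  paste(head(rownames(m)[quantified & (is.na(mw) | mw <= 0)], 10),
                        collapse = ", ")))
  }
  hist_genes <- intersect(annotation$gene[annotation$is_histone], rownames(m))
  if (!length(hist_genes)) abort("annotation flags no histone gene present in the matrix.")
  hm <- m[hist_genes, , drop = FALSE]
  no_hist <- colSums(!is.na(hm)) == 0
  if (any(no_hist)) {
    abort(sprintf("no detected histone in sample(s): %s",
                  paste(colnames(m)[no_hist], collapse = ", ")))
  }
  mD <- params$dna_mass_per_cell
  copies <- if (params$signal_kind == "mass_proportional") {
    denom <- colSums(hm, na.rm = TRUE)
    mass <- sweep(m, 2, mD / denom, "*")
    mass * AVOGADRO / mw
  } else {
    denom <- colSums(hm * mw[hist_genes], na.rm = TRUE)
    sweep(m, 2, mD * AVOGADRO / denom, "*")
  }
  em_replace(copies, "copies_per_cell")
}

#' Ribosome-anchored RNA ruler
#'
#' Convert FPKM to absolute mRNA copies per cell by anchoring on the
#' ribosome count. Ribosomal-protein copy numbers from the matched protein
#' layer give the ribosome count per cell (1:1 protein:rRNA stoichiometry;
#' the median over ribosomal-protein paralogs is used for robustness to
#' dropout). Total RNA mass follows from the rRNA mass per ribosome and the
#' rRNA fraction of total RNA; the mRNA mass fraction and mean mRNA molar
#' mass then give the total mRNA molecule count `N_mRNA`, which is
#' distributed over genes proportionally to FPKM (molar-proportional).
#'
#' @param fpkm An `expr_mat` with unit `"fpkm"`; columns must match
#'   `protein_copies` columns by name (e.g. population-level means).
#' @param protein_copies An `expr_mat` with unit `"copies_per_cell"`.
#' @param annotation Gene annotation with `is_ribosomal`.
#' @param params A [ruler_params()] object.
#' @param min_ribosomal Minimum number of detected ribosomal proteins per
#'   sample; default 3.
#' @return An `expr_mat` with unit `"copies_per_cell"`; per sample, copies
#'   sum exactly to the estimated `N_mRNA` (stored in attribute
#'   `n_mrna`).
#' @export
rna_ruler <- function(fpkm, protein_copies, annotation,
                      params = ruler_params(), min_ribosomal = 3L) {
  require_unit(fpkm, "fpkm")
  require_unit(protein_copies, "copies_per_cell")
  f <- em_values(fpkm)
  pc <- em_values(protein_copies)
  common <- intersect(colnames(f), colnames(pc))
  if (!length(common)) abort("no shared samples between FPKM and protein copies.")
  f <- f[, common, drop = FALSE]
  pc <- pc[, common, drop = FALSE]
  rb_genes <- intersect(annotation$gene[annotation$is_ribosomal], rownames(pc))
  rb <- pc[rb_genes, , drop = FALSE]
  ndet <- colSums(!is.na(rb))
  if (any(ndet < min_ribosomal)) {
    abort(sprintf("fewer than %d detected ribosomal proteins in sample(s): %s",
                  min_ribosomal,
                  paste(common[ndet < min_ribosomal], collapse = ", ")))
  }
  n_ribosome <- apply(rb, 2, median, na.rm = TRUE)
  total_rna_mass <- n_ribosome * params$rrna_mass_per_ribosome / AVOGADRO /
    params$rrna_fraction_of_total_rna
  n_mrna <- total_rna_mass * params$mrna_mass_fraction_of_total_rna *
    AVOGADRO / params$mean_mrna_molar_mass
  tot_f <- colSums(f, na.rm = TRUE)
  if (any(tot_f <= 0)) {
    abort(sprintf("zero total FPKM in sample(s): %s",
                  paste(common[tot_f <= 0], collapse = ", ")))
  }
  copies <- sweep(f, 2, n_mrna / tot_f, "*")
  out <- em_replace(copies, "copies_per_cell")
  attr(out, "n_mrna") <- setNames(n_mrna, common)
  out
}
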