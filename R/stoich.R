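# Elemental stoichiometry of the coarse-grained macromolecular pools.
#
# All ratios are mol:mol. Nucleic-acid ratios are derived from the residue
# composition of the four nucleotide monophosphates as incorporated in the
# polymer (one phosphorus per residue), weighted by genomic GC content.

# Atoms of C and N per nucleotide-monophosphate residue (base + sugar;
# the phosphate carries the single P). Ribose/deoxyribose contribute 5 C.
.nucleotide_atoms <- list(
  RNA = list(
    A = c(C = 10, N = 5),  # adenine C5N5 + ribose C5
    G = c(C = 10, N = 5),  # guanine C5N5O + ribose C5
    C = c(C = 9,  N = 3),  # cytosine C4N3O + ribose C5
    U = c(C = 9,  N = 2)   # uracil C4N2O2 + ribose C5
  ),
  DNA = list(
    A = c(C = 10, N = 5),
    G = c(C = 10, N = 5),
    C = c(C = 9,  N = 3),
    T = c(C = 10, N = 2)   # thymine C5N2O2 + deoxyribose C5
  )
)

#' Mean C and N atoms per phosphorus in a nucleic acid of given GC content
#'
#' Computes the GC-weighted mean number of carbon and nitrogen atoms per
#' phosphorus over the four nucleotide-monophosphate residues, assuming
#' equal G and C fractions (`gc_fraction/2` each) and equal A and U (RNA)
#' or A and T (DNA) fractions.
#'
#' @param gc_fraction Genomic GC fraction, in `[0, 1]`.
#' @param kind `"RNA"` or `"DNA"`.
#' @return Named numeric vector with elements `C_per_P` and `N_per_P`.
#' @examples
#' nucleic_acid_ratios(0.563, "RNA")  # c(C_per_P = 9.5, N_per_P = 3.7815)
#' @export
nucleic_acid_ratios <- function(gc_fraction, kind = c("RNA", "DNA")) {
  kind <- match.arg(kind)
  if (!is.numeric(gc_fraction) || length(gc_fraction) != 1L || is.na(gc_fraction) ||
      gc_fraction < 0 || gc_fraction > 1) {
    abort_domain("`gc_fraction` must be a single number in [0, 1]")
  }
  atoms <- .nucleotide_atoms[[kind]]
  # residue frequencies: G = C = gc/2, the two A/T (or A/U) bases split the rest
  w <- c(A = (1 - gc_fraction) / 2, G = gc_fraction / 2,
         C = gc_fraction / 2)
  w[[setdiff(names(atoms), names(w))]] <- (1 - gc_fraction) / 2
  c_per_p <- sum(vapply(names(atoms), function(b) w[[b]] * atoms[[b]][["C"]], 0))
  n_per_p <- sum(vapply(names(atoms), function(b) w[[b]] * atoms[[b]][["N"]], 0))
  c(C_per_P = c_per_p, N_per_P = n_per_p)
}

#' Stoichiometry of the nitrogen and phosphorus storage polymers
#'
#' Nitrogen is stored as cyanophycin, an equimolar aspartate-arginine
#' polymer; its C:N follows from the residue composition (Asp C4N1 +
#' Arg C6N4 per residue pair). Phosphorus is stored as polyphosphate,
#' which carries no carbon.
#'
#' @return Named numeric vector with `cyanophycin_CN` (mol C per mol N)
#'   and `polyphosphate_CP` (mol C per mol P, always 0).
#' @export
storage_polymer_ratios <- function() {
  asp <- c(C = 4, N = 1)
  arg <- c(C = 6, N = 4)
  pair <- asp + arg
  c(cyanophycin_CN = unname(pair[["C"]] / pair[["N"]]),
    polyphosphate_CP = 0)
}

#' Construct the set of elemental conversion constants
#'
#' Fixed mol:mol elemental ratios of the macromolecular pools. Defaults are
#' for a cyanobacterium-like composition: protein N:C = 1/3.82 (average
#' across species), chlorophyll a N:C = 4/55, thylakoid phospholipid
#' C:P = 40 (phosphatidylglycerol with C16 fatty acids), and nucleic-acid
#' ratios computed from the genomic GC fraction (default 0.563).
#'
#' @param gc_fraction Genomic GC fraction used for the RNA/DNA ratios.
#' @param Y_Pro_NC Protein N:C (mol N per mol C).
#' @param Y_Chl_NC Chlorophyll N:C.
#' @param Y_Plip_CP Phospholipid C:P (mol C per mol P). Taken as the
#'   conventional constant 40 rather than re-derived from structure.
#' @param Y_Nsto_CN Nitrogen-storage polymer C:N; defaults to cyanophycin.
#' @return An object of class `stoich_ratios`: a named list with fields
#'   `Y_Pro_NC`, `Y_Chl_NC`, `Y_DNA_NC`, `Y_DNA_PC`, `Y_RNA_NP`,
#'   `Y_RNA_CP`, `Y_Plip_CP`, `Y_Nsto_CN`, `gc_fraction`.
#' @examples
#' r <- default_ratios()
#' r$Y_RNA_CP   # 9.5 mol C per mol P in RNA
#' @export
stoich_ratios <- function(gc_fraction = 0.563,
                          Y_Pro_NC = 1 / 3.82,
                          Y_Chl_NC = 4 / 55,
                          Y_Plip_CP = 40,
                          Y_Nsto_CN = storage_polymer_ratios()[["cyanophycin_CN"]]) {
  rna <- nucleic_acid_ratios(gc_fraction, "RNA")
  dna <- nucleic_acid_ratios(gc_fraction, "DNA")
  out <- list(
    Y_Pro_NC = Y_Pro_NC,
    Y_Chl_NC = Y_Chl_NC,
    Y_DNA_NC = unname(dna[["N_per_P"]] / dna[["C_per_P"]]),
    Y_DNA_PC = unname(1 / dna[["C_per_P"]]),
    Y_RNA_NP = unname(rna[["N_per_P"]]),
    Y_RNA_CP = unname(rna[["C_per_P"]]),
    Y_Plip_CP = Y_Plip_CP,
    Y_Nsto_CN = Y_Nsto_CN,
    gc_fraction = gc_fraction
  )
  ratios <- vapply(out[setdiff(names(out), "gc_fraction")], identity, 0)
  if (any(ratios < 0) || any(!is.finite(ratios))) {
    abort_domain("all stoichiometric ratios must be finite and nonnegative")
  }
  structure(out, class = "stoich_ratios")
}

#' @rdname stoich_ratios
#' @export
default_ratios <- function() stoich_ratios()

#' @export
print.stoich_ratios <- function(x, ...) {
  cat("Elemental conversion constants (mol:mol), GC =", x$gc_fraction, "\n")
  for (nm in setdiff(names(x), "gc_fraction")) {
    cat(sprintf("  %-10s %.6g\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Table of macromolecular C:N:P stoichiometry
#'
#' Summarizes the C:N:P of each macromolecular pool implied by a
#' `stoich_ratios` object, one row per molecule, normalized to the
#' conventional reference element (N for protein and chlorophyll, P for
#' nucleic acids and phospholipid).
#'
#' @param ratios A [stoich_ratios()] object.
#' @return A tibble with columns `molecule`, `C`, `N`, `P`.
#' @export
stoich_table <- function(ratios = default_ratios()) {
  rna <- nucleic_acid_ratios(ratios$gc_fraction, "RNA")
  dna <- nucleic_acid_ratios(ratios$gc_fraction, "DNA")
  tibble::tibble(
    molecule = c("chlorophyll", "protein", "RNA", "DNA",
                 "phospholipid", "C_store", "N_store", "P_store"),
    C = c(4 / ratios$Y_Chl_NC, 1 / ratios$Y_Pro_NC,
          rna[["C_per_P"]], dna[["C_per_P"]],
          ratios$Y_Plip_CP, 1, ratios$Y_Nsto_CN, 0),
    N = c(4, 1, rna[["N_per_P"]], dna[["N_per_P"]], 0, 0, 1, 0),
    P = c(0, 0, 1, 1, 1, 0, 0, 1)
  )
}
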