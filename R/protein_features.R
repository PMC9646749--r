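#' Translate an ORF to a peptide
#'
#' Standard genetic code; a terminal stop codon is dropped. By construction
#' of the four ORF types no internal stop can occur, so an internal stop
#' raises an error (it indicates the input is not one of the typed ORFs).
#'
#' @param orf_sequence DNA string with length divisible by 3, or
#'   `NULL`/empty for an absent ORF.
#' @return The peptide as a one-letter-code string (possibly empty).
#' @examples
#' translate_orf("ATGAAATAG")  # "MK"
#' @export
translate_orf <- function(orf_sequence) {
  if (is.null(orf_sequence) || !nzchar(orf_sequence)) return("")
  L <- nchar(orf_sequence)
  if (L %% 3L != 0L) {
    stop("ORF length ", L, " is not divisible by 3", call. = FALSE)
  }
  starts <- seq(1L, L - 2L, by = 3L)
  codons <- substring(orf_sequence, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("ORF contains a non-ACGT codon", call. = FALSE)
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) stop("internal stop codon in ORF", call. = FALSE)
  paste(aa, collapse = "")
}

peptide_chars <- function(peptide) strsplit(peptide, "", fixed = TRUE)[[1]]

# net charge of the peptide at a given pH under the Bjellqvist pKa set,
# with residue-specific terminal pKa overrides
peptide_charge <- function(counts, first, last, pH) {
  pos_pk <- c(
    Nterm = unname(ifelse(first %in% names(PKA_NTERM), PKA_NTERM[first], PKA_POSITIVE[["Nterm"]])),
    PKA_POSITIVE[c("K", "R", "H")]
  )
  neg_pk <- c(
    Cterm = unname(ifelse(last %in% names(PKA_CTERM), PKA_CTERM[last], PKA_NEGATIVE[["Cterm"]])),
    PKA_NEGATIVE[c("D", "E", "C", "Y")]
  )
  pos_n <- c(Nterm = 1, counts[c("K", "R", "H")])
  neg_n <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  positive <- sum(pos_n / (1 + 10^(pH - pos_pk)))
  negative <- sum(neg_n / (1 + 10^(neg_pk - pH)))
  positive - negative
}

#' Theoretical isoelectric point of a peptide
#'
#' The pH at which the peptide's net charge is zero, solved by bisection on
#' the Henderson--Hasselbalch charge balance over the ionisable groups
#' (free termini plus D, E, C, Y, H, K, R side chains) with the Bjellqvist
#' pKa set used by Expasy ProtParam. Converges to `|Q| < 1e-4`.
#'
#' @param peptide One-letter-code peptide string.
#' @return pH in `(0, 14)`; 0 for an empty peptide.
#' @export
isoelectric_point <- function(peptide) {
  if (!nzchar(peptide)) return(0)
  chars <- peptide_chars(peptide)
  counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(a) sum(chars == a), numeric(1))
  first <- chars[1]
  last <- chars[length(chars)]
  lo <- 0; hi <- 14
  for (iter in 1:100) {
    mid <- (lo + hi) / 2
    q <- peptide_charge(counts, first, last, mid)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Molecular weight of a peptide
#'
#' Sum of average residue masses plus one water (the free amino-acid masses
#' minus one water per peptide bond).
#'
#' @param peptide One-letter-code peptide string.
#' @return Mass in Daltons; 0 for an empty peptide.
#' @export
molecular_weight <- function(peptide) {
  if (!nzchar(peptide)) return(0)
  chars <- peptide_chars(peptide)
  sum(RESIDUE_MASS[chars]) - (length(chars) - 1L) * WATER_MASS
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte--Doolittle hydropathy over the peptide's residues. Positive
#' values are hydrophobic, negative hydrophilic.
#'
#' @param peptide One-letter-code peptide string.
#' @return The GRAVY value; 0 for an empty peptide.
#' @export
gravy <- function(peptide) {
  if (!nzchar(peptide)) return(0)
  mean(KYTE_DOOLITTLE[peptide_chars(peptide)])
}

#' Aromaticity of a peptide
#'
#' Fraction of aromatic residues (Phe, Trp, Tyr).
#'
#' @param peptide One-letter-code peptide string.
#' @return A fraction in `[0, 1]`; 0 for an empty peptide.
#' @export
aromaticity <- function(peptide) {
  if (!nzchar(peptide)) return(0)
  chars <- peptide_chars(peptide)
  sum(chars %in% c("F", "W", "Y")) / length(chars)
}

#' Guruprasad instability index
#'
#' `II = (10 / L) * sum` of the dipeptide instability weights (DIWV) over
#' the peptide's `L - 1` adjacent residue pairs. Values above 40 suggest an
#' unstable protein in vitro. Peptides shorter than 2 residues score 0.
#'
#' @param peptide One-letter-code peptide string.
#' @return The instability index.
#' @export
instability_index <- function(peptide) {
  L <- nchar(peptide)
  if (L < 2L) return(0)
  chars <- peptide_chars(peptide)
  sum(DIWV[cbind(chars[-L], chars[-1])]) * 10 / L
}

#' Protein features of the four max ORFs
#'
#' Translates each max ORF and computes the five physicochemical features
#' (isoelectric point, molecular weight, GRAVY, aromaticity, instability
#' index) for each, yielding the 20-value protein feature block. Absent
#' ORFs contribute zeros.
#'
#' @param orfs An `orf_set` from [find_typed_orfs()].
#' @return A named numeric vector of 20 features
#'   (`pi_t0`, `mw_t0`, ..., `instability_t3`).
#' @export
protein_features <- function(orfs) {
  out <- numeric(0)
  for (t in c("t0", "t1", "t2", "t3")) {
    o <- orfs[[t]]
    pep <- if (is.null(o)) "" else translate_orf(o$sequence)
    vals <- c(
      isoelectric_point(pep), molecular_weight(pep), gravy(pep),
      aromaticity(pep), instability_index(pep)
    )
    names(vals) <- paste0(c("pi_", "mw_", "gravy_", "aromaticity_", "instability_"), t)
    out <- c(out, vals)
  }
  out
}
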