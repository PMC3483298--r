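# Nearest-neighbor duplex thermodynamics, SantaLucia (1998) unified
# parameters. dH in kcal/mol, dS in cal/(mol K); the ten unique stacks are
# expanded to all sixteen dinucleotides so Tm(x) == Tm(reverse_complement(x))
# holds by table symmetry.
.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Oligonucleotide melting temperature
#'
#' Nearest-neighbor Tm (SantaLucia 1998 unified parameter set) with terminal
#' initiation penalties and an entropic salt correction
#' (0.368 x (N-1) x ln[Na+]). Defaults mirror the assay's reaction
#' conditions: 50 mM monovalent-cation equivalent and 500 nM of each primer.
#' The duplex is assumed non-self-complementary (total-strand concentration
#' divided by four).
#'
#' @param seq nucleotide string(s), length >= 8.
#' @param na_molar monovalent cation concentration, mol/L.
#' @param oligo_molar total oligonucleotide concentration, mol/L.
#' @return Tm in degrees Celsius (vectorised over `seq`).
#' @examples
#' melting_temperature("GCGCGCGCGC") > melting_temperature("ATATATATAT")
#' @export
melting_temperature <- function(seq, na_molar = 0.05, oligo_molar = 500e-9) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    s <- toupper(s)
    if (!grepl("^[ACGT]+$", s)) stop("Tm: sequence must be A/C/G/T", call. = FALSE)
    n <- nchar(s)
    if (n < 8L) stop("Tm: sequence too short (need >= 8 nt)", call. = FALSE)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    stacks <- paste0(ch[-n], ch[-1])
    dh <- sum(.nn_dh[stacks])
    ds <- sum(.nn_ds[stacks])
    # initiation: terminal G.C pair 0.1 / -2.8, terminal A.T pair 2.3 / 4.1
    for (end in ch[c(1L, n)]) {
      if (end %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else                      { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (n - 1L) * log(na_molar)
    tm_k <- dh * 1000 / (ds + 1.987 * log(oligo_molar / 4))
    tm_k - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}
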