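## Nearest-neighbor duplex thermodynamics.
##
## Unified DNA nearest-neighbor parameters (SantaLucia-type table of
## dinucleotide enthalpies/entropies with terminal initiation terms),
## monovalent-salt entropy correction, and an equivalent-monovalent
## heuristic for divalent cations (Na_eq = Na + 120 sqrt(Mg[mM]) mM).

## dH in kcal/mol, dS in cal/(mol K); keys are the 5'->3' top-strand
## dinucleotide of the duplex step.
.nn_dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
## terminal initiation terms, per 5'/3' end
.nn_init <- list("A" = c(dH = 2.3, dS = 4.1), "T" = c(dH = 2.3, dS = 4.1),
                 "G" = c(dH = 0.1, dS = -2.8), "C" = c(dH = 0.1, dS = -2.8))
## symmetry correction for self-complementary duplexes
.nn_sym <- c(dH = 0, dS = -1.4)

.nn_thermo <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("sequence contains a non-ACGT character")
  }
  if (length(chars) < 2) stop("domain shorter than 2 nt")
  steps <- paste0(chars[-length(chars)], chars[-1])
  dH <- sum(.nn_dH[steps]) + .nn_init[[chars[1]]]["dH"] +
    .nn_init[[chars[length(chars)]]]["dH"]
  dS <- sum(.nn_dS[steps]) + .nn_init[[chars[1]]]["dS"] +
    .nn_init[[chars[length(chars)]]]["dS"]
  c(dH = unname(dH), dS = unname(dS))
}

#' Duplex melting temperature from nearest-neighbor thermodynamics
#'
#' Computes the two-state melting temperature of a perfectly matched DNA
#' duplex: `Tm = 1000 dH / (dS' + R ln(CT/x)) - 273.15`, where dH/dS are
#' the nearest-neighbor sums with terminal initiation terms, x is 4 for a
#' non-self-complementary duplex (1 with the symmetry correction for a
#' self-complementary one), and the entropy carries the monovalent-salt
#' correction `dS' = dS + 0.368 (N-1) ln[Na+]`.  Divalent salt is folded in
#' through the equivalent-monovalent heuristic
#' `[Na+]_eq = [Na+] + 0.120 sqrt([Mg2+] in M) * sqrt(1000)` (i.e.
#' 120 sqrt(mM) in mM).
#'
#' @param sequence top-strand sequence, 5'->3', A/C/G/T only.
#' @param strandConcM total strand concentration, molar (default 1e-6).
#' @param monovalentM monovalent cation concentration, molar (default 0.15).
#' @param divalentM divalent cation concentration, molar (default 0).
#' @return melting temperature in degrees C.
#' @examples
#' duplexTm("GCTAGCTAGG")  # about 34.4 degC at 1 uM, 150 mM Na+
#' @export
duplexTm <- function(sequence, strandConcM = 1e-6, monovalentM = 0.15,
                     divalentM = 0) {
  stopifnot(strandConcM > 0, monovalentM > 0, divalentM >= 0)
  sequence <- toupper(sequence)
  th <- .nn_thermo(sequence)
  selfcomp <- identical(sequence, .revcomp(sequence))
  if (selfcomp) th <- th + .nn_sym
  n <- nchar(sequence)
  na_eq <- monovalentM + 120 * sqrt(divalentM * 1000) / 1000
  dS <- th["dS"] + 0.368 * (n - 1) * log(na_eq)
  k <- if (selfcomp) strandConcM else strandConcM / 4
  unname(1000 * th["dH"] / (dS + .sheetkit_const$gas_constant * log(k)) - 273.15)
}

#' Per-domain melting temperatures of an F-unit design
#'
#' Extracts the core, arm and the two sticky-end domain duplexes from the
#' design's strand sequences and computes each melting temperature with
#' [duplexTm()] under common conditions.  With the design's duplex lengths
#' (21/16/10 bp) the ordering Tm(core) > Tm(arm) > Tm(sticky ends) drives
#' the hierarchical assembly: the core hybridizes first, then the arms,
#' and finally the sticky ends.
#'
#' @param design a [FUnitDesign-class] with sequences (see
#'   [makeDesignSequences()]).
#' @param strandConcM,monovalentM,divalentM conditions passed to
#'   [duplexTm()].
#' @return a [DomainTmSet-class].
#' @export
domainMeltingTemperatures <- function(design, strandConcM = 1e-6,
                                      monovalentM = 0.15, divalentM = 0) {
  if (!length(design@sequences)) {
    stop("design has no sequences; call makeDesignSequences() first")
  }
  lay <- .funit_layout(design)
  A <- design@sequences$A
  dom <- function(idx) substr(A, idx[1], idx[length(idx)])
  tm <- function(s) duplexTm(s, strandConcM, monovalentM, divalentM)
  new("DomainTmSet",
      tmCore = tm(dom(lay$A$core)),
      tmArm = tm(dom(lay$A$armL)),
      tmSe1 = tm(dom(lay$A$se1)),
      tmSe2 = tm(dom(lay$A$se2)),
      conditions = list(strandConcM = strandConcM, monovalentM = monovalentM,
                        divalentM = divalentM))
}
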