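# Published repeat motifs of the ridged-eye flounder (Pleuronichthys
# cornutus) control region: the worked example the clone-comparison and
# birth-signature operations are demonstrated on.

#' Ridged-eye flounder control-region repeat motifs
#'
#' The repeat cluster at the 3' end of the *P. cornutus* control region has
#' three motif types: a 5'-TR (near CSB3), an M-TR between them, and a 3'-TR
#' (near tRNA-Phe) with two single-base variants. Two individuals carry a
#' newly born M-TR: in DS-03 a 58-base unit of the otherwise unrepeated
#' 65-base section is tandemly duplicated, in QD-07 a 48-base unit is
#' present in four or five copies. In both, the unit's first bases recur
#' immediately after the tract (TTTAA and AACACT) — the birth signature.
#'
#' @return named list:
#' \describe{
#'   \item{tr5}{5'-TR motif ATATTACA}
#'   \item{tr3}{3'-TR motif TTTAATGT}
#'   \item{tr3_v1,tr3_v2}{single-base 3'-TR variants TGTAATGT, TATAATGT}
#'   \item{mtr_section}{the 65-base section, unrepeated in 18 of 20
#'     individuals}
#'   \item{ds03_unit,ds03_flank}{DS-03 duplicated 58-mer and the sequence
#'     following its tract}
#'   \item{qd07_prefix,qd07_unit,qd07_flank}{QD-07 leading bases, duplicated
#'     48-mer and following sequence}
#' }
#' @export
flounder_motifs <- function() {
  list(
    tr5 = "ATATTACA",
    tr3 = "TTTAATGT",
    tr3_v1 = "TGTAATGT",
    tr3_v2 = "TATAATGT",
    mtr_section = paste0("TTTATAACACTATTTATCAAAATACTCAAATTT",
                         "GTGGTGCCCAGGATATTTAGAACACTTTAATG"),
    ds03_unit = paste0("TTTAAAACACTATTTATCAAAATACTCAAATTT",
                       "GTGGTGCCCAGGATATTTAGAACAC"),
    ds03_flank = "TTTAATG",
    qd07_prefix = "TTTGT",
    qd07_unit = paste0("AACACTATTTATCAAAATACTCAAATTT",
                       "GTGGTGCCCAGGATATTTAG"),
    qd07_flank = "AACACTTTAATG"
  )
}

#' The flounder 3'-TR motif alphabet
#'
#' Convenience wrapper: canonical TTTAATGT (symbol "R") with variants
#' v1 = TGTAATGT and v2 = TATAATGT at Hamming distance 1.
#'
#' @return a [motif_alphabet()].
#' @export
flounder_tr3_alphabet <- function() {
  m <- flounder_motifs()
  motif_alphabet(m$tr3, c(v1 = m$tr3_v1, v2 = m$tr3_v2), max_hamming = 1L)
}
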