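#' Residue alphabets used by positional scanning peptide arrays
#'
#' The fixed-residue dimension of a PSPA comprises the 20 natural amino
#' acids plus two phospho-residues, phosphothreonine ("t") and
#' phosphotyrosine ("y").  Randomized (non-fixed) positions of the peptide
#' library contain a background mixture of natural amino acids that always
#' excludes Tyr and Cys; the extended library used for dual-specificity
#' kinases additionally excludes Ser and Thr, giving background sizes of
#' 18 and 16 respectively.
#'
#' @format Character vectors in fixed row order.
#' @name alphabets
NULL

#' @rdname alphabets
#' @export
AA_NATURAL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @rdname alphabets
#' @export
AA_PTM <- c("t", "y")

#' @rdname alphabets
#' @export
AA_FIXED <- c(AA_NATURAL, AA_PTM)

#' Peptide positions flanking the central phosphoacceptor
#'
#' Positions -5..-1 and +1..+5; position 0 is the central Tyr and is never
#' varied on the array.
#' @export
PSPA_POSITIONS <- c(-5:-1, 1:5)

.position_labels <- function(pos = PSPA_POSITIONS) as.character(pos)

#' Randomized-background residues for a given library
#'
#' @param background_size 18 (standard library, all natural amino acids
#'   except Tyr and Cys) or 16 (extended library, additionally lacking Ser
#'   and Thr).
#' @return Character vector of background residue letters.
#' @export
background_residues <- function(background_size) {
  if (!background_size %in% c(18L, 16L)) {
    stop("background_size must be 18 or 16, got ", background_size)
  }
  excl <- if (background_size == 18L) c("Y", "C") else c("S", "T", "Y", "C")
  setdiff(AA_NATURAL, excl)
}

#' Number of unique peptide mixtures on a full array
#'
#' One mixture per (fixed residue, fixed position) pair: 22 residues at
#' each of 10 positions.
#'
#' @return Integer count of fixed (residue, position) peptide mixtures.
#' @export
pspa_library_size <- function() {
  length(AA_FIXED) * length(PSPA_POSITIONS)
}
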