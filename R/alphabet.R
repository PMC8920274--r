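#' @useDynLib protstab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Canonical symbol orders. These are frozen so that one-hot row indices are
# stable across sessions and checkpoints; do not reorder.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.PRIMARY_EM <- c(.AA20, "X", "J", "O")   # 20 residues + pad, start, stop
.SECONDARY  <- c("L", "E", "H", "X", "J", "O")
.GM_STOP    <- "O"
.PRIMARY_GM <- c(setdiff(.AA20, "C"), .GM_STOP)  # cysteine excluded + stop
.HYDROPHOBIC <- c("A", "F", "I", "L", "M", "V", "W", "Y")

#' Alphabets used throughout the package
#'
#' `primaryAlphabet()` returns the 23-symbol alphabet used by the evaluator
#' and unfolded-state models: the 20 amino acids in fixed order followed by
#' `"X"` (padding), `"J"` (start) and `"O"` (stop). `secondaryAlphabet()`
#' returns the 6 secondary-structure symbols (loop, strand, helix, pad,
#' start, stop). `generatorAlphabet()` returns the generator's output
#' vocabulary: 19 amino acids (cysteine is excluded because disulfide bonds
#' confound the proteolysis assay) plus the stop token. The symbol orders
#' are fixed so that one-hot row indices are reproducible.
#'
#' @return A character vector of symbols.
#' @examples
#' length(primaryAlphabet())    # 23
#' length(generatorAlphabet())  # 20 = 19 residues + stop
#' @export
primaryAlphabet <- function() .PRIMARY_EM

#' @rdname primaryAlphabet
#' @export
secondaryAlphabet <- function() .SECONDARY

#' @rdname primaryAlphabet
#' @export
generatorAlphabet <- function() .PRIMARY_GM

#' @rdname primaryAlphabet
#' @export
aminoAcids <- function() .AA20

#' Hydrophobic residue class
#'
#' The eight-residue nonpolar class \{A,F,I,L,M,V,W,Y\} used both for
#' patterned scrambles (hydrophobic/hydrophilic patterning is preserved)
#' and as the large forbidden-target set during constrained refinement.
#' One definition is shared by all modules.
#'
#' @return Character vector of eight amino-acid letters.
#' @export
hydrophobicResidues <- function() .HYDROPHOBIC

.splitSeq <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.checkSymbols <- function(x, alphabet, what = "sequence") {
  ch <- .splitSeq(x)
  bad <- setdiff(unique(ch), alphabet)
  if (length(bad) > 0L) {
    stop(sprintf("illegal %s symbol(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
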