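#' The fourteen-type sequence perturbation suite
#'
#' Registry of the fourteen perturbation types used to probe the
#' evaluator's sensitivity to sequence disruption: three single-site
#' changes at uniformly random positions (substitution, insertion,
#' deletion), their three "central" variants restricted to exclude the
#' first and last ten residues, sequence reversal, four cyclic shifts
#' (moving the first 1, 5, 10 or 20 residues to the end), and three
#' half-keeps (first 50\%, last 50\%, even-indexed 50\%). The registry is
#' configurable: `cyclicShifts` and the half-keep modes may be overridden.
#'
#' @param cyclicShifts integer vector of shift amounts (default
#'   `c(1, 5, 10, 20)`).
#' @return `perturbationTypes` returns a character vector of type names.
#' @examples
#' perturbationTypes()
#' @export
perturbationTypes <- function(cyclicShifts = c(1L, 5L, 10L, 20L)) {
  c("substitution", "insertion", "deletion",
    "central_substitution", "central_insertion", "central_deletion",
    "reversal", paste0("cyclic_shift_", cyclicShifts),
    "half_first", "half_last", "half_even")
}

#' Apply a perturbation to a design
#'
#' Applies one of the registered perturbation types to the primary
#' sequence of a single design. Substitutions draw the replacement
#' uniformly from the 19 non-identical amino acids; insertions draw a
#' uniform residue and position (len+1 slots); central variants restrict
#' the touched position to exclude the first and last ten residues (and so
#' require length >= 21). Rearrangements (reversal, cyclic shifts)
#' preserve the residue multiset exactly. The perturbed design keeps its
#' id with a type suffix, drops its secondary string (no longer aligned),
#' and is tagged `provenance = "perturbed"`.
#'
#' @param design a [ProteinDesignSet-class] of length 1, or a plain
#'   sequence string.
#' @param type a name from [perturbationTypes()].
#' @param seed integer seed for the positional/residue draws.
#' @return An object of the same kind as `design` (perturbed).
#' @examples
#' perturbDesign("MKVLA", "reversal")        # "ALVKM"
#' perturbDesign("MKVLA", "cyclic_shift_1")  # "KVLAM"
#' @export
perturbDesign <- function(design, type, seed = 0L) {
  if (is(design, "ProteinDesignSet")) {
    stopifnot(length(design) == 1L)
    newSeq <- perturbSequence(design@primary, type, seed)
    return(ProteinDesignSet(id = paste0(design@id, "|", type),
                            primary = newSeq, secondary = NA_character_,
                            designClass = design@designClass,
                            provenance = "perturbed"))
  }
  perturbSequence(design, type, seed)
}

#' @rdname perturbDesign
#' @param sequence a primary sequence string.
#' @export
perturbSequence <- function(sequence, type, seed = 0L) {
  ch <- .splitSeq(sequence)
  len <- length(ch)
  rng <- .localRNG(seed)
  pick <- function(n) 1L + (rng(n) - 1L)

  if (grepl("^cyclic_shift_", type)) {
    n <- as.integer(sub("^cyclic_shift_", "", type))
    if (len <= n) stop("sequence too short for ", type, call. = FALSE)
    return(paste(c(ch[-seq_len(n)], ch[seq_len(n)]), collapse = ""))
  }
  central <- grepl("^central_", type)
  if (central && len < 21L) {
    stop("central perturbations require length >= 21", call. = FALSE)
  }
  base <- sub("^central_", "", type)
  switch(base,
    substitution = {
      pos <- if (central) 10L + pick(len - 20L) else pick(len)
      ch[pos] <- setdiff(.AA20, ch[pos])[pick(19L)]
      paste(ch, collapse = "")
    },
    insertion = {
      # position among len+1 slots; central: insertion point strictly
      # inside the central region
      slot <- if (central) 10L + pick(len - 19L) else pick(len + 1L) - 1L
      res <- .AA20[pick(20L)]
      paste(append(ch, res, after = slot), collapse = "")
    },
    deletion = {
      pos <- if (central) 10L + pick(len - 20L) else pick(len)
      paste(ch[-pos], collapse = "")
    },
    reversal = paste(rev(ch), collapse = ""),
    half_first = paste(ch[seq_len(len %/% 2L)], collapse = ""),
    half_last = paste(ch[(len - len %/% 2L + 1L):len], collapse = ""),
    half_even = paste(ch[seq(2L, len, by = 2L)], collapse = ""),
    stop("unknown perturbation type: ", type, call. = FALSE)
  )
}

# Deterministic local RNG (linear congruential, Numerical Recipes
# constants) so perturbations never disturb R's global RNG stream.
# Returns a closure: rng(n) gives an integer in 1..n.
.localRNG <- function(seed) {
  state <- (as.numeric(seed) + 12345) %% 4294967296
  function(n) {
    state <<- (1664525 * state + 1013904223) %% 4294967296
    1L + as.integer(floor(state / 4294967296 * n))
  }
}
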