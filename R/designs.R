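#' ProteinDesignSet: a set of designed mini-proteins
#'
#' The container that flows through every stage of the pipeline: primary
#' sequences over the 20-amino-acid alphabet, optional aligned secondary
#' strings over \{L,E,H\}, a design-class label (topology x library x
#' method) and a provenance tag. Sequences must be 1--145 residues so they
#' fit the middle-145 placement window of the 23 x 175 encoding.
#'
#' @slot id character vector of unique design identifiers.
#' @slot primary character vector of primary sequences.
#' @slot secondary character vector of secondary strings (`NA` if absent);
#'   when present, same length as the paired primary.
#' @slot designClass character vector of class labels.
#' @slot provenance character vector; one of `expert`, `generated`,
#'   `scramble`, `natural`, `perturbed`, `refined`.
#'
#' @export
setClass("ProteinDesignSet",
  representation(id = "character", primary = "character",
                 secondary = "character", designClass = "character",
                 provenance = "character"))

.PROVENANCE <- c("expert", "generated", "scramble", "natural",
                 "perturbed", "refined")

setValidity("ProteinDesignSet", function(object) {
  n <- length(object@id)
  if (length(object@primary) != n || length(object@secondary) != n ||
      length(object@designClass) != n || length(object@provenance) != n)
    return("all slots must have equal length")
  if (anyDuplicated(object@id)) return("design ids must be unique")
  len <- nchar(object@primary)
  if (any(len < 1L | len > 145L))
    return("primary sequences must be 1..145 residues (placement window)")
  ok <- !vapply(object@primary, function(p)
    any(!.splitSeq(p) %in% .AA20), logical(1))
  if (!all(ok)) return("primary sequences must use the 20-AA alphabet")
  has2 <- !is.na(object@secondary)
  if (any(nchar(object@secondary[has2]) != len[has2]))
    return("secondary strings must match primary length")
  if (any(has2)) {
    ok2 <- vapply(object@secondary[has2], function(s)
      all(.splitSeq(s) %in% c("L", "E", "H")), logical(1))
    if (!all(ok2)) return("secondary strings must be over {L,E,H}")
  }
  if (any(!object@provenance %in% .PROVENANCE))
    return(sprintf("provenance must be one of: %s",
                   paste(.PROVENANCE, collapse = ", ")))
  TRUE
})

#' Construct a ProteinDesignSet
#'
#' @param id character vector of unique ids.
#' @param primary character vector of primary sequences (20-AA alphabet,
#'   1--145 residues).
#' @param secondary optional character vector over \{L,E,H\}, aligned
#'   one-to-one with `primary`; `NA` where absent.
#' @param designClass optional class labels (default `"unclassified"`).
#' @param provenance provenance tags (default `"expert"`).
#' @return A [ProteinDesignSet-class] object.
#' @examples
#' ds <- ProteinDesignSet(id = "d1", primary = "MKVLAT", secondary = "LHHHHL")
#' primarySeq(ds)
#' @export
ProteinDesignSet <- function(id, primary, secondary = NA_character_,
                             designClass = "unclassified",
                             provenance = "expert") {
  n <- length(primary)
  new("ProteinDesignSet",
      id = as.character(id),
      primary = as.character(primary),
      secondary = rep_len(as.character(secondary), n),
      designClass = rep_len(as.character(designClass), n),
      provenance = rep_len(as.character(provenance), n))
}

#' @describeIn ProteinDesignSet-class number of designs
#' @param x a `ProteinDesignSet`
#' @export
setMethod("length", "ProteinDesignSet", function(x) length(x@id))

#' @describeIn ProteinDesignSet-class subset by index, logical or id
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "ProteinDesignSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@id)
  new("ProteinDesignSet", id = x@id[i], primary = x@primary[i],
      secondary = x@secondary[i], designClass = x@designClass[i],
      provenance = x@provenance[i])
})

#' @describeIn ProteinDesignSet-class design identifiers
#' @export
designId <- function(x) x@id

#' @describeIn ProteinDesignSet-class primary sequences (named by id)
#' @export
primarySeq <- function(x) stats::setNames(x@primary, x@id)

#' @describeIn ProteinDesignSet-class secondary strings (named by id)
#' @export
secondarySeq <- function(x) stats::setNames(x@secondary, x@id)

#' @describeIn ProteinDesignSet-class design class labels
#' @export
designClass <- function(x) stats::setNames(x@designClass, x@id)

#' @describeIn ProteinDesignSet-class provenance tags
#' @export
provenance <- function(x) stats::setNames(x@provenance, x@id)

setMethod("show", "ProteinDesignSet", function(object) {
  n <- length(object)
  cat(sprintf("ProteinDesignSet with %d design%s\n", n,
              if (n == 1L) "" else "s"))
  if (n > 0L) {
    cat(sprintf("  lengths: %d..%d residues; secondary present for %d\n",
                min(nchar(object@primary)), max(nchar(object@primary)),
                sum(!is.na(object@secondary))))
    tab <- table(object@provenance)
    cat("  provenance:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  }
})

#' Combine two design sets
#' @param x,y `ProteinDesignSet` objects with disjoint ids.
#' @return the concatenated `ProteinDesignSet`.
#' @export
combineDesigns <- function(x, y) {
  new("ProteinDesignSet", id = c(x@id, y@id), primary = c(x@primary, y@primary),
      secondary = c(x@secondary, y@secondary),
      designClass = c(x@designClass, y@designClass),
      provenance = c(x@provenance, y@provenance))
}

#' Read and write design sets
#'
#' Primary sequences travel as FASTA (via Biostrings); secondary strings,
#' class labels and provenance travel in a tab-separated companion table
#' with columns `id`, `secondary`, and optionally `design_class`,
#' `provenance`.
#'
#' @param fasta path to a FASTA file of primary sequences.
#' @param secondaryTsv optional path to the companion TSV.
#' @return `readDesigns` returns a [ProteinDesignSet-class].
#' @export
readDesigns <- function(fasta, secondaryTsv = NULL) {
  aa <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(aa))
  sec <- rep(NA_character_, length(aa))
  cls <- rep("unclassified", length(aa))
  prov <- rep("expert", length(aa))
  if (!is.null(secondaryTsv)) {
    tab <- utils::read.delim(secondaryTsv, comment.char = "#",
                             stringsAsFactors = FALSE)
    m <- match(ids, tab$id)
    if ("secondary" %in% names(tab)) sec <- tab$secondary[m]
    if ("design_class" %in% names(tab)) {
      cls <- tab$design_class[m]
      cls[is.na(cls)] <- "unclassified"
    }
    if ("provenance" %in% names(tab)) {
      prov <- tab$provenance[m]
      prov[is.na(prov)] <- "expert"
    }
  }
  ProteinDesignSet(id = ids, primary = as.character(aa), secondary = sec,
                   designClass = cls, provenance = prov)
}

#' @rdname readDesigns
#' @param x a `ProteinDesignSet`.
#' @param header optional named list written as `# key: value` comment
#'   lines at the top of the TSV.
#' @export
writeDesigns <- function(x, fasta, secondaryTsv = NULL, header = NULL) {
  aa <- Biostrings::AAStringSet(stats::setNames(x@primary, x@id))
  Biostrings::writeXStringSet(aa, fasta, width = 60L)
  if (!is.null(secondaryTsv)) {
    df <- data.frame(id = x@id, secondary = x@secondary,
                     design_class = x@designClass, provenance = x@provenance,
                     stringsAsFactors = FALSE)
    writeStampedTSV(df, secondaryTsv, header = header)
  }
  invisible(fasta)
}
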