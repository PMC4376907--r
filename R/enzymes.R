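#' @import methods
#' @importClassesFrom Biostrings DNAStringSet BStringSet
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom stats cor sd setNames rbinom rbeta runif
#' @importFrom utils head tail read.delim write.table
NULL

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Restriction enzyme
#'
#' An `Enzyme` couples an IUPAC recognition site with the position of the
#' top-strand cut inside that site. The cut offset is the number of bases of
#' the recognition site that remain on the left fragment, so `PstI`
#' (CTGCA^G) has offset 5 and `MspI` (C^CGG) offset 1.
#'
#' @slot name single identifier string.
#' @slot recognition recognition site using IUPAC nucleotide codes.
#' @slot cutOffset integer in `[0, nchar(recognition)]`; top-strand cut
#'   position relative to the start of the recognition site.
#'
#' @examples
#' Enzyme("EcoRI", "GAATTC", 1L)
#' gbsEnzyme("ApeKI")
#' @export
setClass("Enzyme",
    representation(name = "character", recognition = "character",
                   cutOffset = "integer"))

setValidity("Enzyme", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@recognition) != 1L || !nzchar(object@recognition))
        msg <- c(msg, "'recognition' must be a single non-empty string")
    else {
        bad <- setdiff(strsplit(object@recognition, "")[[1]], IUPAC_CODES)
        if (length(bad))
            msg <- c(msg, paste0("recognition contains non-IUPAC letters: ",
                                 paste(unique(bad), collapse = ", ")))
    }
    if (length(object@cutOffset) != 1L || is.na(object@cutOffset) ||
        object@cutOffset < 0L || object@cutOffset > nchar(object@recognition))
        msg <- c(msg, "'cutOffset' must lie in [0, nchar(recognition)]")
    if (length(msg)) msg else TRUE
})

#' @describeIn Enzyme constructor.
#' @param name enzyme name.
#' @param recognition IUPAC recognition site (uppercased internally).
#' @param cutOffset top-strand cut offset into the recognition site.
#' @export
Enzyme <- function(name, recognition, cutOffset) {
    new("Enzyme", name = as.character(name),
        recognition = toupper(as.character(recognition)),
        cutOffset = as.integer(cutOffset))
}

.builtinEnzymes <- list(
    ApeKI = c(recognition = "GCWGC", offset = 1),
    PstI  = c(recognition = "CTGCAG", offset = 5),
    MspI  = c(recognition = "CCGG", offset = 1))

#' Built-in GBS enzymes
#'
#' Returns one of the enzymes commonly used for GBS library construction:
#' `ApeKI` (G^CWGC, one-enzyme protocols), `PstI` (CTGCA^G, rare cutter) and
#' `MspI` (C^CGG, common cutter). All three sites are palindromic under
#' IUPAC complement, so a single-strand scan finds every cut site.
#'
#' @param name one of `"ApeKI"`, `"PstI"`, `"MspI"`.
#' @return an [Enzyme] object.
#' @examples
#' gbsEnzyme("PstI")
#' @export
gbsEnzyme <- function(name) {
    name <- match.arg(name, names(.builtinEnzymes))
    spec <- .builtinEnzymes[[name]]
    Enzyme(name, spec[["recognition"]], as.integer(spec[["offset"]]))
}

#' @describeIn Enzyme enzyme name accessor.
#' @param x an `Enzyme`.
#' @export
enzymeName <- function(x) x@name

#' @describeIn Enzyme recognition-site accessor.
#' @export
recognitionSite <- function(x) x@recognition

#' @describeIn Enzyme cut-offset accessor.
#' @export
cutOffset <- function(x) x@cutOffset

#' Restriction-site remnant left at read starts
#'
#' After cutting and adapter ligation, a sequencing read entering a
#' fragment crosses the recognition site from its nearest cut: the
#' remnant is the recognition site minus the bases removed by the
#' shorter of the two strand cuts (`TGCAG` for PstI, `CGG` for MspI,
#' `CWGC` for ApeKI). Assumes a palindromic site, as all built-ins are.
#'
#' @param enzyme an [Enzyme].
#' @return remnant string expected at the start of reads from this
#'   enzyme's fragment ends.
#' @export
enzymeRemnant <- function(enzyme) {
    stopifnot(is(enzyme, "Enzyme"))
    len <- nchar(enzyme@recognition)
    substr(enzyme@recognition, min(enzyme@cutOffset,
                                   len - enzyme@cutOffset) + 1L, len)
}

setMethod("show", "Enzyme", function(object) {
    site <- object@recognition
    marked <- paste0(substr(site, 1, object@cutOffset), "^",
                     substr(site, object@cutOffset + 1L, nchar(site)))
    cat("Enzyme ", object@name, ": ", marked, "\n", sep = "")
})
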