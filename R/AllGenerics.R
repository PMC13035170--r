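#' @include massChem.R
NULL

#' Neutral monoisotopic mass of a peptide
#'
#' Computes the neutral (uncharged) monoisotopic relative molecular mass of a
#' peptide: the sum of its residue masses, one water, and the mass shifts of
#' all attached modifications. This is the quantity conventionally reported
#' as Mr(calc) by search engines.
#'
#' @param object a [Peptide-class] object, or a plain character sequence
#'   (interpreted as an unmodified peptide).
#' @param ... ignored.
#' @return numeric(1), neutral mass in Da at full precision. Rounding for
#'   presentation is the caller's business (see [roundHalfUp()]).
#' @examples
#' peptideNeutralMass("G")  # glycine + water = 75.032029
#' p <- Peptide("PNSRHDNVSPSK", "HexNAc@S9; HexNAc@S11")
#' peptideNeutralMass(p)    # 1742.807 (prints as Mr(calc) 1742.81)
#' @export
setGeneric("peptideNeutralMass", function(object, ...)
  standardGeneric("peptideNeutralMass"))

#' @rdname Peptide-class
#' @param object,x a `Peptide` object.
#' @export
setGeneric("peptideSequence", function(object) standardGeneric("peptideSequence"))

#' @rdname Peptide-class
#' @export
setGeneric("modifications", function(object) standardGeneric("modifications"))

#' @rdname Spectrum-class
#' @export
setGeneric("scanId", function(object) standardGeneric("scanId"))

#' @rdname Spectrum-class
#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))

#' @rdname Spectrum-class
#' @export
setGeneric("precursorCharge", function(object) standardGeneric("precursorCharge"))

#' @rdname Spectrum-class
#' @export
setGeneric("peakTable", function(object) standardGeneric("peakTable"))

#' @rdname EvidenceReport-class
#' @export
setGeneric("tier", function(object) standardGeneric("tier"))

#' @rdname EvidenceReport-class
#' @export
setGeneric("tierReasons", function(object) standardGeneric("tierReasons"))

#' @rdname EvidenceReport-class
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))

#' @rdname EvidenceReport-class
#' @export
setGeneric("peakMatches", function(object) standardGeneric("peakMatches"))
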