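#' @include AllGenerics.R massChem.R
NULL

## ---------------------------------------------------------------- Peptide

#' Peptide: a residue sequence with positioned modifications
#'
#' The unit whose mass and fragments are computed. The `mods` slot is a
#' data.frame with columns `position` (1-based), `name` and `delta` (Da);
#' validity enforces the standard 20-letter alphabet, in-range positions,
#' target-residue rules and at most one modification per position.
#'
#' @slot sequence uppercase residue string.
#' @slot mods data.frame of positioned modifications.
#' @aliases Peptide
#' @examples
#' p <- Peptide("PNSRHDNVSPSK", "HexNAc@S9; HexNAc@S11")
#' peptideNeutralMass(p)
#' modifications(p)
#' @export
setClass("Peptide",
  representation(sequence = "character", mods = "data.frame"),
  prototype(sequence = "G",
            mods = data.frame(position = integer(), name = character(),
                              delta = numeric(), stringsAsFactors = FALSE)))

setValidity("Peptide", function(object) {
  seq <- object@sequence
  if (length(seq) != 1 || is.na(seq) || !nzchar(seq))
    return("sequence must be a single non-empty string")
  letters <- strsplit(seq, "")[[1]]
  if (!all(letters %in% names(residueMasses)))
    return(paste0("sequence contains a letter outside the 20 standard residues: ",
                  paste(unique(letters[!letters %in% names(residueMasses)]),
                        collapse = ", ")))
  m <- object@mods
  if (!all(c("position", "name", "delta") %in% colnames(m)))
    return("mods needs columns position, name, delta")
  if (nrow(m)) {
    if (any(m$position < 1 | m$position > nchar(seq)))
      return("modification position outside 1..length")
    if (anyDuplicated(m$position))
      return("two modifications share a position")
    reg <- defaultModifications()
    for (i in seq_len(nrow(m))) {
      tg <- reg$targets[match(m$name[i], reg$name)]
      if (!is.na(tg)) {
        res <- substr(seq, m$position[i], m$position[i])
        if (!grepl(res, tg, fixed = TRUE))
          return(paste0(m$name[i], " not allowed on ", res, m$position[i]))
      }
    }
  }
  TRUE
})

#' Construct a Peptide
#'
#' @param sequence uppercase residue string.
#' @param mods either `NULL`, an annotation string such as
#'   `"HexNAc@S9; HexNAc@S11"`, or a data.frame with columns `position`,
#'   `name`, `delta`.
#' @param registry modification definitions used to resolve names and
#'   target rules; see [defaultModifications()].
#' @return a [Peptide-class] object.
#' @rdname Peptide-class
#' @export
Peptide <- function(sequence, mods = NULL, registry = defaultModifications()) {
  if (is.null(mods)) {
    mods <- data.frame(position = integer(), name = character(),
                       delta = numeric(), stringsAsFactors = FALSE)
  } else if (is.character(mods)) {
    mods <- parseModSpec(mods, sequence, registry)
  } else {
    mods <- as.data.frame(mods)[, c("position", "name", "delta")]
  }
  mods <- mods[order(mods$position), , drop = FALSE]
  rownames(mods) <- NULL
  methods::new("Peptide", sequence = sequence, mods = mods)
}

#' @rdname Peptide-class
#' @export
setMethod("peptideSequence", "Peptide", function(object) object@sequence)

#' @rdname Peptide-class
#' @export
setMethod("modifications", "Peptide", function(object) object@mods)

#' @rdname Peptide-class
#' @export
setMethod("length", "Peptide", function(x) nchar(x@sequence))

setMethod("show", "Peptide", function(object) {
  m <- object@mods
  modtxt <- if (nrow(m)) {
    paste(sprintf("%s@%s%d", m$name,
                  substring(object@sequence, m$position, m$position),
                  m$position), collapse = "; ")
  } else "none"
  cat("Peptide ", object@sequence, " (", nchar(object@sequence),
      " residues)\n  modifications: ", modtxt,
      sprintf("\n  Mr(calc): %.4f Da\n", peptideNeutralMass(object)), sep = "")
})

#' @rdname peptideNeutralMass
#' @export
setMethod("peptideNeutralMass", "Peptide", function(object, ...) {
  sum(.residueMassVector(object@sequence)) + massConstants[["water"]] +
    sum(object@mods$delta)
})

#' @rdname peptideNeutralMass
#' @export
setMethod("peptideNeutralMass", "character", function(object, ...) {
  sum(.residueMassVector(object)) + massConstants[["water"]]
})

## --------------------------------------------------------------- Spectrum

#' Spectrum: a centroided MS/MS peak list
#'
#' Peaks are stored sorted ascending by m/z; validity enforces positive
#' m/z, non-negative intensities and a precursor charge within 1..7 (the
#' search convention covers 2-7+; 1 is tolerated on input). Missing
#' precursor information is represented as `NA`.
#'
#' @slot scanId scan label, unique within a run.
#' @slot precursorMz precursor m/z (may be `NA`).
#' @slot precursorCharge integer charge (may be `NA`).
#' @slot mz,intensity parallel numeric peak vectors.
#' @aliases Spectrum
#' @export
setClass("Spectrum",
  representation(scanId = "character", precursorMz = "numeric",
                 precursorCharge = "integer", mz = "numeric",
                 intensity = "numeric"),
  prototype(scanId = "scan", precursorMz = NA_real_,
            precursorCharge = NA_integer_, mz = numeric(),
            intensity = numeric()))

setValidity("Spectrum", function(object) {
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity lengths differ")
  if (length(object@mz) && any(object@mz <= 0))
    return("all peak m/z must be positive")
  if (length(object@mz) && any(object@intensity < 0))
    return("intensities must be non-negative")
  if (is.unsorted(object@mz))
    return("peaks must be sorted ascending by m/z")
  z <- object@precursorCharge
  if (!is.na(z) && (z < 1 || z > 7))
    return("precursor charge must be within 1..7")
  TRUE
})

#' Construct a Spectrum
#'
#' Peaks are sorted on construction; input order is irrelevant.
#'
#' @param scanId scan label.
#' @param mz,intensity peak vectors (equal length).
#' @param precursorMz,precursorCharge precursor descriptors, `NA` if unknown.
#' @return a [Spectrum-class] object.
#' @rdname Spectrum-class
#' @export
Spectrum <- function(scanId, mz = numeric(), intensity = numeric(),
                     precursorMz = NA_real_, precursorCharge = NA_integer_) {
  o <- order(mz)
  methods::new("Spectrum", scanId = as.character(scanId), mz = mz[o],
               intensity = intensity[o], precursorMz = as.numeric(precursorMz),
               precursorCharge = as.integer(precursorCharge))
}

#' @rdname Spectrum-class
#' @export
setMethod("scanId", "Spectrum", function(object) object@scanId)

#' @rdname Spectrum-class
#' @export
setMethod("precursorMz", "Spectrum", function(object) object@precursorMz)

#' @rdname Spectrum-class
#' @export
setMethod("precursorCharge", "Spectrum", function(object) object@precursorCharge)

#' @rdname Spectrum-class
#' @export
setMethod("peakTable", "Spectrum", function(object)
  data.frame(mz = object@mz, intensity = object@intensity))

#' @rdname Spectrum-class
#' @export
setMethod("length", "Spectrum", function(x) length(x@mz))

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum ", object@scanId, ": ", length(object@mz), " peaks",
      sprintf(", precursor %.4f m/z (%s+)\n",
              object@precursorMz,
              ifelse(is.na(object@precursorCharge), "?",
                     object@precursorCharge)), sep = "")
})

## -------------------------------------------------------------- PSMRecord

#' PSMRecord: one peptide-spectrum match from a search engine
#'
#' Carries the assigned peptide, the engine ion score and expectation
#' value, and the observed precursor. Scores are consumed as inputs, never
#' recomputed.
#'
#' @slot spectrumId scan label the match refers to.
#' @slot peptide a [Peptide-class].
#' @slot ionScore engine ion score (finite).
#' @slot pExpect expectation value, strictly positive.
#' @slot precursorMzObserved observed precursor m/z (may be `NA`).
#' @slot charge precursor charge 1..7.
#' @slot sourceStrain free-text sample label (e.g. "WT-N2-L1").
#' @aliases PSMRecord
#' @export
setClass("PSMRecord",
  representation(spectrumId = "character", peptide = "Peptide",
                 ionScore = "numeric", pExpect = "numeric",
                 precursorMzObserved = "numeric", charge = "integer",
                 sourceStrain = "character"),
  prototype(sourceStrain = NA_character_, precursorMzObserved = NA_real_))

setValidity("PSMRecord", function(object) {
  if (!is.finite(object@ionScore)) return("ionScore must be finite")
  if (!is.finite(object@pExpect) || object@pExpect <= 0)
    return("pExpect must be in (0, Inf)")
  if (is.na(object@charge) || object@charge < 1 || object@charge > 7)
    return("charge must be within 1..7")
  TRUE
})

#' Construct a PSMRecord
#'
#' @param spectrumId scan label.
#' @param peptide a [Peptide-class] or sequence string.
#' @param ionScore,pExpect engine score and expectation value.
#' @param precursorMzObserved observed precursor m/z (`NA` to fall back on
#'   the spectrum's own precursor at validation time).
#' @param charge precursor charge state.
#' @param sourceStrain sample label.
#' @return a [PSMRecord-class] object.
#' @rdname PSMRecord-class
#' @export
PSMRecord <- function(spectrumId, peptide, ionScore, pExpect,
                      precursorMzObserved = NA_real_, charge = 2L,
                      sourceStrain = NA_character_) {
  if (is.character(peptide)) peptide <- Peptide(peptide)
  methods::new("PSMRecord", spectrumId = as.character(spectrumId),
               peptide = peptide, ionScore = as.numeric(ionScore),
               pExpect = as.numeric(pExpect),
               precursorMzObserved = as.numeric(precursorMzObserved),
               charge = as.integer(charge),
               sourceStrain = as.character(sourceStrain))
}

setMethod("show", "PSMRecord", function(object) {
  cat("PSMRecord ", object@spectrumId, ": ", object@peptide@sequence,
      sprintf(" (score %.1f, expect %.3g, %d+)\n", object@ionScore,
              object@pExpect, object@charge), sep = "")
})

## --------------------------------------------------------- EvidenceReport

#' EvidenceReport: the outcome of all diagnostic checks on one PSM
#'
#' Produced by [validatePSM()]. The `diagnostics` slot is a named list
#' (oxoniumPrimaryFound, oxoniumSecondaryFound, neutralLossPrecursor,
#' neutralLossFragmentCount, siteSupport table, precursorPpm,
#' matchedFraction); `tier` is one of `rejected`, `candidate`, `high`,
#' `very_high`; `reasons` is the ordered list of rule citations that
#' fired, so a human can audit every demotion.
#'
#' @slot psm the classified [PSMRecord-class].
#' @slot diagnostics named list of diagnostic outcomes.
#' @slot tier confidence tier label.
#' @slot reasons ordered character vector of rule citations.
#' @slot mrCalc neutral calculated mass of the assigned peptide.
#' @slot matches data.frame of fragment-to-peak matches.
#' @aliases EvidenceReport
#' @export
setClass("EvidenceReport",
  representation(psm = "PSMRecord", diagnostics = "list", tier = "character",
                 reasons = "character", mrCalc = "numeric",
                 matches = "data.frame"))

setValidity("EvidenceReport", function(object) {
  if (!object@tier %in% c("rejected", "candidate", "high", "very_high"))
    return("tier must be rejected/candidate/high/very_high")
  if (abs(object@mrCalc - peptideNeutralMass(object@psm@peptide)) > 1e-9)
    return("mrCalc must equal peptideNeutralMass of the assigned peptide")
  TRUE
})

#' @rdname EvidenceReport-class
#' @param object an `EvidenceReport`.
#' @export
setMethod("tier", "EvidenceReport", function(object) object@tier)

#' @rdname EvidenceReport-class
#' @export
setMethod("tierReasons", "EvidenceReport", function(object) object@reasons)

#' @rdname EvidenceReport-class
#' @export
setMethod("diagnostics", "EvidenceReport", function(object) object@diagnostics)

#' @rdname EvidenceReport-class
#' @export
setMethod("peakMatches", "EvidenceReport", function(object) object@matches)

setMethod("show", "EvidenceReport", function(object) {
  d <- object@diagnostics
  cat("EvidenceReport for ", object@psm@spectrumId, " (",
      object@psm@peptide@sequence, ")\n",
      sprintf("  Mr(calc) %.4f Da, score %.1f, expect %.3g\n",
              object@mrCalc, object@psm@ionScore, object@psm@pExpect),
      "  tier: ", object@tier, "\n",
      "  oxonium primary/secondary: ", d$oxoniumPrimaryFound, "/",
      d$oxoniumSecondaryFound, "; neutral loss (precursor/fragment pairs): ",
      d$neutralLossPrecursor, "/", d$neutralLossFragmentCount, "\n",
      sprintf("  precursor error %.2f ppm, matched fraction %.2f\n",
              d$precursorPpm, d$matchedFraction),
      "  reasons: ", paste(object@reasons, collapse = "; "), "\n", sep = "")
})
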