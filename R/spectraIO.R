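#' @include AllClasses.R fragments.R
NULL

## Peak-list / PSM-table ingestion and tolerance-based peak matching.
## MGF is the canonical interchange format.

#' Read an MGF peak-list file
#'
#' Parses a Mascot Generic Format file (BEGIN IONS / END IONS blocks with
#' TITLE, PEPMASS, CHARGE headers). Peaks are sorted on load; blocks with
#' no peaks are preserved as empty spectra. A charge that cannot be parsed
#' is recorded as missing and flagged with a warning; a structurally
#' malformed block raises an error naming the block ordinal.
#'
#' @param path MGF file path.
#' @return list of [Spectrum-class] objects.
#' @export
readMGF <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  begins <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(begins) != length(ends))
    stop("unbalanced BEGIN IONS/END IONS (", length(begins), " vs ",
         length(ends), ")")
  out <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    if (ends[b] < begins[b])
      stop("malformed MGF: block ", b, " ends before it begins")
    block <- lines[seq.int(begins[b] + 1L, length.out = ends[b] - begins[b] - 1L)]
    block <- block[nzchar(trimws(block))]
    isHeader <- grepl("^[A-Z]+=", block)
    hdr <- block[isHeader]
    getHdr <- function(key) {
      v <- hdr[startsWith(hdr, paste0(key, "="))]
      if (length(v)) sub(paste0("^", key, "="), "", v[1]) else NA_character_
    }
    title <- getHdr("TITLE")
    if (is.na(title)) title <- paste0("index=", b)
    pepmass <- getHdr("PEPMASS")
    precMz <- if (is.na(pepmass)) NA_real_ else
      suppressWarnings(as.numeric(strsplit(trimws(pepmass), "\\s+")[[1]][1]))
    if (!is.na(pepmass) && is.na(precMz))
      stop("malformed MGF: block ", b, " has unparseable PEPMASS '",
           pepmass, "'")
    chg <- getHdr("CHARGE")
    precZ <- NA_integer_
    if (!is.na(chg)) {
      m <- regmatches(chg, regexec("^([0-9]+)\\+?$", trimws(chg)))[[1]]
      if (length(m) == 2) {
        precZ <- as.integer(m[2])
      } else {
        warning("block ", b, " (", title, "): unparseable CHARGE '", chg,
                "', recorded as missing")
      }
    }
    peakLines <- block[!isHeader]
    if (length(peakLines)) {
      fields <- strsplit(trimws(peakLines), "\\s+")
      bad <- which(vapply(fields, length, integer(1)) < 2)
      if (length(bad))
        stop("malformed MGF: block ", b, " peak line '", peakLines[bad[1]],
             "' lacks m/z and intensity")
      mz <- as.numeric(vapply(fields, `[[`, character(1), 1))
      int <- as.numeric(vapply(fields, `[[`, character(1), 2))
      if (anyNA(mz) || anyNA(int))
        stop("malformed MGF: block ", b, " has a non-numeric peak value")
    } else {
      mz <- numeric(); int <- numeric()
    }
    out[[b]] <- Spectrum(title, mz, int, precMz, precZ)
  }
  out
}

#' Write spectra to an MGF file
#'
#' Inverse of [readMGF()]; m/z and intensity are written at 6 decimal
#' places, so a write/read round trip is lossless to that precision.
#'
#' @param spectra list of [Spectrum-class] objects (or a single one).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMGF <- function(spectra, path) {
  if (methods::is(spectra, "Spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s@scanId), con)
    if (!is.na(s@precursorMz))
      writeLines(sprintf("PEPMASS=%.6f", s@precursorMz), con)
    if (!is.na(s@precursorCharge))
      writeLines(sprintf("CHARGE=%d+", s@precursorCharge), con)
    if (length(s@mz))
      writeLines(sprintf("%.6f %.6f", s@mz, s@intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read a PSM table
#'
#' Reads a CSV of peptide-spectrum matches with mandatory columns
#' `spectrum_id`, `peptide`, `modifications`, `ion_score`, `p_expect`,
#' `precursor_mz`, `charge` (optional `source_strain`). Modification
#' syntax is `"HexNAc@S9; Oxidation@M18"`. Rows violating peptide or PSM
#' invariants (unknown residues, a modification on a disallowed residue,
#' out-of-range charge, non-positive expect) are quarantined into a reject
#' report rather than silently dropped.
#'
#' @param path CSV file path.
#' @param registry modification definitions; see [defaultModifications()].
#' @return list with elements `records` (list of [PSMRecord-class]) and
#'   `rejected` (data.frame with columns `row`, `spectrum_id`, `peptide`,
#'   `reason`).
#' @export
readPSMTable <- function(path, registry = defaultModifications()) {
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("spectrum_id", "peptide", "modifications", "ion_score",
                 "p_expect", "precursor_mz", "charge")
  missing <- setdiff(mandatory, colnames(tab))
  if (length(missing))
    stop("PSM table lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (!"source_strain" %in% colnames(tab))
    tab$source_strain <- rep(NA_character_, nrow(tab))
  records <- list()
  rejected <- data.frame(row = integer(), spectrum_id = character(),
                         peptide = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    rec <- tryCatch({
      pep <- Peptide(toupper(trimws(tab$peptide[i])),
                     tab$modifications[i], registry)
      PSMRecord(tab$spectrum_id[i], pep, tab$ion_score[i], tab$p_expect[i],
                tab$precursor_mz[i], tab$charge[i], tab$source_strain[i])
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      rejected <- rbind(rejected, data.frame(
        row = i, spectrum_id = as.character(tab$spectrum_id[i]),
        peptide = as.character(tab$peptide[i]), reason = rec,
        stringsAsFactors = FALSE))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  list(records = records, rejected = rejected)
}

#' Match theoretical fragments to observed peaks
#'
#' For every fragment, the nearest observed peak within the tolerance is
#' returned (at most one per fragment; a peak may serve several
#' fragments). When two peaks are exactly equidistant the more intense one
#' is chosen, which keeps matching deterministic and order-independent.
#'
#' @param spectrum a [Spectrum-class].
#' @param fragments a fragment table from [generateFragments()].
#' @param tol matching tolerance, in Da (default 0.05, the conventional
#'   fragment tolerance) or in ppm.
#' @param unit `"da"` or `"ppm"`.
#' @return data.frame: the matched fragment rows plus `observedMz`,
#'   `observedIntensity`, `errorDa`, `errorPpm`. Fragments with no peak in
#'   range are absent.
#' @export
matchPeaks <- function(spectrum, fragments, tol = 0.05,
                       unit = c("da", "ppm")) {
  unit <- match.arg(unit)
  stopifnot(tol > 0)
  mz <- spectrum@mz
  if (!length(mz) || !nrow(fragments)) {
    out <- fragments[integer(0), , drop = FALSE]
    out$observedMz <- numeric(); out$observedIntensity <- numeric()
    out$errorDa <- numeric(); out$errorPpm <- numeric()
    return(out)
  }
  idx <- integer(nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    target <- fragments$mz[i]
    tolDa <- if (unit == "da") tol else tol * 1e-6 * target
    j <- findInterval(target, mz)
    cand <- unique(pmin(pmax(c(j, j + 1L), 1L), length(mz)))
    d <- abs(mz[cand] - target)
    ok <- cand[d <= tolDa]
    if (!length(ok)) { idx[i] <- NA_integer_; next }
    dok <- abs(mz[ok] - target)
    best <- ok[dok == min(dok)]
    if (length(best) > 1)  # equidistant: higher intensity wins
      best <- best[which.max(spectrum@intensity[best])]
    idx[i] <- best[1]
  }
  keep <- !is.na(idx)
  out <- fragments[keep, , drop = FALSE]
  out$observedMz <- mz[idx[keep]]
  out$observedIntensity <- spectrum@intensity[idx[keep]]
  out$errorDa <- out$observedMz - out$mz
  out$errorPpm <- ppmError(out$observedMz, out$mz)
  rownames(out) <- NULL
  out
}
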