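## Monoisotopic mass arithmetic: the residue table, small-molecule constants
## and the m/z / ppm conversions every downstream stage depends on.

#' Monoisotopic residue masses
#'
#' Named numeric vector of monoisotopic residue (not free amino acid) masses
#' in Da for the 20 standard amino acids. I and L are kept as distinct
#' letters with identical mass. The table is a constant; treat it as
#' read-only.
#'
#' @format named numeric, names are one-letter residue codes.
#' @export
residueMasses <- c(
  G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
  V =  99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Small-molecule mass constants
#'
#' Monoisotopic masses (Da) used throughout: `water` (terminal H2O of an
#' intact peptide and of y ions), `proton` (charge carrier), `ammonia`
#' (NH3 loss), and `hexnac` (the HexNAc residue delta, 203.079373 Da, whose
#' loss is the O-GlcNAc diagnostic printed as 203.0794).
#'
#' @format named numeric.
#' @export
massConstants <- c(
  water   = 18.010565,
  proton  =  1.007276,
  ammonia = 17.026549,
  hexnac  = 203.079373
)

#' Built-in modification definitions
#'
#' The three modifications of the standard O-GlcNAc search convention:
#' variable HexNAc on S/T (+203.079373 Da), variable oxidation on M
#' (+15.994915 Da) and carbamidomethylation of C (+57.021464 Da).
#' Carbamidomethyl is defined here but applied per peptide, never
#' unconditionally, so a PSM annotated with an unmodified Cys keeps it.
#'
#' @return data.frame with columns `name`, `delta` (Da), `targets`
#'   (string of allowed one-letter residue codes).
#' @seealso [readModificationTable()] to load additional definitions.
#' @export
defaultModifications <- function() {
  data.frame(
    name    = c("HexNAc", "Carbamidomethyl", "Oxidation"),
    delta   = c(203.079373, 57.021464, 15.994915),
    targets = c("ST", "C", "M"),
    stringsAsFactors = FALSE
  )
}

#' Load modification definitions from a YAML config file
#'
#' The file is a YAML sequence of maps with fields `name`, `delta` and
#' `targets` (e.g. `- {name: Phospho, delta: 79.966331, targets: STY}`).
#' Entries are appended to the built-in table; a redefined name overrides
#' the built-in entry.
#'
#' @param path path to a YAML file.
#' @return data.frame in the format of [defaultModifications()].
#' @export
readModificationTable <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  extra <- do.call(rbind, lapply(raw, function(x) {
    if (is.null(x$name) || is.null(x$delta) || is.null(x$targets))
      stop("modification entry needs fields 'name', 'delta', 'targets'")
    data.frame(name = as.character(x$name), delta = as.numeric(x$delta),
               targets = as.character(x$targets), stringsAsFactors = FALSE)
  }))
  base <- defaultModifications()
  rbind(base[!base$name %in% extra$name, ], extra)
}

#' Parse a modification annotation string
#'
#' Parses the PSM-table syntax `"HexNAc@S9; Oxidation@M18"` into a
#' positioned modification table, checking every position against the
#' peptide sequence and the modification's allowed target residues.
#'
#' @param spec character(1); empty string or `NA` means no modifications.
#' @param sequence the peptide sequence the positions refer to.
#' @param registry modification definitions, see [defaultModifications()].
#' @return data.frame with columns `position` (1-based), `name`, `delta`.
#' @export
parseModSpec <- function(spec, sequence, registry = defaultModifications()) {
  empty <- data.frame(position = integer(), name = character(),
                      delta = numeric(), stringsAsFactors = FALSE)
  if (is.null(spec) || length(spec) == 0 || is.na(spec) || !nzchar(trimws(spec)))
    return(empty)
  parts <- trimws(strsplit(spec, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  out <- lapply(parts, function(tok) {
    m <- regmatches(tok, regexec("^([A-Za-z0-9_-]+)@([A-Z])([0-9]+)$", tok))[[1]]
    if (length(m) != 4)
      stop("cannot parse modification token '", tok,
           "' (expected e.g. 'HexNAc@S9')")
    name <- m[2]; res <- m[3]; pos <- as.integer(m[4])
    row <- registry[registry$name == name, ]
    if (nrow(row) != 1)
      stop("unknown modification '", name, "'")
    if (pos < 1 || pos > nchar(sequence))
      stop("modification position ", pos, " outside sequence of length ",
           nchar(sequence))
    at <- substr(sequence, pos, pos)
    if (at != res)
      stop("annotation says ", res, pos, " but sequence has ", at,
           " at position ", pos)
    data.frame(position = pos, name = name, delta = row$delta,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## internal: residue masses for a sequence, with position-level error reporting
.residueMassVector <- function(sequence) {
  letters <- strsplit(sequence, "")[[1]]
  bad <- which(!letters %in% names(residueMasses))
  if (length(bad))
    stop("unknown residue letter '", letters[bad[1]], "' at position ", bad[1])
  unname(residueMasses[letters])
}

#' Convert a neutral mass to m/z
#'
#' `(neutral_mass + charge * proton) / charge` with the proton at
#' 1.007276 Da.
#'
#' @param neutralMass neutral monoisotopic mass in Da (vectorised).
#' @param charge positive integer charge state.
#' @return m/z values.
#' @examples
#' mzFromMass(1742.807, 1)   # 1743.814
#' mzFromMass(2124.045, 2)   # 1063.030
#' @export
mzFromMass <- function(neutralMass, charge) {
  if (any(charge < 1) || any(charge != as.integer(charge)))
    stop("charge must be a positive integer")
  (neutralMass + charge * massConstants[["proton"]]) / charge
}

#' Convert an m/z back to a neutral mass
#'
#' Inverse of [mzFromMass()].
#'
#' @inheritParams mzFromMass
#' @param mz observed m/z.
#' @return neutral mass in Da.
#' @export
massFromMz <- function(mz, charge) {
  if (any(charge < 1) || any(charge != as.integer(charge)))
    stop("charge must be a positive integer")
  mz * charge - charge * massConstants[["proton"]]
}

#' Signed relative mass error in parts per million
#'
#' @param observed observed m/z (or mass).
#' @param theoretical theoretical m/z (or mass); must be positive.
#' @return signed ppm, `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppmError <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Round half away from zero
#'
#' Presentation-time rounding used when comparing against printed Mr(calc)
#' values (base R `round` rounds half to even, which can differ at the
#' reported precision).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
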