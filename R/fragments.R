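#' @include AllClasses.R
NULL

## Theoretical fragment-ion and diagnostic-ion generation. Fragment tables
## are plain data.frames (one row per ion), the convention of the
## Bioconductor mass-spec stack.

#' Generate theoretical backbone fragments for a (glyco)peptide
#'
#' Emits the b/y series for every backbone cut site, optionally with
#' ammonia-loss (-17.026549), water-loss (-18.010565) and HexNAc-loss
#' (-203.079373) derivatives, at charge 1 and optionally 2. A fragment
#' "carries" a modification when its residue span includes a modified
#' position; HexNAc loss is only generated for HexNAc-carrying fragments.
#' NH3 and H2O losses are offered on all fragments (residue-conditional
#' rules can be enabled via `residueConditionalLosses`, in which case NH3
#' loss requires K/R/N/Q and H2O loss requires S/T/E/D in the span).
#' The c/z(dot) series of electron-driven fragmentation can be added with
#' `series`; the default is b/y only, the series used for validation.
#'
#' @param peptide a [Peptide-class] (or sequence string).
#' @param maxCharge 1 or 2; doubly charged ions are emitted only for
#'   fragments with neutral mass at least `doublyChargedMinMass`.
#' @param losses character subset of `c("NH3", "H2O", "HexNAc")`; empty
#'   means plain series only.
#' @param series backbone series to emit, subset of `c("b","y","c","z")`.
#' @param doublyChargedMinMass neutral-mass floor (Da) for 2+ fragments.
#' @param residueConditionalLosses logical; see above.
#' @return data.frame with columns `series`, `index`, `charge`, `loss`,
#'   `neutral` (Da), `mz`, `carriesMod`, `carriesHexNAc`, `label`.
#'   A length-1 peptide yields zero rows.
#' @examples
#' generateFragments(Peptide("GK"))
#' @export
generateFragments <- function(peptide, maxCharge = 1,
                              losses = character(),
                              series = c("b", "y"),
                              doublyChargedMinMass = 800,
                              residueConditionalLosses = FALSE) {
  if (is.character(peptide)) peptide <- Peptide(peptide)
  stopifnot(maxCharge %in% c(1, 2))
  if (length(losses))
    losses <- match.arg(losses, c("NH3", "H2O", "HexNAc"), several.ok = TRUE)
  series <- match.arg(series, c("b", "y", "c", "z"), several.ok = TRUE)
  n <- nchar(peptide@sequence)
  empty <- data.frame(series = character(), index = integer(),
                      charge = integer(), loss = character(),
                      neutral = numeric(), mz = numeric(),
                      carriesMod = logical(), carriesHexNAc = logical(),
                      label = character(), stringsAsFactors = FALSE)
  if (n < 2) return(empty)

  res <- .residueMassVector(peptide@sequence)
  mods <- peptide@mods
  delta <- numeric(n)
  if (nrow(mods)) delta[mods$position] <- mods$delta
  hexpos <- mods$position[mods$name == "HexNAc"]

  cumN <- cumsum(res + delta)            # prefix sums, N-terminal
  water <- massConstants[["water"]]
  total <- cumN[n] + water
  i <- seq_len(n - 1)

  rows <- list()
  addSeries <- function(ser, index, neutral, carriesMod, carriesHex) {
    data.frame(series = ser, index = index, charge = NA_integer_,
               loss = "none", neutral = neutral, mz = NA_real_,
               carriesMod = carriesMod, carriesHexNAc = carriesHex,
               label = paste0(ser, index), stringsAsFactors = FALSE)
  }
  nModLeft  <- vapply(i, function(k) any(mods$position <= k), logical(1))
  nHexLeft  <- vapply(i, function(k) any(hexpos <= k), logical(1))
  nModRight <- vapply(i, function(k) any(mods$position > n - k), logical(1))
  nHexRight <- vapply(i, function(k) any(hexpos > n - k), logical(1))

  if ("b" %in% series)
    rows$b <- addSeries("b", i, cumN[i], nModLeft, nHexLeft)
  if ("y" %in% series)
    rows$y <- addSeries("y", i, total - cumN[n - i], nModRight, nHexRight)
  if ("c" %in% series)  # c = b + NH3
    rows$c <- addSeries("c", i, cumN[i] + massConstants[["ammonia"]],
                        nModLeft, nHexLeft)
  if ("z" %in% series)  # z(dot) = y - NH3 + H
    rows$z <- addSeries("z", i, total - cumN[n - i] -
                          massConstants[["ammonia"]] + 1.007825,
                        nModRight, nHexRight)
  frag <- do.call(rbind, rows)

  # loss derivatives
  lossMass <- c(NH3 = massConstants[["ammonia"]],
                H2O = massConstants[["water"]],
                HexNAc = massConstants[["hexnac"]])
  lossSuffix <- c(NH3 = "*", H2O = "o", HexNAc = "-HexNAc")
  seqChars <- strsplit(peptide@sequence, "")[[1]]
  spanHas <- function(ser, idx, set) {
    span <- if (ser %in% c("b", "c")) seqChars[seq_len(idx)]
            else seqChars[seq.int(n - idx + 1, n)]
    any(span %in% set)
  }
  deriv <- lapply(losses, function(ls) {
    keep <- if (ls == "HexNAc") frag$carriesHexNAc else rep(TRUE, nrow(frag))
    if (residueConditionalLosses && ls == "NH3")
      keep <- keep & mapply(spanHas, frag$series, frag$index,
                            MoreArgs = list(set = c("K", "R", "N", "Q")))
    if (residueConditionalLosses && ls == "H2O")
      keep <- keep & mapply(spanHas, frag$series, frag$index,
                            MoreArgs = list(set = c("S", "T", "E", "D")))
    d <- frag[keep, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    d$loss <- ls
    d$neutral <- d$neutral - lossMass[[ls]]
    d$label <- paste0(d$series, d$index, lossSuffix[[ls]])
    d
  })
  frag <- rbind(frag, do.call(rbind, deriv))

  # charge states
  charges <- seq_len(maxCharge)
  out <- do.call(rbind, lapply(charges, function(z) {
    f <- frag
    if (z == 2) f <- f[f$neutral >= doublyChargedMinMass, , drop = FALSE]
    if (!nrow(f)) return(NULL)
    f$charge <- z
    f$mz <- mzFromMass(f$neutral, z)
    if (z == 2) f$label <- paste0(f$label, "++")
    f
  }))
  if (is.null(out)) return(empty)
  out <- out[out$neutral > 0, , drop = FALSE]
  out <- out[order(out$series, out$index, out$charge, out$loss), ]
  rownames(out) <- NULL
  out
}

#' The HexNAc oxonium diagnostic ion set
#'
#' The primary HexNAc oxonium ion at m/z 204.0867 and its secondary
#' fragments at 138.055 and 144.066, the diagnostic trio scanned for in
#' every candidate glycopeptide spectrum. The set is extensible via
#' `extraSecondary` (e.g. 126.055, 168.066) but immutable within a run.
#'
#' @param extraSecondary additional secondary oxonium m/z values.
#' @return list with elements `primary` (numeric(1)) and `secondary`
#'   (numeric vector).
#' @export
oxoniumTargets <- function(extraSecondary = numeric()) {
  list(primary = 204.0867,
       secondary = c(138.055, 144.066, extraSecondary))
}

#' Pair HexNAc-carrying fragments with their neutral-loss counterparts
#'
#' Every fragment that carries HexNAc and has a HexNAc-loss variant in the
#' table is paired with it; the neutral-mass difference of each pair is the
#' HexNAc delta, 203.0794 Da at the conventional 4 dp. On the m/z scale the
#' difference divides by the charge.
#'
#' @param fragments a fragment table from [generateFragments()] generated
#'   with `"HexNAc"` among the losses.
#' @return data.frame with columns `series`, `index`, `charge`,
#'   `intactMz`, `lossMz`, `deltaNeutral`. Zero rows when the peptide
#'   carries no HexNAc.
#' @export
hexnacLossPairs <- function(fragments) {
  intact <- fragments[fragments$loss == "none" & fragments$carriesHexNAc, ]
  lost <- fragments[fragments$loss == "HexNAc", ]
  if (!nrow(intact) || !nrow(lost))
    return(data.frame(series = character(), index = integer(),
                      charge = integer(), intactMz = numeric(),
                      lossMz = numeric(), deltaNeutral = numeric(),
                      stringsAsFactors = FALSE))
  key <- function(d) paste(d$series, d$index, d$charge)
  j <- match(key(intact), key(lost))
  ok <- !is.na(j)
  intact <- intact[ok, ]; lost <- lost[j[ok], ]
  out <- data.frame(series = intact$series, index = intact$index,
                    charge = intact$charge, intactMz = intact$mz,
                    lossMz = lost$mz,
                    deltaNeutral = intact$neutral - lost$neutral,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Export a fragment table to CSV
#'
#' @param fragments a fragment table from [generateFragments()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeFragmentTable <- function(fragments, path) {
  utils::write.csv(fragments[, c("series", "index", "charge", "loss",
                                 "mz", "carriesMod")],
                   path, row.names = FALSE)
  invisible(path)
}
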