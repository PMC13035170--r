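#' @include validator.R
NULL

## Seeded generator of ground-truth glycoproteomes and EThcD-like spectra.
## Planted peak masses go through the same mass arithmetic the validator
## uses, so zero-noise recovery is exact by construction (and verified by
## test, not assumed).

## average eukaryote proteome residue frequencies, adequate for tryptic
## peptide emulation
.residueFreq <- c(
  A = 0.065, R = 0.053, N = 0.049, D = 0.053, C = 0.020, Q = 0.041,
  E = 0.065, G = 0.054, H = 0.023, I = 0.062, L = 0.086, K = 0.064,
  M = 0.026, F = 0.048, P = 0.049, S = 0.081, T = 0.059, W = 0.011,
  Y = 0.031, V = 0.062
)

#' Simulation configuration
#'
#' Conditions for the synthetic glycoproteome and spectra: tryptic
#' C-terminal K/R peptides with at most `missedCleavageMax` internal K/R,
#' lengths from a discretised gamma whose mode sits in the 15-19 bin,
#' stochastic HexNAc occupancy (1-2 sites) on S/T for a `glycoFraction`
#' of peptides, full b/y ladders with ammonia/water derivatives, HexNAc
#' intact/loss pairs, oxonium and precursor-loss peaks for glycopeptides,
#' Gaussian ppm-scale m/z jitter, uniform noise peaks, and shifted-gamma
#' class-conditional ion-score distributions (glyco mass roughly 25-45,
#' decoys mostly below 20; the score model is explicitly synthetic).
#' The seed is mandatory: every run is exactly reproducible.
#'
#' @param nPeptides number of peptides (one spectrum each).
#' @param glycoFraction fraction of peptides carrying HexNAc.
#' @param seed integer RNG seed (mandatory).
#' @param lengthShape,lengthScale gamma parameters of the length
#'   distribution (defaults give mode (shape-1)*scale = 17).
#' @param lengthMin,lengthMax length clipping bounds.
#' @param missedCleavageMax maximum internal K/R count.
#' @param missedCleavageProb sampling weights for 0..max missed cleavages.
#' @param mzJitterPpm Gaussian m/z jitter s.d. in ppm (0 = exact peaks).
#' @param noisePeaks uniform-random noise peaks per spectrum.
#' @param ladderCompleteness probability each theoretical fragment peak is
#'   emitted.
#' @param plantOxonium,plantPrecursorLoss emit the diagnostic peaks for
#'   glycopeptides.
#' @param residueFreq sampling frequencies for the 20 residues.
#' @param scoreGlyco,scoreDecoy lists `(shift, shape, scale)` of the
#'   shifted-gamma score models.
#' @return validated named list.
#' @export
simulationConfig <- function(nPeptides = 200, glycoFraction = 0.5, seed,
                             lengthShape = 9.5, lengthScale = 2,
                             lengthMin = 7, lengthMax = 45,
                             missedCleavageMax = 2,
                             missedCleavageProb = c(0.6, 0.3, 0.1),
                             mzJitterPpm = 0, noisePeaks = 0,
                             ladderCompleteness = 1,
                             plantOxonium = TRUE, plantPrecursorLoss = TRUE,
                             residueFreq = .residueFreq,
                             scoreGlyco = list(shift = 25, shape = 2.5,
                                               scale = 5),
                             scoreDecoy = list(shift = 4, shape = 2,
                                               scale = 3)) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(nPeptides >= 1,
            glycoFraction >= 0, glycoFraction <= 1,
            ladderCompleteness >= 0, ladderCompleteness <= 1,
            mzJitterPpm >= 0, noisePeaks >= 0, missedCleavageMax >= 0,
            length(missedCleavageProb) >= missedCleavageMax + 1)
  if (glycoFraction > 0 &&
      sum(residueFreq[c("S", "T")], na.rm = TRUE) == 0)
    stop("glycoFraction > 0 but the residue alphabet excludes S and T")
  list(nPeptides = as.integer(nPeptides), glycoFraction = glycoFraction,
       seed = as.integer(seed), lengthShape = lengthShape,
       lengthScale = lengthScale, lengthMin = as.integer(lengthMin),
       lengthMax = as.integer(lengthMax),
       missedCleavageMax = as.integer(missedCleavageMax),
       missedCleavageProb = missedCleavageProb,
       mzJitterPpm = mzJitterPpm, noisePeaks = as.integer(noisePeaks),
       ladderCompleteness = ladderCompleteness,
       plantOxonium = plantOxonium, plantPrecursorLoss = plantPrecursorLoss,
       residueFreq = residueFreq, scoreGlyco = scoreGlyco,
       scoreDecoy = scoreDecoy)
}

#' Generate a synthetic tryptic glycoproteome
#'
#' Samples `cfg$nPeptides` tryptic-like peptides: C-terminal K/R, at most
#' `missedCleavageMax` internal K/R, lengths from the configured
#' distribution. A `glycoFraction` of peptides receive 1-2 HexNAc on
#' uniformly chosen S/T positions (a designated glycopeptide with no S/T
#' in its sampled sequence has one internal residue substituted by S or
#' T, so peptides without S/T are never glyco). Cysteines are annotated
#' with carbamidomethyl, the fixed-modification convention. Seeds the RNG
#' from `cfg$seed`, so regeneration is exact.
#'
#' @param cfg a [simulationConfig()].
#' @return list of [Peptide-class] with a logical `isGlyco` attribute.
#' @export
generatePeptides <- function(cfg) {
  set.seed(cfg$seed)
  freq <- cfg$residueFreq
  internalFreq <- freq[!names(freq) %in% c("K", "R")]
  internalFreq <- internalFreq / sum(internalFreq)
  isGlyco <- logical(cfg$nPeptides)
  peps <- vector("list", cfg$nPeptides)
  for (i in seq_len(cfg$nPeptides)) {
    len <- round(stats::rgamma(1, shape = cfg$lengthShape,
                               scale = cfg$lengthScale))
    len <- min(max(len, cfg$lengthMin), cfg$lengthMax)
    body <- sample(names(internalFreq), len - 1, replace = TRUE,
                   prob = internalFreq)
    nMissed <- sample(0:cfg$missedCleavageMax, 1,
                      prob = cfg$missedCleavageProb[
                        seq_len(cfg$missedCleavageMax + 1)])
    if (nMissed > 0 && len > 2) {
      at <- sample(seq_len(len - 1), min(nMissed, len - 2))
      body[at] <- sample(c("K", "R"), length(at), replace = TRUE)
    }
    terminal <- sample(c("K", "R"), 1)
    seqChars <- c(body, terminal)

    glyco <- stats::runif(1) < cfg$glycoFraction
    if (glyco && !any(seqChars[-len] %in% c("S", "T"))) {
      sub <- if (len > 2) sample(seq_len(len - 1), 1) else 1L
      seqChars[sub] <- sample(c("S", "T"), 1)
    }
    sequence <- paste(seqChars, collapse = "")
    mods <- character()
    if (glyco) {
      st <- which(seqChars %in% c("S", "T"))
      nSites <- min(sample(1:2, 1), length(st))
      sites <- sort(st[sample.int(length(st), nSites)])
      mods <- c(mods, sprintf("HexNAc@%s%d", seqChars[sites], sites))
    }
    cys <- which(seqChars == "C")
    if (length(cys))
      mods <- c(mods, sprintf("Carbamidomethyl@C%d", cys))
    peps[[i]] <- Peptide(sequence,
                         if (length(mods)) paste(mods, collapse = "; "))
    isGlyco[i] <- glyco
  }
  attr(peps, "isGlyco") <- isGlyco
  peps
}

#' Simulate one EThcD-like spectrum with ground truth
#'
#' Emits the b/y ladder with ammonia/water derivatives (each peak kept
#' with probability `ladderCompleteness`), HexNAc intact/loss fragment
#' pairs, the oxonium trio and the precursor-minus-HexNAc peak for
#' glycopeptides, Gaussian ppm m/z jitter and uniform noise peaks. A
#' non-glyco spectrum never receives a noise peak within 0.06 Da of an
#' oxonium target, so oxonium absence is guaranteed by construction. The
#' ion score and expectation value are drawn from the class-conditional
#' models, and the intended zero-noise tier is recorded.
#'
#' Uses (does not reset) the current RNG stream; seed once per dataset.
#'
#' @param peptide a [Peptide-class].
#' @param cfg a [simulationConfig()].
#' @param scanId spectrum identifier.
#' @return list with `spectrum` ([Spectrum-class]) and `truth` (one-row
#'   data.frame: identifiers, modification string, class, planted
#'   diagnostics, score, expect, intended `true_class`).
#' @export
simulateSpectrum <- function(peptide, cfg, scanId = "SYN_0001") {
  glyco <- any(peptide@mods$name == "HexNAc")
  neutral <- peptideNeutralMass(peptide)
  z <- sample(2:3, 1)
  jitter <- function(mz) {
    if (cfg$mzJitterPpm > 0)
      mz * (1 + stats::rnorm(length(mz), 0, cfg$mzJitterPpm) * 1e-6)
    else mz
  }
  losses <- c("NH3", "H2O", if (glyco) "HexNAc")
  frags <- generateFragments(peptide, maxCharge = 1, losses = losses)
  keep <- stats::runif(nrow(frags)) <= cfg$ladderCompleteness
  if (!glyco) {
    # decoy spectra are oxonium-free by construction: drop backbone ions
    # that happen to fall into a diagnostic window
    forbid <- c(oxoniumTargets()$primary, oxoniumTargets()$secondary)
    keep <- keep & vapply(frags$mz, function(x)
      all(abs(x - forbid) > 0.06), logical(1))
  }
  fragMz <- frags$mz[keep]
  mz <- jitter(fragMz)
  int <- stats::runif(length(mz), 20, 100)

  planted <- list(oxonium = FALSE, precursorLoss = FALSE,
                  nLadder = sum(keep),
                  nHexPairs = nrow(hexnacLossPairs(frags[keep, , drop = FALSE])))
  if (glyco && cfg$plantOxonium) {
    ox <- oxoniumTargets()
    oxMz <- c(ox$primary, ox$secondary)
    mz <- c(mz, jitter(oxMz))
    int <- c(int, stats::runif(length(oxMz), 120, 200))
    planted$oxonium <- TRUE
  }
  if (glyco && cfg$plantPrecursorLoss) {
    nlMz <- mzFromMass(neutral - massConstants[["hexnac"]], z)
    mz <- c(mz, jitter(nlMz))
    int <- c(int, stats::runif(1, 50, 120))
    planted$precursorLoss <- TRUE
  }
  if (cfg$noisePeaks > 0) {
    forbidden <- c(oxoniumTargets()$primary, oxoniumTargets()$secondary)
    noise <- numeric(0)
    while (length(noise) < cfg$noisePeaks) {
      cand <- stats::runif(cfg$noisePeaks - length(noise), 100, 1800)
      if (!glyco)  # keep decoy spectra oxonium-free by construction
        cand <- cand[vapply(cand, function(x)
          all(abs(x - forbidden) > 0.06), logical(1))]
      noise <- c(noise, cand)
    }
    mz <- c(mz, noise)
    int <- c(int, stats::runif(length(noise), 1, 20))
  }
  precMz <- jitter(mzFromMass(neutral, z))
  spec <- Spectrum(scanId, mz, int, precMz, z)

  sc <- if (glyco) cfg$scoreGlyco else cfg$scoreDecoy
  score <- sc$shift + stats::rgamma(1, shape = sc$shape, scale = sc$scale)
  expect <- if (glyco) 10^-stats::runif(1, 2, 5) else 10^-stats::runif(1, 1, 3)
  trueClass <- if (expect >= 0.05 || score <= 20) "rejected"
    else if (score < 30 || !glyco) "candidate"
    else if (score >= 40) "very_high" else "high"

  m <- peptide@mods
  modStr <- if (nrow(m)) paste(sprintf("%s@%s%d", m$name,
                                       substring(peptide@sequence,
                                                 m$position, m$position),
                                       m$position), collapse = "; ") else ""
  truth <- data.frame(
    spectrum_id = scanId, peptide = peptide@sequence,
    modifications = modStr, is_glyco = glyco, charge = z,
    ion_score = score, p_expect = expect,
    precursor_mz = precMz,
    planted_oxonium = planted$oxonium,
    planted_precursor_loss = planted$precursorLoss,
    planted_ladder_peaks = planted$nLadder,
    planted_hexnac_pairs = planted$nHexPairs,
    true_class = trueClass, stringsAsFactors = FALSE)
  list(spectrum = spec, truth = truth)
}

#' Simulate a full dataset in memory
#'
#' Seeds from `cfg$seed`, generates the peptides and one spectrum per
#' peptide (scan ids `SYN_0001`, ...), and assembles the PSM table the
#' search engine would have produced.
#'
#' @param cfg a [simulationConfig()].
#' @return list: `spectra` (list of [Spectrum-class]), `psms` (data.frame
#'   in [readPSMTable()] column layout), `truth` (ground-truth
#'   data.frame).
#' @export
simulateDataset <- function(cfg) {
  peps <- generatePeptides(cfg)  # seeds the stream
  ids <- sprintf("SYN_%04d", seq_along(peps))
  if (anyDuplicated(ids)) stop("spectrum id collision")
  sims <- lapply(seq_along(peps), function(i)
    simulateSpectrum(peps[[i]], cfg, ids[i]))
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  psms <- data.frame(
    spectrum_id = truth$spectrum_id, peptide = truth$peptide,
    modifications = truth$modifications, ion_score = truth$ion_score,
    p_expect = truth$p_expect, precursor_mz = truth$precursor_mz,
    charge = truth$charge, source_strain = "synthetic",
    stringsAsFactors = FALSE)
  list(spectra = lapply(sims, `[[`, "spectrum"), psms = psms,
       truth = truth)
}

#' Emit a synthetic dataset to disk
#'
#' Writes `spectra.mgf`, `psms.csv` and `ground_truth.csv` into `dir`,
#' cross-referenced by spectrum id; all three round-trip through the
#' package's own readers. Identical configs (same seed) produce
#' byte-identical files.
#'
#' @param cfg a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
emitDataset <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- simulateDataset(cfg)
  paths <- c(mgf = file.path(dir, "spectra.mgf"),
             psms = file.path(dir, "psms.csv"),
             truth = file.path(dir, "ground_truth.csv"))
  writeMGF(d$spectra, paths[["mgf"]])
  psms <- d$psms
  psms$ion_score <- sprintf("%.4f", psms$ion_score)
  psms$p_expect <- sprintf("%.6g", psms$p_expect)
  psms$precursor_mz <- sprintf("%.6f", psms$precursor_mz)
  utils::write.csv(psms, paths[["psms"]], row.names = FALSE, quote = FALSE)
  truth <- d$truth
  truth$ion_score <- sprintf("%.4f", truth$ion_score)
  truth$p_expect <- sprintf("%.6g", truth$p_expect)
  truth$precursor_mz <- sprintf("%.6f", truth$precursor_mz)
  utils::write.csv(truth, paths[["truth"]], row.names = FALSE, quote = TRUE)
  invisible(paths)
}
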