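# Shared fixtures, built in code at test time.

# PSM records from the rows of a simulated PSM table
psmRecordsFromTable <- function(psms) {
  lapply(seq_len(nrow(psms)), function(i) {
    r <- psms[i, ]
    PSMRecord(r$spectrum_id, Peptide(r$peptide, r$modifications),
              r$ion_score, r$p_expect, r$precursor_mz, r$charge,
              r$source_strain)
  })
}

# a spectrum containing exactly the theoretical peaks of a peptide
# (full ladder + diagnostics), no jitter, no noise
plantedSpectrum <- function(peptide, scanId = "planted", charge = 2L,
                            losses = c("NH3", "H2O", "HexNAc"),
                            withOxonium = TRUE, withPrecursorLoss = TRUE) {
  if (is.character(peptide)) peptide <- Peptide(peptide)
  glyco <- any(modifications(peptide)$name == "HexNAc")
  if (!glyco) losses <- setdiff(losses, "HexNAc")
  frags <- generateFragments(peptide, maxCharge = 1, losses = losses)
  mz <- frags$mz
  if (glyco && withOxonium) {
    ox <- oxoniumTargets()
    mz <- c(mz, ox$primary, ox$secondary)
  }
  neutral <- peptideNeutralMass(peptide)
  if (glyco && withPrecursorLoss)
    mz <- c(mz, mzFromMass(neutral - massConstants[["hexnac"]], charge))
  mz <- unique(mz)
  Spectrum(scanId, mz, rep(100, length(mz)),
           precursorMz = mzFromMass(neutral, charge),
           precursorCharge = charge)
}

# exhaustive hypergeometric upper-tail oracle: direct sum of the pmf over
# all outcomes >= x, using only choose() -- independent of phyper
hyperTailOracle <- function(x, termSize, backgroundSize, querySize) {
  ks <- seq(0, min(termSize, querySize))
  pmf <- choose(termSize, ks) * choose(backgroundSize - termSize,
                                       querySize - ks) /
    choose(backgroundSize, querySize)
  sum(pmf[ks >= x])
}

# random peptide sequence (uniform residues, no terminal rule)
randomSequence <- function(len) {
  paste(sample(names(glycoEvidence::residueMasses), len, replace = TRUE),
        collapse = "")
}
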