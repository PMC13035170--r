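# Diagnostic battery and tiered confidence classification.

test_that("oxonium scan implements the 'primary with secondary and/or' semantics", {
  both <- Spectrum("s", c(138.0550, 204.0867), c(1, 1))
  expect_equal(scanOxonium(both), list(primary = TRUE, secondary = TRUE))
  onlySecondary <- Spectrum("s", 144.0660, 1)
  expect_equal(scanOxonium(onlySecondary),
               list(primary = FALSE, secondary = TRUE))
  empty <- Spectrum("s", numeric(), numeric())
  expect_equal(scanOxonium(empty), list(primary = FALSE, secondary = FALSE))
  outside <- Spectrum("s", 204.15, 1)
  expect_false(scanOxonium(outside, tol = 0.05)$primary)
})

test_that("neutral-loss detection sees precursor and fragment-pair evidence", {
  p <- Peptide("PNSRHDNVSPSK", "HexNAc@S9")
  s <- plantedSpectrum(p, charge = 2L)
  nl <- detectNeutralLoss(s, p)
  expect_true(nl$precursor)
  expect_gte(nl$fragmentPairs, 1)

  # only the precursor-loss peak, no fragment pairs
  neutral <- peptideNeutralMass(p)
  sPrec <- Spectrum("s", mzFromMass(neutral - massConstants[["hexnac"]], 2),
                    1, mzFromMass(neutral, 2), 2L)
  nlPrec <- detectNeutralLoss(sPrec, p)
  expect_true(nlPrec$precursor)
  expect_equal(nlPrec$fragmentPairs, 0L)

  expect_error(detectNeutralLoss(s, Peptide("PNSRHDNVSPSK")), "undefined")
})

test_that("site support requires a covering modified ion bracketed by an unmodified one", {
  p <- Peptide("PNSRHDNVSPSK", "HexNAc@S9")
  full <- plantedSpectrum(p)
  fr <- generateFragments(p, losses = c("NH3", "H2O", "HexNAc"))
  m <- matchPeaks(full, fr, tol = 0.05)
  ss <- siteSupport(m, p)
  expect_equal(ss$position, 9)
  expect_true(ss$flankingB)
  expect_true(ss$flankingY)

  # only y1..y2 matched: site 4 residues from the C terminus unsupported
  y12 <- fr[fr$series == "y" & fr$index <= 2 & fr$loss == "none", ]
  sSmall <- Spectrum("s", y12$mz, rep(1, nrow(y12)))
  ssSmall <- siteSupport(matchPeaks(sSmall, fr, tol = 0.05), p)
  expect_false(ssSmall$flankingY)

  # no matches at all -> both flags false
  none <- matchPeaks(Spectrum("s", 1000, 1), fr, tol = 0.05)
  ss0 <- siteSupport(none, p)
  expect_false(ss0$flankingB || ss0$flankingY)
  expect_error(siteSupport(m, Peptide("PNSRHDNVSPSK")), "undefined")
})

passingDiag <- function() {
  list(isGlyco = TRUE, oxoniumPrimaryFound = TRUE,
       oxoniumSecondaryFound = TRUE, neutralLossPrecursor = TRUE,
       neutralLossFragmentCount = 2L,
       siteSupport = data.frame(position = 9, flankingB = TRUE,
                                flankingY = TRUE),
       precursorPpm = 1.2, matchedFraction = 0.8)
}

test_that("score tiers follow the worked boundaries with diagnostics held passing", {
  d <- passingDiag()
  mk <- function(score, expect = 0.001)
    PSMRecord("s", Peptide("PNSRHDNVSPSK", "HexNAc@S9"), score, expect)
  expect_equal(classifyPSM(mk(41.0), d)$tier, "very_high")
  expect_equal(classifyPSM(mk(33.6), d)$tier, "high")
  expect_equal(classifyPSM(mk(22.2), d)$tier, "candidate")
  expect_equal(classifyPSM(mk(20.0), d)$tier, "rejected")   # strict > 20
  expect_equal(classifyPSM(mk(30.0), d)$tier, "high")       # >= 30 inclusive
  expect_equal(classifyPSM(mk(40.0), d)$tier, "very_high")  # >= 40 inclusive
  expect_equal(classifyPSM(mk(50, expect = 0.05), d)$tier, "rejected")
  expect_equal(classifyPSM(mk(50, expect = 0.2), d)$tier, "rejected")
})

test_that("failed diagnostics demote a high-scoring PSM with explicit reasons", {
  mk <- function() PSMRecord("s", Peptide("PNSRHDNVSPSK", "HexNAc@S9"),
                             41.0, 0.001)
  ablations <- list(
    oxoniumPrimaryFound = "primary oxonium",
    oxoniumSecondaryFound = "secondary oxonium",
    precursorPpm = "ppm")
  for (field in names(ablations)) {
    d <- passingDiag()
    d[[field]] <- if (field == "precursorPpm") 15 else FALSE
    out <- classifyPSM(mk(), d)
    expect_equal(out$tier, "candidate")
    expect_true(any(grepl(ablations[[field]], out$reasons)),
                info = field)
  }
  d <- passingDiag()
  d$neutralLossPrecursor <- FALSE; d$neutralLossFragmentCount <- 0L
  expect_match(classifyPSM(mk(), d)$reasons[2], "neutral loss")
  d <- passingDiag()
  d$siteSupport$flankingB <- FALSE; d$siteSupport$flankingY <- FALSE
  expect_match(classifyPSM(mk(), d)$reasons[2], "flanking")
  # neutral loss satisfied by either level alone
  d <- passingDiag(); d$neutralLossPrecursor <- FALSE
  expect_equal(classifyPSM(mk(), d)$tier, "very_high")
  d <- passingDiag(); d$neutralLossFragmentCount <- 0L
  expect_equal(classifyPSM(mk(), d)$tier, "very_high")
})

test_that("tier is monotone in ion score at fixed diagnostics", {
  d <- passingDiag()
  ranks <- c(rejected = 0, candidate = 1, high = 2, very_high = 3)
  scores <- c(5, 19.9, 20, 20.1, 25, 29.9, 30, 35, 39.9, 40, 60)
  tiers <- vapply(scores, function(sc)
    classifyPSM(PSMRecord("s", Peptide("PNSRHDNVSPSK", "HexNAc@S9"),
                          sc, 1e-3), d)$tier, character(1))
  expect_true(all(diff(ranks[tiers]) >= 0))
})

test_that("validatePSM recovers planted evidence end-to-end and explains ablations", {
  p <- Peptide("PNSRHDNVSPSK", "HexNAc@S9; HexNAc@S11")
  s <- plantedSpectrum(p, scanId = "scan1", charge = 2L)
  psm <- PSMRecord("scan1", p, 41.0, 0.001,
                   precursorMzObserved = precursorMz(s), charge = 2L)
  rep1 <- validatePSM(psm, s)
  expect_s4_class(rep1, "EvidenceReport")
  expect_equal(tier(rep1), "very_high")
  expect_equal(rep1@mrCalc, peptideNeutralMass(p))
  expect_equal(diagnostics(rep1)$precursorPpm, 0)

  # oxonium peaks removed -> demoted with the oxonium rule cited
  sNoOx <- plantedSpectrum(p, scanId = "scan1", charge = 2L,
                           withOxonium = FALSE)
  rep2 <- validatePSM(psm, sNoOx)
  expect_equal(tier(rep2), "candidate")
  expect_true(any(grepl("oxonium", tierReasons(rep2))))

  # non-glyco decoy can never be high/very_high
  decoy <- Peptide("DELPAIRLLEEDK")
  sd <- plantedSpectrum(decoy, scanId = "scan2", charge = 2L)
  repD <- validatePSM(PSMRecord("scan2", decoy, 55, 1e-4,
                                precursorMz(sd), 2L), sd)
  expect_equal(tier(repD), "candidate")
  expect_true(any(grepl("no HexNAc site", tierReasons(repD))))

  expect_error(validatePSM(psm, sd), "scan2")
  expect_error(validateDataset(list(psm), list(sd)), "scan1")

  # determinism: identical inputs give identical reports
  rep1b <- validatePSM(psm, s)
  expect_identical(tierReasons(rep1), tierReasons(rep1b))
  expect_identical(peakMatches(rep1), peakMatches(rep1b))
})

test_that("validation config round-trips through YAML with defaults preserved", {
  cfg <- validationConfig()
  expect_equal(cfg$fragmentTol, 0.05)
  expect_equal(cfg$precursorTol, 0.08)
  expect_equal(cfg$ppmBand, 10)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fragmentTol: 0.02", "requireOxoniumSecondary: no",
               "oxonium:", "  primary: 204.0867",
               "  secondary: [138.055, 144.066, 168.066]"), path)
  cfg2 <- readValidationConfig(path)
  expect_equal(cfg2$fragmentTol, 0.02)
  expect_false(cfg2$requireOxoniumSecondary)
  expect_true(168.066 %in% cfg2$oxonium$secondary)
  expect_equal(cfg2$ppmBand, 10)  # untouched default
  writeLines("bogusField: 1", path)
  expect_error(readValidationConfig(path), "bogusField")
})
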