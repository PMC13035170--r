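# MGF / PSM-table ingestion and tolerance-based peak matching.

test_that("MGF write/read round-trips spectra losslessly to 6 dp", {
  s1 <- Spectrum("scan=1", c(500.123456, 204.0867, 138.055),
                 c(10.5, 99.123456, 3), 880.403, 2L)
  s2 <- Spectrum("scan=2", numeric(), numeric())  # empty block preserved
  path <- withr::local_tempfile(fileext = ".mgf")
  writeMGF(list(s1, s2), path)
  back <- readMGF(path)
  expect_length(back, 2)
  expect_equal(scanId(back[[1]]), "scan=1")
  expect_equal(back[[1]]@mz, sort(s1@mz), tolerance = 1e-6)
  expect_equal(back[[1]]@intensity, s1@intensity[order(s1@mz)],
               tolerance = 1e-6)
  expect_equal(precursorMz(back[[1]]), 880.403, tolerance = 1e-6)
  expect_equal(precursorCharge(back[[1]]), 2L)
  expect_length(back[[2]]@mz, 0)
})

test_that("MGF parser normalizes peak order, flags bad charge, errors on malformed blocks", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=t1", "PEPMASS=500.25", "CHARGE=banana",
               "300.1 5", "200.1 3", "END IONS"), path)
  expect_warning(sp <- readMGF(path), "unparseable CHARGE")
  expect_equal(sp[[1]]@mz, c(200.1, 300.1))  # sorted on load
  expect_true(is.na(precursorCharge(sp[[1]])))

  writeLines(c("BEGIN IONS", "TITLE=t1", "PEPMASS=500.25",
               "not_a_peak", "END IONS"), path)
  expect_error(readMGF(path), "block 1")
  writeLines(c("BEGIN IONS", "TITLE=t1", "100 1", "END IONS",
               "BEGIN IONS", "TITLE=t2", "100 1"), path)
  expect_error(readMGF(path), "unbalanced")
})

test_that("PSM tables parse mods, quarantine invalid rows, and report missing columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "spectrum_id,peptide,modifications,ion_score,p_expect,precursor_mz,charge,source_strain",
    "s1,PNSRHDNVSPSK,HexNAc@S9; HexNAc@S11,41.0,0.001,872.41,2,WT-N2-L1",
    "s2,PNSRHDNVSPSK,HexNAc@A3,35.0,0.001,872.41,2,WT-N2-L1",
    "s3,PEPTIDEZ,,30.0,0.001,500.0,2,WT-N2-L1",
    "s4,VGLIAARRTGR,HexNAc@T9,22.0,0.01,686.9,2,Tau-adult"), path)
  res <- readPSMTable(path)
  expect_length(res$records, 2)
  rec <- res$records[[1]]
  expect_equal(nrow(modifications(rec@peptide)), 2)
  expect_equal(rec@ionScore, 41.0)
  expect_equal(nrow(res$rejected), 2)
  expect_match(res$rejected$reason[res$rejected$spectrum_id == "s2"],
               "sequence has")
  expect_match(res$rejected$reason[res$rejected$spectrum_id == "s3"],
               "outside the 20 standard")

  # empty file with header -> empty record list, no rejects
  writeLines("spectrum_id,peptide,modifications,ion_score,p_expect,precursor_mz,charge",
             path)
  res2 <- readPSMTable(path)
  expect_length(res2$records, 0)
  expect_equal(nrow(res2$rejected), 0)

  writeLines(c("spectrum_id,peptide,ion_score", "a,GK,10"), path)
  expect_error(readPSMTable(path), "p_expect")
})

test_that("peak matching finds planted peaks exactly and respects the tolerance boundary", {
  p <- Peptide("PNSRHDNVSPSK", "HexNAc@S9")
  fr <- generateFragments(p)
  planted <- Spectrum("s", fr$mz, rep(1, nrow(fr)))
  m <- matchPeaks(planted, fr, tol = 0.05)
  expect_equal(nrow(m), nrow(fr))
  expect_equal(m$errorDa, rep(0, nrow(m)))
  expect_equal(m$errorPpm, rep(0, nrow(m)))

  displaced <- Spectrum("s", fr$mz + 0.06, rep(1, nrow(fr)))
  expect_equal(nrow(matchPeaks(displaced, fr, tol = 0.05)), 0)
})

test_that("nearest peak wins; exact ties break by intensity; ppm mode scales with mass", {
  fr <- generateFragments(Peptide("GK"))
  target <- fr$mz[1]
  s <- Spectrum("s", c(target - 0.03, target + 0.01), c(100, 1))
  m <- matchPeaks(s, fr[1, ], tol = 0.05)
  expect_equal(m$observedMz, target + 0.01)  # nearer beats more intense
  sTie <- Spectrum("s", c(target - 0.02, target + 0.02), c(1, 100))
  mTie <- matchPeaks(sTie, fr[1, ], tol = 0.05)
  expect_equal(mTie$observedIntensity, 100)

  # 10 ppm window at m/z 58 is ~0.00058 Da
  sPpm <- Spectrum("s", target + 0.001, 1)
  expect_equal(nrow(matchPeaks(sPpm, fr[1, ], tol = 10, unit = "ppm")), 0)
  expect_equal(nrow(matchPeaks(sPpm, fr[1, ], tol = 20, unit = "ppm")), 1)
})

test_that("matching is order-independent and one-to-at-most-one per fragment", {
  set.seed(31)
  p <- Peptide("DELPAIRLISLEEDMTK", "HexNAc@S10")
  fr <- generateFragments(p, losses = c("NH3", "H2O", "HexNAc"))
  mz <- c(fr$mz + rnorm(nrow(fr), 0, 0.01), runif(50, 100, 1800))
  int <- runif(length(mz), 1, 100)
  perm <- sample(seq_along(mz))
  m1 <- matchPeaks(Spectrum("a", mz, int), fr, tol = 0.05)
  m2 <- matchPeaks(Spectrum("a", mz[perm], int[perm]), fr, tol = 0.05)
  expect_equal(m1, m2)
  expect_lte(nrow(m1), nrow(fr))
  expect_false(anyDuplicated(paste(m1$series, m1$index, m1$charge,
                                   m1$loss)) > 0)
})
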