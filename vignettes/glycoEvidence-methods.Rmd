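---
title: "Validating O-GlcNAc glycopeptide identifications: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating O-GlcNAc glycopeptide identifications: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoEvidence)
```

## The problem

O-GlcNAcylation attaches a single N-acetylglucosamine (HexNAc, +203.079373
Da) to serine or threonine hydroxyls of intracellular proteins. Identifying
O-GlcNAc glycopeptides from tandem mass spectrometry is harder than ordinary
peptide identification: the modification is labile, site assignment is
ambiguous, and a search engine will happily annotate HexNAc onto spectra
with no glycan evidence at all. Practice therefore layers a manual
inspection on top of the engine's score: are the HexNAc oxonium ions
present? Is the 203.0794 Da neutral loss observed? Do b/y backbone ions
bracket the assigned site? `glycoEvidence` turns that inspection into a
deterministic, auditable procedure, and pairs it with a synthetic-data
generator so that every stage can be exercised end to end without any
external download.

## Mass model

A peptide's neutral monoisotopic mass is the sum of its residue masses,
one water, and all modification deltas:

$$M = \sum_i m_{r_i} + m_{\mathrm{H_2O}} + \sum_j \Delta_j .$$

Residue masses are the standard monoisotopic values at six decimal places
(`residueMasses`); I and L are distinct letters with identical mass. The
built-in modifications are HexNAc (+203.079373, S/T), carbamidomethyl
(+57.021464, C) and oxidation (+15.994915, M); others can be loaded from a
YAML table. Carbamidomethyl is treated as a per-peptide annotation rather
than an unconditional addition: a PSM explicitly annotated with an
unmodified cysteine keeps it, which is required to reproduce one of the
worked examples in the test suite (a 33-mer whose calculated mass is only
consistent with a bare Cys). `m/z = (M + z\,m_p)/z` with the proton at
1.007276 Da, and mass error is reported as signed ppm.

Comparison against values printed at two decimals uses round-half-away-
from-zero (`roundHalfUp`), applied at report time only; all internal
arithmetic is full precision. One known edge: the pentaglycosylated
14-mer RARDSASSSSSHSK computes to 2477.09 at 2 dp under a five-site HexNAc
configuration, 0.01 below the value reported alongside it in the
literature this convention follows; the package does not force agreement.

## Fragment model

For each backbone cut site $i$ the generator emits $b_i$ (N-terminal
prefix) and $y_{N-i}$ (C-terminal suffix + water), so that
$b_i + y_{N-i} = M$ exactly — an identity the tests enforce to $10^{-9}$
Da over a thousand random peptides. Ammonia- and water-loss derivatives
(y*, y°) are offered on all fragments by default; residue-conditional
rules are available but off, since manual annotation practice applies the
derivatives without restriction. HexNAc loss is generated only for
fragments whose span covers a modified site, giving intact/loss pairs
separated by exactly 203.0794 Da (4 dp) on the neutral scale. EThcD also
produces c/z ions; these are implemented but disabled by default because
the validation convention relies on b/y. Doubly charged fragments are
emitted only above 800 Da neutral mass (configurable) to bound the match
space — the convention evaluates 1+ and 2+ states but states no rule, so
the floor is this package's own choice.

## Matching

Peak matching is nearest-within-tolerance: each theoretical fragment takes
at most one observed peak; peaks are reusable across fragments (no
bipartite assignment), mirroring how a human annotates a spectrum and
keeping matching linear. Exact-tie distances break toward the higher
intensity peak, which makes matching deterministic and independent of
peak input order. The default tolerance is 0.05 Da (the fragment-ion
search setting); ppm-based matching is available as an option, and both
Da and ppm errors are recorded per match so either gate can be applied
afterwards. The precursor tolerance (0.08 Da) and the 5–10 ppm band are
carried in the same configuration object.

## The diagnostic battery and tier ladder

`validatePSM` computes, per PSM:

* **Oxonium scan** — a peak within tolerance of 204.0867 (primary), and
  of 138.055 and/or 144.066 (secondary; one suffices). The default rule
  requires primary AND at least one secondary; a config switch relaxes to
  primary-only.
* **Neutral loss** — at the precursor level (a peak at the m/z of
  $M - 203.079$ for charge $z$ or $z-1$) and at the fragment level
  (intact/loss ion pairs both matched). Either level satisfies the rule;
  both are recorded separately, because the convention does not say which
  level the inspection used.
* **Site support** — a HexNAc site at position $k$ is b-supported when a
  matched b ion covers it (index ≥ k, hence carrying the modification)
  and a matched b ion ends before it without carrying any modification,
  bracketing the site; y-support is the mirror image. A site at the first
  (last) residue cannot have a left (right) bracket and the covering ion
  alone suffices.
* **Precursor ppm** — the "5–10 ppm" criterion is read as an acceptance
  band $|\mathrm{ppm}| \le 10$, with $\le 5$ reported as a quality grade;
  a literal requirement of *at least* 5 ppm error would be physically
  nonsensical, and the same source also phrases it as "5–10 ppm or less".

Classification: expectation value ≥ 0.05 or score ≤ 20 (strictly more
than 20 is required) → `rejected`; score in (20, 30) → `candidate`;
score ≥ 30 with all enabled diagnostics passing → `high`; additionally
score ≥ 40 → `very_high`. A score ≥ 30 PSM that fails diagnostics is
demoted to `candidate` with every failed rule cited in `reasons`. The
conjunctive reading (all three diagnostic classes simultaneously) is the
default, with per-rule toggles, since the convention is not fully
explicit about subsets. A PSM whose assigned peptide carries no HexNAc
can never exceed `candidate`: the O-GlcNAc diagnostics are undefined for
it, which is exactly what makes planted decoys a specificity control.
Tier is monotone in score at fixed diagnostics, and no report with
expect ≥ 0.05 ever exceeds `rejected` — both properties are tested.

## Enrichment and orthologs

Over-representation uses the upper hypergeometric tail (probability of at
least the observed overlap when drawing $|query|$ genes from the
background), BH adjustment across all tested terms, and binning of the
adjusted values at the three conventional reporting thresholds (< 0.01,
< 0.001, < 1e-4). This is a deliberate stand-in for network-service
enrichment: interaction-network construction, edge confidence and shell
expansion are out of scope, and the FDR bins are the reportable surface.
The background defaults to the union of all annotation genes, explicitly
and reproducibly. The hypergeometric tail is cross-checked against an
exhaustive enumeration oracle (direct sum of the pmf via binomial
coefficients) for backgrounds up to 60, to $10^{-12}$.

Ortholog agreement consumes labelled per-source mapping tables in which
absence is encoded explicitly (an `NA` ortholog, not a missing row), and
tabulates per-source counts, both/neither counts and the percentage of
genes mapped by at least one source. On the canonical 9-gene toy
configuration (7 mapped by one source, 5 by the other, 2 by neither) the
at-least-one percentage is 7/9 ≈ 78%.

## The synthetic-data generator

The generator emulates the study conditions the analysis assumes, not
real instrument output:

* tryptic peptides ending in K/R with at most 2 missed cleavages
  (sampling weights 0.6/0.3/0.1 for 0/1/2), lengths from a discretised
  gamma (shape 9.5, scale 2 → mode 17, clipped to 7..45) whose modal
  width-5 bin is 15–19;
* residues drawn from average proteome frequencies rather than a real
  digest — adequate for mass arithmetic, not for homology;
* HexNAc on 1–2 uniformly chosen S/T sites for a configurable fraction
  (default 0.5) of peptides; designated glycopeptides lacking S/T have
  one internal residue substituted so the realized fraction stays at the
  nominal binomial rate;
* full b/y ladders with derivatives, HexNAc intact/loss pairs, the
  oxonium trio and the precursor-loss peak for glycopeptides, all
  computed through the same mass arithmetic the validator uses, so
  zero-noise recovery is exact by construction (verified by test, not
  assumed); decoy spectra are kept free of any peak within 0.06 Da of an
  oxonium target, including coincidental backbone ions;
* Gaussian ppm-scale m/z jitter and uniform noise peaks as the two noise
  dials; ion scores from shifted gammas (glyco: 25 + Γ(2.5, 5), mass
  roughly 25–45; decoys: 4 + Γ(2, 3), mostly below 20) — explicitly
  synthetic, as no score model is prescribed by the convention.

What passing tests on this generator shows: the decision procedure
recovers exactly the evidence that was planted, degrades monotonically
under jitter, and never promotes a decoy. What it does not show:
performance on real spectra with isotope clusters, chimeric
fragmentation, intensity-dependent noise or co-eluting glycoforms — none
of which are modelled.

## Problem sizes and numerical choices

The shipped tests use 200 synthetic spectra for the end-to-end recovery
check, 500 spectra per jitter level for the degradation check, 1000
simulated null queries for the ORA type-I calibration, and 1000 random
peptides for the complementarity identity — sizes chosen to make sampling
error negligible relative to the assertions while keeping the default
suite around a minute. The ORA calibration uses background 5000, term
100, query 100, where the discrete test's achievable size (0.0490,
computed analytically from the hypergeometric pmf) sits closest to the
nominal 0.05; the empirical rate is compared within three binomial
standard errors. Degenerate inputs are contract-checked rather than
silently handled: empty queries, peptides without HexNAc passed to
HexNAc-specific checks, duplicate ortholog rows and malformed MGF blocks
all raise informative errors, while invalid PSM rows are quarantined into
a reject report so no row is silently dropped.

## Limitations

Scores and expectation values are consumed, never recomputed; there is no
target-decoy FDR estimation and no site-localization probability beyond
the flanking-ion flags. mzML ingestion is limited to what MGF carries;
profile-mode peak picking is out of scope. The generator's realism limits
are listed above. Enrichment results depend entirely on the supplied GMT
collections; the package performs no live queries.
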