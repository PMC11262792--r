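---
title: "mirTarScan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirTarScan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirTarScan)
```

mirTarScan bundles the computational layer of a hepatic miRNA study
design: detecting candidate miRNA binding sites in 3'-UTRs, annotating the
sequence context of each site, asking which miRNAs are conserved between
human and mouse, screening a cohort for miRNA--trait associations, and
quantifying qPCR validation experiments. This vignette explains each model,
the tunable parameters, the synthetic data used to test everything, and
the design decisions taken where more than one reasonable convention
exists.

## Seed-match site detection

A mature miRNA recognises its target principally through its *seed*,
nucleotides 2--7 (core) or 2--8 of the 5' end. Numbering miRNA positions
1..n from the 5' end, the five canonical site classes map to target-strand
DNA motifs (written 5'→3'):

| class | target motif | target-side extras |
|---|---|---|
| 8mer | revcomp(nt 2--8) + A | A opposite position 1 |
| 7mer-m8 | revcomp(nt 2--8) | pairing extends to position 8 |
| 7mer-A1 | revcomp(nt 2--7) + A | A opposite position 1 |
| 6mer | revcomp(nt 2--7) | core only |
| offset-6mer | revcomp(nt 3--8) | core shifted by one |

The priority order 8mer > 7mer-m8 > 7mer-A1 > 6mer > offset-6mer reflects
the canonical efficacy hierarchy. The A opposite miRNA position 1 is
required to be a literal adenosine in the target, not complementarity to
position 1 — the canonical definition of A1 sites.

Worked example: for hsa-miR-182-5p (`UUUGGCAAUGGUAGAACUCACACU`) the
7mer-m8 target motif is `TTGCCAA`; mutating the central C to A
(`TTGACAA`) abolishes every canonical site, which is the classic
seed-mutant control of a luciferase reporter assay.

```{r}
seedMotifs("UUUGGCAAUGGUAGAACUCACACU")
siteTable(scanUTR(c("hsa-miR-182-5p" = "UUUGGCAAUGGUAGAACUCACACU"),
                  c(LRP6 = "ACGTACGTTGCCAATACGT")))
```

**Locus grouping.** Different classes matching the same seed alignment are
one biological site: an 8mer match necessarily contains a 7mer-m8, a
7mer-A1, a 6mer and (given position-8 pairing) an offset-6mer. We define
the *register* of a match as the target coordinate pairing miRNA
position 2 and collapse all classes sharing a register into one reported
site, labeled with the highest-priority class; the full class list is kept
in `all_modes`. `scanUTR(collapse = FALSE)` instead enumerates every
(class, position) match — the representation a naive sliding-window
enumeration produces, used by the oracle-equivalence tests. Overlapping
sites at *different* registers are all reported: nothing merges them, and
the cooperativity feature needs them.

**Coordinates and alphabets.** miRNAs are held as RNA, UTRs as DNA; all
cross-alphabet comparisons pass through explicit reverse-complement
normalisation. Coordinates are 0-based half-open internally (`start0`,
`end0`); the GRanges container renders 1-based ranges for interoperability.
`N` in a UTR matches nothing, so a site overlapping `N` is never reported.

## Binding-context features

For each site the package reports, without combining them into a score:

* `local_au` — fraction of A/T among up to 30 nt on each side of the site
  (60 nt surrounding the seed, site excluded, windows truncated at UTR
  ends, `N` excluded from numerator and denominator). AU-rich flanks
  correlate with site accessibility.
* `tp_pairing` — the longest run of contiguous Watson--Crick pairs between
  miRNA positions 12--17 (the canonical 3'-supplementary region) and the
  UTR 5' of the site, anchored at the seed register with a ±2 nt target
  offset. The window and offset are parameters; the defaults follow the
  canonical supplementary-pairing geometry.
* `dist_stop`, `dist_end`, `rel_pos`, `near_stop` — position within the
  UTR; `rel_pos = min(dist_stop, dist_end)/length ≤ 0.5`, and
  `near_stop` flags sites starting within 15 nt of the stop codon. The
  distance is reported without a valence: whether stop-codon proximity is
  favourable is left to the analyst.
* `coop_partners` — other sites on the same UTR (any miRNA) whose
  inter-site gap lies in [8, 40] nt, the range in which neighbouring
  sites typically act cooperatively; both bounds are parameters.

No composite context score is computed: the study workflow this package
supports selects targets from the feature table plus literature review,
and inventing a score would misrepresent that procedure.

## Cross-species conservation

A miRNA is treated as conserved between two species when nucleotides 2--8
(the 7mer seed) are identical; whole-sequence identity and arm annotation
are deliberately ignored, and id pairs are reported for inspection.
Because several mature miRNAs can share a seed, both tallies are emitted:
per seed family and per expressed mature miRNA of the query species (the
counting unit of the human--mouse overlap figure this mirrors).

## The interaction store

Validated interactions (miRTarBase/TarBase-style dumps) and the scanner's
own predictions live in one flat table keyed by
(mirna_id, gene_symbol, source, evidence, db_origin); gene symbols are
upper-cased on import and re-imports are idempotent. The store is an
in-memory S4 object with TSV import/export — a deliberate minimal design:
the workflow uses it only as a lookup, and full database-schema fidelity
is out of scope. `verifyAgainstUTRs()` re-scans each stored gene's UTR and
flags records whose UTR is unavailable as `"no-utr"` rather than dropping
them. The manual literature-based triage step of the original workflow is
representable only as an evidence tag.

## The cohort association screen

For each miRNA *m* and response *y* the model is

    y = b0 + b1*NAS + b2*age + b3*sex + b4*BMI + b5*log2(m)

linear for continuous traits, logistic for T2D status. When the response
is itself a covariate (NAS), it is removed from the design. `b5` is the
effect of one log2 unit of miRNA expression on the trait; association is
the Wald test of `b5`. Confounder models

    age (or BMI) = b0 + b1*HbA1c + b3*sex + b4*BMI (or age) + b5*log2(m)

flag miRNAs whose expression tracks age or BMI. A candidate must (i) pass
the expression filter (best group-mean log2 value strictly above 2.3,
the threshold below which array expression is not considered confidently
detectable), (ii) associate with at least two distinct responses at raw
p < 0.05, (iii) trip neither confounder flag, and (iv) optionally be
seed-conserved in the second species. Raw p-values drive candidacy, with
BH q-values (per response family) carried along — mirroring a screen in
which FDR control across hundreds of miRNAs leaves no survivor and
candidate triage therefore proceeds on raw significance plus orthogonal
filters. "At least two" and "T2D required among them" are both exposed
as parameters.

Degenerate fits are handled honestly: constant responses and collinear
designs raise errors; logistic fits that fail IRLS convergence (tolerance
1e-8, 100 iterations) or show numerically 0/1 fitted probabilities
(quasi-separation) are flagged `converged = FALSE`, their p-value is
withheld, and they never count as associations. Missing phenotype values
are removed per model (complete-case), with the n used recorded per fit.
The DABG rule (probeset expressed iff strictly more than half of its
probes detect signal at p < 0.05) is provided for workflows that start
from probe-level detection p-values.

`associationScreen()` shares one design matrix across the miRNAs of a
response and fits via the same least-squares/IRLS primitives as
`lm()`/`glm()`; `fitTraitModel()` is the single-fit reference
implementation and the test suite asserts row-by-row agreement between
the two paths.

**A property of the exclusion rule worth knowing.** If a miRNA genuinely
drives a trait that appears as a covariate in the confounder models
(HbA1c), conditioning on that trait induces a spurious partial association
between the miRNA and age/BMI (collider conditioning), so strong drivers
of HbA1c can be excluded as "confounded". This is inherent to the rule,
not an implementation artifact; the synthetic recovery experiment
therefore plants its candidate effects on T2D, glucose and triglycerides,
which do not enter the confounder models.

## ΔΔCt qPCR quantification

Per sample, `dCt = Ct(target) − Ct(housekeeper)`; per group,
`ddCt = mean dCt(group) − mean dCt(reference)` and `fold = 2^(−ddCt)`,
i.e. the fold change is computed from group means of dCt (not from
per-sample fold averages), so the reference group's fold is exactly 1 and
lower dCt in a test group gives fold > 1. Outliers are removed *before*
group statistics by a single-pass rule: a sample is excluded when its dCt
lies strictly outside mean ± 3 SD, with mean and SD pooled over all
samples for the gene (both groups together); a value at exactly 3 SD is
kept, and the rule is skipped with a warning below n = 3. Two groups are
compared by Student's t-test on dCt, three or more by one-way ANOVA.
Confounder-adjusted correlations residualise both variables on the
adjusters (ordinary least squares) and correlate the residuals — partial
correlation, which reduces exactly to plain Pearson with no adjusters;
a family of such correlations gets BH q-values. Amplification-efficiency
correction (Pfaffl) is out of scope.

## Synthetic data: what it emulates, and what it does not

Generators are pure functions of their arguments plus a seed.

* `genUTRs()` draws background residues i.i.d. at a requested GC content
  and splices motifs at exact positions. There is no dinucleotide
  structure, no repeat content and no secondary-structure model — enough
  to give the scanner planted truth and realistic background match rates,
  not a model of real UTR composition.
* `genCohort()` draws age ~ U(20, 70) years, sex ~ Bernoulli(0.5),
  BMI ~ U(32, 85) kg/m² (the range of a severely obese bariatric cohort),
  NAS uniform on 0--7. Continuous traits are linear in the covariates with
  Gaussian noise in plausible clinical units (HbA1c: intercept 5.6 %,
  noise SD 0.8; glucose: 80 mg/dl, SD 12; insulin: 6 mU/l, SD 4;
  triglycerides: 90 mg/dl, SD 35). T2D follows a logistic model whose
  linear predictor is centred to hit a target prevalence (default 0.5, a
  matched case/control design). Planted effects add `beta × (expression −
  baseline)` to a response; proxy miRNAs track standardised age with
  residual SD 0.5. Real cohorts have correlated covariates, non-Gaussian
  traits, batch structure and measurement error, none of which are
  simulated — so passing recovery tests demonstrates correctness of the
  screening machinery, not field performance.
* `genCt()` draws housekeeper Ct ~ N(20, 0.3²) cycles and target Ct as
  housekeeper + a group-specific dCt draw; injected outliers are displaced
  by 8 SDs of the pooled dCt distribution (comfortably beyond the 6-SD
  planting minimum needed for unambiguous single-pass detection).

The recovery experiment reported by `scripts/acceptance.R` uses 20
cohorts of n = 500 samples × 200 miRNAs with 5 planted candidates
(effects as above: T2D logit 1.0, glucose 6, triglycerides 15 per log2
unit) and 3 age proxies; these sizes give each planted effect essentially
full single-test power while keeping a full run in the low minutes on one
core. The scanner oracle comparison uses 1000 random miRNA/UTR pairs with
UTRs up to 5 kb.

## Numerical choices and edge cases

* Strict inequalities at the documented boundaries: expression filter
  (> 2.3), DABG (> 50 % of probes), outlier exclusion (strictly outside
  ±3 SD).
* BH q-values come from `stats::p.adjust`; the tests hold them against a
  brute-force step-up enumeration. Linear algebra is QR-based via
  `lm.fit`; tests compare against explicit normal-equations solutions.
* `auContent` returns `NA` (not 0) when a site leaves no flank residue;
  `adjustedCorrelation` returns `NA` when residual variance is
  numerically zero (tolerance 1e-12 relative) — e.g. when a variable is
  adjusted on itself.
* Zero-variance fold-change comparisons (noiseless simulation) report the
  exact closed-form fold with an `NA` test statistic rather than failing.
* Ties in site priority cannot occur (the class priority is a strict
  total order); duplicate motifs across classes (e.g. a homopolymer seed
  making the 6mer and offset-6mer motifs identical) are distinct matches
  at distinct registers and are reported separately, exactly as a naive
  enumeration would.

## Known limitations

Non-canonical sites (3'-compensatory, centred, bulged seeds),
thermodynamic duplex energies, secondary-structure accessibility,
conservation-weighted scoring and pathway enrichment are all out of
scope. The conservation module matches seeds only — a conserved seed with
divergent 3' ends is still called conserved. The interaction store does
not model the full provenance schema of public interaction databases.
RMA normalisation of raw arrays is upstream of this package: the screen
consumes a pre-normalised log2 matrix.
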