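---
title: "Screening for phosphatase peptide substrates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for phosphatase peptide substrates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ptpscreen` ranks phosphotyrosine (pY) peptides by their resemblance to the
known dephosphorylation sites of an anchor phosphatase — PTP1B throughout
the defaults — and post-processes docked phosphatase–peptide complexes with
explicit geometric rules. This vignette explains the underlying models,
the tunable parameters, the synthetic data used for validation, and the
numerical and design choices a maintainer should know about.

## The peptide library

Tyrosine phosphatase specificity is dominated by the residues immediately
flanking the pY; peptide-library and microarray work on PTP substrate
recognition has typically used windows of about 11 residues, so the
library unit here is the 11-mer `x₋₅…x₋₁ Y x₊₁…x₊₅` centred on an
annotated site. Sites closer than five residues to a terminus are kept
and padded with the blank symbol `-`, which acts as the 21st letter of the
scoring alphabet; the published protocols are silent on terminal sites,
and padding retains them without distorting the frequency estimates of
real residues. Identical 11-mers arising from different proteins are
collapsed into one window that remembers all of its `(protein, position)`
sources — scoring is sequence-determined, so duplicates would only bias
ranks. Windows containing `X` (unknown residue) are dropped with a
warning because no frequency estimate exists for them.

The negative (background) class is every tyrosine of proteins carrying
**no** pY annotation at all. The exclusion is deliberately protein-level:
on sparsely annotated proteomes an unannotated tyrosine on a
phosphoprotein is more likely an unmeasured site than a true negative.
`enumerate_background_windows(..., exclusion = "site")` switches to
site-level exclusion for densely annotated inputs.

## The three scores

**Method 1 — information content.** For flank position $j$ the positive
alignment gives frequencies $f(i,j)$ over the 20 amino acids and column
information $R_j = \log_2 20 - (H_j + e_n)$ bits, where
$H_j = -\sum_i f(i,j)\log_2 f(i,j)$ and $e_n = 19/(2\ln 2\, n)$ is the
standard small-sample correction for $n$ sequences ($R_j$ clamped at 0).
A window scores $\sum_{j\neq 0} f(x_j, j)\,R_j$. The correction defaults
to on, matching common logo practice; both modes are tested. Blanks score
zero, and blank positions are excluded from the column frequencies so a
padded alignment does not dilute $R_j$.

**Method 2 — PSSM log-odds.** Three 21×10 column-stochastic matrices are
built: positive (known sites), negative (background tyrosines) and total
(the pooled multiset, i.e. the sample-size-weighted mixture of the two).
The combining formula in the original description of this family of
scores is not available in a machine-readable form, so the package
defines and documents its own default:

$$S(x) = \sum_{j\neq 0} \log_2
  \frac{f^+(x_j,j) + \alpha\, f^t(x_j,j)}
       {f^-(x_j,j) + \alpha\, f^t(x_j,j)},$$

a log-odds with a total-matrix pseudocount, $\alpha = 0.05$ by default.
This choice is symmetric (swapping classes negates the score), finite for
any symbol observed in either class, and reduces to plain log-odds as
$\alpha \to 0$. A symbol absent from both classes contributes 0. The
formula identifier is written into model sidecars and run manifests so
every score table is traceable; the scoring entry point is the single
place to plug in an alternative.

**Method 3 — calibrated classifier.** The original protocol used a
full-featured phosphorylation-site predictor retrained on
dephosphorylation data. `ptpscreen` provides an interface-compatible,
deliberately simple stand-in: a ridge-penalised logistic model
(`glmnet`, $\alpha_{ridge}=0$, $\lambda = 0.01$) over a one-hot encoding
of the 10 flank positions (21 symbols each) plus flank amino-acid
composition. Disorder predictions and KNN-profile features of the
original tool are out of scope; an import adapter
(`read_external_scores()`) lets externally produced score files slot into
the consensus instead. The decision threshold is not a model output: half
of the negatives (chosen by the run seed — the only randomness in the
package) are held out of fitting, and the threshold is the smallest
observed score at which no more than $1-\text{specificity}$ of these
calibration negatives pass, the order-statistic analogue of a
specificity ≥ 95 % cut. If ties at the top of the score range make even
the largest score too permissive, the threshold steps just above the
maximum (no negative passes).

**Consensus.** Each method ranks all $N$ windows (descending score, ties
broken lexicographically by peptide so reruns are bit-identical); a
window is a candidate iff its rank is $\le \lceil qN\rceil$ under all
three methods, with $q = 0.1$ by default as in strict-cutoff practice.
Strict ranks with deterministic tie order were chosen over
include-all-ties because the latter makes the consensus size
discontinuous in the data. The consensus is provably a subset of each
method's top-$q$ set and monotone in $q$; both properties are asserted in
the test suite. The classifier scores windows (deduplicated peptides)
like the other two methods; since identical peptides receive identical
scores, mapping per-site verdicts through window sources ("any passing
source site passes the peptide") coincides with this and needs no
separate code path.

## Biological filters

A candidate gene passes when it is a known substrate of the anchor
phosphatase or of any phosphatase sharing at least one substrate with the
anchor, **or** when it co-occurs with the anchor gene in at least one
pathway. Co-membership "in the same KEGG and NCI-PID pathways" is read as
a disjunction across collections — one shared pathway in either collection
suffices — because requiring simultaneous hits in every collection makes
the filter fragile to collection coverage; `pathway_mode = "all"` provides
the strict conjunction. Matching is gene-level and case-normalised;
isoform mapping is the user's responsibility. The filter is monotone
(adding substrates or pathways never removes a pass), and anchor
substrates always pass — both properties are tested.

## Pose criteria

Docked poses are compared against a reference complex (for PTP1B,
crystallographic phosphatase–peptide complexes of the 1EEO family) after a
least-squares rigid superposition (Kabsch, SVD-based, proper rotation
enforced) on phosphatase Cα atoms shared by residue number. The published
criteria were applied by manual inspection; all thresholds here are
explicit, configurable operationalisations:

* **(i) pY in the catalytic site** — distance from the pY phosphorus to
  the centroid of the pocket Cα atoms (default residues 214–221, the
  P-loop) ≤ 7 Å, inclusive. The 7 Å default spans the pocket radius plus
  the phosphate arm of a bound pY.
* **(ii) N→C orientation** — angle between the pose's Cα(pY−2)→Cα(pY+2)
  vector and the reference's < 90°, strict, with a pY±1 fallback for
  short peptides. 90° is the natural indifference point between "same"
  and "opposite" threading.
* **(iii) hydrogen bonds** — heavy-atom donor–acceptor distances ≤ 3.5 Å,
  inclusive: Asp-48 OD1/OD2 to backbone N of pY (bond 1) and of pY+1
  (bond 2); Arg-47 backbone N to backbone O of pY−2 (bond 3). "Residue 1"
  and "residue −2" of the structural literature are read as peptide
  positions pY+1 and pY−2. No hydrogens are assumed; 3.5 Å is the
  conventional heavy-atom H-bond limit. A missing atom marks the bond
  absent with a reason instead of failing the pose.

A pose is accepted iff (i) and (ii) hold and at least two of the three
bonds are present. Acceptance is invariant under any global rigid motion
of the pose (superposition removes it; asserted to 10⁻⁶), and relaxing
any cutoff can only accept more poses. Orientation is judged against a
single reference by default; a user can vote across several references by
evaluating against each. Phosphotyrosine is recognised by residue name
(`PTR` and common variants, extensible via `py_resno`).

## Synthetic data: what it does and does not emulate

`generate_proteome()` builds the statistical world the scoring assumes:
positive windows whose flanks are drawn from a per-position mixture of
preferred residues and background, decoy annotated windows with background
flanks, and unannotated background proteins supplying negatives. The
default motif is strongly acidic N-terminal to the pY (D/E preferred with
weight 0.7 at −5…−1, milder E/V/L preference at +1/+2), echoing the
acidic character of validated PTP1B substrate peptides such as
EEEDIpYEVLPD. Defaults — 60 positive sites, 240 decoys, 120 background
proteins of 150–250 residues, uniform background composition (a
human-proteome-like preset ships as `HUMAN_AA_FREQS`) — keep the
positive/decoy imbalance and positive-class size in the regime of a real
dephosphorylation-site screen while staying small enough that a full
pipeline run takes seconds. Each annotated site sits on its own protein
at an interior position, so generated windows never need padding; padding
is exercised by dedicated unit fixtures instead.

What passing on this generator shows: the arithmetic, calibration,
ranking, and consensus logic are correct, and the pipeline recovers a
planted motif (≥ 90 % of planted sites in the q = 0.25 consensus, 5-seed
median, asserted in the tests). What it does not show: performance on
real proteomes, where motifs are weaker and structured, annotations are
biased towards well-studied proteins, background composition is
non-uniform and negatives are contaminated with unannotated true sites.
Toy poses likewise encode only the criteria geometry — an idealised
P-loop, Asp-48/Arg-47 fragment and a 5-residue peptide with ≥ 0.5 Å
margins on every criterion — not docking realism.

## Numerical choices and degenerate inputs

* Logo columns that are all blank (possible only in degenerate alignments)
  get zero information; `0·log 0` is treated as 0 throughout.
* `score_pssm` requires α > 0, so denominators vanish only for symbols
  absent from all data, which contribute 0 by contract.
* Ranking uses `order(-score, peptide)`; every rank vector is a
  permutation of 1..N, so `ceiling(q·N)` cuts are unambiguous.
* Superposition needs ≥ 3 shared Cα atoms; determinant correction in the
  SVD guarantees a proper rotation even for reflective optima.
* Masses use IUPAC/CODATA monoisotopic and standard-atomic-weight residue
  tables hard-coded in the source; phosphorylation adds exactly
  79.966331 Da, acetylation 42.010565 Da, amidation −0.984016 Da
  (monoisotopic). The conventional "calculated MW" of a synthesis table
  is reported as the integer part (floor) of the monoisotopic mass, which
  is how the published values for six of the eight reference peptides are
  reproduced exactly; the remaining two are documented mismatches in the
  source table (one arithmetic, one likely a sequence-length typo) and
  are excluded from validation.
* All TSV/GMT/FASTA/PDB I/O goes through standard parsers (Biostrings,
  bio3d, base R); the only bespoke writer is the fixed-width PDB ATOM
  formatter used for synthetic poses.

## Problem sizes

The test suite and examples run the generator at 300–420 proteins with
60–300 annotated sites and ~1000–1500 background windows, and the
classifier on a few hundred windows per class — sizes chosen so a
complete validation run finishes in well under a minute on one core while
keeping binomial calibration checks meaningful. Scaling to a full
proteome (thousands of proteins, tens of thousands of tyrosines) is a
matter of input size only; no algorithm here is worse than
O(windows × alphabet × positions).

## Known limitations

* The method-2 combining formula is this package's documented default,
  not a reproduction of the original figure; results from other
  implementations of "PSSM scores" need not match numerically.
* The method-3 stand-in is a linear model; it deliberately trades the
  original predictor's feature richness for transparency and
  determinism. Use the external-score adapter to substitute a stronger
  predictor.
* Database-dependent outcomes of the original screen (library size,
  consensus counts, specific protein ranks) depend on 2016-era annotation
  snapshots and are not reproduction targets; the package validates the
  algorithmic properties instead.
* Pose criteria use distances and angles only — no energies, no solvent,
  no hydrogen positions; they are a post-docking sieve, not a scoring
  function.
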