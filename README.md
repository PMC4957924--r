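# ptpscreen

Computational screening for candidate phosphotyrosine (pY) **peptide
substrates of protein tyrosine phosphatases**, with PTP1B (gene *PTPN1*) as
the anchor enzyme. Phosphatase substrate specificity is far less charted
than kinase specificity; `ptpscreen` implements a desk-scale protocol that
ranks pY-centred peptides by how much they look like known
dephosphorylation sites, filters the hits for biological plausibility, and
post-processes docked phosphatase–peptide poses with explicit geometric
acceptance criteria. It is aimed at phosphatase biochemists who want a
short list of peptides worth synthesising.

## What it computes

**Peptide library.** From protein sequences (FASTA) and pY-site annotations
(TSV), the package extracts non-redundant 11-mer windows `x = x₋₅ … x₋₁ Y
x₊₁ … x₊₅` centred on each annotated tyrosine, padding past the termini
with the blank symbol `-` (the 21st letter of the scoring alphabet).

**Three scores per window.**

1. *Information content (sequence logo).* From the positive alignment
   (known dephosphorylation sites) each flank column j gets
   `R_j = log₂20 − (H_j + e_n)` bits, with `H_j = −Σᵢ f(i,j) log₂ f(i,j)`
   and small-sample correction `e_n = 19/(2·ln2·n)`; the window score is
   `Σ_j height(x_j, j)` with `height(i,j) = f(i,j)·R_j`.
2. *PSSM log-odds.* Positive, negative (background tyrosines from proteins
   without any pY annotation) and pooled "total" frequency matrices over
   the 21-symbol alphabet; the score is
   `Σ_j log₂[(f⁺ + α f_t)/(f⁻ + α f_t)]` with pseudocount weight
   `α = 0.05`.
3. *Calibrated classifier.* A ridge-penalised logistic model over one-hot
   window encoding plus flank composition, thresholded on held-out
   negatives so that specificity ≥ 95 %.

**Consensus.** A peptide is a candidate when it ranks in the top fraction
`q` (default 10 %) under **all three** methods.

**Biological filters.** Candidates must be substrates of the anchor
phosphatase or of a phosphatase sharing substrates with it (DEPOD-style
table), or share a KEGG / NCI-PID pathway with the anchor gene (GMT
files).

**Pose criteria.** Docked complexes (PDB) are superposed on a reference
complex by phosphatase Cα atoms (Kabsch) and accepted iff (i) the pY
phosphorus lies within 7 Å of the catalytic P-loop centroid, (ii) the
peptide N→C direction agrees with the reference (angle < 90°), and (iii)
at least two of the three canonical hydrogen bonds are formed (Asp-48
carboxylate to backbone N of pY and of pY+1; Arg-47 backbone N to backbone
O of pY−2; heavy-atom distance ≤ 3.5 Å).

**Phosphopeptide masses.** Monoisotopic/average masses of N-acetylated,
C-amidated phosphopeptides in `pY` notation, plus theoretical [M+H]⁺ and
[M+Na]⁺ ions, for checking synthesis products.

## Worked example

```r
library(ptpscreen)

## masses of two synthesised substrate peptides
mass_report(c("DPSDNpYAEPID", "STEPQpYQPGEN"))[, c("peptide", "calc_mw", "mz_Na")]
#>        peptide calc_mw    mz_Na
#> 1 DPSDNpYAEPID    1355 1378.481
#> 2 STEPQpYQPGEN    1369 1392.508

## a synthetic proteome with a planted acidic motif, then the full
## sequence-based stage
sp <- motif_spec(seed = 7)
pr <- generate_proteome(sp, dir = "demo")
pos <- pr$truth[pr$truth$planted, c("protein_id", "position")]
pos$residue <- "Y"
write.table(pos, "demo/positives.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

cfg <- run_config(fasta = "demo/proteome.fasta", sites = "demo/sites.tsv",
                  positive_sites = "demo/positives.tsv",
                  out_dir = "demo/out", q = 0.25, seed = 7)
rec <- run_predict(cfg)
c(library = nrow(rec), consensus = sum(rec$in_consensus))
#>   library consensus
#>       300        67
mean(pr$truth$peptide[pr$truth$planted] %in% rec$peptide[rec$in_consensus])
#> [1] 0.9833333
```

300 annotated windows are scored by the three methods; 67 survive the
q = 0.25 consensus, and 98 % of the 60 planted motif-bearing sites are
among them. `demo/out/candidates.tsv` holds peptide, scores, ranks and the
consensus flag; `manifest_predict.json` records every parameter, the
formula id, the seed and input checksums for bit-identical reruns.

A command-line front end wraps the same functions:

```sh
exec/ptpscreen simulate  --out-dir sim --seed 3
exec/ptpscreen predict   --fasta sim/proteome.fasta --sites sim/sites.tsv \
                         --positive-sites sim/positives.tsv --q 0.25 --seed 3
exec/ptpscreen mass      --peptides DPSDNpYAEPID,STEPQpYQPGEN
exec/ptpscreen pose-eval --reference ref.pdb --poses poses/
```

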