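# repairmap

Indel pattern-guided mapping of CRISPR/Cas9 double-strand break (DSB)
repair outcomes.

Cas9 breaks are resolved by competing repair pathways whose products are
distinguishable in amplicon sequencing: fast non-homologous end joining
leaves 1 bp (often flank-templated) insertions and small non-homologous
deletions, while microhomology-mediated end joining (MMEJ) deletes between
short (≥ 2 bp) repeats and accumulates late. `repairmap` is for researchers
who want to quantify these outcomes, model their kinetics, and screen for
the genes that regulate them:

* **Classification** — align amplicon reads to the reference, left-normalize
  indels, detect junction microhomology (MH), and assign each allele one of
  seven mechanistic patterns: `1bp Ins`, `Large Ins`, `MH Small Del`,
  `NonMH Small Del`, `MH Large Del`, `NonMH Large Del`, `Mut`. The MH
  length of a deletion of length *L* at left-normalized start *s* is the
  largest *k* with `ref[s..s+k-1] == ref[s+L..s+L+k-1]` — equivalently the
  placement-ambiguity span of the deletion.
* **Kinetics** — fit the three-state model
  *u* →(k_cut)→ *b* →(k_err)→ *e*, with perfect repair *b* →(k_perf)→ *u*
  and observed editing `F(t) = f_max · e(t)`, where `f_max` (the maximal
  editable fraction) comes from a logistic fit to the editing time course.
* **Screen statistics** — per-guide Fisher exact tests against pooled
  non-targeting controls (one-sided tails + log2 fold change), directional
  global ranking, gene-level Robust Rank Aggregation
  `rho = min_j BetaCDF(r_(j); j, k-j+1)` with permutation p-values,
  weighted Stouffer z-integration of two target-site libraries, and hit
  calling at `|log2FC| > 0.5`, `p < .05`.
* **Synthetic data** — seed-deterministic generators for loci with planted
  microhomology, edited reads with truth labels, kinetic time courses, and
  genome-scale-composition screens (19,050 genes × 6 guides + 1,864
  miRNAs × 4 + 1,000 non-targeting = 122,756 guides at full scale) with
  planted effects.

## Worked example

```r
library(repairmap)

# a 120 bp locus with planted 2 bp and 3 bp microhomology deletions
loc <- genTargetLocus(mhDesign = data.frame(offset = c(-4, -6),
                                            len = c(4, 9), mh = c(2, 3)),
                      seed = 7)

ed <- c("1bp Ins" = 0.15, "Large Ins" = 0.05, "MH Small Del" = 0.20,
        "NonMH Small Del" = 0.15, "MH Large Del" = 0.10,
        "NonMH Large Del" = 0.10, "Mut" = 0.08)
sp <- spectrumSpec(c(ed / sum(ed) * 0.85, Unedited = 0.15))
reads <- genEditedReads(loc, sp, 3000, seed = 11)
summarizeSpectrum(classifyReads(reads, loc))
#> OutcomeSpectrum: 2538 edited reads, editing fraction 0.846
#>                 count proportion
#> 1bp Ins           469     0.1848
#> Large Ins         153     0.0603
#> MH Small Del      612     0.2411
#> NonMH Small Del   444     0.1749
#> MH Large Del      303     0.1194
#> NonMH Large Del   339     0.1336
#> Mut               218     0.0859
```

The proportions recover the generating spectrum (e.g. MH Small Del 0.241
vs the true 0.85 × 0.20/0.83 ≈ 0.205 of edited reads, within binomial
error at n = 2538), and the editing fraction 0.846 matches the 0.85
edited-fraction setting.

Kinetics — simulate a noisy time course and fit the rates:

```r
truth <- c(k_cut = 0.3, k_err = 0.13, k_perf = 1e-6, f_max = 0.8)
tc <- genTimecourseCounts(truth, depth = 5000, seed = 2)
fitRepairODE(tc$edited_fraction$time_h,
             tc$edited_fraction$edited_fraction, fMax = 0.8)
#> KineticFit
#>   k_cut  = 0.2654 /h
#>   k_err  = 0.1422 /h
#>   k_perf = 0.0007802 /h
#>   f_max  = 0.8
#>   R^2 = 0.999248
#>   flags: k_perf_weakly_identified
```

`k_cut` and `k_err` land near the truth at this depth; `k_perf` is orders
of magnitude slower than `k_err` and is correctly flagged as weakly
identified rather than reported as precise.

Screen — plant one MMEJ suppressor (knockout triples the MH Small Del
frequency) among 200 genes and find it:

```r
spc <- screenSpec(nGenes = 200, nMirna = 20, nNontarget = 50,
                  plantedEffects = data.frame(gene = "GENE00042",
                                              pattern = "MH Small Del",
                                              fc = 3))
ds <- genScreenDataset(spc, seed = 5)
rec <- filterGuides(guideRecords(ds$counts, ds$manifest))$kept
sc <- screenScores(rec, "MH Small Del", "inhibiting", nPerm = 2000)
head(sc[, c("gene", "n_guides", "rra_rho", "p_empirical", "log2fc")], 3)
#>          gene n_guides      rra_rho  p_empirical    log2fc
#> 42  GENE00042        6 1.060835e-14 0.0004997501 1.0057172
#> 208   MIR0008        4 1.195275e-03 0.0039980010 0.1936160
#> 133 GENE00133        6 2.655233e-03 0.0134932534 0.1989687
```

The planted gene tops the ranking by eleven orders of magnitude in RRA
score, with log2FC ≈ 1 (the renormalized 3× shift of a 0.26-frequency
outcome) against a background of ≈ 0.2.

A command-line wrapper over the same functions is installed at
`inst/scripts/repairmap.R` with `simulate`, `classify`, `kinetics`,
`screen` and `cluster` subcommands; `runPipeline()` chains the screen
stages end to end and writes provenance-stamped TSVs plus a JSON-lines run
log.

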