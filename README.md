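# mbcsig

Integrative multi-omic analysis of human memory B cell subsets.

Human class-switched memory B cells (swMBC, CD27⁺IgG⁺ or CD27⁺IgA⁺) differ
from naive B cells (NBC, CD27⁻IgD⁺) in a way that is shared across antibody
classes: a *core transcriptional signature* of genes differentially
expressed in **both** IgG-vs-NBC and IgA-vs-NBC contrasts that **cancels**
in the IgG-vs-IgA contrast, accompanied by a heavier somatic-mutation load
in rearranged IgH V genes, a remodeled chromatin landscape, downregulation
of the MIR181 microRNA family with de-repression ("release") of its target
genes, and a distinctive lncRNA profile including a MIR181 sponge. `mbcsig`
implements that whole analysis chain as a tested R package, for
computational immunologists who want to run, probe or extend it — on their
own count matrices or on the package's synthetic data with planted ground
truth.

## What is implemented

* **Differential expression** — TMM scaling factors and an exact
  conditional negative-binomial test. Counts are modeled as NB with
  variance μ + φμ², per-feature dispersions are estimated by method of
  moments and shrunk 50% toward a matrix-wide common value, and the
  p-value is the exact probability, under equal group means and given the
  two-group total *t*, of a group-B sum at least as improbable as the one
  observed (group sums being NB with size n<sub>g</sub>/φ). As φ → 0 this
  is the exact conditional binomial test. BH FDR throughout.
* **Signature extraction** — `core_signature()`: feature ∈ signature iff
  p<sub>adj</sub> < threshold with the same sign in both vs-NBC contrasts
  *and* p ≥ 0.05 in the isotype contrast (cancellation); IgH
  constant-region features are set aside by class. Plus PCA embedding with
  silhouette and 95% prediction ellipses, and row-standardized heatmap
  matrices.
* **Ig repertoire** — germline V/D/J assignment, usage profiles and
  Spearman conservation, CDR3 length statistics, and the error-corrected
  somatic-hypermutation frequency: corrected = max(raw − 0.008, 0)
  change/base, with silent/replacement × FR/CDR breakdown.
* **ATAC integration** — peak-set Venn comparison, differential
  accessibility (raw p < 0.05 screen), DE↔DAR concordance within a gene
  ± 10 kb window, and motif-displacement (MD) scores.
* **ncRNA screens** — canonical seed-site scanning (6mer / 7mer-A1 /
  7mer-m8 / 8mer), nearest-neighbor duplex ΔG, the miRNA target-release
  rule (site + inverse Spearman correlation), lncRNA cis/trans
  co-expression, and the sponge screen.
* **Synthetic data** — `generate_expression()`, `generate_repertoire()`,
  `generate_atac()`, `generate_annotation()` produce every input with
  planted truth mirroring the emulated study design (4 subsets × 3
  subjects; 17-up/7-down core signature; 6-up/13-down miRNA profile with
  MIR181a/b analogues carrying the real MIR181-5p seed; 43.6/11.9/44.5%
  peak Venn; 35.4% DE↔DAR concordance; per-subset SHM rates with a 0.008
  error floor).

`run_pipeline(pipeline_config())` chains everything end to end and writes
TSV/BED/FASTA outputs with an md5 manifest; identical seeds give identical
hashes. See the methods vignette (`vignettes/mbcsig-methods.Rmd`) for the
models, defaults and known limitations.

## Worked example

```r
library(mbcsig)

# synthetic study: 4 B cell subsets x 3 subjects, planted 17-up/7-down core
cfg  <- generator_config(seed = 1)
plan <- signature_plan(cfg)
expr <- generate_expression(cfg, plan)
cm   <- filter_expressed(expr$counts, 1, unit = "RPKM")

de_igg <- nb_exact_test(cm, "NBC", "IgG")
de_iga <- nb_exact_test(cm, "NBC", "IgA")
de_iso <- nb_exact_test(cm, "IgA", "IgG")

# intersection + cancellation at an attainable threshold
sig <- core_signature(de_igg, de_iga, de_iso, p_adj_core = 1e-3)
print(sig)
#> signature_set: 113 up, 32 down (1 excluded by class) at p_adj < 0.001, cancellation at 0.05
head(sig$table[, c("feature", "direction", "p_a", "p_b", "p_cancel")], 3)
#>   feature direction          p_a          p_b p_cancel
#> 1  G00001        up 2.095858e-08 8.040744e-07        1
#> 2  G00002        up 2.301283e-09 2.075270e-05        1
#> 3  G00004        up 1.392206e-07 6.635153e-07        1

# repertoire: error-corrected SHM frequency of the IgA+ subset
rp  <- repertoire_plan()
sim <- generate_repertoire(rp, 10000, "IgA", seed = 1)
mf  <- mutation_frequency(assign_vdj(sim$reads, rp$db))
c(raw = mf$raw_freq, corrected = mf$corrected_freq)
#>       raw corrected
#> 0.0647466 0.0567466
```

The signature at `p_adj < 1e-3` is the planted core (both vs-NBC contrasts
significant, isotype contrast null — `p_cancel` ≈ 1) together with the
broader planted DE layer; the one class-excluded feature is an IgH
constant-region analogue that passes both screens but is reported
separately. The corrected mutation frequency recovers the planted IgA⁺
per-base rate (0.0566) after subtracting the 0.008 sequencing/polymerase
error floor from the raw mismatch rate.

Note on thresholds: at the synthetic scale (triplicates, NB dispersion
0.1) the attainable significance of an exact NB test is bounded far above
the study-grade `1e-29` screen, so the default stringent threshold returns
an empty signature on synthetic data; the vignette quantifies this.

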