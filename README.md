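# ribobind

Analysis pipeline for characterizing the RNA-binding activity of an
RRM-domain protein across three experimental readouts: **RIP-Seq
enrichment calling**, **microscale thermophoresis (MST) binding-curve
analysis**, and **docked-pose ensemble surface mapping** — plus seeded
synthetic-data generators so every stage runs and is testable without any
external data.

## Who this is for

Groups combining transcriptome-wide protein–RNA interaction screens
(RNA immunoprecipitation sequencing against a non-specific antibody
control) with in-vitro affinity measurements (MST on a labeled RNA
titrated with protein) and structural docking models (rigid RNA poses on a
receptor domain), who need the three bespoke computational steps in
between reproducible and tested:

1. which transcripts are *enriched*, how reproducibly, and whether binding
   looks co- or post-transcriptional;
2. what the *dissociation constants* are per MST readout, and when a
   readout must be reported as **n.d.** (not determined);
3. which *receptor residues* the retained docking poses implicate, after
   removing geometrically non-physiological poses.

## The models in brief

**RIP-Seq.** Expression per transcript is FPKM = `count * 1e9 /
(length_nt * total_mapped_fragments)`. A transcript is positive in a
replicate when FPKM(RIP) > FPKM(control); *stringent* when the
pseudocounted fold change `(FPKM_RIP + 0.1)/(FPKM_ctrl + 0.1)` exceeds 2
in ≥ 2 replicates. Intron-overlapping read counts classify binding as
co-transcriptional (any intronic read) vs post-transcriptional (none).
RIP-qPCR validation uses ΔΔCt: fold enrichment `2^(−ΔΔCt)` =
`2^(Ct_control − Ct_specific)` and percent input
`100 * 2^((Ct_input − log2(1/f)) − Ct_specific)` for input fraction `f`.

**MST.** Each capillary trace (cold 5 s / IR-on 30 s / off 5 s) is
normalized to its cold-window mean; three readouts are extracted — T-jump
(value 1.25 s after laser-on), thermophoresis (mean of the last 1 s of the
on-window), back diffusion (value 2.5 s after laser-off) — and each is fit
against the titrated protein concentration `L` with the 1:1 mass-action
isotherm with ligand depletion:

    FB(L) = ((T + L + Kd) − sqrt((T + L + Kd)² − 4·T·L)) / (2·T)
    y(L)  = f_free + (f_bound − f_free) · FB(L)

Series showing aggregation-like instability at high concentration
(top-quartile roughness > 5× bottom-quartile, or residual blow-up) are
flagged irregular and the size-sensitive thermophoresis Kd is reported
**n.d.**, while the early T-jump still fits.

**Docking surface.** Poses are dropped if any receptor atom lies within
5 Å of a terminal nucleotide (end-binding artifact) or any RNA atom lies
within 2.5 Å of a partner subunit of a reference complex (clash). Over
retained poses, a receptor residue is in contact when any of its atoms is
< 5 Å from any RNA atom; the per-residue contact frequency maps the
RNA-binding surface.

## Worked example

```r
library(ribobind)

## 1. RIP-Seq: 500 transcripts, 3 replicates, 10% planted 4-fold binders
sim <- gen_rip_counts(seed = 1)
rec <- call_enrichment(sim$rip_samples, sim$ctrl_samples, sim$models)
sum(rec$stringent)                      # 56  (50 planted binders + 6 FP)
replicate_overlap(rec)
#>     1     2     3   1&2   1&3   2&3 1&2&3
#>    62    48    58    51    68    50    99
qpcr_fold_enrichment(27, 30)            # 8   (2^(30-27))

## 2. MST: clean binder vs aggregating series
s <- gen_mst_series(0.87e-6, rna_id = "SNHG8", seed = 1)
kd_table(list(lapply(c("tjump", "thermophoresis", "backdiffusion"),
                     function(r) fit_isotherm(s, r))))
#>     rna kd_tjump_uM kd_thermophoresis_uM kd_backdiffusion_uM
#>   SNHG8        0.95                 0.88                1.17

agg <- gen_mst_series(0.21e-6, aggregation_mode = TRUE,
                      rna_id = "SETD1A_mRNA", seed = 1)
kd_table(list(lapply(c("tjump", "thermophoresis", "backdiffusion"),
                     function(r) fit_isotherm(agg, r))))
#>           rna kd_tjump_uM kd_thermophoresis_uM kd_backdiffusion_uM
#>   SETD1A_mRNA        0.21                 n.d.                0.25

## 3. Docking: 70 poses, planted terminal/clash violations and a hotspot
g <- gen_pose_ensemble(hotspot_bias = 3, seed = 1)
cfm <- contact_frequency(g$ensemble)
cfm
#> Contact-frequency map: 35/70 poses retained
#>   (terminal: 21, clash: 14, both: 0 dropped)
#> Top residues:
#>  residue_index residue_name contact_count  frequency
#>             51          LEU             5 0.14285714
#>             64          ASP             5 0.14285714
#>             40          VAL             4 0.11428571
```

Reading the output: the enrichment stage recovers all 50 planted binders
(sensitivity 1.0 at this seed) at a ~1% false-positive rate; the Venn
cells are disjoint counts of transcripts positive in exactly that
replicate subset. The Kd table reproduces the three-readout layout with
`n.d.` where the irregularity screen suppressed the thermophoresis fit;
the fitted T-jump Kd (0.95 µM for a 0.87 µM truth; 0.21 µM for a 0.21 µM
truth) is a single-seed draw — acceptance uses 20-seed medians. The filter
report shows 35 of 70 poses retained and why each dropped pose fell.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ribobind.R", package = "ribobind"))')
Rscript $CLI mst-sim  --kd 8.7e-7 --seed 1 --out traces/
Rscript $CLI mst-fit  --series traces/ --readout all --out fits/
Rscript $CLI sim-rip  --n 500 --seed 1 --out ripdir/
Rscript $CLI rip-enrich --counts ripdir/counts.tsv --models ripdir/models.tsv \
            --pseudocount 0.1 --out ripout/
Rscript $CLI sim-poses --n 70 --seed 1 --out posedir/
Rscript $CLI dock-surface --receptor posedir/receptor.pdb --poses posedir/poses \
            --reference posedir/reference.pdb --out dockout/
```

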