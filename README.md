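# thgratio

Noise-corrected basal-cell-cytoplasm to collagen-fiber THG brightness
ratiometry for two-channel harmonic generation microscopy (HGM) of human
skin.

## The problem

Melanin dominates third-harmonic generation (THG) contrast in human skin:
in pigmented skin the melanin packed into basal keratinocyte cytoplasm
outshines every other THG source. To know how bright keratinocyte cytoplasm
is *without* melanin — the intrinsic baseline against which repigmentation
can be detected — one images vitiligo lesions, where melanocytes are
absent, and compares the THG brightness of basal-cell cytoplasm with that
of dermal collagen fibers at the dermal–epidermal junction (DEJ), using the
collagen (an SHG-bright, melanin-independent structure) as an internal
reference. A low intrinsic ratio means even small melanin deposits produce
a large relative THG change, which is what makes HGM useful for grading
early, subclinical repigmentation during phototherapy.

For a subimage at the DEJ the quantity of interest is the noise-corrected
brightness ratio

```
        THG_cytoplasm − noise
  R  =  ─────────────────────
        THG_collagen  − noise
```

where `THG_cytoplasm` and `THG_collagen` are mean THG grayscale values over
segmented basal-cell cytoplasm and collagen fiber masks, and `noise` is the
mean THG level of uniformly dark (photomultiplier-noise-only) regions,
estimated outside the analysis ROI at a deep subimage. The correction makes
`R` invariant to detector gain and offset. A stack's ratio is the mean over
its qualified subimages; a cohort is summarised as mean ± SEM over stacks.

The package implements the five-phase measurement protocol around this
ratio:

1. **Previewing** — reject stacks that are motion-blurred, show THG-bright
   melanin pieces among basal cells, or whose provisional ratio exceeds the
   phototype-I value of 1.6 (melanin suspected).
2. **ROI selection** — keep only pixels with SNR ≳ 10: a rectangular ROI is
   the bounding box of the largest connected component above a 1600
   grayscale threshold (≈ 10.7 × the ~150 noise floor); Otsu thresholding
   is available as an alternative.
3. **Screening** — a DEJ subimage qualifies if SHG > 1600 covers strictly
   more than 25% of the ROI, fiber orientation is clear
   (structure-tensor coherence), and at least 10 basal cells are
   distinguishable; a stack needs three qualified subimages.
4. **Processing** — collagen segmented from SHG (threshold + ridge filter),
   cytoplasm/nuclei from THG (Otsu + distance-transform watershed), with
   declarative manual exclusions; then the ratio above.
5. **Inspecting** — stacks with ratio > 1.6 are excluded as
   melanin-containing; the cohort mean ± SEM is reported.

Because the underlying patient stacks are not public, the package ships a
seeded synthetic skin-stack generator (`generate_stack()`, presets via
`skin_preset()`) that emulates the assumed image structure — DEJ cell
mosaic with THG-dark nuclei, oriented SHG-bright fiber tubes with weaker
co-registered THG, edge vignetting, a ~150-grayscale noise floor, optional
melanin caps, depth attenuation — with voxel-level ground truth, so the
whole pipeline is testable end to end. The seven-point Physician Global
Assessment (PGA) score table used in vitiligo phototherapy trials is
included (`pga_table()`, `pga_score()`).

## Worked example

```r
library(thgratio)

## three synthetic vitiligo (melanin-free) stacks through the five phases
inputs <- list(lesion_a = skin_preset("paper_cohort", seed = 1),
               lesion_b = skin_preset("paper_cohort", seed = 2),
               lesion_c = skin_preset("paper_cohort", seed = 3))
res <- run_pipeline(run_config(inputs))
print(res)
#> cohort: 3 stacks included, ratio 1.097 +/- 0.005 (mean +/- SEM)

res$qc[1:5, c("stack_id", "depth_index", "coverage", "coherence",
              "cell_count", "qualified", "ratio")]
#>   stack_id depth_index  coverage coherence cell_count qualified    ratio
#> 1 lesion_a          40 0.4086938 0.5348257         78      TRUE 1.098108
#> 2 lesion_a          41 0.4086938 0.5357582         81      TRUE 1.098360
#> 3 lesion_a          42 0.4086938 0.5348852         81      TRUE 1.099654
#> 4 lesion_a          43 0.4086938 0.5358514         81      TRUE 1.097348
#> 5 lesion_a          44 0.4086938 0.5351076         79      TRUE 1.098272

## the generator's configured truth for comparison
generate_stack(skin_preset("paper_cohort", seed = 1))$truth$true_ratio
#> [1] 1.106

pga_score("Perifollicular repigmentation with confluence <10% of the lesion")
#> [1] 2
```

Each `qc` row is one screened DEJ subimage: the SHG coverage fraction of
the ROI, the fiber orientation coherence, the segmented basal-cell count,
whether the subimage qualified, and its noise-corrected ratio. The cohort
mean (1.097) recovers the generator's configured intrinsic ratio
(1809 − 150)/(1650 − 150) = 1.106 to within the segmentation bias of a few
parts per thousand.

File-based workflows and a shell entry point are available:
`write_stack()`/`read_stack()` for TIFF stacks, and
`inst/cli/thg-ratio.R` with `simulate`, `run` and `pga` subcommands.

## Acceptance script

`scripts/acceptance.R` regenerates everything from scratch with the
installed package: it builds 14 melanin-free cohort stacks
(256×256×96, seeds derived from `--seed`), runs the full five-phase
pipeline to obtain the cohort mean ratio, then builds 10 default-preset
stacks and averages the deep-frame noise estimates. Run it from the
repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/thg-ratio-protocol.Rmd` documents the model and its
assumptions, every tunable threshold with its default and rationale, what
the synthetic generator does and does not emulate, and the numerical
design choices.
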