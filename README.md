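# capscreen

Simulation and quantification toolkit for automated in vivo compound screens
that use zebrafish **CaP (caudal primary) motor-axon growth beyond the
horizontal myoseptum (HM)** as a read-out of neuromuscular-synapse
stabilisation.

## The assay

In zebrafish embryos at 28–30 hpf, the CaP motor axon grows ventrally, pauses
at the horizontal myoseptum where it forms *en passant* synapses with muscle
pioneer cells, and then grows on. In *chondrolectin* (*chodl*) mutants these
synapses do not mature and most axons stall at the HM, which makes axon length
a fast, quantifiable proxy for synapse stability. A plate-based screen scores,
for each compound, how many of the eight scoreable axons (somites 7–14, one
side) have grown beyond the HM, and normalises that to the DMSO-treated mutant
internal control:

```
RI = (crossed / scored)_treated  /  (crossed / scored)_control
```

A compound is a first-stage **hit** when RI ≥ 2.5 — the value reached when,
say, 5 of 8 treated axons cross versus 2 of 8 in controls. Second-stage
analysis measures total axon length (percent of control), and synapse
morphology is quantified as pre-/postsynaptic puncta count, area and labelling
intensity in a 400 µm² ROI at the HM, with the pre/post overlap taken as the
synaptic area. Group comparisons are normality-gated (Shapiro–Wilk): one-way
ANOVA with Dunnett's or Tukey's test when all groups look normal, otherwise
Kruskal–Wallis with Dunn's test (t-test / Mann–Whitney U for two groups), with
post-hoc power at the observed effect size.

The package has five parts:

| module | exported surface |
|---|---|
| synthetic embryos | `generate_embryo()`, `simulate_cohort()`, `generate_screen()`, `list_presets()`, `render_embryo()`, `write_embryo()` |
| axon phenotyping | `trace_axon()`, `axon_length()`, `classify_hm()`, `count_branches()`, `quantify_axons()`, `score_abnormal()` |
| synapse puncta | `extract_roi()`, `subtract_background()`, `binarize()`, `quantify_puncta()`, `overlap_stats()`, `measure_embryo()` |
| screen statistics | `exclude_toxic()`, `rescue_index()`, `call_hits()`, `percent_of_control()`, `compare_groups()`, `posthoc_power()` |
| formats & pipeline | `read_manifest()`, `run_config()`, `run_pipeline()`, CLI in `inst/exec/capscreen` |

The synthetic-embryo generator renders lateral-view trunk images (channel 1 =
motor-neuron reporter, channels 2–3 = pre-/postsynaptic labels) together with
a complete ground-truth sidecar (true lengths, crossings, branches, puncta,
toxicity state), so every quantification stage can be validated against known
truth. Presets encode the study conditions — the *chodl* control (mean stalled
axon length 35.06 µm, 2/8 axons crossing), validated hits (dipyridamole, IOX1,
MG132 at their reported percent-of-control ratios), the wild-type control, and
the UBEI-41 (UBA1-inhibition) SMA model with its abnormal-axon rates.

## Worked example

```r
library(capscreen)
geom <- embryo_geometry()

# one synthetic chodl-mutant control embryo, fully reproducible from the seed
e <- generate_embryo("chodl-DMSO", seed = 7)
quantify_axons(e$image, geom)
#>   axon_id exit_col present length_um hm_status branch_count
#> 1       1       40    TRUE  48.79899   stalled            0
#> 2       2       80    TRUE  30.55635   stalled            0
#> 3       3      120    TRUE  27.65685   stalled            0
#> ...
#> 8       8      320    TRUE  48.65685   crossed            0
```

Seven of eight axons are stalled at the myoseptum — the mutant phenotype. The
worked rescue-index example:

```r
treated <- data.frame(n_scored = 8, n_crossed = 5)
control <- data.frame(n_scored = 8, n_crossed = 2)
rescue_index(treated, control)
#> [1] 2.5
call_hits(data.frame(rescue_index = 2.5))$hit
#> [1] TRUE
```

Synapse morphology of the same embryo (averaged over 5 hemisegment ROIs; the
enlarged presynaptic area and reduced number of discernible puncta are the
mutant synapse phenotype):

```r
measure_embryo(e$image, geom)
#> synapse_measurement over 5 hemisegments
#>   pre      count  2.00  area   87.80 um^2  intensity 0.4159
#>   post     count  3.40  area   52.00 um^2  intensity 0.1948
#>   overlap  count  3.00  area   48.60 um^2  intensity 0.4969
```

Normality-gated group comparison with observed power:

```r
set.seed(1)
compare_groups(list(DMSO = rnorm(20, 35, 7), dipyridamole = rnorm(20, 47, 9)))
#> stat_report: Student t-test (gate: parametric)
#>   omnibus statistic 4.6889 p = 3.492e-05
#>   observed power 0.9954
```

A whole screen, end to end:

```r
cfg <- run_config(seed = 1, n_compounds = 20, n_active = 2, outdir = "run1")
bundle <- run_pipeline(cfg)   # manifest.csv, screen_results.csv, summary.json
bundle$report
```

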