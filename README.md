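# pactrace

Simulation and inference of headful packaging of bacterial DNA by
temperate *pac*-type phages.

## The problem

Some temperate phages package far more of their host's chromosome than
classical generalized transduction predicts, and they package it from one
specific place: the flank of their own attachment site.  The mechanism is
lateral-transduction-like: during productive replication a phage genome
occasionally recombines into the chromosome at *attB*, the integrated copy
supplies a *pac* site, and the terminase — which packages fixed-length
"headfuls" slightly larger than one genome — walks out of the prophage,
across the *attL* junction, and processively into one side of the host
chromosome.  In virion sequencing this leaves a characteristic fingerprint:

* a host-read fraction concentrated over several hundred kb on **one side**
  of *attB*, decaying geometrically with distance;
* **hybrid attP/B reads** (host sequence on one side of the shared 17-bp
  core, phage on the other), all from the same junction;
* a coverage **wave** whose period is the headful size
  `H = L_p (1 + r)` — for a 65,149-bp phage with terminal redundancy
  `r = 0.10`, `H = 71,664` bp, so waves spaced ~72 kb;
* a flat ~1X background of packaged host DNA everywhere else.

`pactrace` is for researchers who want to simulate this mechanism with
known truth, validate the inference chain, and run the same inference on
their own (simulated or real, FASTQ/SAM) virion sequencing data.  It
provides:

* **genome model** — build host/phage/lysogen coordinate frames around a
  shared att core (`randomGenome`, `plantAttCore`, `buildLysogen`,
  `exciseProphage`, `lysogenToSource`);
* **simulator** — pac-initiated processive headful packaging with
  initiation jitter, geometric series lengths (mean `m`), att
  integration, episomal circular permutation, uniform background, and
  paired-end reads with per-read truth (`simulateExperiment`,
  `moleculesToReads`);
* **classifier** — exact 31-mer seed mapping against both frames with
  hybrid-junction calling (`kmerIndex`, `classifyReads`,
  `summarizeClasses`), or external SAM alignments
  (`readSamAlignments`);
* **inference** — binned coverage, background, near-att fraction, flank
  extent, wave period by detrended autocorrelation (`-> H`, `-> r`),
  headful-window decay (`-> m`), pac position, exact binomial
  directionality (`analyzePackaging` and the underlying estimators);
* **statistics** — Wilson proportion intervals, uncorrected 2x2
  chi-square with the `< 2.2e-16` reporting convention, exact two-sided
  binomial test, condition comparison (`proportionWithCI`, `chisq2x2`,
  `binomTestTwoSided`, `compareConditions`).

A thin CLI with `simulate` / `analyze` / `compare` subcommands is
installed at `inst/cli/pactrace`.

## Worked example

Simulate an induction-style experiment in which every series initiates
from an integrated copy, then run the full inference chain:

```r
library(pactrace)

cfg <- defaultRunConfig("induction", n_series = 3000L, f_int = 1,
                        bg_rate = 0, pairs_per_kb = 0.2, seed = 11L)
sim <- runSimulate(cfg, "demo/sim")          # refs, FASTQ pair, truth, config
res <- runAnalyze(sim$paths$host, sim$paths$phage, sim$paths$att,
                  sim$paths$fastq1, sim$paths$fastq2,
                  outDir = "demo/analysis", config = cfg)
res$estimates
```

```
PackagingEstimates
  host fraction:      0.8152
  near-att fraction:  0.992 (208112 / 209823)
  wave period T:      70625 bp
  headful H:          70625 bp
  redundancy r:       0.084
  processivity m:     2.95
  pac position:       24500 bp (peak 42500)
  direction:          left (left 222 / right 0, p = 2.97e-67)
  flank extent:       827000 bp
  background depth:   0.850 X
```

Reading the numbers: the simulation used `r = 0.10` (`H = 71,664`),
`m = 3`, pac at 23,500 and packaging toward *attL* — the detected wave
period estimates the headful within ~1.5%, the window-decay estimator
recovers the mean series length, the pac onset lands within a kilobase of
truth, all 222 hybrid reads sit on the left junction (exact binomial
`p = 3e-67`), and the enriched flank extends ~0.8 Mb on that side only.
With `f_int = 1` most packaged DNA is host (host fraction 0.82); the
calibrated condition presets (`defaultRunConfig("induction")` /
`"infection"`) instead put the host fraction at the percent level.
`runCompare(reportA, reportB, outDir)` then contrasts two conditions
(fraction ratio, Wilson intervals, chi-square).

The methods vignette (`vignettes/headful-packaging.Rmd`) documents the
generative model, the calibration of the condition presets, every
estimator's assumptions and the design decisions behind them.

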