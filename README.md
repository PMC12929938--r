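# poreDelay

Classification of delayed nanopore translocation events for DNA-barcoded
probe assays.

## The problem

A DNA-barcoded probe passing through a nanopore produces a transient
ionic-current event (recorded at 5 kHz, clipped to 200–700 pA). If the
probe has bound its target miRNA, the probe–target duplex stalls while it
unzips in the pore, leaving a contiguous **low-variability current
plateau** in the final quarter of the event (fractional position ≥ 0.7).
Events with the plateau are **delayed** — the target is present; events
without it are **non-delayed**. The fraction of delayed events per sample
rises with target concentration along a Hill curve, making the pore a
quantitative, label-free miRNA sensor.

poreDelay is for researchers building or analyzing such assays. It
implements the full analysis chain:

* **MSD rule** — min–max normalize the trace, split into 75 bins, call a
  delay when more than 10 consecutive bins beyond fractional position 0.7
  have standard deviation below σ = 0.003 (`classifyMsd`);
* **Spectral-entropy rule** — per-frame normalized Shannon entropy of the
  spectrogram power distribution,
  SE(t) = −Σₘ P(t,m) log₂ P(t,m) / log₂ N ∈ [0,1]; a delay is any frame
  beyond 0.7 dropping below SE = 0.495 (`classifySe`);
* **Convolutional classifier** — traces rendered as 56×56 grayscale line
  images; a LeNet-style network (conv 16 → pool → conv 32 → pool → FC 64 →
  FC 2) trained with Adam and early stopping; Grad-CAM saliency maps
  (`cnnTrain`, `cnnPredict`, `gradCam`);
* **Barcode read filter** — Smith–Waterman local alignment (+5/−4/−8) to
  the 38-nt reference barcode with four pass rules (`localAlign`,
  `filterReads`);
* **Evaluation and quantification** — accuracy/precision/recall/F1/MCC/AUC,
  min–max radar scaling, 3×MAD outlier gate, per-replicate baseline
  correction, and unweighted Hill fits
  response(C) = V·C^n/(K^n + C^n) with EC50 = K (`computeMetrics`,
  `fitHill`, `runDoseResponse`);
* **Synthetic signal simulator** — seeded generators for delayed,
  non-delayed and "noisy-delay" contaminant events, concentration cohorts
  and barcode reads (`generateEvent`, `generateDataset`,
  `generateDoseResponse`, `generateReads`), standing in for raw data that
  are not publicly deposited.

A thin command-line wrapper with verbs `simulate`, `classify`, `align`,
`benchmark` and `dose` ships in `inst/scripts/poredelay`.

## Worked example

```r
library(poreDelay)
cfg <- simConfig()                      # 5 kHz, 200-700 pA band, defaults
ev <- generateEvent(cfg, "delayed", seed = 7)
ev
#> EventTrace delayed_7 : 2990 samples @ 5000 Hz, label = delayed
#>   current range [200.0, 700.0] pA

classifyMsd(ev)
#>    event_id method   label        score delay_start_frac run_length
#> 1 delayed_7    msd delayed 0.0001313151        0.7090301         14
```

The event's quiet plateau starts at fractional position 0.709 and spans 14
consecutive bins whose normalized sd (score 0.00013) sits far below the
0.003 threshold, so the MSD rule calls it delayed. The SE rule agrees — its
minimum regional entropy, 0.135, is well under 0.495:

```r
classifySe(ev)[, c("label", "score", "delay_start_frac")]
#>     label    score delay_start_frac
#> 1 delayed 0.135444         0.727592
```

Read filtering and dose–response quantification:

```r
g <- generateReads(200, errorRate = 0.02, seed = 1)
res <- filterReads(g$reads)
#> read filter: 184/200 passed (92.0%)

out <- runDoseResponse(cohortSpec(nEventsPerConc = 100), cfg,
                       method = "msd", seed = 3)
out$fit
#> HillFit: nh = 2.680, Ke = 1.129 nM, Vmax = 38.63%, R^2 = 0.9924
```

At 2% per-base error most reads still carry an intact GGG-anchored barcode
(92% pass). The fitted EC50 of 1.13 nM and Vmax of 38.6% recover the
cohort's generating curve (Ke = 1.19 nM, Vmax = 36.59%) to within the
binomial sampling noise of 100 events per concentration cell.

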