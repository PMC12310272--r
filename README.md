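# netLTP

Network-level quantification of long-term potentiation (LTP) from evoked
field-potential recordings on high-density CMOS microelectrode arrays
(64 x 64 electrodes, 42 um pitch, 14 kHz per electrode).

Classical LTP experiments track the initial slope of the field EPSP
(fEPSP) at a single site: after calibrating the stimulus to the intensity
that evokes 60% of the maximal slope, test pulses at 0.033 Hz establish a
baseline, a single 100 Hz / 1 s high-frequency train (HFS) induces
potentiation, and LTP is called when post-tetanic responses exceed
baseline by at least 40%,

&nbsp;&nbsp;&nbsp;&nbsp;*LTP iff* mean over the evaluation window of
100 x slope(t) / slope_baseline >= 140%.

On a full-grid array the same experiment becomes a mapping problem across
the hippocampal laminae (CA strata SO/SP/SR/SLM, dentate ML/GCL/hilus).
netLTP provides, as a tested R package:

- a **synthetic session generator** (full protocol, layer-structured
  evoked EPSP / population-spike waveforms, distance-ordered latencies,
  layer-specific potentiation, silent-electrode recruitment, seeded
  noise) with complete ground truth — the deposited substitute for raw
  recordings that are not publicly available;
- **preprocessing**: zero-phase 4th-order Butterworth band-pass
  (1-500 Hz) as second-order sections, artifact blanking, stimulus-
  aligned epochs, baseline correction;
- **LTP quantification**: fEPSP slopes, input/output-curve calibration,
  normalized potentiation time courses, the inclusive >= 40% criterion,
  phase-integrated plasticity percent per layer, voltage-variation maps,
  Kolmogorov-Smirnov group contrasts;
- **waveform classification**: PCA + k-means over evoked waveform shapes
  (k = 4 for CA, 3 for DG), scored as the mean diagonal probability of
  the cluster-vs-layer confusion matrix;
- **temporal clustering**: peak latencies grouped into
  initial/central/terminal clusters (Ward linkage with local boundary
  refinement), per-cluster latency-change and recruitment-fold
  statistics;
- **kernel current source density (kCSD)**: 2-D kernel estimation with
  a thickness-integrated homogeneous forward model, cross-validated
  ridge regularization, sink/source counting and integration, and an
  interpolated-potential comparison baseline.

See the methods vignette (`vignettes/network-ltp-methods.Rmd`) for the
models, assumptions, parameter defaults and numerical choices.

## Worked example

Simulate one default dentate-gyrus session and analyze it end to end:

```r
library(netLTP)
session <- simulateSession("DG", seed = 42,
                           phases = c("baseline", "post_tetanic"))
res <- analyzeSession(session, classifySeed = 42)

round(100 * res$accuracyBaseline, 1)
#> [1] 100
res$plasticity
#>   layer plasticityPct   n
#> 1   GCL        157.03 138
#> 2     H        122.34 221
#> 3    ML         35.49 301
round(res$latency$changePct, 2)
#>  initial  central terminal
#>    -7.27    -4.74    10.92
round(res$latency$recruitmentFold, 2)
#>  initial  central terminal
#>      1.8      1.7      1.9
res$detect
#>   layer meanPct   ltp onsetMin
#> 1   GCL   261.4  TRUE        1
#> 2     H   225.9  TRUE        2
#> 3    ML   136.5 FALSE       20
```

Reading the output: baseline evoked waveforms classify into the three DG
laminae with a mean diagonal probability of 1.0; the recovered
phase-integrated plasticity (157.0% in GCL, 122.3% in the hilus, 35.5%
in ML) matches the generator's injected layer gains (157/122/35); peak
latencies shorten by ~7.3% and ~4.7% in the initial and central clusters
and lengthen by ~10.9% in the terminal cluster (injected: -7.3/-4.8/
+10.8); active-electrode counts grow 1.8/1.7/1.9-fold (exactly the
injected recruitment); and the LTP criterion fires in GCL and hilus but
not in ML, whose sustained gain sits below the 40% threshold.

`runPipeline()` wraps the same stages (plus kCSD maps) for both networks
into a JSON report with figures, and `saveSession()`/`loadSession()`
persist sessions in a documented on-disk container
(`inst/schema/container.md`). A thin command-line wrapper lives at
`inst/scripts/netltp.R`.

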