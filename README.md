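# intervalKinetics

Measures how long a DNA-binding protein stays bound in a living cell from
single-molecule fluorescence movies — even when the bound lifetime is a
hundred times longer than the photobleaching lifetime of its fluorescent
tag. It implements the interval-imaging (time-lapse) analysis used to
measure DNA-binding lifetimes of fluorescent-protein fusions of bacterial
DNA-repair factors such as the transcription-repair coupling factor Mfd:
spot detection with a discoidal average filter, consecutive-frame linking
of foci into binding events, cumulative residence time distributions
(CRTDs) per dark-interval condition, and a global photobleaching-corrected
exponential-mixture fit with bootstrap uncertainties. A synthetic-data
generator emulates the whole two-phase acquisition, so the pipeline is
fully testable without raw microscope data.

## The model

A focus disappears when the molecule dissociates (rate `k_off`, in real
time) or its fluorophore bleaches (rate `k_b`, only while illuminated).
With exposures `τ_int` separated by dark intervals `τ_d` (frame period
`τ_tl = τ_int + τ_d`), the apparent loss rate of mixture component *i* in
condition *c* is

    k_eff(i,c) = k_b · τ_int / τ_tl(c) + k_off(i)

and the CRTD of condition *c* is fitted by

    S_c(t) = s_c · Σ_i A_i · exp(−k_eff(i,c) · t),

with `k_b`, `k_off(i)` and the fractions `A_i` shared across all
conditions and one free scale `s_c` per condition. Varying `τ_d` from 0
(continuous imaging) to 9.9 s changes the weight of `k_b` by two orders of
magnitude, which is what makes the two rates separable; equivalently
`k_eff·τ_tl` is linear in `τ_tl` with slope `k_off` and intercept
`k_b·τ_int` (`linearizedRates()`). Uncertainties follow the standard
convention: ten refits on random 80% subsamples of the events, reported as
mean ± SD of the bootstrap distribution.

## Worked example

Simulate a protein with a 29-s bound lifetime under the full 11-condition
protocol (0.1-s exposures, dark intervals 0–9.9 s, bleaching lifetime 1 s
of illuminated exposure), then fit:

```r
library(intervalKinetics)

protocol <- acquisitionProtocol()          # the 11-condition schedule
truth <- kineticModel(lifetimes = 29, kb = 1)

dwells <- do.call(rbind, lapply(seq_along(tauD(protocol)), function(ci) {
  dur <- sampleDwellTimes(truth, 2000, seed = 10 + ci)
  ev <- simulateObservedFrames(dur, truth, protocol, ci, seed = 20 + ci)
  data.frame(condition_id = ci, n_frames = ev$observed_n_frames,
             censored = ev$censored)
}))

fit <- bootstrapFit(dwells, protocol, modelOrder = 1, seed = 30)
fit
#> GlobalFitResult: 1-exponential global fit over 11 condition(s)
#>   single: lifetime 29.88 s (koff 0.03346 /s), amplitude 1.000
#>   shared kb 1.02 per illuminated s; RSS 6.104 over 591 points; converged
#>   bootstrap: 10 replicate(s); see bootstrapSummary()

bootstrapSummary(fit)
#>        parameter       mean           sd  n
#> 1             kb  1.0205008 0.0062675184 10
#> 2  lifetime_slow 29.8426352 0.4031818622 10
#> 3      koff_slow  0.0335146 0.0004516043 10
#> 4 amplitude_slow  1.0000000 0.0000000000 10
```

The fit recovers the 29-s truth (29.8 ± 0.4 s) and the 1 s⁻¹ bleaching
rate from ~22,000 simulated events. At a translocation rate of 4
nucleotides per second, a 29-s residence corresponds to an expected
scanning distance of

```r
expectedScanningDistance(4, 29)
#> [1] 116
```

nucleotides along the DNA.

Starting from movies instead of dwell tables:

```r
fix <- makeFixtureDataset("demo", truth, protocol, 500, mode = "movies")
movie <- readMovie(fix$conditionPaths[1])
foci <- detectStack(movie)                       # flatten + filter + threshold 8
events <- linkFoci(foci, radiusPx = 3)           # consecutive-frame linking
dwells1 <- extractDwells(events, protocol, 1)
```

`runPipeline("config.yaml")` orchestrates all stages with one seed and
writes every intermediate table; `inst/scripts/interval-pipeline.R`
exposes the same stages as `simulate` / `detect` / `track` / `fit` /
`report` subcommands.

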