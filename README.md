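# needlecav

Quantification of cavitation activity around spring-loaded core needle
biopsy ("biopsy gun") devices from co-registered high-speed shadowgraphy
video and hydrophone recordings.

When a spring-loaded biopsy needle fires, the tip accelerates violently,
stops abruptly, and oscillates laterally at several metres per second.
In water and soft tissue-mimicking hydrogels this motion can nucleate
transient cavitation bubble clouds in the wake of the tip — mechanically
aggressive events that matter both for device safety assessment and for
potential imaging applications. `needlecav` implements the complete
measurement chain used to characterize this phenomenon:

- **Projected bubble area** (`bubble_area_series`): each video frame is
  binarized (Otsu or fixed threshold, dark = silhouette); the bubble area
  is the number of dark pixels in excess of the needle-at-rest count,
  scaled by the pixel pitch: `A = max(0, N_dark − N_rest) · p²`, with
  `p = 25 µm/px` for the reference optics. Replicate recordings are pooled
  pointwise as mean ± sample SD (`aggregate_replicates`).
- **Needle-tip kinematics** (`detect_features`, `track_klt`,
  `kinematics`): minimum-eigenvalue (Shi–Tomasi) corner detection seeds a
  pyramidal Kanade–Lucas–Tomasi tracker; sub-pixel displacement is
  differentiated once for velocity, twice for acceleration.
- **Calibrated acoustics** (`spl_spectrogram`, `detect_bursts`,
  `detect_tone_ridges`): short-time Fourier spectrograms of the hydrophone
  pressure trace on the underwater SPL scale,
  `SPL = 20·log₁₀(p_rms / 1 µPa)`, calibrated so a pure tone's peak bin
  reads its true band SPL; broadband bursts and persistent 10–30 kHz
  ringing tones are extracted automatically.
- **Hydrodynamic characterization** (`cavitation_number`,
  `reynolds_number`, `flow_regime`): the cavitation number
  `Ca = (p − p_v)/(½ρu²)` and Reynolds number `Re = uLρ/μ` at the measured
  peak lateral tip velocity, with wake-regime classification
  (laminar < 49 ≤ vortex transition ≤ 190 < turbulent).
- **Ground-truthed synthetic recordings** (`generate_video`,
  `generate_audio`, `write_fixture_bundle`): a simulator that emulates the
  experiment — dark needle silhouette (side-cut or front-cut geometry)
  with programmable firing motion, elliptical bubble clouds with
  analytically known projected areas, and pressure traces with prescribed
  bursts and ringing tones — so every stage is testable without the
  original recordings.

## Worked example

A full synthetic side-cut firing in water — 650 frames of 288×384 px at
100 000 frames/s covering the far-end stop, with a co-registered 0.06 s
hydrophone trace:

```r
library(needlecav)

scene  <- side_cut_demo_scene(seed = 1)
gen    <- generate_video(scene)
audio  <- generate_audio(side_cut_demo_audio(seed = 1))
rec    <- experiment_record(gen$video, audio,
                            needle_type = "side_cut", medium = "water")
report <- run_pipeline(rec)
print(report)
#> needlecav report: side_cut needle in water
#>   max area       3.299 mm2 at t = 0.02541 s (duration 3.14 ms)
#>   peak |vy|      7.97 m/s (stop at t = 0.02538 s)
#>   peak SPL       122.8 dB re 1 uPa at 15 kHz
#>   bursts         3; tone ridges: 1
#>   Ca = 3.122, Re = 16778 (turbulent)
```

Reading the numbers: the bubble cloud peaks at 3.299 mm² just after the
stop (the generator's analytic ground truth is 3.298 mm², i.e. the
estimator is accurate to ~0.05 %); the tracked stylet tip reaches
7.97 m/s laterally, above the ~7 m/s level at which cavitation onset is
observed; the acoustic stream shows the three-burst side-cut firing
signature plus a persistent 15 kHz structural ringing tone; and the shaft
flow at that tip speed has Re ≈ 16 800, well inside the turbulent regime.
With a threshold of 0.05 mm² the cavitation episode lasts 0.83 ms:

```r
summarize_area(report$areas, area_threshold = 0.05)
#> Max area 3.299 mm2 at t = 0.02541 s; duration above 0.05 mm2: 0.83 ms
```

`write_report(report, "out/")` writes the flat CSV series and a JSON
summary. A command-line front end over the same functions is installed at
`inst/cli/needlecav.R`
(`simulate | quantify | track | acoustics | hydro | report`).

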