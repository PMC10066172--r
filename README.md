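# coolspot

Analysis of **heated-arena center-finding trials** — the "dry" analogue of
the Morris water maze used with insects. An animal explores an enclosure
whose floor is aversively heated everywhere except an inconspicuous cool
refuge spot (⌀ 60 mm, 25 °C) at the geometric center; with no visual,
olfactory or thermal-gradient cues available, finding the spot faster over
repeated trials indicates learning of the enclosure layout. Four enclosure
shapes of approximately equal area (709 cm² ± 3%) are supported: circle
(⌀ 30 cm), square (edge 27 cm), equilateral triangle (edge 40 cm) and an
asymmetric quadrilateral (edges 37/24/23/26 cm, angles 67/80/100/113°).

The package is for behavioural researchers working with this paradigm (or
similar open-field / place-learning setups) who need a tested, scriptable
pipeline from raw tracking tables to learning statistics and strategy
classification.

## What it computes

* **Arena geometry** — canonical arenas from printed dimensions (cm frame,
  cool spot at the origin), areas, centroids, point containment and the
  minimum Cartesian distance to the perimeter; landmark-based
  least-squares similarity calibration of pixel coordinates.
* **Trial metrics** — on-spot bouts with gap bridging, successful stays
  (≥ 5 s), latency to first arrival (censored at trial end), time-on-spot
  proportion, path length, rest time, wall-following (thigmotaxis) time,
  and pooled occupancy heatmaps.
* **Learning slopes** — per-trial change of √(time-on-spot proportion) and
  of log(latency + 1), estimated by per-animal OLS aggregated across
  animals with t and bootstrap 95% CIs:
  slope = mean(βᵢ), se = sd(βᵢ)/√n.
* **Strategy clustering** — each approach path (the 3 s preceding a
  successful stay) becomes a min–max-scaled wall-distance series d(t);
  pairwise dynamic time warping
  DTW(a,b) = min over monotone warping paths of Σ |aᵢ − bⱼ|
  (symmetric1/symmetric2 step patterns, optional Sakoe–Chiba band) feeds
  k-medoids (PAM, BUILD + SWAP) with silhouette-based selection of k = 4,
  medoid extraction, and cluster × arena-shape contingency tables.
* **Elementary tests** — exact/approximate Mann–Whitney U, Bonferroni
  adjustment, 2×2 chi-square.
* **Synthetic data** — an arena-constrained generator that emulates the
  four observed approach strategies (wall-following then direct; inward
  spiral; arch-like ventures; center-out-and-return) and across-trial
  learning with known ground truth, so every stage is testable.

## Worked example

```r
library(coolspot)

arena <- build_arena("circle")
sprintf("area: %.2f cm^2, spot radius: %.1f cm",
        arena_area(arena), arena$spot_radius)

sess <- file.path(tempdir(), "demo")
cfg  <- session_config(shape = "circle", n_animals = 5, n_trials = 6,
                       seed = 42)
run_simulate(cfg, sess)
an <- run_analyze(sess, file.path(sess, "report"))
cl <- run_cluster(sess, file.path(sess, "report"))
cl$scan
```

Output:

```
area: 706.86 cm^2, spot radius: 3.0 cm
simulated 30 trials (circle, 5 animals, condition heated)
analyzed 30 trials (0 censored latencies)
sqrt-proportion slope: +0.0200 per trial (95% CI 0.0158 to 0.0243)
log-latency slope:     -0.1905 per trial (95% CI -0.2047 to -0.1763)
clustered 31 approach paths at k = 4 (mean silhouette 0.800)
  k silhouette_mean total_cost
1 2       0.5333838  138.31293
2 3       0.7264226   68.64618
3 4       0.8002703   40.08626
4 5       0.6513032   37.30063
5 6       0.6394301   35.15377
6 7       0.6375708   32.92311
7 8       0.3104381   30.85339
```

Reading this: the session was generated with a positive learning trend on
the transformed scales, and the two-stage estimator recovers a positive
√proportion slope (more time on the spot per trial) and a negative
log-latency slope (faster arrivals per trial), each with its 95% CI. The
silhouette scan peaks at k = 4, the number of planted strategy archetypes.
`run_analyze()`/`run_cluster()` also write `metrics.csv`, `slopes.json`,
per-shape occupancy grids, `clusters.csv`, `medoids.csv` and
`validity.json`, with the resolved configuration, into the report
directory.

Recordings of real sessions are ingested with `read_tracking_table()`
(canonical 12-column tracker dialect with landmark columns, or a minimal
pre-calibrated `time_s,x_cm,y_cm` form) and flow through the same
`run_analyze()`/`run_cluster()` calls.

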