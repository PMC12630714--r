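# urbiso — urban isolation and the geography of political violence

`urbiso` is an R package for studying how politically motivated violence
relates to **city size** and **geographical isolation**.  It is aimed at
spatial epidemiologists and conflict researchers who work with
event-level violence records (date, location, category, fatalities), a
city table (coordinates, population), and a highway network, and who want
reproducible answers to two questions:

1. Does violence scale sub- or super-linearly with city population?
2. Do isolated, poorly connected cities suffer more casualties per capita
   than central, well-connected ones?

## The statistics at its core

* **Urban scaling.** For a per-city violence measure $V_i$ the power law
  $V_i = \alpha P_i^\beta$ is fitted by OLS of $\log_{10} V$ on
  $\log_{10} P$ over cities with $V_i > 0$.  $\beta < 1$ (sublinear) means
  small cities carry more violence per capita.
* **Isolation classes.** The degree $D_j$ of a city is its number of
  highway edges: high isolation $D_j \le 2$, medium $3 \le D_j \le 5$,
  low $D_j \ge 6$.
* **Gravity-flow centrality** (a flow-weighted betweenness): every city
  pair exchanges a flow $F_{o,d} = P_o P_d / N_{o,d}^{\gamma}$
  ($\gamma = 2.8$; $N_{o,d}$ = fastest-route travel time, +2 h per border
  crossing), routed along the fastest path;
  $C_j = \sum_{\{o,d\}} F_{o,d} H_{o,d}(j)$ accumulates the flow of routes
  passing through $j$.
* **Event assignment.** Event $i$ is attached to its nearest city $j$ when
  the great-circle distance $d_{ij} < \delta$ (swept 1–30 km); farther
  events are rural.
* **Lethality.** $\phi_\delta(j)$ = assigned casualties per 100,000
  inhabitants (per year); group lethality pools casualties over pooled
  population.  The isolation impact $\theta_\delta$ is the high/low-
  isolation lethality ratio; the centrality impact $\theta^c_\delta$
  compares bottom vs top centrality quartiles.  A half-event subsampling
  procedure (1000 replicates) checks that $\theta > 1$ is not carried by a
  few extreme events.

A synthetic-world generator (`generate_city_system()`,
`generate_events()`) produces city systems, networks and event streams
with planted $\beta$ and planted isolation multipliers, so the whole
pipeline is validated by recovering known ground truth.

## Worked example

```r
library(urbiso)

cfg <- synthetic_config(n_cities = 300, target_casualties = 20000,
                        beta_true = 1, isolation_multiplier = 5.4,
                        seed = 11)
run <- run_pipeline(run_config(synthetic = cfg, deltas = c(10, 20),
                               reps = 200, seed = 11,
                               out_dir = file.path(tempdir(), "demo")))
res <- attr(run, "results")
res$scaling[, c("measure", "delta_km", "beta", "beta_se", "n_cities_used")]
res$impacts
```

Output of this exact script (seed 11):

```
         measure delta_km      beta    beta_se n_cities_used
1 casualties_all       10 0.8413821 0.04213077           299
2 casualties_vac       10 0.7819614 0.04844626           285
3 casualties_all       20 0.8413821 0.04213077           299
4 casualties_vac       20 0.7819614 0.04844626           285
  delta_km theta_isolation theta_centrality        measure
1       10        4.963617         3.585894 casualties_all
2       20        4.963617         3.585894 casualties_all
```

Reading it: `theta_isolation` recovers the planted multiplier of 5.4
within counting noise — people in high-isolation cities face about five
times the casualty rate of low-isolation cities.  The fitted exponents
sit *below* the planted per-capita-neutral `beta_true = 1`: the extra
violence planted in isolated cities lands disproportionately in small
cities (isolated cities are small), which by itself induces apparent
sublinear scaling — exactly the interplay between city size and isolation
the package is built to dissect.  The two thresholds coincide here
because, with a 15 km minimum city spacing and 2 km coordinate jitter,
every urban event is already captured at 10 km.  The run directory
additionally contains
`city_violence.csv`, `metrics.csv`, `subsamples.csv` (the 200 half-event
$\theta$ replicates), `truth.json` (the planted parameters) and
`report.md` with the planted-vs-recovered comparison.

Real data drop in through the same interfaces: `read_cities()`,
`read_network()`, `read_events()` (native CSV/GeoJSON schemas plus an
`"acled"` export dialect), then
`run_pipeline(run_config(paths = list(...)))`.

## Package layout

* `R/data_model.R` — readers/writers/validators for cities, networks,
  events
* `R/synthetic_data.R` — the planted-truth world generator
* `R/network_metrics.R` + `src/dijkstra.cpp` — degrees, isolation classes,
  fastest paths, gravity-flow centrality (compiled Dijkstra with a
  deterministic tie rule)
* `R/event_assignment.R` — haversine nearest-city assignment and per-city
  aggregation
* `R/scaling_analysis.R` — scaling fits, dragon-king and subsample
  robustness, start-year truncation
* `R/lethality_analysis.R` — lethality rates, impact ratios, half-event
  subsampling, $\delta$ sweeps
* `R/cli_report.R` — `run_pipeline()`, fixtures, reporting;
  `inst/cli/urbiso` is a command-line wrapper
* `vignettes/urban-isolation-violence.Rmd` — the methods vignette
  (model, assumptions, parameter choices, limitations)
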