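# hospflow

Hospital processes — an emergency trauma room above all — depend on a
tangle of devices, staff, rooms and transport routes. A ransomware attack
that takes the CT scanner offline, a security patch that slows every
scan, or a mass-casualty surge that overruns the trauma team all turn
into the same measurable thing: longer per-patient treatment and, past a
threshold, patients who take irreversible damage or need resuscitation
before they can be treated. `hospflow` is a hybrid discrete-event /
agent-based simulator for quantifying exactly that, aimed at hospital
risk managers, business-continuity planners and health-systems
researchers.

## The model in brief

* **Process**: a BPMN 2.0 graph (start, tasks, exclusive/parallel
  gateways, end). Each task `A` binds to an area `A_r`, a duration `D`
  (minutes, per-injury-group overridable) and resource demands `R`.
  Redundant branches are chosen at run time by estimated time to
  completion.
* **Hospital**: areas with a transit-time matrix and per-area
  inventories. Portable resources above an area's minimum stock can be
  lent across areas, paying the transit time; attachable devices (e.g. a
  mobile ventilator) stay with the patient until detached. Quarantined
  areas freeze everything inside; merely blocked areas can still lend.
* **Patients**: agents of injury groups `G` defined by exact 9-region AIS
  signatures, with priority, arrival time `T_start` and optional
  deadlines. TTD (time till damage) elapsing flags the patient damaged —
  the process has failed for them, but they continue. TTR (time to
  reanimation) elapsing removes the patient and releases all resources.
  Therapy tasks extend both clocks by configured deltas at completion.
* **Disruptions**: time-scheduled modifiers — device outages, efficiency
  changes (duration scales as `nominal × 100 / eff`), transit changes,
  deactivation, quarantine — with half-open effectivity; in-flight
  activities finish under old parameters.
* **Indicators**: per-group baseline = one patient alone through the
  unmodified process; per-patient delay = actual − baseline duration;
  plus damaged/removed counts and mean % duration increase.

Given identical configuration the engine is fully deterministic: same
scenario, same byte-identical event log.

## Worked example

The package ships a fully synthetic trauma-room fixture: 26 tasks over
five areas (ambulance bay, ETR, CT, OR, ICU), a standard trauma-team
roster, one stationary CT scanner, and six injury groups. The
mass-casualty scenario sends twelve patients (two per group) in two
batches, minutes [3, 15] and [39, 89]:

```r
library(hospflow)

fx  <- build_etr_fixture(seed = 1)
mci <- fx$scenarios$mci
res <- simulate_scenario(mci)
summary(res)
#> patients: 12  completed: 12  damaged: 5  removed: 0  mean duration: 267.7 min

base <- compute_baseline(mci)
round(base, 1)
#>    g1    g2    g3    g4    g5    g6
#> 115.3 112.3 109.2  87.1  87.1  87.1
```

Alone, a patient of group g1 takes 115.3 min; under the surge the
average treatment takes 267.7 min (mean delay 168.1 min, worst 291.4
min) and five patients cross their time-till-damage deadline — the
overload in one line.

Sweeping a CT-scanner outage of rising duration over the
regular-operations scenario (same twelve patients, arriving hours apart)
reproduces the canonical degradation curve — no measurable effect while
the outage is shorter than the time to the first scan, then monotone
growth:

```r
run_outage_sweep(fx$scenarios$regular, "ct_scanner", c(0, 60, 120, 180, 240))
#> <hf_sweep> kind=outage on ct_scanner
#>  grid_value mean_pct_increase mean_delay_min max_delay_min ...
#>           0               0.0            0.0           0.0
#>          60               0.0            0.0           0.0
#>         120               4.5            4.5          53.7
#>         180               9.5            9.5         113.7
#>         240              16.7           16.6         175.0
```

`run_efficiency_sweep()` does the same for a scanner slowed by a security
measure (100/80/60/40% efficiency), and
`run_emergency_plan_comparison()` evaluates mass-casualty emergency
plans: boosting all trauma-room resources helps until the single CT
scanner saturates (utilization → 1), after which only a second scanner
buys further improvement.

A command-line wrapper is installed with the package:

```sh
Rscript inst/cli/hospflow simulate --fixture etr --seed 1 --out out/
Rscript inst/cli/hospflow sweep --kind outage --grid 0,60,120 --out out/
```

writing `events.jsonl`, `patients.csv`, `summary.csv` and `sweep.csv`.
Scenarios round-trip through `save_scenario()` / `load_scenario()`
(BPMN + YAML + CSV).

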