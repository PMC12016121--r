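---
title: "Simulating hospital patient flow under disruption: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating hospital patient flow under disruption: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hospflow)
```

## The model

`hospflow` simulates clinical processes — the bundled example is an
emergency trauma room (ETR) — as a hybrid of discrete-event simulation
(DES) and agent-based simulation (ABS). The *process* is a directed graph
read from a BPMN 2.0 subset: one start event, one end event, tasks in
between, exclusive gateways that branch conditionally on the patient's
injury group, parallel gateways for concurrent blocks, and exclusive
splits that may be marked *redundant*, in which case the branch is chosen
at run time by estimated time to completion rather than by label. Each
task binds to an area, a default duration in minutes, a list of resource
demands, optional per-group duration overrides and optional therapy
deltas.

The *hospital* is a set of areas connected by a directed transit-time
matrix, with per-area inventories of resource instances. Resource types
are devices (stationary or portable, portable ones optionally
*attachable*, staying with the patient across tasks) or staff grouped by
skill class (always portable). An area will lend idle portable instances
to another area as long as its stock stays at or above a configured
minimum; dispatched instances travel for the inter-area transit time
before the receiving task can start, and return home as soon as the task
(or attachment) that needed them ends. A *blocked* (deactivated) area
cannot host task execution but can still lend; a *quarantined* area
freezes everything inside it.

*Patients* are agents: each belongs to an injury group defined by an
exact region-wise Abbreviated Injury Scale (AIS) signature (9 regions,
severities 0–6) and carries an arrival time, a priority and two optional
deadlines. Time till damage (TTD) marks irreversible harm: when it
elapses the patient is flagged *damaged* but continues through the
process. Time to reanimation (TTR) marks the need for cardio-pulmonary
resuscitation: when it elapses the patient is removed from the process
and every held or attached resource is released. Deadline clocks run in
wall time from arrival — waiting, transport and treatment all count — and
are extended only by explicit therapy deltas credited when a task
completes (stopping a bleed extends both clocks; an x-ray extends
neither).

*Disruptions* are time-scheduled modifiers: device outages, efficiency
changes, transit-time changes, area deactivation and quarantine.
Efficiency acts multiplicatively on duration (`nominal × 100 / eff`); a
task's effective duration is gated by the *minimum* efficiency across the
resource types it demands, the reading under which a slowed CT scanner
slows the scan no matter how fast the staff are. Modifier effectivity is
half-open `[t, next change)`: activities already in flight finish under
the parameters they started with, which avoids retroactive rescaling and
keeps the event order well-defined.

## The engine and its determinism contract

The core is a continuous-time event queue with a strictly monotone
sequence number as tie-breaker. All state changes — arrivals, allocation
grants, dispatches, task starts/ends, transports, returns, deadline hits,
modifier applications — are events; the engine draws no random numbers,
so two runs of the same scenario produce byte-identical serialized event
logs. All randomness lives in cohort generation, which is a pure function
of `(groups, counts, windows, seed)` through an isolated RNG stream.

Allocation is non-preemptive: a granted instance finishes its task even
if a higher-priority patient arrives, matching the atomicity of clinical
actions. Waiting requests are scanned in `(priority desc, arrival asc,
patient id)` order whenever capacity is freed; local idle instances are
taken first, shortfalls are filled from the lender with the smallest
transit time (ties broken lexicographically by area id). With one
resource type and equal priorities this reduces to FIFO, which the test
suite asserts.

For redundant splits the estimator sums, along each alternative branch,
the effective task durations plus inbound transit plus a congestion term
per demanded type: the backlog minutes currently running or queued on
that type in the task's area divided by the number of in-service
instances there (infinite if none). Ties fall to the first-declared
branch. This is one concrete reading of "estimated time until completion"
and is deliberately a small, replaceable function.

Two semantics were genuinely open and are resolved as follows. First,
fine-grained (sub-interval) resource holds are granted together with all
other demands at task start — deterministic gating — and released at
`start + offset + length`, so the benefit of the fine-grained mode is
early release rather than late acquisition. Second, after a parallel
block the patient's location is the end area of the latest-finishing
branch (ties: first-declared); the closed-form path-duration oracle uses
the same rule, and the equivalence of the two is checked over randomly
generated processes rather than assumed.

## Performance indicators

Before a scenario run, the *baseline* is computed per injury group by
simulating a derived scenario with all modifiers stripped and a single
patient of that group arriving alone at minute zero — treatment duration
under optimal conditions. Per patient, *delay* is actual duration minus
the group baseline; the run summary reports mean and maximum delay over
completing patients, the mean actual duration, and the damaged and
removed counts. The sweep tables report the mean percentage duration
increase as `100 × (mean actual − mean baseline) / mean baseline` over
completing patients; removed patients are excluded from the mean but
counted. Baselines deliberately strip *all* modifiers, including
beneficial ones: the reference is the unperturbed process.

`resource_utilization()` measures a type's busy minutes divided by
instance count times the type's own service window (first start to last
end), so a single scanner serving back-to-back reads 1 regardless of how
long the whole run is.

## The synthetic fixture and what it does not show

The real 26-task trauma-room parameterization and the registry-derived
per-group durations behind the original study are not public, so the
bundled fixture is synthetic and labelled as such. It follows the
canonical three-phase trauma narrative — stabilization (airway,
intubation with an attached ventilator, circulation, bleeding control),
a second survey with line therapy running in parallel to x-ray and
ultrasound imaging, then catheter, image analysis and CT — ending in the
operating room for the three most severe groups and the intensive care
unit for the rest: 26 tasks across five areas (ambulance bay, ETR, CT,
OR, ICU). Staffing follows the standard trauma-team roster (trauma
leader, junior surgeon, anesthetist, two surgical nurses, one anesthetic
nurse, radiographer) extended by a radiologist; OR and ICU keep their own
nurses. The CT scan occupies the stationary scanner itself, with the
console work not tied to the bore — this keeps the single scanner the
binding constraint in overload, which is the premise of the
emergency-plan comparison, and lets a second scanner genuinely run in
parallel.

Every task duration is drawn once, uniformly from a documented per-task
range (e.g. CT scan 10–14 min, initial surgery 8–15 min), and frozen by
the fixture seed; the two most severe groups carry 30% / 15% longer
bleeding-control and surgery durations. Deadline ranges are synthetic and
deliberately wide — TTD 120–360 min, TTR 360–720 min — because realistic
per-group deadline data was left open by the source material; the wide
TTR keeps removals from dominating the demonstration scenarios while the
TTD still produces damage counts under load.

Three named scenarios define the study conditions. The *MCI* surge sends
twelve patients, two per group, in two batches: six arriving in minutes
[3, 15] and six in [39, 89]. The *regular* scenario sends the same twelve
patients one at a time roughly four hours apart — a steady severe-trauma
inflow a single trauma room absorbs without queueing, so the unmodified
run reproduces the baseline exactly and the outage/efficiency sweeps
start from a clean 0% identity point. The synthetic registry cohort
(`synthetic_trdgu_cohort()`) emulates per-action timestamps (arrival ≤
x-ray ≤ CT ≤ surgery) with uniform jitter around per-group means, and
`aggregate_action_durations()` recovers those means — the
duration-estimation path one would run on real registry data.

Passing tests on this fixture demonstrate the mechanics — conservation,
lending discipline, deadline semantics, monotone disruption response,
scanner saturation — not numeric agreement with any real trauma room.
Absolute durations, slopes and percentages depend entirely on the
synthetic parameterization and will differ from clinical reality.

## Numerical choices and problem sizes

Durations are continuous minutes in double precision; the oracle tests
use dyadic durations (multiples of ¼ min) so closed-form sums are exact,
and the engine/oracle equivalence is asserted to 1e-9. Monotonicity
assertions use a 1e-9 slack for accumulated floating-point noise. The
scenario save format writes doubles as `%.17g`, so a saved and reloaded
scenario reproduces the original event log byte for byte.

The shipped analyses use 12-patient cohorts, a 9-point outage grid
(0–240 min in 30-min steps), the 4-point efficiency grid {100, 80, 60,
40}% and a 9-point boost grid (0–200% in 25% steps) with one and two CT
scanners — sizes chosen so a full sweep suite runs in well under two
minutes on a single core while still exhibiting the saturation and
monotonicity structure of interest. Sweeps re-run the full simulation per
grid point rather than reusing warm state, preserving the determinism
contract.

## Known limitations

Consumable stock depletion, staff shifts and fatigue, stochastic task
durations, preemption of running tasks, and survival modelling beyond
reanimation removal are out of scope. Branch-condition labels and the
redundant-branch estimator are single concrete readings of informally
specified behaviour. The fixture's numbers are synthetic throughout;
only qualitative shapes (monotone degradation, overload delay, scanner
saturation) are claimed.
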