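# Synthetic fixtures: a minimal process for unit tests and a full
# emergency-trauma-room (ETR) bundle emulating a real trauma pathway. The
# real 26-task parameterization and registry-derived durations are not
# public; every number here is synthetic, drawn once from documented
# uniform ranges and frozen by the seed.

#' Minimal test fixture
#'
#' One area, two sequential tasks, one portable and one stationary
#' resource type, one injury group. Small integer durations so expected
#' values are computable by hand.
#'
#' @return List with `graph`, `hospital`, `groups`.
#' @export
build_minimal_fixture <- function() {
  graph <- process_graph(
    tasks = list(
      task_node("T1", area_id = "A", duration_min = 5,
                demands = list(resource_demand("nurse"))),
      task_node("T2", area_id = "A", duration_min = 3,
                demands = list(resource_demand("scanner")))),
    edges = data.frame(from = c("start", "T1", "T2"),
                       to = c("T1", "T2", "end")),
    start_id = "start", end_id = "end")
  hosp <- hf_hospital(
    areas = list(hf_area("A")),
    transit = matrix(0, 1, 1, dimnames = list("A", "A")),
    resource_types = list(
      hf_resource_type("nurse", "staff", "portable", skill_class = "nursing"),
      hf_resource_type("scanner", "device", "stationary")),
    inventory = data.frame(type_id = c("nurse", "scanner"),
                           area_id = "A", count = 1L))
  groups <- list(injury_group("g1", ais_profile(c(1, 0, 0, 1, 0, 0, 0, 0, 0))))
  list(graph = graph, hospital = hosp, groups = groups)
}

# Task table of the synthetic ETR process: id, area, duration range (min),
# demands, deadline deltas. Three phases (stabilization; second survey
# with imaging; catheter + CT) then an OR-or-ICU conditional split.
hf_etr_task_table <- function() {
  D <- function(type, n = 1, action = "use") list(type_id = type, count = n, action = action)
  list(
    list(id = "T01_handover",        area = "AMB", lo = 2,  hi = 4,  dem = list()),
    list(id = "T02_team_briefing",   area = "ETR", lo = 2,  hi = 4,  dem = list(D("trauma_leader"), D("surgical_nurse"))),
    list(id = "T03_airway_check",    area = "ETR", lo = 1,  hi = 3,  dem = list(D("trauma_leader"), D("anesthetist"))),
    list(id = "T04_intubation",      area = "ETR", lo = 3,  hi = 6,  dem = list(D("anesthetist"), D("anesthetic_nurse"), D("ventilator", action = "attach"))),
    list(id = "T05_breathing_check", area = "ETR", lo = 1,  hi = 3,  dem = list(D("trauma_leader"))),
    list(id = "T06_circulation",     area = "ETR", lo = 1,  hi = 3,  dem = list(D("junior_surgeon"), D("monitor"))),
    list(id = "T07_stop_bleeding",   area = "ETR", lo = 4,  hi = 8,  dem = list(D("trauma_leader"), D("surgical_nurse")), ttd = 30, ttr = 30),
    list(id = "T08_survey_review",   area = "ETR", lo = 1,  hi = 3,  dem = list(D("trauma_leader"))),
    # parallel block: line therapy vs imaging
    list(id = "T09_iv_access",       area = "ETR", lo = 3,  hi = 6,  dem = list(D("anesthetic_nurse"), D("infusion_pump"))),
    list(id = "T10_medication",      area = "ETR", lo = 2,  hi = 4,  dem = list(D("anesthetist")), ttr = 20),
    list(id = "T11_volume_therapy",  area = "ETR", lo = 3,  hi = 6,  dem = list(D("anesthetic_nurse")), ttd = 20),
    list(id = "T12_xray_thorax",     area = "ETR", lo = 3,  hi = 5,  dem = list(D("radiographer"), D("xray_machine"))),
    list(id = "T13_xray_pelvis",     area = "ETR", lo = 2,  hi = 4,  dem = list(D("radiographer"), D("xray_machine"))),
    list(id = "T14_ultrasound",      area = "ETR", lo = 3,  hi = 6,  dem = list(D("junior_surgeon"), D("ultrasound"))),
    list(id = "T15_second_review",   area = "ETR", lo = 2,  hi = 4,  dem = list(D("trauma_leader"))),
    list(id = "T16_catheter",        area = "ETR", lo = 2,  hi = 4,  dem = list(D("surgical_nurse"))),
    list(id = "T17_image_analysis",  area = "ETR", lo = 2,  hi = 5,  dem = list(D("radiologist"))),
    list(id = "T18_ct_transfer_prep", area = "ETR", lo = 1, hi = 3,  dem = list(D("surgical_nurse"))),
    # scan occupies the scanner; the radiographer runs the console and is
    # not tied to the bore, so a second scanner can genuinely run in parallel
    list(id = "T19_ct_scan",         area = "CT",  lo = 10, hi = 14, dem = list(D("ct_scanner"))),
    list(id = "T20_ct_analysis",     area = "CT",  lo = 3,  hi = 6,  dem = list(D("radiologist"))),
    # OR branch
    list(id = "T21_or_preparation",  area = "OR",  lo = 3,  hi = 6,  dem = list(D("surgical_nurse"))),
    list(id = "T22_anesthesia",      area = "OR",  lo = 3,  hi = 6,  dem = list(D("anesthetist"))),
    list(id = "T23_initial_surgery", area = "OR",  lo = 8,  hi = 15, dem = list(D("trauma_leader"), D("junior_surgeon"), D("surgical_nurse"), D("ventilator", action = "detach")), ttd = 60, ttr = 60),
    list(id = "T24_post_op",         area = "OR",  lo = 3,  hi = 6,  dem = list(D("anesthetic_nurse"))),
    # ICU branch
    list(id = "T25_icu_admission",   area = "ICU", lo = 2,  hi = 5,  dem = list(D("anesthetic_nurse"), D("ventilator", action = "detach"))),
    list(id = "T26_icu_stabilize",   area = "ICU", lo = 4,  hi = 8,  dem = list(D("anesthetic_nurse"), D("monitor")))
  )
}

#' Synthetic emergency-trauma-room fixture bundle
#'
#' A 26-task process across five areas — ambulance (AMB), Emergency
#' Trauma Room (ETR), Computed Tomography (CT), Operation Room (OR) and
#' Intensive Care Unit (ICU) — following the canonical three-phase trauma
#' pathway: stabilization (airway, breathing, circulation, bleeding
#' control), second survey with parallel line therapy and x-ray/ultrasound
#' imaging, then catheter, image analysis and CT scan, ending in the OR
#' (severe groups) or the ICU. Staff follow a standard trauma-team roster
#' (trauma leader, junior surgeon, anesthetist, two surgical and one
#' anesthetic nurse, radiographer); devices include a portable x-ray,
#' ultrasound, a single stationary CT scanner, monitors, attachable
#' ventilators and infusion pumps, and a defibrillator.
#'
#' All durations are synthetic: each task's duration is drawn once,
#' uniformly from a documented per-task range, and frozen by `seed`. Six
#' injury groups with distinct AIS signatures get synthetic TTD ranges of
#' 120-360 min and TTR ranges of 360-720 min; the two most severe groups
#' carry longer bleeding-control and surgery durations.
#'
#' @param seed Integer seed freezing the synthetic durations and deadline
#'   draws.
#' @return List with `graph`, `hospital`, `groups`, `seed` and
#'   `scenarios` (a named list holding the `mci` scenario built with the
#'   same seed).
#' @export
build_etr_fixture <- function(seed = 1L) {
  rng <- hf_rng(seed)
  tab <- hf_etr_task_table()
  tasks <- lapply(tab, function(r) {
    dur <- round(rng$unif(r$lo, r$hi), 1)
    gd <- list()
    if (r$id %in% c("T07_stop_bleeding", "T23_initial_surgery")) {
      gd <- list(g1 = round(dur * 1.3, 1), g2 = round(dur * 1.15, 1))
    }
    task_node(r$id, area_id = r$area, duration_min = dur,
              demands = lapply(r$dem, function(d) do.call(resource_demand, d)),
              group_durations = gd,
              ttd_delta_min = r$ttd %||% 0, ttr_delta_min = r$ttr %||% 0)
  })
  seq_edge <- function(from, to, label = NA_character_)
    data.frame(from = from, to = to, label = label, stringsAsFactors = FALSE)
  edges <- rbind(
    seq_edge("start", "T01_handover"),
    seq_edge("T01_handover", "T02_team_briefing"),
    seq_edge("T02_team_briefing", "T03_airway_check"),
    seq_edge("T03_airway_check", "T04_intubation"),
    seq_edge("T04_intubation", "T05_breathing_check"),
    seq_edge("T05_breathing_check", "T06_circulation"),
    seq_edge("T06_circulation", "T07_stop_bleeding"),
    seq_edge("T07_stop_bleeding", "T08_survey_review"),
    seq_edge("T08_survey_review", "P1_split"),
    seq_edge("P1_split", "T09_iv_access"),
    seq_edge("T09_iv_access", "T10_medication"),
    seq_edge("T10_medication", "T11_volume_therapy"),
    seq_edge("T11_volume_therapy", "P1_join"),
    seq_edge("P1_split", "T12_xray_thorax"),
    seq_edge("T12_xray_thorax", "T13_xray_pelvis"),
    seq_edge("T13_xray_pelvis", "T14_ultrasound"),
    seq_edge("T14_ultrasound", "P1_join"),
    seq_edge("P1_join", "T15_second_review"),
    seq_edge("T15_second_review", "T16_catheter"),
    seq_edge("T16_catheter", "T17_image_analysis"),
    seq_edge("T17_image_analysis", "T18_ct_transfer_prep"),
    seq_edge("T18_ct_transfer_prep", "T19_ct_scan"),
    seq_edge("T19_ct_scan", "T20_ct_analysis"),
    seq_edge("T20_ct_analysis", "X1_split"),
    seq_edge("X1_split", "T21_or_preparation", "g1, g2, g3"),
    seq_edge("T21_or_preparation", "T22_anesthesia"),
    seq_edge("T22_anesthesia", "T23_initial_surgery"),
    seq_edge("T23_initial_surgery", "T24_post_op"),
    seq_edge("T24_post_op", "X1_join"),
    seq_edge("X1_split", "T25_icu_admission", "g4, g5, g6"),
    seq_edge("T25_icu_admission", "T26_icu_stabilize"),
    seq_edge("T26_icu_stabilize", "X1_join"),
    seq_edge("X1_join", "end"))
  graph <- process_graph(
    tasks = tasks, edges = edges,
    gateways = c(P1_split = "parallel_split", P1_join = "parallel_join",
                 X1_split = "exclusive_split", X1_join = "exclusive_join"),
    start_id = "start", end_id = "end")

  areas <- list(
    hf_area("AMB", "Ambulance bay"),
    hf_area("ETR", "Emergency Trauma Room"),
    hf_area("CT", "Computed Tomography"),
    hf_area("OR", "Operation Room"),
    hf_area("ICU", "Intensive Care Unit",
            min_stock = list(ventilator = 1, monitor = 1)))
  # trauma room adjacent to CT and OR (short in-house corridors); the
  # ambulance bay and ICU are further out
  aid <- c("AMB", "ETR", "CT", "OR", "ICU")
  tm <- matrix(c(0, 2, 4, 5, 6,
                 2, 0, 2, 2, 4,
                 4, 2, 0, 3, 4,
                 5, 2, 3, 0, 3,
                 6, 4, 4, 3, 0),
               5, 5, byrow = TRUE, dimnames = list(aid, aid))
  rtypes <- list(
    hf_resource_type("trauma_leader", "staff", "portable", "trauma_surgery"),
    hf_resource_type("junior_surgeon", "staff", "portable", "surgery"),
    hf_resource_type("anesthetist", "staff", "portable", "anesthesia"),
    hf_resource_type("surgical_nurse", "staff", "portable", "nursing_surgical"),
    hf_resource_type("anesthetic_nurse", "staff", "portable", "nursing_anesthetic"),
    hf_resource_type("radiographer", "staff", "portable", "radiology"),
    hf_resource_type("radiologist", "staff", "portable", "radiology_md"),
    hf_resource_type("xray_machine", "device", "portable"),
    hf_resource_type("ultrasound", "device", "portable"),
    hf_resource_type("ct_scanner", "device", "stationary"),
    hf_resource_type("monitor", "device", "portable"),
    hf_resource_type("ventilator", "device", "portable", attachable = TRUE),
    hf_resource_type("infusion_pump", "device", "portable"),
    hf_resource_type("defibrillator", "device", "portable"))
  # ETR holds the trauma-team roster plus its devices; OR and ICU keep
  # their own nursing staff; ICU holds a lendable reserve of monitors and
  # ventilators above its minimum stock
  inventory <- data.frame(
    type_id = c("trauma_leader", "junior_surgeon", "anesthetist",
                "surgical_nurse", "anesthetic_nurse", "radiographer",
                "radiologist",
                "xray_machine", "ultrasound", "monitor", "ventilator",
                "infusion_pump", "defibrillator",
                "ct_scanner", "surgical_nurse",
                "anesthetic_nurse", "monitor", "ventilator"),
    area_id = c(rep("ETR", 13), "CT", "OR", "ICU", "ICU", "ICU"),
    count = c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 2L, 5L, 3L, 1L, 1L, 1L, 1L, 2L, 2L),
    stringsAsFactors = FALSE)
  hosp <- hf_hospital(areas, tm, rtypes, inventory)

  sigs <- list(
    g1 = c(4, 0, 0, 4, 3, 0, 0, 2, 0),   # severe head/thorax/abdomen
    g2 = c(3, 1, 0, 4, 0, 2, 0, 0, 0),
    g3 = c(0, 0, 0, 3, 3, 0, 2, 2, 0),
    g4 = c(2, 0, 1, 2, 0, 0, 0, 3, 0),
    g5 = c(1, 0, 0, 2, 2, 0, 1, 0, 1),
    g6 = c(1, 1, 0, 1, 0, 0, 2, 1, 0))
  prio <- c(g1 = 3L, g2 = 3L, g3 = 2L, g4 = 2L, g5 = 1L, g6 = 1L)
  groups <- lapply(names(sigs), function(g) {
    ttd <- sort(c(round(rng$unif(120, 240)), round(rng$unif(240, 360))))
    ttr <- sort(c(round(rng$unif(360, 540)), round(rng$unif(540, 720))))
    injury_group(g, ais_profile(sigs[[g]]), priority = prio[[g]],
                 ttd_range_min = ttd, ttr_range_min = ttr)
  })
  bundle <- list(graph = graph, hospital = hosp, groups = groups,
                 seed = as.integer(seed))
  bundle$scenarios <- list(mci = build_mci_scenario(bundle, seed),
                           regular = build_regular_scenario(bundle, seed))
  bundle
}

#' Regular-operations scenario on a fixture bundle
#'
#' Twelve patients, two per injury group, arriving one at a time roughly
#' four hours apart — the steady severe-trauma inflow of a single trauma
#' room under normal operations (a handful of majors per day), as opposed
#' to the two-batch mass-casualty surge. Patients do not overlap in the
#' unmodified run, so every one is treated at its baseline speed; this is
#' the cohort used for the device-outage and efficiency-loss sweeps, where
#' the question is how a disruption degrades an otherwise absorbable
#' patient stream.
#'
#' @param bundle Fixture bundle with six groups (see [build_etr_fixture()]).
#' @param seed Integer seed for arrival and deadline draws.
#' @return An [hf_scenario()].
#' @export
build_regular_scenario <- function(bundle, seed = 1L) {
  counts <- stats::setNames(rep(2L, length(bundle$groups)),
                            vapply(bundle$groups, function(g) g$id, ""))
  n <- sum(counts)
  windows <- lapply(seq_len(n), function(i) c(240 * (i - 1), 240 * (i - 1) + 30, 1))
  cohort <- generate_patients(bundle$groups, counts,
                              arrival_windows = windows, seed = seed)
  hf_scenario(bundle$graph, bundle$hospital, bundle$groups, cohort,
              modifiers = list(), seed = as.integer(seed),
              horizon_min = 240 * n + 2000)
}

#' Mass-casualty scenario on a fixture bundle
#'
#' Twelve patients, two per injury group, arriving in two batches of six:
#' the first between minute 3 and 15, the second between minute 39 and 89.
#'
#' @param bundle Fixture bundle with six groups (see [build_etr_fixture()]).
#' @param seed Integer seed for arrival and deadline draws.
#' @return An [hf_scenario()].
#' @export
build_mci_scenario <- function(bundle, seed = 1L) {
  if (length(bundle$groups) != 6L)
    hf_stop("InvalidScenario", "MCI scenario needs the six-group bundle")
  counts <- stats::setNames(rep(2L, 6), vapply(bundle$groups, function(g) g$id, ""))
  cohort <- generate_patients(bundle$groups, counts,
                              arrival_windows = list(c(3, 15, 6), c(39, 89, 6)),
                              seed = seed)
  hf_scenario(bundle$graph, bundle$hospital, bundle$groups, cohort,
              modifiers = list(), seed = as.integer(seed), horizon_min = 5000)
}

#' Synthetic trauma-registry-like cohort
#'
#' Emulates a registry of per-action timestamps inside the trauma room:
#' each record carries an AIS profile equal to one of the group signatures
#' plus monotone timestamps (arrival <= x-ray <= CT <= surgery/ICU
#' handoff) whose inter-action gaps are jittered uniformly around
#' per-group generating means. [aggregate_action_durations()] recovers
#' mean per-action durations per group, emulating the duration-estimation
#' path from registry data.
#'
#' @param n Number of records (>= 1).
#' @param groups List of [injury_group()] objects.
#' @param seed Integer seed.
#' @return Data frame with `record_id`, `group_id`, nine `ais_*` columns
#'   and `t_arrival_min`, `t_xray_min`, `t_ct_min`, `t_surgery_min`.
#' @export
synthetic_trdgu_cohort <- function(n, groups, seed = 1L) {
  if (n < 1) hf_stop("InvalidScenario", "n must be >= 1")
  rng <- hf_rng(seed)
  gid <- vapply(groups, function(g) g$id, "")
  rows <- lapply(seq_len(n), function(i) {
    k <- ((i - 1L) %% length(groups)) + 1L
    g <- groups[[k]]
    m <- hf_trdgu_means(k)
    arr <- rng$unif(0, 10000)
    d_x <- rng$unif(m["xray"] * 0.5, m["xray"] * 1.5)
    d_c <- rng$unif(m["ct"] * 0.5, m["ct"] * 1.5)
    d_s <- rng$unif(m["surgery"] * 0.5, m["surgery"] * 1.5)
    sig <- as.integer(g$ais_signature)
    c(list(record_id = sprintf("r%05d", i), group_id = g$id),
      stats::setNames(as.list(sig), paste0("ais_", tolower(names(g$ais_signature)))),
      list(t_arrival_min = arr, t_xray_min = arr + d_x,
           t_ct_min = arr + d_x + d_c, t_surgery_min = arr + d_x + d_c + d_s))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# Generating means (minutes) of the synthetic registry, per group index.
hf_trdgu_means <- function(k) {
  c(xray = 8 + k, ct = 12 + k, surgery = 30 + 2 * k)
}

#' Mean per-action durations per group from a registry-like cohort
#'
#' @param records Data frame from [synthetic_trdgu_cohort()].
#' @return Data frame: `group_id`, `action` (xray/ct/surgery), `mean_min`,
#'   `n`.
#' @export
aggregate_action_durations <- function(records) {
  durs <- data.frame(
    group_id = rep(records$group_id, 3),
    action = rep(c("xray", "ct", "surgery"), each = nrow(records)),
    dur = c(records$t_xray_min - records$t_arrival_min,
            records$t_ct_min - records$t_xray_min,
            records$t_surgery_min - records$t_ct_min))
  agg <- stats::aggregate(dur ~ group_id + action, data = durs,
                          FUN = function(x) c(mean = mean(x), n = length(x)))
  data.frame(group_id = agg$group_id, action = agg$action,
             mean_min = agg$dur[, "mean"], n = agg$dur[, "n"])
}
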