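#' Baseline treatment duration per injury group
#'
#' The "best pathway" reference: for each group in the cohort, a derived
#' scenario is simulated with all modifiers stripped and a single patient
#' of that group arriving alone at minute zero, so every resource is
#' directly accessible. The resulting completion time is the treatment
#' duration under optimal conditions.
#'
#' @param spec An [hf_scenario()].
#' @return Named numeric vector: group id -> baseline minutes.
#' @export
compute_baseline <- function(spec) {
  gids <- unique(spec$cohort$group_id)
  out <- stats::setNames(numeric(length(gids)), gids)
  for (g in gids) {
    g_rows <- spec$cohort[spec$cohort$group_id == g, , drop = FALSE]
    solo <- g_rows[1, , drop = FALSE]
    solo$patient_id <- "baseline"
    solo$t_start_min <- 0
    base_spec <- hf_scenario(spec$graph, spec$hospital, spec$groups,
                             cohort = solo, modifiers = list(),
                             seed = spec$seed, horizon_min = spec$horizon_min)
    res <- simulate_scenario(base_spec)
    if (!identical(res$patients$status, "completed"))
      hf_stop("InvalidScenario", "baseline patient of group %s did not complete", g)
    out[g] <- res$patients$duration_min
  }
  out
}

#' Delay and outcome indicators of a run
#'
#' Per patient, the delay is the actual treatment duration minus the
#' group's baseline duration; removed patients have no delay and are
#' counted separately. The summary reports the mean and maximum delay over
#' completing patients, the damaged and removed counts, and the mean
#' actual duration.
#'
#' @param result An `hf_result`.
#' @param baselines Named vector from [compute_baseline()].
#' @return List with `per_patient` (data frame) and the summary scalars
#'   `mean_delay_min`, `max_delay_min`, `mean_duration_min`, `damaged`,
#'   `removed`, `completed`, `mean_pct_increase`.
#' @export
compute_indicators <- function(result, baselines) {
  p <- result$patients
  missing <- setdiff(unique(p$group_id), names(baselines))
  if (length(missing))
    hf_stop("MissingBaseline", "no baseline for group(s): %s", paste(missing, collapse = ", "))
  p$baseline_min <- unname(baselines[p$group_id])
  p$delay_min <- ifelse(p$status == "completed", p$duration_min - p$baseline_min, NA_real_)
  done <- p$status == "completed"
  mean_act <- if (any(done)) mean(p$duration_min[done]) else NA_real_
  mean_base <- if (any(done)) mean(p$baseline_min[done]) else NA_real_
  list(per_patient = p,
       completed = sum(done),
       damaged = sum(p$damaged),
       removed = sum(p$removed),
       mean_delay_min = if (any(done)) mean(p$delay_min[done]) else NA_real_,
       max_delay_min = if (any(done)) max(p$delay_min[done]) else NA_real_,
       mean_duration_min = mean_act,
       mean_baseline_min = mean_base,
       mean_pct_increase = if (any(done)) 100 * (mean_act - mean_base) / mean_base else NA_real_)
}

hf_sweep_row <- function(grid_value, ind) {
  data.frame(grid_value = grid_value,
             mean_pct_increase = ind$mean_pct_increase,
             mean_delay_min = ind$mean_delay_min,
             max_delay_min = ind$max_delay_min,
             mean_duration_min = ind$mean_duration_min,
             completed = ind$completed,
             damaged = ind$damaged,
             removed = ind$removed)
}

#' Sweep over resource outage durations
#'
#' For each grid duration `d`, all instances of `resource_type` are taken
#' out of service over `[0, d)` minutes and the full scenario is
#' re-simulated from scratch; indicators are computed against the
#' modifier-free baseline. Models e.g. a ransomware outage of the CT
#' scanner with a rising restoration time.
#'
#' @param spec An [hf_scenario()].
#' @param resource_type Resource-type id to disable.
#' @param grid Outage durations in minutes; must include 0 (the identity
#'   point reproducing the unmodified run).
#' @return Object of class `hf_sweep` with `table` (one row per grid
#'   value) and `runs` (per-patient rows per grid value).
#' @export
run_outage_sweep <- function(spec, resource_type, grid = seq(0, 240, by = 30)) {
  if (!0 %in% grid) hf_stop("InvalidScenario", "outage grid must include 0")
  grid <- sort(unique(grid))
  base <- compute_baseline(spec)
  runs <- list(); rows <- list()
  for (d in grid) {
    mods <- spec$modifiers
    if (d > 0) {
      mods <- c(mods, list(hf_modifier(0, "resource_outage_start", resource_type),
                           hf_modifier(d, "resource_outage_end", resource_type)))
    }
    s <- spec; s$modifiers <- mods
    res <- simulate_scenario(s)
    ind <- compute_indicators(res, base)
    rows[[length(rows) + 1L]] <- hf_sweep_row(d, ind)
    runs[[as.character(d)]] <- ind$per_patient
  }
  structure(list(kind = "outage", resource_type = resource_type,
                 table = do.call(rbind, rows), runs = runs, baselines = base),
            class = "hf_sweep")
}

#' Sweep over resource efficiency percentages
#'
#' For each grid value `e`, the efficiency of `resource_type` is set to
#' `e`% from minute zero (task durations scale by 100/e) and the scenario
#' is re-simulated. Models a security measure that prolongs, e.g., every
#' CT scan.
#'
#' @param spec An [hf_scenario()].
#' @param resource_type Resource-type id.
#' @param grid Efficiency percentages (> 0), e.g. `c(100, 80, 60, 40)`.
#' @return An `hf_sweep` (rows ordered by increasing grid value).
#' @export
run_efficiency_sweep <- function(spec, resource_type, grid = c(100, 80, 60, 40)) {
  if (any(grid <= 0)) hf_stop("NonPositiveEfficiency", "efficiency grid must be > 0")
  grid <- sort(unique(grid))
  base <- compute_baseline(spec)
  runs <- list(); rows <- list()
  for (e in grid) {
    mods <- spec$modifiers
    if (e != 100) mods <- c(mods, list(hf_modifier(0, "set_efficiency", resource_type, e)))
    s <- spec; s$modifiers <- mods
    res <- simulate_scenario(s)
    ind <- compute_indicators(res, base)
    rows[[length(rows) + 1L]] <- hf_sweep_row(e, ind)
    runs[[as.character(e)]] <- ind$per_patient
  }
  structure(list(kind = "efficiency", resource_type = resource_type,
                 table = do.call(rbind, rows), runs = runs, baselines = base),
            class = "hf_sweep")
}

#' @export
print.hf_sweep <- function(x, ...) {
  cat(sprintf("<hf_sweep> kind=%s on %s\n", x$kind, x$resource_type))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Utilization of a resource type over a run
#'
#' Total busy minutes of the type's instances (from task_start durations
#' in the event log) divided by instance count times the type's service
#' window (first task start to last task end involving the type). A
#' saturated single scanner serving back-to-back reads 1.
#'
#' @param result An `hf_result`.
#' @param resource_type Resource-type id.
#' @return Fraction in `[0, 1]`.
#' @export
resource_utilization <- function(result, resource_type) {
  ev <- result$events
  inst <- result$spec$hospital$instances
  ids <- inst$id[inst$type_id == resource_type]
  if (!length(ids) || !nrow(ev)) return(0)
  starts <- ev[ev$kind == "task_start", , drop = FALSE]
  busy <- 0; t0 <- Inf; t1 <- -Inf
  for (i in seq_len(nrow(starts))) {
    used <- strsplit(starts$instances[i], ";", fixed = TRUE)[[1]]
    k <- sum(used %in% ids)
    if (k == 0) next
    busy <- busy + starts$value[i] * k
    t0 <- min(t0, starts$time[i])
    t1 <- max(t1, starts$time[i] + starts$value[i])
  }
  if (!is.finite(t0) || t1 <= t0) return(0)
  min(1, busy / (length(ids) * (t1 - t0)))
}

#' Compare mass-casualty emergency plans
#'
#' Simulates the scenario under an emergency plan that boosts the
#' efficiency of every resource type used in the trauma room — except the
#' CT scanner, which cannot work faster than its capacity — over a grid of
#' boost percentages, optionally with a second CT scanner added. Reports
#' mean treatment duration, improvement versus the unboosted single-CT
#' run, and CT utilization, so the saturation of the single scanner is
#' visible.
#'
#' @param spec An [hf_scenario()] (typically the MCI scenario).
#' @param boost_grid Efficiency boost percentages added to 100 (0 = plain
#'   run), e.g. `seq(0, 200, by = 25)`.
#' @param ct_type Resource-type id of the CT scanner.
#' @param ct_area Area id where an added scanner is homed.
#' @param ct_counts CT scanner counts to compare, default `c(1, 2)`.
#' @return Data frame: `boost_pct`, `ct_count`, `mean_duration_min`,
#'   `improvement_min`, `improvement_pct`, `ct_utilization`.
#' @export
run_emergency_plan_comparison <- function(spec, boost_grid = seq(0, 200, by = 25),
                                          ct_type = "ct_scanner",
                                          ct_area = "CT", ct_counts = c(1, 2)) {
  boost_grid <- sort(unique(boost_grid))
  # resource types used by trauma-room tasks, CT excluded
  etr_types <- unique(unlist(lapply(spec$graph$tasks, function(t)
    if (identical(t$area_id, "ETR"))
      vapply(t$demands, function(d) d$type_id, "") else character())))
  boosted_types <- setdiff(etr_types, ct_type)
  base <- compute_baseline(spec)
  rows <- list(); ref <- NA_real_
  for (nct in ct_counts) {
    hosp <- spec$hospital
    if (nct > 1) {
      inv <- hosp$inventory
      i <- which(inv$type_id == ct_type)[1]
      inv$count[i] <- inv$count[i] + (nct - 1)
      hosp <- hf_hospital(hosp$areas, hosp$transit, hosp$resource_types, inv)
    }
    for (b in boost_grid) {
      mods <- spec$modifiers
      if (b > 0) for (ty in boosted_types)
        mods <- c(mods, list(hf_modifier(0, "set_efficiency", ty, 100 + b)))
      s <- hf_scenario(spec$graph, hosp, spec$groups, spec$cohort,
                       modifiers = mods, seed = spec$seed,
                       horizon_min = spec$horizon_min)
      res <- simulate_scenario(s)
      ind <- compute_indicators(res, base)
      if (nct == ct_counts[1] && b == 0) ref <- ind$mean_duration_min
      rows[[length(rows) + 1L]] <- data.frame(
        boost_pct = b, ct_count = nct,
        mean_duration_min = ind$mean_duration_min,
        improvement_min = ref - ind$mean_duration_min,
        improvement_pct = 100 * (ref - ind$mean_duration_min) / ref,
        ct_utilization = resource_utilization(res, ct_type),
        damaged = ind$damaged, removed = ind$removed)
    }
  }
  do.call(rbind, rows)
}
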