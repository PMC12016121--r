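#' Scenario specification
#'
#' The unit of one reproducible simulation run: a process, a hospital, the
#' injury groups, a patient cohort, time-scheduled modifiers and a horizon.
#' All randomness lives in cohort generation; given the same spec the
#' simulation is fully deterministic.
#'
#' @param graph An `hf_process`.
#' @param hospital An `hf_hospital`.
#' @param groups List of [injury_group()] objects.
#' @param cohort Data frame as returned by [generate_patients()].
#' @param modifiers List of [hf_modifier()] objects.
#' @param seed Seed recorded for provenance (cohort generation happens
#'   before the spec is built; the engine itself draws no random numbers).
#' @param horizon_min Simulation horizon in minutes.
#' @return An object of class `hf_scenario`.
#' @export
hf_scenario <- function(graph, hospital, groups, cohort, modifiers = list(),
                        seed = NA_integer_, horizon_min = 1e5) {
  names(groups) <- vapply(groups, function(g) g$id, "")
  bad <- setdiff(unique(cohort$group_id), names(groups))
  if (length(bad)) hf_stop("InvalidScenario", "cohort references unknown group(s): %s",
                           paste(bad, collapse = ", "))
  if (nrow(cohort) && horizon_min <= max(cohort$t_start_min))
    hf_stop("InvalidScenario", "horizon must exceed the last arrival")
  structure(list(graph = graph, hospital = hospital, groups = groups,
                 cohort = cohort, modifiers = modifiers,
                 seed = seed, horizon_min = horizon_min),
            class = "hf_scenario")
}

# ---- internal mutable simulation state -------------------------------------

hf_new_state <- function(spec) {
  st <- new.env(parent = emptyenv())
  st$spec <- spec
  st$graph <- spec$graph
  st$groups <- spec$groups
  st$clock <- 0
  st$areas <- lapply(spec$hospital$areas, unclass)
  st$transit <- spec$hospital$transit
  st$resource_types <- spec$hospital$resource_types
  inst <- spec$hospital$instances
  rt <- spec$hospital$resource_types
  inst$mobility <- vapply(inst$type_id, function(t) rt[[t]]$mobility, "")
  inst$attachable <- vapply(inst$type_id, function(t) rt[[t]]$attachable, TRUE)
  inst$attached_to <- NA_character_
  inst$busy_until <- 0
  st$instances <- inst
  st$eff <- stats::setNames(rep(100, length(rt)), names(rt))
  st$outage <- stats::setNames(rep(FALSE, length(rt)), names(rt))
  st$patients <- list()
  st$reqq <- list()
  st$joins <- list()
  st$ev_time <- numeric(); st$ev_kind <- character()
  st$ev_alive <- logical(); st$ev_data <- list()
  st$scan_at <- -1
  st$log <- vector("list", 256L); st$nlog <- 0L
  st
}

hf_schedule <- function(st, time, kind, data = list()) {
  i <- length(st$ev_time) + 1L
  st$ev_time[i] <- max(time, st$clock)
  st$ev_kind[i] <- kind
  st$ev_alive[i] <- TRUE
  st$ev_data[[i]] <- data
  i
}

hf_cancel <- function(st, i) {
  if (length(i)) st$ev_alive[i] <- FALSE
  invisible(NULL)
}

hf_pop <- function(st) {
  idx <- which(st$ev_alive)
  if (!length(idx)) return(NULL)
  j <- idx[order(st$ev_time[idx], idx)[1]]
  st$ev_alive[j] <- FALSE
  list(i = j, time = st$ev_time[j], kind = st$ev_kind[j], data = st$ev_data[[j]])
}

hf_log <- function(st, kind, patient = NA, task = NA, area = NA,
                   instances = character(), from = NA, to = NA, eta = NA,
                   value = NA, detail = NA) {
  st$nlog <- st$nlog + 1L
  if (st$nlog > length(st$log)) st$log <- c(st$log, vector("list", length(st$log)))
  st$log[[st$nlog]] <- list(
    time = st$clock, seq = st$nlog, kind = kind,
    patient = as.character(patient), task = as.character(task),
    area = as.character(area),
    instances = paste(instances, collapse = ";"),
    from = as.character(from), to = as.character(to),
    eta = as.numeric(eta), value = as.numeric(value),
    detail = as.character(detail))
}

hf_irow <- function(st, ids) match(ids, st$instances$id)

hf_schedule_scan <- function(st) {
  if (st$scan_at < st$clock) {
    hf_schedule(st, st$clock, "scan")
    st$scan_at <- st$clock
  }
}

# ---- patient deadline bookkeeping ------------------------------------------

hf_set_deadline_events <- function(st, pid) {
  p <- st$patients[[pid]]
  hf_cancel(st, c(p$ttd_ev, p$ttr_ev))
  p$ttd_ev <- if (!is.na(p$ttd_abs) && !p$damaged && p$status %in% c("waiting", "in_task", "in_transit"))
    hf_schedule(st, p$ttd_abs, "ttd", list(pid = pid)) else NULL
  p$ttr_ev <- if (!is.na(p$ttr_abs) && p$status %in% c("waiting", "in_task", "in_transit"))
    hf_schedule(st, p$ttr_abs, "ttr", list(pid = pid)) else NULL
  st$patients[[pid]] <- p
}

# ---- token advancement ------------------------------------------------------

hf_advance <- function(st, tok) {
  repeat {
    kind <- hf_node_kind(st$graph, tok$node)
    if (kind == "task") { hf_enter_task(st, tok); return(invisible(NULL)) }
    if (kind == "end") { hf_complete_patient(st, tok$pid); return(invisible(NULL)) }
    if (kind %in% c("start", "exclusive_join")) {
      tok$node <- hf_next_single(st$graph, tok$node)
    } else if (kind == "exclusive_split") {
      g <- st$groups[[st$patients[[tok$pid]]$group_id]]
      tok$node <- if (tok$node %in% st$graph$redundant_groups) {
        choose_redundant_branch(st, tok$pid, g, tok$node)
      } else {
        hf_resolve_branch(st$graph, tok$node, g$id, g$branch_labels)
      }
    } else if (kind == "parallel_split") {
      join <- hf_matching_join(st$graph, tok$node)
      outs <- st$graph$edges$to[hf_out_edges(st$graph, tok$node)]
      key <- paste(tok$pid, join, sep = "|")
      st$joins[[key]] <- list(expected = length(outs), times = numeric(),
                              locs = character(), branches = integer())
      for (i in seq_along(outs)) {
        hf_advance(st, list(pid = tok$pid, node = outs[i], loc = tok$loc,
                            branch = i, join = join))
      }
      return(invisible(NULL))
    } else if (kind == "parallel_join") {
      key <- paste(tok$pid, tok$node, sep = "|")
      jr <- st$joins[[key]]
      jr$times <- c(jr$times, st$clock)
      jr$locs <- c(jr$locs, tok$loc %||% NA_character_)
      jr$branches <- c(jr$branches, tok$branch %||% 0L)
      st$joins[[key]] <- jr
      if (length(jr$times) < jr$expected) return(invisible(NULL))
      ord <- order(jr$branches)
      times <- jr$times[ord]; locs <- jr$locs[ord]
      best <- which.max(times)  # latest branch; ties -> first declared
      loc <- locs[best]
      p <- st$patients[[tok$pid]]; p$location <- loc; st$patients[[tok$pid]] <- p
      tok <- list(pid = tok$pid, node = hf_next_single(st$graph, tok$node),
                  loc = loc, branch = NULL, join = NULL)
    } else {
      hf_stop("InvalidScenario", "token stuck at %s (%s)", tok$node, kind)
    }
  }
}

hf_enter_task <- function(st, tok) {
  task <- st$graph$tasks[[tok$node]]
  if (is.null(tok$loc)) tok$loc <- task$area_id  # patient starts in first task's area
  if (!identical(tok$loc, task$area_id)) {
    tt <- transit_time(st$transit, tok$loc, task$area_id)
    p <- st$patients[[tok$pid]]
    p$status <- "in_transit"; st$patients[[tok$pid]] <- p
    hf_log(st, "transport_start", patient = tok$pid, task = task$id,
           from = tok$loc, to = task$area_id, eta = st$clock + tt)
    hf_schedule(st, st$clock + tt, "transport_end",
                list(tok = tok, from = tok$loc))
    return(invisible(NULL))
  }
  p <- st$patients[[tok$pid]]
  p$location <- tok$loc; p$status <- "waiting"; st$patients[[tok$pid]] <- p
  st$reqq[[length(st$reqq) + 1L]] <- list(pid = tok$pid, task_id = task$id,
                                          tok = tok, enq = st$clock)
  hf_schedule_scan(st)
}

# ---- allocation -------------------------------------------------------------

hf_req_order <- function(st) {
  if (!length(st$reqq)) return(integer())
  pr <- vapply(st$reqq, function(r) -st$groups[[st$patients[[r$pid]]$group_id]]$priority, 0)
  at <- vapply(st$reqq, function(r) st$patients[[r$pid]]$t_start, 0)
  pid <- vapply(st$reqq, function(r) r$pid, "")
  order(pr, at, pid)
}

hf_try_grant <- function(st, req) {
  task <- st$graph$tasks[[req$task_id]]
  area <- task$area_id
  ar <- st$areas[[area]]
  if (!isTRUE(ar$active) || isTRUE(ar$quarantined)) return(FALSE)
  inst <- st$instances
  demands <- Filter(function(d) d$action %in% c("use", "attach"), task$demands)
  plan <- list()      # per demand: list(local = ids, borrowed = list(id, from, tt))
  taken <- character()
  for (d in demands) {
    if (isTRUE(st$outage[d$type_id])) return(FALSE)
    loc_rows <- which(inst$type_id == d$type_id & inst$location == area &
                      inst$state == "idle" & !inst$id %in% taken)
    loc_rows <- loc_rows[order(inst$id[loc_rows])]
    n_local <- min(length(loc_rows), d$count)
    local <- inst$id[loc_rows[seq_len(n_local)]]
    taken <- c(taken, local)
    need <- d$count - n_local
    borrowed <- list()
    if (need > 0) {
      rt <- st$resource_types[[d$type_id]]
      if (is.null(rt) || rt$mobility == "stationary") return(FALSE)
      lenders <- setdiff(names(st$areas), area)
      avail <- vapply(lenders, function(a) {
        lc <- lendable_count(st, a, d$type_id)
        idle_here <- inst$id[inst$type_id == d$type_id & inst$location == a &
                             inst$state == "idle" & !inst$id %in% taken]
        min(lc, length(idle_here))
      }, 0)
      lenders <- lenders[avail > 0]
      if (length(lenders)) {
        tts <- vapply(lenders, function(a) transit_time(st$transit, a, area), 0)
        lenders <- lenders[order(tts, lenders)]
        for (a in lenders) {
          if (need == 0) break
          cand <- inst$id[inst$type_id == d$type_id & inst$location == a &
                          inst$state == "idle" & !inst$id %in% taken]
          cand <- sort(cand)
          k <- min(need, lendable_count(st, a, d$type_id), length(cand))
          if (k < 1) next
          for (id in cand[seq_len(k)])
            borrowed[[length(borrowed) + 1L]] <-
              list(id = id, from = a, tt = transit_time(st$transit, a, area))
          taken <- c(taken, cand[seq_len(k)])
          need <- need - k
        }
      }
      if (need > 0) return(FALSE)
    }
    plan[[length(plan) + 1L]] <- list(demand = d, local = local, borrowed = borrowed)
  }

  # grant: reserve instances, dispatch borrowed ones, schedule the start
  all_ids <- unlist(c(lapply(plan, function(p) p$local),
                      lapply(plan, function(p) vapply(p$borrowed, function(b) b$id, ""))))
  all_ids <- as.character(all_ids %||% character())
  hf_log(st, "alloc_granted", patient = req$pid, task = task$id, area = area,
         instances = all_ids)
  max_tt <- 0
  for (pl in plan) {
    st$instances$state[hf_irow(st, pl$local)] <- "reserved"
    for (b in pl$borrowed) {
      r <- hf_irow(st, b$id)
      st$instances$state[r] <- "in_transit"
      hf_log(st, "resource_dispatch", patient = req$pid, task = task$id,
             instances = b$id, from = b$from, to = area, eta = st$clock + b$tt)
      max_tt <- max(max_tt, b$tt)
    }
  }
  hf_schedule(st, st$clock + max_tt, "task_start",
              list(tok = req$tok, task_id = task$id, plan = plan, ids = all_ids))
  TRUE
}

hf_scan <- function(st) {
  for (i in hf_req_order(st)) {
    if (hf_try_grant(st, st$reqq[[i]])) st$reqq[[i]] <- NA
  }
  st$reqq <- Filter(function(r) !identical(r, NA), st$reqq)
}

# ---- task lifecycle ---------------------------------------------------------

hf_task_eff <- function(st, task) {
  types <- unique(vapply(Filter(function(d) d$action %in% c("use", "attach"),
                                task$demands), function(d) d$type_id, ""))
  if (!length(types)) return(100)
  min(st$eff[types])
}

hf_on_task_start <- function(st, data) {
  tok <- data$tok; task <- st$graph$tasks[[data$task_id]]
  p <- st$patients[[tok$pid]]
  if (p$status %in% c("completed", "removed_reanimation")) return(invisible(NULL))
  rows <- hf_irow(st, data$ids)
  if (length(rows)) {
    st$instances$state[rows] <- "busy"
    st$instances$location[rows] <- task$area_id
  }
  g <- st$groups[[p$group_id]]
  dur <- task$group_durations[[g$id]] %||% task$duration_min
  dur_eff <- effective_duration(dur, hf_task_eff(st, task))
  if (length(rows)) st$instances$busy_until[rows] <- st$clock + dur_eff
  p$status <- "in_task"; st$patients[[tok$pid]] <- p
  hf_log(st, "task_start", patient = tok$pid, task = task$id, area = task$area_id,
         instances = data$ids, value = dur_eff)
  # early release for sub-interval holds (held from start, freed at offset+length)
  for (pl in data$plan) {
    d <- pl$demand
    if (d$hold_mode == "sub_interval") {
      rel_at <- st$clock + min(d$sub_interval[1] + d$sub_interval[2], dur_eff)
      ids <- c(pl$local, vapply(pl$borrowed, function(b) b$id, ""))
      hf_schedule(st, rel_at, "sub_release",
                  list(pid = tok$pid, ids = ids, area = task$area_id))
    }
  }
  hf_schedule(st, st$clock + dur_eff, "task_end",
              list(tok = tok, task_id = task$id, plan = data$plan))
}

# Release one instance from service in `area`; route home with transit if
# borrowed, respect quarantine/outage blocking.
hf_release_inst <- function(st, id, area, detail = NA) {
  r <- hf_irow(st, id)
  home <- st$instances$home_area[r]
  st$instances$attached_to[r] <- NA_character_
  st$instances$busy_until[r] <- st$clock
  if (identical(home, area)) {
    if (isTRUE(st$areas[[area]]$quarantined) || isTRUE(st$outage[st$instances$type_id[r]])) {
      st$instances$state[r] <- "blocked"
    } else {
      st$instances$state[r] <- "idle"
    }
    st$instances$location[r] <- area
    if (!is.na(detail))
      hf_log(st, "resource_return", instances = id, from = area, to = area,
             eta = st$clock, detail = detail)
  } else {
    tt <- transit_time(st$transit, area, home)
    st$instances$state[r] <- "in_transit"
    hf_log(st, "resource_return", instances = id, from = area, to = home,
           eta = st$clock + tt, detail = detail)
    hf_schedule(st, st$clock + tt, "inst_home", list(id = id))
  }
  hf_schedule_scan(st)
}

hf_on_task_end <- function(st, data) {
  tok <- data$tok; task <- st$graph$tasks[[data$task_id]]
  p <- st$patients[[tok$pid]]
  dispo <- character()
  for (pl in data$plan) {
    d <- pl$demand
    ids <- c(pl$local, vapply(pl$borrowed, function(b) b$id, ""))
    if (d$hold_mode == "sub_interval") next  # released earlier
    if (d$action == "attach") {
      rows <- hf_irow(st, ids)
      st$instances$state[rows] <- "attached"
      st$instances$attached_to[rows] <- tok$pid
      p$attached <- c(p$attached, ids)
      dispo <- c(dispo, paste0(ids, "=attached"))
    } else {
      for (id in ids) {
        r <- hf_irow(st, id)
        if (identical(st$instances$home_area[r], task$area_id)) {
          dispo <- c(dispo, paste0(id, "=idle"))
        } else {
          dispo <- c(dispo, paste0(id, "=return"))
        }
      }
    }
  }
  hf_log(st, "task_end", patient = tok$pid, task = task$id, area = task$area_id,
         instances = unlist(lapply(data$plan, function(pl)
           if (pl$demand$hold_mode == "sub_interval") character()
           else c(pl$local, vapply(pl$borrowed, function(b) b$id, "")))),
         detail = paste(dispo, collapse = ","))
  for (pl in data$plan) {
    d <- pl$demand
    if (d$hold_mode == "sub_interval" || d$action == "attach") next
    for (id in c(pl$local, vapply(pl$borrowed, function(b) b$id, "")))
      hf_release_inst(st, id, task$area_id)
  }
  # detach demands: send the attached instance(s) of the type home
  for (d in Filter(function(d) d$action == "detach", task$demands)) {
    att <- p$attached
    att_rows <- hf_irow(st, att)
    hit <- att[st$instances$type_id[att_rows] == d$type_id]
    if (length(hit) < d$count)
      hf_stop("DetachNotAttached", "patient %s has no attached %s to detach", tok$pid, d$type_id)
    hit <- sort(hit)[seq_len(d$count)]
    for (id in hit) hf_release_inst(st, id, p$location %||% task$area_id, detail = "detach")
    p$attached <- setdiff(p$attached, hit)
  }
  # therapy deltas apply at completion and push pending deadline events
  if (task$ttd_delta_min != 0 && !is.na(p$ttd_abs)) p$ttd_abs <- p$ttd_abs + task$ttd_delta_min
  if (task$ttr_delta_min != 0 && !is.na(p$ttr_abs)) p$ttr_abs <- p$ttr_abs + task$ttr_delta_min
  p$path <- c(p$path, task$id)
  p$status <- "waiting"
  st$patients[[tok$pid]] <- p
  hf_set_deadline_events(st, tok$pid)
  tok$loc <- task$area_id
  tok$node <- hf_next_single(st$graph, task$id)
  hf_advance(st, tok)
}

hf_complete_patient <- function(st, pid) {
  p <- st$patients[[pid]]
  p$status <- "completed"; p$completion <- st$clock
  st$patients[[pid]] <- p
  hf_cancel(st, c(p$ttd_ev, p$ttr_ev))
  for (id in p$attached)
    hf_release_inst(st, id, p$location, detail = "detach")
  p <- st$patients[[pid]]; p$attached <- character(); st$patients[[pid]] <- p
  hf_log(st, "patient_completed", patient = pid,
         value = st$clock - p$t_start)
}

# ---- deadline events --------------------------------------------------------

hf_on_ttd <- function(st, data) {
  p <- st$patients[[data$pid]]
  if (!p$status %in% c("waiting", "in_task", "in_transit")) return(invisible(NULL))
  if (p$ttd_abs > st$clock) return(invisible(NULL))  # superseded by a delta
  p$damaged <- TRUE
  st$patients[[data$pid]] <- p
  hf_log(st, "ttd_hit", patient = data$pid, value = p$ttd_abs)
}

hf_on_ttr <- function(st, data) {
  pid <- data$pid
  p <- st$patients[[pid]]
  if (!p$status %in% c("waiting", "in_task", "in_transit")) return(invisible(NULL))
  if (p$ttr_abs > st$clock) return(invisible(NULL))
  hf_log(st, "ttr_hit", patient = pid, value = p$ttr_abs)
  p$status <- "removed_reanimation"
  st$patients[[pid]] <- p
  hf_cancel(st, p$ttd_ev)
  # cancel queued allocation requests
  st$reqq <- Filter(function(r) !identical(r$pid, pid), st$reqq)
  # cancel this patient's pending events and release everything held
  for (i in which(st$ev_alive)) {
    d <- st$ev_data[[i]]
    dpid <- d$pid %||% d$tok$pid
    if (!identical(dpid, pid)) next
    k <- st$ev_kind[i]
    st$ev_alive[i] <- FALSE
    if (k == "task_end") {
      task <- st$graph$tasks[[d$task_id]]
      for (pl in d$plan) {
        if (pl$demand$hold_mode == "sub_interval") next
        for (id in c(pl$local, vapply(pl$borrowed, function(b) b$id, "")))
          hf_release_inst(st, id, task$area_id, detail = "release_on_removal")
      }
    } else if (k == "task_start") {
      # granted but not started: free reserved instances; dispatched ones
      # turn around once they arrive
      task <- st$graph$tasks[[d$task_id]]
      for (pl in d$plan) {
        for (id in pl$local)
          hf_release_inst(st, id, task$area_id, detail = "release_on_removal")
        for (b in pl$borrowed) {
          eta <- st$ev_time[i]  # start time = latest dispatch arrival
          hf_schedule(st, eta, "inst_cancel_arrive",
                      list(id = b$id, area = task$area_id))
        }
      }
    } else if (k == "sub_release") {
      for (id in d$ids) hf_release_inst(st, id, d$area, detail = "release_on_removal")
    }
  }
  p <- st$patients[[pid]]
  for (id in p$attached) hf_release_inst(st, id, p$location, detail = "detach")
  p$attached <- character()
  st$patients[[pid]] <- p
  hf_schedule_scan(st)
}

# ---- modifiers --------------------------------------------------------------

hf_apply_modifier <- function(st, m) {
  hf_log(st, "modifier_applied", area = if (m$kind %in% c(
    "deactivate_area", "reactivate_area", "quarantine_area", "lift_quarantine"))
    m$target else NA,
    value = if (is.null(m$value)) NA else as.numeric(m$value),
    detail = m$kind,
    from = if (m$kind == "set_transit") m$target[1] else NA,
    to = if (m$kind == "set_transit") m$target[2] else NA,
    task = if (m$kind %in% c("set_efficiency", "resource_outage_start",
                             "resource_outage_end")) m$target else NA)
  inst <- st$instances
  switch(m$kind,
    deactivate_area = { st$areas[[m$target]]$active <- FALSE },
    reactivate_area = { st$areas[[m$target]]$active <- TRUE; hf_schedule_scan(st) },
    quarantine_area = {
      if (is.null(st$areas[[m$target]])) hf_stop("UnknownTarget", "unknown area %s", m$target)
      st$areas[[m$target]]$quarantined <- TRUE
      rows <- which(inst$location == m$target & inst$state == "idle")
      st$instances$state[rows] <- "blocked"
    },
    lift_quarantine = {
      st$areas[[m$target]]$quarantined <- FALSE
      rows <- which(st$instances$location == m$target &
                    st$instances$state == "blocked" &
                    !st$outage[st$instances$type_id])
      st$instances$state[rows] <- "idle"
      hf_schedule_scan(st)
    },
    set_transit = {
      st$transit[m$target[1], m$target[2]] <- as.numeric(m$value)
    },
    set_efficiency = {
      if (!m$target %in% names(st$eff)) hf_stop("UnknownTarget", "unknown type %s", m$target)
      if (as.numeric(m$value) <= 0)
        hf_stop("NonPositiveEfficiency", "efficiency must be > 0")
      st$eff[m$target] <- as.numeric(m$value)
    },
    resource_outage_start = {
      st$outage[m$target] <- TRUE
      rows <- which(st$instances$type_id == m$target & st$instances$state == "idle")
      st$instances$state[rows] <- "blocked"
    },
    resource_outage_end = {
      st$outage[m$target] <- FALSE
      rows <- which(st$instances$type_id == m$target &
                    st$instances$state == "blocked")
      rows <- rows[!vapply(st$instances$location[rows],
                           function(a) isTRUE(st$areas[[a]]$quarantined), TRUE)]
      st$instances$state[rows] <- "idle"
      hf_schedule_scan(st)
    },
    hf_stop("UnknownTarget", "unknown modifier kind %s", m$kind))
}

# ---- redundant branch choice ------------------------------------------------

#' Estimated-time choice among redundant branches
#'
#' For each alternative branch of a redundant exclusive split, sums the
#' effective task durations (group override, current efficiency) plus
#' inbound transit, plus a congestion estimate per demanded resource type:
#' the backlog minutes currently running or queued on that type in the
#' task's area divided by the number of in-service instances there
#' (infinite if none are in service). The branch with the smallest
#' estimate wins; ties go to the first-declared branch. The estimator is
#' pluggable: pass a different `estimator` to [simulate()] via the state.
#'
#' @param st Simulation state (internal) or an environment exposing
#'   `graph`, `instances`, `transit`, `eff`, `clock`, `reqq`, `areas`.
#' @param pid Patient id.
#' @param group The patient's [injury_group()].
#' @param split Gateway id of the redundant exclusive split.
#' @return The target node id of the chosen branch.
#' @keywords internal
choose_redundant_branch <- function(st, pid, group, split) {
  outs <- st$graph$edges$to[hf_out_edges(st$graph, split)]
  loc0 <- st$patients[[pid]]$location
  est <- vapply(outs, function(start) {
    total <- 0; node <- start; loc <- loc0
    repeat {
      kind <- hf_node_kind(st$graph, node)
      if (kind != "task") break  # branch estimated up to its first merge/gateway
      task <- st$graph$tasks[[node]]
      dur <- task$group_durations[[group$id]] %||% task$duration_min
      dur <- effective_duration(dur, hf_task_eff(st, task))
      if (!is.null(loc) && !identical(loc, task$area_id))
        total <- total + transit_time(st$transit, loc, task$area_id)
      loc <- task$area_id
      total <- total + dur
      for (d in Filter(function(d) d$action %in% c("use", "attach"), task$demands)) {
        inst <- st$instances
        rows <- which(inst$type_id == d$type_id & inst$location == task$area_id)
        in_service <- sum(inst$state[rows] != "blocked")
        if (in_service == 0 || isTRUE(st$outage[d$type_id])) return(Inf)
        backlog <- sum(pmax(0, inst$busy_until[rows] - st$clock))
        for (r in st$reqq) {
          qt <- st$graph$tasks[[r$task_id]]
          if (!identical(qt$area_id, task$area_id)) next
          for (qd in qt$demands) if (qd$type_id == d$type_id) {
            qg <- st$groups[[st$patients[[r$pid]]$group_id]]
            qdur <- qt$group_durations[[qg$id]] %||% qt$duration_min
            backlog <- backlog + effective_duration(qdur, hf_task_eff(st, qt)) * qd$count
          }
        }
        total <- total + backlog / max(1, in_service)
      }
      node <- hf_next_single(st$graph, node)
    }
    total
  }, 0)
  outs[which.min(est)]
}

# ---- main loop --------------------------------------------------------------

#' Run a scenario simulation
#'
#' The hybrid DES/ABS core: patients are agents moving through the process
#' graph; resource allocation, cross-area lending, transport, redundant
#' branch choice, deadline events and time-scheduled modifiers are
#' discrete events on a continuous-time queue with deterministic
#' tie-breaking. Two runs of the same spec produce identical event logs.
#'
#' A patient whose time-till-damage elapses is flagged damaged and
#' continues; a patient whose time-to-reanimation elapses is removed from
#' the process and all held or attached resources are released.
#'
#' @param spec An [hf_scenario()].
#' @return An object of class `hf_result`: `events` (ordered event log as
#'   a data frame), `patients` (per-patient outcomes), `resources` (final
#'   instance states) and the `spec`.
#' @export
simulate_scenario <- function(spec) {
  viol <- validate_process(spec$graph)
  if (length(viol))
    hf_stop("InvalidScenario", "process invalid: %s", paste(viol, collapse = "; "))
  st <- hf_new_state(spec)
  co <- spec$cohort
  for (i in seq_len(nrow(co))) {
    hf_schedule(st, co$t_start_min[i], "arrival", list(row = i))
  }
  for (m in spec$modifiers) hf_schedule(st, m$at_min, "modifier", list(m = m))

  repeat {
    ev <- hf_pop(st)
    if (is.null(ev)) break
    if (ev$time > spec$horizon_min) break
    st$clock <- ev$time
    d <- ev$data
    switch(ev$kind,
      arrival = {
        r <- co[d$row, ]
        pid <- r$patient_id
        st$patients[[pid]] <- list(
          id = pid, group_id = r$group_id, t_start = r$t_start_min,
          ttd_abs = if (is.na(r$ttd_min)) NA_real_ else r$t_start_min + r$ttd_min,
          ttr_abs = if (is.na(r$ttr_min)) NA_real_ else r$t_start_min + r$ttr_min,
          status = "waiting", location = NULL, completion = NA_real_,
          damaged = FALSE, attached = character(), path = character(),
          ttd_ev = NULL, ttr_ev = NULL)
        hf_log(st, "arrival", patient = pid, value = r$t_start_min)
        hf_set_deadline_events(st, pid)
        hf_advance(st, list(pid = pid, node = st$graph$start_id, loc = NULL))
      },
      transport_end = {
        tok <- d$tok
        p <- st$patients[[tok$pid]]
        if (p$status %in% c("completed", "removed_reanimation")) {} else {
          task <- st$graph$tasks[[tok$node]]
          tok$loc <- task$area_id
          p$location <- task$area_id
          if (length(p$attached))
            st$instances$location[hf_irow(st, p$attached)] <- task$area_id
          p$status <- "waiting"
          st$patients[[tok$pid]] <- p
          hf_log(st, "transport_end", patient = tok$pid, task = tok$node,
                 from = d$from, to = task$area_id)
          st$reqq[[length(st$reqq) + 1L]] <- list(pid = tok$pid, task_id = task$id,
                                                  tok = tok, enq = st$clock)
          hf_schedule_scan(st)
        }
      },
      task_start = hf_on_task_start(st, d),
      task_end = hf_on_task_end(st, d),
      sub_release = {
        for (id in d$ids) hf_release_inst(st, id, d$area, detail = "sub_interval_release")
      },
      inst_home = {
        r <- hf_irow(st, d$id)
        loc <- st$instances$home_area[r]
        st$instances$location[r] <- loc
        blocked <- isTRUE(st$areas[[loc]]$quarantined) ||
          isTRUE(st$outage[st$instances$type_id[r]])
        st$instances$state[r] <- if (blocked) "blocked" else "idle"
        hf_schedule_scan(st)
      },
      inst_cancel_arrive = {
        r <- hf_irow(st, d$id)
        st$instances$location[r] <- d$area
        st$instances$state[r] <- "busy"  # momentarily, for uniform release
        hf_release_inst(st, d$id, d$area, detail = "release_on_removal")
      },
      modifier = hf_apply_modifier(st, d$m),
      ttd = hf_on_ttd(st, d),
      ttr = hf_on_ttr(st, d),
      scan = { st$scan_at <- -1; hf_scan(st) },
      hf_stop("InvalidScenario", "unknown event kind %s", ev$kind))
  }

  events <- do.call(rbind, lapply(st$log[seq_len(st$nlog)], function(e)
    as.data.frame(e, stringsAsFactors = FALSE)))
  if (is.null(events)) events <- data.frame()
  pats <- do.call(rbind, lapply(st$patients, function(p) data.frame(
    patient_id = p$id, group_id = p$group_id, t_start_min = p$t_start,
    status = p$status, completion_min = p$completion,
    duration_min = if (is.na(p$completion)) NA_real_ else p$completion - p$t_start,
    damaged = p$damaged,
    removed = identical(p$status, "removed_reanimation"),
    in_flight = p$status %in% c("waiting", "in_task", "in_transit"),
    path = paste(p$path, collapse = ";"),
    stringsAsFactors = FALSE)))
  if (is.null(pats)) pats <- data.frame()
  rownames(pats) <- NULL
  structure(list(events = events, patients = pats,
                 resources = st$instances, spec = spec),
            class = "hf_result")
}

#' @export
print.hf_result <- function(x, ...) {
  cat(sprintf("<hf_result> %d events, %d patients (%d completed, %d damaged, %d removed)\n",
              nrow(x$events), nrow(x$patients),
              sum(x$patients$status == "completed"),
              sum(x$patients$damaged), sum(x$patients$removed)))
  invisible(x)
}

#' @export
summary.hf_result <- function(object, ...) {
  p <- object$patients
  out <- list(
    patients = nrow(p),
    completed = sum(p$status == "completed"),
    damaged = sum(p$damaged),
    removed = sum(p$removed),
    mean_duration_min = mean(p$duration_min[p$status == "completed"]))
  class(out) <- "summary.hf_result"
  out
}

#' @export
print.summary.hf_result <- function(x, ...) {
  cat(sprintf("patients: %d  completed: %d  damaged: %d  removed: %d  mean duration: %.1f min\n",
              x$patients, x$completed, x$damaged, x$removed, x$mean_duration_min))
  invisible(x)
}
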