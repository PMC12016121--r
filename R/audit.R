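#' Audit a simulation event log
#'
#' Replays the ordered event log of an [simulate_scenario()] result
#' independently of the engine's internal state and checks the structural
#' invariants every valid run must satisfy:
#'
#' * conservation / non-preemption — every instance is in exactly one
#'   state at any instant; allocation, dispatch, start, end and return
#'   events only ever find the instance in the state the transition
#'   expects, so no instance can serve two tasks at once;
#' * minimum stock — no lending dispatch leaves the lender's idle count of
#'   that type below the configured minimum stock;
#' * quarantine hermeticity — between a quarantine and its lift no
#'   allocation, dispatch or task event involves an instance located in
#'   the quarantined area.
#'
#' @param result An `hf_result`.
#' @return Character vector of violation records; empty if the log is
#'   consistent.
#' @export
audit_log <- function(result) {
  ev <- result$events
  hosp <- result$spec$hospital
  v <- character()
  if (!nrow(ev)) return(v)

  inst <- hosp$instances
  state <- stats::setNames(rep("idle", nrow(inst)), inst$id)
  loc <- stats::setNames(inst$home_area, inst$id)
  eta_to <- stats::setNames(rep(NA_character_, nrow(inst)), inst$id)
  eta_at <- stats::setNames(rep(NA_real_, nrow(inst)), inst$id)
  type_of <- stats::setNames(inst$type_id, inst$id)
  quarantined <- character()

  settle <- function(now) {
    # apply due in-transit arrivals
    due <- names(eta_at)[!is.na(eta_at) & eta_at <= now]
    for (id in due) {
      state[[id]] <<- "idle"
      loc[[id]] <<- eta_to[[id]]
      eta_at[[id]] <<- NA_real_
      eta_to[[id]] <<- NA_character_
    }
  }
  ids_of <- function(s) if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
  check_q <- function(ids, what, t) {
    for (id in ids) if (loc[[id]] %in% quarantined)
      v <<- c(v, sprintf("quarantine_breach: %s %s at %s (in %s)", what, id, hf_num(t), loc[[id]]))
  }

  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    settle(e$time)
    ids <- ids_of(e$instances)
    switch(e$kind,
      alloc_granted = {
        check_q(ids, "alloc_granted", e$time)
        for (id in ids) {
          if (!identical(state[[id]], "idle"))
            v <- c(v, sprintf("bad_alloc_state: %s is %s at %s", id, state[[id]], hf_num(e$time)))
          state[[id]] <- "reserved"
        }
      },
      resource_dispatch = {
        for (id in ids) {
          if (!identical(state[[id]], "reserved"))
            v <- c(v, sprintf("bad_dispatch_state: %s is %s at %s", id, state[[id]], hf_num(e$time)))
          if (loc[[id]] %in% quarantined)
            v <- c(v, sprintf("quarantine_breach: dispatch %s from %s at %s", id, loc[[id]], hf_num(e$time)))
          # min-stock: idle count of this type at the lender, after removal
          lender <- e$from; type <- type_of[[id]]
          idle_there <- sum(state == "idle" & loc == lender & type_of == type)
          ms <- hosp$areas[[lender]]$min_stock[[type]] %||% 0
          if (idle_there < ms)
            v <- c(v, sprintf("min_stock_breach: %s at %s has %d idle %s < min %d after dispatch of %s",
                              type, lender, idle_there, type, as.integer(ms), id))
          state[[id]] <- "dispatching"
          loc[[id]] <- e$to
        }
      },
      task_start = {
        check_q(ids, "task_start", e$time)
        for (id in ids) {
          if (!state[[id]] %in% c("reserved", "dispatching"))
            v <- c(v, sprintf("preemption_or_bad_start: %s is %s at %s", id, state[[id]], hf_num(e$time)))
          state[[id]] <- "busy"
          loc[[id]] <- e$area
        }
      },
      task_end = {
        pairs <- if (is.na(e$detail) || !nzchar(e$detail)) character()
                 else strsplit(e$detail, ",", fixed = TRUE)[[1]]
        dmap <- stats::setNames(sub(".*=", "", pairs), sub("=.*", "", pairs))
        for (id in ids) {
          if (!identical(state[[id]], "busy"))
            v <- c(v, sprintf("bad_end_state: %s is %s at %s", id, state[[id]], hf_num(e$time)))
          d <- if (id %in% names(dmap)) dmap[[id]] else "idle"
          state[[id]] <- switch(d, attached = "attached", idle = "idle", "busy")
          # "return" stays busy until its resource_return event (same timestamp)
        }
      },
      resource_return = {
        for (id in ids) {
          if (!state[[id]] %in% c("busy", "attached", "reserved"))
            v <- c(v, sprintf("bad_return_state: %s is %s at %s", id, state[[id]], hf_num(e$time)))
          state[[id]] <- "in_transit"
          eta_to[[id]] <- e$to
          eta_at[[id]] <- e$eta
        }
      },
      modifier_applied = {
        if (identical(e$detail, "quarantine_area")) quarantined <- union(quarantined, e$area)
        if (identical(e$detail, "lift_quarantine")) quarantined <- setdiff(quarantined, e$area)
      },
      {})
  }
  v
}
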