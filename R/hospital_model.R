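#' Hospital area
#'
#' Areas host tasks and hold resource inventories. A deactivated (blocked)
#' area cannot execute tasks but may still lend resources out (e.g. a local
#' blackout); a quarantined area freezes everything inside it. `min_stock`
#' is the per-type floor below which the area will not lend.
#'
#' @param id,name Identifiers.
#' @param active,quarantined Initial flags.
#' @param min_stock Named list/vector: resource-type id -> minimum count.
#' @param on_call Marks the special area holding off-duty staff; transit to
#'   and from it uses the hospital's average travel time.
#' @return An object of class `hf_area`.
#' @export
hf_area <- function(id, name = id, active = TRUE, quarantined = FALSE,
                    min_stock = list(), on_call = FALSE) {
  structure(list(id = id, name = name, active = active,
                 quarantined = quarantined,
                 min_stock = as.list(min_stock), on_call = on_call),
            class = "hf_area")
}

#' Resource type
#'
#' Devices are stationary (CT, MRI) or portable; portable devices may be
#' attachable, i.e. remain with the patient across tasks. Staff are a
#' resource category of their own, grouped by skill class, and always
#' portable.
#'
#' @param id Identifier.
#' @param category `"device"` or `"staff"`.
#' @param mobility `"stationary"` or `"portable"`; staff must be portable.
#' @param skill_class Optional skill-class label (staff only).
#' @param attachable Portable devices that stay with the patient.
#' @return An object of class `hf_rtype`.
#' @export
hf_resource_type <- function(id, category = c("device", "staff"),
                             mobility = c("portable", "stationary"),
                             skill_class = NULL, attachable = FALSE) {
  category <- match.arg(category)
  mobility <- match.arg(mobility)
  if (category == "staff" && mobility != "portable")
    hf_stop("InvalidResourceType", "staff are portable (%s)", id)
  if (mobility == "stationary" && attachable)
    hf_stop("InvalidResourceType", "stationary types cannot be attachable (%s)", id)
  structure(list(id = id, category = category, mobility = mobility,
                 skill_class = skill_class, attachable = attachable),
            class = "hf_rtype")
}

#' Hospital configuration
#'
#' Combines areas, the directed inter-area transit matrix, resource types
#' and the per-area inventory. The inventory is expanded into individual
#' resource instances (`"<type>@<area>#<k>"`), each starting idle in its
#' home area.
#'
#' @param areas List of [hf_area()] objects.
#' @param transit Square numeric matrix of transit minutes with area ids as
#'   dimnames; the diagonal must be zero. Rows/columns for the on-call
#'   area, if present, should carry the hospital's average travel time.
#' @param resource_types List of [hf_resource_type()] objects.
#' @param inventory Data frame with columns `type_id`, `area_id`, `count`.
#' @return An object of class `hf_hospital`.
#' @export
hf_hospital <- function(areas, transit, resource_types, inventory) {
  names(areas) <- vapply(areas, function(a) a$id, "")
  names(resource_types) <- vapply(resource_types, function(r) r$id, "")
  if (sum(vapply(areas, function(a) isTRUE(a$on_call), TRUE)) > 1L)
    hf_stop("InvalidHospital", "at most one on_call area")
  aid <- names(areas)
  if (!identical(sort(rownames(transit)), sort(aid)) ||
      !identical(sort(colnames(transit)), sort(aid)))
    hf_stop("InvalidHospital", "transit matrix dimnames must equal the area ids")
  transit <- transit[aid, aid, drop = FALSE]
  if (any(diag(transit) != 0)) hf_stop("InvalidHospital", "transit diagonal must be 0")
  if (any(!is.finite(transit)) || any(transit < 0))
    hf_stop("InvalidHospital", "transit entries must be finite and >= 0")
  inventory <- as.data.frame(inventory, stringsAsFactors = FALSE)
  bad <- setdiff(inventory$type_id, names(resource_types))
  if (length(bad)) hf_stop("InvalidHospital", "inventory references unknown type(s): %s",
                           paste(bad, collapse = ", "))
  bad <- setdiff(inventory$area_id, aid)
  if (length(bad)) hf_stop("InvalidHospital", "inventory references unknown area(s): %s",
                           paste(bad, collapse = ", "))
  inst <- do.call(rbind, lapply(seq_len(nrow(inventory)), function(i) {
    r <- inventory[i, ]
    if (r$count < 1) return(NULL)
    data.frame(id = sprintf("%s@%s#%d", r$type_id, r$area_id, seq_len(r$count)),
               type_id = r$type_id, home_area = r$area_id,
               stringsAsFactors = FALSE)
  }))
  inst$location <- inst$home_area
  inst$state <- "idle"
  inst$efficiency_pct <- 100
  structure(list(areas = areas, transit = transit,
                 resource_types = resource_types,
                 inventory = inventory, instances = inst),
            class = "hf_hospital")
}

#' @export
print.hf_hospital <- function(x, ...) {
  cat(sprintf("<hf_hospital> %d areas, %d resource types, %d instances\n",
              length(x$areas), length(x$resource_types), nrow(x$instances)))
  invisible(x)
}

#' Time-scheduled scenario modifier
#'
#' Modifiers express the disruption being simulated and are applied at a
#' fixed simulation minute, with half-open effectivity: a change at minute
#' `t` affects everything starting at or after `t`; activities already in
#' flight finish under the old parameters.
#'
#' @param at_min Simulation minute at which the change takes effect.
#' @param kind One of `deactivate_area`, `reactivate_area`,
#'   `quarantine_area`, `lift_quarantine`, `set_transit`, `set_efficiency`,
#'   `resource_outage_start`, `resource_outage_end`.
#' @param target Area id, resource-type id, or `c(from, to)` area pair for
#'   `set_transit`.
#' @param value Minutes (`set_transit`) or percentage (`set_efficiency`).
#' @return An object of class `hf_modifier`.
#' @export
hf_modifier <- function(at_min, kind, target, value = NULL) {
  kinds <- c("deactivate_area", "reactivate_area", "quarantine_area",
             "lift_quarantine", "set_transit", "set_efficiency",
             "resource_outage_start", "resource_outage_end")
  if (!kind %in% kinds) hf_stop("InvalidModifier", "unknown modifier kind '%s'", kind)
  if (at_min < 0) hf_stop("InvalidModifier", "at_min must be >= 0")
  structure(list(at_min = as.numeric(at_min), kind = kind,
                 target = target, value = value),
            class = "hf_modifier")
}

#' Transit time between two areas
#'
#' Looks up the transit matrix entry, honouring any `set_transit` modifiers
#' effective at the query time (half-open: a change at minute t applies to
#' queries at >= t). The diagonal is always zero.
#'
#' @param transit Transit matrix (as in [hf_hospital()]).
#' @param a,b Area ids.
#' @param at Query time in minutes.
#' @param modifiers Optional list of [hf_modifier()] objects.
#' @return Minutes.
#' @export
transit_time <- function(transit, a, b, at = 0, modifiers = list()) {
  if (!a %in% rownames(transit)) hf_stop("UnknownArea", "unknown area '%s'", a)
  if (!b %in% colnames(transit)) hf_stop("UnknownArea", "unknown area '%s'", b)
  if (identical(a, b)) return(0)
  val <- transit[a, b]
  for (m in modifiers) {
    if (m$kind == "set_transit" && m$at_min <= at &&
        identical(m$target[1], a) && identical(m$target[2], b))
      val <- as.numeric(m$value)
  }
  val
}

#' Effective task duration under a resource efficiency
#'
#' Efficiency acts multiplicatively on duration: at 50% efficiency a task
#' takes twice its nominal time, at 200% half.
#'
#' @param nominal_min Nominal duration in minutes.
#' @param efficiency_pct Efficiency percentage (> 0).
#' @return Minutes.
#' @export
effective_duration <- function(nominal_min, efficiency_pct) {
  if (any(efficiency_pct <= 0))
    hf_stop("NonPositiveEfficiency", "efficiency must be > 0, got %s", efficiency_pct)
  nominal_min * 100 / efficiency_pct
}

#' Count of instances an area can lend
#'
#' Idle, non-attached, portable instances of a type located in the area,
#' above the area's minimum stock. Quarantined and inactive-for-lending
#' conditions: a quarantined area lends nothing; a merely deactivated
#' (blocked) area may still lend. Stationary types are never lendable.
#'
#' @param state A simulation state or `hf_hospital` (its `areas`,
#'   `resource_types`, `instances` are consulted).
#' @param area Area id.
#' @param type_id Resource-type id.
#' @return Non-negative integer.
#' @export
lendable_count <- function(state, area, type_id) {
  ar <- state$areas[[area]]
  if (is.null(ar)) hf_stop("UnknownArea", "unknown area '%s'", area)
  rt <- state$resource_types[[type_id]]
  if (is.null(rt) || rt$mobility == "stationary") return(0L)
  if (isTRUE(ar$quarantined)) return(0L)
  inst <- state$instances
  idle <- sum(inst$type_id == type_id & inst$location == area & inst$state == "idle")
  max(0L, idle - as.integer(ar$min_stock[[type_id]] %||% 0L))
}
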