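# Scenario round-trip: a scenario directory holds process.bpmn (BPMN 2.0
# XML), config.yaml (task metadata, hospital, groups, modifiers, seed,
# horizon) and cohort.csv. Fixture-generated scenarios serialize through
# the same writers that user data goes through.

hf_bpmn_ns <- "http://www.omg.org/spec/BPMN/20100524/MODEL"

#' Serialize a process graph to BPMN 2.0 XML
#'
#' Writes the supported subset (start/end event, task, exclusive and
#' parallel gateways, sequence flows with branch-label names). Task
#' metadata is not embedded; it travels in the sidecar config.
#'
#' @param graph An `hf_process`.
#' @param path Output file; if `NULL` the XML text is returned.
#' @return The XML text, invisibly when written to a file.
#' @export
write_bpmn <- function(graph, path = NULL) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<definitions xmlns="%s" targetNamespace="urn:hospflow">', hf_bpmn_ns),
    '  <process id="process_1">',
    sprintf('    <startEvent id="%s"/>', graph$start_id),
    sprintf('    <endEvent id="%s"/>', graph$end_id))
  for (t in graph$tasks)
    lines <- c(lines, sprintf('    <task id="%s" name="%s"/>', t$id, esc(t$name)))
  for (gid in names(graph$gateways)) {
    el <- if (startsWith(unname(graph$gateways[gid]), "exclusive"))
      "exclusiveGateway" else "parallelGateway"
    lines <- c(lines, sprintf('    <%s id="%s"/>', el, gid))
  }
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    nm <- if (is.na(e$label[i]) || !nzchar(e$label[i])) ""
          else sprintf(' name="%s"', esc(e$label[i]))
    lines <- c(lines, sprintf('    <sequenceFlow id="flow_%d" sourceRef="%s" targetRef="%s"%s/>',
                              i, e$from[i], e$to[i], nm))
  }
  lines <- c(lines, "  </process>", "</definitions>")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

hf_demand_to_list <- function(d) {
  out <- list(type_id = d$type_id, count = d$count, hold_mode = d$hold_mode,
              action = d$action)
  if (!is.null(d$sub_interval)) out$sub_interval <- as.list(d$sub_interval)
  out
}

#' Save a scenario to a directory
#'
#' Writes `process.bpmn`, `config.yaml` and `cohort.csv` so that
#' [load_scenario()] reconstructs an equal spec.
#'
#' @param spec An [hf_scenario()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_scenario <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bpmn(spec$graph, file.path(dir, "process.bpmn"))
  hosp <- spec$hospital
  cfg <- list(
    tasks = stats::setNames(lapply(spec$graph$tasks, function(t) list(
      name = t$name, area = t$area_id, duration_min = t$duration_min,
      demands = lapply(t$demands, hf_demand_to_list),
      group_durations = t$group_durations,
      ttd_delta_min = t$ttd_delta_min, ttr_delta_min = t$ttr_delta_min)),
      names(spec$graph$tasks)),
    redundant_groups = as.list(spec$graph$redundant_groups),
    areas = lapply(unname(hosp$areas), function(a) list(
      id = a$id, name = a$name, active = a$active, quarantined = a$quarantined,
      min_stock = a$min_stock, on_call = a$on_call)),
    transit = stats::setNames(lapply(rownames(hosp$transit), function(a)
      as.list(stats::setNames(as.numeric(hosp$transit[a, ]), colnames(hosp$transit)))),
      rownames(hosp$transit)),
    resource_types = lapply(unname(hosp$resource_types), function(r) list(
      id = r$id, category = r$category, mobility = r$mobility,
      skill_class = r$skill_class, attachable = r$attachable)),
    inventory = lapply(seq_len(nrow(hosp$inventory)), function(i) list(
      type_id = hosp$inventory$type_id[i], area_id = hosp$inventory$area_id[i],
      count = as.integer(hosp$inventory$count[i]))),
    groups = lapply(unname(spec$groups), function(g) list(
      id = g$id, ais_signature = as.integer(g$ais_signature),
      priority = g$priority,
      ttd_range_min = if (is.null(g$ttd_range_min)) NULL else as.numeric(g$ttd_range_min),
      ttr_range_min = if (is.null(g$ttr_range_min)) NULL else as.numeric(g$ttr_range_min),
      branch_labels = g$branch_labels)),
    modifiers = lapply(spec$modifiers, function(m) list(
      at_min = m$at_min, kind = m$kind, target = as.character(m$target),
      value = m$value)),
    seed = spec$seed, horizon_min = spec$horizon_min)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  co <- spec$cohort
  for (j in seq_along(co)) if (is.double(co[[j]]))
    co[[j]] <- sprintf("%.17g", co[[j]])  # lossless double round-trip
  utils::write.csv(co, file.path(dir, "cohort.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Load a scenario from a directory
#'
#' Reads `process.bpmn`, `config.yaml` and `cohort.csv` back into an
#' [hf_scenario()]. Cross-reference problems (unknown areas, resource
#' types, groups) are collected and reported together in a single
#' `ConfigError`.
#'
#' @param dir Scenario directory written by [save_scenario()].
#' @return An `hf_scenario`.
#' @export
load_scenario <- function(dir) {
  need <- file.path(dir, c("process.bpmn", "config.yaml", "cohort.csv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) hf_stop("ConfigError", "missing file(s): %s", paste(miss, collapse = ", "))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  task_meta <- lapply(cfg$tasks, function(t) list(
    name = t$name, area = t$area, duration_min = t$duration_min,
    demands = lapply(t$demands, function(d) {
      if (!is.null(d$sub_interval)) d$sub_interval <- as.numeric(unlist(d$sub_interval))
      d
    }),
    group_durations = t$group_durations,
    ttd_delta_min = t$ttd_delta_min, ttr_delta_min = t$ttr_delta_min))
  graph <- parse_bpmn(file.path(dir, "process.bpmn"), task_meta,
                      redundant_groups = unlist(cfg$redundant_groups) %||% character())

  errs <- character()
  area_ids <- vapply(cfg$areas, function(a) a$id, "")
  type_ids <- vapply(cfg$resource_types, function(r) r$id, "")
  for (t in graph$tasks)
    if (!is.na(t$area_id) && !t$area_id %in% area_ids)
      errs <- c(errs, sprintf("task %s references unknown area '%s'", t$id, t$area_id))
  for (t in graph$tasks) for (d in t$demands)
    if (!d$type_id %in% type_ids)
      errs <- c(errs, sprintf("task %s demands unknown resource type '%s'", t$id, d$type_id))
  for (iv in cfg$inventory) {
    if (!iv$area_id %in% area_ids)
      errs <- c(errs, sprintf("inventory references unknown area '%s'", iv$area_id))
    if (!iv$type_id %in% type_ids)
      errs <- c(errs, sprintf("inventory references unknown resource type '%s'", iv$type_id))
  }
  if (length(errs)) hf_stop("ConfigError", "configuration errors:\n- %s",
                            paste(errs, collapse = "\n- "))

  areas <- lapply(cfg$areas, function(a)
    hf_area(a$id, a$name %||% a$id, a$active %||% TRUE, a$quarantined %||% FALSE,
            a$min_stock %||% list(), a$on_call %||% FALSE))
  tm <- matrix(0, length(area_ids), length(area_ids),
               dimnames = list(area_ids, area_ids))
  for (a in names(cfg$transit)) for (b in names(cfg$transit[[a]]))
    tm[a, b] <- as.numeric(cfg$transit[[a]][[b]])
  rtypes <- lapply(cfg$resource_types, function(r)
    hf_resource_type(r$id, r$category, r$mobility, r$skill_class, r$attachable %||% FALSE))
  inv <- do.call(rbind, lapply(cfg$inventory, function(i)
    data.frame(type_id = i$type_id, area_id = i$area_id, count = i$count,
               stringsAsFactors = FALSE)))
  hosp <- hf_hospital(areas, tm, rtypes, inv)
  groups <- lapply(cfg$groups, function(g)
    injury_group(g$id, ais_profile(unlist(g$ais_signature)), g$priority %||% 0L,
                 if (is.null(g$ttd_range_min)) NULL else as.numeric(unlist(g$ttd_range_min)),
                 if (is.null(g$ttr_range_min)) NULL else as.numeric(unlist(g$ttr_range_min)),
                 g$branch_labels %||% list()))
  mods <- lapply(cfg$modifiers, function(m)
    hf_modifier(m$at_min, m$kind, unlist(m$target), m$value))
  cohort <- utils::read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  hf_scenario(graph, hosp, groups, cohort, mods,
              seed = cfg$seed %||% NA_integer_,
              horizon_min = cfg$horizon_min %||% 1e5)
}

#' Write an event log as JSON lines
#'
#' One event per line with a stable field order, suitable for diffing:
#' identically configured runs produce byte-identical files.
#'
#' @param result An `hf_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(result, path) {
  ev <- result$events
  con <- file(path, open = "wb")  # binary: fixed \n on every platform
  on.exit(close(con))
  for (i in seq_len(nrow(ev))) {
    row <- lapply(ev[i, , drop = FALSE], function(x) x[[1]])
    row <- Filter(function(x) !(length(x) == 1 && is.na(x)) &&
                    !(is.character(x) && !nzchar(x)), row)
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA, na = "null"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Write per-patient outcomes and a run summary as CSV
#'
#' `patients.csv` carries one row per patient; `summary.csv` has the fixed
#' columns `patients`, `completed`, `damaged`, `removed`,
#' `mean_duration_min`, `mean_delay_min`, `max_delay_min`.
#'
#' @param result An `hf_result`.
#' @param dir Output directory.
#' @param baselines Optional baseline vector; when given, delays are
#'   included.
#' @return `dir`, invisibly.
#' @export
write_result_csv <- function(result, dir, baselines = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- result$patients
  mean_delay <- NA_real_; max_delay <- NA_real_
  if (!is.null(baselines)) {
    ind <- compute_indicators(result, baselines)
    p <- ind$per_patient
    mean_delay <- ind$mean_delay_min; max_delay <- ind$max_delay_min
  }
  utils::write.csv(p, file.path(dir, "patients.csv"), row.names = FALSE)
  s <- data.frame(patients = nrow(p),
                  completed = sum(p$status == "completed"),
                  damaged = sum(p$damaged), removed = sum(p$removed),
                  mean_duration_min = mean(p$duration_min[p$status == "completed"]),
                  mean_delay_min = mean_delay, max_delay_min = max_delay)
  utils::write.csv(s, file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a sweep table as CSV
#'
#' @param sweep An `hf_sweep` or the data frame from
#'   [run_emergency_plan_comparison()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  tab <- if (inherits(sweep, "hf_sweep")) sweep$table else sweep
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
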