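#' Resource demand of a task
#'
#' Describes one resource requirement of a task: how many instances of a
#' resource type are needed, for how much of the task they are held, and
#' whether the task merely uses the resource or attaches/detaches it to or
#' from the patient (e.g. a mobile ventilator that stays with the patient
#' from intubation until surgery).
#'
#' @param type_id Resource type identifier.
#' @param count Number of instances required (>= 1).
#' @param hold_mode Either `"full_task"` (the instance is held for the whole
#'   task; the simplified timing mode) or `"sub_interval"` (held only for a
#'   window inside the task; the fine-grained timing mode).
#' @param sub_interval Numeric `c(offset_min, length_min)`, required when
#'   `hold_mode = "sub_interval"`.
#' @param action `"use"`, `"attach"` or `"detach"`.
#' @return An object of class `hf_demand`.
#' @export
resource_demand <- function(type_id, count = 1L,
                            hold_mode = c("full_task", "sub_interval"),
                            sub_interval = NULL,
                            action = c("use", "attach", "detach")) {
  hold_mode <- match.arg(hold_mode)
  action <- match.arg(action)
  if (!hf_is_id(type_id)) hf_stop("InvalidDemand", "type_id must be a single non-empty string")
  if (!is.numeric(count) || count < 1) hf_stop("InvalidDemand", "count must be >= 1")
  if (hold_mode == "sub_interval") {
    if (is.null(sub_interval) || length(sub_interval) != 2L || any(sub_interval < 0))
      hf_stop("InvalidDemand", "sub_interval needs c(offset, length) >= 0")
  } else if (!is.null(sub_interval)) {
    hf_stop("InvalidDemand", "sub_interval only allowed with hold_mode='sub_interval'")
  }
  structure(list(type_id = type_id, count = as.integer(count),
                 hold_mode = hold_mode,
                 sub_interval = if (is.null(sub_interval)) NULL else as.numeric(sub_interval),
                 action = action),
            class = "hf_demand")
}

#' Task node of a process
#'
#' A task binds a process step to an area, a default duration in minutes,
#' a list of resource demands, optional per-injury-group duration
#' overrides, and optional therapy effects that extend a patient's
#' time-till-damage (TTD) and time-to-reanimation (TTR) deadlines when the
#' task completes (e.g. stopping heavy bleeding extends both; an x-ray
#' extends neither).
#'
#' @param id,name Identifiers; `name` defaults to `id`.
#' @param area_id Area in which the task executes.
#' @param duration_min Default duration in minutes (>= 0).
#' @param demands List of [resource_demand()] objects.
#' @param group_durations Named list/vector: injury-group id -> duration
#'   override in minutes.
#' @param ttd_delta_min,ttr_delta_min Minutes added to the patient's TTD /
#'   TTR deadline when this task completes.
#' @return An object of class `hf_task`.
#' @export
task_node <- function(id, area_id, duration_min, name = id,
                      demands = list(), group_durations = list(),
                      ttd_delta_min = 0, ttr_delta_min = 0) {
  if (!hf_is_id(id)) hf_stop("InvalidTask", "task id must be a single non-empty string")
  if (!is.numeric(duration_min) || duration_min < 0)
    hf_stop("InvalidTask", "duration_min must be >= 0 (task %s)", id)
  gd <- as.list(group_durations)
  if (length(gd) && any(unlist(gd) < 0))
    hf_stop("InvalidTask", "group duration overrides must be >= 0 (task %s)", id)
  for (d in demands) {
    if (!inherits(d, "hf_demand")) hf_stop("InvalidTask", "demands must be hf_demand objects")
    if (d$hold_mode == "sub_interval" &&
        d$sub_interval[1] + d$sub_interval[2] > duration_min)
      hf_stop("InvalidTask", "sub_interval exceeds task duration (task %s)", id)
  }
  structure(list(id = id, name = name, area_id = area_id,
                 duration_min = as.numeric(duration_min),
                 demands = demands, group_durations = gd,
                 ttd_delta_min = as.numeric(ttd_delta_min),
                 ttr_delta_min = as.numeric(ttr_delta_min)),
            class = "hf_task")
}

#' Process graph
#'
#' A clinical process: one start event, one end event, tasks and gateways
#' in between connected by sequence flows. Exclusive gateways branch
#' conditionally on the patient's injury group (edge labels are matched
#' against group ids; an unlabeled edge is the default branch). Parallel
#' gateways fork/join concurrent blocks. Exclusive splits listed in
#' `redundant_groups` are redundant alternatives: the simulation picks the
#' branch with the smallest estimated time to completion instead of
#' matching labels.
#'
#' @param tasks List of [task_node()] objects.
#' @param edges Data frame with columns `from`, `to` and optional `label`.
#' @param gateways Named character vector: gateway id -> kind, one of
#'   `exclusive_split`, `exclusive_join`, `parallel_split`, `parallel_join`.
#' @param start_id,end_id Ids of the start and end event nodes.
#' @param redundant_groups Character vector of exclusive-split gateway ids
#'   whose outgoing branches are redundant alternatives.
#' @return An object of class `hf_process`.
#' @export
process_graph <- function(tasks, edges, gateways = character(),
                          start_id = "start", end_id = "end",
                          redundant_groups = character()) {
  names(tasks) <- vapply(tasks, function(t) t$id, "")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$label)) edges$label <- NA_character_
  edges <- edges[, c("from", "to", "label")]
  structure(list(tasks = tasks, edges = edges,
                 gateways = gateways, start_id = start_id, end_id = end_id,
                 redundant_groups = redundant_groups),
            class = "hf_process")
}

#' @export
print.hf_process <- function(x, ...) {
  cat(sprintf("<hf_process> %d tasks, %d gateways, %d edges\n",
              length(x$tasks), length(x$gateways), nrow(x$edges)))
  invisible(x)
}

hf_out_edges <- function(graph, id) which(graph$edges$from == id)
hf_in_edges <- function(graph, id) which(graph$edges$to == id)
hf_node_kind <- function(graph, id) {
  if (id == graph$start_id) return("start")
  if (id == graph$end_id) return("end")
  if (id %in% names(graph$tasks)) return("task")
  if (id %in% names(graph$gateways)) return(unname(graph$gateways[id]))
  "unknown"
}

#' Parse a BPMN 2.0 document into a process graph
#'
#' Reads the supported BPMN subset — `process`, `startEvent`, `endEvent`,
#' `task`, `exclusiveGateway`, `parallelGateway`, `sequenceFlow` — and
#' merges sidecar task metadata (area, duration, demands, deadline deltas)
#' by task id. Gateway direction (split vs join) is inferred from the
#' degree. Sequence-flow `name` attributes become branch labels.
#'
#' @param document BPMN 2.0 XML as a string or file path.
#' @param task_meta Named list keyed by BPMN task id. Each entry may have
#'   `area`, `duration_min`, `demands` (list of lists with the
#'   [resource_demand()] fields), `group_durations`, `ttd_delta_min`,
#'   `ttr_delta_min`.
#' @param strict If `TRUE` (default) unsupported BPMN elements raise a
#'   `MalformedProcess` error; otherwise they are skipped with a warning.
#' @param redundant_groups Passed through to [process_graph()].
#' @return An `hf_process`.
#' @export
parse_bpmn <- function(document, task_meta = list(), strict = TRUE,
                       redundant_groups = character()) {
  doc <- if (is.character(document) && length(document) == 1L &&
             !grepl("<", document, fixed = TRUE) && file.exists(document)) {
    xml2::read_xml(document)
  } else xml2::read_xml(document)

  procs <- xml2::xml_find_all(doc, ".//*[local-name()='process']")
  if (length(procs) != 1L)
    hf_stop("MalformedProcess", "document must contain exactly one process element (found %d)",
            length(procs))
  proc <- procs[[1]]

  kids <- xml2::xml_children(proc)
  supported <- c("startEvent", "endEvent", "task", "exclusiveGateway",
                 "parallelGateway", "sequenceFlow")
  starts <- character(); ends <- character(); task_ids <- character()
  gw <- character(); gw_kind <- character()
  ef <- character(); et <- character(); el <- character()
  for (k in kids) {
    nm <- xml2::xml_name(k)
    id <- xml2::xml_attr(k, "id")
    if (!nm %in% supported) {
      if (strict) hf_stop("MalformedProcess", "unsupported BPMN element <%s> in strict mode", nm)
      warning(sprintf("ignoring unsupported BPMN element <%s>", nm))
      next
    }
    switch(nm,
      startEvent = { starts <- c(starts, id) },
      endEvent = { ends <- c(ends, id) },
      task = { task_ids <- c(task_ids, id) },
      exclusiveGateway = { gw <- c(gw, id); gw_kind <- c(gw_kind, "exclusive") },
      parallelGateway = { gw <- c(gw, id); gw_kind <- c(gw_kind, "parallel") },
      sequenceFlow = {
        ef <- c(ef, xml2::xml_attr(k, "sourceRef"))
        et <- c(et, xml2::xml_attr(k, "targetRef"))
        el <- c(el, xml2::xml_attr(k, "name"))
      })
  }
  if (length(starts) != 1L)
    hf_stop("MalformedProcess", "expected exactly one startEvent, found %d", length(starts))
  if (length(ends) != 1L)
    hf_stop("MalformedProcess", "expected exactly one endEvent, found %d", length(ends))

  unknown_meta <- setdiff(names(task_meta), task_ids)
  if (length(unknown_meta))
    hf_stop("MalformedProcess", "task metadata for unknown id(s): %s",
            paste(unknown_meta, collapse = ", "))

  tasks <- lapply(task_ids, function(id) {
    m <- task_meta[[id]] %||% list()
    dem <- lapply(m$demands %||% list(), function(d) {
      if (inherits(d, "hf_demand")) d else do.call(resource_demand, d)
    })
    task_node(id = id,
              area_id = m$area %||% NA_character_,
              duration_min = m$duration_min %||% 0,
              name = m$name %||% id,
              demands = dem,
              group_durations = m$group_durations %||% list(),
              ttd_delta_min = m$ttd_delta_min %||% 0,
              ttr_delta_min = m$ttr_delta_min %||% 0)
  })

  # split/join from degree
  gateways <- character()
  for (i in seq_along(gw)) {
    outd <- sum(ef == gw[i]); ind <- sum(et == gw[i])
    kind <- if (outd > 1L && ind <= 1L) "split"
            else if (ind > 1L && outd <= 1L) "join"
            else if (strict) hf_stop("MalformedProcess", "ambiguous gateway degree at %s", gw[i])
            else "split"
    gateways[gw[i]] <- paste0(gw_kind[i], "_", kind)
  }

  process_graph(tasks = tasks,
                edges = data.frame(from = ef, to = et, label = el,
                                   stringsAsFactors = FALSE),
                gateways = gateways,
                start_id = starts, end_id = ends,
                redundant_groups = redundant_groups)
}

#' Validate a process graph
#'
#' Checks the structural invariants of a process graph: reachability from
#' the start event, co-reachability of the end event, balanced parallel
#' blocks (every parallel split reconverges in a single parallel join
#' common to all branches), redundant groups naming real exclusive splits,
#' tasks having an area, and detach demands naming a type attached
#' somewhere upstream in the graph.
#'
#' Violations are returned as data, not raised: an empty character vector
#' means the graph is valid.
#'
#' @param graph An `hf_process`.
#' @return Character vector of `"rule: id"` violation records.
#' @export
validate_process <- function(graph) {
  v <- character()
  ids <- c(graph$start_id, graph$end_id, names(graph$tasks), names(graph$gateways))
  bad_ref <- setdiff(unique(c(graph$edges$from, graph$edges$to)), ids)
  for (b in bad_ref) v <- c(v, sprintf("unknown_node: %s", b))
  if (length(bad_ref)) return(v)

  reach_from <- function(seed, forward = TRUE) {
    seen <- seed; frontier <- seed
    while (length(frontier)) {
      nxt <- if (forward) graph$edges$to[graph$edges$from %in% frontier]
             else graph$edges$from[graph$edges$to %in% frontier]
      frontier <- setdiff(unique(nxt), seen)
      seen <- c(seen, frontier)
    }
    seen
  }
  fwd <- reach_from(graph$start_id, TRUE)
  bwd <- reach_from(graph$end_id, FALSE)
  for (id in setdiff(ids, c(fwd, graph$start_id)))
    v <- c(v, sprintf("unreachable: %s", id))
  for (id in setdiff(ids, c(bwd, graph$end_id)))
    v <- c(v, sprintf("no_path_to_end: %s", id))

  for (gid in names(graph$gateways)) {
    if (graph$gateways[gid] == "parallel_split") {
      jn <- tryCatch(hf_matching_join(graph, gid), error = function(e) NULL)
      if (is.null(jn)) v <- c(v, sprintf("unbalanced_parallel: %s", gid))
    }
  }

  for (rg in graph$redundant_groups) {
    if (!identical(unname(graph$gateways[rg]), "exclusive_split"))
      v <- c(v, sprintf("redundant_not_exclusive_split: %s", rg))
  }

  attachable_seen <- unlist(lapply(graph$tasks, function(t)
    vapply(Filter(function(d) d$action == "attach", t$demands),
           function(d) d$type_id, "")))
  for (t in graph$tasks) {
    if (is.na(t$area_id)) v <- c(v, sprintf("missing_area: %s", t$id))
    for (d in t$demands) {
      if (d$action == "detach" && !d$type_id %in% attachable_seen)
        v <- c(v, sprintf("detach_without_attach: %s/%s", t$id, d$type_id))
    }
  }
  v
}

# Matching parallel_join of a split: each branch is walked with a nesting
# counter (nested splits increment, joins decrement), following the first
# outgoing edge at inner splits; all branches must end at the same join.
hf_matching_join <- function(graph, split) {
  walk_to_join <- function(node) {
    depth <- 0L; steps <- 0L
    repeat {
      steps <- steps + 1L
      if (steps > 10000L) hf_stop("MalformedProcess", "cycle while matching parallel join")
      kind <- hf_node_kind(graph, node)
      if (kind == "parallel_join") {
        if (depth == 0L) return(node)
        depth <- depth - 1L
      } else if (kind == "parallel_split") {
        depth <- depth + 1L
      } else if (kind == "end") {
        return(NULL)
      } else if (kind == "unknown") {
        return(NULL)
      }
      outs <- graph$edges$to[graph$edges$from == node]
      if (!length(outs)) return(NULL)
      node <- outs[1]
    }
  }
  joins <- lapply(graph$edges$to[hf_out_edges(graph, split)], walk_to_join)
  if (any(vapply(joins, is.null, TRUE))) hf_stop("MalformedProcess", "no join for %s", split)
  ujoins <- unique(unlist(joins))
  if (length(ujoins) != 1L) hf_stop("MalformedProcess", "branches of %s reach different joins", split)
  ujoins
}

# Resolve the outgoing edge of an exclusive split for a group.
# Order: explicit choice (edge label or target id) > edge labeled with the
# group id (labels may hold comma-separated group lists) > unlabeled default.
hf_resolve_branch <- function(graph, split, group_id, branch_choices = list()) {
  outs <- graph$edges[hf_out_edges(graph, split), , drop = FALSE]
  choice <- branch_choices[[split]]
  if (!is.null(choice)) {
    hit <- which(outs$label == choice | outs$to == choice)
    if (!length(hit)) hf_stop("UnresolvedBranch", "choice '%s' not a branch of %s", choice, split)
    return(outs$to[hit[1]])
  }
  labs <- strsplit(ifelse(is.na(outs$label), "", outs$label), ",[ ]*")
  hit <- which(vapply(labs, function(l) group_id %in% l, TRUE))
  if (length(hit)) return(outs$to[hit[1]])
  dflt <- which(is.na(outs$label) | outs$label == "")
  if (length(dflt)) return(outs$to[dflt[1]])
  hf_stop("UnresolvedBranch", "no branch of %s matches group %s", split, group_id)
}

#' Nominal path duration of a group through a process
#'
#' The expected processing time without any delay ("best pathway"): the sum
#' of effective task durations (per-group override when configured) plus
#' inter-area transit times along the path the group takes, with a parallel
#' block contributing the maximum over its branches. No queueing, no
#' modifiers, no resource contention. The patient is assumed to start in
#' the area of the first task on the path.
#'
#' @param graph An `hf_process`.
#' @param group_id Injury-group id used for duration overrides and branch
#'   conditions.
#' @param hospital An `hf_hospital` (supplies the transit matrix).
#' @param branch_choices Named list split-id -> branch label/target,
#'   resolving redundant splits (and overriding conditional ones).
#' @return Duration in minutes.
#' @export
nominal_path_duration <- function(graph, group_id, hospital,
                                  branch_choices = list()) {
  walk <- function(node, loc, stop_at) {
    total <- 0
    repeat {
      if (!is.null(stop_at) && node == stop_at)
        return(list(min = total, loc = loc, node = node))
      kind <- hf_node_kind(graph, node)
      if (kind == "end") return(list(min = total, loc = loc, node = node))
      if (kind == "task") {
        t <- graph$tasks[[node]]
        dur <- t$group_durations[[group_id]] %||% t$duration_min
        if (!is.null(loc) && !identical(loc, t$area_id))
          total <- total + transit_time(hospital$transit, loc, t$area_id)
        loc <- t$area_id
        total <- total + dur
        node <- hf_next_single(graph, node)
      } else if (kind %in% c("start", "exclusive_join", "parallel_join")) {
        node <- hf_next_single(graph, node)
      } else if (kind == "exclusive_split") {
        if (node %in% graph$redundant_groups && is.null(branch_choices[[node]]))
          hf_stop("UnresolvedBranch", "redundant split %s needs a branch choice", node)
        node <- hf_resolve_branch(graph, node, group_id, branch_choices)
      } else if (kind == "parallel_split") {
        join <- hf_matching_join(graph, node)
        outs <- graph$edges$to[hf_out_edges(graph, node)]
        branches <- lapply(outs, function(b) walk(b, loc, join))
        sums <- vapply(branches, function(b) b$min, 0)
        best <- which.max(sums)  # ties: first declared, matching the engine
        total <- total + sums[best]
        loc <- branches[[best]]$loc
        node <- hf_next_single(graph, join)
      } else {
        hf_stop("MalformedProcess", "cannot traverse node %s (%s)", node, kind)
      }
    }
  }
  walk(graph$start_id, NULL, NULL)$min
}

hf_next_single <- function(graph, node) {
  outs <- graph$edges$to[hf_out_edges(graph, node)]
  if (length(outs) != 1L)
    hf_stop("MalformedProcess", "node %s must have exactly one outgoing edge", node)
  outs
}
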