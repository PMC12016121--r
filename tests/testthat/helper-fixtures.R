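# Shared helpers: tiny hand-built processes and a random-process generator
# whose durations are dyadic rationals (k/4 minutes), so path sums are
# exact in floating point and closed-form comparisons are exact.

one_group <- function(id = "g1", ...) {
  injury_group(id, ais_profile(c(1, 0, 0, 0, 0, 0, 0, 0, 0)), ...)
}

# A single-area hospital with `count` instances of one portable type.
tiny_hospital <- function(count = 1L, areas = "A", transit = NULL,
                          inventory = NULL, min_stock = list()) {
  if (is.null(transit)) {
    transit <- matrix(0, length(areas), length(areas),
                      dimnames = list(areas, areas))
  }
  if (is.null(inventory))
    inventory <- data.frame(type_id = "res", area_id = areas[1], count = count)
  hf_hospital(
    areas = lapply(areas, function(a) hf_area(a, min_stock = min_stock)),
    transit = transit,
    resource_types = list(hf_resource_type("res", "device", "portable")),
    inventory = inventory)
}

# Linear process: one task per duration, all in `area`, each demanding one
# "res" unless demands = FALSE.
linear_process <- function(durations, area = "A", demands = TRUE,
                           ttd_deltas = NULL, ttr_deltas = NULL) {
  n <- length(durations)
  ids <- sprintf("T%d", seq_len(n))
  tasks <- lapply(seq_len(n), function(i)
    task_node(ids[i], area_id = if (length(area) > 1) area[i] else area,
              duration_min = durations[i],
              demands = if (isTRUE(demands)) list(resource_demand("res")) else list(),
              ttd_delta_min = if (is.null(ttd_deltas)) 0 else ttd_deltas[i],
              ttr_delta_min = if (is.null(ttr_deltas)) 0 else ttr_deltas[i]))
  process_graph(tasks,
                edges = data.frame(from = c("start", ids), to = c(ids, "end")),
                start_id = "start", end_id = "end")
}

solo_cohort <- function(t_start = 0, ttd = NA_real_, ttr = NA_real_,
                        group = "g1", id = "p001") {
  data.frame(patient_id = id, group_id = group, t_start_min = t_start,
             ttd_min = ttd, ttr_min = ttr, stringsAsFactors = FALSE)
}

# Random small process: a chain of segments, each either a task or a
# 2-branch parallel block, over up to 3 areas with plentiful local
# resources (no queueing, no lending for a single patient).
random_small_process <- function(n_tasks_max = 8, n_parallel_max = 2) {
  areas <- c("A1", "A2", "A3")
  dy <- function() sample(4:40, 1) / 4   # dyadic duration
  n_parallel <- sample(0:n_parallel_max, 1)
  budget <- sample(max(2, 2 * n_parallel):n_tasks_max, 1)
  tasks <- list(); edges <- NULL; gateways <- character()
  tid <- 0; new_task <- function() {
    tid <<- tid + 1
    id <- sprintf("T%d", tid)
    tasks[[id]] <<- task_node(id, area_id = sample(areas, 1),
                              duration_min = dy(),
                              demands = if (stats::runif(1) < 0.7)
                                list(resource_demand("res")) else list())
    id
  }
  add_edge <- function(from, to)
    edges <<- rbind(edges, data.frame(from = from, to = to,
                                      label = NA_character_))
  cur <- "start"; used <- 0; blocks <- 0
  while (used < budget) {
    if (blocks < n_parallel && budget - used >= 2 && stats::runif(1) < 0.4) {
      blocks <- blocks + 1
      sp <- sprintf("PS%d", blocks); jn <- sprintf("PJ%d", blocks)
      gateways[sp] <- "parallel_split"; gateways[jn] <- "parallel_join"
      add_edge(cur, sp)
      for (b in 1:2) {
        len <- sample(1:min(2, budget - used), 1)
        prev <- sp
        for (k in seq_len(len)) { id <- new_task(); add_edge(prev, id); prev <- id; used <- used + 1 }
        add_edge(prev, jn)
      }
      cur <- jn
    } else {
      id <- new_task(); add_edge(cur, id); cur <- id; used <- used + 1
    }
  }
  add_edge(cur, "end")
  graph <- process_graph(tasks, edges, gateways, "start", "end")
  tm <- matrix(sample(0:6, 9, replace = TRUE), 3, 3, dimnames = list(areas, areas))
  diag(tm) <- 0
  hosp <- hf_hospital(
    areas = lapply(areas, hf_area), transit = tm,
    resource_types = list(hf_resource_type("res", "device", "portable")),
    inventory = data.frame(type_id = "res", area_id = areas, count = 50L))
  list(graph = graph, hospital = hosp)
}

etr_fixture_cached <- local({
  fx <- NULL
  function(seed = 1L) {
    if (is.null(fx)) fx <<- build_etr_fixture(seed)
    fx
  }
})
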