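two_patient_cohort <- function(t2 = 0) {
  rbind(solo_cohort(id = "p001"), solo_cohort(t_start = t2, id = "p002"))
}

test_that("two same-priority patients contending for one instance complete at 10 and 20", {
  g <- linear_process(10)
  spec <- hf_scenario(g, tiny_hospital(1L), list(one_group()), two_patient_cohort())
  res <- simulate_scenario(spec)
  expect_equal(sort(res$patients$completion_min), c(10, 20))
  # FIFO: first-arrived (by id tie-break) completes first
  expect_equal(res$patients$completion_min[res$patients$patient_id == "p001"], 10)
  expect_equal(audit_log(res), character())
})

test_that("borrowed resources delay the task start by exactly the transit time", {
  tm <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  hosp <- tiny_hospital(areas = c("A", "B"), transit = tm,
                        inventory = data.frame(type_id = "res", area_id = "B",
                                               count = 1L))
  g <- linear_process(10, area = "A")
  spec <- hf_scenario(g, hosp, list(one_group()), solo_cohort())
  res <- simulate_scenario(spec)
  starts <- res$events[res$events$kind == "task_start", ]
  expect_equal(starts$time, 5)                     # grant at 0 + transit 5
  expect_equal(res$patients$completion_min, 15)
  disp <- res$events[res$events$kind == "resource_dispatch", ]
  expect_equal(disp$from, "B"); expect_equal(disp$to, "A")
  ret <- res$events[res$events$kind == "resource_return", ]
  expect_equal(ret$time, 15)                       # returns right after task end
  expect_equal(audit_log(res), character())
})

test_that("lending picks the closest lender and never breaks min stock", {
  areas <- c("A", "B", "C")
  tm <- matrix(c(0, 5, 8,
                 5, 0, 9,
                 8, 9, 0), 3, 3, byrow = TRUE, dimnames = list(areas, areas))
  hosp <- hf_hospital(
    areas = list(hf_area("A"), hf_area("B"), hf_area("C", min_stock = list(res = 1))),
    transit = tm,
    resource_types = list(hf_resource_type("res", "device", "portable")),
    inventory = data.frame(type_id = "res", area_id = c("B", "C"), count = c(1L, 2L)))
  g <- linear_process(10, area = "A")
  spec <- hf_scenario(g, hosp, list(one_group()), solo_cohort())
  res <- simulate_scenario(spec)
  disp <- res$events[res$events$kind == "resource_dispatch", ]
  expect_equal(disp$from, "B")  # transit 5 beats 8
  expect_equal(audit_log(res), character())

  # demand 2: second instance must come from C but only 1 is above min stock
  g2 <- process_graph(list(task_node("T1", "A", 10,
                                     demands = list(resource_demand("res", 2)))),
                      edges = data.frame(from = c("start", "T1"), to = c("T1", "end")))
  res2 <- simulate_scenario(hf_scenario(g2, hosp, list(one_group()), solo_cohort()))
  disp2 <- res2$events[res2$events$kind == "resource_dispatch", ]
  expect_setequal(disp2$from, c("B", "C"))
  expect_equal(sum(disp2$from == "C"), 1)
  expect_equal(audit_log(res2), character())
})

test_that("higher-priority patients are served first at a shared queue", {
  g <- linear_process(10)
  groups <- list(one_group("lo", priority = 1L),
                 injury_group("hi", ais_profile(c(2, rep(0, 8))), priority = 5L))
  co <- rbind(
    data.frame(patient_id = "p_lo", group_id = "lo", t_start_min = 0,
               ttd_min = NA_real_, ttr_min = NA_real_),
    data.frame(patient_id = "p_hi", group_id = "hi", t_start_min = 0,
               ttd_min = NA_real_, ttr_min = NA_real_))
  res <- simulate_scenario(hf_scenario(g, tiny_hospital(1L), groups, co))
  p <- res$patients
  expect_lt(p$completion_min[p$patient_id == "p_hi"],
            p$completion_min[p$patient_id == "p_lo"])
})

test_that("with one resource and equal priorities completion order equals arrival order", {
  g <- linear_process(3)
  set.seed(5)
  arr <- sort(round(stats::runif(6, 0, 4), 2))
  co <- do.call(rbind, lapply(seq_along(arr), function(i)
    solo_cohort(t_start = arr[i], id = sprintf("p%03d", i))))
  res <- simulate_scenario(hf_scenario(g, tiny_hospital(1L), list(one_group()), co))
  p <- res$patients[order(res$patients$t_start_min), ]
  expect_true(all(diff(p$completion_min) > 0))
  expect_equal(audit_log(res), character())
})

test_that("attached devices move with the patient and are unavailable to others", {
  tm <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  hosp <- hf_hospital(
    areas = list(hf_area("A"), hf_area("B")),
    transit = tm,
    resource_types = list(hf_resource_type("vent", "device", "portable",
                                           attachable = TRUE)),
    inventory = data.frame(type_id = "vent", area_id = "A", count = 1L))
  g <- process_graph(
    tasks = list(
      task_node("T1", "A", 5, demands = list(resource_demand("vent", action = "attach"))),
      task_node("T2", "B", 6),
      task_node("T3", "B", 2, demands = list(resource_demand("vent", action = "detach")))),
    edges = data.frame(from = c("start", "T1", "T2", "T3"),
                       to = c("T1", "T2", "T3", "end")))
  co <- rbind(solo_cohort(id = "p001"), solo_cohort(t_start = 1, id = "p002"))
  res <- simulate_scenario(hf_scenario(g, hosp, list(one_group()), co))
  ev <- res$events
  # p001: attach during T1 [0,5], transit 4, T2 [9,15], T3 [15,17], then return 4
  p1_done <- ev[ev$kind == "patient_completed" & ev$patient == "p001", "time"]
  expect_equal(p1_done, 17)
  ret <- ev[ev$kind == "resource_return" & grepl("vent", ev$instances), ]
  expect_equal(ret$time[1], 17)          # detach at T3 end, in area B
  expect_equal(ret$eta[1], 21)           # 4 min back home
  # p002 could only start T1 after the ventilator was home again
  p2_start <- min(ev[ev$kind == "task_start" & ev$patient == "p002", "time"])
  expect_equal(p2_start, 21)
  expect_equal(audit_log(res), character())
})

test_that("detaching in the home area frees the instance immediately", {
  hosp <- hf_hospital(
    areas = list(hf_area("A")),
    transit = matrix(0, 1, 1, dimnames = list("A", "A")),
    resource_types = list(hf_resource_type("vent", "device", "portable",
                                           attachable = TRUE)),
    inventory = data.frame(type_id = "vent", area_id = "A", count = 1L))
  g <- process_graph(
    tasks = list(
      task_node("T1", "A", 5, demands = list(resource_demand("vent", action = "attach"))),
      task_node("T2", "A", 3, demands = list(resource_demand("vent", action = "detach")))),
    edges = data.frame(from = c("start", "T1", "T2"), to = c("T1", "T2", "end")))
  co <- rbind(solo_cohort(id = "p001"), solo_cohort(id = "p002"))
  res <- simulate_scenario(hf_scenario(g, hosp, list(one_group()), co))
  p <- res$patients
  expect_equal(sort(p$completion_min), c(8, 16))  # zero return transit
  expect_equal(audit_log(res), character())
})

test_that("redundant splits are chosen by estimated time including backlog", {
  # branches: short (15 min, needs "ct") vs long (20 min, needs nothing)
  mk_graph <- function() process_graph(
    tasks = list(
      task_node("SHORT", "A", 15, demands = list(resource_demand("ct"))),
      task_node("LONG", "A", 20),
      task_node("PRE", "A", 40, demands = list(resource_demand("ct")))),
    edges = data.frame(
      from = c("start", "s0", "s0", "PRE", "s1", "s1", "SHORT", "LONG", "j1"),
      to = c("s0", "PRE", "s1", "s1", "SHORT", "LONG", "j1", "j1", "end"),
      label = c(NA, "blocker", NA, NA, NA, NA, NA, NA, NA)),
    gateways = c(s0 = "exclusive_split", s1 = "exclusive_split",
                 j1 = "exclusive_join"),
    redundant_groups = "s1")
  hosp <- hf_hospital(
    areas = list(hf_area("A")),
    transit = matrix(0, 1, 1, dimnames = list("A", "A")),
    resource_types = list(hf_resource_type("ct", "device", "stationary")),
    inventory = data.frame(type_id = "ct", area_id = "A", count = 1L))
  grp <- list(one_group("g1"), one_group("blocker"))

  # idle scanner: 15 < 20, short branch wins
  res <- simulate_scenario(hf_scenario(mk_graph(), hosp, grp, solo_cohort()))
  expect_match(res$patients$path, "SHORT")
  expect_equal(res$patients$duration_min, 15)

  # blocker occupies the scanner for 40 min first: 15 + 40 > 20, long branch wins
  co <- rbind(
    data.frame(patient_id = "p000", group_id = "blocker", t_start_min = 0,
               ttd_min = NA_real_, ttr_min = NA_real_),
    data.frame(patient_id = "p001", group_id = "g1", t_start_min = 1,
               ttd_min = NA_real_, ttr_min = NA_real_))
  res2 <- simulate_scenario(hf_scenario(mk_graph(), hosp, grp, co))
  p1 <- res2$patients[res2$patients$patient_id == "p001", ]
  expect_match(p1$path, "LONG")
  expect_equal(p1$duration_min, 20)
})

test_that("equal redundant estimates fall back to the first-declared branch", {
  g <- process_graph(
    tasks = list(task_node("B1", "A", 10), task_node("B2", "A", 10)),
    edges = data.frame(from = c("start", "s1", "s1", "B1", "B2"),
                       to = c("s1", "B1", "B2", "end", "end")),
    gateways = c(s1 = "exclusive_split"),
    redundant_groups = "s1")
  res <- simulate_scenario(hf_scenario(g, tiny_hospital(5L), list(one_group()),
                                       solo_cohort()))
  expect_equal(res$patients$path, "B1")
})

test_that("sub-interval holds release the resource before the task ends", {
  g <- process_graph(
    tasks = list(task_node("T1", "A", 10, demands = list(
      resource_demand("res", hold_mode = "sub_interval", sub_interval = c(2, 3))))),
    edges = data.frame(from = c("start", "T1"), to = c("T1", "end")))
  co <- rbind(solo_cohort(id = "p001"), solo_cohort(id = "p002"))
  res <- simulate_scenario(hf_scenario(g, tiny_hospital(1L), list(one_group()), co))
  # p001 holds res over [0, 5); p002's task can start at 5, not 10
  starts <- res$events[res$events$kind == "task_start", ]
  expect_equal(sort(starts$time), c(0, 5))
  expect_equal(sort(res$patients$completion_min), c(10, 15))
  expect_equal(audit_log(res), character())
})

test_that("in-flight tasks keep their duration when efficiency changes mid-task", {
  g <- linear_process(10)
  spec <- hf_scenario(g, tiny_hospital(), list(one_group()), solo_cohort(),
                      modifiers = list(hf_modifier(5, "set_efficiency", "res", 50)))
  res <- simulate_scenario(spec)
  expect_equal(res$patients$duration_min, 10)  # started before the change
})
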