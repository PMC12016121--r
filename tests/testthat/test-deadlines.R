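# Deadline semantics: TTD marks damage without stopping the patient, TTR
# removes the patient and releases resources, therapy deltas push pending
# deadline events.

test_that("TTR removal fires at the exact effective deadline and releases resources", {
  g <- linear_process(10)
  spec <- hf_scenario(g, tiny_hospital(1L), list(one_group()),
                      solo_cohort(t_start = 2, ttr = 5),
                      modifiers = list(
                        hf_modifier(0, "resource_outage_start", "res"),
                        hf_modifier(60, "resource_outage_end", "res")))
  res <- simulate_scenario(spec)
  p <- res$patients
  expect_equal(p$status, "removed_reanimation")
  expect_true(p$removed)
  expect_true(is.na(p$completion_min))
  ttr_ev <- res$events[res$events$kind == "ttr_hit", ]
  expect_equal(ttr_ev$time, 7)  # t_start 2 + TTR 5
  expect_equal(audit_log(res), character())
})

test_that("mid-task TTR removal frees the instance for the next patient", {
  g <- linear_process(30)
  co <- rbind(solo_cohort(id = "p001", ttr = 10),
              solo_cohort(id = "p002"))
  res <- simulate_scenario(hf_scenario(g, tiny_hospital(1L), list(one_group()), co))
  p <- res$patients
  expect_true(p$removed[p$patient_id == "p001"])
  # p002 starts right at the removal instant, not after p001's 30 min
  expect_equal(p$completion_min[p$patient_id == "p002"], 40)
  expect_equal(audit_log(res), character())
})

test_that("TTD marks damage but the patient continues to completion", {
  g <- linear_process(c(10, 10), demands = FALSE)
  spec <- hf_scenario(g, tiny_hospital(), list(one_group()),
                      solo_cohort(ttd = 15))
  res <- simulate_scenario(spec)
  p <- res$patients
  expect_true(p$damaged)
  expect_equal(p$status, "completed")
  expect_equal(p$completion_min, 20)
  expect_equal(res$events[res$events$kind == "ttd_hit", "time"], 15)
})

test_that("a completed patient never logs a late ttd_hit", {
  g <- linear_process(10, demands = FALSE)
  res <- simulate_scenario(hf_scenario(g, tiny_hospital(), list(one_group()),
                                       solo_cohort(ttd = 60)))
  expect_false(any(res$events$kind == "ttd_hit"))
  expect_false(res$patients$damaged)
})

test_that("therapy deltas applied at task completion move pending deadline events", {
  # T1 ends at 40 with +30 TTD; old deadline 65 moves to 95, inside T2
  g <- linear_process(c(40, 60), demands = FALSE, ttd_deltas = c(30, 0))
  res <- simulate_scenario(hf_scenario(g, tiny_hospital(), list(one_group()),
                                       solo_cohort(ttd = 65)))
  ttd_ev <- res$events[res$events$kind == "ttd_hit", ]
  expect_equal(ttd_ev$time, 95)
  expect_true(res$patients$damaged)

  # with a shorter second task the pushed deadline is never reached
  g2 <- linear_process(c(40, 50), demands = FALSE, ttd_deltas = c(30, 0))
  res2 <- simulate_scenario(hf_scenario(g2, tiny_hospital(), list(one_group()),
                                        solo_cohort(ttd = 65)))
  expect_false(any(res2$events$kind == "ttd_hit"))
  expect_false(res2$patients$damaged)
})

test_that("TTR deltas also delay removal", {
  # without the delta the patient dies at 50 during T2; the +30 from T1 saves it
  g <- linear_process(c(40, 35), demands = FALSE, ttr_deltas = c(30, 0))
  res <- simulate_scenario(hf_scenario(g, tiny_hospital(), list(one_group()),
                                       solo_cohort(ttr = 50)))
  expect_equal(res$patients$status, "completed")
  g0 <- linear_process(c(40, 35), demands = FALSE)
  res0 <- simulate_scenario(hf_scenario(g0, tiny_hospital(), list(one_group()),
                                        solo_cohort(ttr = 50)))
  expect_equal(res0$patients$status, "removed_reanimation")
  expect_equal(res0$events[res0$events$kind == "ttr_hit", "time"], 50)
})

test_that("a removed patient holding an attachment sends it home at removal time", {
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
      task_node("T2", "B", 30),
      task_node("T3", "B", 2, demands = list(resource_demand("vent", action = "detach")))),
    edges = data.frame(from = c("start", "T1", "T2", "T3"),
                       to = c("T1", "T2", "T3", "end")))
  res <- simulate_scenario(hf_scenario(g, hosp, list(one_group()),
                                       solo_cohort(ttr = 20)))
  # removal at 20, during T2 in area B; the ventilator starts home immediately
  ret <- res$events[res$events$kind == "resource_return", ]
  expect_equal(ret$time, 20)
  expect_equal(ret$eta, 24)
  expect_equal(res$resources$state, "idle")
  expect_equal(res$resources$location, "A")
  expect_equal(audit_log(res), character())
})
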