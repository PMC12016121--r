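bpmn_doc <- function(body) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<definitions xmlns="http://www.omg.org/spec/BPMN/20100524/MODEL">\n',
         '<process id="p1">\n', body, '\n</process>\n</definitions>')
}

test_that("parse_bpmn maps a minimal document with sidecar metadata", {
  doc <- bpmn_doc(paste(
    '<startEvent id="start"/>', '<endEvent id="end"/>',
    '<task id="T1" name="triage"/>',
    '<sequenceFlow id="f1" sourceRef="start" targetRef="T1"/>',
    '<sequenceFlow id="f2" sourceRef="T1" targetRef="end"/>', sep = "\n"))
  g <- parse_bpmn(doc, list(T1 = list(area = "ETR", duration_min = 10)))
  expect_length(g$tasks, 1)
  expect_equal(g$tasks$T1$duration_min, 10)
  expect_equal(g$tasks$T1$area_id, "ETR")
  expect_equal(validate_process(g), character())
})

test_that("parse_bpmn rejects malformed documents", {
  two_starts <- bpmn_doc(paste(
    '<startEvent id="s1"/>', '<startEvent id="s2"/>', '<endEvent id="e"/>',
    '<task id="T1"/>',
    '<sequenceFlow id="f1" sourceRef="s1" targetRef="T1"/>',
    '<sequenceFlow id="f2" sourceRef="T1" targetRef="e"/>', sep = "\n"))
  expect_error(parse_bpmn(two_starts), class = "MalformedProcess")
  unknown_meta <- bpmn_doc(paste(
    '<startEvent id="s"/>', '<endEvent id="e"/>', '<task id="T1"/>',
    '<sequenceFlow id="f1" sourceRef="s" targetRef="T1"/>',
    '<sequenceFlow id="f2" sourceRef="T1" targetRef="e"/>', sep = "\n"))
  expect_error(parse_bpmn(unknown_meta, list(TX = list(duration_min = 1))),
               class = "MalformedProcess")
  odd_element <- bpmn_doc(paste(
    '<startEvent id="s"/>', '<endEvent id="e"/>',
    '<intermediateThrowEvent id="x"/>', '<task id="T1"/>',
    '<sequenceFlow id="f1" sourceRef="s" targetRef="T1"/>',
    '<sequenceFlow id="f2" sourceRef="T1" targetRef="e"/>', sep = "\n"))
  expect_error(parse_bpmn(odd_element, strict = TRUE), class = "MalformedProcess")
  expect_warning(g <- parse_bpmn(odd_element, strict = FALSE), "ignoring")
  expect_length(g$tasks, 1)
})

test_that("parse_bpmn reconstructs a parallel block equal to a hand-built graph", {
  doc <- bpmn_doc(paste(
    '<startEvent id="start"/>', '<endEvent id="end"/>',
    '<task id="T1"/>', '<task id="T2"/>',
    '<parallelGateway id="ps"/>', '<parallelGateway id="pj"/>',
    '<sequenceFlow id="f1" sourceRef="start" targetRef="ps"/>',
    '<sequenceFlow id="f2" sourceRef="ps" targetRef="T1"/>',
    '<sequenceFlow id="f3" sourceRef="ps" targetRef="T2"/>',
    '<sequenceFlow id="f4" sourceRef="T1" targetRef="pj"/>',
    '<sequenceFlow id="f5" sourceRef="T2" targetRef="pj"/>',
    '<sequenceFlow id="f6" sourceRef="pj" targetRef="end"/>', sep = "\n"))
  meta <- list(T1 = list(area = "A", duration_min = 10),
               T2 = list(area = "A", duration_min = 20))
  g <- parse_bpmn(doc, meta)
  expect_equal(unname(g$gateways["ps"]), "parallel_split")
  expect_equal(unname(g$gateways["pj"]), "parallel_join")
  hand <- process_graph(
    tasks = list(task_node("T1", "A", 10), task_node("T2", "A", 20)),
    edges = data.frame(from = c("start", "ps", "ps", "T1", "T2", "pj"),
                       to = c("ps", "T1", "T2", "pj", "pj", "end")),
    gateways = c(ps = "parallel_split", pj = "parallel_join"))
  hosp <- tiny_hospital()
  expect_identical(sort(g$edges$to[g$edges$from == "ps"]),
                   sort(hand$edges$to[hand$edges$from == "ps"]))
  expect_equal(nominal_path_duration(g, "g1", hosp),
               nominal_path_duration(hand, "g1", hosp))
})

test_that("validate_process reports violations as data", {
  fx <- etr_fixture_cached()
  expect_equal(validate_process(fx$graph), character())

  orphan <- process_graph(
    tasks = list(task_node("T1", "A", 5), task_node("T2", "A", 5)),
    edges = data.frame(from = c("start", "T1"), to = c("T1", "end")))
  v <- validate_process(orphan)
  expect_true(any(grepl("unreachable: T2", v)))

  unbalanced <- process_graph(
    tasks = list(task_node("T1", "A", 5), task_node("T2", "A", 5)),
    edges = data.frame(from = c("start", "ps", "ps", "T1", "T2"),
                       to = c("ps", "T1", "T2", "end", "end")),
    gateways = c(ps = "parallel_split"))
  v <- validate_process(unbalanced)
  expect_true(any(grepl("unbalanced_parallel: ps", v)))
  # validation is idempotent: a second pass yields the identical list
  expect_identical(v, validate_process(unbalanced))
})

test_that("nominal_path_duration follows durations, transit, max-parallel and overrides", {
  hosp1 <- tiny_hospital()
  expect_equal(nominal_path_duration(linear_process(10), "g1", hosp1), 10)

  # two areas, transit 5 between them
  tm <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  hosp2 <- tiny_hospital(areas = c("A", "B"), transit = tm)
  g2 <- linear_process(c(10, 20), area = c("A", "B"))
  expect_equal(nominal_path_duration(g2, "g1", hosp2), 35)

  par <- process_graph(
    tasks = list(task_node("T1", "A", 10), task_node("T2", "A", 20)),
    edges = data.frame(from = c("start", "ps", "ps", "T1", "T2", "pj"),
                       to = c("ps", "T1", "T2", "pj", "pj", "end")),
    gateways = c(ps = "parallel_split", pj = "parallel_join"))
  expect_equal(nominal_path_duration(par, "g1", hosp1), 20)

  ovr <- process_graph(
    tasks = list(task_node("T1", "A", 10, group_durations = list(g1 = 12))),
    edges = data.frame(from = c("start", "T1"), to = c("T1", "end")))
  expect_equal(nominal_path_duration(ovr, "g1", hosp1), 12)
  expect_equal(nominal_path_duration(ovr, "g2", hosp1), 10)
})

test_that("nominal duration is additive over concatenation and invariant to relabeling", {
  hosp <- tiny_hospital()
  d1 <- c(2.5, 7.25); d2 <- c(3.75, 1.5, 4.25)
  g12 <- linear_process(c(d1, d2))
  expect_equal(nominal_path_duration(g12, "g1", hosp),
               nominal_path_duration(linear_process(d1), "g1", hosp) +
                 nominal_path_duration(linear_process(d2), "g1", hosp))
  relabeled <- linear_process(c(d1, d2))
  names(relabeled$tasks) <- NULL
  relabeled$tasks <- lapply(relabeled$tasks, function(t) { t$id <- paste0("X", t$id); t })
  names(relabeled$tasks) <- vapply(relabeled$tasks, function(t) t$id, "")
  relabeled$edges$from <- ifelse(relabeled$edges$from == "start", "start",
                                 paste0("X", relabeled$edges$from))
  relabeled$edges$to <- ifelse(relabeled$edges$to == "end", "end",
                               paste0("X", relabeled$edges$to))
  expect_equal(nominal_path_duration(relabeled, "g1", hosp),
               nominal_path_duration(g12, "g1", hosp))
})

test_that("greedy per-split redundant choice achieves the brute-force minimum", {
  # two redundant splits in sequence, 2 branches each
  mk <- function(d) task_node(d[1], "A", as.numeric(d[2]))
  tasks <- lapply(list(c("A1", 7), c("A2", 9), c("B1", 4), c("B2", 12)), mk)
  edges <- data.frame(
    from = c("start", "s1", "s1", "A1", "A2", "j1", "s2", "s2", "B1", "B2", "j2"),
    to = c("s1", "A1", "A2", "j1", "j1", "s2", "B1", "B2", "j2", "j2", "end"))
  g <- process_graph(tasks, edges,
                     gateways = c(s1 = "exclusive_split", j1 = "exclusive_join",
                                  s2 = "exclusive_split", j2 = "exclusive_join"),
                     redundant_groups = c("s1", "s2"))
  hosp <- tiny_hospital()
  choices <- expand.grid(s1 = c("A1", "A2"), s2 = c("B1", "B2"),
                         stringsAsFactors = FALSE)
  all_vals <- apply(choices, 1, function(ch)
    nominal_path_duration(g, "g1", hosp, branch_choices = as.list(ch)))
  greedy <- nominal_path_duration(g, "g1", hosp,
                                  branch_choices = list(s1 = "A1", s2 = "B1"))
  expect_equal(greedy, min(all_vals))
  expect_equal(greedy, 11)
})

test_that("unresolved redundant splits raise UnresolvedBranch", {
  g <- process_graph(
    tasks = list(task_node("A1", "A", 5), task_node("A2", "A", 6)),
    edges = data.frame(from = c("start", "s1", "s1", "A1", "A2"),
                       to = c("s1", "A1", "A2", "end", "end"),
                       label = c(NA, "x", "y", NA, NA)),
    gateways = c(s1 = "exclusive_split"),
    redundant_groups = "s1")
  expect_error(nominal_path_duration(g, "g1", tiny_hospital()),
               class = "UnresolvedBranch")
})
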