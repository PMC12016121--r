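#' AIS injury profile
#'
#' The Abbreviated Injury Scale rates nine body regions on a 0-6 severity
#' scale (0 = uninjured, 1 = Minor ... 6 = Maximum, i.e. currently
#' untreatable). Patients with identical region-wise ratings form an
#' injury group.
#'
#' @param severities Named or unnamed integer vector of length 9 in the
#'   canonical region order: Head, Face, Neck, Thorax, Abdomen, Spine,
#'   UpperExtremity, LowerExtremity, External.
#' @return An object of class `hf_ais` (named integer vector).
#' @export
ais_profile <- function(severities) {
  regions <- c("Head", "Face", "Neck", "Thorax", "Abdomen", "Spine",
               "UpperExtremity", "LowerExtremity", "External")
  s <- as.integer(severities)
  if (length(s) != 9L) hf_stop("InvalidAIS", "AIS profile needs exactly 9 regions")
  if (any(s < 0L | s > 6L)) hf_stop("InvalidAIS", "AIS severities must be in [0, 6]")
  names(s) <- regions
  structure(s, class = "hf_ais")
}

#' Injury group
#'
#' Patients are treated as agents of an injury group: a set of patients
#' with equivalent AIS ratings sharing path, durations, priority and
#' deadline ranges. TTD (time till damage) is the minutes until a patient
#' takes irreversible damage if untreated — reaching it marks the process
#' failed for that patient, who nevertheless continues. TTR (time to
#' reanimate) is the minutes until cardio-pulmonary resuscitation is
#' required — reaching it removes the patient from the simulation.
#'
#' @param id Group identifier.
#' @param ais_signature An [ais_profile()].
#' @param priority Integer; larger means treated first.
#' @param ttd_range_min,ttr_range_min `c(lo, hi)` minutes, or `NULL` if the
#'   deadline is not configured for this group.
#' @param branch_labels Named list split-id -> branch label, overriding
#'   edge-label matching for conditional splits.
#' @return An object of class `hf_group`.
#' @export
injury_group <- function(id, ais_signature, priority = 0L,
                         ttd_range_min = NULL, ttr_range_min = NULL,
                         branch_labels = list()) {
  for (r in list(ttd_range_min, ttr_range_min)) {
    if (!is.null(r) && (length(r) != 2L || r[1] > r[2] || any(r < 0)))
      hf_stop("InvalidGroup", "deadline range must be c(lo, hi) with 0 <= lo <= hi")
  }
  structure(list(id = id, ais_signature = ais_signature,
                 priority = as.integer(priority),
                 ttd_range_min = ttd_range_min, ttr_range_min = ttr_range_min,
                 branch_labels = as.list(branch_labels)),
            class = "hf_group")
}

#' Generate a patient cohort
#'
#' Draws each patient's TTD/TTR uniformly from its group's configured
#' range and its arrival time uniformly within its assigned arrival
#' window. Patients are generated group by group in the order of `groups`,
#' window slots assigned in window order, so the cohort is a pure function
#' of `(groups, counts, windows, seed)`.
#'
#' @param groups List of [injury_group()] objects.
#' @param counts Named integer vector/list: group id -> number of patients.
#' @param arrival_windows List of `c(lo_min, hi_min, n)` windows; the `n`
#'   must sum to the total patient count. Patients are assigned to windows
#'   round-robin across groups so each window gets a mix of groups.
#' @param seed Integer seed; required.
#' @return Data frame with columns `patient_id`, `group_id`, `t_start_min`,
#'   `ttd_min`, `ttr_min` and the nine `ais_*` severity columns.
#' @export
generate_patients <- function(groups, counts, arrival_windows, seed) {
  if (missing(seed)) hf_stop("CountMismatch", "seed is required")
  names(groups) <- vapply(groups, function(g) g$id, "")
  counts <- unlist(counts)
  n_total <- sum(counts)
  wins <- lapply(arrival_windows, as.numeric)
  if (sum(vapply(wins, function(w) w[3], 0)) != n_total)
    hf_stop("CountMismatch", "window sizes must sum to the total patient count (%d)", n_total)

  # interleave groups so every window holds a mix: g1,g2,...,g1,g2,...
  order_gid <- unlist(lapply(seq_len(max(counts)), function(k) {
    gids <- names(counts)[counts >= k]
    gids
  }))
  win_of <- rep(seq_along(wins), vapply(wins, function(w) w[3], 0))

  rng <- hf_rng(seed)
  rows <- lapply(seq_len(n_total), function(i) {
    g <- groups[[order_gid[i]]]
    w <- wins[[win_of[i]]]
    t0 <- rng$unif(w[1], w[2])
    ttd <- if (is.null(g$ttd_range_min)) NA_real_ else rng$unif(g$ttd_range_min[1], g$ttd_range_min[2])
    ttr <- if (is.null(g$ttr_range_min)) NA_real_ else rng$unif(g$ttr_range_min[1], g$ttr_range_min[2])
    sig <- as.integer(g$ais_signature)
    c(list(patient_id = sprintf("p%03d", i), group_id = g$id,
           t_start_min = t0, ttd_min = ttd, ttr_min = ttr),
      stats::setNames(as.list(sig), paste0("ais_", tolower(names(g$ais_signature)))))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# Self-contained uniform RNG stream (L'Ecuyer via base R, isolated so that
# cohort generation never perturbs or depends on the caller's RNG state).
hf_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister")
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  env$unif <- function(lo, hi) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- stats::runif(1, lo, hi)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    x
  }
  env
}

#' Classify an AIS profile into an injury group
#'
#' Group equivalence is exact region-wise match of the AIS signature. A
#' custom matcher can be supplied for coarser equivalences.
#'
#' @param profile An [ais_profile()].
#' @param groups List of [injury_group()] objects with distinct signatures.
#' @param matcher Function `(profile, signature) -> logical`; defaults to
#'   exact equality over the nine regions.
#' @return The matching group id.
#' @export
ais_classify <- function(profile, groups,
                         matcher = function(p, s) all(as.integer(p) == as.integer(s))) {
  for (g in groups) if (matcher(profile, g$ais_signature)) return(g$id)
  hf_stop("UnclassifiedPatient", "no group signature matches the profile")
}

#' Effective TTD/TTR deadlines of a patient
#'
#' Deadline clocks run in wall time from the patient's arrival — waiting,
#' transport and treatment all count — and are extended only by explicit
#' therapy deltas of completed tasks: `deadline = t_start + initial +
#' sum(deltas)`.
#'
#' @param t_start_min Arrival minute.
#' @param ttd_min,ttr_min Initial deadline offsets in minutes (`NA` if not
#'   configured).
#' @param completed_tasks List of [task_node()] objects (or a data frame
#'   with `ttd_delta_min`, `ttr_delta_min`) already completed.
#' @return Named numeric `c(ttd_abs_min =, ttr_abs_min =)`, `NA` where
#'   unconfigured.
#' @export
effective_deadlines <- function(t_start_min, ttd_min, ttr_min,
                                completed_tasks = list()) {
  dt <- sum(vapply(completed_tasks, function(t) t$ttd_delta_min, 0))
  dr <- sum(vapply(completed_tasks, function(t) t$ttr_delta_min, 0))
  c(ttd_abs_min = if (is.na(ttd_min)) NA_real_ else t_start_min + ttd_min + dt,
    ttr_abs_min = if (is.na(ttr_min)) NA_real_ else t_start_min + ttr_min + dr)
}
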