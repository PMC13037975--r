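#' @name trial_engine
#' @title Trial protocol execution
#' @description
#' Executes the dispatch-trial protocol on a synthetic cohort: 1:1
#' randomization of each comparison with a memory keyed on the member set
#' (so repeating an identical comparison returns the same arm), dispatcher
#' re-randomization with an added patient (the mechanism behind protocol
#' violations), arm-dependent dispatcher decisions, and participant-flow
#' accounting.
NULL

#' Create a randomization registry
#'
#' The registry remembers the arm assigned to each distinct member set so
#' that repeated randomizations of the same patients always receive the
#' same arm.
#'
#' @return An environment used by [randomize_rcs()].
#' @export
new_randomization_registry <- function() {
  new.env(parent = emptyenv())
}

#' Randomize one RCS to a study arm
#'
#' Assigns `control` or `intervention` with equal probability using the
#' current RNG stream. If the identical member set (compared as a sorted
#' set) was randomized before in the same registry, the prior arm is
#' returned instead of a fresh draw.
#'
#' @param member_ids Character vector of at least 2 member ids.
#' @param registry Registry from [new_randomization_registry()].
#' @return A list with `arm` and `repeat_of_same_set` (logical).
#' @export
randomize_rcs <- function(member_ids, registry) {
  if (length(member_ids) < 2L) {
    stop("an RCS requires at least 2 eligible members")
  }
  key <- paste(sort(member_ids), collapse = ";")
  if (!is.null(registry[[key]])) {
    return(list(arm = registry[[key]], repeat_of_same_set = TRUE))
  }
  arm <- if (stats::runif(1) < 0.5) "control" else "intervention"
  registry[[key]] <- arm
  list(arm = arm, repeat_of_same_set = FALSE)
}

#' Simulate the randomization-event log
#'
#' Walks the cohort's RCS in chronological order, randomizes each, and with
#' arm-dependent probability (`repeat_prob_control`,
#' `repeat_prob_intervention`) emulates a dispatcher re-rolling the
#' allocation by re-randomizing the comparison with one newly recruited
#' patient added. The grown member set is a different set, so it receives a
#' fresh 1:1 draw; when its arm differs from the original, both events will
#' later be excluded as protocol violations by [resolve_repeats()].
#'
#' @param cohort Output of [generate_cohort()].
#' @param config An [trial_config()] object.
#' @return A list with `events` (event log: `event_id`, `rcs_id`, `members`
#'   as a `";"`-joined id string, `arm`, `month`, `time`) and `patients`
#'   (the patient table, including any extra patients recruited during
#'   repeat randomizations).
#' @export
simulate_events <- function(cohort, config) {
  validate_config(config)
  seeds <- stage_seeds(config$seed)
  patients <- cohort$patients
  with_seed(seeds[["events"]], {
    rcs_ids <- unique(patients$rcs_id)
    month <- patients$month[match(rcs_ids, patients$rcs_id)]
    tm <- month + stats::runif(length(rcs_ids))  # within-month offset
    ord <- order(tm)
    registry <- new_randomization_registry()
    members_by_rcs <- split(patients$patient_id, patients$rcs_id)

    ev_members <- ev_arm <- ev_rcs <- character(0)
    ev_month <- integer(0)
    ev_time <- numeric(0)
    extras <- list()
    n_existing <- nrow(patients)
    for (i in ord) {
      rid <- rcs_ids[i]
      mem <- members_by_rcs[[rid]]
      r1 <- randomize_rcs(mem, registry)
      ev_rcs <- c(ev_rcs, rid)
      ev_members <- c(ev_members, paste(sort(mem), collapse = ";"))
      ev_arm <- c(ev_arm, r1$arm)
      ev_month <- c(ev_month, month[i])
      ev_time <- c(ev_time, tm[i])
      p_rep <- if (r1$arm == "control") config$repeat_prob_control else
        config$repeat_prob_intervention
      if (stats::runif(1) < p_rep) {
        extra <- draw_patients(1L, config, id_offset = n_existing)
        n_existing <- n_existing + 1L
        extra$rcs_id <- rid
        extra$month <- month[i]
        extras[[length(extras) + 1L]] <- extra
        mem2 <- c(mem, extra$patient_id)
        r2 <- randomize_rcs(mem2, registry)
        ev_rcs <- c(ev_rcs, rid)
        ev_members <- c(ev_members, paste(sort(mem2), collapse = ";"))
        ev_arm <- c(ev_arm, r2$arm)
        ev_month <- c(ev_month, month[i])
        ev_time <- c(ev_time, tm[i] + 1e-4)
      }
    }
    if (length(extras)) {
      patients <- rbind(patients, do.call(rbind, extras))
    }
    events <- data.frame(
      event_id = sprintf("E%05d", seq_along(ev_rcs)),
      rcs_id = ev_rcs, members = ev_members, arm = ev_arm,
      month = ev_month, time = ev_time, stringsAsFactors = FALSE)
    list(events = events, patients = patients)
  })
}

split_members <- function(members) strsplit(members, ";", fixed = TRUE)

#' Resolve repeated and overlapping randomizations
#'
#' Applies the protocol's exclusion rules to a time-ordered event log.
#' Events are grouped into connected components by shared members; within
#' a component:
#' \itemize{
#'   \item a single event is analyzable as-is;
#'   \item if all events carry the same arm (which is automatic for
#'     identical member sets), only the last is analyzable and earlier
#'     ones are marked `superseded`;
#'   \item if arms disagree (possible only when the member set changed
#'     between randomizations), every event in the component is excluded
#'     as a `violation`.
#' }
#' Superseded events are those where no ambulance was dispatched before the
#' members appeared in another randomization; together with violations they
#' form the protocol-exclusion count of the participant flow.
#'
#' @param events Event log from [simulate_events()] (or any data frame with
#'   `event_id`, `members`, `arm`, `time`).
#' @return The event log with a `status` column
#'   (`"analyzed"`, `"superseded"` or `"violation"`), plus attributes; use
#'   `subset(x, status == "analyzed")` for the analyzable set.
#' @export
resolve_repeats <- function(events) {
  ev <- events[order(events$time), , drop = FALSE]
  mem_list <- split_members(ev$members)
  # union-find over events sharing any member
  parent <- seq_len(nrow(ev))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  seen <- new.env(parent = emptyenv())  # patient id -> representative event
  for (i in seq_len(nrow(ev))) {
    for (p in mem_list[[i]]) {
      j <- seen[[p]]
      if (is.null(j)) {
        seen[[p]] <- i
      } else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(nrow(ev)), find, integer(1))
  status <- rep("analyzed", nrow(ev))
  for (grp in split(seq_len(nrow(ev)), comp)) {
    if (length(grp) == 1L) next
    arms <- unique(ev$arm[grp])
    if (length(arms) > 1L) {
      status[grp] <- "violation"
    } else {
      status[grp[-length(grp)]] <- "superseded"  # grp is time-ordered
    }
  }
  ev$status <- status
  ev[match(events$event_id, ev$event_id), , drop = FALSE]
}

#' Dispatcher decision for one comparison
#'
#' In the control arm the dispatcher (with the triaging nurses) prioritizes
#' the patient they perceive as sickest: the argmax of perceived acuity.
#' In the intervention arm the dispatcher defers to the model's top-ranked
#' patient with probability `compliance_prob` and otherwise falls back to
#' the nurse choice. Risk scores are computed (and the model top recorded)
#' in both arms, but only displayed in the intervention arm.
#'
#' @param member_ids Character vector of member ids.
#' @param arm `"control"` or `"intervention"`.
#' @param model_scores Named numeric composite scores for the members.
#' @param perceived Named numeric perceived acuities for the members.
#' @param compliance_prob Probability of deferring to the model.
#' @return A list with `prioritized_id`, `model_top_id`, `nurse_top_id` and
#'   `deferred` (logical).
#' @export
dispatcher_decision <- function(member_ids, arm, model_scores, perceived,
                                compliance_prob) {
  ms <- model_scores[member_ids]
  pv <- perceived[member_ids]
  argmax <- function(x) {   # seeded-uniform tie-break
    top <- which(x == max(x))
    if (length(top) > 1L) top <- sample(top, 1L)
    member_ids[top]
  }
  model_top <- argmax(ms)
  nurse_top <- argmax(pv)
  if (arm == "intervention" && stats::runif(1) < compliance_prob) {
    list(prioritized_id = model_top, model_top_id = model_top,
         nurse_top_id = nurse_top, deferred = TRUE)
  } else {
    list(prioritized_id = nurse_top, model_top_id = model_top,
         nurse_top_id = nurse_top, deferred = FALSE)
  }
}

#' Simulate dispatcher decisions for all analyzable events
#'
#' Draws one nurse perception per patient (latent acuity plus
#' `nurse_noise_sd` noise), applies [dispatcher_decision()] to every
#' analyzable event (with the deferral probability optionally drifting on
#' the logit scale by `compliance_drift_per_month`), classifies comparison
#' confidence by the median-gap rule calibrated on the run's own gaps, and
#' builds the dispatch log (prioritized patient assigned the first
#' ambulance; delayed members follow in random order with lognormal
#' delays).
#'
#' @param resolved Resolved event log from [resolve_repeats()].
#' @param patients Patient table.
#' @param predictions Prediction table from [synthetic_predictions()].
#' @param config An [trial_config()] object.
#' @return A list with `decisions` (one row per analyzable event) and
#'   `dispatch_log` (one row per dispatched ambulance), plus the gap
#'   `cutoff` used for confidence classification.
#' @export
simulate_decisions <- function(resolved, patients, predictions, config) {
  validate_config(config)
  seeds <- stage_seeds(config$seed)
  with_seed(seeds[["decisions"]], {
    keep <- resolved[resolved$status == "analyzed", , drop = FALSE]
    score <- stats::setNames(predictions$composite, predictions$patient_id)
    perceived <- stats::setNames(
      patients$latent_acuity + stats::rnorm(nrow(patients), 0, config$nurse_noise_sd),
      patients$patient_id)
    mem_list <- split_members(keep$members)
    gaps <- vapply(mem_list, function(m) top_two_gap(score[m]), numeric(1))
    cutoff <- calibrate_confidence_cutoff(gaps)
    confidence <- classify_confidence(gaps, cutoff)

    n <- nrow(keep)
    prioritized <- model_top <- nurse_top <- character(n)
    deferred <- logical(n)
    for (i in seq_len(n)) {
      c_eff <- stats::plogis(stats::qlogis(config$compliance_prob) +
                               config$compliance_drift_per_month * keep$month[i])
      d <- dispatcher_decision(mem_list[[i]], keep$arm[i], score, perceived, c_eff)
      prioritized[i] <- d$prioritized_id
      model_top[i] <- d$model_top_id
      nurse_top[i] <- d$nurse_top_id
      deferred[i] <- d$deferred
    }
    decisions <- data.frame(
      event_id = keep$event_id, rcs_id = keep$rcs_id, members = keep$members,
      arm = keep$arm, month = keep$month, prioritized_id = prioritized,
      model_top_id = model_top, nurse_top_id = nurse_top,
      deferred = deferred, gap = gaps, confidence = confidence,
      stringsAsFactors = FALSE)

    # dispatch log: prioritized first, delayed members in random order with
    # lognormal inter-dispatch delays (ordering is all that matters downstream)
    logs <- lapply(seq_len(n), function(i) {
      mem <- mem_list[[i]]
      delayed <- setdiff(mem, prioritized[i])
      if (length(delayed) > 1L) delayed <- sample(delayed)
      ids <- c(prioritized[i], delayed)
      t0 <- stats::rlnorm(1, log(30), 0.4)
      delays <- cumsum(c(t0, stats::rlnorm(length(delayed), log(25), 0.5)))
      data.frame(event_id = keep$event_id[i], rcs_id = keep$rcs_id[i],
                 patient_id = ids, dispatch_order = seq_along(ids),
                 dispatch_minutes = round(delays, 1), stringsAsFactors = FALSE)
    })
    list(decisions = decisions, dispatch_log = do.call(rbind, logs),
         cutoff = as.numeric(cutoff))
  })
}

#' Participant-flow (CONSORT-style) accounting
#'
#' Reconciles the event log into flow counts: randomized events, protocol
#' exclusions (superseded randomizations and arm-mismatch violations),
#' opt-out exclusions among the remaining events, and the analyzed set with
#' per-arm RCS and patient counts. Fails loudly if the counts do not
#' reconcile.
#'
#' @param resolved Resolved event log from [resolve_repeats()].
#' @param patients Patient table with the `optout` column filled in.
#' @return A list of class `rcs_flow` with the counts.
#' @export
consort_flow <- function(resolved, patients) {
  optout_ids <- patients$patient_id[patients$optout]
  keep <- resolved[resolved$status == "analyzed", , drop = FALSE]
  mem_list <- split_members(keep$members)
  has_optout <- vapply(mem_list, function(m) any(m %in% optout_ids), logical(1))
  analyzed <- keep[!has_optout, , drop = FALSE]
  an_members <- split_members(analyzed$members)
  arm_patients <- tapply(lengths(an_members), analyzed$arm, sum)
  flow <- list(
    randomized_rcs = nrow(resolved),
    protocol_violation_rcs = sum(resolved$status != "analyzed"),
    optout_excluded_rcs = sum(has_optout),
    analyzed_rcs = nrow(analyzed),
    analyzed_rcs_by_arm = table(analyzed$arm),
    analyzed_patients_by_arm = arm_patients,
    analyzed_patients = sum(lengths(an_members)))
  if (flow$analyzed_rcs !=
      flow$randomized_rcs - flow$protocol_violation_rcs - flow$optout_excluded_rcs) {
    stop("participant flow fails to reconcile")  # internal consistency error
  }
  class(flow) <- "rcs_flow"
  flow
}

#' @export
print.rcs_flow <- function(x, ...) {
  cat("Participant flow\n")
  cat(sprintf("  randomized events:        %d\n", x$randomized_rcs))
  cat(sprintf("  protocol exclusions:      %d\n", x$protocol_violation_rcs))
  cat(sprintf("  opt-out exclusions:       %d\n", x$optout_excluded_rcs))
  cat(sprintf("  analyzed RCS:             %d (control %d / intervention %d)\n",
              x$analyzed_rcs, x$analyzed_rcs_by_arm[["control"]],
              x$analyzed_rcs_by_arm[["intervention"]]))
  cat(sprintf("  analyzed patients:        %d\n", x$analyzed_patients))
  invisible(x)
}
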