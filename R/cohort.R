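# ---------------------------------------------------------------------------
# Cohort engine: decision tree (detection -> assessment -> strategy) feeding
# the cure-pathway Markov process with provider-dependent transitions.
#
# State layout (per unit cohort), all masses:
#   pools    nd, selfm, cont, stopped, imp_done, succ
#   arrivals a_gp, a_ns_init, a_ns_meds, a_ppt, a_spec_fresh, a_spec_ppt
#            (incontinent mass starting a treatment attempt this cycle)
#   queues   q_med_gp, q_med_ns, q_med_spec, q_train_ppt, q_train_ns
#            (improved mass receiving a continuation treatment this cycle)
#
# Timing convention: patients occupy the start-of-cycle state for the whole
# cycle (no half-cycle correction); treatment during cycle t changes the
# state from cycle t+1 on. Referral consumes no extra cycle: referred
# failures start their next attempt in the following cycle, and mass
# redirected within a provider node (specialist -> physiotherapist) is
# treated in the same cycle.
# ---------------------------------------------------------------------------

.act_cols <- c("assess_gp", "assess_ppt", "assess_ns",
               "gp_meds", "gp_life", "gp_uti", "gp_train", "medcont_gp",
               "ns_init", "ns_uti", "ns_meds", "medcont_ns", "traincont_ns",
               "ppt_pfmt", "ppt_bio", "train2_ppt",
               "spec_surg", "spec_cons", "spec_meds", "medcont_spec")

.occ_cols <- c("nd", "selfm", "cont", "stopped", "active", "improved", "succ")

# Structural wiring of the cure pathway where the source tables are silent.
# These are model choices, fixed once (see the methods vignette):
#  * ns_improver: what happens to patients improved after the initial
#    nurse-specialist programme ("train_once": one continuation cycle of
#    behavioural training with the second-cycle training effectiveness;
#    "medcont": medication-continuation rule; "none": retain improvement).
#  * train_repeat: whether training continuation repeats beyond the second
#    cycle for patients still (only) improved.
#  * referred_gp_node: whether failures referred back to the GP pass the
#    immediate-referral decision again (FALSE: the GP treats them directly).
.default_wiring <- function() {
  list(ns_improver = "train_once", train_repeat = FALSE,
       referred_gp_node = FALSE)
}

.norm <- function(x) {
  s <- sum(x)
  if (s <= 0) return(x * 0)
  x / s
}

# Arm- (and scenario-) level configuration of the engine.
.arm_config <- function(arm, ps, scenario = NULL) {
  arm <- match.arg(arm, c("current", "new"))
  v <- ps$values
  cur <- list(
    arm = "current",
    primary = "gp",              # wiring of the primary-care lane
    primary_consult = "gp",      # price of primary-care consultations
    detection = v[["detection_incident_current"]],
    strat = .norm(c(cure = v[["cur_strat_cure"]],
                    cont = v[["cur_strat_containment"]],
                    self = v[["cur_strat_self"]])),
    assess = .norm(c(gp = v[["cur_assess_gp"]], ppt = v[["cur_assess_ppt"]],
                     ns = 0)),
    pfmt_improvement = v[["ppt_pfmt_improvement_current"]],
    train2 = .norm(c(imp = v[["train2_improvement_current"]],
                     succ = v[["train2_success_current"]])),
    extra_detection = 0,
    reengage_self = FALSE,
    newly_detected_strat = NULL,   # cure/containment split for extra detection
    implementation = FALSE
  )
  if (arm == "current") return(cur)

  new <- list(
    arm = "new",
    primary = "ns",
    primary_consult = "ns",
    detection = v[["detection_incident_new"]],
    strat = .norm(c(cure = v[["new_strat_cure"]],
                    cont = v[["new_strat_containment"]],
                    self = v[["new_strat_self"]])),
    assess = c(gp = 0, ppt = 0, ns = 1),
    pfmt_improvement = v[["ppt_pfmt_improvement_new"]],
    train2 = .norm(c(imp = v[["train2_improvement_new"]],
                     succ = v[["train2_success_new"]])),
    extra_detection = v[["extra_detection_ns"]],
    reengage_self = TRUE,
    newly_detected_strat = .norm(c(cure = v[["new_strat_cure"]],
                                   cont = v[["new_strat_containment"]])),
    implementation = TRUE
  )
  if (is.null(scenario)) return(new)

  if (scenario == "detection_only") {
    # the NS finds and assesses patients (consultations at the NS tariff)
    # but care delivery and effectiveness are those of the usual pathway
    out <- cur
    out$arm <- "new"
    out$primary_consult <- "ns"
    out$detection <- new$detection
    out$assess <- c(gp = 0, ppt = 0, ns = 1)
    out$extra_detection <- new$extra_detection
    out$reengage_self <- FALSE
    out$newly_detected_strat <- .norm(c(cure = v[["cur_strat_cure"]],
                                        cont = v[["cur_strat_containment"]]))
    out$implementation <- TRUE
    return(out)
  }
  if (scenario == "effectiveness_only") {
    # NS-led treatment retained, detection stays at usual-care level
    out <- new
    out$detection <- cur$detection
    out$extra_detection <- 0
    out$reengage_self <- FALSE
    out$implementation <- TRUE
    return(out)
  }
  stop("unknown scenario: ", scenario, call. = FALSE)
}

#' Allocate an incident cohort over the decision tree
#'
#' Applies detection, initial assessment and the treatment-strategy split to
#' one unit of newly incident patients, returning the strategy allocation
#' (undetected / treatment for cure / containment only / self-management).
#'
#' @param arm `"current"` or `"new"`.
#' @param ps A `ui_params` object.
#' @return A list of class `ui_allocation` with the four strategy masses
#'   (summing to 1) plus provider routing for the first treatment cycle.
#' @examples
#' a <- allocate_incident_cohort("current", base_case_parameters())
#' a$undetected   # 0.496
#' @export
allocate_incident_cohort <- function(arm, ps) {
  allocate_incident_cohort_cfg(.arm_config(arm, ps))
}

# Build the initial engine state + cycle-1 arrivals from an allocation.
.init_state <- function(alloc, cfg, ps) {
  v <- ps$values
  st <- stats::setNames(numeric(17), c(
    "nd", "selfm", "cont", "stopped", "imp_done", "succ",
    "a_gp", "a_ns_init", "a_ns_meds", "a_ppt", "a_spec_fresh", "a_spec_ppt",
    "q_med_gp", "q_med_ns", "q_med_spec", "q_train_ppt", "q_train_ns"))
  st["nd"] <- alloc$undetected
  st["cont"] <- alloc$containment_only
  st["selfm"] <- alloc$self_management
  st["stopped"] <- alloc$stopped
  cure <- alloc$cure

  if (identical(alloc$cohort, "incident")) {
    if (cfg$primary == "gp") {
      # PPT-assessed incident cases go straight to the physiotherapist;
      # the rest start with a GP treatment attempt. The GP's
      # immediate-referral split takes effect for patients whose first
      # attempt fails (see the methods vignette on referral timing).
      m_ppt_assessed <- cure * cfg$assess[["ppt"]]
      st["a_ppt"] <- m_ppt_assessed
      st["a_gp"] <- cure - m_ppt_assessed
    } else {
      st["a_ns_init"] <- cure
    }
  } else {
    split <- .norm(c(v[["prev_provider_gp"]], v[["prev_provider_ppt"]],
                     v[["prev_provider_spec"]]))
    if (cfg$primary == "gp") {
      st["a_gp"] <- cure * split[1]
    } else {
      st["a_ns_init"] <- cure * split[1]
    }
    st["a_ppt"] <- st["a_ppt"] + cure * split[2]
    st["a_spec_fresh"] <- st["a_spec_fresh"] + cure * split[3]
  }
  st
}

# One cycle of the cure pathway. st: state vector entering the cycle.
# Returns list(state, act): state entering the next cycle and the activity
# row (treated masses / consult events) of this cycle.
.engine_step <- function(st, cfg, ps, wiring) {
  v <- ps$values
  act <- stats::setNames(numeric(length(.act_cols)), .act_cols)
  nxt <- st
  nxt[c("a_gp", "a_ns_init", "a_ns_meds", "a_ppt", "a_spec_fresh",
        "a_spec_ppt", "q_med_gp", "q_med_ns", "q_med_spec",
        "q_train_ppt", "q_train_ns")] <- 0

  add_primary <- function(m) {
    slot <- if (cfg$primary == "gp") "a_gp" else "a_ns_meds"
    nxt[slot] <<- nxt[slot] + m
  }
  p76 <- v[["med_second_cycle"]]
  refsplit_gp <- .norm(c(v[["gp_ref_ppt"]], v[["gp_ref_spec"]]))
  refsplit_ns <- .norm(c(v[["ns_ref_ppt"]], v[["ns_ref_spec"]]))
  refsplit_ppt <- .norm(c(v[["ppt_fail_to_gp"]], v[["ppt_fail_to_spec"]]))
  ns_fail <- .norm(c(cont = v[["ns_fail_continue"]],
                     ref = v[["ns_fail_referred"]]))

  ## specialist redirect: fresh arrivals without prior PFMT may be sent on
  to_ppt <- st[["a_spec_fresh"]] * v[["spec_to_ppt"]]
  spec_m <- st[["a_spec_fresh"]] - to_ppt + st[["a_spec_ppt"]]
  ppt_m <- st[["a_ppt"]] + to_ppt

  ## GP lane -----------------------------------------------------------------
  m <- st[["a_gp"]]
  if (m > 0) {
    if (wiring$referred_gp_node) {
      ref0 <- m * v[["gp_immediate_referral"]]
      ppt_m <- ppt_m + ref0 * refsplit_gp[1]          # treated this cycle
      spec_m <- spec_m + ref0 * refsplit_gp[2]
      m <- m - ref0
    }
    mix <- .norm(c(v[["gp_mix_meds"]], v[["gp_mix_lifestyle"]],
                   v[["gp_mix_uti"]], v[["gp_mix_training"]]))
    mm <- m * mix
    act[c("gp_meds", "gp_life", "gp_uti", "gp_train")] <- mm
    s <- mm[1] * v[["gp_meds_success"]] + mm[2] * v[["gp_lifestyle_success"]] +
      mm[3] * v[["gp_uti_success"]] + mm[4] * v[["gp_training_success"]]
    imp_med <- mm[1] * v[["gp_meds_improvement"]]
    imp_oth <- mm[2] * v[["gp_lifestyle_improvement"]] +
      mm[3] * v[["gp_uti_improvement"]] + mm[4] * v[["gp_training_improvement"]]
    fail <- m - s - imp_med - imp_oth
    nxt["succ"] <- nxt[["succ"]] + s
    nxt["q_med_gp"] <- nxt[["q_med_gp"]] + imp_med * p76
    nxt["imp_done"] <- nxt[["imp_done"]] + imp_med * (1 - p76) + imp_oth
    ref <- fail * v[["gp_immediate_referral"]]
    nxt["a_ppt"] <- nxt[["a_ppt"]] + ref * refsplit_gp[1]
    nxt["a_spec_fresh"] <- nxt[["a_spec_fresh"]] + ref * refsplit_gp[2]
    nxt["stopped"] <- nxt[["stopped"]] + fail - ref
  }

  ## NS initial programme ----------------------------------------------------
  m <- st[["a_ns_init"]]
  if (m > 0) {
    mix <- .norm(c(v[["ns_initial_share"]], v[["ns_uti_share"]]))
    m_in <- m * mix[1]; m_ut <- m * mix[2]
    act["ns_init"] <- m_in
    act["ns_uti"] <- m_ut
    s <- m_in * v[["ns_initial_success"]] + m_ut * v[["ns_uti_success"]]
    imp_in <- m_in * v[["ns_initial_improvement"]]
    imp_ut <- m_ut * v[["ns_uti_improvement"]]
    fail <- m - s - imp_in - imp_ut
    nxt["succ"] <- nxt[["succ"]] + s
    nxt["imp_done"] <- nxt[["imp_done"]] + imp_ut
    if (wiring$ns_improver == "train_once") {
      nxt["q_train_ns"] <- nxt[["q_train_ns"]] + imp_in
    } else if (wiring$ns_improver == "medcont") {
      nxt["q_med_ns"] <- nxt[["q_med_ns"]] + imp_in * p76
      nxt["imp_done"] <- nxt[["imp_done"]] + imp_in * (1 - p76)
    } else {
      nxt["imp_done"] <- nxt[["imp_done"]] + imp_in
    }
    nxt["a_ns_meds"] <- nxt[["a_ns_meds"]] + fail * ns_fail[["cont"]]
    ref <- fail * ns_fail[["ref"]]
    nxt["a_ppt"] <- nxt[["a_ppt"]] + ref * refsplit_ns[1]
    nxt["a_spec_fresh"] <- nxt[["a_spec_fresh"]] + ref * refsplit_ns[2]
  }

  ## NS medication attempt ---------------------------------------------------
  m <- st[["a_ns_meds"]]
  if (m > 0) {
    m_med <- m * v[["ns_meds_share"]]
    act["ns_meds"] <- m_med
    nxt["stopped"] <- nxt[["stopped"]] + (m - m_med)
    s <- m_med * v[["ns_meds_success"]]
    imp <- m_med * v[["ns_meds_improvement"]]
    fail <- m_med - s - imp
    nxt["succ"] <- nxt[["succ"]] + s
    nxt["q_med_ns"] <- nxt[["q_med_ns"]] + imp * p76
    nxt["imp_done"] <- nxt[["imp_done"]] + imp * (1 - p76)
    ref <- fail * v[["ns_fail_referred"]]
    nxt["a_ppt"] <- nxt[["a_ppt"]] + ref * refsplit_ns[1]
    nxt["a_spec_fresh"] <- nxt[["a_spec_fresh"]] + ref * refsplit_ns[2]
    nxt["stopped"] <- nxt[["stopped"]] + fail - ref
  }

  ## pelvic physiotherapist lane --------------------------------------------
  if (ppt_m > 0) {
    mix <- .norm(c(v[["ppt_pfmt_share"]], v[["ppt_bio_share"]]))
    m_pf <- ppt_m * mix[1]; m_bio <- ppt_m * mix[2]
    act["ppt_pfmt"] <- m_pf
    act["ppt_bio"] <- m_bio
    s <- m_pf * v[["ppt_pfmt_success"]] + m_bio * v[["ppt_bio_success"]]
    imp <- m_pf * cfg$pfmt_improvement + m_bio * v[["ppt_bio_improvement"]]
    fail <- ppt_m - s - imp
    nxt["succ"] <- nxt[["succ"]] + s
    tc <- v[["train_continue"]]
    nxt["q_train_ppt"] <- nxt[["q_train_ppt"]] + imp * tc
    nxt["imp_done"] <- nxt[["imp_done"]] + imp * (1 - tc)
    add_primary(fail * refsplit_ppt[1])
    nxt["a_spec_ppt"] <- nxt[["a_spec_ppt"]] + fail * refsplit_ppt[2]
  }

  ## specialist lane ----------------------------------------------------------
  if (spec_m > 0) {
    mix <- .norm(c(v[["spec_mix_surgery"]], v[["spec_mix_conservative"]],
                   v[["spec_mix_meds"]]))
    mm <- spec_m * mix
    act[c("spec_surg", "spec_cons", "spec_meds")] <- mm
    s <- mm[1] * v[["spec_surgery_success"]] +
      mm[2] * v[["spec_conservative_success"]] +
      mm[3] * v[["spec_meds_success"]]
    imp_med <- mm[3] * v[["spec_meds_improvement"]]
    imp_oth <- mm[1] * v[["spec_surgery_improvement"]] +
      mm[2] * v[["spec_conservative_improvement"]]
    fail <- spec_m - s - imp_med - imp_oth
    nxt["succ"] <- nxt[["succ"]] + s
    nxt["q_med_spec"] <- nxt[["q_med_spec"]] + imp_med * p76
    nxt["imp_done"] <- nxt[["imp_done"]] + imp_med * (1 - p76) + imp_oth
    add_primary(fail * v[["spec_fail_to_gp"]])
    nxt["stopped"] <- nxt[["stopped"]] + fail * (1 - v[["spec_fail_to_gp"]])
  }

  ## continuation treatments (mass already improved) --------------------------
  mc <- .norm(c(imp = v[["med_cont_improvement"]], succ = v[["med_cont_success"]]))
  for (lane in c("gp", "ns", "spec")) {
    q <- st[[paste0("q_med_", lane)]]
    if (q > 0) {
      act[paste0("medcont_", lane)] <- q
      nxt["succ"] <- nxt[["succ"]] + q * mc[["succ"]]
      nxt["imp_done"] <- nxt[["imp_done"]] + q * mc[["imp"]]
    }
  }
  q <- st[["q_train_ppt"]]
  if (q > 0) {
    act["train2_ppt"] <- q
    nxt["succ"] <- nxt[["succ"]] + q * cfg$train2[["succ"]]
    rem <- q * cfg$train2[["imp"]]
    if (wiring$train_repeat) {
      tc <- v[["train_continue"]]
      nxt["q_train_ppt"] <- nxt[["q_train_ppt"]] + rem * tc
      nxt["imp_done"] <- nxt[["imp_done"]] + rem * (1 - tc)
    } else {
      nxt["imp_done"] <- nxt[["imp_done"]] + rem
    }
  }
  q <- st[["q_train_ns"]]
  if (q > 0) {
    act["traincont_ns"] <- q
    nxt["succ"] <- nxt[["succ"]] + q * cfg$train2[["succ"]]
    nxt["imp_done"] <- nxt[["imp_done"]] + q * cfg$train2[["imp"]]
  }

  if (abs(sum(nxt) - sum(st)) > 1e-9) {
    stop("mass conservation violated in cure_pathway_step", call. = FALSE)
  }
  list(state = nxt, act = act)
}

.occ_row <- function(st) {
  c(nd = st[["nd"]], selfm = st[["selfm"]], cont = st[["cont"]],
    stopped = st[["stopped"]],
    active = st[["a_gp"]] + st[["a_ns_init"]] + st[["a_ns_meds"]] +
      st[["a_ppt"]] + st[["a_spec_fresh"]] + st[["a_spec_ppt"]],
    improved = st[["imp_done"]] + st[["q_med_gp"]] + st[["q_med_ns"]] +
      st[["q_med_spec"]] + st[["q_train_ppt"]] + st[["q_train_ns"]],
    succ = st[["succ"]])
}

# Core runner shared by run_cohort and the prevalent warm-up.
.run_engine <- function(alloc, cfg, ps, horizon, wiring = .default_wiring()) {
  st <- .init_state(alloc, cfg, ps)
  occ <- matrix(0, nrow = horizon + 1, ncol = length(.occ_cols),
                dimnames = list(NULL, .occ_cols))
  activity <- matrix(0, nrow = max(horizon, 1), ncol = length(.act_cols),
                     dimnames = list(NULL, .act_cols))
  occ[1, ] <- .occ_row(st)
  # assessment consultations are booked in the first cycle
  if (horizon >= 1 && !is.null(alloc$newly_detected) && alloc$newly_detected > 0) {
    activity[1, c("assess_gp", "assess_ppt", "assess_ns")] <-
      alloc$newly_detected * cfg$assess
  }
  if (horizon >= 1) {
    for (t in seq_len(horizon)) {
      step <- .engine_step(st, cfg, ps, wiring)
      st <- step$state
      activity[t, ] <- activity[t, ] + step$act
      occ[t + 1, ] <- .occ_row(st)
      if (abs(sum(occ[t + 1, ]) - 1) > 1e-9) {
        stop("cohort mass not conserved at cycle ", t, call. = FALSE)
      }
    }
  }
  structure(list(
    occupancy = occ, activity = activity, state = st,
    arm = cfg$arm, cohort = alloc$cohort, cfg = cfg, allocation = alloc,
    horizon = horizon,
    cycle_length_years = ps$settings$cycle_length_years
  ), class = "ui_trace")
}

#' Run a cohort through the model
#'
#' Propagates one unit cohort (incident or prevalent) through the decision
#' tree and the cure-pathway Markov process for the model horizon
#' (12 three-month cycles by default).
#'
#' @param arm `"current"` or `"new"`.
#' @param cohort `"incident"` or `"prevalent"`.
#' @param ps A `ui_params` object.
#' @param horizon Number of cycles (default: the `horizon_cycles` setting).
#' @param scenario Optional scenario name (see [run_scenario()]); `NULL` for
#'   the base case.
#' @return A `ui_trace` object: per-cycle state occupancy (rows `0..horizon`,
#'   where row *t* is the state after *t* cycles), the per-cycle treatment
#'   activity used for costing, and the initial allocation.
#' @examples
#' tr <- run_cohort("current", "incident", base_case_parameters())
#' outcome_summary(tr)
#' @export
run_cohort <- function(arm, cohort = c("incident", "prevalent"), ps,
                       horizon = NULL, scenario = NULL) {
  cohort <- match.arg(cohort)
  stopifnot(inherits(ps, "ui_params"))
  if (is.null(horizon)) horizon <- ps$settings$horizon_cycles
  cfg <- .arm_config(arm, ps, scenario)
  alloc <- if (cohort == "incident") {
    allocate_incident_cohort_cfg(cfg)
  } else {
    derive_prevalent_allocation(arm, ps, scenario = scenario)
  }
  .run_engine(alloc, cfg, ps, horizon)
}

# allocation from a prepared config (lets scenarios reuse the tree)
allocate_incident_cohort_cfg <- function(cfg) {
  det <- cfg$detection
  structure(list(
    undetected = 1 - det,
    cure = det * cfg$strat[["cure"]],
    containment_only = det * cfg$strat[["cont"]],
    self_management = det * cfg$strat[["self"]],
    stopped = 0,
    cohort = "incident",
    newly_detected = det,
    provider_split = NULL
  ), class = "ui_allocation")
}

#' Derive the prevalent-cohort allocation by a one-year warm-up
#'
#' Prevalent patients are already distributed along the care pathway. Their
#' starting allocation is obtained by running the usual-care incident model
#' for one year (4 cycles), removing the patients whose treatment succeeded
#' (success plus improvement — the mass that has left the incontinent care
#' pathway), and renormalizing the remainder over the four strategy
#' categories. Patients who failed out of active treatment are counted with
#' the never-detected-but-incontinent pool; still-active patients form the
#' residual treated-for-cure share, split in equal thirds over GP,
#' physiotherapist and specialist.
#'
#' Under new care the nurse specialist additionally detects an extra share
#' of the never-detected pool (14 percentage points) at model start; the
#' newly detected are allocated to cure/containment in the new-care incident
#' proportions, and self-managers are re-engaged into the cure pathway.
#'
#' @param arm `"current"` or `"new"`.
#' @param ps A `ui_params` object.
#' @param scenario Optional scenario name (see [run_scenario()]).
#' @return A `ui_allocation` with strategy shares summing to 1, the removed
#'   (treated-successfully) share of the warm-up cohort in `removed`, and
#'   the newly detected mass (for assessment costing) in `newly_detected`.
#' @export
derive_prevalent_allocation <- function(arm, ps, scenario = NULL) {
  stopifnot(inherits(ps, "ui_params"))
  arm <- match.arg(arm, c("current", "new"))
  cfg_cur <- .arm_config("current", ps)
  warm <- .run_engine(allocate_incident_cohort_cfg(cfg_cur), cfg_cur, ps,
                      horizon = ps$settings$warmup_cycles)
  st <- warm$state
  final <- .occ_row(st)
  removed <- final[["succ"]] + final[["improved"]]
  keep <- 1 - removed
  alloc <- list(
    undetected = (final[["nd"]] + final[["stopped"]]) / keep,
    cure = final[["active"]] / keep,
    containment_only = final[["cont"]] / keep,
    self_management = final[["selfm"]] / keep,
    stopped = 0,
    cohort = "prevalent",
    removed = removed,
    newly_detected = 0,
    provider_split = c(gp = 1, ppt = 1, spec = 1) / 3
  )

  cfg <- .arm_config(arm, ps, scenario)
  extra <- min(cfg$extra_detection, alloc$undetected)
  if (extra > 0 || cfg$reengage_self) {
    newly <- extra
    alloc$undetected <- alloc$undetected - extra
    split <- cfg$newly_detected_strat
    if (is.null(split)) split <- c(cure = 0.5, cont = 0.5)
    alloc$cure <- alloc$cure + extra * split[["cure"]]
    alloc$containment_only <- alloc$containment_only + extra * split[["cont"]]
    if (cfg$reengage_self) {
      alloc$cure <- alloc$cure + alloc$self_management
      newly <- newly + alloc$self_management
      alloc$self_management <- 0
    }
    alloc$newly_detected <- newly
  }
  structure(alloc, class = "ui_allocation")
}

#' Advance a cohort trace by one cycle of the cure pathway
#'
#' Applies one cycle of provider-dependent treatment, continuation and
#' referral to the trace's current state and appends the new occupancy row.
#' Mass conservation is enforced at 1e-9. Intended for stepwise inspection
#' of the pathway; [run_cohort()] is the canonical runner (it also books
#' the first-cycle assessment consultations, which a manual step after a
#' zero-cycle trace does not).
#'
#' @param trace A `ui_trace`.
#' @param ps The `ui_params` the trace was built with.
#' @return The extended `ui_trace` (horizon increased by one).
#' @export
cure_pathway_step <- function(trace, ps) {
  stopifnot(inherits(trace, "ui_trace"), inherits(ps, "ui_params"))
  step <- .engine_step(trace$state, trace$cfg, ps, .default_wiring())
  trace$state <- step$state
  row <- .occ_row(step$state)
  if (abs(sum(row) - 1) > 1e-9) {
    stop("cohort mass not conserved in cure_pathway_step", call. = FALSE)
  }
  trace$occupancy <- rbind(trace$occupancy, row)
  if (trace$horizon == 0) {
    trace$activity[1, ] <- step$act       # placeholder row from horizon 0
  } else {
    trace$activity <- rbind(trace$activity, step$act)
  }
  trace$horizon <- trace$horizon + 1L
  trace
}

#' Summarise cohort outcomes at the horizon
#'
#' @param trace A `ui_trace` from [run_cohort()].
#' @return A list of class `ui_outcomes`: `pct_success` (cumulative mass
#'   that reached the success state, in percent), `pct_improved` (mass in
#'   the improvement state at the horizon) and `pct_not_improved`
#'   (everything else: undetected, containment-only, self-management and
#'   still/again incontinent patients). The three sum to 100.
#' @export
outcome_summary <- function(trace) {
  stopifnot(inherits(trace, "ui_trace"))
  final <- trace$occupancy[nrow(trace$occupancy), ]
  s <- 100 * final[["succ"]]
  i <- 100 * final[["improved"]]
  structure(list(pct_success = s, pct_improved = i,
                 pct_not_improved = 100 - s - i),
            class = "ui_outcomes")
}

#' @export
print.ui_outcomes <- function(x, ...) {
  cat(sprintf("success %.1f%% | improved %.1f%% | not improved %.1f%%\n",
              x$pct_success, x$pct_improved, x$pct_not_improved))
  invisible(x)
}

#' @export
print.ui_trace <- function(x, ...) {
  cat(sprintf("<ui_trace> arm=%s cohort=%s, %d cycles\n",
              x$arm, x$cohort, x$horizon))
  print(outcome_summary(x))
  invisible(x)
}

#' @export
print.ui_allocation <- function(x, ...) {
  cat(sprintf(paste0("<ui_allocation> %s: undetected %.2f%% | cure %.2f%% | ",
                     "containment %.2f%% | self %.2f%%\n"),
              x$cohort, 100 * x$undetected, 100 * x$cure,
              100 * x$containment_only, 100 * x$self_management))
  invisible(x)
}

#' Export a cohort trace as a data frame
#'
#' @param x A `ui_trace`.
#' @param ... Unused.
#' @return A data frame with one row per cycle (0..horizon) and one column
#'   per occupancy category.
#' @export
as.data.frame.ui_trace <- function(x, ...) {
  data.frame(cycle = 0:x$horizon, as.data.frame(x$occupancy))
}
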