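# ---------------------------------------------------------------------------
# Costing and health benefits. Costs are booked per cycle from two sources:
#   * state-based costs from the start-of-cycle occupancy (containment pads,
#     adverse events, formal home care, informal care),
#   * activity-based costs from the treatments delivered during the cycle
#     (consultations, therapies, travel).
# All amounts are 2013 euros; no discounting (zero rate over the 3-year
# horizon) and no half-cycle correction.
# ---------------------------------------------------------------------------

.cost_categories <- c("gp_ns", "ppt", "specialist", "containment_insured",
                      "adverse_events", "formal_home_care", "implementation",
                      "travel", "out_of_pocket_containment", "informal_care")

.payer_categories <- c("gp_ns", "ppt", "specialist", "containment_insured",
                       "adverse_events", "formal_home_care", "implementation")

# the printed annual implementation cost corresponds to this share of the
# total training cost (share of the UI+FI population the model covers)
.impl_base_share <- 0.238

#' Per-cycle cost matrix of a cohort trace
#'
#' @param trace A `ui_trace`.
#' @param ps A `ui_params` object.
#' @return A `horizon x 10` matrix of euro amounts per unit cohort, one
#'   column per cost category (implementation is booked at the results
#'   level, not here).
#' @export
cycle_cost_matrix <- function(trace, ps) {
  stopifnot(inherits(trace, "ui_trace"), inherits(ps, "ui_params"))
  v <- ps$values
  H <- trace$horizon
  out <- matrix(0, nrow = H, ncol = length(.cost_categories),
                dimnames = list(NULL, .cost_categories))
  if (H == 0) return(out)
  occ <- trace$occupancy
  act <- trace$activity
  primary_consult <- if (identical(trace$cfg$primary_consult, "ns"))
    v[["cost_consult_ns"]] else v[["cost_consult_gp"]]
  n_init <- v[["ns_consults_initial"]]

  ae_rate <- v[["uti_per_cycle"]] * v[["cost_uti_event"]] +
    v[["fracture_per_cycle"]] * v[["cost_fracture"]] +
    v[["skin_per_cycle"]] * v[["cost_skin"]]

  for (t in seq_len(H)) {
    s <- occ[t, ]                       # state occupied during cycle t
    a <- act[t, ]
    incont_ins <- s[["cont"]] + s[["stopped"]] + s[["active"]]
    incont_oop <- s[["nd"]] + s[["selfm"]]
    non_success <- 1 - s[["succ"]]

    out[t, "containment_insured"] <- incont_ins * v[["cost_pads_failure"]] +
      s[["improved"]] * v[["cost_pads_improvement"]] +
      s[["succ"]] * v[["cost_pads_success"]]
    out[t, "out_of_pocket_containment"] <- incont_oop * v[["cost_pads_oop"]]
    out[t, "adverse_events"] <- non_success * ae_rate
    out[t, "formal_home_care"] <- v[["formal_care_share"]] *
      ((incont_ins + incont_oop) * v[["cost_formal_failure"]] +
         s[["improved"]] * v[["cost_formal_improvement"]] +
         s[["succ"]] * v[["cost_formal_success"]])
    out[t, "informal_care"] <- v[["informal_care_share"]] *
      ((incont_ins + incont_oop) * v[["cost_informal_failure"]] +
         s[["improved"]] * v[["cost_informal_improvement"]] +
         s[["succ"]] * v[["cost_informal_success"]])

    ## primary care lane (GP or NS) -----------------------------------------
    gp_ns_visits <- a[["assess_gp"]] + a[["assess_ns"]] +
      a[["gp_meds"]] + a[["gp_life"]] + a[["gp_uti"]] + a[["gp_train"]] +
      a[["medcont_gp"]] +
      n_init * a[["ns_init"]] + a[["ns_uti"]] + a[["ns_meds"]] +
      a[["medcont_ns"]] + a[["traincont_ns"]]
    out[t, "gp_ns"] <-
      a[["assess_gp"]] * v[["cost_consult_gp"]] +
      a[["assess_ns"]] * v[["cost_consult_ns"]] +
      (a[["gp_meds"]] + a[["gp_life"]] + a[["gp_uti"]] + a[["gp_train"]] +
         a[["medcont_gp"]]) * primary_consult +
      (a[["gp_meds"]] + a[["medcont_gp"]]) * v[["cost_meds_gp_ns"]] +
      a[["gp_life"]] * v[["cost_lifestyle_gp"]] +
      a[["gp_uti"]] * v[["cost_uti_treatment"]] +
      a[["gp_train"]] * v[["cost_training_gp"]] +
      (n_init * a[["ns_init"]] + a[["ns_uti"]] + a[["ns_meds"]] +
         a[["medcont_ns"]] + a[["traincont_ns"]]) * v[["cost_consult_ns"]] +
      (a[["ns_meds"]] + a[["medcont_ns"]]) * v[["cost_meds_gp_ns"]] +
      a[["ns_uti"]] * v[["cost_uti_treatment"]]

    ## physiotherapist lane ---------------------------------------------------
    ppt_visits <- a[["assess_ppt"]] + a[["ppt_pfmt"]] + a[["ppt_bio"]] +
      a[["train2_ppt"]]
    out[t, "ppt"] <- ppt_visits * v[["cost_consult_ppt"]] +
      (a[["ppt_pfmt"]] + a[["train2_ppt"]]) * v[["cost_pfmt"]] +
      a[["ppt_bio"]] * v[["cost_pfmt_bio"]]

    ## specialist lane --------------------------------------------------------
    spec_visits <- a[["spec_surg"]] + a[["spec_cons"]] + a[["spec_meds"]] +
      a[["medcont_spec"]]
    out[t, "specialist"] <- spec_visits * v[["cost_consult_spec"]] +
      a[["spec_surg"]] * v[["cost_surgery"]] +
      a[["spec_cons"]] * v[["cost_conservative"]] +
      (a[["spec_meds"]] + a[["medcont_spec"]]) * v[["cost_meds_spec"]]

    out[t, "travel"] <- gp_ns_visits * v[["cost_travel_gp_ns"]] +
      ppt_visits * v[["cost_travel_ppt"]] +
      spec_visits * v[["cost_travel_spec"]]
  }
  out
}

#' Cost vector of one cycle
#'
#' @param trace A `ui_trace`.
#' @param cycle Cycle index in `1..horizon`.
#' @param ps A `ui_params` object.
#' @return A named numeric vector of class `ui_costs` (euro per unit cohort,
#'   one element per cost category).
#' @export
cycle_cost_vector <- function(trace, cycle, ps) {
  stopifnot(cycle >= 1, cycle <= trace$horizon)
  m <- cycle_cost_matrix(trace, ps)
  structure(m[cycle, ], class = "ui_costs")
}

#' Total cost vector of a trace
#'
#' @inheritParams cycle_cost_matrix
#' @return A named numeric vector of class `ui_costs`.
#' @export
cost_vector <- function(trace, ps) {
  structure(colSums(cycle_cost_matrix(trace, ps)), class = "ui_costs")
}

#' Payer-perspective total of a cost vector
#'
#' Medical costs reimbursed by the health care payer: consultations and
#' treatments, insured containment, adverse events, formal home care and
#' implementation. Travel, out-of-pocket containment and informal care are
#' excluded.
#' @param cv A `ui_costs` vector.
#' @return Euro amount.
#' @export
payer_total <- function(cv) sum(cv[.payer_categories])

#' Societal-perspective total of a cost vector
#'
#' @param cv A `ui_costs` vector.
#' @return Euro amount (payer total plus travel, out-of-pocket containment
#'   and informal care).
#' @export
societal_total <- function(cv) sum(cv[.cost_categories])

#' Total QALYs of a cohort trace
#'
#' Quality-adjusted life years accrued over the trace: each cycle
#' contributes `cycle_length x sum(occupancy x state utility)`, with the
#' incontinent pools (undetected, containment-only, self-management,
#' stopped, in active treatment) at the failure utility, the improvement
#' state at the improvement utility and (exited) successes at the success
#' utility.
#'
#' @param trace A `ui_trace`.
#' @param ps A `ui_params` object.
#' @param utilities Optional named vector overriding
#'   `c(success=, improvement=, failure=)`.
#' @return QALYs per patient over the trace horizon.
#' @examples
#' ps <- base_case_parameters()
#' tr <- run_cohort("current", "incident", ps)
#' total_qalys(tr, ps)
#' @export
total_qalys <- function(trace, ps, utilities = NULL) {
  stopifnot(inherits(trace, "ui_trace"))
  v <- ps$values
  if (is.null(utilities)) {
    utilities <- c(success = v[["utility_success"]],
                   improvement = v[["utility_improvement"]],
                   failure = v[["utility_failure"]])
  }
  H <- trace$horizon
  if (H == 0) return(0)
  occ <- trace$occupancy[seq_len(H), , drop = FALSE]  # start-of-cycle states
  incont <- rowSums(occ[, c("nd", "selfm", "cont", "stopped", "active"),
                        drop = FALSE])
  sum(trace$cycle_length_years *
        (incont * utilities[["failure"]] +
           occ[, "improved"] * utilities[["improvement"]] +
           occ[, "succ"] * utilities[["success"]]))
}

#' Implementation cost per patient
#'
#' The annual implementation cost of the new care pathway (training the
#' nurse specialists, scaled by the share of the training cost attributed
#' to the modelled population) divided by the yearly national patient pool
#' (prevalent + incident cases).
#'
#' @param ps A `ui_params` object.
#' @param population Yearly patient pool; defaults to
#'   `n_prevalent + n_incident`.
#' @return Euro per patient-year.
#' @export
implementation_cost_per_patient <- function(ps, population = NULL) {
  v <- ps$values
  if (is.null(population)) population <- v[["n_prevalent"]] + v[["n_incident"]]
  if (population <= 0) stop("patient pool must be positive", call. = FALSE)
  annual <- v[["cost_implementation_annual"]] *
    ps$settings$implementation_share / .impl_base_share
  annual / population
}

#' Per-patient costs and QALYs for both arms
#'
#' Runs the model for both arms on the mixed first-year patient population
#' (prevalent and incident cohorts, weighted by their national counts) and
#' accumulates 3-year costs per category and QALYs per patient, with
#' incrementals (new minus current) for the payer and societal perspective.
#'
#' @param ps A `ui_params` object.
#' @param scenario Optional scenario name applied to the new-care arm (see
#'   [run_scenario()]).
#' @return An object of class `ui_results`: a data frame with one row per
#'   cost category plus perspective totals and QALYs, columns `current`,
#'   `new`, `difference`. Traces and cohort-level details are attached as
#'   attributes.
#' @examples
#' \donttest{
#' res <- per_patient_results(base_case_parameters())
#' res
#' }
#' @export
per_patient_results <- function(ps, scenario = NULL) {
  stopifnot(inherits(ps, "ui_params"))
  v <- ps$values
  w_inc <- v[["n_incident"]] / (v[["n_incident"]] + v[["n_prevalent"]])
  w_prev <- 1 - w_inc

  mix_arm <- function(arm, scen) {
    tr_inc <- run_cohort(arm, "incident", ps, scenario = scen)
    tr_prev <- run_cohort(arm, "prevalent", ps, scenario = scen)
    cv <- w_inc * cost_vector(tr_inc, ps) + w_prev * cost_vector(tr_prev, ps)
    if (.arm_config(arm, ps, scen)$implementation) {
      cv[["implementation"]] <- cv[["implementation"]] +
        implementation_cost_per_patient(ps)
    }
    q <- w_inc * total_qalys(tr_inc, ps) + w_prev * total_qalys(tr_prev, ps)
    list(costs = structure(cv, class = "ui_costs"), qalys = q,
         traces = list(incident = tr_inc, prevalent = tr_prev))
  }
  cur <- mix_arm("current", NULL)
  new <- mix_arm("new", scenario)

  rows <- c(.cost_categories, "total_healthcare", "total_societal", "qalys")
  val <- function(a, what) {
    if (what == "total_healthcare") return(payer_total(a$costs))
    if (what == "total_societal") return(societal_total(a$costs))
    if (what == "qalys") return(a$qalys)
    a$costs[[what]]
  }
  df <- data.frame(
    quantity = rows,
    current = vapply(rows, function(r) val(cur, r), numeric(1)),
    new = vapply(rows, function(r) val(new, r), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  df$difference <- df$new - df$current
  structure(df, class = c("ui_results", "data.frame"),
            details = list(current = cur, new = new, scenario = scenario,
                           weights = c(incident = w_inc, prevalent = w_prev)))
}

#' Extract the incremental results of a results table
#'
#' @param res A `ui_results` object.
#' @return A list: `delta_cost_societal`, `delta_cost_payer`, `delta_qalys`.
#' @export
incrementals <- function(res) {
  stopifnot(inherits(res, "ui_results"))
  get <- function(q) res$difference[res$quantity == q]
  list(delta_cost_societal = get("total_societal"),
       delta_cost_payer = get("total_healthcare"),
       delta_qalys = get("qalys"))
}

#' @export
print.ui_results <- function(x, digits = 0, ...) {
  cat("Costs and QALYs per patient over 3 years (euro; QALYs unrounded)\n")
  disp <- x
  money <- disp$quantity != "qalys"
  for (col in c("current", "new", "difference")) {
    disp[[col]] <- ifelse(money, round(disp[[col]], digits),
                          round(disp[[col]], 4))
  }
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' @export
print.ui_costs <- function(x, ...) {
  df <- data.frame(category = names(unclass(x)),
                   eur = round(unclass(x), 2))
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("payer total %.2f | societal total %.2f\n",
              payer_total(x), societal_total(x)))
  invisible(x)
}

#' Export a results table as CSV or JSON
#'
#' @param res A `ui_results`.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_results <- function(res, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(unclass(res))[
      c("quantity", "current", "new", "difference")],
      path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.csv(as.data.frame(unclass(res))[
      c("quantity", "current", "new", "difference")], path, row.names = FALSE)
  }
  invisible(path)
}
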