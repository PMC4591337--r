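# Domains a parameter value can live in. probability/utility/fraction are
# bounded to [0,1]; cost-eur is non-negative; counts are non-negative integers.
.param_domains <- c("probability", "rate-per-year", "cost-eur", "utility",
                    "count", "fraction")

# ---------------------------------------------------------------------------
# The base-case registry. One row per scalar input of the model, with its
# domain, the distribution it takes in probabilistic sensitivity analysis
# (beta for [0,1]-bounded, uniform for costs, fixed for structural inputs),
# the branch group it must sum to one with (NA if none), and a source tag.
# ---------------------------------------------------------------------------
.base_registry <- function() {
  p <- function(name, value, domain, psa, group = NA_character_, source = "") {
    data.frame(name = name, value = value, domain = domain, psa = psa,
               group = group, source = source, stringsAsFactors = FALSE)
  }
  rows <- list(
    ## -- population (structural; excluded from OWSA/PSA) --------------------
    p("n_elderly",             2591357, "count", "fixed", NA, "population"),
    p("multimorbid_share",        0.31, "fraction", "fixed", NA, "population"),
    p("n_eligible",             808503, "count", "fixed", NA, "population"),
    p("incidence_yearly",        0.032, "rate-per-year", "fixed", NA, "population"),
    p("prevalence",               0.25, "fraction", "fixed", NA, "population"),
    p("n_incident",              25872, "count", "fixed", NA, "population"),
    p("n_prevalent",             58306, "count", "fixed", NA, "population"),
    p("n_prevalent_national",   202126, "count", "fixed", NA, "population"),
    p("prevalent_female_share",   0.77, "fraction", "fixed", NA, "population"),

    ## -- detection and strategy allocation ---------------------------------
    p("detection_incident_current", 0.504, "probability", "beta", NA, "detection"),
    p("detection_incident_new",     0.64,  "probability", "beta", NA, "detection"),
    p("extra_detection_ns",         0.14,  "probability", "beta", NA, "detection"),
    p("cur_assess_gp",  0.95, "probability", "beta", "cur_assess", "assessment"),
    p("cur_assess_ppt", 0.05, "probability", "beta", "cur_assess", "assessment"),
    p("cur_strat_cure",        0.37, "probability", "beta", "cur_strat", "strategy"),
    p("cur_strat_containment", 0.61, "probability", "beta", "cur_strat", "strategy"),
    p("cur_strat_self",        0.02, "probability", "beta", "cur_strat", "strategy"),
    p("new_strat_cure",        0.39, "probability", "beta", "new_strat", "strategy"),
    p("new_strat_containment", 0.61, "probability", "beta", "new_strat", "strategy"),
    p("new_strat_self",        0.00, "probability", "beta", "new_strat", "strategy"),
    p("prev_provider_gp",   1/3, "probability", "fixed", "prev_split", "prevalent split"),
    p("prev_provider_ppt",  1/3, "probability", "fixed", "prev_split", "prevalent split"),
    p("prev_provider_spec", 1/3, "probability", "fixed", "prev_split", "prevalent split"),

    ## -- GP lane (usual care primary provider) -----------------------------
    p("gp_immediate_referral", 0.51, "probability", "beta", NA, "GP node"),
    p("gp_ref_ppt",  0.57, "probability", "beta", "gp_ref", "GP node"),
    p("gp_ref_spec", 0.43, "probability", "beta", "gp_ref", "GP node"),
    p("gp_mix_meds",      0.79, "probability", "beta", "gp_mix", "GP node"),
    p("gp_mix_lifestyle", 0.17, "probability", "beta", "gp_mix", "GP node"),
    p("gp_mix_uti",       0.04, "probability", "beta", "gp_mix", "GP node"),
    p("gp_mix_training",  0.00, "probability", "beta", "gp_mix", "GP node"),
    p("gp_meds_improvement",      0.63, "probability", "beta", NA, "effectiveness"),
    p("gp_meds_success",          0.16, "probability", "beta", NA, "effectiveness"),
    p("gp_lifestyle_improvement", 0.10, "probability", "beta", NA, "effectiveness"),
    p("gp_lifestyle_success",     0.00, "probability", "beta", NA, "effectiveness"),
    p("gp_uti_improvement",       0.40, "probability", "beta", NA, "effectiveness"),
    p("gp_uti_success",           0.10, "probability", "beta", NA, "effectiveness"),
    p("gp_training_improvement",  0.00, "probability", "beta", NA, "effectiveness"),
    p("gp_training_success",      0.00, "probability", "beta", NA, "effectiveness"),
    p("med_second_cycle",    0.76, "probability", "beta", NA, "effectiveness"),
    p("med_cont_improvement", 0.80, "probability", "beta", "med_cont", "effectiveness"),
    p("med_cont_success",     0.20, "probability", "beta", "med_cont", "effectiveness"),

    ## -- nurse specialist lane (new care primary provider) ------------------
    p("ns_initial_share", 0.96, "probability", "beta", "ns_mix", "NS node"),
    p("ns_uti_share",     0.04, "probability", "beta", "ns_mix", "NS node"),
    p("ns_initial_improvement", 0.21, "probability", "beta", NA, "effectiveness"),
    p("ns_initial_success",     0.31, "probability", "beta", NA, "effectiveness"),
    p("ns_uti_improvement",     0.80, "probability", "beta", NA, "effectiveness"),
    p("ns_uti_success",         0.20, "probability", "beta", NA, "effectiveness"),
    p("ns_fail_continue",       0.40, "probability", "beta", "ns_fail", "NS node"),
    p("ns_meds_share",          1.00, "probability", "beta", NA, "NS node"),
    p("ns_meds_improvement",    0.63, "probability", "beta", NA, "effectiveness"),
    p("ns_meds_success",        0.16, "probability", "beta", NA, "effectiveness"),
    p("ns_fail_referred",       0.60, "probability", "beta", "ns_fail", "NS node"),
    p("ns_ref_ppt",  0.33, "probability", "beta", "ns_ref", "NS node"),
    p("ns_ref_spec", 0.67, "probability", "beta", "ns_ref", "NS node"),

    ## -- pelvic physiotherapist lane ----------------------------------------
    p("ppt_pfmt_share", 0.95, "probability", "beta", "ppt_mix", "PPT node"),
    p("ppt_bio_share",  0.05, "probability", "beta", "ppt_mix", "PPT node"),
    p("ppt_pfmt_improvement_current", 0.62, "probability", "beta", NA, "effectiveness"),
    p("ppt_pfmt_improvement_new",     0.37, "probability", "beta", NA, "effectiveness"),
    p("ppt_pfmt_success",             0.00, "probability", "beta", NA, "effectiveness"),
    p("ppt_bio_improvement",          0.45, "probability", "beta", NA, "effectiveness"),
    p("ppt_bio_success",              0.23, "probability", "beta", NA, "effectiveness"),
    p("train_continue", 1.00, "probability", "beta", NA, "effectiveness"),
    p("train2_improvement_current", 0.44, "probability", "beta", "train2_cur", "effectiveness"),
    p("train2_success_current",     0.56, "probability", "beta", "train2_cur", "effectiveness"),
    p("train2_improvement_new",     0.46, "probability", "beta", "train2_new", "effectiveness"),
    p("train2_success_new",         0.54, "probability", "beta", "train2_new", "effectiveness"),
    p("ppt_fail_to_gp",   0.33, "probability", "beta", "ppt_ref", "PPT node"),
    p("ppt_fail_to_spec", 0.67, "probability", "beta", "ppt_ref", "PPT node"),

    ## -- specialist lane -----------------------------------------------------
    p("spec_to_ppt", 0.40, "probability", "beta", NA, "specialist node"),
    p("spec_mix_surgery",      0.17, "probability", "beta", "spec_mix", "specialist node"),
    p("spec_mix_conservative", 0.02, "probability", "beta", "spec_mix", "specialist node"),
    p("spec_mix_meds",         0.81, "probability", "beta", "spec_mix", "specialist node"),
    p("spec_surgery_improvement",      0.08, "probability", "beta", NA, "effectiveness"),
    p("spec_surgery_success",          0.77, "probability", "beta", NA, "effectiveness"),
    p("spec_conservative_improvement", 0.34, "probability", "beta", NA, "effectiveness"),
    p("spec_conservative_success",     0.00, "probability", "beta", NA, "effectiveness"),
    p("spec_meds_improvement",         0.63, "probability", "beta", NA, "effectiveness"),
    p("spec_meds_success",             0.16, "probability", "beta", NA, "effectiveness"),
    p("spec_fail_to_gp", 1.00, "probability", "beta", NA, "specialist node"),

    ## -- adverse events and care use ----------------------------------------
    p("uti_yearly_oab",     0.457, "rate-per-year", "beta", NA, "adverse events"),
    p("uti_yearly_no_oab",  0.154, "rate-per-year", "beta", NA, "adverse events"),
    p("fall_per_cycle",     0.0041, "probability", "beta", NA, "adverse events"),
    p("fracture_given_fall", 0.057, "probability", "beta", NA, "adverse events"),
    p("skin_per_cycle",      0.08,  "probability", "beta", NA, "adverse events"),
    p("informal_care_share", 0.43,  "probability", "beta", NA, "care use"),
    p("formal_care_share",   0.47,  "probability", "beta", NA, "care use"),
    p("care_reduction_improved", 0.10, "fraction", "beta", NA, "care use"),
    p("care_reduction_success",  0.25, "fraction", "beta", NA, "care use"),

    ## -- unit costs (2013 euros) --------------------------------------------
    p("cost_consult_gp",    30.48, "cost-eur", "uniform", NA, "unit cost"),
    p("cost_consult_ns",    41.39, "cost-eur", "uniform", NA, "unit cost"),
    p("cost_meds_gp_ns",   114.96, "cost-eur", "uniform", NA, "unit cost"),
    p("cost_lifestyle_gp",  30.48, "cost-eur", "uniform", NA, "unit cost"),
    p("cost_training_gp",   30.48, "cost-eur", "uniform", NA, "unit cost"),
    p("cost_uti_treatment",  2.51, "cost-eur", "uniform", NA, "unit cost"),
    p("cost_consult_ppt",   39.19, "cost-eur", "uniform", NA, "unit cost"),
    p("cost_pfmt",         205.73, "cost-eur", "uniform", NA, "unit cost"),
    p("cost_pfmt_bio",     216.23, "cost-eur", "uniform", NA, "unit cost"),
    p("cost_consult_spec", 130.62, "cost-eur", "uniform", NA, "unit cost"),
    p("cost_surgery",      317.97, "cost-eur", "uniform", NA, "unit cost"),
    p("cost_meds_spec",    317.16, "cost-eur", "uniform", NA, "unit cost"),
    p("cost_conservative", 137.74, "cost-eur", "uniform", NA, "unit cost"),
    p("cost_pads_success",      0.00, "cost-eur", "uniform", NA, "containment"),
    p("cost_pads_improvement", 71.22, "cost-eur", "uniform", NA, "containment"),
    p("cost_pads_failure",     97.70, "cost-eur", "uniform", NA, "containment"),
    p("cost_pads_oop",         97.70, "cost-eur", "uniform", NA, "containment"),
    p("cost_uti_event",      2.51, "cost-eur", "uniform", NA, "adverse events"),
    p("cost_fracture",    2944.36, "cost-eur", "uniform", NA, "adverse events"),
    p("cost_skin",           6.49, "cost-eur", "uniform", NA, "adverse events"),
    p("cost_formal_failure",   3859.38, "cost-eur", "uniform", NA, "home care"),
    p("cost_informal_failure", 2128.99, "cost-eur", "uniform", NA, "informal care"),
    p("cost_travel_gp_ns",  3.51, "cost-eur", "uniform", NA, "travel"),
    p("cost_travel_ppt",   13.94, "cost-eur", "uniform", NA, "travel"),
    p("cost_travel_spec",   4.79, "cost-eur", "uniform", NA, "travel"),
    p("cost_implementation_annual", 426496, "cost-eur", "uniform", NA, "implementation"),
    p("ns_salary_monthly",  3728, "cost-eur", "fixed", NA, "salary"),
    p("ns_workable_hours",  1540, "count",    "fixed", NA, "salary"),
    p("ns_consults_initial",   3, "count",    "fixed", NA, "NS node"),

    ## -- utilities ------------------------------------------------------------
    p("utility_success", 0.8595, "utility", "beta", NA, "quality of life"),
    p("utility_failure", 0.8246, "utility", "beta", NA, "quality of life")
  )
  do.call(rbind, rows)
}

#' Construct the complete base-case parameter set
#'
#' Returns the full published base case of the model: population counts,
#' detection and care-pathway probabilities for both arms, treatment
#' effectiveness, adverse-event and care-use rates, 2013-euro unit costs and
#' health-state utilities, together with the structural settings (3-month
#' cycles, 12-cycle horizon, implementation cost share, zero discounting).
#' Decimal-comma percentages in the source tables (e.g. "50,40%") are stored
#' as plain decimal fractions (0.504).
#'
#' Derived quantities (per-cycle adverse-event probabilities, the improvement
#' utility, state-dependent home-care costs) are filled in by
#' [derive_cycle_probabilities()], which is applied before the set is
#' returned.
#'
#' @return An object of class `ui_params`: a list with elements `values`
#'   (named numeric vector), `meta` (data frame describing domain, PSA
#'   distribution, branch group and source of every entry) and `settings`
#'   (structural constants).
#' @examples
#' ps <- base_case_parameters()
#' ps_get(ps, "detection_incident_current")  # 0.504
#' ps_get(ps, "utility_success")             # 0.8595
#' @export
base_case_parameters <- function() {
  reg <- .base_registry()
  ps <- structure(list(
    values = stats::setNames(reg$value, reg$name),
    meta = reg[, c("name", "domain", "psa", "group", "source")],
    settings = list(
      cycle_length_years = 0.25,
      horizon_cycles = 12L,
      implementation_share = 0.238,
      discount_rate = 0,
      warmup_cycles = 4L,
      uti_use_rounded = FALSE
    )
  ), class = "ui_params")
  derive_cycle_probabilities(ps)
}

#' Look up a parameter value by name
#'
#' @param ps A `ui_params` object.
#' @param name Parameter name.
#' @return The numeric value.
#' @export
ps_get <- function(ps, name) {
  stopifnot(inherits(ps, "ui_params"))
  if (!name %in% names(ps$values)) {
    stop("unknown parameter: ", name, call. = FALSE)
  }
  unname(ps$values[[name]])
}

#' Replace parameter values
#'
#' @param ps A `ui_params` object.
#' @param ... Named values to set, e.g. `ps_set(ps, gp_mix_meds = 0.8)`.
#' @return The modified `ui_params` object (derived values are refreshed).
#' @export
ps_set <- function(ps, ...) {
  upd <- list(...)
  bad <- setdiff(names(upd), names(ps$values))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  ps$values[names(upd)] <- unlist(upd)
  derive_cycle_probabilities(ps)
}

#' @export
print.ui_params <- function(x, ...) {
  cat("<ui_params> ", length(x$values), " parameters\n", sep = "")
  cat("  horizon: ", x$settings$horizon_cycles, " cycles of ",
      x$settings$cycle_length_years, " years\n", sep = "")
  grp <- table(x$meta$source)
  cat("  blocks: ", paste(names(grp), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Derive per-cycle and composite parameters
#'
#' Adds to the set every quantity the model derives from its raw inputs:
#'
#' * yearly excess urinary-tract-infection incidence attributable to
#'   incontinence (incidence with overactive bladder minus incidence
#'   without: 45.7% - 15.4% = 30.3%),
#' * the per-cycle UTI probability (yearly excess divided by the four
#'   3-month cycles in a year; 7.575% unrounded, displayed as 8%),
#' * the per-cycle fracture probability (falls per cycle x fractures per
#'   fall = 0.41% x 5.7% = 0.023%),
#' * the improvement-state utility (mean of the success and failure
#'   utilities),
#' * state-dependent formal and informal home-care costs (failure-state
#'   cost reduced by 10% for improved and 25% for successful patients).
#'
#' @param ps A `ui_params` object holding the raw inputs.
#' @return The same object with the derived entries added/refreshed.
#' @export
derive_cycle_probabilities <- function(ps) {
  stopifnot(inherits(ps, "ui_params"))
  v <- ps$values
  if (v[["uti_yearly_oab"]] > 1 || v[["uti_yearly_no_oab"]] > 1) {
    stop("yearly UTI rates exceed 1", call. = FALSE)
  }
  excess <- v[["uti_yearly_oab"]] - v[["uti_yearly_no_oab"]]
  uti_cycle <- excess / 4
  if (isTRUE(ps$settings$uti_use_rounded)) uti_cycle <- round(uti_cycle, 2)
  derived <- c(
    uti_excess_yearly = excess,
    uti_per_cycle = uti_cycle,
    fracture_per_cycle = v[["fall_per_cycle"]] * v[["fracture_given_fall"]],
    utility_improvement = derive_improvement_utility(
      v[["utility_success"]], v[["utility_failure"]]),
    cost_formal_improvement = v[["cost_formal_failure"]] *
      (1 - v[["care_reduction_improved"]]),
    cost_formal_success = v[["cost_formal_failure"]] *
      (1 - v[["care_reduction_success"]]),
    cost_informal_improvement = v[["cost_informal_failure"]] *
      (1 - v[["care_reduction_improved"]]),
    cost_informal_success = v[["cost_informal_failure"]] *
      (1 - v[["care_reduction_success"]]),
    ns_salary_annual = 12 * v[["ns_salary_monthly"]],
    ns_hourly_wage = 12 * v[["ns_salary_monthly"]] / v[["ns_workable_hours"]]
  )
  ps$values[names(derived)] <- derived
  new <- setdiff(names(derived), ps$meta$name)
  if (length(new)) {
    dom <- ifelse(grepl("^cost_|salary|wage", new), "cost-eur",
                  ifelse(grepl("utility", new), "utility", "probability"))
    ps$meta <- rbind(ps$meta, data.frame(
      name = new, domain = dom, psa = "fixed", group = NA_character_,
      source = "derived", stringsAsFactors = FALSE))
  }
  ps
}

#' Utility of the improvement health state
#'
#' The improvement state (at least 50% fewer incontinence episodes) carries
#' the arithmetic mean of the utilities of the success (continent) and
#' failure (incontinent) states.
#'
#' @param u_success Utility of the success state, in \[0, 1\].
#' @param u_incontinent Utility of the incontinent state, in \[0, 1\].
#' @return The mean of the two utilities.
#' @examples
#' derive_improvement_utility(0.8595, 0.8246)  # 0.84205
#' @export
derive_improvement_utility <- function(u_success, u_incontinent) {
  stopifnot(u_success >= 0, u_success <= 1,
            u_incontinent >= 0, u_incontinent <= 1)
  (u_success + u_incontinent) / 2
}

#' Target population arithmetic
#'
#' Computes the size of the modelled population: community-dwelling elderly
#' (65+) with four or more chronic diseases, the yearly number of detected
#' incident urinary-incontinence cases (eligible population times yearly
#' incidence, rounded down), and the prevalent case pool with its sex split.
#' The printed eligible-population count is authoritative; the 31%
#' multimorbidity share is a rounded display of age-sex-stratified shares
#' and is not used in the multiplication.
#'
#' @param ps A `ui_params` object.
#' @return A list with `n_eligible`, `n_incident`, `n_prevalent`,
#'   `n_prevalent_national`, `n_women`, `n_men`.
#' @examples
#' target_population(base_case_parameters())$n_incident  # 25872
#' @export
target_population <- function(ps) {
  v <- ps$values
  n_inc <- floor(v[["n_eligible"]] * v[["incidence_yearly"]])
  n_prev <- v[["n_prevalent"]]
  list(
    n_eligible = unname(v[["n_eligible"]]),
    n_incident = unname(n_inc),
    n_prevalent = unname(n_prev),
    n_prevalent_national = unname(v[["n_prevalent_national"]]),
    n_women = round(unname(n_prev * v[["prevalent_female_share"]])),
    n_men = round(unname(n_prev * (1 - v[["prevalent_female_share"]])))
  )
}

# Names the cohort engine requires; validation reports a missing-name error
# if any is absent.
.required_names <- function() {
  c("detection_incident_current", "detection_incident_new",
    "extra_detection_ns", "cur_assess_gp", "cur_assess_ppt",
    "cur_strat_cure", "cur_strat_containment", "cur_strat_self",
    "new_strat_cure", "new_strat_containment", "new_strat_self",
    "gp_immediate_referral", "gp_ref_ppt", "gp_ref_spec",
    "gp_mix_meds", "gp_mix_lifestyle", "gp_mix_uti", "gp_mix_training",
    "gp_meds_improvement", "gp_meds_success", "med_second_cycle",
    "med_cont_improvement", "med_cont_success",
    "ns_initial_share", "ns_uti_share", "ns_initial_improvement",
    "ns_initial_success", "ns_fail_continue", "ns_fail_referred",
    "ns_ref_ppt", "ns_ref_spec", "ns_meds_improvement", "ns_meds_success",
    "ppt_pfmt_share", "ppt_bio_share", "ppt_pfmt_success",
    "ppt_bio_improvement", "ppt_bio_success", "train_continue",
    "ppt_fail_to_gp", "ppt_fail_to_spec", "spec_to_ppt",
    "spec_mix_surgery", "spec_mix_conservative", "spec_mix_meds",
    "spec_surgery_improvement", "spec_surgery_success",
    "spec_meds_improvement", "spec_meds_success",
    "utility_success", "utility_failure", "utility_improvement",
    "uti_per_cycle", "fracture_per_cycle", "skin_per_cycle",
    "formal_care_share", "informal_care_share",
    "cost_formal_failure", "cost_informal_failure", "cost_pads_failure")
}

#' Validate a parameter set
#'
#' Checks every invariant of the model's inputs: domain bounds
#' (probabilities, utilities and fractions in \[0, 1\]; costs non-negative;
#' counts non-negative integers), branch groups summing to one within
#' tolerance 0.01, the utility ordering (incontinent <= improvement <=
#' success), and completeness of the names the pathway engine needs.
#'
#' @param ps A `ui_params` object.
#' @param tol Branch-group sum tolerance (default 0.01).
#' @return An object of class `ui_validation`: a data frame of violations
#'   (zero rows when the set is valid) with columns `rule`, `where`,
#'   `message`.
#' @export
validate_parameter_set <- function(ps, tol = 0.01) {
  stopifnot(inherits(ps, "ui_params"))
  v <- ps$values
  m <- ps$meta
  bad <- list()
  note <- function(rule, where, msg) {
    bad[[length(bad) + 1L]] <<- data.frame(
      rule = rule, where = where, message = msg, stringsAsFactors = FALSE)
  }

  missing <- setdiff(.required_names(), names(v))
  if (length(missing)) {
    note("incomplete set", paste(missing, collapse = ","),
         "names required by the pathway engine are missing")
  }

  for (i in seq_len(nrow(m))) {
    nm <- m$name[i]
    if (!nm %in% names(v)) next
    x <- v[[nm]]
    dom <- m$domain[i]
    if (!is.finite(x)) { note("non-finite", nm, "value is not finite"); next }
    if (dom %in% c("probability", "utility", "fraction")) {
      if (x < 0 || x > 1) {
        note(paste0(dom, " out of [0,1]"), nm, sprintf("value %.4f", x))
      }
    } else if (dom == "cost-eur") {
      if (x < 0) note("negative cost", nm, sprintf("value %.2f", x))
    } else if (dom == "count") {
      if (x < 0 || abs(x - round(x)) > 1e-9) {
        note("count not a non-negative integer", nm, sprintf("value %.4f", x))
      }
    } else if (dom == "rate-per-year") {
      if (x < 0) note("negative rate", nm, sprintf("value %.4f", x))
    }
  }

  for (g in unique(stats::na.omit(m$group))) {
    nms <- m$name[!is.na(m$group) & m$group == g]
    nms <- intersect(nms, names(v))
    s <- sum(v[nms])
    if (abs(s - 1) > tol) {
      note("branch sum != 1", g, sprintf("group sums to %.4f", s))
    }
  }

  if (all(c("utility_failure", "utility_improvement", "utility_success")
          %in% names(v))) {
    if (!(v[["utility_failure"]] <= v[["utility_improvement"]] + 1e-12 &&
          v[["utility_improvement"]] <= v[["utility_success"]] + 1e-12)) {
      note("utility ordering", "utilities",
           "requires u_incontinent <= u_improvement <= u_success")
    }
  }

  out <- if (length(bad)) do.call(rbind, bad) else
    data.frame(rule = character(), where = character(),
               message = character(), stringsAsFactors = FALSE)
  class(out) <- c("ui_validation", class(out))
  out
}

#' @export
print.ui_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("parameter set valid: no violations\n")
  } else {
    cat(nrow(x), "violation(s):\n")
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  [%s] %s: %s\n", x$rule[i], x$where[i], x$message[i]))
    }
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report A `ui_validation` object.
#' @return A JSON string.
#' @export
validation_to_json <- function(report) {
  jsonlite::toJSON(list(valid = nrow(report) == 0,
                        violations = as.data.frame(unclass(report))),
                   auto_unbox = TRUE, pretty = TRUE)
}

#' Write a parameter set to a YAML configuration file
#'
#' The file has blocks `values` (every scalar, decimal points only) and
#' `settings`; reading it back with [read_parameters()] reproduces the set
#' exactly.
#'
#' @param ps A `ui_params` object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path) {
  stopifnot(inherits(ps, "ui_params"))
  out <- list(
    values = as.list(ps$values),
    settings = ps$settings
  )
  # full precision so the round trip is exact
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' Read a parameter set from a YAML configuration file
#'
#' Values are merged over the base-case registry so that metadata (domains,
#' PSA distributions, branch groups) is preserved; unknown names are
#' rejected. Derived parameters are refreshed after loading.
#'
#' @param path File path of a YAML file written by [write_parameters()] (or
#'   hand-edited in the same layout).
#' @return A `ui_params` object.
#' @export
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  ps <- base_case_parameters()
  vals <- unlist(raw$values)
  known <- names(vals) %in% names(ps$values)
  if (any(!known)) {
    stop("unknown parameter(s) in config: ",
         paste(names(vals)[!known], collapse = ", "), call. = FALSE)
  }
  ps$values[names(vals)] <- vals
  if (!is.null(raw$settings)) {
    for (nm in names(raw$settings)) ps$settings[[nm]] <- raw$settings[[nm]]
    ps$settings$horizon_cycles <- as.integer(ps$settings$horizon_cycles)
    ps$settings$warmup_cycles <- as.integer(ps$settings$warmup_cycles)
  }
  derive_cycle_probabilities(ps)
}
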