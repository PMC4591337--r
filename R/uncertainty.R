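# ---------------------------------------------------------------------------
# One-way (tornado) and probabilistic sensitivity analysis.
#
# PSA distributions follow the conventions of the analysis: parameters
# bounded to [0,1] (transition probabilities, utilities, shares) take a
# beta distribution with mean equal to the base value and a standard error
# of se_frac x mean (method-of-moments shape parameters); all other
# parameters (costs) vary uniformly on mean x (1 +/- se_frac). Branch
# groups are renormalized after sampling; improvement+success outcome
# pairs are rescaled when a draw pushes their sum above 1.
# ---------------------------------------------------------------------------

.outcome_pairs <- list(
  c("gp_meds_improvement", "gp_meds_success"),
  c("gp_lifestyle_improvement", "gp_lifestyle_success"),
  c("gp_uti_improvement", "gp_uti_success"),
  c("gp_training_improvement", "gp_training_success"),
  c("ns_initial_improvement", "ns_initial_success"),
  c("ns_uti_improvement", "ns_uti_success"),
  c("ns_meds_improvement", "ns_meds_success"),
  c("ppt_pfmt_improvement_current", "ppt_pfmt_success"),
  c("ppt_pfmt_improvement_new", "ppt_pfmt_success"),
  c("ppt_bio_improvement", "ppt_bio_success"),
  c("spec_surgery_improvement", "spec_surgery_success"),
  c("spec_conservative_improvement", "spec_conservative_success"),
  c("spec_meds_improvement", "spec_meds_success")
)

.repair_groups <- function(ps) {
  m <- ps$meta
  for (g in unique(stats::na.omit(m$group))) {
    nms <- m$name[!is.na(m$group) & m$group == g]
    s <- sum(ps$values[nms])
    if (s > 0) ps$values[nms] <- ps$values[nms] / s
  }
  for (pr in .outcome_pairs) {
    s <- sum(ps$values[pr])
    if (s > 1) ps$values[pr] <- ps$values[pr] / s
  }
  ps
}

#' Method-of-moments beta shape parameters
#'
#' For a beta distribution with mean `m` and standard deviation `s`,
#' `alpha + beta = m(1-m)/s^2 - 1`, `alpha = m (alpha+beta)`. When the
#' requested variance is infeasible (`s^2 >= m(1-m)`) the standard
#' deviation is clamped to 95% of the feasible maximum.
#'
#' @param m Mean in (0,1).
#' @param s Target standard deviation.
#' @return Named vector `c(alpha=, beta=)`.
#' @export
beta_moments <- function(m, s) {
  stopifnot(m > 0, m < 1, s > 0)
  smax <- sqrt(m * (1 - m))
  if (s >= smax) s <- 0.95 * smax
  nu <- m * (1 - m) / s^2 - 1
  c(alpha = m * nu, beta = (1 - m) * nu)
}

#' Draw one random parameter set for probabilistic sensitivity analysis
#'
#' Samples every non-structural parameter from its assigned distribution
#' (beta with SE = `se_frac` x mean for \[0,1\]-bounded parameters, uniform
#' mean x (1 +/- `se_frac`) otherwise), renormalizes branch groups, and
#' refreshes the derived parameters. Uses the R random number generator;
#' seed control is the caller's (see [probabilistic_sensitivity()]).
#'
#' @param ps A `ui_params` object (the means).
#' @param se_frac Standard error as a fraction of the mean (0.2 or 0.4 in
#'   the analyses; any positive value is accepted).
#' @return A new `ui_params` object.
#' @export
sample_parameter_set <- function(ps, se_frac = 0.2) {
  stopifnot(inherits(ps, "ui_params"), se_frac >= 0)
  if (se_frac == 0) return(ps)
  m <- ps$meta
  v <- ps$values
  rbeta_mom <- function(base) {
    if (base <= 0 || base >= 1) return(base)   # degenerate: stays fixed
    sh <- beta_moments(base, se_frac * base)
    stats::rbeta(1, sh[["alpha"]], sh[["beta"]])
  }
  # Two quantities are sampled as constructed contrasts rather than
  # independently (see the methods vignette):
  #  * the NS's extra detection among prevalent cases is the (sampled)
  #    gap between the new-care and usual-care detection rates,
  #  * the success utility is the failure utility plus the continence
  #    utility decrement (both utilities come from the same survey; their
  #    contrast, not their levels, carries the health gain).
  constructed <- c("extra_detection_ns", "utility_success")
  for (i in seq_len(nrow(m))) {
    nm <- m$name[i]
    if (nm %in% constructed) next
    base <- v[[nm]]
    if (m$psa[i] == "beta") {
      v[[nm]] <- rbeta_mom(base)
    } else if (m$psa[i] == "uniform") {
      if (base == 0) next
      v[[nm]] <- stats::runif(1, base * (1 - se_frac), base * (1 + se_frac))
    }
  }
  base_gap <- ps$values[["detection_incident_new"]] -
    ps$values[["detection_incident_current"]]
  if (base_gap > 0) {
    # scaled so that the draw collapses to the base-case extra detection as
    # the sampling spread goes to zero
    v[["extra_detection_ns"]] <- max(
      v[["detection_incident_new"]] - v[["detection_incident_current"]], 0) *
      ps$values[["extra_detection_ns"]] / base_gap
  } else {
    v[["extra_detection_ns"]] <- rbeta_mom(ps$values[["extra_detection_ns"]])
  }
  dec <- ps$values[["utility_success"]] - ps$values[["utility_failure"]]
  v[["utility_success"]] <- min(1, v[["utility_failure"]] + rbeta_mom(dec))
  ps$values <- v
  ps <- .repair_groups(ps)
  derive_cycle_probabilities(ps)
}

# Set one parameter for the one-way analysis, keeping the set coherent:
# bounded domains are capped to [0,1], other members of a branch group are
# rescaled to the remaining mass, and outcome-pair partners are reduced
# when the pair would exceed 1.
.set_owsa_value <- function(ps, nm, val) {
  i <- match(nm, ps$meta$name)
  dom <- ps$meta$domain[i]
  if (dom %in% c("probability", "utility", "fraction")) {
    val <- min(max(val, 0), 1)
  } else if (dom == "cost-eur") {
    val <- max(val, 0)
  }
  ps$values[[nm]] <- val
  g <- ps$meta$group[i]
  if (!is.na(g)) {
    others <- setdiff(ps$meta$name[!is.na(ps$meta$group) &
                                     ps$meta$group == g], nm)
    s <- sum(ps$values[others])
    if (s > 0) {
      ps$values[others] <- ps$values[others] * (1 - val) / s
    }
  }
  for (pr in .outcome_pairs) {
    if (nm %in% pr) {
      other <- setdiff(pr, nm)
      excess <- sum(ps$values[pr]) - 1
      if (excess > 0) {
        ps$values[other] <- pmax(ps$values[other] - excess, 0)
      }
    }
  }
  derive_cycle_probabilities(ps)
}

#' One-way sensitivity analysis (tornado)
#'
#' Recomputes the per-patient incremental results with every non-structural
#' parameter set, one at a time, to mean x (1 - `range_frac`) and mean x
#' (1 + `range_frac`) (probabilities capped at 1, branch groups
#' renormalized). Parameters whose perturbation cannot produce a valid set
#' are skipped and logged in the `skipped` attribute.
#'
#' @param ps A `ui_params` object.
#' @param range_frac Relative perturbation (default 0.4, i.e. +/-40%).
#' @return A data frame of class `ui_tornado`, ordered by decreasing range
#'   of the societal incremental cost, with the low/high incremental
#'   societal cost, payer cost and QALYs per parameter.
#' @export
one_way_sensitivity <- function(ps, range_frac = 0.4) {
  stopifnot(inherits(ps, "ui_params"))
  base <- incrementals(per_patient_results(ps))
  m <- ps$meta
  vary <- m$name[m$psa != "fixed" & m$source != "derived"]
  rows <- list(); skipped <- character()
  for (nm in vary) {
    b <- ps$values[[nm]]
    eval_at <- function(mult) {
      tryCatch({
        psx <- .set_owsa_value(ps, nm, b * mult)
        incrementals(per_patient_results(psx))
      }, error = function(e) NULL)
    }
    lo <- eval_at(1 - range_frac)
    hi <- eval_at(1 + range_frac)
    if (is.null(lo) || is.null(hi)) { skipped <- c(skipped, nm); next }
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = nm, base_value = b,
      dcost_societal_low = lo$delta_cost_societal,
      dcost_societal_high = hi$delta_cost_societal,
      dcost_payer_low = lo$delta_cost_payer,
      dcost_payer_high = hi$delta_cost_payer,
      dqaly_low = lo$delta_qalys, dqaly_high = hi$delta_qalys,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$range <- abs(out$dcost_societal_high - out$dcost_societal_low)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  structure(out, class = c("ui_tornado", "data.frame"),
            base = base, range_frac = range_frac, skipped = skipped)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` parameter sets with [sample_parameter_set()] and runs
#' the full per-patient model on each, summarising the joint uncertainty in
#' incremental costs and QALYs.
#'
#' @param ps A `ui_params` object.
#' @param n_draws Number of draws (default 1000).
#' @param se_frac Standard error as a fraction of the mean (0.2 default;
#'   0.4 for the wide-uncertainty analysis).
#' @param seed Integer seed; the analysis is fully reproducible given the
#'   seed.
#' @return An object of class `ui_psa`: the per-draw incrementals
#'   (`draws`), and a `summary` list with the probability of cost savings
#'   (societal), of a QALY loss, of dominance (cost-saving and more
#'   effective), and 2.5/97.5 percentiles of incremental cost and QALYs.
#' @examples
#' \donttest{
#' psa <- probabilistic_sensitivity(base_case_parameters(),
#'                                  n_draws = 100, seed = 1)
#' psa$summary$prob_cost_saving
#' }
#' @export
probabilistic_sensitivity <- function(ps, n_draws = 1000, se_frac = 0.2,
                                      seed = 1L) {
  stopifnot(inherits(ps, "ui_params"), n_draws >= 1)
  set.seed(seed)
  dsoc <- dpay <- dq <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    inc <- incrementals(per_patient_results(sample_parameter_set(ps, se_frac)))
    dsoc[i] <- inc$delta_cost_societal
    dpay[i] <- inc$delta_cost_payer
    dq[i] <- inc$delta_qalys
  }
  draws <- data.frame(dcost_societal = dsoc, dcost_payer = dpay, dqaly = dq)
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  structure(list(
    n_draws = n_draws, se_frac = se_frac, seed = seed, draws = draws,
    summary = list(
      prob_cost_saving = mean(dsoc < 0),
      prob_cost_saving_payer = mean(dpay < 0),
      prob_qaly_loss = mean(dq < 0),
      prob_dominant = mean(dsoc < 0 & dq > 0),
      ci_dcost_societal = qs(dsoc),
      ci_dqaly = qs(dq),
      mean_dcost_societal = mean(dsoc),
      mean_dqaly = mean(dq))
  ), class = "ui_psa")
}

#' @export
print.ui_psa <- function(x, ...) {
  s <- x$summary
  cat(sprintf("PSA: %d draws, SE = %.0f%% of mean (seed %d)\n",
              x$n_draws, 100 * x$se_frac, x$seed))
  cat(sprintf("  P(cost saving, societal) = %.1f%%\n",
              100 * s$prob_cost_saving))
  cat(sprintf("  P(QALY loss)             = %.1f%%\n", 100 * s$prob_qaly_loss))
  cat(sprintf("  P(dominant)              = %.1f%%\n", 100 * s$prob_dominant))
  cat(sprintf("  dCost societal 95%% range: %.0f to %.0f euro\n",
              s$ci_dcost_societal[1], s$ci_dcost_societal[2]))
  cat(sprintf("  dQALY 95%% range: %.4f to %.4f\n",
              s$ci_dqaly[1], s$ci_dqaly[2]))
  invisible(x)
}
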