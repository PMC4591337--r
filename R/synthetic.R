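# ---------------------------------------------------------------------------
# Synthetic data: a parametric life table standing in for national
# statistics, randomized-but-valid parameter sets for property testing,
# and an individual-level microsimulation that re-implements the care
# pathway patient by patient, independently of the cohort engine, as a
# cross-validation oracle.
# ---------------------------------------------------------------------------

#' Generate a synthetic life table
#'
#' A Gompertz-type mortality curve by 5-year age band (65-100) and sex:
#' `q(age) = base_q65 * exp(slope * (age - 65))`, with a male excess
#' multiplier and a seeded lognormal level shift per sex. This is a
#' synthetic stand-in for national life tables, not observed data; budget
#' impact computed from it is indicative only.
#'
#' @param seed Integer seed (deterministic output given the seed).
#' @param base_q65 Yearly death probability at age 65 (female), in (0,1).
#' @param slope Log-linear increase per year of age (default 0.085,
#'   doubling roughly every 8 years). `slope = 0` gives a flat profile.
#' @param male_excess Multiplier on male mortality (default 1.5).
#' @return A data frame with columns `age_band`, `sex`, `q_yearly`.
#' @export
generate_life_table <- function(seed = 1L, base_q65 = 0.025, slope = 0.085,
                                male_excess = 1.5) {
  if (base_q65 <= 0 || base_q65 >= 1) {
    stop("base_q65 must lie in (0,1)", call. = FALSE)
  }
  if (slope < 0) stop("slope must be non-negative", call. = FALSE)
  ages <- seq(65, 100, by = 5)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  shift <- exp(stats::rnorm(2, 0, 0.05))    # one level factor per sex
  rows <- list()
  for (s in c("male", "female")) {
    mult <- if (s == "male") male_excess * shift[1] else shift[2]
    q <- pmin(base_q65 * mult * exp(slope * (ages - 65)), 0.99)
    rows[[s]] <- data.frame(age_band = ages, sex = s, q_yearly = q,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a randomized but valid parameter set
#'
#' Draws every non-structural parameter at random within its domain
#' (probabilities uniform on \[0,1\], costs log-normally scattered around
#' the template values, utilities ordered), renormalizes branch groups and
#' refreshes the derived values. The result always passes
#' [validate_parameter_set()]; it is meant for property-based testing of
#' the engine invariants, not as a plausible clinical scenario.
#'
#' @param seed Integer seed.
#' @param ps_template Template `ui_params` (defaults to the base case).
#' @return A valid `ui_params` object.
#' @export
generate_random_parameter_set <- function(seed,
                                          ps_template = base_case_parameters()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ps <- ps_template
  m <- ps$meta
  for (i in seq_len(nrow(m))) {
    nm <- m$name[i]
    if (m$psa[i] == "fixed" || m$source[i] == "derived") next
    if (m$psa[i] == "beta") {
      ps$values[[nm]] <- stats::runif(1)
    } else {
      ps$values[[nm]] <- ps$values[[nm]] * exp(stats::rnorm(1, 0, 0.5))
    }
  }
  u <- sort(stats::runif(2, 0.4, 1))
  ps$values[["utility_failure"]] <- u[1]
  ps$values[["utility_success"]] <- u[2]
  # yearly UTI rates: keep excess non-negative and below 1
  r <- sort(stats::runif(2, 0, 1))
  ps$values[["uti_yearly_no_oab"]] <- r[1]
  ps$values[["uti_yearly_oab"]] <- r[2]
  ps <- .repair_groups(ps)
  derive_cycle_probabilities(ps)
}

# categorical draw: index in 1..length(probs) for each row of u
.rdraw <- function(u, probs) {
  probs <- probs / sum(probs)
  findInterval(u, cumsum(probs)[-length(probs)]) + 1L
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_patients` one at a time through the detection tree and the
#' cure pathway by sequential random draws at every decision node, using
#' the same parameters and structural wiring as the cohort engine but none
#' of its code. The empirical state occupancies converge to the cohort
#' engine's deterministic occupancies at rate `1/sqrt(n)`, which makes the
#' microsimulation an independent cross-check of the engine.
#'
#' @param arm `"current"` or `"new"`.
#' @param cohort `"incident"` or `"prevalent"`. For the prevalent cohort
#'   the starting allocation (itself defined via the engine warm-up) is
#'   taken as an input.
#' @param ps A `ui_params` object.
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed (a fixed seed fully determines every path).
#' @param horizon Number of cycles (default: the model horizon).
#' @return An object of class `ui_microsim`: `occupancy` (rows
#'   `0..horizon`, columns `incontinent`, `improved`, `success`,
#'   proportions), `se` (binomial standard errors), `n_patients`, `seed`.
#' @export
microsim_oracle <- function(arm, cohort = c("incident", "prevalent"), ps,
                            n_patients = 10000, seed = 1L, horizon = NULL) {
  cohort <- match.arg(cohort)
  arm <- match.arg(arm, c("current", "new"))
  stopifnot(n_patients >= 1)
  if (is.null(horizon)) horizon <- ps$settings$horizon_cycles
  v <- ps$values
  w <- .default_wiring()
  n <- as.integer(n_patients)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # location codes
  ND <- 1L; CONT <- 2L; SELF <- 3L; STOP <- 4L; DONE <- 5L
  GP <- 6L; NSI <- 7L; NSM <- 8L; PPT <- 9L; SPF <- 10L; SPP <- 11L
  QMG <- 12L; QMN <- 13L; QMS <- 14L; QTP <- 15L; QTN <- 16L; SUC <- 17L
  improved_codes <- c(DONE, QMG, QMN, QMS, QTP, QTN)

  primary_gp <- arm == "current"
  PRIM <- if (primary_gp) GP else NSM   # where referred-back failures go
  det <- if (primary_gp) v[["detection_incident_current"]] else
    v[["detection_incident_new"]]
  strat <- if (primary_gp) {
    c(v[["cur_strat_cure"]], v[["cur_strat_containment"]],
      v[["cur_strat_self"]])
  } else {
    c(v[["new_strat_cure"]], v[["new_strat_containment"]],
      v[["new_strat_self"]])
  }
  pfmt_imp <- if (primary_gp) v[["ppt_pfmt_improvement_current"]] else
    v[["ppt_pfmt_improvement_new"]]
  t2 <- if (primary_gp) {
    c(imp = v[["train2_improvement_current"]],
      succ = v[["train2_success_current"]])
  } else {
    c(imp = v[["train2_improvement_new"]], succ = v[["train2_success_new"]])
  }
  t2 <- t2 / sum(t2)

  loc <- integer(n)
  if (cohort == "incident") {
    detected <- stats::runif(n) < det
    loc[!detected] <- ND
    idx <- which(detected)
    s <- .rdraw(stats::runif(length(idx)), strat)
    loc[idx[s == 2L]] <- CONT
    loc[idx[s == 3L]] <- SELF
    cure <- idx[s == 1L]
    if (primary_gp) {
      u <- stats::runif(length(cure))
      ppt_assessed <- u < v[["cur_assess_ppt"]] /
        (v[["cur_assess_ppt"]] + v[["cur_assess_gp"]])
      loc[cure[ppt_assessed]] <- PPT
      loc[cure[!ppt_assessed]] <- GP
    } else {
      loc[cure] <- NSI
    }
  } else {
    alloc <- derive_prevalent_allocation(arm, ps)
    probs <- c(alloc$undetected, alloc$cure, alloc$containment_only,
               alloc$self_management)
    s <- .rdraw(stats::runif(n), probs)
    loc[s == 1L] <- ND
    loc[s == 3L] <- CONT
    loc[s == 4L] <- SELF
    cure <- which(s == 2L)
    pr <- .rdraw(stats::runif(length(cure)), c(1, 1, 1) / 3)
    loc[cure[pr == 1L]] <- if (primary_gp) GP else NSI
    loc[cure[pr == 2L]] <- PPT
    loc[cure[pr == 3L]] <- SPF
  }

  occ <- matrix(0, nrow = horizon + 1, ncol = 3,
                dimnames = list(NULL, c("incontinent", "improved", "success")))
  snap <- function(loc) {
    c(mean(!loc %in% c(improved_codes, SUC)),
      mean(loc %in% improved_codes), mean(loc == SUC))
  }
  occ[1, ] <- snap(loc)

  p76 <- v[["med_second_cycle"]]
  ns_fail_cont <- v[["ns_fail_continue"]] /
    (v[["ns_fail_continue"]] + v[["ns_fail_referred"]])
  refer_outcome <- function(k, p_ref, p_ppt, dest_ppt, dest_spec, dest_stay) {
    # returns destination codes for k failures
    out <- rep(dest_stay, k)
    ref <- stats::runif(k) < p_ref
    toppt <- stats::runif(k) < p_ppt
    out[ref & toppt] <- dest_ppt
    out[ref & !toppt] <- dest_spec
    out
  }
  three_way <- function(k, p_succ, p_imp) {
    # 1 success, 2 improvement, 3 failure
    .rdraw(stats::runif(k), c(p_succ, p_imp, max(1 - p_succ - p_imp, 0)))
  }

  for (t in seq_len(horizon)) {
    nxt <- loc

    # specialist redirect (fresh arrivals only, same cycle)
    spf <- which(loc == SPF)
    redirected <- spf[stats::runif(length(spf)) < v[["spec_to_ppt"]]]
    ppt_now <- c(which(loc == PPT), redirected)
    spec_now <- c(which(loc == SPP), setdiff(spf, redirected))

    ## GP treatment
    i <- which(loc == GP)
    if (length(i)) {
      ther <- .rdraw(stats::runif(length(i)),
                     c(v[["gp_mix_meds"]], v[["gp_mix_lifestyle"]],
                       v[["gp_mix_uti"]], v[["gp_mix_training"]]))
      psucc <- c(v[["gp_meds_success"]], v[["gp_lifestyle_success"]],
                 v[["gp_uti_success"]], v[["gp_training_success"]])[ther]
      pimp <- c(v[["gp_meds_improvement"]], v[["gp_lifestyle_improvement"]],
                v[["gp_uti_improvement"]], v[["gp_training_improvement"]])[ther]
      u <- stats::runif(length(i))
      res <- ifelse(u < psucc, 1L, ifelse(u < psucc + pimp, 2L, 3L))
      nxt[i[res == 1L]] <- SUC
      impmed <- i[res == 2L & ther == 1L]
      nxt[impmed] <- ifelse(stats::runif(length(impmed)) < p76, QMG, DONE)
      nxt[i[res == 2L & ther != 1L]] <- DONE
      fl <- i[res == 3L]
      nxt[fl] <- refer_outcome(length(fl), v[["gp_immediate_referral"]],
                               v[["gp_ref_ppt"]] /
                                 (v[["gp_ref_ppt"]] + v[["gp_ref_spec"]]),
                               PPT, SPF, STOP)
    }

    ## NS initial programme
    i <- which(loc == NSI)
    if (length(i)) {
      init <- stats::runif(length(i)) <
        v[["ns_initial_share"]] / (v[["ns_initial_share"]] + v[["ns_uti_share"]])
      res <- integer(length(i))
      res[init] <- three_way(sum(init), v[["ns_initial_success"]],
                             v[["ns_initial_improvement"]])
      res[!init] <- three_way(sum(!init), v[["ns_uti_success"]],
                              v[["ns_uti_improvement"]])
      nxt[i[res == 1L]] <- SUC
      imp_in <- i[res == 2L & init]
      nxt[i[res == 2L & !init]] <- DONE
      if (w$ns_improver == "train_once") {
        nxt[imp_in] <- QTN
      } else if (w$ns_improver == "medcont") {
        nxt[imp_in] <- ifelse(stats::runif(length(imp_in)) < p76, QMN, DONE)
      } else {
        nxt[imp_in] <- DONE
      }
      fl <- i[res == 3L]
      cont <- stats::runif(length(fl)) < ns_fail_cont
      nxt[fl[cont]] <- NSM
      refs <- fl[!cont]
      toppt <- stats::runif(length(refs)) <
        v[["ns_ref_ppt"]] / (v[["ns_ref_ppt"]] + v[["ns_ref_spec"]])
      nxt[refs[toppt]] <- PPT
      nxt[refs[!toppt]] <- SPF
    }

    ## NS medication attempt
    i <- which(loc == NSM)
    if (length(i)) {
      treated <- stats::runif(length(i)) < v[["ns_meds_share"]]
      nxt[i[!treated]] <- STOP
      ii <- i[treated]
      res <- three_way(length(ii), v[["ns_meds_success"]],
                       v[["ns_meds_improvement"]])
      nxt[ii[res == 1L]] <- SUC
      imp <- ii[res == 2L]
      nxt[imp] <- ifelse(stats::runif(length(imp)) < p76, QMN, DONE)
      fl <- ii[res == 3L]
      nxt[fl] <- refer_outcome(length(fl), v[["ns_fail_referred"]],
                               v[["ns_ref_ppt"]] /
                                 (v[["ns_ref_ppt"]] + v[["ns_ref_spec"]]),
                               PPT, SPF, STOP)
    }

    ## physiotherapist
    i <- ppt_now
    if (length(i)) {
      pf <- stats::runif(length(i)) <
        v[["ppt_pfmt_share"]] / (v[["ppt_pfmt_share"]] + v[["ppt_bio_share"]])
      res <- integer(length(i))
      res[pf] <- three_way(sum(pf), v[["ppt_pfmt_success"]], pfmt_imp)
      res[!pf] <- three_way(sum(!pf), v[["ppt_bio_success"]],
                            v[["ppt_bio_improvement"]])
      nxt[i[res == 1L]] <- SUC
      imp <- i[res == 2L]
      nxt[imp] <- ifelse(stats::runif(length(imp)) < v[["train_continue"]],
                         QTP, DONE)
      fl <- i[res == 3L]
      togp <- stats::runif(length(fl)) <
        v[["ppt_fail_to_gp"]] / (v[["ppt_fail_to_gp"]] + v[["ppt_fail_to_spec"]])
      nxt[fl[togp]] <- PRIM
      nxt[fl[!togp]] <- SPP
    }

    ## specialist
    i <- spec_now
    if (length(i)) {
      ther <- .rdraw(stats::runif(length(i)),
                     c(v[["spec_mix_surgery"]], v[["spec_mix_conservative"]],
                       v[["spec_mix_meds"]]))
      psucc <- c(v[["spec_surgery_success"]], v[["spec_conservative_success"]],
                 v[["spec_meds_success"]])[ther]
      pimp <- c(v[["spec_surgery_improvement"]],
                v[["spec_conservative_improvement"]],
                v[["spec_meds_improvement"]])[ther]
      u <- stats::runif(length(i))
      res <- ifelse(u < psucc, 1L, ifelse(u < psucc + pimp, 2L, 3L))
      nxt[i[res == 1L]] <- SUC
      impmed <- i[res == 2L & ther == 3L]
      nxt[impmed] <- ifelse(stats::runif(length(impmed)) < p76, QMS, DONE)
      nxt[i[res == 2L & ther != 3L]] <- DONE
      fl <- i[res == 3L]
      back <- stats::runif(length(fl)) < v[["spec_fail_to_gp"]]
      nxt[fl[back]] <- PRIM
      nxt[fl[!back]] <- STOP
    }

    ## continuation cycles
    for (qc in c(QMG, QMN, QMS)) {
      i <- which(loc == qc)
      if (length(i)) {
        nxt[i] <- ifelse(stats::runif(length(i)) < v[["med_cont_success"]] /
                           (v[["med_cont_success"]] + v[["med_cont_improvement"]]),
                         SUC, DONE)
      }
    }
    i <- which(loc == QTP)
    if (length(i)) {
      sc <- stats::runif(length(i)) < t2[["succ"]]
      nxt[i[sc]] <- SUC
      rem <- i[!sc]
      if (w$train_repeat) {
        nxt[rem] <- ifelse(stats::runif(length(rem)) < v[["train_continue"]],
                           QTP, DONE)
      } else {
        nxt[rem] <- DONE
      }
    }
    i <- which(loc == QTN)
    if (length(i)) {
      sc <- stats::runif(length(i)) < t2[["succ"]]
      nxt[i[sc]] <- SUC
      nxt[i[!sc]] <- DONE
    }

    loc <- nxt
    occ[t + 1, ] <- snap(loc)
  }

  se <- sqrt(occ * (1 - occ) / n)
  structure(list(occupancy = occ, se = se, n_patients = n, seed = seed,
                 arm = arm, cohort = cohort, horizon = horizon),
            class = "ui_microsim")
}

#' @export
print.ui_microsim <- function(x, ...) {
  f <- x$occupancy[nrow(x$occupancy), ]
  cat(sprintf(
    "<ui_microsim> %s/%s, n=%d: success %.2f%% (SE %.2f), improved %.2f%%\n",
    x$arm, x$cohort, x$n_patients, 100 * f[["success"]],
    100 * x$se[nrow(x$se), "success"], 100 * f[["improved"]]))
  invisible(x)
}

#' Aggregate engine occupancy to the three health states
#'
#' Helper for comparing a cohort trace against the microsimulation oracle.
#'
#' @param trace A `ui_trace`.
#' @return A matrix with columns `incontinent`, `improved`, `success`.
#' @export
aggregate_occupancy <- function(trace) {
  occ <- trace$occupancy
  cbind(
    incontinent = rowSums(occ[, c("nd", "selfm", "cont", "stopped", "active"),
                              drop = FALSE]),
    improved = occ[, "improved"],
    success = occ[, "succ"]
  )
}
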