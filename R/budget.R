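# ---------------------------------------------------------------------------
# National budget impact: yearly incident inflow on top of the prevalent
# pool, with attrition by death and nursing-home admission applied at year
# boundaries, uniformly across pathway states (no state-dependent mortality
# is available). Patients who die or move to a nursing home accrue no
# further costs.
# ---------------------------------------------------------------------------

#' Build a demography table from a life table
#'
#' @param life_table A data frame as returned by [generate_life_table()]
#'   (columns `age_band`, `sex`, `q_yearly`).
#' @param weights Optional stratum weights (same row order); defaults to a
#'   synthetic age pyramid of the multimorbid 65+ population combined with
#'   the 23/77 male/female split of the prevalent cases.
#' @param nursing_home_rate Yearly probability of moving to a nursing home
#'   (default 0.04).
#' @return A data frame of class `ui_demography` with columns `age_band`,
#'   `sex`, `weight`, `q1`, `q2`, `q3` (cumulative 1/2/3-year death
#'   probabilities) and the nursing-home rate as an attribute.
#' @export
build_demography <- function(life_table, weights = NULL,
                             nursing_home_rate = 0.04) {
  stopifnot(all(c("age_band", "sex", "q_yearly") %in% names(life_table)))
  lt <- life_table
  if (is.null(weights)) {
    # synthetic age pyramid: multimorbidity rises, survivorship falls
    age_w <- c("65" = 0.24, "70" = 0.24, "75" = 0.20, "80" = 0.15,
               "85" = 0.10, "90" = 0.05, "95" = 0.015, "100" = 0.005)
    sex_w <- c(male = 0.23, female = 0.77)
    weights <- age_w[as.character(lt$age_band)] * sex_w[lt$sex]
  }
  weights <- weights / sum(weights)
  q <- lt$q_yearly
  if (any(q < 0 | q > 1)) stop("death probabilities outside [0,1]",
                               call. = FALSE)
  out <- data.frame(
    age_band = lt$age_band, sex = lt$sex, weight = weights,
    q1 = 1 - (1 - q), q2 = 1 - (1 - q)^2, q3 = 1 - (1 - q)^3,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "nursing_home_rate") <- nursing_home_rate
  class(out) <- c("ui_demography", class(out))
  out
}

#' Read a demography file
#'
#' @param path CSV with columns `age_band,sex,weight,q1,q2,q3`.
#' @param nursing_home_rate Yearly nursing-home admission probability.
#' @return A `ui_demography` object.
#' @export
read_demography <- function(path, nursing_home_rate = 0.04) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_band", "sex", "weight", "q1", "q2", "q3")
  if (!all(need %in% names(df))) {
    stop("demography file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df$weight <- df$weight / sum(df$weight)
  attr(df, "nursing_home_rate") <- nursing_home_rate
  class(df) <- c("ui_demography", class(df))
  df
}

# Stratum-weighted probability of still being in the community k years
# after entry (alive and not admitted to a nursing home).
.retention <- function(demo, k) {
  if (k == 0) return(1)
  nh <- attr(demo, "nursing_home_rate")
  qk <- demo[[paste0("q", k)]]
  if (any(qk > 1 | qk < 0)) stop("attrition probabilities exceed 1",
                                 call. = FALSE)
  sum(demo$weight * (1 - qk)) * (1 - nh)^k
}

#' National budget impact over the analysis period
#'
#' Projects national costs for both arms: the first year covers all
#' prevalent and incident patients; each later year adds a fresh incident
#' cohort while existing patients are attenuated by stratum-weighted
#' mortality and nursing-home admission at year boundaries. Implementation
#' costs of the new arm are booked nationally per year.
#'
#' @param ps A `ui_params` object.
#' @param demo A `ui_demography` object (synthetic or user-supplied).
#' @param years Projection horizon in years (default 3).
#' @param cohorts Which cohorts to include (default both).
#' @return An object of class `ui_budget`: per-arm and incremental totals
#'   (euro) for the societal and payer perspective.
#' @export
project_budget_impact <- function(ps, demo, years = 3,
                                  cohorts = c("prevalent", "incident")) {
  stopifnot(inherits(ps, "ui_params"), inherits(demo, "ui_demography"))
  v <- ps$values
  cycles_per_year <- round(1 / ps$settings$cycle_length_years)

  arm_totals <- function(arm) {
    total <- stats::setNames(numeric(length(.cost_categories)),
                             .cost_categories)
    entries <- list()
    if ("prevalent" %in% cohorts) {
      entries[[length(entries) + 1L]] <-
        list(cohort = "prevalent", entry = 1, n = v[["n_prevalent_national"]])
    }
    if ("incident" %in% cohorts) {
      for (y in seq_len(years)) {
        entries[[length(entries) + 1L]] <-
          list(cohort = "incident", entry = y, n = v[["n_incident"]])
      }
    }
    cost_cache <- list()
    for (e in entries) {
      key <- e$cohort
      if (is.null(cost_cache[[key]])) {
        tr <- run_cohort(arm, e$cohort, ps)
        cost_cache[[key]] <- cycle_cost_matrix(tr, ps)
      }
      cm <- cost_cache[[key]]
      max_cycles <- (years - e$entry + 1) * cycles_per_year
      for (cyc in seq_len(min(nrow(cm), max_cycles))) {
        k <- (cyc - 1) %/% cycles_per_year   # years since cohort entry
        total <- total + e$n * .retention(demo, k) * cm[cyc, ]
      }
    }
    if (arm == "new") {
      total[["implementation"]] <- total[["implementation"]] +
        v[["cost_implementation_annual"]] *
        ps$settings$implementation_share / .impl_base_share * years
    }
    total
  }
  cur <- arm_totals("current")
  new <- arm_totals("new")
  out <- data.frame(
    perspective = c("societal", "payer"),
    current = c(societal_total(structure(cur, class = "ui_costs")),
                payer_total(structure(cur, class = "ui_costs"))),
    new = c(societal_total(structure(new, class = "ui_costs")),
            payer_total(structure(new, class = "ui_costs"))),
    stringsAsFactors = FALSE
  )
  out$incremental <- out$new - out$current
  structure(out, class = c("ui_budget", "data.frame"),
            categories = list(current = cur, new = new), years = years)
}

#' @export
print.ui_budget <- function(x, ...) {
  cat(sprintf("Budget impact over %d years (million euro)\n",
              attr(x, "years")))
  disp <- as.data.frame(unclass(x))[c("perspective", "current", "new",
                                      "incremental")]
  disp[-1] <- round(disp[-1] / 1e6, 1)
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}
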