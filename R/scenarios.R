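# ---------------------------------------------------------------------------
# Scenario analyses and ICER computation. Scenarios are pure parameter /
# configuration transforms over the same engine (no forks):
#   * full_implementation: the complete training cost is attributed to the
#     modelled population (implementation share 100% instead of 23.8%),
#   * detection_only: the nurse specialist improves detection but care
#     effectiveness equals the usual pathway (NS consultations still occur
#     and are costed at the NS tariff),
#   * effectiveness_only: NS-led treatment retained but detection stays at
#     the usual-care level.
# ---------------------------------------------------------------------------

#' Run a scenario analysis
#'
#' @param name One of `"full_implementation"`, `"detection_only"`,
#'   `"effectiveness_only"`.
#' @param ps A `ui_params` object.
#' @return A `ui_results` table (see [per_patient_results()]).
#' @examples
#' \donttest{
#' run_scenario("full_implementation", base_case_parameters())
#' }
#' @export
run_scenario <- function(name, ps) {
  stopifnot(inherits(ps, "ui_params"))
  name <- match.arg(name, c("full_implementation", "detection_only",
                            "effectiveness_only"))
  if (name == "full_implementation") {
    ps$settings$implementation_share <- 1.0
    return(per_patient_results(ps))
  }
  per_patient_results(ps, scenario = name)
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' @param delta_cost Incremental cost (euro), new minus comparator.
#' @param delta_qaly Incremental QALYs.
#' @param tol Values within `tol` of zero are treated as zero.
#' @return A list of class `ui_icer`: `delta_cost`, `delta_qaly`,
#'   `classification` (`"dominant"`, `"dominated"`, `"icer-defined"` or
#'   `"equivalent"`) and `icer` (euro/QALY; `NA` unless icer-defined).
#' @examples
#' icer(58, 0.004)    # 14500 euro/QALY
#' icer(-402, 0.005)  # dominant
#' @export
icer <- function(delta_cost, delta_qaly, tol = 1e-12) {
  dc <- if (abs(delta_cost) <= tol) 0 else delta_cost
  dq <- if (abs(delta_qaly) <= tol) 0 else delta_qaly
  if (dc == 0 && dq == 0) {
    cls <- "equivalent"; val <- NA_real_
  } else if (dc <= 0 && dq >= 0) {
    cls <- "dominant"; val <- NA_real_
  } else if (dc >= 0 && dq <= 0) {
    cls <- "dominated"; val <- NA_real_
  } else {
    cls <- "icer-defined"; val <- dc / dq
  }
  structure(list(delta_cost = delta_cost, delta_qaly = delta_qaly,
                 classification = cls, icer = val),
            class = "ui_icer")
}

#' @export
print.ui_icer <- function(x, ...) {
  cat(sprintf("dCost %.2f, dQALY %.5f -> %s", x$delta_cost, x$delta_qaly,
              x$classification))
  if (!is.na(x$icer)) cat(sprintf(" (%.0f euro/QALY)", x$icer))
  cat("\n")
  invisible(x)
}
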