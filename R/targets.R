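#' Transform IC50 values to regression targets
#'
#' Maps an IC50 measurement (nM) to the unit-interval regression target
#' \deqn{y = 1 - \log(IC_{50}) / \log(\mathrm{cap})}{y = 1 - log(IC50)/log(cap)}
#' clipped to \[0, 1\]. With the default 50000 nM cap (the standard ceiling on
#' quantitative binding-affinity measurements), an IC50 of 1 nM maps to 1 and
#' the cap maps to 0; the transform is strictly decreasing in between, so
#' stronger binders get larger targets.
#'
#' @param ic50_nm Positive IC50 value(s) in nM.
#' @param cap_nm Cap of the transform, > 1. Default 50000 nM.
#' @return Numeric vector of targets in \[0, 1\].
#' @examples
#' ic50_to_target(c(1, 500, 50000))
#' @seealso [target_to_ic50()]
#' @export
ic50_to_target <- function(ic50_nm, cap_nm = 50000) {
  if (any(!is.finite(ic50_nm)) || any(ic50_nm <= 0)) {
    stop("ic50_nm must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(cap_nm) || length(cap_nm) != 1L || cap_nm <= 1) {
    stop("cap_nm must be a single value > 1", call. = FALSE)
  }
  pmin(pmax(1 - log(ic50_nm) / log(cap_nm), 0), 1)
}

#' Back-transform regression targets to IC50
#'
#' Exact inverse of [ic50_to_target()] on \[0, 1\]:
#' \eqn{IC_{50} = \mathrm{cap}^{1-y}}. Raw model outputs are unconstrained
#' reals, so values outside \[0, 1\] are clipped first (with a warning) before
#' conversion; predictions are reported in nM on the clipped scale.
#'
#' @param y Regression target(s).
#' @inheritParams ic50_to_target
#' @return IC50 value(s) in nM.
#' @export
target_to_ic50 <- function(y, cap_nm = 50000) {
  if (any(y < 0 | y > 1, na.rm = TRUE)) {
    warning("clipping ", sum(y < 0 | y > 1, na.rm = TRUE),
            " target value(s) outside [0, 1] before IC50 conversion",
            call. = FALSE)
    y <- pmin(pmax(y, 0), 1)
  }
  cap_nm^(1 - y)
}

# Map IC50-space inequality codes to the bound direction in y-space. The log
# transform reverses order: IC50 < bound means y > y(bound) ("at_least"), and
# IC50 > bound means y < y(bound) ("at_most").
ineq_to_bound <- function(inequality) {
  out <- c(EQ = "point", LT = "at_least", GT = "at_most")[inequality]
  if (any(is.na(out))) {
    stop("inequality must be one of EQ, LT, GT", call. = FALSE)
  }
  unname(out)
}

#' Censored mean-squared-error loss
#'
#' Squared-error loss extended to censored (qualitative) measurements. For a
#' point target the loss is the usual `(y_pred - y)^2`. For a target known
#' only as a bound in y-space, only violations are penalised:
#' `"at_least"` (true value is at least `y`) penalises under-prediction with
#' `max(0, y - y_pred)^2`, and `"at_most"` penalises over-prediction with
#' `max(0, y_pred - y)^2`. This lets qualitative records (e.g. non-binders
#' reported only as "IC50 above the assay bound") contribute to training
#' without asserting an exact affinity.
#'
#' @param y_pred Predicted target value(s).
#' @param y True target value(s) or bound(s), in \[0, 1\].
#' @param bound Character vector: `"point"`, `"at_least"` or `"at_most"`
#'   (recycled).
#' @param reduce If `TRUE` (default) return the unweighted mean over records,
#'   else the per-record losses.
#' @return Non-negative loss value(s).
#' @examples
#' censored_mse(0.5, 0.3, "at_most")   # 0.04: over-prediction penalised
#' censored_mse(0.8, 0.6, "at_least")  # 0: bound satisfied
#' @export
censored_mse <- function(y_pred, y, bound = "point", reduce = TRUE) {
  n <- max(length(y_pred), length(y), length(bound))
  y_pred <- rep_len(y_pred, n)
  y <- rep_len(y, n)
  bound <- rep_len(bound, n)
  if (!all(bound %in% c("point", "at_least", "at_most"))) {
    stop("bound must be 'point', 'at_least' or 'at_most'", call. = FALSE)
  }
  resid <- y_pred - y
  loss <- ifelse(
    bound == "point", resid^2,
    ifelse(bound == "at_least", pmax(0, -resid)^2, pmax(0, resid)^2)
  )
  if (reduce) mean(loss) else loss
}

#' Binary binder label from an IC50 threshold
#'
#' A peptide is labelled a binder iff its IC50 is strictly below the
#' threshold. Conventional thresholds: 500 nM for MHC class I, 1000 nM for
#' class II, and 100000 nM for assays that only distinguish binders from
#' non-binders at the measurement ceiling.
#'
#' @param ic50_nm Positive IC50 value(s) in nM.
#' @param threshold_nm Positive binder threshold in nM (default 500).
#' @return Integer vector of 0/1 labels.
#' @examples
#' binder_label(c(499, 500, 501))  # 1 0 0
#' @export
binder_label <- function(ic50_nm, threshold_nm = 500) {
  if (any(ic50_nm <= 0) || threshold_nm <= 0) {
    stop("ic50_nm and threshold_nm must be positive", call. = FALSE)
  }
  as.integer(ic50_nm < threshold_nm)
}

# Attach y-space targets and bound directions to affinity records.
# Qualitative LT records (IC50 below bound) become "at_least" targets in
# y-space, GT records become "at_most"; quantitative records are points.
records_to_targets <- function(records, cap_nm = 50000) {
  tibble::tibble(
    peptide = records$peptide,
    y = ic50_to_target(records$ic50_nm, cap_nm),
    bound = ineq_to_bound(records$inequality)
  )
}
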