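#' @include AllClasses.R
NULL

#' External-set performance report
#'
#' Two flavors of external R2 are computed, because published QSAR tables
#' rarely say which one they print: the squared Pearson correlation
#' between observed and predicted (insensitive to additive bias) and the
#' predictive R2, \eqn{1 - \sum (obs - pred)^2 / \sum (obs -
#' \bar y_{train})^2}, which penalizes bias against the training mean.
#'
#' @param y_obs,y_pred observed and predicted pEC50, equal length >= 3.
#' @param training_mean mean activity of the training set (for the
#'   predictive R2); defaults to \code{mean(y_obs)}.
#' @return list with \code{r2_test_pearson}, \code{r2_test_predictive},
#'   \code{rmse}.
#' @export
externalReport <- function(y_obs, y_pred, training_mean = mean(y_obs)) {
  if (length(y_obs) != length(y_pred) || length(y_obs) < 3L)
    stop("y_obs and y_pred must have equal length >= 3")
  if (stats::sd(y_obs) == 0) stop("y_obs is constant")
  list(r2_test_pearson = stats::cor(y_obs, y_pred)^2,
       r2_test_predictive =
         1 - sum((y_obs - y_pred)^2) / sum((y_obs - training_mean)^2),
       rmse = sqrt(mean((y_obs - y_pred)^2)))
}

#' Golbraikh-Tropsha external acceptability test
#'
#' The canonical criterion bundle for deciding whether an externally
#' validated QSAR model is acceptable: cross-validated Q2 above 0.5,
#' external r2 above 0.6, a near-unity regression-through-origin slope in
#' at least one direction with the corresponding through-origin r0^2
#' close to r2, and a small gap between the two through-origin r0^2
#' values.  Slopes: \eqn{k = \sum y\hat y / \sum \hat y^2},
#' \eqn{k' = \sum y\hat y / \sum y^2}; \eqn{r_0^2} is computed for
#' observed against \eqn{k\hat y}, \eqn{r_0'^2} for predicted against
#' \eqn{k' y}.
#'
#' @param y_obs,y_pred observed and predicted activity, equal length >= 3.
#' @param q2 cross-validated Q2 of the underlying model.
#' @return list with \code{q2}, \code{r2}, \code{r0_sq},
#'   \code{r0_sq_prime}, \code{k}, \code{k_prime}, a named logical
#'   \code{criteria} vector and \code{overall_pass} (their conjunction).
#' @export
golbraikhTropsha <- function(y_obs, y_pred, q2) {
  if (length(y_obs) != length(y_pred) || length(y_obs) < 3L)
    stop("y_obs and y_pred must have equal length >= 3")
  if (all(y_pred == 0)) stop("all predictions are zero")
  r2 <- stats::cor(y_obs, y_pred)^2
  k <- sum(y_obs * y_pred) / sum(y_pred^2)
  k_prime <- sum(y_obs * y_pred) / sum(y_obs^2)
  r0_sq <- 1 - sum((y_obs - k * y_pred)^2) / sum((y_obs - mean(y_obs))^2)
  r0_sq_prime <- 1 - sum((y_pred - k_prime * y_obs)^2) /
    sum((y_pred - mean(y_pred))^2)
  crit <- c(
    q2_gt_0.5 = q2 > 0.5,
    r2_gt_0.6 = r2 > 0.6,
    slope_and_r0 =
      ((r2 - r0_sq) / r2 < 0.1 && k >= 0.85 && k <= 1.15) ||
      ((r2 - r0_sq_prime) / r2 < 0.1 && k_prime >= 0.85 && k_prime <= 1.15),
    r0_gap_lt_0.3 = abs(r0_sq - r0_sq_prime) < 0.3)
  list(q2 = q2, r2 = r2, r0_sq = r0_sq, r0_sq_prime = r0_sq_prime,
       k = k, k_prime = k_prime, criteria = crit,
       overall_pass = all(crit))
}

#' Write an external validation report
#'
#' JSON report of \code{\link{externalReport}} and
#' \code{\link{golbraikhTropsha}}, plus a CSV pairwise table (id,
#' observed, predicted, residual).
#'
#' @param ids compound identifiers.
#' @param y_obs,y_pred observed and predicted pEC50.
#' @param q2 cross-validated Q2 of the model.
#' @param json_path,csv_path output paths (either may be \code{NULL} to
#'   skip).
#' @param training_mean training-set mean activity.
#' @return the combined report list, invisibly.
#' @export
writeValidationReport <- function(ids, y_obs, y_pred, q2,
                                  json_path = NULL, csv_path = NULL,
                                  training_mean = mean(y_obs)) {
  rep <- c(externalReport(y_obs, y_pred, training_mean),
           golbraikhTropsha(y_obs, y_pred, q2))
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, digits = NA, auto_unbox = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(data.frame(id = ids, obs = y_obs, pred = y_pred,
                                residual = y_obs - y_pred),
                     csv_path, row.names = FALSE)
  invisible(rep)
}
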