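# Error metrics used by every experiment report: RMSE, MAE, MDAPE and nRMSE,
# per dimension and pooled overall.

#' Root-mean-square and mean-absolute error
#'
#' Computed over all entries of equally shaped arrays.
#'
#' @param pred,truth Numeric vectors/matrices of the same shape.
#' @export
rmse <- function(pred, truth) {
  check_shapes(pred, truth)
  sqrt(mean((pred - truth)^2))
}

#' @rdname rmse
#' @export
mae <- function(pred, truth) {
  check_shapes(pred, truth)
  mean(abs(pred - truth))
}

#' Median absolute percentage error (as a fraction)
#'
#' Median of `|pred - truth| / |truth|` over the entries whose `|truth|`
#' exceeds a small floor; entries at (numerically) zero truth are excluded so
#' that trajectories touching zero keep a defined MDAPE. Returns `NA` when all
#' entries are excluded.
#'
#' @inheritParams rmse
#' @param floor Exclusion floor on `|truth|` (default 1e-12).
#' @export
mdape <- function(pred, truth, floor = 1e-12) {
  check_shapes(pred, truth)
  keep <- abs(truth) > floor
  if (!any(keep)) return(NA_real_)
  stats::median(abs(pred[keep] - truth[keep]) / abs(truth[keep]))
}

#' Normalized RMSE
#'
#' RMSE divided by an explicit normalizer: the range of the truth
#' (`mode = "range"`, default) or the mean absolute truth (`mode = "mean"`).
#' A zero range falls back to mean mode; if both normalizers are zero the
#' result is `NA`.
#'
#' @inheritParams rmse
#' @param mode `"range"` or `"mean"`.
#' @export
nrmse <- function(pred, truth, mode = c("range", "mean")) {
  mode <- match.arg(mode)
  r <- rmse(pred, truth)
  norm <- if (mode == "range") diff(range(truth)) else mean(abs(truth))
  if (norm == 0 && mode == "range") norm <- mean(abs(truth))
  if (norm == 0) return(NA_real_)
  r / norm
}

check_shapes <- function(pred, truth) {
  if (length(pred) == 0L) stop("empty input")
  if (length(pred) != length(truth) ||
      !identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical shapes")
  invisible(TRUE)
}

#' Full error report, per dimension and pooled overall
#'
#' One row per column of the inputs plus an `Overall` row whose entries pool
#' all (dimension, time) pairs -- not an average of the per-dimension metrics.
#'
#' @param pred,truth `n x V` matrices (vectors are treated as one column).
#' @param names Optional column labels.
#' @param nrmse_mode Normalizer mode for [nrmse()], recorded in the result.
#' @return A `data.frame` with columns `dimension, RMSE, MAE, MDAPE, nRMSE` and
#'   attribute `nrmse_mode`.
#' @export
error_report <- function(pred, truth, names = NULL, nrmse_mode = "range") {
  if (!is.matrix(pred)) pred <- matrix(pred, ncol = 1L)
  if (!is.matrix(truth)) truth <- matrix(truth, ncol = 1L)
  check_shapes(pred, truth)
  if (is.null(names)) names <- colnames(truth)
  if (is.null(names)) names <- paste0("dim", seq_len(ncol(truth)))
  one <- function(p, tr) c(RMSE = rmse(p, tr), MAE = mae(p, tr),
                           MDAPE = mdape(p, tr),
                           nRMSE = nrmse(p, tr, nrmse_mode))
  rows <- t(vapply(seq_len(ncol(pred)),
                   function(k) one(pred[, k], truth[, k]), numeric(4L)))
  rows <- rbind(rows, one(as.vector(pred), as.vector(truth)))
  out <- data.frame(dimension = c(names, "Overall"), rows,
                    row.names = NULL, check.names = FALSE)
  attr(out, "nrmse_mode") <- nrmse_mode
  out
}
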