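#' Default RBF scale grid
#'
#' Thirty logarithmically spaced values spanning `(0, 1)`, from `1e-4` to
#' `0.999`.  Log spacing matters because on raw count data the squared
#' distances entering the RBF kernel range over several orders of magnitude,
#' so the useful values of `nu` do too.
#'
#' @param n Number of grid points.
#' @param lower,upper Grid end points, strictly inside `(0, 1)`.
#' @return Increasing numeric vector of length `n`.
#' @export
default_nu_grid <- function(n = 30L, lower = 1e-4, upper = 0.999) {
  stopifnot(n >= 1L, lower > 0, upper < 1, lower <= upper)
  exp(seq(log(lower), log(upper), length.out = n))
}

#' Select the RBF scale by matching a target reject rate
#'
#' Fits the ball once per grid value of `nu` with `C` held fixed, records
#' the achieved training reject rate of each fit, and keeps the `nu` whose
#' achieved rate is closest to `target_reject`; ties are broken toward the
#' smallest `nu` (the smoothest kernel).  The full per-`nu` diagnostic table
#' is always computed, so the trade-off can be inspected even after a winner
#' is found.  The procedure is deterministic: equal inputs give identical
#' output.
#'
#' With a held-out set of additional non-DE genes (`validation`), the rule
#' changes to the supplementary-style criterion: among grid values whose
#' training reject rate is within `0.05` of the target (all values if none
#' qualify), choose the `nu` with the smallest validation reject rate, ties
#' again toward the smallest `nu`.
#'
#' @param x Training feature matrix (known non-DE genes, rows) as in
#'   [meb_fit()].
#' @param C Soft-margin penalty, fixed during the search (default 0.1).
#' @param nu_grid Increasing vector of candidate scales in `(0, 1)`; see
#'   [default_nu_grid()].
#' @param target_reject Target fraction of training genes left outside the
#'   ball, in `[0, 1)`.  Default 0.10; use 0.20 for cross-species analyses
#'   (see the `preset` argument of [sfmeb()]).
#' @param validation Optional matrix of held-out non-DE gene features.
#' @param log1p Passed to [meb_fit()].
#' @return A list of class `"meb_tune"`: `model` (the refitted `"meb"` at the
#'   chosen scale), `chosen_nu`, `train_reject` (achieved rate at
#'   `chosen_nu`), and `per_nu`, a data frame with one row per grid point
#'   (`nu`, `train_reject`, `r_squared`, and `valid_reject` when a
#'   validation set was given; `NA` rows mark grid values whose fit failed).
#' @export
meb_tune <- function(x, C = 0.1, nu_grid = default_nu_grid(),
                     target_reject = 0.10, validation = NULL, log1p = FALSE) {
  x <- as_feature_matrix(x)
  stopifnot(length(nu_grid) >= 1L, all(diff(nu_grid) > 0))
  if (any(nu_grid <= 0 | nu_grid >= 1))
    stop("'nu_grid' must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(target_reject) || target_reject < 0 || target_reject >= 1)
    stop("'target_reject' must be in [0, 1)", call. = FALSE)
  m <- length(nu_grid)
  per_nu <- data.frame(nu = nu_grid, train_reject = NA_real_,
                       r_squared = NA_real_)
  if (!is.null(validation)) per_nu$valid_reject <- NA_real_
  models <- vector("list", m)
  failures <- character(0)
  for (i in seq_len(m)) {
    fit <- tryCatch(meb_fit(x, "rbf", nu = nu_grid[i], C = C, log1p = log1p),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("nu = %g: %s", nu_grid[i],
                                      conditionMessage(fit)))
      next
    }
    models[[i]] <- fit
    per_nu$train_reject[i] <- training_reject_rate(fit)
    per_nu$r_squared[i] <- fit$r_squared
    if (!is.null(validation))
      per_nu$valid_reject[i] <- mean(predict(fit, validation) > 0)
  }
  ok <- which(!is.na(per_nu$train_reject))
  if (length(ok) == 0L)
    stop("tuning failed at every grid value:\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  if (is.null(validation)) {
    dev <- abs(per_nu$train_reject[ok] - target_reject)
    best <- ok[which.min(dev)]  # which.min: first = smallest nu on ties
  } else {
    near <- ok[abs(per_nu$train_reject[ok] - target_reject) <= 0.05]
    if (length(near) == 0L) near <- ok
    best <- near[which.min(per_nu$valid_reject[near])]
  }
  structure(
    list(model = models[[best]], chosen_nu = nu_grid[best],
         train_reject = per_nu$train_reject[best], per_nu = per_nu,
         target_reject = target_reject, C = C, failures = failures),
    class = "meb_tune")
}

#' @export
print.meb_tune <- function(x, ...) {
  cat("RBF scale selection by reject-rate matching\n")
  cat("  grid: ", nrow(x$per_nu), " values in [",
      format(min(x$per_nu$nu)), ", ", format(max(x$per_nu$nu)), "]\n",
      sep = "")
  cat("  target reject rate: ", format(x$target_reject),
      "   achieved: ", format(round(x$train_reject, 4)), "\n", sep = "")
  cat("  chosen nu: ", format(x$chosen_nu), "  (C = ", format(x$C), ")\n",
      sep = "")
  if (length(x$failures))
    cat("  ", length(x$failures), " grid value(s) failed to fit\n", sep = "")
  invisible(x)
}
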