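#' Fit a soft-margin minimum enclosing ball to non-DE genes
#'
#' Trains the scaling-free minimum enclosing ball on the raw count vectors of
#' a set of genes assumed non-differentially expressed (housekeeping genes
#' within a species, conserved orthologs across species).  The ball is fitted
#' in an implicit kernel feature space: the primal problem minimizes
#' \eqn{R^2 + C \sum_i \xi_i} subject to
#' \eqn{||\phi(x_i) - c||^2 \le R^2 + \xi_i,\ \xi_i \ge 0}, and is solved
#' through its dual (see [solve_meb_dual()]).  The squared radius is
#' recovered from the Karush-Kuhn-Tucker conditions as the squared feature
#' distance from the center to the boundary support vectors (those with
#' \eqn{0 < \alpha_i < C}).
#'
#' Counts are used as-is: the method is scaling-free by construction and no
#' library-size normalization is applied.  Genes whose counts are all zero in
#' the training set are retained with a warning; a training set whose rows
#' are all identical fits a degenerate ball of radius 0 (every distinct gene
#' is then called DE under the RBF kernel), again with a warning.
#'
#' @param x Numeric matrix of training features: one row per known non-DE
#'   gene, one column per sample (raw counts), or an object accepted by
#'   [as_feature_matrix()].
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param nu RBF scale parameter (ignored for the linear kernel).  See
#'   [meb_tune()] for data-driven selection.
#' @param C Soft-margin penalty; the default 0.1 allows up to roughly 10% of
#'   the training genes to lie outside the ball.  Requires
#'   `nrow(x) * C >= 1`.
#' @param log1p If `TRUE`, apply `log1p` to the counts before fitting (and to
#'   any new data scored against the model).  Off by default: the raw-count
#'   scale is the point of the method.
#' @return An object of class `"meb"` with components `x` (training matrix),
#'   `kernel`, `nu`, `C`, `alpha`, `objective`, `r_squared`, `boundary_sv`,
#'   `offset` (the quadratic form \eqn{\alpha^T K \alpha}) and `log1p`.
#' @examples
#' set.seed(1)
#' x <- matrix(rpois(40, 50), ncol = 2)
#' fit <- meb_fit(x, nu = 1e-3, C = 1)
#' fit$r_squared
#' predict(fit, matrix(c(500, 5), 1))  # a far-away gene scores positive
#' @export
meb_fit <- function(x, kernel = c("rbf", "linear"), nu = 1, C = 0.1,
                    log1p = FALSE) {
  kernel <- match.arg(kernel)
  x <- as_feature_matrix(x)
  if (log1p) x <- base::log1p(x)
  if (any(rowSums(x) == 0))
    warning(sum(rowSums(x) == 0), " training gene(s) have all-zero counts; ",
            "they are retained", call. = FALSE)
  K <- gram_matrix(x, kernel, nu)
  sol <- solve_meb_dual(K, C)
  rad <- meb_radius(K, sol$alpha, C)
  if (nrow(x) > 1L && all(stats::dist(x) < 1e-12))
    warning("all training genes are identical: the fitted ball is degenerate ",
            "(radius 0) and every distinct gene will be called DE",
            call. = FALSE)
  structure(
    list(x = x, kernel = kernel, nu = if (kernel == "rbf") nu else NA_real_,
         C = C, alpha = sol$alpha, objective = sol$objective,
         r_squared = rad$r_squared, boundary_sv = rad$boundary_sv,
         offset = drop(crossprod(sol$alpha, K %*% sol$alpha)),
         log1p = log1p),
    class = "meb")
}

#' Decision values and DE calls from a fitted ball
#'
#' The decision function of the fitted ball is
#' \deqn{f(x) = K(x, x) - 2 \sum_j \alpha_j K(x, x_j)
#'   + \sum_{jk} \alpha_j \alpha_k K(x_j, x_k) - R^2,}
#' the squared feature-space distance to the center minus the squared
#' radius.  A gene is called DE when `f > 0` (strictly outside the ball) and
#' non-DE otherwise.  For the RBF kernel, a point infinitely far from every
#' training gene attains the finite limit `1 + offset - r_squared`.
#'
#' @param object A fitted `"meb"` model.
#' @param newdata Matrix (or vector) of count features with the same number
#'   of samples as the training data.  Defaults to the training set.
#' @param type `"decision"` for the signed value `f(x)`, `"class"` for the
#'   factor of calls (`"DE"` / `"nonDE"`).
#' @param ... Unused.
#' @return Numeric vector of decision values, or a factor of calls.
#' @export
predict.meb <- function(object, newdata = object$x,
                        type = c("decision", "class"), ...) {
  type <- match.arg(type)
  newx <- as_feature_matrix(newdata)
  if (object$log1p && !identical(newdata, object$x)) newx <- base::log1p(newx)
  Kx <- cross_kernel(newx, object$x, object$kernel, object$nu)
  kxx <- if (object$kernel == "rbf") rep(1, nrow(newx)) else rowSums(newx^2)
  f <- kxx - 2 * drop(Kx %*% object$alpha) + object$offset - object$r_squared
  names(f) <- rownames(newx)
  if (type == "decision") f
  else factor(ifelse(f > 0, "DE", "nonDE"), levels = c("nonDE", "DE"))
}

#' @export
fitted.meb <- function(object, ...) predict.meb(object, ...)

#' @export
coef.meb <- function(object, ...) object$alpha

#' Training reject rate of a fitted ball
#'
#' Fraction of training genes that fall strictly outside the fitted ball
#' (decision value > 0), i.e. the proportion of known non-DE genes the model
#' would itself call DE.  This is the quantity the kernel scale is tuned
#' against: it is the knob controlling the type-I error of the detector.
#'
#' @param model A fitted `"meb"` object.
#' @return A number in `[0, 1]`.
#' @export
training_reject_rate <- function(model) {
  stopifnot(inherits(model, "meb"))
  mean(predict(model) > 0)
}

#' Score all genes of a count matrix against a fitted ball
#'
#' Computes the signed decision value of every gene, the DE/nonDE call, and
#' a ranking by decreasing score: the further outside the ball, the stronger
#' the differential-expression signal.  Ties keep the input gene order.
#'
#' @param model A fitted `"meb"` object.
#' @param counts A [count_matrix()] or a plain numeric matrix whose columns
#'   match the training sample layout.
#' @return A data frame with columns `gene_id`, `score`, `call` and `rank`
#'   (1 = most DE-like), in the input gene order.
#' @export
score_genes <- function(model, counts) {
  x <- if (inherits(counts, "count_matrix")) counts$counts else counts
  f <- predict(model, x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("g", seq_along(f))
  ord <- order(-f)  # stable: ties stay in input order
  rnk <- integer(length(f)); rnk[ord] <- seq_along(f)
  data.frame(gene_id = ids, score = unname(f),
             call = ifelse(f > 0, "DE", "nonDE"), rank = rnk,
             stringsAsFactors = FALSE)
}

#' @export
print.meb <- function(x, ...) {
  cat("Soft-margin minimum enclosing ball (", x$kernel, " kernel)\n", sep = "")
  cat("  training genes: ", nrow(x$x), "  samples: ", ncol(x$x), "\n", sep = "")
  if (x$kernel == "rbf") cat("  nu: ", format(x$nu), "\n", sep = "")
  cat("  C: ", format(x$C), "   R^2: ", format(x$r_squared), "\n", sep = "")
  cat("  boundary support vectors: ", length(x$boundary_sv),
      "   training reject rate: ",
      format(round(training_reject_rate(x), 4)), "\n", sep = "")
  invisible(x)
}

#' @export
summary.meb <- function(object, ...) {
  f <- predict(object)
  out <- list(model = object, reject = mean(f > 0),
              n_sv = sum(object$alpha > 1e-7 * object$C),
              decision = summary(f))
  class(out) <- "summary.meb"
  out
}

#' @export
print.summary.meb <- function(x, ...) {
  print(x$model)
  cat("  support vectors (alpha > 0): ", x$n_sv, "\n", sep = "")
  cat("  training decision values:\n")
  print(x$decision)
  invisible(x)
}
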