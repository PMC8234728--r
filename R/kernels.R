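#' Kernel functions for count feature vectors
#'
#' Genes are represented by their raw count vectors across all samples
#' (no normalization, no log transform unless requested upstream).  Two
#' kernels are supported: the radial basis function (RBF) kernel
#' \deqn{K(x, y) = \exp(-\nu \, ||x - y||^2)}
#' with scale parameter \eqn{\nu > 0}, and the plain linear kernel
#' \eqn{K(x, y) = x^T y}.
#'
#' @param x,y Numeric vectors of equal length (per-sample counts of a gene).
#' @param kernel Either `"rbf"` (default) or `"linear"`.
#' @param nu Positive RBF scale parameter; ignored for the linear kernel.
#' @return A single numeric kernel value; in `(0, 1]` for the RBF kernel.
#' @examples
#' kernel_value(c(1, 2), c(1, 2))            # 1 for RBF, x == y
#' kernel_value(c(1, 2), c(3, 4), "linear")  # 11
#' @export
kernel_value <- function(x, y, kernel = c("rbf", "linear"), nu = 1) {
  kernel <- match.arg(kernel)
  if (length(x) != length(y))
    stop("kernel_value(): 'x' and 'y' have different lengths (",
         length(x), " vs ", length(y), ")", call. = FALSE)
  if (kernel == "rbf") {
    check_nu(nu)
    exp(-nu * sum((x - y)^2))
  } else {
    sum(x * y)
  }
}

check_nu <- function(nu) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0)
    stop("RBF scale 'nu' must be a single positive number", call. = FALSE)
  invisible(nu)
}

#' Gram matrix of a training set
#'
#' Computes the full kernel matrix of a set of feature vectors.  For the RBF
#' kernel the diagonal is identically 1 and the matrix is positive
#' semidefinite.
#'
#' @param x Numeric matrix, one row per gene, one column per sample.
#' @inheritParams kernel_value
#' @return Symmetric `nrow(x)` x `nrow(x)` kernel matrix.
#' @export
gram_matrix <- function(x, kernel = c("rbf", "linear"), nu = 1) {
  kernel <- match.arg(kernel)
  x <- as_feature_matrix(x)
  if (kernel == "linear") return(tcrossprod(x))
  check_nu(nu)
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0  # numerical noise from the expansion
  K <- exp(-nu * d2)
  diag(K) <- 1
  K
}

# kernel values between new rows and the training rows (m x n matrix)
cross_kernel <- function(newx, train, kernel, nu) {
  newx <- as_feature_matrix(newx)
  if (ncol(newx) != ncol(train))
    stop("feature dimension mismatch: new data has ", ncol(newx),
         " samples, training data has ", ncol(train), call. = FALSE)
  if (kernel == "linear") return(tcrossprod(newx, train))
  d2 <- outer(rowSums(newx^2), rowSums(train^2), "+") - 2 * tcrossprod(newx, train)
  d2[d2 < 0] <- 0
  exp(-nu * d2)
}

as_feature_matrix <- function(x) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature data must be numeric", call. = FALSE)
  if (anyNA(x)) stop("feature data contains missing values", call. = FALSE)
  storage.mode(x) <- "double"
  x
}
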