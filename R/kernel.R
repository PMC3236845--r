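#' Kernel specification
#'
#' Describes the discriminant family used both for random-projection entropy
#' estimation and for the SVM base learners:
#' \describe{
#'   \item{linear}{\eqn{f(x) = w'x + c}.}
#'   \item{poly2}{homogeneous degree-2 polynomial kernel
#'     \eqn{K(u, v) = (u'v)^2}, i.e. central conic decision boundaries.}
#'   \item{gaussian}{RBF kernel \eqn{K(u, v) = \exp(-\gamma ||u - v||^2)}.}
#' }
#'
#' @param kind Kernel family: `"linear"`, `"poly2"` or `"gaussian"`.
#' @param gamma Positive width parameter, required for (and only meaningful
#'   for) the Gaussian kernel.
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("poly2")
#' kernel_spec("gaussian", gamma = 0.01)
#' @export
kernel_spec <- function(kind = c("linear", "poly2", "gaussian"), gamma = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (is.null(gamma) || !is.numeric(gamma) || length(gamma) != 1L ||
        is.na(gamma) || gamma <= 0) {
      stop("the gaussian kernel requires a single gamma > 0", call. = FALSE)
    }
    gamma <- as.numeric(gamma)
  } else if (!is.null(gamma)) {
    stop("gamma is only meaningful for the gaussian kernel", call. = FALSE)
  }
  structure(list(kind = kind, gamma = gamma), class = "kernel_spec")
}

#' @export
format.kernel_spec <- function(x, ...) {
  if (x$kind == "gaussian") sprintf("gaussian(gamma=%g)", x$gamma) else x$kind
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("<kernel_spec>", format(x), "\n")
  invisible(x)
}

.as_kernel_spec <- function(x) {
  if (inherits(x, "kernel_spec")) return(x)
  if (is.character(x) && length(x) == 1L) return(kernel_spec(x))
  stop("expected a kernel_spec or a kernel name", call. = FALSE)
}

#' Kernel (Gram) matrix between two sample sets
#'
#' @param spec A [kernel_spec()].
#' @param x,y Numeric matrices with one sample per row and identical column
#'   count; `y` defaults to `x`.
#' @return The `nrow(x)` by `nrow(y)` matrix of kernel evaluations.
#' @export
kernel_matrix <- function(spec, x, y = x) {
  spec <- .as_kernel_spec(spec)
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (ncol(x) != ncol(y)) stop("dimension mismatch between x and y", call. = FALSE)
  g <- x %*% t(y)
  switch(spec$kind,
    linear = g,
    poly2 = g^2,
    gaussian = {
      d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * g
      exp(-spec$gamma * pmax(d2, 0))
    }
  )
}

#' Evaluate a dual-form discriminant
#'
#' Computes \eqn{f(x) = \sum_i \alpha_i K(x_i, x) + c} for each query row,
#' the kernel-space analogue of `w'x + c` in which the normal vector is a
#' weighted sum of support samples.
#'
#' @param support_features Matrix of support samples (rows).
#' @param alpha Numeric weight vector, one entry per support sample.
#' @param offset Scalar intercept `c`.
#' @param kernel A [kernel_spec()].
#' @param x Query samples, a matrix (or a single vector).
#' @return Numeric vector of scores, one per query row.
#' @export
kernel_score <- function(support_features, alpha, offset, kernel, x) {
  kernel <- .as_kernel_spec(kernel)
  support_features <- as.matrix(support_features)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (length(alpha) != nrow(support_features)) {
    stop("need one alpha weight per support sample", call. = FALSE)
  }
  if (ncol(x) != ncol(support_features)) {
    stop("dimension mismatch between query and support samples", call. = FALSE)
  }
  drop(kernel_matrix(kernel, x, support_features) %*% alpha) + offset
}
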