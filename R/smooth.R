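# Regression-spline smooth terms.
#
# Bases are cubic regression splines with knots at covariate quantiles,
# built through mgcv::smoothCon: the penalty is the exact integrated squared
# second derivative of the represented spline, and the sum-to-zero
# identifiability constraint is absorbed into a (J-1)-column
# reparameterization (not post-hoc demeaning), so the penalty remains exact
# under the constraint. Beyond the knot range the spline continues linearly,
# matching the penalty's null space.

#' Build a centered cubic regression-spline basis
#'
#' Constructs a cubic regression-spline basis of dimension \code{k} for a
#' continuous covariate, with knots at quantiles of the unique covariate
#' values, the exact second-order roughness penalty
#' \eqn{\int f''(x)^2\,dx}, and the sum-to-zero constraint
#' \eqn{\sum_i f(x_i) = 0} absorbed by reparameterization. The returned
#' design block has \code{k - 1} columns, each summing to zero; the penalty
#' has rank \code{k - 2}, leaving a one-dimensional (linear) null space.
#'
#' @param x numeric covariate vector with at least \code{k} distinct values.
#' @param k basis dimension (number of knots), at least 4.
#' @param label covariate name used in error messages and reports.
#' @return an object of class \code{"smooth_basis"} with elements \code{X}
#'   (n x (k-1) centered design block), \code{S} ((k-1) x (k-1) penalty),
#'   \code{knots}, \code{k}, \code{label} and the underlying \code{mgcv}
#'   smooth object.
#' @examples
#' b <- smooth_basis(seq(0, 1, length.out = 100), k = 10, label = "x")
#' max(abs(colSums(b$X)))   # sum-to-zero by construction
#' @export
smooth_basis <- function(x, k = 10, label = "x") {
  if (k < 4) stop("basis dimension 'k' must be at least 4")
  nu <- length(unique(x))
  if (nu < k) {
    stop(sprintf("covariate '%s' has only %d distinct values; need at least %d",
                 label, nu, k))
  }
  dat <- stats::setNames(data.frame(x = as.numeric(x)), label)
  spec <- .cr_spec(label, k)
  sm <- mgcv::smoothCon(spec, data = dat, absorb.cons = TRUE,
                        scale.penalty = FALSE)[[1]]
  structure(list(X = sm$X, S = sm$S[[1]], knots = sm$xp, k = k,
                 label = label, sm = sm),
            class = "smooth_basis")
}

# a cubic-regression smooth spec for an arbitrarily named covariate
.cr_spec <- function(label, k) {
  spec <- eval(parse(text = sprintf('mgcv::s(%s, k = %d, bs = "cr")',
                                    label, as.integer(k))))
  spec
}

#' Evaluate a fitted smooth at new covariate values
#'
#' Evaluates the centered spline represented by \code{beta} at \code{x_new}.
#' Values beyond the knot range are linear continuations of the spline (the
#' natural behavior of the second-order penalty null space).
#'
#' @param basis a \code{"smooth_basis"} object.
#' @param beta coefficient vector of length \code{ncol(basis$X)}.
#' @param x_new numeric vector of evaluation points.
#' @return numeric vector of fitted smooth values.
#' @export
eval_smooth <- function(basis, beta, x_new) {
  if (!inherits(basis, "smooth_basis")) {
    stop("'basis' must be created by smooth_basis()")
  }
  if (length(beta) != ncol(basis$X)) {
    stop(sprintf("'beta' has length %d but the basis has %d columns",
                 length(beta), ncol(basis$X)))
  }
  nd <- stats::setNames(data.frame(x = as.numeric(x_new)), basis$label)
  drop(mgcv::PredictMat(basis$sm, nd) %*% beta)
}
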