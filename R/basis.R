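#' P-spline basis specification
#'
#' Build a B-spline basis specification with equally spaced inner knots on
#' `[x_min, x_max]`. The `degree` boundary knots added on each side continue
#' the equal spacing (they are not replicated), so the difference penalty
#' treats boundary coefficients the same way as interior ones. The basis forms
#' a partition of unity exactly on the inner range.
#'
#' @param x_min,x_max Range of the predictor (age, years) covered by the
#'   inner knots; `x_min < x_max`.
#' @param n_knots Number of equally spaced inner knots (including both
#'   endpoints). The conventional choice for norming models in this package
#'   is 24 knots on the observed age range.
#' @param degree Polynomial degree of the B-splines (default 3, cubic).
#' @param penalty_order Order of the difference penalty associated with the
#'   basis. Defaults to 2, capped at `n_basis - 1` for very small bases; an
#'   explicitly supplied order must satisfy `penalty_order < n_basis`.
#' @return An object of class `spline_basis_spec` with fields `knots` (the
#'   full knot vector including boundary extensions), `inner_knots`, `degree`,
#'   `n_basis`, `penalty_order`, and `inner_range`.
#' @examples
#' spec <- make_knots(5, 21, n_knots = 24)
#' spec$n_basis
#' @export
make_knots <- function(x_min, x_max, n_knots, degree = 3L, penalty_order = NULL) {
  stopifnot(is.numeric(x_min), is.numeric(x_max), length(x_min) == 1L,
            length(x_max) == 1L)
  if (!is.finite(x_min) || !is.finite(x_max) || x_min >= x_max) {
    stop("invalid knot range: need x_min < x_max, got [", x_min, ", ", x_max, "]")
  }
  n_knots <- as.integer(n_knots)
  degree <- as.integer(degree)
  if (degree < 0L) stop("degree must be a non-negative integer")
  if (n_knots < degree + 2L) {
    stop("n_knots (", n_knots, ") too small: need at least degree + 2 = ",
         degree + 2L, " inner knots")
  }
  inner <- seq(x_min, x_max, length.out = n_knots)
  h <- (x_max - x_min) / (n_knots - 1L)
  knots <- c(x_min - h * rev(seq_len(degree)), inner, x_max + h * seq_len(degree))
  n_basis <- length(knots) - degree - 1L
  if (is.null(penalty_order)) {
    penalty_order <- min(2L, n_basis - 1L)   # cap for very small bases
  } else {
    penalty_order <- as.integer(penalty_order)
    if (n_basis <= penalty_order) {
      stop("basis too small: n_basis = ", n_basis,
           " must exceed penalty_order = ", penalty_order)
    }
  }
  structure(
    list(knots = knots, inner_knots = inner, degree = degree,
         n_basis = n_basis, penalty_order = penalty_order,
         inner_range = c(x_min, x_max)),
    class = "spline_basis_spec"
  )
}

#' @export
print.spline_basis_spec <- function(x, ...) {
  cat("P-spline basis: degree", x$degree, "|", length(x$inner_knots),
      "inner knots on [", x$inner_range[1], ",", x$inner_range[2], "] |",
      x$n_basis, "basis functions | penalty order", x$penalty_order, "\n")
  invisible(x)
}

#' B-spline design matrix
#'
#' Evaluate the basis of a [make_knots()] specification at predictor values.
#' Rows sum to one (partition of unity) and have at most `degree + 1`
#' non-zero entries. Values outside the inner knot range are rejected:
#' prediction outside the knot range is undefined, and callers that need to
#' tolerate out-of-range ages must clamp first (see [clamp_ages()]).
#'
#' @param x Numeric vector of predictor values within `spec$inner_range`.
#' @param spec A `spline_basis_spec`.
#' @return A `length(x)` by `spec$n_basis` matrix.
#' @export
bspline_design <- function(x, spec) {
  stopifnot(inherits(spec, "spline_basis_spec"), is.numeric(x))
  if (anyNA(x) || any(!is.finite(x))) stop("x contains non-finite values")
  lo <- spec$inner_range[1]; hi <- spec$inner_range[2]
  eps <- 1e-8 * (hi - lo)
  if (any(x < lo - eps | x > hi + eps)) {
    bad <- which(x < lo - eps | x > hi + eps)
    stop("x outside the inner knot range [", lo, ", ", hi, "] at ",
         length(bad), " position(s), first index ", bad[1],
         "; clamp ages before evaluating the basis")
  }
  x <- pmin(pmax(x, lo), hi)
  B <- splines::splineDesign(knots = spec$knots, x = x, ord = spec$degree + 1L,
                             outer.ok = FALSE)
  # splineDesign drops the last basis function's support endpoint half-open;
  # with equally extended knots the returned matrix already has n_basis cols.
  stopifnot(ncol(B) == spec$n_basis)
  B
}

#' Difference penalty matrix
#'
#' Construct the P-spline penalty \eqn{K = D^\top D}, where `D` is the
#' `order`-th forward-difference operator on coefficient vectors of length
#' `n_basis`. `K` is symmetric positive semi-definite with rank
#' `n_basis - order`; its null space contains polynomial coefficient
#' sequences up to degree `order - 1`.
#'
#' @param n_basis Number of basis coefficients.
#' @param order Difference order, `0 < order < n_basis`.
#' @return An object of class `penalty_matrix`: list with `matrix`, `order`,
#'   and `rank`.
#' @export
difference_penalty <- function(n_basis, order = 2L) {
  n_basis <- as.integer(n_basis); order <- as.integer(order)
  if (order <= 0L) stop("penalty order must be positive")
  if (order >= n_basis) {
    stop("penalty order (", order, ") must be smaller than n_basis (",
         n_basis, ")")
  }
  D <- diff(diag(n_basis), differences = order)
  K <- crossprod(D)
  structure(list(matrix = K, order = order, rank = n_basis - order),
            class = "penalty_matrix")
}

#' Serialize / restore a basis specification
#'
#' Stage-two fits must reuse stage-one knot locations bit-exactly, so the
#' specification round-trips through JSON with full double precision.
#'
#' @param spec A `spline_basis_spec`.
#' @return `basis_to_list()` returns a plain list; `basis_from_list()`
#'   rebuilds the `spline_basis_spec`.
#' @export
basis_to_list <- function(spec) {
  stopifnot(inherits(spec, "spline_basis_spec"))
  list(inner_knots = spec$inner_knots, degree = spec$degree,
       penalty_order = spec$penalty_order)
}

#' @rdname basis_to_list
#' @param x A list as produced by `basis_to_list()`.
#' @export
basis_from_list <- function(x) {
  inner <- as.numeric(x$inner_knots)
  degree <- as.integer(x$degree)
  n <- length(inner)
  spec <- make_knots(inner[1], inner[n], n_knots = n, degree = degree,
                     penalty_order = as.integer(x$penalty_order))
  # preserve the exact serialized inner knots (guards against fp drift in seq)
  spec$inner_knots <- inner
  h <- (inner[n] - inner[1]) / (n - 1L)
  spec$knots <- c(inner[1] - h * rev(seq_len(degree)), inner,
                  inner[n] + h * seq_len(degree))
  spec
}
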