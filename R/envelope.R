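#' Cmin/Cmax envelope of the entropy-complexity plane
#'
#' For a fixed alphabet size \code{L}, statistical complexity is not a
#' function of entropy: at each \eqn{H} the achievable \eqn{C} values span a
#' band between two boundary curves, \eqn{C_{min}(H)} and \eqn{C_{max}(H)},
#' both vanishing at \eqn{H = 0} and \eqn{H = 1}. The boundaries are traced by
#' two one-parameter extremal families of distributions:
#' \itemize{
#'   \item lower boundary: one component \eqn{p \in [1/L, 1]}, the remaining
#'     \eqn{L - 1} components sharing \eqn{(1 - p)} equally;
#'   \item upper boundary: \eqn{m} components exactly zero
#'     (\eqn{m = 1, \dots, L-1}), one free component \eqn{p}, and the
#'     remaining \eqn{L - m - 1} components sharing \eqn{(1 - p)} equally.
#' }
#' The function evaluates both families on dense parameter grids, takes the
#' pointwise extremes of \eqn{C} binned by \eqn{H}, and interpolates onto a
#' regular \eqn{H} grid.
#'
#' @param L alphabet size (e.g. \code{factorial(D)} for ordinal patterns).
#' @param n_grid number of \eqn{H} grid points (>= 10).
#' @param n_scan number of parameter values scanned per family branch.
#' @return object of class \code{complexity_envelope}: list with \code{L},
#'   \code{H} (grid), \code{Cmin}, \code{Cmax}.
#' @examples
#' env <- complexity_envelope(24)
#' range(env$Cmax)
#' @export
complexity_envelope <- function(L, n_grid = 1000L, n_scan = 4000L) {
  L <- as.integer(L)
  if (L < 2L) stop("L must be >= 2")
  if (n_grid < 10L) stop("n_grid must be >= 10")

  hgrid <- seq(0, 1, length.out = n_grid)

  hc_of <- function(pm) {
    # pm: matrix, rows are distributions along one branch
    H <- apply(pm, 1L, normalized_entropy)
    Q <- apply(pm, 1L, disequilibrium)
    cbind(H = H, C = H * Q)
  }
  # interpolate one branch's C(H) curve onto the part of the grid it spans
  branch_on_grid <- function(pts) {
    o <- order(pts[, "H"])
    stats::approx(pts[o, "H"], pts[o, "C"], xout = hgrid,
                  ties = max)$y # NA outside the branch's H range
  }
  # parameter grid concentrated near 0, where -p log p makes H move fastest
  pgrid <- function(upper) upper * seq(0, 1, length.out = n_scan)^2

  # lower boundary: one component p in [1/L, 1], the rest equal
  pa <- 1 / L + (1 - 1 / L) * seq(0, 1, length.out = n_scan)^2
  cmin <- branch_on_grid(hc_of(cbind(pa, matrix((1 - pa) / (L - 1),
                                                n_scan, L - 1L))))

  # upper boundary: max over branches with m zeros, one free component
  # p in [0, 1/(L-m)] and the rest equal; branch m joins the uniform over
  # L-m-1 symbols to the uniform over L-m symbols
  cmax <- rep(NA_real_, n_grid)
  for (m in 0:(L - 2L)) {
    nz <- L - m
    pb <- pgrid(1 / nz)
    fam <- if (nz == 2L) cbind(pb, 1 - pb, matrix(0, length(pb), m))
           else cbind(pb, matrix((1 - pb) / (nz - 1L), length(pb), nz - 1L),
                      matrix(0, length(pb), m))
    cb <- branch_on_grid(hc_of(fam))
    cmax <- pmax(cmax, cb, na.rm = TRUE)
  }
  # the small-p side of the lower-boundary family also bounds from above
  ps <- pgrid(1 / L)
  cmax <- pmax(cmax,
               branch_on_grid(hc_of(cbind(ps, matrix((1 - ps) / (L - 1),
                                                     length(ps), L - 1L)))),
               na.rm = TRUE)

  # endpoints are exact: C = 0 at both H extremes
  cmin[c(1L, n_grid)] <- 0
  cmax[c(1L, n_grid)] <- 0
  fill <- function(v) stats::approx(hgrid[!is.na(v)], v[!is.na(v)],
                                    xout = hgrid, rule = 2)$y
  cmin <- fill(cmin)
  cmax <- fill(cmax)
  cmin <- pmin(cmin, cmax)

  structure(list(L = L, H = hgrid, Cmin = cmin, Cmax = cmax),
            class = "complexity_envelope")
}

#' Interpolated envelope bounds at given entropy values
#'
#' @param env \code{complexity_envelope}.
#' @param H numeric entropy values in \eqn{[0, 1]}.
#' @return data.frame with columns \code{H}, \code{Cmin}, \code{Cmax}.
#' @export
envelope_bounds <- function(env, H) {
  stopifnot(inherits(env, "complexity_envelope"))
  data.frame(H = H,
             Cmin = stats::approx(env$H, env$Cmin, xout = H, rule = 2)$y,
             Cmax = stats::approx(env$H, env$Cmax, xout = H, rule = 2)$y)
}

#' Test whether HxC points lie inside the envelope
#'
#' @param env \code{complexity_envelope}.
#' @param H,C numeric vectors of plane coordinates.
#' @param tol tolerance allowed beyond the interpolated boundary.
#' @return logical vector.
#' @export
in_envelope <- function(env, H, C, tol = 1e-6) {
  b <- envelope_bounds(env, H)
  C >= b$Cmin - tol & C <= b$Cmax + tol
}

#' @export
print.complexity_envelope <- function(x, ...) {
  cat(sprintf("Complexity envelope for L = %d (%d-point H grid); peak Cmax = %.4f at H = %.3f\n",
              x$L, length(x$H), max(x$Cmax), x$H[which.max(x$Cmax)]))
  invisible(x)
}

#' Plot the entropy-complexity plane envelope
#'
#' @param x \code{complexity_envelope}.
#' @param ... passed to \code{plot}.
#' @export
plot.complexity_envelope <- function(x, ...) {
  graphics::plot(x$H, x$Cmax, type = "l", lty = 2, xlab = "H", ylab = "C",
                 ylim = c(0, max(x$Cmax) * 1.05),
                 main = sprintf("H x C plane, L = %d", x$L), ...)
  graphics::lines(x$H, x$Cmin, lty = 2)
  invisible(x)
}
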