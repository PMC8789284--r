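# Direct least-squares ellipse fitting and perpendicular arc-length
# projection, used to linearize the dorsal-rim arc of column centers so that
# synapse positions along the rim can be profiled in one dimension.

#' Construct an ellipse model
#'
#' @param center Numeric length-2 center (um).
#' @param a,b Semi-axes with `a >= b > 0` (um).
#' @param angle Rotation of the major axis, radians in `[0, pi)`.
#' @return Object of class `ellipse_model`.
#' @export
ellipse_model <- function(center, a, b, angle = 0) {
  stopifnot(length(center) == 2, is.finite(a), is.finite(b))
  if (!(a > 0 && b > 0)) stop("semi-axes must be positive")
  if (b > a) { tmp <- a; a <- b; b <- tmp; angle <- angle + pi / 2 }
  angle <- angle %% pi
  structure(list(center = as.numeric(center), a = a, b = b, angle = angle),
            class = "ellipse_model")
}

#' @export
print.ellipse_model <- function(x, ...) {
  cat(sprintf("<ellipse_model> center (%.3f, %.3f), a = %.3f, b = %.3f, angle = %.4f rad\n",
              x$center[1], x$center[2], x$a, x$b, x$angle))
  invisible(x)
}

#' @export
coef.ellipse_model <- function(object, ...) {
  c(cx = object$center[1], cy = object$center[2], a = object$a, b = object$b,
    angle = object$angle)
}

#' Points on an ellipse at given parametric angles
#' @param object An `ellipse_model`.
#' @param t Parametric angles (radians).
#' @param ... Unused.
#' @return n x 2 matrix of points.
#' @export
predict.ellipse_model <- function(object, t, ...) {
  ct <- cos(object$angle); st <- sin(object$angle)
  xe <- object$a * cos(t); ye <- object$b * sin(t)
  cbind(object$center[1] + ct * xe - st * ye,
        object$center[2] + st * xe + ct * ye)
}

#' Fit an ellipse to 2-D points by direct least squares
#'
#' Algebraic conic fit with the ellipse-specific constraint
#' `4AC - B^2 = 1` (the numerically stable partitioned formulation of the
#' direct least-squares ellipse fit), followed by conversion of the conic
#' coefficients to center, semi-axes and rotation angle. The fit is
#' deterministic and invariant (equivariant) under translation and rotation
#' of the point set. A geometric refinement minimizing orthogonal distances
#' is available via `refine = TRUE`.
#'
#' @param points n x 2 numeric matrix or data frame (n >= 6, not collinear).
#' @param refine If `TRUE`, polish the algebraic estimate by
#'   Gauss-Newton-free minimization of summed squared orthogonal distances
#'   ([stats::optim()] on the five geometric parameters).
#' @return An [ellipse_model()].
#' @examples
#' t <- seq(0, 2 * pi, length.out = 13)[-13]
#' fit_ellipse_lsq(cbind(10 * cos(t), 10 * sin(t)))  # circle, a = b = 10
#' @export
fit_ellipse_lsq <- function(points, refine = FALSE) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  if (nrow(points) < 6) stop("need at least 6 points for an ellipse fit")
  if (any(!is.finite(points))) stop("non-finite points")
  # center/scale for conditioning; undo afterwards
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  sc <- max(stats::sd(points[, 1]), stats::sd(points[, 2]))
  if (!is.finite(sc) || sc == 0) stop("degenerate point configuration")
  x <- (points[, 1] - mx) / sc
  y <- (points[, 2] - my) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-14) stop("degenerate (collinear?) point configuration")
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  # premultiply by inv(C1), C1 = [[0,0,2],[0,-1,0],[2,0,0]]
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("no ellipse solution (degenerate configuration)")
  a1 <- evec[, ok[1]]
  coefs <- c(a1, as.numeric(Tm %*% a1))  # A B C D E F in scaled frame
  mod <- .conic_to_ellipse(coefs)
  # undo scaling: x = (X - mx)/sc
  mod <- ellipse_model(center = c(mod$center[1] * sc + mx,
                                  mod$center[2] * sc + my),
                       a = mod$a * sc, b = mod$b * sc, angle = mod$angle)
  if (refine) mod <- .refine_ellipse(mod, points)
  mod
}

# conic A x^2 + B xy + C y^2 + D x + E y + F = 0 -> geometric parameters
.conic_to_ellipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("conic is not an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  # value of the quadratic form at the center
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  theta <- 0.5 * atan2(B, A - C)
  ct <- cos(theta); st <- sin(theta)
  Ap <- A * ct^2 + B * ct * st + C * st^2
  Cp <- A * st^2 - B * ct * st + C * ct^2
  a2 <- -Fc / Ap
  b2 <- -Fc / Cp
  if (!(a2 > 0 && b2 > 0)) stop("conic is not an ellipse")
  ellipse_model(center = c(cx, cy), a = sqrt(a2), b = sqrt(b2), angle = theta)
}

.refine_ellipse <- function(mod, points) {
  obj <- function(p) {
    m <- tryCatch(ellipse_model(p[1:2], p[3], p[4], p[5]),
                  error = function(e) NULL)
    if (is.null(m)) return(1e12)
    sum(vapply(seq_len(nrow(points)), function(i)
      arc_position(points[i, ], m)$normal_distance^2, numeric(1)))
  }
  p0 <- c(mod$center, mod$a, mod$b, mod$angle)
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  ellipse_model(fit$par[1:2], fit$par[3], fit$par[4], fit$par[5])
}

# arc length along the ellipse from parametric angle 0 (positive major-axis
# vertex) to t, by adaptive quadrature; monotone in t on [0, 2*pi)
.ellipse_arc_length <- function(ellipse, t) {
  a <- ellipse$a; b <- ellipse$b
  speed <- function(s) sqrt(a^2 * sin(s)^2 + b^2 * cos(s)^2)
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    stats::integrate(speed, 0, ti, rel.tol = 1e-10,
                     subdivisions = 400L)$value
  }, numeric(1))
}

#' Perpendicular projection of a point onto an ellipse
#'
#' Finds the foot point (nearest point on the ellipse) by robust 1-D
#' minimization of the squared distance over the parametric angle: a dense
#' coarse scan bracketing the optimum followed by [stats::optimize()]
#' refinement. Returns the arc length of the foot point from the reference
#' vertex (the positive major-axis vertex, parametric angle 0, arc
#' increasing with parametric angle) and the signed normal distance
#' (positive outside the ellipse, negative inside).
#'
#' @param point Numeric length-2 point (um).
#' @param ellipse An [ellipse_model()].
#' @return List with `t` (parametric angle of the foot point in `[0, 2*pi)`),
#'   `foot` (length-2 point), `arc_length` (um) and `normal_distance`
#'   (signed, um).
#' @examples
#' e <- ellipse_model(c(0, 0), 10, 10)
#' arc_position(c(0, 12), e)  # quarter circle: arc = 10 * pi/2, distance 2
#' @export
arc_position <- function(point, ellipse) {
  stopifnot(inherits(ellipse, "ellipse_model"), length(point) == 2)
  p <- as.numeric(point)
  if (sqrt(sum((p - ellipse$center)^2)) < 1e-12 * max(ellipse$a, 1))
    stop("point at ellipse center: perpendicular projection is ambiguous")
  # work in the ellipse frame
  ct <- cos(ellipse$angle); st <- sin(ellipse$angle)
  q <- c(ct * (p[1] - ellipse$center[1]) + st * (p[2] - ellipse$center[2]),
         -st * (p[1] - ellipse$center[1]) + ct * (p[2] - ellipse$center[2]))
  a <- ellipse$a; b <- ellipse$b
  d2 <- function(t) (a * cos(t) - q[1])^2 + (b * sin(t) - q[2])^2
  tt <- seq(0, 2 * pi, length.out = 721)[-721]
  i <- which.min(d2(tt))
  w <- 2 * pi / 720
  opt <- stats::optimize(d2, interval = c(tt[i] - w, tt[i] + w), tol = 1e-12)
  t0 <- opt$minimum %% (2 * pi)
  if (2 * pi - t0 < 1e-6) t0 <- 0  # foot at the reference vertex, not wrap
  foot_local <- c(a * cos(t0), b * sin(t0))
  foot <- c(ellipse$center[1] + ct * foot_local[1] - st * foot_local[2],
            ellipse$center[2] + st * foot_local[1] + ct * foot_local[2])
  dist <- sqrt(max(opt$objective, 0))
  inside <- (q[1] / a)^2 + (q[2] / b)^2 < 1
  list(t = t0, foot = foot,
       arc_length = .ellipse_arc_length(ellipse, t0),
       normal_distance = if (inside) -dist else dist)
}

#' Arc positions for many points
#' @param points n x 2 matrix.
#' @param ellipse An [ellipse_model()].
#' @return Data frame with columns `arc_length_um`, `normal_distance_um`, `t`.
#' @export
arc_positions <- function(points, ellipse) {
  points <- as.matrix(points)
  res <- lapply(seq_len(nrow(points)), function(i)
    arc_position(points[i, ], ellipse))
  data.frame(arc_length_um = vapply(res, `[[`, numeric(1), "arc_length"),
             normal_distance_um = vapply(res, `[[`, numeric(1), "normal_distance"),
             t = vapply(res, `[[`, numeric(1), "t"))
}

#' Write an ellipse model as JSON
#' @param ellipse An [ellipse_model()].
#' @param path Output file.
#' @export
write_ellipse <- function(ellipse, path) {
  stopifnot(inherits(ellipse, "ellipse_model"))
  jsonlite::write_json(list(center = ellipse$center, a = ellipse$a,
                            b = ellipse$b, angle = ellipse$angle),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
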