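# Analytic score and Hessian of the left-truncated log-density with respect
# to theta = (a, b, sigma2).
#
# Writing L = Lambda(x) = (a/b)(e^{bx}-1), Lb = Lambda(x_breve),
# Q = 1 + s L, Qb = 1 + s Lb (s = sigma2), the truncated log-density is
#   g = log a + b x - (1 + 1/s) log Q + (1/s) log Qb .
# The a/b partials only involve Q and the parameter derivatives of Lambda and
# are regular at s = 0. The s partials contain 1/s and 1/s^2 singular-looking
# combinations whose singular parts cancel; they are isolated in two scalar
# helpers evaluated by power series in u = s L when u is small:
#   B(s, L) = {log(1+u) - u/(1+u)}/s^2                -> L^2/2       as s -> 0
#   A(s, L) = {-2 log(1+u) + 2u/(1+u) + u^2/(1+u)^2}/s^3 -> -(2/3) L^3
# so that
#   g_s  = B(s, L) - L/Q - B(s, Lb)
#   g_ss = A(s, L) + L^2/Q^2 - A(s, Lb) .
# Series coefficients: B: sum_{k>=2} (-1)^k (k-1)/k u^k,
#                      A: sum_{k>=3} (-1)^k (k-3+2/k) u^k.

# switch point: at |u| = 0.02 the order-12 series truncation error (~1e-21
# relative) and the direct evaluation's cancellation error (~1e-12 relative)
# are both negligible
.gg_u_switch <- 0.02

.gg_B <- function(s, L) {
  if (s == 0) return(L^2 / 2)
  u <- s * L
  small <- abs(u) < .gg_u_switch
  g <- numeric(length(u))
  if (any(small)) {
    us <- u[small]
    acc <- 0
    for (k in 2:12) acc <- acc + (-1)^k * (k - 1) / k * us^k
    g[small] <- acc
  }
  if (any(!small)) {
    ul <- u[!small]
    g[!small] <- log1p(ul) - ul / (1 + ul)
  }
  g / s^2
}

.gg_A <- function(s, L) {
  if (s == 0) return(-2 / 3 * L^3)
  u <- s * L
  small <- abs(u) < .gg_u_switch
  f <- numeric(length(u))
  if (any(small)) {
    us <- u[small]
    acc <- 0
    for (k in 3:12) acc <- acc + (-1)^k * (k - 3 + 2 / k) * us^k
    f[small] <- acc
  }
  if (any(!small)) {
    ul <- u[!small]
    f[!small] <- -2 * log1p(ul) + 2 * ul / (1 + ul) + ul^2 / (1 + ul)^2
  }
  f / s^3
}

# All first- and second-order partials of the truncated log-density,
# vectorized over x. Returns a list of vectors; Hessian elements are the six
# unique entries in (a, b, s) ordering.
.gg_dlog <- function(x, p, xb) {
  a <- p$a; b <- p$b; s <- p$sigma2
  E  <- exp(b * x);  Eb <- exp(b * xb)
  L  <- gg_cumhaz(x, a, b);  Lb <- gg_cumhaz(xb, a, b)
  Q  <- 1 + s * L;  Qb <- 1 + s * Lb
  # parameter derivatives of Lambda at x and at the truncation age
  La   <- expm1(b * x) / b
  Lba  <- expm1(b * xb) / b
  Ld   <- a * x * E / b - L / b                      # d Lambda / d b
  Lbd  <- a * xb * Eb / b - Lb / b
  Lab  <- x * E / b - expm1(b * x) / b^2
  Lbab <- xb * Eb / b - expm1(b * xb) / b^2
  Lbb  <- a * x^2 * E / b - 2 * a * x * E / b^2 + 2 * L / b^2
  Lbbb <- a * xb^2 * Eb / b - 2 * a * xb * Eb / b^2 + 2 * Lb / b^2

  list(
    d_a = 1 / a - (1 + s) * La / Q + Lba / Qb,
    d_b = x - (1 + s) * Ld / Q + Lbd / Qb,
    d_s = .gg_B(s, L) - L / Q - .gg_B(s, Lb),
    d_aa = -1 / a^2 + (1 + s) * s * La^2 / Q^2 - s * Lba^2 / Qb^2,
    d_ab = -(1 + s) * (Lab / Q - s * La * Ld / Q^2) +
      (Lbab / Qb - s * Lba * Lbd / Qb^2),
    d_as = -La / Q + (1 + s) * La * L / Q^2 - Lba * Lb / Qb^2,
    d_bb = -(1 + s) * (Lbb / Q - s * Ld^2 / Q^2) +
      (Lbbb / Qb - s * Lbd^2 / Qb^2),
    d_bs = -Ld / Q + (1 + s) * Ld * L / Q^2 - Lbd * Lb / Qb^2,
    d_ss = .gg_A(s, L) + L^2 / Q^2 - .gg_A(s, Lb)
  )
}

check_above_trunc <- function(x, t) {
  check_model_age(x)
  if (any(x <= t$x_breve) && t$x_breve > 0)
    stop("model ages must strictly exceed the truncation age ", t$x_breve)
  invisible(x)
}

#' Score of the truncated log-density
#'
#' Gradient of \eqn{\log f_{X|X>\breve x}(x;\theta)} with respect to
#' \eqn{\theta = (a, b, \sigma^2)}, evaluated analytically with exact
#' \eqn{\sigma^2 = 0} limits.
#'
#' @param x Model age(s) at death, each above the truncation model age.
#' @param p A [gg_params()] object.
#' @param trunc `NULL` or a [truncation_scheme()] / calendar truncation age.
#' @return For scalar `x` a named numeric vector `(a, b, sigma2)`; for vector
#'   `x` a matrix with one row per age.
#' @export
gg_score <- function(x, p, trunc = NULL) {
  stopifnot(inherits(p, "gg_params"))
  t <- as_trunc(trunc, p)
  check_above_trunc(x, t)
  d <- .gg_dlog(x, p, t$x_breve)
  out <- cbind(a = d$d_a, b = d$d_b, sigma2 = d$d_s)
  if (length(x) == 1L) out[1L, ] else out
}

#' Hessian of the truncated log-density
#'
#' Second-order partials of \eqn{\log f_{X|X>\breve x}(x;\theta)} with respect
#' to \eqn{\theta = (a, b, \sigma^2)}, as a symmetric 3 x 3 matrix. The
#' \eqn{\sigma^2 \to 0} limits are built in, so the boundary case is evaluated
#' exactly.
#'
#' @inheritParams gg_score
#' @return A symmetric 3 x 3 matrix (scalar `x`); for vector `x`, the matrices
#'   are returned as an `length(x) x 6` matrix of the unique elements with
#'   columns `aa, ab, as, bb, bs, ss`.
#' @export
gg_hessian <- function(x, p, trunc = NULL) {
  stopifnot(inherits(p, "gg_params"))
  t <- as_trunc(trunc, p)
  check_above_trunc(x, t)
  d <- .gg_dlog(x, p, t$x_breve)
  if (length(x) == 1L) {
    matrix(c(d$d_aa, d$d_ab, d$d_as,
             d$d_ab, d$d_bb, d$d_bs,
             d$d_as, d$d_bs, d$d_ss), 3L, 3L,
           dimnames = list(c("a", "b", "sigma2"), c("a", "b", "sigma2")))
  } else {
    cbind(aa = d$d_aa, ab = d$d_ab, as = d$d_as,
          bb = d$d_bb, bs = d$d_bs, ss = d$d_ss)
  }
}

# assemble a 3x3 symmetric matrix from the 6 unique elements (aa ab as bb bs ss)
.gg_mat3 <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3L, 3L,
         dimnames = list(c("a", "b", "sigma2"), c("a", "b", "sigma2")))
}
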