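# Gauss hypergeometric 2F1(1, b; b+1; -x) for x >= 0, b > 0.
#
# This is the only 2F1 the scenario-2 closed form needs: it is the Euler
# integral b * int_0^1 t^(b-1) / (1 + x t) dt, smooth on [0,1] for b >= 1.
# The defining series diverges for x > 1, and the Pfaff-transformed series
# 2F1(1,1;b+1;w)/(1+x) with w = x/(1+x) converges too slowly once w -> 1
# (x along the logistic tails reaches e^9 and beyond), so large arguments go
# through adaptive quadrature of the Euler integral instead.

hyp2f1_1b_series <- function(b, x) {
  # Pfaff: 2F1(1, b; b+1; -x) = (1+x)^-1 * 2F1(1, 1; b+1; x/(1+x));
  # term recursion t_{k+1} = t_k * (k+1) w / (b+1+k).
  w <- x / (1 + x)
  term <- 1
  acc <- 1
  k <- 0
  repeat {
    term <- term * (k + 1) * w / (b + 1 + k)
    acc <- acc + term
    k <- k + 1
    if (abs(term) < 1e-16 * abs(acc) || k > 4000) break
  }
  acc / (1 + x)
}

hyp2f1_1b_quad <- function(b, x) {
  # b * int_0^1 t^(b-1) / (1 + x t) dt
  val <- integrate(function(t) t^(b - 1) / (1 + x * t),
                   lower = 0, upper = 1,
                   rel.tol = 1e-12, abs.tol = 0,
                   subdivisions = 400L)
  b * val$value
}

#' Gauss hypergeometric function 2F1(1, b; b+1; -x)
#'
#' Special case of the Gauss hypergeometric function arising in the logistic
#' (scenario 2) closed-form occupancy solution. Evaluated by a Pfaff-transformed
#' series for moderate arguments and adaptive quadrature of the Euler integral
#' representation for large ones, where the series converges too slowly.
#'
#' @param b Second numerator parameter, `b > 0`.
#' @param x Negated argument, `x >= 0` (the function is evaluated at `-x`).
#' @return Numeric vector of 2F1(1, b; b+1; -x) values, in (0, 1].
#' @examples
#' hyp2f1_1b(1, 2)      # log(1 + x) / x
#' log(3) / 2
#' @export
hyp2f1_1b <- function(b, x) {
  check_positive(b, "b")
  check_positive(x, "x", allow_zero = TRUE)
  n <- max(length(b), length(x))
  b <- rep_len(b, n)
  x <- rep_len(x, n)
  vapply(seq_len(n), function(i) {
    if (x[i] == 0) return(1)
    w <- x[i] / (1 + x[i])
    # for large b the transformed series terms collapse like k!/b^k even at
    # w near 1; quadrature is only needed for small b with large arguments
    if (w <= 0.8 || b[i] >= 50) {
      hyp2f1_1b_series(b[i], x[i])
    } else {
      hyp2f1_1b_quad(b[i], x[i])
    }
  }, numeric(1))
}
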