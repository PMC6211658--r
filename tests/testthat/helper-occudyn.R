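# shared helpers: log-uniform parameter draws and a quick simulate wrapper

r_logunif <- function(n, lo, hi) {
  10^stats::runif(n, log10(lo), log10(hi))
}

# numeric half-maximum width (in seconds) of the scenario-1 availability
# curve measured on the un-normalized piecewise law (buildup to plateau,
# decay restarting at the plateau), threshold at half the plateau --
# an independent oracle for the functional-window formula
measure_window_s1 <- function(ki, k_minus_i) {
  gamma <- k_minus_i / ki
  f_build <- function(tau) (1 - exp(-tau)) - 0.5
  f_decay <- function(tau) exp(-gamma * (tau - 3)) - 0.5
  lo <- stats::uniroot(f_build, c(1e-12, 3), tol = 1e-12)$root
  hi <- stats::uniroot(f_decay, c(3, 3 + 2 * log(2) / gamma), tol = 1e-12)$root
  (hi - lo) / ki
}
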