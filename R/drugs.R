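# Marketed-drug kinetic profiling: record validation and the kon/koff/Kd
# summary statistics.

# thresholds as conventionally printed: slow koff is t1/2 >~ 30 min
.kon_fast <- 1e5      # 1/M/s
.koff_slow <- 3.9e-4  # 1/s
.kd_potent <- 1e-9    # M

#' Validate a table of drug kinetic records
#'
#' Checks internal consistency of published kinetics: `t_half` against
#' `ln 2 / koff` and `Kd` against `koff / kon`, each within a relative
#' tolerance (printed values are rounded). Violations are reported as
#' warnings, not errors, and flagged in the output.
#'
#' @param drugs Data frame with columns `drug`, `target`, `kon_M_per_s`,
#'   `koff_per_s`, `t_half_min`, `kd_M` (the batch CSV header).
#' @param tol Relative tolerance for the consistency checks (default 0.1).
#' @return The input as a tibble with logical columns `t_half_consistent`
#'   and `kd_consistent` appended.
#' @examples
#' drug_records(load_fixture("table4"))
#' @export
drug_records <- function(drugs, tol = 0.1) {
  need <- c("drug", "target", "kon_M_per_s", "koff_per_s", "t_half_min", "kd_M")
  if (!is.data.frame(drugs) || !all(need %in% names(drugs))) {
    abort(paste0("`drugs` must have columns: ", paste(need, collapse = ", ")),
          class = "occudyn_domain_error")
  }
  drugs <- as_tibble(drugs)
  t_half_pred <- log(2) / drugs$koff_per_s / 60
  kd_pred <- drugs$koff_per_s / drugs$kon_M_per_s
  drugs$t_half_consistent <- abs(drugs$t_half_min - t_half_pred) <=
    tol * t_half_pred
  drugs$kd_consistent <- abs(drugs$kd_M - kd_pred) <= tol * kd_pred
  n_bad <- sum(!drugs$t_half_consistent) + sum(!drugs$kd_consistent)
  if (n_bad > 0) {
    warn(sprintf("%d printed value(s) deviate >%.0f%% from ln2/koff or koff/kon (kept as printed).",
                 n_bad, 100 * tol))
  }
  drugs
}

#' Kinetic-profile summary of a drug set
#'
#' Computes the binding-kinetics census used to argue that marketed drugs were
#' (wittingly or not) optimized for fast association rather than long
#' residence time: fractions with fast `kon` (`>= 1e5` /M/s), slow `koff`
#' (`< 3.9e-4` /s, residence half-life over ~30 min), sub-nanomolar `Kd`, and
#' the kon-driven (`koff > 3.9e-4` and `kon > 1e5`) versus koff-driven
#' (`koff < 3.9e-4` and `kon < 1e5`) quadrants. Inequalities are strict or
#' inclusive exactly as conventionally printed.
#'
#' @inheritParams drug_records
#' @return One-row tibble with `n_records`, integer counts (`n_*`), raw
#'   fractions (`frac_*`), and display percentages rounded to the nearest
#'   integer (`pct_*`) for each of the five statistics.
#' @examples
#' drugset_summary(load_fixture("table4"))  # 72% fast-kon, 44% sub-nM Kd
#' @export
drugset_summary <- function(drugs) {
  drugs <- drug_records(drugs, tol = Inf)  # structure check only
  if (nrow(drugs) == 0) {
    abort("`drugs` must contain at least one record.",
          class = "occudyn_domain_error")
  }
  kon <- drugs$kon_M_per_s
  koff <- drugs$koff_per_s
  kd <- drugs$kd_M
  n <- nrow(drugs)
  counts <- c(
    kon_ge_1e5 = sum(kon >= .kon_fast),
    koff_slow = sum(koff < .koff_slow),
    kd_sub_nM = sum(kd < .kd_potent),
    kon_driven = sum(koff > .koff_slow & kon > .kon_fast),
    koff_driven = sum(koff < .koff_slow & kon < .kon_fast)
  )
  out <- tibble(n_records = n)
  for (nm in names(counts)) {
    out[[paste0("n_", nm)]] <- unname(counts[nm])
    out[[paste0("frac_", nm)]] <- unname(counts[nm]) / n
    out[[paste0("pct_", nm)]] <- round(100 * unname(counts[nm]) / n)
  }
  out
}
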