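# Time-bracket binning, clone-size sign test, rank-sum comparison,
# normalized chimerism AUC and DSA-positivity calls. All deterministic.

.brackets <- c("pre", "early", "mid", "late")

#' Assign post-operative days to time brackets
#'
#' POD 0 is `pre` (pre-transplant), 1-90 `early`, 91-365 `mid`, and
#' anything beyond 365 `late`.
#'
#' @param pod integer vector of post-operative days, `>= 0`.
#' @return character vector of bracket names.
#' @export
assign_bracket <- function(pod) {
  if (any(is.na(pod)) || any(pod < 0)) stop("pod must be non-negative")
  out <- character(length(pod))
  out[pod == 0] <- "pre"
  out[pod >= 1 & pod <= 90] <- "early"
  out[pod >= 91 & pod <= 365] <- "mid"
  out[pod > 365] <- "late"
  out
}

#' Sign test on clone-size changes between two time points
#'
#' Over clones present at both time points, counts those that grew (`+`)
#' and shrank (`-`); unchanged clones are excluded. The p-value is the
#' exact two-sided binomial at success probability one half (doubled
#' smaller tail, capped at 1). With zero informative clones the p-value is
#' undefined: `NA` is returned together with a warning of class
#' `bcrflow_no_informative_clones`.
#'
#' @param sizes_t1,sizes_t2 named numeric vectors mapping clone id to size
#'   at the earlier and later time point, over a shared patient/tissue.
#' @return list with `n_plus`, `n_minus`, `p_value`.
#' @export
sign_test_clone_sizes <- function(sizes_t1, sizes_t2) {
  shared <- intersect(names(sizes_t1), names(sizes_t2))
  d <- sizes_t2[shared] - sizes_t1[shared]
  n_plus <- sum(d > 0)
  n_minus <- sum(d < 0)
  n <- n_plus + n_minus
  if (n == 0L) {
    warning(warningCondition("no informative clones for sign test",
                             class = "bcrflow_no_informative_clones"))
    return(list(n_plus = 0L, n_minus = 0L, p_value = NA_real_))
  }
  p <- min(1, 2 * pbinom(min(n_plus, n_minus), n, 0.5))
  list(n_plus = n_plus, n_minus = n_minus, p_value = p)
}

# two-sided Mann-Whitney U statistic and p-value
.mwu_exact <- function(x, y) {
  # exact distribution via stats::pwilcox (no ties)
  nx <- length(x); ny <- length(y)
  U <- round(sum(rank(c(x, y))[seq_len(nx)]) - nx * (nx + 1) / 2)
  lo <- min(U, nx * ny - U)
  p <- stats::pwilcox(lo, nx, ny) +
    (1 - stats::pwilcox(nx * ny - lo - 1L, nx, ny))
  min(1, p)
}

.mwu_normal <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  n <- nx + ny
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sig2 <= 0) return(1)
  z <- (U - nx * ny / 2) / sqrt(sig2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Two-sided Mann-Whitney U comparison
#'
#' Nonparametric comparison of two independent samples. Uses the exact U
#' distribution when the combined sample size is at most 20 and there are
#' no ties; otherwise a normal approximation with tie correction.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @return the two-sided p-value.
#' @export
rank_sum_compare <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  if (length(pooled) <= 20L && !anyDuplicated(pooled))
    .mwu_exact(group_a, group_b)
  else
    .mwu_normal(group_a, group_b)
}

#' Normalized chimerism area under the curve
#'
#' Trapezoidal area under a chimerism time series within a time bracket,
#' divided by the days of measurement (last POD minus first POD in the
#' bracket); a flat series returns its constant, so the result stays on
#' the percent scale. With fewer than two points in the bracket the value
#' is undefined: `NA` with a warning of class `bcrflow_auc_undefined`.
#'
#' @param series data.frame with `pod` (strictly increasing) and `percent`
#'   in `[0, 100]`.
#' @param bracket optional bracket name; when given, only points whose POD
#'   falls in that bracket are used.
#' @return normalized AUC in `[0, 100]`, or `NA_real_`.
#' @export
chimerism_auc_normalized <- function(series, bracket = NULL) {
  s <- series[order(series$pod), , drop = FALSE]
  if (any(duplicated(s$pod))) stop("pods must be strictly increasing")
  if (any(s$percent < 0 | s$percent > 100)) stop("percent must be in [0, 100]")
  if (!is.null(bracket)) s <- s[assign_bracket(s$pod) == bracket, , drop = FALSE]
  if (nrow(s) < 2L) {
    warning(warningCondition("fewer than two points in bracket; AUC undefined",
                             class = "bcrflow_auc_undefined"))
    return(NA_real_)
  }
  span <- s$pod[nrow(s)] - s$pod[1]
  auc <- sum(diff(s$pod) * (head(s$percent, -1) + s$percent[-1]) / 2)
  auc / span
}

#' Filter chimerism points by parent-gate event count
#'
#' Retains measurements backed by at least `min_events` cells in the
#' flow-cytometry parent gate (default 40); points with a missing count
#' are dropped with a warning.
#'
#' @param series data.frame with a `parent_gate_count` column.
#' @param min_events minimum number of gated events, default 40.
#' @return the filtered series.
#' @export
parent_gate_filter <- function(series, min_events = 40L) {
  miss <- is.na(series$parent_gate_count)
  if (any(miss))
    warning(sum(miss), " point(s) dropped: missing parent gate count")
  series[!miss & series$parent_gate_count >= min_events, , drop = FALSE]
}

#' Call donor-specific antibody positivity
#'
#' A specimen is DSA-positive when its single-antigen-bead MFI reaches the
#' stated increment over baseline: 2,000 MFI for serum, 500 MFI for
#' concentrated culture supernatants. Vectorized over `mfi`/`baseline`.
#'
#' @param mfi measured mean fluorescence intensity, `>= 0`.
#' @param baseline normalized baseline (serum) or culture-medium control
#'   (supernatant) MFI, `>= 0`.
#' @param specimen `"serum"` or `"supernatant"`.
#' @return logical vector.
#' @export
call_dsa_positive <- function(mfi, baseline, specimen = c("serum", "supernatant")) {
  specimen <- match.arg(specimen)
  if (any(mfi < 0) || any(baseline < 0)) stop("MFI values must be non-negative")
  cut <- if (specimen == "serum") 2000 else 500
  (mfi - baseline) >= cut
}
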