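## Statistical primitives used throughout the pipeline. They are thin,
## contract-enforcing wrappers around base stats and the survival package:
## the value added here is fixed mode selection, direction labelling and
## degenerate-input handling, not the estimators themselves.

#' Tie-aware Spearman rank correlation with t-approximation p-value
#'
#' rs is the Pearson correlation of mid-ranks. The two-sided p-value uses
#' the t approximation `t = rs * sqrt((n - 2) / (1 - rs^2))` with n - 2
#' degrees of freedom (the behaviour of common statistical packages at the
#' sample sizes of TCGA stage groups); at rs = +-1 the p-value is floored
#' at the smallest representable positive double rather than reported as 0.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @return list with `rs`, `p_value`, `n`.
#' @examples
#' spearmanTest(1:5, c(2, 4, 6, 8, 10))$rs  # 1
#' @export
spearmanTest <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need n >= 4 for a Spearman p-value")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("degenerate input: constant vector")
  rs <- stats::cor(rank(x), rank(y))
  p <- spearmanPvalue(rs, n)
  list(rs = rs, p_value = p, n = n)
}

## two-sided t-approximation p; vectorized over rs
spearmanPvalue <- function(rs, n) {
  denom <- pmax(1 - rs^2, .Machine$double.eps)
  tstat <- rs * sqrt((n - 2) / denom)
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  pmax(pmin(p, 1), .Machine$double.xmin)
}

#' Two-sided Mann-Whitney U test
#'
#' U from rank sums with mid-ranks for ties. Mode `"auto"` uses exact
#' enumeration when `n1 * n2 <= 400` and there are no ties, otherwise the
#' normal approximation with tie and continuity correction. Direction is
#' the group with the larger rank sum (equivalently, stochastically larger
#' values); `"none"` when U equals its null mean or p = 1.
#'
#' @param x,y numeric vectors (both non-empty, combined length >= 4 for a
#'   p-value).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list with `statistic` (U for x vs y), `p_value`, `direction`
#'   (`"group1_higher"`, `"group2_higher"`, `"none"`), `mode_used`.
#' @export
mannWhitney <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("empty group")
  if (length(x) + length(y) < 4) stop("need >= 4 observations for a p-value")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
    exact = TRUE,
    normal = FALSE,
    auto = (length(x) * length(y) <= 400) && !ties
  )
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE, alternative = "two.sided"))
  u <- unname(wt$statistic)
  mu <- length(x) * length(y) / 2
  direction <- if (u > mu) "group1_higher" else if (u < mu) "group2_higher" else "none"
  p <- wt$p.value
  if (is.na(p)) p <- 1  # fully tied data carry no evidence
  p <- min(max(p, .Machine$double.xmin), 1)
  if (p >= 1) direction <- "none"
  list(statistic = u, p_value = p, direction = direction,
       mode_used = if (use_exact) "exact" else "normal")
}

#' Kaplan-Meier product-limit fit
#'
#' `S(t) = prod over event times <= t of (1 - d_i / n_i)`. Fitted through
#' [survival::survfit]; only times with at least one death appear in the
#' curve, so a fully censored sample yields a flat curve at 1.
#'
#' @param times non-negative follow-up times.
#' @param events logical, TRUE = death observed.
#' @return a [KMCurve-class].
#' @export
kmFit <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("negative follow-up time")
  events <- as.logical(events)
  if (!any(events)) {
    return(new("KMCurve", times = numeric(0), surv = numeric(0),
               at_risk = integer(0), n_events = integer(0),
               n = length(times)))
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  new("KMCurve",
      times = fit$time[keep], surv = fit$surv[keep],
      at_risk = as.integer(fit$n.risk[keep]),
      n_events = as.integer(fit$n.event[keep]),
      n = length(times))
}

#' Survival probability of a KM curve at given times
#'
#' @param curve a [KMCurve-class].
#' @param t numeric times.
#' @return step-function values S(t).
#' @export
kmSurvAt <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve@times <= tt)
    if (!length(i)) 1 else curve@surv[max(i)]
  }, numeric(1))
}

## restricted mean survival time up to tau (area under the KM step curve)
rmst <- function(curve, tau) {
  ts <- c(0, curve@times[curve@times <= tau], tau)
  ss <- c(1, curve@surv[curve@times <= tau])
  sum(ss * diff(ts))
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' Chi-square on 1 df from the observed-minus-expected deaths over pooled
#' event times with hypergeometric variance, via [survival::survdiff].
#' The worse-surviving group (smaller restricted mean survival up to the
#' shorter group's last follow-up) is labelled as the direction; with no
#' deaths in either group p = 1 and direction `"none"`.
#'
#' @param times1,events1,times2,events2 follow-up times and death
#'   indicators for the two groups.
#' @return list with `statistic` (chi-square), `p_value`, `direction`
#'   (`"group1_worse"`, `"group2_worse"`, `"none"`).
#' @export
logrankTest <- function(times1, events1, times2, events2) {
  if (!length(times1) || !length(times2)) stop("empty group")
  events1 <- as.logical(events1); events2 <- as.logical(events2)
  if (!any(events1) && !any(events2)) {
    return(list(statistic = 0, p_value = 1, direction = "none"))
  }
  time <- c(times1, times2)
  status <- c(events1, events2)
  grp <- rep(c(1L, 2L), c(length(times1), length(times2)))
  ## a zero hypergeometric variance (e.g. every subject dying at one time)
  ## carries no evidence against the null
  sd <- tryCatch(survival::survdiff(survival::Surv(time, status) ~ grp),
                 error = function(e) NULL)
  if (is.null(sd)) return(list(statistic = 0, p_value = 1, direction = "none"))
  chisq <- unname(sd$chisq)
  p <- min(max(stats::pchisq(chisq, df = 1, lower.tail = FALSE), .Machine$double.xmin), 1)
  k1 <- kmFit(times1, events1); k2 <- kmFit(times2, events2)
  tau <- min(max(times1), max(times2))
  r1 <- rmst(k1, tau); r2 <- rmst(k2, tau)
  direction <- if (p >= 1 || isTRUE(all.equal(r1, r2))) "none"
               else if (r1 < r2) "group1_worse" else "group2_worse"
  list(statistic = chisq, p_value = p, direction = direction)
}
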