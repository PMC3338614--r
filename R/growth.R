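#' Exponential-phase growth rate from an OD time series
#'
#' The growth rate is the slope of the natural log of optical density versus
#' time during the exponential growth phase. The exponential window is chosen
#' by sliding-window search in the "easy linear" style: among all windows of
#' at least \code{min_points} consecutive readings whose linear fit of
#' ln(OD) on time has R-squared of at least \code{r2_min}, the one with the
#' steepest slope wins (growth decelerates monotonically, so the steepest
#' log-linear stretch is the exponential phase), with slope ties broken by
#' the longer window. If no window qualifies (noisy flat cultures), the full
#' series is fit and its slope (about 0 for flat cultures) is returned.
#'
#' @param time time points in hours (strictly increasing, >= 6 points).
#' @param od OD600 readings (> 0 after blank subtraction).
#' @param min_points minimum window length; default one tenth of the series
#'   (at least 5 points), which damps noise-chasing on dense plate-reader
#'   series while keeping short toy series usable.
#' @param r2_min R-squared threshold defining "linear enough".
#' @param blank optional constant blank OD subtracted before the log.
#' @return list of class \code{growth_rate}: \code{rate} (/hour),
#'   \code{window} (start/end indices), \code{r2}, \code{n}.
#' @examples
#' t <- seq(0, 10, by = 0.25)
#' growth_rate(t, 0.1 * exp(0.4 * t))$rate  # 0.4
#' @export
growth_rate <- function(time, od, min_points = NULL, r2_min = 0.99, blank = 0) {
  if (length(time) != length(od)) stop("time and od lengths differ")
  if (length(time) < 6) stop("need at least 6 time points")
  if (is.unsorted(time, strictly = TRUE)) stop("times must be strictly increasing")
  od <- od - blank
  if (any(od <= 0)) stop("nonpositive OD values (after blanking)")
  y <- log(od)
  n <- length(y)
  if (is.null(min_points)) min_points <- max(5, round(n / 10))
  min_points <- min(min_points, n)

  # cumulative sums for O(1) window regressions
  ct <- cumsum(time); ct2 <- cumsum(time^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2); cty <- cumsum(time * y)
  wsum <- function(cs, i, j) cs[j] - if (i > 1) cs[i - 1] else 0
  win_fit <- function(i, j) {
    m <- j - i + 1
    st <- wsum(ct, i, j); st2 <- wsum(ct2, i, j)
    sy <- wsum(cy, i, j); sy2 <- wsum(cy2, i, j); sty <- wsum(cty, i, j)
    sxx <- st2 - st^2 / m
    sxy <- sty - st * sy / m
    syy <- sy2 - sy^2 / m
    slope <- sxy / sxx
    ssr <- max(0, syy - slope * sxy)
    r2 <- if (syy <= .Machine$double.eps * max(1, sy2))
      1 else max(0, min(1, 1 - ssr / syy))
    c(slope = slope, r2 = r2)
  }

  best <- NULL
  slope_tol <- 1e-8
  for (len in seq(min_points, n)) {
    for (i in seq_len(n - len + 1)) {
      f <- win_fit(i, i + len - 1)
      if (f[["r2"]] < r2_min) next
      better <- is.null(best) ||
        f[["slope"]] > best$rate + slope_tol * max(1, abs(best$rate)) ||
        (abs(f[["slope"]] - best$rate) <= slope_tol * max(1, abs(best$rate)) &&
           len > best$n)
      if (better)
        best <- list(rate = f[["slope"]], window = c(i, i + len - 1),
                     r2 = f[["r2"]], n = len)
    }
  }
  if (is.null(best)) {
    f <- win_fit(1, n)
    best <- list(rate = f[["slope"]], window = c(1, n), r2 = f[["r2"]], n = n)
  }
  structure(best, class = "growth_rate")
}

#' @export
print.growth_rate <- function(x, ...) {
  cat(sprintf("growth_rate: %.4g /h over points %d-%d (R^2 = %.4f)\n",
              x$rate, x$window[1], x$window[2], x$r2))
  invisible(x)
}

#' Growth rates for a table of curves
#'
#' Applies \code{\link{growth_rate}} per strain (and replicate, if present)
#' and aggregates replicates as arithmetic mean and standard deviation.
#'
#' @param curves data.frame with columns strain, time_h, od and optionally
#'   replicate.
#' @param ... passed to \code{\link{growth_rate}}.
#' @return data.frame with columns strain, rate_per_h, sd, r2 (mean across
#'   replicates), n_replicates.
#' @export
growth_rates <- function(curves, ...) {
  split_cols <- if ("replicate" %in% names(curves))
    interaction(curves$strain, curves$replicate, drop = TRUE) else curves$strain
  per_curve <- do.call(rbind, lapply(split(curves, split_cols), function(d) {
    d <- d[order(d$time_h), ]
    gr <- growth_rate(d$time_h, d$od, ...)
    data.frame(strain = d$strain[1], rate = gr$rate, r2 = gr$r2)
  }))
  agg <- do.call(rbind, lapply(split(per_curve, per_curve$strain), function(d) {
    data.frame(strain = d$strain[1], rate_per_h = mean(d$rate),
               sd = if (nrow(d) > 1) sd(d$rate) else NA_real_,
               r2 = mean(d$r2), n_replicates = nrow(d))
  }))
  rownames(agg) <- NULL
  agg
}

#' Relative growth-rate reduction
#'
#' @param rate_strain growth rate of the perturbed strain.
#' @param rate_control growth rate of the matched control (> 0).
#' @return \code{1 - rate_strain / rate_control} (0.2 = a 20\% reduction).
#' @export
relative_reduction <- function(rate_strain, rate_control) {
  if (any(rate_control <= 0)) stop("rate_control must be > 0")
  1 - rate_strain / rate_control
}

#' Classify the graded growth impact on a knockout strain
#'
#' Applies the published decision rule for synthetic-lethal knockouts
#' crossed with the graded dominant mutant: HIGH when the growth-rate
#' reduction at the strongest promoter exceeds \code{high_threshold} (20\%)
#' and the reduction trend over PS is increasing; NONE when the maximum
#' reduction stays below \code{none_threshold}; MODERATE otherwise. The trend
#' p-value comes from the Jonckheere-Terpstra statistic over the ordered PS
#' levels.
#'
#' @param reductions named numeric vector (names = PS levels) of relative
#'   reductions, covering at least 3 PS levels; the value at the maximum PS
#'   must be present (not NA).
#' @param high_threshold reduction at the strongest promoter defining HIGH.
#' @param none_threshold maximum reduction below which the strain is
#'   unaffected.
#' @return list of class \code{impact_call}: \code{label} ("HIGH",
#'   "MODERATE", "NONE"), \code{max_reduction}, \code{reduction_at_max_ps},
#'   \code{trend_p}, \code{reductions}.
#' @examples
#' classify_impact(c("0.16" = .05, "0.32" = .10, "0.68" = .18, "0.95" = .30))
#' @export
classify_impact <- function(reductions, high_threshold = 0.20,
                            none_threshold = 0.05) {
  ps <- as.numeric(names(reductions))
  if (anyNA(ps)) stop("reductions must be named by numeric PS levels")
  if (length(ps) < 3) stop("need reductions for at least 3 PS levels")
  o <- order(ps)
  ps <- ps[o]; red <- as.numeric(reductions[o])
  if (is.na(red[length(red)])) stop("reduction at the highest PS level is missing")

  jt <- jt_test(red[!is.na(red)], ps[!is.na(red)], alternative = "increasing")
  increasing <- jt$statistic > jt$expected
  at_max <- red[length(red)]
  label <- if (at_max > high_threshold && increasing) "HIGH"
  else if (max(red, na.rm = TRUE) < none_threshold) "NONE"
  else "MODERATE"
  structure(list(label = label, max_reduction = max(red, na.rm = TRUE),
                 reduction_at_max_ps = at_max, trend_p = jt$p.value,
                 reductions = setNames(red, ps)),
            class = "impact_call")
}

#' @export
print.impact_call <- function(x, ...) {
  cat(sprintf("impact_call: %s (reduction at max PS %.3f, trend p %.3g)\n",
              x$label, x$reduction_at_max_ps, x$trend_p))
  invisible(x)
}

#' Impact calls for a synthetic-lethal growth study
#'
#' Full growth-assay pipeline over a long-format table of curves: estimates
#' per-(gene, PS) growth rates, computes relative reductions against each
#' gene's no-mutant control (PS = 0 rows), and classifies every knockout.
#'
#' @param curves data.frame with columns gene, ps (0 for the no-mutant
#'   control), time_h, od, and optionally replicate.
#' @param ... thresholds passed to \code{\link{classify_impact}}.
#' @return data.frame with columns gene, label, max_reduction, trend_p.
#' @export
growth_study_impacts <- function(curves, ...) {
  need <- c("gene", "ps", "time_h", "od")
  if (!all(need %in% names(curves)))
    stop("curves must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(curves, curves$gene), function(d) {
    d$strain <- sprintf("%s@%g", d$gene, d$ps)
    rates <- growth_rates(d[, intersect(names(d), c("strain", "time_h", "od", "replicate"))])
    rates$ps <- as.numeric(sub(".*@", "", rates$strain))
    ctrl <- rates$rate_per_h[rates$ps == 0]
    if (length(ctrl) != 1) stop("gene ", d$gene[1], ": need exactly one PS = 0 control")
    mut <- rates[rates$ps > 0, ]
    red <- setNames(relative_reduction(mut$rate_per_h, ctrl), mut$ps)
    call <- classify_impact(red, ...)
    data.frame(gene = d$gene[1], label = call$label,
               max_reduction = call$max_reduction, trend_p = call$trend_p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
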