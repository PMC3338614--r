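#' Hill-slope competitive-inhibition model
#'
#' Signal as a function of the dominant mutant's relative promoter strength:
#' \deqn{signal(PS) = Bottom + \frac{Top - Bottom}{1 + (PS/IC50)^h}}
#' \emph{Top} is the signal with no competition (PS = 0), \emph{Bottom} the
#' signal of a competitively saturated system, and the IC50 is the promoter
#' strength at which the signal sits exactly halfway between the two.
#'
#' @param ps promoter strength(s), >= 0. May also be a \code{hill_fit}, in
#'   which case use \code{predict()} instead.
#' @param top,bottom,ic50,h model parameters (top > bottom, ic50 > 0, h > 0).
#' @return predicted signal(s).
#' @examples
#' hill_signal(0.3, top = 100, bottom = 20, ic50 = 0.3)  # halfway: 60
#' @export
hill_signal <- function(ps, top, bottom, ic50, h = 1) {
  if (any(ps < 0)) stop("ps must be >= 0")
  if (ic50 <= 0 || h <= 0) stop("ic50 and h must be > 0")
  bottom + (top - bottom) / (1 + (ps / ic50)^h)
}

#' Fit the Hill-slope competitive-inhibition model
#'
#' Least-squares fit of (top, bottom, ic50, and optionally the Hill slope h)
#' to replicated signal-vs-promoter-strength observations, by bounded
#' Levenberg-Marquardt with multiple starts on a log-spaced IC50 grid (the
#' RSS surface is multimodal in IC50 for noisy sparse curves). Replicates are
#' fit as individual observations by default so replicate count weights the
#' loss; set \code{average_replicates} to fit per-strength means.
#'
#' Bounds keep fits physical: top in [0.5, 2] x max observed, bottom in
#' [0, 2 x min observed], ic50 in [min(ps > 0)/10, 10 x max(ps)], h in
#' [0.2, 10]. A flat response is reported as \code{converged = FALSE} with an
#' undefined IC50 rather than a fabricated value.
#'
#' @param ps promoter strengths (>= 0; at least 4 distinct values), or a
#'   data.frame with columns \code{ps} and \code{signal}.
#' @param signal observed signals (same length as \code{ps}).
#' @param fix_slope if non-NULL, fix the Hill slope at this value (> 0)
#'   instead of fitting it.
#' @param fix_bottom if non-NULL, fix the saturated signal at this value
#'   (e.g. an independently measured fully inhibited condition, such as a
#'   knockout); the bottom is then not fitted.
#' @param average_replicates average signals per strength before fitting.
#' @param n_starts number of IC50 starting values.
#' @return object of class \code{hill_fit}: list with \code{top},
#'   \code{bottom}, \code{ic50}, \code{h}, \code{rss}, \code{converged},
#'   \code{n_obs}, \code{df_residual} and standard errors \code{se}.
#' @examples
#' d <- simulate_dose_response(100, 20, 0.3, noise_sd = 0)
#' fit_hill(d$ps, d$signal)
#' @export
fit_hill <- function(ps, signal = NULL, fix_slope = NULL, fix_bottom = NULL,
                     average_replicates = FALSE, n_starts = 7) {
  if (is.data.frame(ps)) {
    signal <- ps$signal
    ps <- ps$ps
  }
  if (length(ps) != length(signal)) stop("ps and signal lengths differ")
  if (!all(is.finite(ps)) || any(ps < 0)) stop("ps values must be finite and >= 0")
  if (!all(is.finite(signal))) stop("signal values must be finite")
  if (length(unique(ps)) < 4)
    stop("at least 4 distinct PS values are required (4 free parameters)")
  if (!is.null(fix_slope) && fix_slope <= 0) stop("fix_slope must be > 0")

  if (average_replicates) {
    signal <- tapply(signal, ps, mean)
    ps <- as.numeric(names(signal))
    signal <- as.numeric(signal)
  }

  out <- list(top = NA_real_,
              bottom = if (is.null(fix_bottom)) NA_real_ else fix_bottom,
              ic50 = NA_real_,
              h = if (is.null(fix_slope)) NA_real_ else fix_slope,
              rss = NA_real_, converged = FALSE, n_obs = length(ps),
              df_residual = NA_integer_,
              se = c(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                     h = NA_real_))
  class(out) <- "hill_fit"

  rng <- diff(range(signal))
  if (rng <= 1e-12 * max(1, abs(mean(signal))))  # flat response: not identifiable
    return(out)

  mx <- max(signal); mn <- min(signal)
  ps_pos <- ps[ps > 0]
  ic_lo <- min(ps_pos) / 10
  ic_hi <- max(ps) * 10
  if (mn >= 0) {
    # physical bounds for a positive signal scale (e.g. RFU)
    top_b <- c(0.5 * mx, 2 * mx)
    bot_b <- c(0, 2 * mn)
  } else {
    # shift-invariant bounds for signed scales (e.g. negated log2 expression)
    top_b <- c(mx - 0.5 * rng, mx + rng)
    bot_b <- c(mn - rng, mn + 0.5 * rng)
  }
  lower <- c(top = top_b[1], bottom = bot_b[1], log_ic50 = log(ic_lo),
             log_h = log(0.2))
  upper <- c(top = top_b[2], bottom = bot_b[2], log_ic50 = log(ic_hi),
             log_h = log(10))

  free_h <- is.null(fix_slope)
  free_b <- is.null(fix_bottom)
  resid_fn <- function(par) {
    h <- if (free_h) exp(par[["log_h"]]) else fix_slope
    b <- if (free_b) par[["bottom"]] else fix_bottom
    signal - hill_signal(ps, par[["top"]], b, exp(par[["log_ic50"]]), h)
  }

  starts <- exp(seq(log(ic_lo), log(ic_hi), length.out = n_starts))
  best <- NULL
  for (ic0 in starts) {
    par0 <- c(top = mx, bottom = mn, log_ic50 = log(ic0), log_h = log(1))
    idx <- intersect(c(1, if (free_b) 2, 3, if (free_h) 4), 1:4)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par0[idx], lower[idx], upper[idx], fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-12, ptol = 1e-12, maxiter = 1000,
                             maxfev = 100000))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(out)

  p <- best$par
  out$top <- p[["top"]]
  out$bottom <- if (free_b) p[["bottom"]] else fix_bottom
  out$ic50 <- exp(p[["log_ic50"]])
  out$h <- if (free_h) exp(p[["log_h"]]) else fix_slope
  out$rss <- best$deviance
  n_par <- length(p)
  out$df_residual <- length(ps) - n_par
  out$converged <- best$info %in% 1:4 && out$top > out$bottom

  # covariance from the LM approximation to the Hessian (2 J'J)
  if (out$converged && out$df_residual > 0) {
    s2 <- out$rss / out$df_residual
    cov <- tryCatch(2 * s2 * solve(best$hessian), error = function(e) NULL)
    if (!is.null(cov) && all(diag(cov) >= 0)) {
      se <- sqrt(diag(cov))
      out$se["top"] <- se[["top"]]
      if (free_b) out$se["bottom"] <- se[["bottom"]]
      out$se["ic50"] <- out$ic50 * se[["log_ic50"]]  # delta method, log scale
      if (free_h) out$se["h"] <- out$h * se[["log_h"]]
    }
  }
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("hill_fit: not converged (flat or degenerate response)\n")
    return(invisible(x))
  }
  cat(sprintf("hill_fit: top=%.4g bottom=%.4g ic50=%.4g h=%.4g (rss=%.4g, n=%d)\n",
              x$top, x$bottom, x$ic50, x$h, x$rss, x$n_obs))
  invisible(x)
}

#' @param object a \code{hill_fit}.
#' @param newdata numeric vector of promoter strengths.
#' @param ... unused.
#' @rdname hill_signal
#' @export
predict.hill_fit <- function(object, newdata, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  hill_signal(newdata, object$top, object$bottom, object$ic50, object$h)
}

#' Compare two IC50 estimates
#'
#' Returns the ratio \code{ic50_b / ic50_a} with an uncertainty propagated
#' from the two fits' residual variances (delta method on the log-scale
#' standard errors). The canonical use is haploid vs diploid reporter
#' strains, where gene dosage doubles the promoter strength needed for
#' half-maximal inhibition.
#'
#' @param fit_a,fit_b converged \code{hill_fit} objects (a = reference).
#' @return list with \code{ratio}, \code{se} and a 95\% interval \code{ci}.
#' @export
compare_ic50 <- function(fit_a, fit_b) {
  if (!inherits(fit_a, "hill_fit") || !inherits(fit_b, "hill_fit"))
    stop("inputs must be hill_fit objects")
  if (!fit_a$converged || !fit_b$converged)
    stop("both fits must have converged to compare IC50s")
  ratio <- fit_b$ic50 / fit_a$ic50
  rel_a <- fit_a$se[["ic50"]] / fit_a$ic50
  rel_b <- fit_b$se[["ic50"]] / fit_b$ic50
  se <- ratio * sqrt(rel_a^2 + rel_b^2)
  ci <- if (is.finite(se)) ratio + c(-1, 1) * qnorm(0.975) * se else c(NA, NA)
  list(ratio = ratio, se = se, ci = ci)
}

#' Write a Hill fit as JSON
#'
#' @param fit a \code{hill_fit}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hill_fit <- function(fit, path) {
  jsonlite::write_json(
    list(top = fit$top, bottom = fit$bottom, ic50 = fit$ic50, h = fit$h,
         rss = fit$rss, converged = fit$converged, n_obs = fit$n_obs),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
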