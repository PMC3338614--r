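#' Configuration for the synthetic expression generator
#'
#' Collects all knobs of the generative model for a synthetic graded
#' dominant-mutant expression study. Defaults reflect the study design the
#' package targets: a promoter-strength (PS) library spanning 0.07--0.95
#' relative strength, biological triplicates, log-normal multiplicative noise
#' (Gaussian on the log2 scale) and an asymptotic effect of 2 log2 units.
#'
#' Gene archetypes:
#' \describe{
#'   \item{CA_UP / CA_DOWN}{catalytically associated: expression follows the
#'     residual catalytic activity \eqn{A(PS) = 1/(1 + (PS/K_g)^h)} so the
#'     mean response is \eqn{baseline \pm effect\,(1 - A(PS))}; the knockout
#'     matches the saturated mutant (\eqn{A = 0}).}
#'   \item{FN}{false negative: graded exactly like CA, but compensated in the
#'     knockout (knockout mean = baseline).}
#'   \item{OPP}{opposite: graded up under the titration but moves the other
#'     way in the knockout (knockout mean = baseline - effect).}
#'   \item{NCA}{non-catalytically associated: flat across the titration,
#'     shifted by +/- effect in the knockout only.}
#'   \item{NULL}{unaffected everywhere.}
#' }
#'
#' @param n_ca_up,n_ca_down,n_nca,n_fn,n_opp,n_null non-negative integers;
#'   number of genes per archetype.
#' @param ps_grid strictly increasing promoter strengths in (0, 1.2].
#' @param n_replicates biological replicates per condition (>= 2).
#' @param noise_sd standard deviation of the additive Gaussian noise on the
#'   log2 scale (>= 0).
#' @param baseline_log2 baseline log2 expression.
#' @param effect_log2 asymptotic absolute log2 fold change (> 0).
#' @param k_range length-2 range (K_min, K_max) from which per-gene grading
#'   midpoints are drawn uniformly; must satisfy 0 < K_min < K_max <=
#'   2 * max(ps_grid).
#' @param hill_slope Hill slope h of the per-gene response (> 0).
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return an object of class \code{synth_config} (a validated list).
#' @examples
#' cfg <- synth_config(n_ca_up = 5, n_null = 5, noise_sd = 0)
#' @export
synth_config <- function(n_ca_up = 50, n_ca_down = 50, n_nca = 50,
                         n_fn = 50, n_opp = 50, n_null = 50,
                         ps_grid = c(0.07, 0.16, 0.32, 0.68, 0.95),
                         n_replicates = 3, noise_sd = 0.25,
                         baseline_log2 = 8, effect_log2 = 2,
                         k_range = c(0.05, 1), hill_slope = 1, seed = 1L) {
  cfg <- list(
    n_ca_up = n_ca_up, n_ca_down = n_ca_down, n_nca = n_nca,
    n_fn = n_fn, n_opp = n_opp, n_null = n_null,
    ps_grid = as.numeric(ps_grid), n_replicates = as.integer(n_replicates),
    noise_sd = noise_sd, baseline_log2 = baseline_log2,
    effect_log2 = effect_log2, k_range = as.numeric(k_range),
    hill_slope = hill_slope, seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  counts <- c("n_ca_up", "n_ca_down", "n_nca", "n_fn", "n_opp", "n_null")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v))
      stop("invalid synth_config field '", f, "': must be a non-negative integer")
  }
  ps <- cfg$ps_grid
  if (length(ps) < 1 || anyNA(ps) || any(ps <= 0) || any(ps > 1.2))
    stop("invalid synth_config field 'ps_grid': values must lie in (0, 1.2]")
  if (is.unsorted(ps, strictly = TRUE))
    stop("invalid synth_config field 'ps_grid': must be strictly increasing")
  if (is.na(cfg$n_replicates) || cfg$n_replicates < 2)
    stop("invalid synth_config field 'n_replicates': must be >= 2")
  if (is.na(cfg$noise_sd) || cfg$noise_sd < 0)
    stop("invalid synth_config field 'noise_sd': must be >= 0")
  if (!is.finite(cfg$baseline_log2))
    stop("invalid synth_config field 'baseline_log2': must be finite")
  if (!is.finite(cfg$effect_log2) || cfg$effect_log2 <= 0)
    stop("invalid synth_config field 'effect_log2': must be > 0")
  kr <- cfg$k_range
  if (length(kr) != 2 || anyNA(kr) || kr[1] <= 0 || kr[1] >= kr[2] ||
      kr[2] > 2 * max(ps))
    stop("invalid synth_config field 'k_range': need 0 < K_min < K_max <= 2*max(ps_grid)")
  if (!is.finite(cfg$hill_slope) || cfg$hill_slope <= 0)
    stop("invalid synth_config field 'hill_slope': must be > 0")
  if (is.na(cfg$seed))
    stop("invalid synth_config field 'seed': must be an integer")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  counts <- unlist(x[c("n_ca_up", "n_ca_down", "n_nca", "n_fn", "n_opp", "n_null")])
  cat("synth_config:", sum(counts), "genes (",
      paste(sprintf("%s=%d", sub("^n_", "", names(counts)), counts), collapse = ", "),
      ")\n", sep = "")
  cat("  PS grid:", paste(x$ps_grid, collapse = ", "),
      "| replicates:", x$n_replicates, "| noise sd:", x$noise_sd, "\n")
  cat("  baseline:", x$baseline_log2, "| effect:", x$effect_log2,
      "| K range: [", x$k_range[1], ",", x$k_range[2], "] | h:", x$hill_slope,
      "| seed:", x$seed, "\n")
  invisible(x)
}
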