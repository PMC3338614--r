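#' Simulate a replicated dose-response curve
#'
#' Draws replicate signals around the Hill-slope competitive-inhibition model
#' \eqn{signal(PS) = Bottom + (Top - Bottom)/(1 + (PS/IC50)^h)} with Gaussian
#' noise, emulating a fluorescent-reporter titration (mean fluorescence vs
#' relative promoter strength of the dominant mutant).
#'
#' @param top signal with no competition (must exceed \code{bottom}).
#' @param bottom signal of a competitively saturated system.
#' @param ic50 promoter strength of half-maximal inhibition (> 0).
#' @param h Hill slope (> 0).
#' @param ps_grid promoter strengths to sample.
#' @param n_replicates replicates per strength.
#' @param noise_sd Gaussian noise sd on the signal scale.
#' @param seed integer seed.
#' @return data.frame with columns ps, replicate, signal.
#' @examples
#' simulate_dose_response(100, 20, 0.3, noise_sd = 0, n_replicates = 1)
#' @export
simulate_dose_response <- function(top, bottom, ic50, h = 1,
                                   ps_grid = c(0.07, 0.16, 0.32, 0.68, 0.95),
                                   n_replicates = 3, noise_sd = 0, seed = 1L) {
  if (!is.finite(top) || !is.finite(bottom) || top <= bottom)
    stop("invalid parameters: top must be greater than bottom")
  if (!is.finite(ic50) || ic50 <= 0) stop("invalid parameters: ic50 must be > 0")
  if (!is.finite(h) || h <= 0) stop("invalid parameters: h must be > 0")
  if (noise_sd < 0) stop("invalid parameters: noise_sd must be >= 0")
  df <- expand.grid(replicate = seq_len(n_replicates), ps = ps_grid)[, 2:1]
  mu <- hill_signal(df$ps, top, bottom, ic50, h)
  withr::with_seed(seed, {
    df$signal <- mu + if (noise_sd > 0) rnorm(nrow(df), 0, noise_sd) else 0
  })
  df[order(df$ps, df$replicate), ]
}

#' Simulate plate-reader growth curves
#'
#' Logistic growth with specified low-density (exponential-phase) rate per
#' strain, emulating an automated plate reader taking OD600 readings on a
#' fixed time grid. Multiplicative log-normal measurement noise is applied.
#' An infinite carrying capacity gives pure exponential growth.
#'
#' @param rates named numeric vector of low-density growth rates (/hour),
#'   one per strain; rates must be >= 0.
#' @param od0 inoculation OD (> 0).
#' @param t_grid time grid in hours (nonempty, increasing).
#' @param noise_sd sd of the multiplicative (log-scale) measurement noise.
#' @param carrying_capacity logistic carrying capacity (> od0; may be Inf).
#' @param seed integer seed.
#' @return data.frame with columns strain, time_h, od.
#' @examples
#' simulate_growth_curves(c(wt = 0.4), t_grid = seq(0, 24, by = 1), noise_sd = 0)
#' @export
simulate_growth_curves <- function(rates, od0 = 0.1,
                                   t_grid = seq(0, 24, by = 1 / 6),
                                   noise_sd = 0, carrying_capacity = 1.5,
                                   seed = 1L) {
  if (length(t_grid) == 0) stop("invalid input: empty time grid")
  if (is.null(names(rates)) || any(!nzchar(names(rates))))
    stop("invalid input: rates must be a named vector (strain -> rate)")
  if (any(rates < 0)) stop("invalid input: rates must be >= 0")
  if (od0 <= 0 || carrying_capacity <= od0)
    stop("invalid input: need 0 < od0 < carrying_capacity")
  logistic_od <- function(r, t) {
    if (!is.finite(carrying_capacity)) return(od0 * exp(r * t))
    K <- carrying_capacity
    K * od0 * exp(r * t) / (K + od0 * (exp(r * t) - 1))
  }
  out <- do.call(rbind, lapply(names(rates), function(s) {
    data.frame(strain = s, time_h = t_grid, od = logistic_od(rates[[s]], t_grid))
  }))
  withr::with_seed(seed, {
    if (noise_sd > 0)
      out$od <- out$od * exp(rnorm(nrow(out), 0, noise_sd))
  })
  rownames(out) <- NULL
  out
}

#' Simulate chromatin-mark annotation sets
#'
#' Builds one gene set per mark by Bernoulli membership over the simulated
#' gene universe. Genes whose archetype grades up under the titration
#' (CA_UP, and the up-graded FN/OPP flavours) have their membership
#' probability reduced by \code{depletion_strength} relative to the
#' background rate, so an engineered depletion of the marks in the graded-up
#' class is recoverable by the enrichment module.
#'
#' @param truth ground-truth gene table (columns gene_id, archetype,
#'   direction), e.g. from \code{\link{simulate_expression}}.
#' @param marks character vector of set (mark) names; defaults to the five
#'   acetylation marks the analysis is designed around.
#' @param background_rate baseline membership probability.
#' @param depletion_strength in [0, 1]; 0 = null construction, 1 = graded-up
#'   genes never carry the mark.
#' @param seed integer seed.
#' @return an \code{\link{annotation_collection}}.
#' @export
simulate_annotations <- function(truth,
                                 marks = c("H2BK11ac", "H2BK16ac", "H3K18ac",
                                           "H3K14ac", "H3K23ac"),
                                 background_rate = 0.3,
                                 depletion_strength = 0, seed = 1L) {
  if (length(marks) == 0) stop("invalid input: marks must be nonempty")
  if (anyDuplicated(marks)) stop("invalid input: mark names must be unique")
  if (depletion_strength < 0 || depletion_strength > 1)
    stop("invalid input: depletion_strength must be in [0, 1]")
  if (background_rate <= 0 || background_rate >= 1)
    stop("invalid input: background_rate must be in (0, 1)")
  graded_up <- truth$archetype == "CA_UP" |
    (truth$archetype %in% c("FN", "OPP") & truth$direction > 0)
  p <- ifelse(graded_up, background_rate * (1 - depletion_strength),
              background_rate)
  sets <- withr::with_seed(seed, {
    setNames(lapply(marks, function(m) {
      truth$gene_id[rbinom(nrow(truth), 1, p) == 1]
    }), marks)
  })
  annotation_collection(sets, truth$gene_id)
}

#' Synthetic reconstruction of the synthetic-lethal growth study
#'
#' Generates growth curves for the 22 knockout strains of the published
#' synthetic-lethal panel, each combined with the dominant mutant at a grid
#' of promoter strengths plus a no-mutant control (PS = 0). The per-strain
#' growth-rate reductions are synthetic: the supplementary per-strain rates
#' are not distributed with the package, so reduction magnitudes are
#' constructed to be consistent with the published qualitative categories
#' (three highly impacted knockouts exceeding a 20\% reduction at high mutant
#' expression, fifteen moderately impacted, four unaffected). Reductions
#' increase with PS along a saturating (Hill-type) profile.
#'
#' @param seed integer seed.
#' @param ps_grid mutant promoter strengths.
#' @param control_rate growth rate (/h) of each knockout without the mutant.
#' @param noise_sd multiplicative OD noise sd.
#' @param n_replicates biological replicates per strain.
#' @return list with \code{curves} (long data.frame: gene, ps, strain,
#'   replicate, time_h, od), \code{expected} (data.frame gene, label) and
#'   \code{reductions} (the constructed reduction at the highest PS).
#' @export
synthetic_lethal_reference <- function(seed = 1L,
                                       ps_grid = c(0.07, 0.16, 0.32, 0.68, 0.95),
                                       control_rate = 0.4, noise_sd = 0.01,
                                       n_replicates = 3) {
  # category magnitudes kept clear of the decision boundaries (0.05 / 0.20)
  # by more than the rate-estimation noise, so labels reflect construction
  high <- c(ccr4 = 0.25, rtt109 = 0.40, rsc2 = 0.28)
  moderate <- setNames(
    seq(0.09, 0.19, length.out = 15),
    c("eaf7", "hhf2", "hht2", "hsl1", "hsl7", "leu2", "mot2", "nam2",
      "not5", "paa1", "pap2", "rad6", "rpd3", "sin3", "snf2"))
  none <- c(elp3 = 0.00, iki3 = 0.01, pho23 = 0.02, spt20 = 0.025)
  max_red <- c(high, moderate, none)

  k_red <- 0.4  # PS midpoint of the reduction profile
  shape <- function(ps) (1 - residual_activity(ps, k_red)) /
    (1 - residual_activity(max(ps_grid), k_red))
  grid <- c(0, ps_grid)
  curves <- do.call(rbind, lapply(names(max_red), function(g) {
    rates <- setNames(control_rate * (1 - max_red[[g]] * shape(grid)),
                      sprintf("%s@%s", g, grid))
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      cc <- simulate_growth_curves(
        rates, noise_sd = noise_sd,
        seed = (seed + 100 * match(g, names(max_red)) + r) %% .Machine$integer.max)
      cc$replicate <- r
      cc$gene <- g
      cc$ps <- as.numeric(sub(".*@", "", cc$strain))
      cc
    }))
  }))
  expected <- data.frame(
    gene = names(max_red),
    label = rep(c("HIGH", "MODERATE", "NONE"),
                c(length(high), length(moderate), length(none))))
  list(curves = curves, expected = expected, reductions = max_red)
}
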