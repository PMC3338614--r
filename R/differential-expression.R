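# Inverse of the trigamma function by Newton iteration on 1/x (the standard
# approach for empirical-Bayes prior-df estimation).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# Method-of-moments fit of a scaled F / scaled inverse-chisq prior to the
# per-gene sample variances s2 (residual df d): returns prior df d0 and
# prior scale s0^2. Zero or non-finite variances are excluded from the
# moment estimation.
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s0sq = if (any(ok)) mean(s2[ok]) else 1))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(emean)
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Differential expression between two sample groups
#'
#' Per-gene log2 fold change (group b minus group a) with a moderated t
#' statistic: per-gene variances are shrunk towards a pooled prior estimated
#' by method of moments from the distribution of log sample variances
#' (empirical Bayes), and the t distribution gains the prior degrees of
#' freedom. Significance uses the raw p-value and fold-change thresholds the
#' analysis is defined with (p < p_max and |log2FC| > lfc_min); BH-adjusted
#' p-values are emitted for information only.
#'
#' @param dataset an \code{\link{expression_dataset}}.
#' @param group_a,group_b either a condition name ("CONTROL", "KNOCKOUT",
#'   "MUTANT") or a character vector of sample ids; each group needs >= 2
#'   replicates. Defaults contrast wild-type control vs knockout.
#' @param ps_a,ps_b optional promoter strength restricting a "MUTANT" group
#'   to one level.
#' @param p_max,lfc_min significance thresholds.
#' @param method "moderated" (default) or "welch" (plain Welch t, mainly for
#'   cross-checks).
#' @return data.frame with columns gene_id, log2fc, t, df, p, p_adj,
#'   significant.
#' @export
differential_expression <- function(dataset, group_a = "CONTROL",
                                    group_b = "KNOCKOUT",
                                    ps_a = NULL, ps_b = NULL,
                                    p_max = 0.05, lfc_min = 1,
                                    method = c("moderated", "welch")) {
  method <- match.arg(method)
  resolve <- function(g, ps) {
    if (length(g) == 1 && g %in% c("CONTROL", "KNOCKOUT", "MUTANT"))
      return(condition_samples(dataset, g, ps))
    missing <- setdiff(g, dataset$design$sample_id)
    if (length(missing))
      stop("unknown sample id(s): ", paste(missing, collapse = ", "))
    g
  }
  ids_a <- resolve(group_a, ps_a)
  ids_b <- resolve(group_b, ps_b)
  if (length(ids_a) < 2 || length(ids_b) < 2)
    stop("each group needs at least 2 replicate samples")

  a <- dataset$expr[, ids_a, drop = FALSE]
  b <- dataset$expr[, ids_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  lfc <- rowMeans(b) - rowMeans(a)
  va <- apply(a, 1, var)
  vb <- apply(b, 1, var)

  if (method == "moderated") {
    d <- na + nb - 2
    s2 <- ((na - 1) * va + (nb - 1) * vb) / d
    prior <- fit_variance_prior(s2, d)
    s2_post <- if (is.finite(prior$d0))
      (prior$d0 * prior$s0sq + d * s2) / (prior$d0 + d)
    else rep(prior$s0sq, length(s2))
    se <- sqrt(s2_post * (1 / na + 1 / nb))
    df <- d + min(prior$d0, 1e6)
    tt <- lfc / se
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    tt <- lfc / se
  }
  # degenerate zero-variance genes: decide by the mean difference alone
  zero <- !is.finite(tt)
  tt[zero] <- ifelse(lfc[zero] == 0, 0, sign(lfc[zero]) * Inf)
  p <- 2 * pt(-abs(tt), df = df)
  p[zero & lfc != 0] <- 0
  p[zero & lfc == 0] <- 1

  out <- data.frame(gene_id = rownames(dataset$expr), log2fc = lfc,
                    t = tt, df = if (length(df) == 1) rep(df, length(tt)) else df,
                    p = p, p_adj = p.adjust(p, "BH"),
                    significant = p < p_max & abs(lfc) > lfc_min,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(p_max = p_max, lfc_min = lfc_min)
  attr(out, "prior") <- if (method == "moderated")
    c(d0 = prior$d0, s0sq = prior$s0sq) else NULL
  out
}
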