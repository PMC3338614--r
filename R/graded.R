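#' Detect monotonically graded genes across the titration
#'
#' A gene is called graded when its expression changes monotonically with
#' increasing dominant-mutant promoter strength. The wild-type control enters
#' the ordered series as PS = 0; the knockout is excluded (it is a separate
#' comparator used only for classification). The call requires both
#' \enumerate{
#'   \item a Jonckheere-Terpstra ordered-trend p-value below \code{p_max}
#'     (two-sided: either direction), and
#'   \item per-level mean log2 expression monotone in the trend direction up
#'     to a tie tolerance.
#' }
#' The tie tolerance is noise-aware: \code{max(tie_tol, tie_tol_se_mult *
#' SE)}, where SE is the standard error of a difference of two level means
#' estimated from the pooled within-level replicate variance. With noise-free
#' data it reduces to the fixed \code{tie_tol} band.
#'
#' @param dataset an \code{\link{expression_dataset}} with a CONTROL
#'   condition and at least 3 mutant PS levels, each replicated.
#' @param p_max trend significance threshold.
#' @param tie_tol minimum tie tolerance in log2 units.
#' @param tie_tol_se_mult multiplier on the level-mean-difference SE.
#' @param exact passed to \code{\link{jt_test}}.
#' @return data.frame with columns gene_id, is_graded, direction ("UP" /
#'   "DOWN"), jt_stat, trend_p, and one \code{mean_ps_<level>} column per
#'   ordered level (control = 0). The numeric PS levels are stored in
#'   \code{attr(, "ps_levels")}.
#' @export
detect_graded <- function(dataset, p_max = 0.05, tie_tol = 0.1,
                          tie_tol_se_mult = 2, exact = NULL) {
  design <- dataset$design
  ps_levels <- sort(unique(design$ps[design$condition == "MUTANT"]))
  if (length(ps_levels) < 3)
    stop("need at least 3 mutant PS levels for graded detection")
  ctrl <- condition_samples(dataset, "CONTROL")
  if (length(ctrl) < 2) stop("need replicated CONTROL samples")
  groups <- c(list(ctrl),
              lapply(ps_levels, function(p) condition_samples(dataset, "MUTANT", p)))
  if (any(lengths(groups) < 2)) stop("every level needs >= 2 replicates")
  levels_ps <- c(0, ps_levels)

  sample_idx <- lapply(groups, function(ids) match(ids, colnames(dataset$expr)))
  g_lab <- rep(seq_along(groups), lengths(groups))
  all_idx <- unlist(sample_idx)

  n_lev <- length(groups)
  genes <- rownames(dataset$expr)
  res <- data.frame(gene_id = genes, is_graded = FALSE,
                    direction = NA_character_, jt_stat = NA_real_,
                    trend_p = NA_real_, stringsAsFactors = FALSE)
  means <- matrix(NA_real_, length(genes), n_lev,
                  dimnames = list(genes, sprintf("mean_ps_%g", levels_ps)))

  for (g in seq_along(genes)) {
    x <- dataset$expr[g, all_idx]
    jt <- jt_test(x, g_lab, alternative = "two.sided", exact = exact)
    m <- tapply(x, g_lab, mean)
    means[g, ] <- m
    dir_up <- jt$z > 0
    # pooled within-level variance -> SE of a difference of level means
    wvar <- sum(tapply(x, g_lab, function(v) sum((v - mean(v))^2))) /
      (length(x) - n_lev)
    nmin <- min(lengths(groups))
    se_diff <- sqrt(2 * wvar / nmin)
    tol <- max(tie_tol, tie_tol_se_mult * se_diff)
    dm <- diff(m)
    monotone <- if (dir_up) all(dm >= -tol) else all(dm <= tol)
    res$jt_stat[g] <- jt$statistic
    res$trend_p[g] <- jt$p.value
    res$direction[g] <- if (dir_up) "UP" else "DOWN"
    res$is_graded[g] <- jt$p.value < p_max && monotone
  }
  out <- cbind(res, as.data.frame(means))
  rownames(out) <- NULL
  attr(out, "ps_levels") <- levels_ps
  attr(out, "p_max") <- p_max
  out
}

# Extract the per-level mean matrix and PS levels from a detect_graded table.
graded_level_means <- function(graded) {
  cols <- grep("^mean_ps_", names(graded), value = TRUE)
  if (!length(cols)) stop("input lacks the per-level mean columns of detect_graded()")
  ps <- attr(graded, "ps_levels")
  if (is.null(ps)) ps <- as.numeric(sub("^mean_ps_", "", cols))
  list(means = as.matrix(graded[, cols, drop = FALSE]), ps = ps)
}

#' Estimate per-gene grading thresholds
#'
#' The grading threshold of a graded gene is the promoter strength at which
#' its response reaches half of its plateau: the midpoint of a Hill fit of
#' mean log2 expression versus PS (reusing the competitive-inhibition model
#' with expression as the signal; up-graded genes are fit on the negated
#' scale so the model's decreasing form applies).
#'
#' Maximal gradation is a plateaued response matching the knockout
#' condition, so when knockout means are supplied via \code{ko_level} and
#' the knockout response is consistent with the titration trend (same
#' direction, at least half the largest in-range response), the plateau of
#' the fit is anchored at the knockout level. This pins down thresholds near
#' or beyond the strongest sampled PS, where an unanchored saturation fit is
#' poorly identified. Genes whose knockout disagrees with the trend
#' (compensated or opposite responders) are fit unanchored. When the fit
#' does not converge, the fallback is the smallest PS whose mean response
#' reaches at least \code{plateau_fraction} of the reference response.
#'
#' @param graded rows of a \code{\link{detect_graded}} table; every row must
#'   be a graded call (\code{is_graded} TRUE), otherwise a state error is
#'   raised.
#' @param ko_level optional named numeric vector (gene id -> knockout mean
#'   log2 expression), the plateau reference.
#' @param plateau_fraction fraction of the plateau defining "maximal
#'   gradation" in the fallback rule.
#' @return data.frame with columns gene_id, threshold_ps, method
#'   ("fit_anchored", "fit" or "plateau").
#' @export
estimate_grading_threshold <- function(graded, ko_level = NULL,
                                       plateau_fraction = 0.9) {
  if (!all(graded$is_graded))
    stop("grading thresholds are defined only for graded genes")
  lm_ <- graded_level_means(graded)
  ps <- lm_$ps
  out <- data.frame(gene_id = graded$gene_id, threshold_ps = NA_real_,
                    method = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(graded))) {
    y <- lm_$means[i, ]
    up <- graded$direction[i] == "UP"
    sgn <- if (up) 1 else -1
    max_resp <- max(sgn * (y - y[1]))
    ko <- if (!is.null(ko_level) && graded$gene_id[i] %in% names(ko_level))
      ko_level[[graded$gene_id[i]]] else NULL
    anchor <- !is.null(ko) && sgn * (ko - y[1]) >= 0.5 * max_resp
    fit <- tryCatch(
      fit_hill(ps, sgn * -y,
               fix_bottom = if (anchor) sgn * -ko else NULL),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      out$threshold_ps[i] <- fit$ic50
      out$method[i] <- if (anchor) "fit_anchored" else "fit"
    } else {
      ref <- if (!is.null(ko) && anchor) sgn * (ko - y[1]) else max_resp
      resp <- sgn * (y - y[1])
      hit <- which(ps > 0 & resp >= plateau_fraction * ref)
      out$threshold_ps[i] <- if (length(hit)) ps[min(hit)] else max(ps)
      out$method[i] <- "plateau"
    }
  }
  out
}

#' Classify genes from the paired knockout / titration design
#'
#' Combines the knockout differential-expression calls with the graded-trend
#' calls into the four (non-mutually exclusive) gene classes:
#' \describe{
#'   \item{CA_U / CA_D}{catalytically associated: graded, up or down.}
#'   \item{NCA}{non-catalytically associated: significant in the knockout but
#'     not graded.}
#'   \item{FN}{false negative: graded but not significant in the knockout
#'     (compensated in the null strain).}
#'   \item{OPP}{opposite: graded and knockout-significant in the opposing
#'     direction.}
#'   \item{UNCAT}{significant at some mutant level vs control but in none of
#'     the classes above (only assessed when \code{de_mutant} is given).}
#' }
#'
#' @param de_ko \code{\link{differential_expression}} table for control vs
#'   knockout.
#' @param graded \code{\link{detect_graded}} table over the same genes.
#' @param de_mutant optional list of differential-expression tables, one per
#'   mutant level vs control, enabling the UNCAT flag.
#' @param thresholds optional \code{\link{estimate_grading_threshold}} table;
#'   its \code{threshold_ps} is merged into the output.
#' @return data.frame of class \code{gene_classification} with logical flag
#'   columns ca_u, ca_d, nca, fn, opp, uncat, a semicolon-joined
#'   \code{classes} column and \code{threshold_ps}.
#' @export
classify_genes <- function(de_ko, graded, de_mutant = NULL, thresholds = NULL) {
  if (!identical(sort(de_ko$gene_id), sort(graded$gene_id)))
    stop("de_ko and graded must cover the same gene universe")
  g <- graded[match(de_ko$gene_id, graded$gene_id), ]
  ko_sig <- de_ko$significant
  ko_up <- ko_sig & de_ko$log2fc > 0
  is_graded <- g$is_graded
  up <- is_graded & g$direction == "UP"
  down <- is_graded & g$direction == "DOWN"

  opp <- is_graded & ko_sig & ((up & !ko_up) | (down & ko_up))
  fn <- is_graded & !ko_sig
  nca <- ko_sig & !is_graded
  uncat <- rep(FALSE, nrow(de_ko))
  if (!is.null(de_mutant)) {
    mut_sig <- Reduce(`|`, lapply(de_mutant, function(d)
      d$significant[match(de_ko$gene_id, d$gene_id)]))
    uncat <- mut_sig & !is_graded & !ko_sig
  }

  out <- data.frame(gene_id = de_ko$gene_id, ca_u = up, ca_d = down,
                    nca = nca, fn = fn, opp = opp, uncat = uncat,
                    threshold_ps = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(thresholds)) {
    idx <- match(out$gene_id, thresholds$gene_id)
    out$threshold_ps <- thresholds$threshold_ps[idx]
  }
  flags <- c(ca_u = "CA_U", ca_d = "CA_D", nca = "NCA", fn = "FN",
             opp = "OPP", uncat = "UNCAT")
  out$classes <- apply(out[, names(flags)], 1, function(r)
    paste(flags[as.logical(r)], collapse = ";"))
  class(out) <- c("gene_classification", class(out))
  out
}

#' Class membership counts
#'
#' @param classification a \code{\link{classify_genes}} table.
#' @return named integer vector of per-class counts (classes overlap, so
#'   counts need not sum to the gene total).
#' @export
class_counts <- function(classification) {
  flags <- c("ca_u", "ca_d", "nca", "fn", "opp", "uncat")
  counts <- vapply(flags, function(f) sum(classification[[f]]), integer(1))
  c(counts, graded = sum(classification$ca_u | classification$ca_d))
}

# Map overlapping class flags to a single best archetype prediction,
# mirroring the generative archetypes (used for recovery studies).
predicted_archetype <- function(classification) {
  ifelse(classification$fn, "FN",
  ifelse(classification$opp, "OPP",
  ifelse(classification$ca_u, "CA_UP",
  ifelse(classification$ca_d, "CA_DOWN",
  ifelse(classification$nca, "NCA", "NULL")))))
}

#' Venn summary of knockout vs graded-titration gene sets
#'
#' Exact set arithmetic over the significance and direction flags: how many
#' up- (down-) regulated genes the knockout and the graded dominant mutant
#' identify in common, how many each identifies alone, the total overlap and
#' the fraction of graded genes that grade up.
#'
#' @param de_ko knockout differential-expression table.
#' @param graded graded-call table over the same genes.
#' @return object of class \code{venn_summary} (a named list of counts; see
#'   \code{\link{venn_from_counts}} for the fields).
#' @export
venn_summary <- function(de_ko, graded) {
  g <- graded[match(de_ko$gene_id, graded$gene_id), ]
  graded_up <- g$is_graded & g$direction == "UP"
  graded_down <- g$is_graded & g$direction == "DOWN"
  ko_up <- de_ko$significant & de_ko$log2fc > 0
  ko_down <- de_ko$significant & de_ko$log2fc < 0
  venn_from_counts(
    common_up = sum(graded_up & ko_up),
    mutant_only_up = sum(graded_up & !ko_up),
    common_down = sum(graded_down & ko_down),
    mutant_only_down = sum(graded_down & !ko_down),
    graded_total = sum(g$is_graded),
    ko_total = sum(de_ko$significant))
}

#' Venn summary from printed counts
#'
#' The same arithmetic as \code{\link{venn_summary}} applied to externally
#' reported counts (e.g. figure captions): overlap = common up + common down,
#' knockout-only = knockout total - overlap, graded-up percentage =
#' 100 x (common up + mutant-only up) / graded total.
#'
#' @param common_up,mutant_only_up,common_down,mutant_only_down direction-
#'   resolved set counts.
#' @param graded_total total graded genes; defaults to the sum of the four
#'   counts above.
#' @param ko_total total knockout-significant genes (optional).
#' @return object of class \code{venn_summary}: list with the input counts
#'   plus \code{overlap}, \code{ko_only}, \code{graded_up},
#'   \code{graded_up_pct} (NA with a flag when the graded set is empty).
#' @examples
#' venn_from_counts(84, 107, 69, 28, graded_total = 288, ko_total = 282)
#' @export
venn_from_counts <- function(common_up, mutant_only_up, common_down,
                             mutant_only_down, graded_total = NULL,
                             ko_total = NULL) {
  if (is.null(graded_total))
    graded_total <- common_up + mutant_only_up + common_down + mutant_only_down
  overlap <- common_up + common_down
  graded_up <- common_up + mutant_only_up
  structure(list(
    common_up = common_up, mutant_only_up = mutant_only_up,
    common_down = common_down, mutant_only_down = mutant_only_down,
    graded_total = graded_total, ko_total = ko_total,
    overlap = overlap,
    ko_only = if (!is.null(ko_total)) ko_total - overlap else NA_integer_,
    graded_up = graded_up,
    graded_up_pct = if (graded_total > 0)
      round(100 * graded_up / graded_total) else NA_real_,
    empty_graded = graded_total == 0
  ), class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("venn_summary:\n")
  cat(sprintf("  up:   common %d, mutant-only %d\n", x$common_up, x$mutant_only_up))
  cat(sprintf("  down: common %d, mutant-only %d\n", x$common_down, x$mutant_only_down))
  cat(sprintf("  overlap %d of %d graded / %s knockout (knockout-only %s)\n",
              x$overlap, x$graded_total,
              if (is.null(x$ko_total)) "?" else x$ko_total,
              if (is.na(x$ko_only)) "?" else x$ko_only))
  if (!is.na(x$graded_up_pct))
    cat(sprintf("  graded up: %d (%d%%)\n", x$graded_up, x$graded_up_pct))
  invisible(x)
}

#' Class fraction at printed precision
#'
#' Percentage of a class count over a total, rounded to a chosen number of
#' decimal digits (reported fractions are typically printed at 0 or 1
#' decimal).
#'
#' @param k class count.
#' @param n total.
#' @param digits decimal digits of the percentage.
#' @return the percentage as a number.
#' @examples
#' class_fraction(36, 288, digits = 1)  # 12.5
#' class_fraction(44, 288)              # 15
#' @export
class_fraction <- function(k, n, digits = 0) {
  if (n <= 0) stop("total must be positive")
  round(100 * k / n, digits)
}
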