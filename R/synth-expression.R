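#' Residual catalytic activity under competitive inhibition
#'
#' \eqn{A(PS) = 1 / (1 + (PS/K)^h)}: the fraction of wild-type catalytic
#' activity remaining when the dominant mutant is expressed at relative
#' promoter strength PS, for a gene (or reporter) with grading midpoint K and
#' Hill slope h. \eqn{A(0) = 1} (no inhibition), \eqn{A(K) = 1/2}.
#'
#' @param ps promoter strength(s), >= 0.
#' @param k grading midpoint (> 0).
#' @param h Hill slope (> 0).
#' @return numeric vector of activities in (0, 1].
#' @export
residual_activity <- function(ps, k, h = 1) {
  stopifnot(all(ps >= 0), k > 0, h > 0)
  1 / (1 + (ps / k)^h)
}

# Mean log2 expression of one gene under one condition.
# condition: "CONTROL", "KNOCKOUT" or "MUTANT" (then ps is used).
archetype_mean <- function(archetype, direction, k_g, h, condition, ps,
                           baseline, effect) {
  response <- function(p) effect * (1 - residual_activity(p, k_g, h))
  switch(archetype,
    CA_UP = switch(condition,
      CONTROL = baseline,
      KNOCKOUT = baseline + effect,
      MUTANT = baseline + response(ps)),
    CA_DOWN = switch(condition,
      CONTROL = baseline,
      KNOCKOUT = baseline - effect,
      MUTANT = baseline - response(ps)),
    FN = switch(condition,
      CONTROL = baseline,
      KNOCKOUT = baseline,
      MUTANT = baseline + direction * response(ps)),
    OPP = switch(condition,
      CONTROL = baseline,
      KNOCKOUT = baseline - direction * effect,
      MUTANT = baseline + direction * response(ps)),
    NCA = switch(condition,
      CONTROL = baseline,
      KNOCKOUT = baseline + direction * effect,
      MUTANT = baseline),
    "NULL" = baseline,
    stop("unknown archetype: ", archetype)
  )
}

#' Construct an expression dataset
#'
#' Bundles a genes x samples log2 expression matrix with its sample design
#' (and, for synthetic data, the ground-truth gene table). Every sample in
#' the matrix must appear exactly once in the design; all values must be
#' finite.
#'
#' @param expr numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param design data.frame with columns \code{sample_id}, \code{condition}
#'   (one of CONTROL, KNOCKOUT, MUTANT) and \code{ps} (numeric promoter
#'   strength; NA for CONTROL/KNOCKOUT).
#' @param truth optional data.frame with columns \code{gene_id},
#'   \code{archetype}, \code{k_g}, \code{direction}.
#' @return an object of class \code{expression_dataset}.
#' @export
expression_dataset <- function(expr, design, truth = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (!all(is.finite(expr)))
    stop("expression values must all be finite")
  need <- c("sample_id", "condition", "ps")
  if (!all(need %in% names(design)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  if (!setequal(colnames(expr), design$sample_id) ||
      anyDuplicated(design$sample_id) || anyDuplicated(colnames(expr)))
    stop("every sample id in the matrix must appear exactly once in the design")
  bad <- setdiff(unique(design$condition), c("CONTROL", "KNOCKOUT", "MUTANT"))
  if (length(bad))
    stop("unknown condition(s) in design: ", paste(bad, collapse = ", "))
  if (any(design$condition == "MUTANT" & !is.finite(design$ps)))
    stop("MUTANT samples need a finite ps in the design")
  design <- design[match(colnames(expr), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(expr = expr, design = design, truth = truth),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$design$condition)
  cat("expression_dataset:", nrow(x$expr), "genes x", ncol(x$expr), "samples\n")
  cat("  conditions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  mut <- sort(unique(x$design$ps[x$design$condition == "MUTANT"]))
  if (length(mut)) cat("  mutant PS levels:", paste(mut, collapse = ", "), "\n")
  if (!is.null(x$truth)) cat("  ground truth attached (", nrow(x$truth), " genes)\n", sep = "")
  invisible(x)
}

#' Sample ids for a condition
#'
#' @param dataset an \code{expression_dataset}.
#' @param condition "CONTROL", "KNOCKOUT" or "MUTANT".
#' @param ps for MUTANT, restrict to one promoter-strength level.
#' @return character vector of sample ids.
#' @export
condition_samples <- function(dataset, condition, ps = NULL) {
  d <- dataset$design
  keep <- d$condition == condition
  if (!is.null(ps)) keep <- keep & !is.na(d$ps) & abs(d$ps - ps) < 1e-9
  d$sample_id[keep]
}

#' Simulate a graded dominant-mutant expression study
#'
#' Generates a log2 expression matrix for the configured gene archetypes
#' under a design of CONTROL, KNOCKOUT and one MUTANT condition per promoter
#' strength in \code{config$ps_grid}, each with \code{config$n_replicates}
#' biological replicates. Per-gene grading midpoints K_g are drawn uniformly
#' from \code{config$k_range}; independent Gaussian noise of sd
#' \code{config$noise_sd} is added per measurement on the log2 scale.
#' Deterministic given the config (which includes the seed).
#'
#' @param config a \code{\link{synth_config}}.
#' @return an \code{\link{expression_dataset}} with ground truth attached.
#' @examples
#' ds <- simulate_expression(synth_config(n_ca_up = 3, n_null = 3, noise_sd = 0))
#' @export
simulate_expression <- function(config) {
  validate_synth_config(config)
  counts <- c(CA_UP = config$n_ca_up, CA_DOWN = config$n_ca_down,
              NCA = config$n_nca, FN = config$n_fn, OPP = config$n_opp,
              "NULL" = config$n_null)
  n_genes <- sum(counts)
  if (n_genes == 0) stop("invalid synth_config: no genes requested")
  archetype <- rep(names(counts), counts)
  gene_id <- sprintf("g%04d", seq_len(n_genes))

  reps <- seq_len(config$n_replicates)
  design <- rbind(
    data.frame(sample_id = sprintf("ctrl_r%d", reps),
               condition = "CONTROL", ps = NA_real_),
    data.frame(sample_id = sprintf("ko_r%d", reps),
               condition = "KNOCKOUT", ps = NA_real_),
    do.call(rbind, lapply(config$ps_grid, function(p)
      data.frame(sample_id = sprintf("mut%.2f_r%d", p, reps),
                 condition = "MUTANT", ps = p)))
  )

  withr::with_seed(config$seed, {
    k_g <- ifelse(archetype %in% c("CA_UP", "CA_DOWN", "FN", "OPP"),
                  runif(n_genes, config$k_range[1], config$k_range[2]),
                  NA_real_)
    # CA direction is fixed by the archetype; NCA shifts either way in the
    # knockout; FN and OPP default to the up-graded flavour, the dominant
    # pattern reported for those classes.
    direction <- ifelse(archetype == "CA_DOWN", -1L, 1L)
    direction[archetype == "NCA"] <- sample(c(-1L, 1L), sum(archetype == "NCA"),
                                            replace = TRUE)
    direction[archetype == "NULL"] <- 0L

    mu <- matrix(NA_real_, n_genes, nrow(design),
                 dimnames = list(gene_id, design$sample_id))
    for (g in seq_len(n_genes)) {
      mu[g, ] <- vapply(seq_len(nrow(design)), function(s) {
        archetype_mean(archetype[g], direction[g], k_g[g], config$hill_slope,
                       design$condition[s], design$ps[s],
                       config$baseline_log2, config$effect_log2)
      }, numeric(1))
    }
    expr <- mu
    if (config$noise_sd > 0)
      expr <- mu + matrix(rnorm(length(mu), 0, config$noise_sd), nrow(mu))
  })

  truth <- data.frame(gene_id = gene_id, archetype = archetype,
                      k_g = k_g, direction = direction,
                      stringsAsFactors = FALSE)
  expression_dataset(expr, design, truth)
}

#' Write / read an expression dataset as TSV
#'
#' The matrix file has a first column \code{gene_id} and one column per
#' sample; the design file has columns \code{sample_id}, \code{condition},
#' \code{ps} (empty for CONTROL/KNOCKOUT). Lines starting with '#' are
#' treated as comments.
#'
#' @param dataset an \code{expression_dataset}.
#' @param matrix_path,design_path,truth_path output/input file paths
#'   (\code{truth_path} optional).
#' @param meta optional named list written as a header comment (see
#'   \code{\link{write_table_commented}}).
#' @return \code{read_expression_dataset} returns an
#'   \code{expression_dataset}; the writer returns its paths invisibly.
#' @export
write_expression_dataset <- function(dataset, matrix_path, design_path,
                                     truth_path = NULL, meta = NULL) {
  mat <- data.frame(gene_id = rownames(dataset$expr), dataset$expr,
                    check.names = FALSE)
  write_table_commented(mat, matrix_path, meta)
  write_table_commented(dataset$design, design_path, meta)
  if (!is.null(truth_path)) {
    if (is.null(dataset$truth)) stop("dataset has no truth table to write")
    write_table_commented(dataset$truth, truth_path, meta)
  }
  invisible(c(matrix_path, design_path, truth_path))
}

#' @rdname write_expression_dataset
#' @export
read_expression_dataset <- function(matrix_path, design_path,
                                    truth_path = NULL) {
  mat <- read.delim(matrix_path, comment.char = "#", check.names = FALSE)
  if (names(mat)[1] != "gene_id")
    stop("malformed matrix file '", matrix_path, "': first column must be gene_id")
  expr <- as.matrix(mat[, -1, drop = FALSE])
  rownames(expr) <- mat$gene_id
  design <- read.delim(design_path, comment.char = "#")
  design$ps <- suppressWarnings(as.numeric(design$ps))
  truth <- if (!is.null(truth_path))
    read.delim(truth_path, comment.char = "#") else NULL
  expression_dataset(expr, design, truth)
}
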