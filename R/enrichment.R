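#' Annotation collection
#'
#' Named gene sets (e.g. genes carrying a chromatin mark) over an explicit
#' gene universe. Every member must belong to the universe and set names must
#' be unique.
#'
#' @param sets named list of character vectors of gene ids.
#' @param universe character vector of all gene ids under consideration
#'   (typically the genes on the expression matrix).
#' @return object of class \code{annotation_collection}.
#' @export
annotation_collection <- function(sets, universe) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list")
  if (anyDuplicated(names(sets))) stop("set names must be unique")
  if (anyDuplicated(universe)) stop("universe contains duplicated gene ids")
  sets <- lapply(sets, unique)
  stray <- setdiff(unlist(sets), universe)
  if (length(stray))
    stop("set members outside the universe: ", paste(head(stray, 5), collapse = ", "))
  structure(list(sets = sets, universe = universe),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat("annotation_collection:", length(x$sets), "sets over",
      length(x$universe), "genes\n")
  sizes <- lengths(x$sets)
  cat(" ", paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Hypergeometric enrichment and depletion tails
#'
#' For an overlap of k genes between a class of size n and an annotation set
#' of size K in a universe of N genes, the enrichment p-value is
#' \eqn{P[X \ge k]} and the depletion p-value \eqn{P[X \le k]} for
#' \eqn{X \sim} Hypergeometric(N, K, n). Both tails include the observed
#' value, so they sum to at least 1.
#'
#' @param k overlap count(s).
#' @param n class size(s).
#' @param K set size(s).
#' @param N universe size(s).
#' @return data.frame with columns k, n, K, N, p_enrich, p_deplete.
#' @examples
#' hyper_test(0, 5, 5, 10)  # depletion p = 1/252
#' @export
hyper_test <- function(k, n, K, N) {
  ok <- k >= 0 & k <= pmin(n, K) & pmax(n, K) <= N &
    k >= n + K - N  # overlap cannot be smaller than forced by the sizes
  if (!all(ok)) stop("inconsistent counts: need max(0, n+K-N) <= k <= min(n, K) <= N")
  data.frame(k = k, n = n, K = K, N = N,
             p_enrich = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
             p_deplete = phyper(k, K, N - K, n))
}

#' Enrichment/depletion of annotation sets within gene classes
#'
#' One hypergeometric test per (gene class, annotation set) pair, with BH
#' adjustment across sets within each class and tail. The classes come from
#' the classification flags; when grading thresholds are present, a derived
#' "GRADED_UP_LOW" class (up-graded genes whose grading threshold is at or
#' below \code{low_threshold_cutoff}) is added — the subclass in which
#' depletion of the catalytic acetylation marks is expected to concentrate.
#'
#' @param classification a \code{\link{classify_genes}} table (or a named
#'   list of character vectors, one per class).
#' @param annotations an \code{\link{annotation_collection}}; its universe
#'   must contain every classified gene.
#' @param low_threshold_cutoff PS cutoff defining a "low" grading threshold
#'   (default: the lowest arrayed titration level).
#' @return data.frame with columns class, set, k, n, K, N, p_enrich,
#'   p_deplete, q_enrich, q_deplete.
#' @export
class_enrichment <- function(classification, annotations,
                             low_threshold_cutoff = 0.32) {
  if (!length(annotations$universe)) stop("empty gene universe")
  if (is.data.frame(classification)) {
    flags <- c(CA_U = "ca_u", CA_D = "ca_d", NCA = "nca", FN = "fn",
               OPP = "opp")
    classes <- lapply(flags, function(f)
      classification$gene_id[classification[[f]]])
    if ("threshold_ps" %in% names(classification)) {
      low <- classification$ca_u &
        !is.na(classification$threshold_ps) &
        classification$threshold_ps <= low_threshold_cutoff
      classes$GRADED_UP_LOW <- classification$gene_id[low]
    }
  } else {
    classes <- classification
  }
  N <- length(annotations$universe)
  out <- do.call(rbind, lapply(names(classes), function(cl) {
    members <- classes[[cl]]
    stray <- setdiff(members, annotations$universe)
    if (length(stray))
      stop("class ", cl, " has genes outside the universe: ",
           paste(head(stray, 5), collapse = ", "))
    res <- do.call(rbind, lapply(names(annotations$sets), function(s) {
      set <- annotations$sets[[s]]
      ht <- hyper_test(length(intersect(members, set)), length(members),
                       length(set), N)
      cbind(data.frame(class = cl, set = s), ht)
    }))
    res$q_enrich <- p.adjust(res$p_enrich, "BH")
    res$q_deplete <- p.adjust(res$p_deplete, "BH")
    res
  }))
  rownames(out) <- NULL
  out
}
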