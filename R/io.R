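#' Write a table with a reproducibility header
#'
#' Writes a TSV (or CSV) preceded by '#' comment lines recording the package
#' version plus any supplied metadata (typically the seed and a config hash),
#' so every output file documents the run that produced it.
#'
#' @param df data.frame to write.
#' @param path output path; a ".csv" extension switches to comma separation.
#' @param meta optional named list, written as \code{# name=value} pairs.
#' @return the path, invisibly.
#' @export
write_table_commented <- function(df, path, meta = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# gradedmut ", as.character(packageVersion("gradedmut"))), con)
  if (length(meta))
    writeLines(sprintf("# %s=%s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = ","),
                              character(1))), con)
  write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Stable fingerprint of a configuration object (md5 of its deparsed form).
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config), tf)
  unname(tools::md5sum(tf))
}

#' Read a replicated dose-response table
#'
#' Expects CSV columns \code{ps}, \code{signal} and optionally
#' \code{replicate}; '#' lines are comments.
#'
#' @param path CSV file path.
#' @return data.frame with columns ps, signal (and replicate if present).
#' @export
read_dose_response <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (!all(c("ps", "signal") %in% names(df)))
    stop("malformed dose-response file '", path, "': need columns ps, signal")
  df
}

#' Read long-format growth curves
#'
#' Expects CSV columns \code{strain}, \code{time_h}, \code{od} and optionally
#' \code{replicate} and \code{ps}; '#' lines are comments.
#'
#' @param path CSV file path.
#' @return data.frame of growth measurements.
#' @export
read_growth_curves <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (!all(c("strain", "time_h", "od") %in% names(df)))
    stop("malformed growth file '", path, "': need columns strain, time_h, od")
  df
}

#' Read / write GMT annotation files
#'
#' GMT is the standard gene-set exchange format: one set per line as
#' \code{name <TAB> description <TAB> gene1 <TAB> gene2 ...}.
#'
#' @param path GMT file path.
#' @param universe gene universe to attach to the collection; defaults to the
#'   union of all set members.
#' @return \code{read_gmt} returns an \code{\link{annotation_collection}}.
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  annotation_collection(sets, universe)
}

#' @rdname read_gmt
#' @param annotations an \code{annotation_collection}.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(annotations, path, descriptions = NULL) {
  sets <- annotations$sets
  if (is.null(descriptions)) descriptions <- rep("synthetic", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
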