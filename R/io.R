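#' Tabular formats
#'
#' Count tables are TSV with taxa as rows (first column `taxon_id`) and
#' samples as columns; metadata TSV has columns sample_id, community,
#' cycles, and optionally group. All writers use deterministic column order
#' and 10 significant digits so outputs diff cleanly.
#'
#' @name cli_io
#' @keywords internal
NULL

#' Read a taxa-by-sample count table
#'
#' @param path TSV path: first column taxon ids, header row of sample ids,
#'   integer cells.
#' @param pseudo_count Optional value added to every cell (0.5 when `TRUE`)
#'   so zero-laden tables yield strictly positive compositions; the returned
#'   matrix then carries attribute `pseudo_count`.
#' @return Numeric `D x N` matrix with dimnames; integer-valued unless a
#'   pseudo-count was applied.
#' @export
read_count_table <- function(path, pseudo_count = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs taxon ids plus >= 1 sample",
                          call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate taxon ids in ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids in ", path, call. = FALSE)
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != round(m)))
    stop("count table cells must be non-negative integers", call. = FALSE)
  rownames(m) <- ids
  if (any(colSums(m) == 0))
    stop("empty sample column(s): ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "), call. = FALSE)
  pc <- if (isTRUE(pseudo_count)) 0.5 else if (is.numeric(pseudo_count) &&
                                               pseudo_count > 0) pseudo_count
        else 0
  if (pc > 0) {
    m <- m + pc
    attr(m, "pseudo_count") <- pc
  }
  m
}

#' Write a count table
#'
#' @param counts `D x N` matrix with dimnames.
#' @param path Output TSV path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(taxon_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with columns sample_id, community, cycles, optional
#'   group.
#' @return Data frame with validated columns.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "community", "cycles")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  if (anyNA(df$cycles) || any(df$cycles < 0) || any(df$cycles != round(df$cycles)))
    stop("metadata cycles must be non-negative integers", call. = FALSE)
  df
}

#' Write sample metadata
#'
#' @param metadata Data frame with sample_id, community, cycles (+ group).
#' @param path Output TSV path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Record simulation ground truth as JSON
#'
#' @param truth A [simulation_truth()].
#' @param path Output JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(lambda = truth$lambda, sigma = truth$sigma,
         seed = truth$seed, depths = truth$depths),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read simulation ground truth
#'
#' @param path JSON written by [write_truth()].
#' @return A [simulation_truth()].
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  simulation_truth(x$lambda, x$sigma, x$seed, x$depths)
}

format_num <- function(x) formatC(x, format = "g", digits = 10)

#' Write a tidy bias-summary CSV
#'
#' One row per (community or pair, metric): cycles, posterior median and
#' 95% interval.
#'
#' @param results List of `bias_result` objects.
#' @param path Output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_bias_summary <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(community = paste(r$community, collapse = ":"),
               metric = r$metric, cycles = r$cycles,
               relative = r$relative,
               median = format_num(r$summary[["median"]]),
               lo95 = format_num(r$summary[["lo95"]]),
               hi95 = format_num(r$summary[["hi95"]]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write a bias surface as long-format CSV
#'
#' @param surface A `bias_surface`.
#' @param path Output CSV path.
#' @export
write_surface <- function(surface, path) {
  df <- surface_to_df(surface)
  df[] <- lapply(df, format_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a distance matrix as square CSV
#'
#' @param dm Symmetric matrix with sample-id dimnames.
#' @param path Output CSV path.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm),
                   apply(dm, 2, format_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
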