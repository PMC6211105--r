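#' Consolidated analysis report
#'
#' Gathers the outputs of the pipeline stages into one deterministic
#' structure suitable for JSON/TSV export: scalar densities, genome-size
#' estimates and their comparison, the population copy-number summary and
#' control validation, and pseudo-scaffold statistics. Only the pieces
#' supplied appear in the report; field order is fixed.
#'
#' @param densities A \code{\link{density_report}}.
#' @param genome_sizes Named list of \code{\link{genome_size}} estimates.
#' @param size_comparison A \code{\link{compare_groups}} result.
#' @param cn_summary A \code{\link{summarize_population}} data.frame.
#' @param controls A \code{\link{control_report}}.
#' @param scaffold_stats An \code{\link{annotate_pseudoscaffolds}}
#'   data.frame.
#' @return Object of class \code{bchrom_report} (a list).
#' @export
build_report <- function(densities = NULL, genome_sizes = NULL,
                         size_comparison = NULL, cn_summary = NULL,
                         controls = NULL, scaffold_stats = NULL) {
  out <- list()
  if (!is.null(densities)) out$densities <- unclass(densities)
  if (!is.null(genome_sizes))
    out$genome_sizes <- lapply(genome_sizes, unclass)
  if (!is.null(size_comparison))
    out$size_comparison <- unclass(size_comparison)
  if (!is.null(cn_summary)) out$cn_summary <- cn_summary
  if (!is.null(controls))
    out$controls <- list(cn_min = controls$cn_min,
                         cn_max = controls$cn_max,
                         pass = controls$pass,
                         n_values = nrow(controls$table),
                         n_failures = nrow(controls$failures))
  if (!is.null(scaffold_stats)) out$scaffold_stats <- scaffold_stats
  class(out) <- "bchrom_report"
  out
}

#' Write a consolidated report as JSON and flat TSV
#'
#' @param report A \code{\link{build_report}} result.
#' @param dir Output directory; writes \code{report.json} and
#'   \code{report.tsv}.
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  flat <- .flatten_report(unclass(report))
  utils::write.table(flat, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

.flatten_report <- function(x, prefix = "") {
  rows <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- x[[nm]]
    if (is.data.frame(v)) next  # tables live in the JSON form
    if (is.list(v)) {
      rows[[length(rows) + 1L]] <- .flatten_report(v, key)
    } else if (length(v) == 1L && is.atomic(v)) {
      rows[[length(rows) + 1L]] <- data.frame(
        key = key, value = as.character(v), stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(key = character(), value = character(),
               stringsAsFactors = FALSE)
}

#' @export
print.bchrom_report <- function(x, ...) {
  cat("bchrom_report with sections:", paste(names(x), collapse = ", "),
      "\n")
  invisible(x)
}
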