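#' Copy-number categories
#'
#' The discrete bands used to report window/fragment copy numbers, on the
#' diploid scale (2 = normal): absent below 0.1, homozygous deletion
#' [0.1, 1.5), heterozygous deletion [1.5, 2.6), normal diploid [2.6, 4],
#' heterozygous duplication (4, 6], multiple duplication above 6. The
#' printed one-decimal band edges (0.1-1.4 / 1.5-2.5 / 2.6-4 / >4) are
#' realized as these continuous half-open boundaries.
#'
#' @format Character vector of the six category labels, in increasing
#'   copy-number order.
#' @export
CN_CATEGORIES <- c("absent", "homozygous_deletion",
                   "heterozygous_deletion", "normal_diploid",
                   "heterozygous_duplication", "multiple_duplication")

#' Classify copy numbers into bands
#'
#' @param cn Numeric vector of non-negative copy numbers.
#' @return A factor with levels \code{\link{CN_CATEGORIES}}.
#' @export
#' @examples
#' classify_cn(c(0, 1, 2, 3, 5, 8))
classify_cn <- function(cn) {
  if (any(is.na(cn)) || any(cn < 0))
    stop("copy numbers must be non-negative and non-missing")
  idx <- ifelse(cn < 0.1, 1L,
         ifelse(cn < 1.5, 2L,
         ifelse(cn < 2.6, 3L,
         ifelse(cn <= 4.0, 4L,
         ifelse(cn <= 6.0, 5L, 6L)))))
  factor(CN_CATEGORIES[idx], levels = CN_CATEGORIES)
}

#' Fragment-level copy number from window copy numbers
#'
#' A fragment's copy number is the unweighted mean of the \code{cn} of all
#' windows lying fully inside the fragment; fragments containing no
#' complete window are reported as \code{NA} (missing), never as zero.
#'
#' @param windows Window table with a \code{cn} column.
#' @param fragments BED-convention data.frame with a \code{name} column.
#' @return Named numeric vector of fragment copy numbers.
#' @export
fragment_cn <- function(windows, fragments) {
  if (is.null(windows$cn)) stop("windows lack cn; run estimate_cn() first")
  out <- stats::setNames(rep(NA_real_, nrow(fragments)), fragments$name)
  for (contig in unique(fragments$chrom)) {
    f <- fragments[fragments$chrom == contig, , drop = FALSE]
    w <- windows[windows$chrom == contig, , drop = FALSE]
    if (nrow(w) == 0L) next
    wir <- IRanges::IRanges(w$start + 1L, w$end)
    fir <- IRanges::IRanges(f$start + 1L, f$end)
    ov <- IRanges::findOverlaps(wir, fir, type = "within")
    if (length(ov) == 0L) next
    means <- tapply(w$cn[S4Vectors::queryHits(ov)],
                    S4Vectors::subjectHits(ov), mean)
    out[f$name[as.integer(names(means))]] <- as.numeric(means)
  }
  out
}

#' Build the individuals-by-fragments copy-number matrix
#'
#' @param fragment_cns A named list (one element per individual) of
#'   \code{\link{fragment_cn}} vectors, all over the same fragments.
#' @param individuals data.frame with columns \code{id},
#'   \code{population}, one row per element of \code{fragment_cns}.
#' @return Object of class \code{cn_matrix}: list with \code{cn}
#'   (numeric matrix, individuals x fragments) and \code{individuals}.
#' @export
cn_matrix <- function(fragment_cns, individuals) {
  stopifnot(length(fragment_cns) == nrow(individuals))
  m <- do.call(rbind, fragment_cns)
  rownames(m) <- individuals$id
  out <- list(cn = m, individuals = individuals)
  class(out) <- "cn_matrix"
  out
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat("cn_matrix:", nrow(x$cn), "individuals x", ncol(x$cn),
      "fragments;", length(unique(x$individuals$population)),
      "populations\n")
  invisible(x)
}

#' @export
as.data.frame.cn_matrix <- function(x, ...) {
  cbind(x$individuals, as.data.frame(x$cn), row.names = NULL)
}

#' Write or read a copy-number matrix as TSV
#'
#' Columns: individual, population, then one column per fragment.
#'
#' @param cnm A \code{cn_matrix}.
#' @param path TSV path.
#' @return \code{read_cn_matrix} returns the restored \code{cn_matrix}.
#' @export
write_cn_matrix <- function(cnm, path) {
  df <- as.data.frame(cnm)
  names(df)[1:2] <- c("individual", "population")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cn_matrix
#' @export
read_cn_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  individuals <- data.frame(id = df$individual,
                            population = df$population,
                            stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- individuals$id
  cn_matrix(lapply(seq_len(nrow(m)), function(i)
    stats::setNames(m[i, ], colnames(m))), individuals)
}

#' Per-population copy-number summaries per fragment
#'
#' For every fragment and population: the min, max, range (max - min) and
#' mean of the individual fragment copy numbers. \code{is_variable} flags
#' fragments where any individual departs from the normal diploid control
#' band [1.5, 3]; \code{is_multiplied} flags fragments where any
#' individual exceeds 3 copies.
#'
#' @param cnm A \code{cn_matrix}.
#' @return data.frame with one row per (fragment, population).
#' @export
summarize_population <- function(cnm) {
  stopifnot(inherits(cnm, "cn_matrix"))
  pops <- unique(cnm$individuals$population)
  rows <- list()
  for (p in pops) {
    sel <- cnm$individuals$population == p
    sub <- cnm$cn[sel, , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      v <- sub[, j]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        fragment_id = colnames(sub)[j],
        population = p,
        n = length(v),
        cn_min = min(v),
        cn_max = max(v),
        cn_range = max(v) - min(v),
        cn_mean = mean(v),
        is_variable = any(v < 1.5 | v > 3.0),
        is_multiplied = any(v > 3.0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate diploidy of control regions across the cohort
#'
#' Reports every (individual, control) copy number together with the
#' global minimum and maximum, and a pass flag that is TRUE when all
#' values lie within the normal diploid band [1.5, 3].
#'
#' @param cnm A \code{cn_matrix} whose columns include the control ids.
#' @param control_ids Character vector of control fragment ids.
#' @return Object of class \code{control_report}: list with \code{table}
#'   (individual, population, control, cn), \code{cn_min}, \code{cn_max},
#'   \code{pass} and \code{failures}.
#' @export
control_report <- function(cnm, control_ids) {
  stopifnot(inherits(cnm, "cn_matrix"))
  if (length(control_ids) == 0L)
    stop("at least one control id is required")
  missing_ids <- setdiff(control_ids, colnames(cnm$cn))
  if (length(missing_ids) > 0L)
    stop("control id not in matrix: ", missing_ids[1])
  sub <- cnm$cn[, control_ids, drop = FALSE]
  tab <- data.frame(
    individual = rep(rownames(sub), times = ncol(sub)),
    population = rep(cnm$individuals$population, times = ncol(sub)),
    control = rep(colnames(sub), each = nrow(sub)),
    cn = as.vector(sub),
    stringsAsFactors = FALSE)
  ok <- tab$cn >= 1.5 & tab$cn <= 3.0
  out <- list(table = tab,
              cn_min = min(tab$cn, na.rm = TRUE),
              cn_max = max(tab$cn, na.rm = TRUE),
              pass = all(ok, na.rm = FALSE) && !any(is.na(tab$cn)),
              failures = tab[!ok | is.na(tab$cn), , drop = FALSE])
  class(out) <- "control_report"
  out
}

#' @export
print.control_report <- function(x, ...) {
  cat("control_report:", nrow(x$table), "values; range [",
      format(x$cn_min, digits = 3), ",", format(x$cn_max, digits = 3),
      "];", if (x$pass) "PASS (all within [1.5, 3])" else
        paste0("FAIL (", nrow(x$failures), " outside [1.5, 3])"), "\n")
  invisible(x)
}
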