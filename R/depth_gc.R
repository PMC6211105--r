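#' Fit a binned GC-bias model to windowed depth
#'
#' Windows are grouped into GC bins of width \code{bin_width}; each bin's
#' mean raw depth is recorded. Bins holding fewer than \code{min_bin_count}
#' windows are unreliable and fall back to the global mean (i.e. no
#' correction for windows in those bins).
#'
#' @param windows Window table with a \code{raw_depth} column.
#' @param bin_width GC-fraction bin width (default 0.025).
#' @param min_bin_count Minimum windows per bin (default 20).
#' @param outlier_sd Iterative sigma-clipping threshold: windows whose raw
#'   depth departs from the running mean by more than this many standard
#'   deviations are excluded from the fit (not from correction), so that
#'   deleted or duplicated regions do not drag the diploid depth baseline.
#'   \code{NULL} disables clipping (default 3).
#' @return An object of class \code{gc_model}: list with \code{bin_width},
#'   \code{bin_means} (named by bin index \code{floor(gc / bin_width)}),
#'   \code{bin_counts}, \code{global_mean}, \code{min_bin_count},
#'   \code{n_clipped}.
#' @export
fit_gc_model <- function(windows, bin_width = 0.025, min_bin_count = 20L,
                         outlier_sd = 3) {
  if (is.null(windows$raw_depth)) stop("windows lack raw_depth")
  if (nrow(windows) < 1L) stop("no windows to fit")
  d <- windows$raw_depth
  if (mean(d) <= 0) stop("no coverage: all window depths are zero")
  keep <- rep(TRUE, length(d))
  if (!is.null(outlier_sd) && length(d) > 2L) {
    for (it in 1:10) {
      m <- mean(d[keep]); s <- stats::sd(d[keep])
      if (!is.finite(s) || s == 0) break
      keep2 <- abs(d - m) <= outlier_sd * s
      if (identical(keep2, keep)) break
      keep <- keep2
    }
    if (!any(keep)) keep <- rep(TRUE, length(d))
  }
  global_mean <- mean(d[keep])
  if (global_mean <= 0) stop("no coverage: all window depths are zero")
  bin <- .gc_bin(windows$gc, bin_width)
  bin_means <- c(tapply(d[keep], bin[keep], mean))
  bin_counts <- c(tapply(d[keep], bin[keep], length))
  low <- bin_counts < min_bin_count
  bin_means[low] <- global_mean
  out <- list(bin_width = bin_width,
              bin_means = bin_means,
              bin_counts = bin_counts,
              global_mean = global_mean,
              min_bin_count = as.integer(min_bin_count),
              n_clipped = sum(!keep))
  class(out) <- "gc_model"
  out
}

# gc == 1 collapses into the last proper bin; the epsilon keeps exact
# bin-boundary GC values (e.g. 0.300 / 0.025) in their nominal bin
.gc_bin <- function(gc, bin_width) {
  pmin(floor(gc / bin_width + 1e-9), floor((1 - 1e-9) / bin_width))
}

#' @export
print.gc_model <- function(x, ...) {
  cat("gc_model:", length(x$bin_means), "bins of width", x$bin_width,
      "| global mean depth", format(x$global_mean, digits = 4), "\n")
  invisible(x)
}

#' Apply GC correction to windowed depth
#'
#' \code{corrected_depth = raw_depth * global_mean / bin_mean} for the
#' window's GC bin; windows in GC bins never seen (or underpopulated)
#' during fitting are left uncorrected (factor 1).
#'
#' @param windows Window table with \code{raw_depth}.
#' @param model A fitted \code{\link{fit_gc_model}}.
#' @return \code{windows} with a \code{corrected_depth} column.
#' @export
gc_correct <- function(windows, model) {
  stopifnot(inherits(model, "gc_model"))
  bin <- as.character(.gc_bin(windows$gc, model$bin_width))
  bm <- model$bin_means[bin]
  bm[is.na(bm)] <- model$global_mean
  bad <- bm == 0 & windows$raw_depth > 0
  if (any(bad))
    stop("GC bin with zero mean depth but nonzero window depth (bin ",
         bin[which(bad)[1]], ")")
  factor <- ifelse(bm == 0, 0, model$global_mean / bm)
  windows$corrected_depth <- windows$raw_depth * factor
  windows
}
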