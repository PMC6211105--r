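#' Calibrate corrected depth against diploid control regions
#'
#' The depth-to-copy-number scale is anchored on designated control
#' regions assumed diploid in every individual (here: two single-exon
#' control genes plus one large control fragment). The calibration value
#' is the median corrected depth over all windows lying fully inside a
#' control interval; the median is robust to residual copy-number
#' variation in individual control windows.
#'
#' @param windows Window table with \code{corrected_depth}.
#' @param controls BED-convention data.frame of control intervals.
#' @param min_windows Minimum number of control windows required
#'   (default 5).
#' @return An object of class \code{cn_calibration}: list with
#'   \code{control_depth}, \code{diploid_cn} (constant 2) and
#'   \code{n_windows}.
#' @export
calibrate <- function(windows, controls, min_windows = 5L) {
  if (is.null(windows$corrected_depth))
    stop("windows lack corrected_depth; run gc_correct() first")
  inside <- .windows_inside(windows, controls)
  if (sum(inside) < min_windows)
    stop("calibration requires at least ", min_windows,
         " control windows; found ", sum(inside))
  control_depth <- stats::median(windows$corrected_depth[inside])
  if (control_depth <= 0)
    stop("control regions have no coverage")
  out <- list(control_depth = control_depth, diploid_cn = 2,
              n_windows = sum(inside))
  class(out) <- "cn_calibration"
  out
}

# logical: window genomic span fully inside any interval of `bed`
.windows_inside <- function(windows, bed) {
  inside <- rep(FALSE, nrow(windows))
  if (is.null(bed) || nrow(bed) == 0L) return(inside)
  for (contig in unique(windows$chrom)) {
    wsel <- windows$chrom == contig
    b <- bed[bed$chrom == contig, , drop = FALSE]
    if (nrow(b) == 0L) next
    wir <- IRanges::IRanges(windows$start[wsel] + 1L, windows$end[wsel])
    bir <- IRanges::IRanges(b$start + 1L, b$end)
    ov <- IRanges::findOverlaps(wir, bir, type = "within")
    hit <- rep(FALSE, length(wir))
    hit[S4Vectors::queryHits(ov)] <- TRUE
    inside[wsel] <- hit
  }
  inside
}

#' @export
print.cn_calibration <- function(x, ...) {
  cat("cn_calibration: control depth", format(x$control_depth, digits = 4),
      "over", x$n_windows, "control windows (diploid = 2)\n")
  invisible(x)
}

#' Convert corrected depth to copy number
#'
#' \code{cn = 2 * corrected_depth / control_depth}: a window whose
#' corrected depth equals the control-region depth reads as diploid.
#'
#' @param windows Window table with \code{corrected_depth}.
#' @param calibration A \code{\link{calibrate}} result.
#' @return \code{windows} with a \code{cn} column.
#' @export
estimate_cn <- function(windows, calibration) {
  stopifnot(inherits(calibration, "cn_calibration"))
  windows$cn <- calibration$diploid_cn * windows$corrected_depth /
    calibration$control_depth
  windows
}

#' Windowed GC-corrected copy number from reads or alignments
#'
#' End-to-end depth stage for one individual: tile repeat-masked windows,
#' ingest alignments (mapping reads exactly if given as sequences), fit
#' and apply the GC correction, calibrate on the control regions, and
#' estimate per-window copy number.
#'
#' @param reference \code{DNAStringSet} or \code{sim_reference}.
#' @param mask,controls BED-convention data.frames (taken from the
#'   \code{sim_reference} if NULL).
#' @param source Reads (\code{DNAStringSet} or FASTQ path),
#'   \code{read_placements}, or a SAM file path.
#' @param window Unmasked bases per window (default 1000).
#' @param gc_bin GC bin width (default 0.025).
#' @param min_bin_count Minimum windows per GC bin (default 20).
#' @return The window table with \code{gc}, \code{raw_depth},
#'   \code{corrected_depth} and \code{cn} columns; the calibration is
#'   attached as attribute \code{calibration}.
#' @export
depth_cnv <- function(reference, source, mask = NULL, controls = NULL,
                      window = 1000L, gc_bin = 0.025,
                      min_bin_count = 20L) {
  if (inherits(reference, "sim_reference")) {
    if (is.null(mask)) mask <- reference$mask
    if (is.null(controls)) controls <- reference$controls
    reference <- reference$seq
  }
  if (is.null(controls) || nrow(controls) == 0L)
    stop("control intervals are required for calibration")
  placements <- if (inherits(x = source, what = "read_placements"))
    source
  else if (is.character(source) && grepl("\\.sam$", source))
    source
  else
    map_reads_exact(source, reference)
  depth <- ingest_alignments(placements, reference)
  win <- tile_windows(reference, mask, window = window)
  win <- window_depth(win, depth)
  model <- fit_gc_model(win, bin_width = gc_bin,
                        min_bin_count = min_bin_count)
  win <- gc_correct(win, model)
  cal <- calibrate(win, controls)
  win <- estimate_cn(win, cal)
  attr(win, "calibration") <- cal
  attr(win, "gc_model") <- model
  win
}
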