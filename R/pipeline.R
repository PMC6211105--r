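#' Run the full copy-number pipeline on a simulated cohort
#'
#' For every individual: simulate GC-biased reads from the planted diploid
#' genome, map them exactly to the reference (reporting all matches),
#' estimate GC-corrected window copy numbers calibrated on the control
#' regions, and aggregate fragment-level copy numbers. Returns the
#' individuals-by-fragments matrix (B fragments plus the control regions
#' as extra columns), per-population summaries, and the control
#' validation.
#'
#' @param cohort A \code{\link{simulate_cohort}} result, or a
#'   \code{\link{sim_config}} (in which case the cohort is simulated
#'   first).
#' @param window Unmasked bases per depth window (default 1000).
#' @param gc_bin GC bin width for the bias model (default 0.025).
#' @param verbose Print per-individual progress.
#' @return Object of class \code{cohort_result}: list with
#'   \code{cohort}, \code{windows} (per-individual window tables),
#'   \code{matrix} (a \code{\link{cn_matrix}} over fragments + controls),
#'   \code{summary} (\code{\link{summarize_population}}),
#'   \code{controls} (\code{\link{control_report}}).
#' @export
run_cohort_pipeline <- function(cohort, window = 1000L, gc_bin = 0.025,
                                verbose = FALSE) {
  if (inherits(cohort, "sim_config")) cohort <- simulate_cohort(cohort)
  stopifnot(inherits(cohort, "sim_cohort"))
  cfg <- cohort$config
  ref <- cohort$reference
  truth <- cohort$truth

  targets <- rbind(ref$fragments[, c("chrom", "start", "end", "name")],
                   ref$controls[, c("chrom", "start", "end", "name")])
  individuals <- truth$individuals
  win_tables <- vector("list", nrow(individuals))
  frag_cns <- vector("list", nrow(individuals))
  names(win_tables) <- names(frag_cns) <- individuals$id

  for (i in seq_len(nrow(individuals))) {
    id <- individuals$id[i]
    if (verbose) message("individual ", id)
    reads <- simulate_reads(truth$genomes[[id]], cfg,
                            seed = .derive_seed(cfg$seed, 100L + i))
    win <- depth_cnv(ref, reads, window = window, gc_bin = gc_bin)
    win_tables[[i]] <- win
    frag_cns[[i]] <- fragment_cn(win, targets)
  }

  cnm <- cn_matrix(frag_cns, individuals)
  out <- list(cohort = cohort,
              windows = win_tables,
              matrix = cnm,
              summary = summarize_population(cnm),
              controls = control_report(cnm, ref$controls$name))
  class(out) <- "cohort_result"
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("cohort_result:", nrow(x$matrix$cn), "individuals,",
      ncol(x$matrix$cn), "fragments (incl. controls)\n")
  print(x$controls)
  invisible(x)
}

#' Per-individual mean copy number over control-region windows
#'
#' The control-diploidy diagnostic: for each individual, the mean
#' estimated copy number across all windows lying fully inside a control
#' interval. In a well-calibrated run every value sits inside the normal
#' diploid band [1.5, 3].
#'
#' @param result A \code{\link{run_cohort_pipeline}} result.
#' @return Named numeric vector, one value per individual.
#' @export
per_individual_control_cn <- function(result) {
  stopifnot(inherits(result, "cohort_result"))
  controls <- result$cohort$reference$controls
  vapply(result$windows, function(w)
    mean(w$cn[.windows_inside(w, controls)]), numeric(1))
}
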