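#' Flow-cytometry genome-size estimate
#'
#' Converts relative fluorescence intensities of propidium-iodide-stained
#' G0/G1 nuclei into DNA content: the sample's 2C size in pg is the
#' standard's 2C size multiplied by the intensity ratio, and 1 pg of DNA
#' corresponds to 0.978e9 bp.
#'
#' @param sample_intensity G0/G1 peak fluorescence of the sample
#'   (arbitrary units).
#' @param standard_intensity Same for the reference standard (e.g.
#'   chicken).
#' @param standard_size_pg 2C DNA content of the standard, pg.
#' @return Object of class \code{genome_size_estimate}: list with the
#'   inputs plus \code{size_pg} and \code{size_bp} (rounded to the
#'   nearest base).
#' @export
#' @examples
#' genome_size(1, 1, 1)$size_bp     # 978000000
genome_size <- function(sample_intensity, standard_intensity,
                        standard_size_pg) {
  if (any(c(sample_intensity, standard_intensity, standard_size_pg) <= 0))
    stop("intensities and standard size must be positive")
  size_pg <- standard_size_pg * sample_intensity / standard_intensity
  out <- list(sample_intensity = sample_intensity,
              standard_intensity = standard_intensity,
              standard_size_pg = standard_size_pg,
              size_pg = size_pg,
              size_bp = round(size_pg * PG_TO_BP))
  class(out) <- "genome_size_estimate"
  out
}

#' Picograms-to-basepairs conversion constant (bp per pg of DNA)
#' @export
PG_TO_BP <- 0.978e9

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("genome_size_estimate: %.3f pg = %s bp (%.0f Mb)\n",
              x$size_pg, format(x$size_bp, big.mark = ","),
              x$size_bp / 1e6))
  invisible(x)
}

#' Variant density per kilobase
#'
#' @param n_snvs Variant count.
#' @param length_bp Sequence length in bp (must be positive).
#' @return Density in variants per kb.
#' @export
#' @examples
#' snv_density(2901, 361036)   # ~8 per kb
snv_density <- function(n_snvs, length_bp) {
  if (length_bp <= 0) stop("length_bp must be positive")
  if (n_snvs < 0) stop("n_snvs must be non-negative")
  n_snvs / (length_bp / 1000)
}

#' Ratio of two per-kb densities
#'
#' @param density_a,density_b Non-negative densities;
#'   \code{density_b > 0}.
#' @return List with \code{ratio} and \code{nearest_integer}.
#' @export
#' @examples
#' density_ratio(30.2, 5.16)   # ~5.85, nearest integer 6
density_ratio <- function(density_a, density_b) {
  if (density_b <= 0) stop("density_b must be positive")
  r <- density_a / density_b
  list(ratio = r, nearest_integer = round(r))
}

#' Two-sample pooled-variance Student t comparison of DNA content
#'
#' Compares per-individual genome sizes (bp) between two groups with the
#' classical two-sided pooled-variance Student t-test; group means and
#' standard deviations are reported in Mb.
#'
#' @param values_a,values_b Numeric vectors of per-individual genome
#'   sizes in bp, each of length >= 2.
#' @return Object of class \code{group_comparison}: list with \code{t},
#'   \code{df}, \code{p_value}, \code{mean_a_mb}, \code{sd_a_mb},
#'   \code{mean_b_mb}, \code{sd_b_mb}, \code{n_a}, \code{n_b}.
#' @export
compare_groups <- function(values_a, values_b) {
  na <- length(values_a)
  nb <- length(values_b)
  if (na < 2L || nb < 2L)
    stop("each group needs at least 2 values")
  ma <- mean(values_a)
  mb <- mean(values_b)
  va <- stats::var(values_a)
  vb <- stats::var(values_b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  t <- if (ma == mb) 0 else
    (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t), df)
  out <- list(t = t, df = df, p_value = p,
              mean_a_mb = ma / 1e6, sd_a_mb = sqrt(va) / 1e6,
              mean_b_mb = mb / 1e6, sd_b_mb = sqrt(vb) / 1e6,
              n_a = na, n_b = nb)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "group_comparison: %.0f +/- %.0f Mb (n=%d) vs %.0f +/- %.0f Mb (n=%d); t = %.3f, df = %d, p = %.3g\n",
    x$mean_a_mb, x$sd_a_mb, x$n_a, x$mean_b_mb, x$sd_b_mb, x$n_b,
    x$t, x$df, x$p_value))
  invisible(x)
}

#' Sequence-density report for a B-derived assembly versus its genome
#'
#' Collects the scalar densities reported for a B-derived assembly:
#' SNV density per kb, gene densities of the whole genome and of the
#' B assembly with their ratio, repeat-masked fractions, and the
#' fraction of the genome the B assembly represents. A note flags a
#' unit inconsistency whenever the stated gene densities are not
#' reproducible from the stated counts and lengths.
#'
#' @param n_snvs SNV count in the B-derived regions.
#' @param b_length_bp Unmasked length of the B-derived regions, bp.
#' @param gene_density_a,gene_density_b Gene densities per kb (genome,
#'   B assembly).
#' @param repeat_fraction_b,repeat_fraction_genome Repeat-masked
#'   fractions.
#' @param b_assembly_bp Total B assembly length (spacers included), bp.
#' @param genome_bp Genome assembly length, bp.
#' @return Object of class \code{density_report}.
#' @export
density_report <- function(n_snvs, b_length_bp,
                           gene_density_a, gene_density_b,
                           repeat_fraction_b = NA_real_,
                           repeat_fraction_genome = NA_real_,
                           b_assembly_bp = NA_real_,
                           genome_bp = NA_real_) {
  rat <- density_ratio(gene_density_a, gene_density_b)
  out <- list(snv_density_per_kb = snv_density(n_snvs, b_length_bp),
              n_snvs = n_snvs,
              b_length_bp = b_length_bp,
              gene_density_a = gene_density_a,
              gene_density_b = gene_density_b,
              density_ratio = rat$ratio,
              density_ratio_nearest = rat$nearest_integer,
              repeat_fraction_b = repeat_fraction_b,
              repeat_fraction_genome = repeat_fraction_genome,
              b_fraction_of_genome =
                if (is.na(b_assembly_bp) || is.na(genome_bp)) NA_real_
                else b_assembly_bp / genome_bp)
  class(out) <- "density_report"
  out
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("density_report: %.2f SNVs/kb (%d over %s bp); gene density %.4g vs %.4g per kb (ratio %.2f ~ %d)\n",
              x$snv_density_per_kb, x$n_snvs,
              format(x$b_length_bp, big.mark = ","),
              x$gene_density_a, x$gene_density_b, x$density_ratio,
              x$density_ratio_nearest))
  if (!is.na(x$b_fraction_of_genome))
    cat(sprintf("  B assembly = %.4g%% of the genome; repeat fraction %.3g vs %.3g\n",
                100 * x$b_fraction_of_genome, x$repeat_fraction_b,
                x$repeat_fraction_genome))
  invisible(x)
}
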