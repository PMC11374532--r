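#' Transcripts per million
#'
#' Length-normalized within-sample abundance:
#' `TPM_gs = (count_gs / length_g) / sum_g'(count_g's / length_g') * 1e6`.
#' Every sample column sums to one million by construction.
#'
#' @param counts non-negative integer gene x sample matrix.
#' @param gene_lengths named lengths in bp covering all genes.
#' @return numeric matrix of TPM values, same dimnames as `counts`.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  if (!all(rownames(counts) %in% names(gene_lengths)))
    stop("lengths missing for some genes")
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive")
  rate <- counts / len
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(rate, 2, tot, `/`) * 1e6
}

#' Per-period mean expression
#'
#' Arithmetic mean of each gene's TPM over the replicates of every
#' (condition, day) cell.
#'
#' @param tpm gene x sample TPM matrix.
#' @param design sample design.
#' @return gene x cell matrix; columns named like `C0`, `T4`.
#' @export
period_means <- function(tpm, design) {
  cell <- paste0(design$condition, design$day)
  cells <- unique(cell)
  out <- vapply(cells, function(cl) {
    rowMeans(tpm[, design$sample[cell == cl], drop = FALSE])
  }, numeric(nrow(tpm)))
  if (!is.matrix(out))
    out <- matrix(out, nrow = 1, dimnames = list(rownames(tpm), cells))
  colnames(out) <- cells
  out
}

#' Expressed-gene filtering
#'
#' A gene is expressed in a period iff its mean TPM is at least
#' `min_tpm` (default 1; mean TPM below 1 defines "not expressed", the
#' boundary value counts as expressed). A gene is globally expressed iff
#' expressed in at least one period; the global set is the default
#' population for enrichment tests.
#'
#' @param means gene x cell matrix from [period_means()].
#' @param min_tpm expressed threshold (default 1.0).
#' @return list: `flags` (logical gene x cell matrix) and `expressed`
#'   (character vector, the global expressed-gene set).
#' @export
filter_expressed <- function(means, min_tpm = 1.0) {
  flags <- means >= min_tpm
  list(flags = flags, expressed = rownames(means)[rowSums(flags) > 0])
}

#' PCA quality control of samples
#'
#' Principal components of per-gene-centered `log2(TPM + 1)` over the
#' globally expressed genes.
#'
#' @param tpm gene x sample TPM matrix.
#' @param design sample design.
#' @param expressed optional expressed-gene subset; default all genes.
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @return list: `coords` (sample x 2 matrix), `var_fraction` (explained
#'   variance fractions, all components), `design`.
#' @export
pca_qc <- function(tpm, design, expressed = NULL, log_transform = TRUE) {
  if (ncol(tpm) < 3) stop("PCA needs >= 3 samples")
  x <- tpm
  if (!is.null(expressed)) x <- x[expressed, , drop = FALSE]
  if (log_transform) x <- log2(x + 1)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x[, 1:2, drop = FALSE], var_fraction = vf,
       design = design)
}

#' Correlation between analyte levels and temporal profiles
#'
#' Pearson correlation of each analyte's per-period values against each
#' expression (or indicator) profile over the same periods. Zero-variance
#' vectors yield NA (correlation undefined).
#'
#' @param hormones analyte x period numeric matrix.
#' @param profiles profile x period numeric matrix (same period columns).
#' @return analyte x profile correlation matrix.
#' @export
hormone_period_correlation <- function(hormones, profiles) {
  if (ncol(hormones) < 3) stop("need >= 3 periods")
  if (ncol(hormones) != ncol(profiles))
    stop("hormone and profile period dimensions differ")
  out <- suppressWarnings(stats::cor(t(hormones), t(profiles)))
  sd_h <- apply(hormones, 1, stats::sd)
  sd_p <- apply(profiles, 1, stats::sd)
  out[sd_h == 0, ] <- NA
  out[, sd_p == 0] <- NA
  out
}
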