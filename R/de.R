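#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (nonzero in all samples) of the
#' ratio of its count to the gene's geometric mean across samples.
#'
#' @param counts gene x sample count matrix.
#' @return named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  keep <- rowSums(counts == 0) == 0
  if (!any(keep))
    stop("no gene nonzero in all samples; consider a pseudo-reference ",
         "fallback (add a pseudo-count upstream)")
  lc <- log(counts[keep, , drop = FALSE])
  geo <- rowMeans(lc)
  f <- apply(exp(sweep(lc, 1, geo)), 2, stats::median)
  if (any(f <= 0)) stop("non-positive size factor")
  f
}

#' Gene-wise negative-binomial dispersion with adaptive moment shrinkage
#'
#' Gene-wise method-of-moments dispersion on size-factor-normalized
#' counts, residual contributions pooled within replicate groups:
#' `alpha_g = max(0, sum_j (n_j-1)(s2_j - m_j) / sum_j (n_j-1)(m_j^2 -
#' s2_j/n_j))` (the `- s2_j/n_j` term removes the plug-in bias of `m_j^2`
#' as an estimate of `mu_j^2`). The shrinkage target is the analogous
#' moment ratio pooled across all genes, which is nearly unbiased.
#'
#' Shrinkage is empirical-Bayes: the between-gene dispersion variance
#' `tau^2` is estimated by moments against the delta-method sampling
#' variance `V_g` of each raw estimate (negative-binomial cumulants up to
#' order four, evaluated at the pooled dispersion), and each gene's prior
#' weight is `max(n_prior / (n_prior + n_reps), V_g / (V_g + tau^2))`.
#' When genes share one dispersion (`tau^2 ~ 0`) the estimator collapses
#' to the pooled value; heterogeneous data retain gene-wise signal, with
#' the fixed `n_prior` weight as a floor.
#'
#' @param counts gene x sample count matrix.
#' @param design sample design.
#' @param factors size factors from [size_factors()].
#' @param n_prior prior sample size setting the minimum shrinkage weight
#'   (default 5).
#' @param floor minimum dispersion (default 1e-8).
#' @return list: `dispersion` (shrunk, per gene), `raw` (gene-wise
#'   pre-shrinkage estimates), `prior` (pooled shrinkage target),
#'   `tau2` (between-gene dispersion variance estimate).
#' @export
estimate_dispersion <- function(counts, design, factors, n_prior = 5,
                                floor = 1e-8) {
  y <- sweep(counts, 2, factors, `/`)
  cell <- paste0(design$condition, design$day)
  cells <- unique(cell)
  G <- nrow(counts)
  num <- numeric(G); den <- numeric(G)
  cell_stats <- list()
  n_per <- integer(0)
  for (cl in cells) {
    idx <- design$sample[cell == cl]
    n <- length(idx)
    if (n < 2) next
    n_per <- c(n_per, n)
    sub <- y[, idx, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    cell_stats[[cl]] <- list(m = m, v = v, n = n)
    ok <- m > 0
    num[ok] <- num[ok] + (n - 1) * (v[ok] - m[ok])
    den[ok] <- den[ok] + (n - 1) * pmax(m[ok]^2 - v[ok] / n, 0)
  }
  if (!length(n_per)) stop("need >= 2 replicates in some group")
  raw <- ifelse(den > 0, pmax(0, num / den), 0)
  names(raw) <- rownames(counts)
  prior <- max(0, sum(num[den > 0]) / sum(den[den > 0]))

  ## delta-method variance of each raw estimate at the pooled dispersion,
  ## from NB cumulants: k2 = m + a m^2, k3 = m + 3a m^2 + 2a^2 m^3,
  ## k4 = m + 7a m^2 + 12a^2 m^3 + 6a^3 m^4;
  ## Var(s2 - xbar) = k4/n + 2 k2^2/(n-1) - 2 k3/n + k2/n.
  a0 <- prior
  Vg <- numeric(G)
  for (cs in cell_stats) {
    m <- pmax(cs$m, 1e-8); n <- cs$n
    k2 <- m + a0 * m^2
    k3 <- m + 3 * a0 * m^2 + 2 * a0^2 * m^3
    k4 <- m + 7 * a0 * m^2 + 12 * a0^2 * m^3 + 6 * a0^3 * m^4
    vnum <- k4 / n + 2 * k2^2 / (n - 1) - 2 * k3 / n + k2 / n
    Vg <- Vg + (n - 1)^2 * vnum
  }
  Vg <- ifelse(den > 0, Vg / pmax(den, 1e-12)^2, Inf)
  ok <- is.finite(Vg)
  tau2 <- max(0, mean((raw[ok] - a0)^2) - mean(Vg[ok]))
  w_floor <- n_prior / (n_prior + mean(n_per))
  w_prior <- pmax(w_floor, Vg / (Vg + tau2))
  w_prior[!is.finite(Vg)] <- 1
  disp <- pmax(w_prior * prior + (1 - w_prior) * raw, floor)
  list(dispersion = disp, raw = raw, prior = prior, tau2 = tau2)
}

#' Define a two-group contrast
#' @param name contrast label (e.g. `"C4_T4"`).
#' @param num numerator cell, `c(condition, day)`.
#' @param den denominator cell, `c(condition, day)`.
#' @return a `contrast_spec` list.
#' @export
contrast_spec <- function(name, num, den) {
  if (identical(num, den)) stop("numerator and denominator groups coincide")
  structure(list(name = name,
                 num = list(condition = num[1], day = as.numeric(num[2])),
                 den = list(condition = den[1], day = as.numeric(den[2]))),
            class = "contrast_spec")
}

group_samples <- function(design, grp) {
  s <- design$sample[design$condition == grp$condition &
                       design$day == grp$day]
  if (!length(s))
    stop("design has no cell (", grp$condition, ", ", grp$day, ")")
  s
}

#' Negative-binomial Wald test for one contrast
#'
#' Group means are fitted on normalized counts; the log2 fold change uses a
#' pseudo-count of 0.5 per group mean; its standard error comes from the NB
#' delta-method variance of the log-ratio (Var(count) = mu s + alpha mu^2
#' s^2 on the raw scale); the two-sided p is normal; BH adjustment is over
#' all genes tested in the contrast. Genes with zero counts in both groups
#' are excluded and flagged.
#'
#' @param counts gene x sample count matrix.
#' @param design sample design.
#' @param contrast a `contrast_spec`.
#' @param factors size factors.
#' @param dispersions per-gene dispersion vector.
#' @param pseudocount added to each group mean for the fold change
#'   (default 0.5).
#' @return a `deg_table` data.frame: gene, baseMean, log2FC, lfcSE,
#'   pvalue, padj; attribute `excluded` lists all-zero genes.
#' @export
wald_test <- function(counts, design, contrast, factors, dispersions,
                      pseudocount = 0.5) {
  s1 <- group_samples(design, contrast$num)
  s2 <- group_samples(design, contrast$den)
  if (length(s1) < 2 || length(s2) < 2)
    stop("both groups need >= 2 replicates")
  y <- sweep(counts, 2, factors, `/`)
  y1 <- y[, s1, drop = FALSE]; y2 <- y[, s2, drop = FALSE]
  mu1 <- rowMeans(y1); mu2 <- rowMeans(y2)
  excluded <- rownames(counts)[mu1 == 0 & mu2 == 0]
  keep <- !(mu1 == 0 & mu2 == 0)

  a <- dispersions[rownames(counts)]
  f1 <- factors[s1]; f2 <- factors[s2]
  ## Var of the normalized-count group mean under NB sampling:
  ## Var(mean_i K_i/f_i) = (mu * sum(1/f_i) + n * alpha * mu^2) / n^2
  v_mean <- function(mu, f, a) {
    n <- length(f)
    (mu * sum(1 / f) + n * a * mu^2) / n^2
  }
  V1 <- v_mean(mu1, f1, a); V2 <- v_mean(mu2, f2, a)
  m1 <- mu1 + pseudocount; m2 <- mu2 + pseudocount
  lfc <- log2(m1 / m2)
  ## second-order delta-method variance of log(mean): V/m^2 + V^2/(2 m^4)
  se <- sqrt(V1 / m1^2 + V1^2 / (2 * m1^4) +
               V2 / m2^2 + V2^2 / (2 * m2^4)) / log(2)
  se <- pmax(se, 1e-8)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))

  tab <- data.frame(gene = rownames(counts),
                    baseMean = rowMeans(cbind(y1, y2)),
                    log2FC = lfc, lfcSE = se, pvalue = p,
                    stringsAsFactors = FALSE)[keep, ]
  tab$padj <- adjust_bh(tab$pvalue)
  rownames(tab) <- NULL
  attr(tab, "contrast") <- contrast$name
  attr(tab, "excluded") <- excluded
  class(tab) <- c("deg_table", "data.frame")
  tab
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up adjustment with monotonicity enforcement over the whole vector.
#' @param p numeric p values in \[0, 1\].
#' @return adjusted p values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Threshold a DEG table into a signed DEG set
#'
#' A gene is called iff `|log2FC| >= lfc_min` (boundary inclusive) and
#' `padj < padj_max` (strict).
#'
#' @param table a `deg_table`.
#' @param lfc_min absolute log2FC threshold (default 1.0).
#' @param padj_max adjusted-p threshold (default 0.05).
#' @return a `deg_set` list: `name`, `genes`, `sign` (named +1/-1),
#'   `log2FC` (named, called genes only).
#' @export
call_degs <- function(table, lfc_min = 1.0, padj_max = 0.05) {
  if (lfc_min <= 0 || padj_max <= 0) stop("thresholds must be positive")
  hit <- abs(table$log2FC) >= lfc_min & table$padj < padj_max
  genes <- table$gene[hit]
  structure(list(name = attr(table, "contrast"), genes = genes,
                 sign = stats::setNames(sign(table$log2FC[hit]), genes),
                 log2FC = stats::setNames(table$log2FC[hit], genes)),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("DEG set %s: %d genes (%d up, %d down)\n",
              x$name %||% "?", length(x$genes), sum(x$sign > 0),
              sum(x$sign < 0)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
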