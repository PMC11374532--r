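test_that("size factors follow the median-of-ratios closed form", {
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(a = c(10L, 20L, 30L), b = c(20L, 40L, 60L))
  rownames(m2) <- paste0("g", 1:3)
  f <- size_factors(m2)
  # every ratio to the geometric mean is constant, so factors are exact
  expect_equal(unname(f[2] / f[1]), 2)
  expect_identical(size_factors(m2), size_factors(m2))

  m3 <- cbind(a = c(0L, 5L), b = c(0L, 7L))
  rownames(m3) <- c("g1", "g2")
  f3 <- size_factors(m3)  # one informative gene remains
  expect_equal(unname(f3[2] / f3[1]), 7 / 5)
  m4 <- cbind(a = c(0L, 5L), b = c(3L, 0L))
  rownames(m4) <- c("g1", "g2")
  expect_error(size_factors(m4), "pseudo-reference")
})

test_that("dispersion estimates recover truth and vanish for Poisson", {
  fx <- nb_two_group(G = 2000, n = 10, disp = 0.1, seed = 21)
  f <- size_factors(fx$counts)
  d <- estimate_dispersion(fx$counts, fx$design, f)
  expect_gte(median(d$dispersion), 0.05)
  expect_lte(median(d$dispersion), 0.2)

  set.seed(22)
  pois <- matrix(rpois(2000 * 20, 100), 2000, 20)
  dimnames(pois) <- list(sprintf("g%04d", 1:2000),
                         c(paste0("C1_", 1:10), paste0("T1_", 1:10)))
  storage.mode(pois) <- "integer"
  des <- validate_design(data.frame(sample = colnames(pois),
                                    condition = rep(c("C", "T"), each = 10),
                                    day = 1, replicate = rep(1:10, 2)))
  dp <- estimate_dispersion(pois, des, size_factors(pois))
  expect_lte(median(dp$dispersion), 0.02)

  # constant counts within groups: raw gene-wise estimate is zero
  const <- matrix(rep(c(5L, 9L), each = 3), 1, 6,
                  dimnames = list("g1", c(paste0("C1_", 1:3),
                                          paste0("T1_", 1:3))))
  desc <- validate_design(data.frame(sample = colnames(const),
                                     condition = rep(c("C", "T"), each = 3),
                                     day = 1, replicate = rep(1:3, 2)))
  dc <- estimate_dispersion(const, desc, setNames(rep(1, 6),
                                                  colnames(const)))
  expect_equal(unname(dc$raw), 0)
})

test_that("the Wald test recovers a planted log2 fold change", {
  fx <- nb_two_group(G = 1000, n = 3, disp = 0.1, lfc = 2, seed = 23)
  f <- size_factors(fx$counts)
  d <- estimate_dispersion(fx$counts, fx$design, f)
  tab <- wald_test(fx$counts, fx$design,
                   contrast_spec("C4_T4", c("T", 4), c("C", 4)),
                   f, d$dispersion)
  de <- tab[tab$gene %in% fx$de_genes, ]
  expect_lt(abs(mean(de$log2FC * fx$de_sign[de$gene]) - 2), 0.3)
  expect_gt(mean(de$padj < 0.05), 0.8)
})

test_that("swapping contrast groups negates log2FC and keeps p", {
  fx <- nb_two_group(G = 300, n = 3, disp = 0.1, lfc = 1, seed = 24)
  f <- size_factors(fx$counts)
  d <- estimate_dispersion(fx$counts, fx$design, f)
  t1 <- wald_test(fx$counts, fx$design,
                  contrast_spec("fwd", c("T", 4), c("C", 4)), f,
                  d$dispersion)
  t2 <- wald_test(fx$counts, fx$design,
                  contrast_spec("rev", c("C", 4), c("T", 4)), f,
                  d$dispersion)
  expect_equal(t1$log2FC, -t2$log2FC)
  expect_equal(t1$pvalue, t2$pvalue)
})

test_that("genes with zero counts in both groups are excluded and flagged", {
  fx <- nb_two_group(G = 50, n = 3, seed = 25)
  fx$counts[7, ] <- 0L
  f <- setNames(rep(1, 6), colnames(fx$counts))
  d <- estimate_dispersion(fx$counts, fx$design, f)
  tab <- wald_test(fx$counts, fx$design,
                   contrast_spec("c", c("T", 4), c("C", 4)), f,
                   d$dispersion)
  expect_false(rownames(fx$counts)[7] %in% tab$gene)
  expect_identical(attr(tab, "excluded"), rownames(fx$counts)[7])
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_bh(0.2), 0.2)
  set.seed(26)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- adjust_bh(p)
    expect_equal(adj, bh_step_up(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
})

test_that("DEG calling uses inclusive lfc and strict padj thresholds", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    baseMean = 10, log2FC = c(1.0, 3, 0.9, -1.4),
                    lfcSE = 1,
                    pvalue = c(0.001, 0.05, 1e-10, 0.001),
                    padj = c(0.01, 0.05, 1e-10, 0.01))
  attr(tab, "contrast") <- "x"
  set <- call_degs(tab)
  expect_true("a" %in% set$genes)         # log2FC exactly 1.0 included
  expect_false("b" %in% set$genes)        # padj exactly 0.05 excluded
  expect_false("c" %in% set$genes)        # small lfc excluded at any padj
  expect_identical(unname(set$sign[c("a", "d")]), c(1, -1))
})

test_that("DEG sets shrink as thresholds tighten", {
  fx <- nb_two_group(G = 800, n = 3, disp = 0.1, lfc = 1.5, seed = 27)
  f <- size_factors(fx$counts)
  d <- estimate_dispersion(fx$counts, fx$design, f)
  tab <- wald_test(fx$counts, fx$design,
                   contrast_spec("c", c("T", 4), c("C", 4)), f,
                   d$dispersion)
  loose <- call_degs(tab, lfc_min = 0.5, padj_max = 0.1)
  mid <- call_degs(tab, lfc_min = 1.0, padj_max = 0.1)
  tight <- call_degs(tab, lfc_min = 1.0, padj_max = 0.01)
  expect_true(all(mid$genes %in% loose$genes))
  expect_true(all(tight$genes %in% mid$genes))
})

test_that("integer rescaling of one sample leaves calls unchanged", {
  fx <- nb_two_group(G = 500, n = 3, disp = 0.1, lfc = 2, seed = 28)
  scaled <- fx$counts
  scaled[, 1] <- scaled[, 1] * 3L
  run <- function(m) {
    f <- size_factors(m)
    d <- estimate_dispersion(m, fx$design, f)
    call_degs(wald_test(m, fx$design,
                        contrast_spec("c", c("T", 4), c("C", 4)), f,
                        d$dispersion))$genes
  }
  a <- run(fx$counts); b <- run(scaled)
  # exact integer scaling is absorbed by the size factors
  expect_gt(length(intersect(a, b)) / length(union(a, b)), 0.95)
})
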