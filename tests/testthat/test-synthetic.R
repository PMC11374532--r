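test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(n_reps = 1), "n_reps")
  expect_error(sim_config(days = c(1, 2)), "days")
  expect_error(sim_config(class_fractions = c(null = 0.5, ns_equal = 0.2,
                                              cppu_only = 0.1,
                                              both_diff = 0.1,
                                              ns_suppressed = 0.2)),
               "sum to 1")
})

test_that("all-null class mass yields no planted genes", {
  cfg <- sim_config(n_genes = 50, n_tfs = 0,
                    class_fractions = c(null = 1, ns_equal = 0,
                                        cppu_only = 0, both_diff = 0,
                                        ns_suppressed = 0),
                    seed = 42)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$truth$classes == "null"))
})

test_that("identical config and seed reproduce counts exactly", {
  cfg <- sim_config(n_genes = 100, seed = 7)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$classes, s2$truth$classes)
  s3 <- simulate_counts(sim_config(n_genes = 100, seed = 8))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("realized treatment effect of cppu_only genes matches the plant", {
  cfg <- sim_config(n_genes = 2000, effect_lfc = 2.0, dispersion = 0.1,
                    n_reps = 3, seed = 1)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  cp <- names(tr$classes)[tr$classes == "cppu_only"]
  d <- sim$design
  y <- sweep(sim$counts, 2, tr$lib_factors, `/`)
  s_t4 <- d$sample[d$condition == "T" & d$day == 4]
  s_c0 <- d$sample[d$condition == "C" & d$day == 0]
  ratio <- log2(rowMeans(y[cp, s_t4])) - log2(rowMeans(y[cp, s_c0]))
  expect_lt(abs(mean(abs(ratio)) - 2.0), 0.15)
})

test_that("generative means reproduce each class's intended Venn pattern", {
  cfg <- sim_config(n_genes = 400, seed = 3)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  # exclude genes whose means were overlaid by a planted TF edge
  excl <- if (!is.null(tr$edges)) tr$edges$target else character(0)
  lfc <- function(g, num, den) tr$cell_log2[g, num] - tr$cell_log2[g, den]
  for (g in setdiff(names(tr$classes), excl)) {
    a <- abs(lfc(g, "C4", "C0")) >= 1   # NS member at day 4
    b <- abs(lfc(g, "T4", "C0")) >= 1   # TS member
    x <- abs(lfc(g, "T4", "C4")) >= 1   # TC member
    want <- switch(tr$classes[g],
                   null = c(FALSE, FALSE, FALSE),
                   ns_equal = c(TRUE, TRUE, FALSE),
                   cppu_only = c(FALSE, TRUE, TRUE),
                   both_diff = c(TRUE, TRUE, TRUE),
                   ns_suppressed = c(TRUE, FALSE, TRUE))
    expect_identical(c(a, b, x), want)
  }
})

test_that("planted promoter motifs land at the recorded coordinates", {
  cfg <- sim_config(seed = 1)
  motifs <- data.frame(id = "MYBBS", library = "libA", consensus = "TAACCA")
  res <- simulate_promoters(
    cfg, motifs, genes = "GX",
    plant = data.frame(gene = "GX", motif = "MYBBS", start = -1594,
                       strand = "+"))
  s <- res$promoters[["GX"]]
  expect_identical(nchar(s), 2000L)
  # ATG-relative start -1594 in a 2000 bp promoter = string offset 406
  # (0-based), i.e. characters 407..412
  expect_identical(substr(s, 407, 412), "TAACCA")
  expect_equal(res$motif_truth$end, -1589)

  res_m <- simulate_promoters(
    cfg, motifs, genes = "GY",
    plant = data.frame(gene = "GY", motif = "MYBBS", start = -1594,
                       strand = "-"))
  expect_identical(substr(res_m$promoters[["GY"]], 407, 412), "TGGTTA")
})

test_that("scrubbed backgrounds contain no stray consensus occurrences", {
  cfg <- sim_config(promoter_length = 1000, seed = 9)
  motifs <- data.frame(id = "M1", library = "libA", consensus = "TAAC")
  res <- simulate_promoters(cfg, motifs, genes = paste0("P", 1:5),
                            plant = data.frame(gene = character(0),
                                               motif = character(0),
                                               start = integer(0),
                                               strand = character(0)))
  hits <- scan_motifs(res$promoters, motifs)
  expect_identical(nrow(hits), 0L)
})

test_that("motif longer than the promoter is a config error", {
  cfg <- sim_config(promoter_length = 5, seed = 1)
  motifs <- data.frame(id = "M1", library = "libA", consensus = "TAACCA")
  expect_error(simulate_promoters(cfg, motifs, genes = "G1"), "config")
})

test_that("zero-coefficient edges leave targets independent of their TF", {
  cfg <- sim_config(n_genes = 500, edge_coef = 0, seed = 4)
  sim <- simulate_counts(cfg)
  y <- log2(sweep(sim$counts, 2, sim$truth$lib_factors, `/`) + 1)
  r <- mapply(function(tf, tg) cor(y[tf, ], y[tg, ]),
              sim$truth$edges$tf, sim$truth$edges$target)
  # under independence at n = 27 samples, sd(r) ~ 1/sqrt(26) ~ 0.2
  expect_lt(mean(abs(r)), 0.25)
  expect_true(all(abs(r) < 0.6))
})

test_that("a strong noise-free edge drives target correlation to 1", {
  cfg <- sim_config(n_genes = 300, edge_coef = 4, edge_noise_sd = 0,
                    dispersion = 0.001, seed = 5)
  sim <- simulate_counts(cfg)
  y <- log2(sweep(sim$counts, 2, sim$truth$lib_factors, `/`) + 1)
  r <- mapply(function(tf, tg) cor(y[tf, ], y[tg, ]),
              sim$truth$edges$tf, sim$truth$edges$target)
  expect_true(all(r > 0.95))
})

test_that("the planted annotation term is concentrated in cppu_only genes", {
  cfg <- sim_config(n_genes = 1000, seed = 6)
  sim <- simulate_counts(cfg)
  anno <- simulate_annotation(cfg, sim$truth)
  memb <- anno$gene[anno$term == "CK_PROCESS"]
  cls <- sim$truth$classes[memb]
  expect_gt(mean(cls == "cppu_only"), 0.5)
})

test_that("the written input bundle is complete and recountable", {
  dir <- file.path(tempdir(), "bundle-recount")
  cfg <- sim_config(n_genes = 150, seed = 11)
  bundle <- simulate_inputs(cfg, dir)
  for (f in c("counts.tsv", "design.tsv", "gene_lengths.tsv",
              "promoters.fa", "motifs.tsv", "annotation.tsv",
              "tf_families.tsv", "truth.json", "MANIFEST.json"))
    expect_true(file.exists(file.path(dir, f)))
  counts <- read_counts(file.path(dir, "counts.tsv"))
  expect_identical(counts, bundle$sim$counts)
  # truth labels recount to the multinomial draw in memory
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(c(table(unlist(truth$classes))),
               c(table(bundle$sim$truth$classes)))
})
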