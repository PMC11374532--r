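test_that("contrast families follow the TC/NS/TS orientation rules", {
  design <- make_design(sim_config(n_genes = 10, seed = 1))
  tc <- build_contrasts(design, "TC")
  expect_length(tc, 4)
  expect_true(all(vapply(tc, function(s) s$num$condition, "") == "T"))
  expect_true(all(vapply(tc, function(s) s$den$condition, "") == "C"))
  expect_equal(vapply(tc, function(s) s$num$day, 1), c(1, 2, 4, 8),
               ignore_attr = TRUE)
  ns <- build_contrasts(design, "NS")
  expect_true(all(vapply(ns, function(s) s$den$condition, "") == "C"))
  expect_true(all(vapply(ns, function(s) s$den$day, 1) == 0))
  ts <- build_contrasts(design, "TS")
  expect_true(all(vapply(ts, function(s) s$num$condition, "") == "T"))
  expect_true(all(vapply(ts, function(s) s$den$day, 1) == 0))
  expect_error(build_contrasts(design, "XX"), "unknown strategy")
  # a missing cell is named in the error
  expect_error(build_contrasts(design[design$condition != "T" |
                                        design$day != 4, ], "TC"),
               "T, 4")
})

test_that("the worked three-set example classifies as expected", {
  rec <- vdeg_classify(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
                       X = c("g3", "g4", "g5"), day = 1)
  expect_identical(rec$gene[rec$class == "g"], "g3")
  expect_identical(rec$gene[rec$class == "f"], "g4")
  expect_identical(rec$gene[rec$class == "e"], character(0))
  expect_identical(sort(rec$gene), c("g3", "g4"))  # g1, g2, g5 excluded
})

test_that("VDEG classification equals brute-force pattern enumeration", {
  set.seed(31)
  pool <- sprintf("g%03d", 1:60)
  for (i in 1:200) {
    A <- sample(pool, rpois(1, 15))
    B <- sample(pool, rpois(1, 15))
    X <- sample(pool, rpois(1, 15))
    rec <- vdeg_classify(A, B, X, day = 4)
    oracle <- vdeg_brute(A, B, X)
    expect_identical(rec$class[order(rec$gene)],
                     oracle$class[order(oracle$gene)])
    # closed form: VDEG union is X intersect (A union B)
    expect_identical(sort(rec$gene), sort(intersect(X, union(A, B))))
  }
})

test_that("the e/f/g classes partition the VDEG set", {
  set.seed(32)
  pool <- sprintf("g%03d", 1:40)
  for (i in 1:50) {
    rec <- vdeg_classify(sample(pool, 12), sample(pool, 12),
                         sample(pool, 12), day = 2)
    expect_identical(anyDuplicated(rec$gene), 0L)
  }
  # X empty means no VDEGs at all
  expect_identical(nrow(vdeg_classify(c("a", "b"), c("b", "c"),
                                      character(0), 1)), 0L)
  # A = B = X = {g1} puts g1 in class g
  one <- vdeg_classify("g1", "g1", "g1", 1)
  expect_identical(one$class, "g")
})

test_that("overlap-d genes never become VDEGs when added to A and B", {
  A <- c("g1", "g2"); B <- c("g2", "g3"); X <- c("g3")
  before <- vdeg_classify(A, B, X, 1)
  after <- vdeg_classify(c(A, "new"), c(B, "new"), X, 1)
  expect_identical(sort(before$gene), sort(after$gene))
})

test_that("direction comes from the same-day T-over-C fold change", {
  rec <- data.frame(gene = c("g1", "g2"), day = 1,
                    class = c("f", "e"), stringsAsFactors = FALSE)
  tab <- data.frame(gene = c("g1", "g2"), baseMean = 5,
                    log2FC = c(2.3, -1.1), lfcSE = 0.2,
                    pvalue = c(1e-5, 1e-4), padj = c(1e-4, 1e-3))
  out <- vdeg_direction(rec, tab)
  expect_identical(out$direction, c("up", "down"))
  expect_error(vdeg_direction(data.frame(gene = "gX", day = 1, class = "f"),
                              tab), "missing")
})

test_that("cross-period sharing tallies directions independently", {
  mk <- function(genes, dir) data.frame(gene = genes,
                                        direction = dir,
                                        stringsAsFactors = FALSE)
  per_day <- list(`1` = mk(c("a", "b"), c("up", "up")),
                  `2` = mk(c("a", "b"), c("up", "up")),
                  `4` = mk(c("a", "flip"), c("up", "up")),
                  `8` = mk(c("flip"), c("down")))
  sh <- shared_across_periods(per_day, k = 3)
  expect_identical(sh$up, "a")       # three periods up
  expect_identical(sh$down, character(0))
  # two periods only is not enough
  expect_false("b" %in% sh$up)
  # a k larger than the day count is an error
  expect_error(shared_across_periods(per_day, k = 5), "exceeds")
  # direction flips keep tallies separate
  per_day$`1` <- mk("flip", "up"); per_day$`2` <- mk("flip", "up")
  sh2 <- shared_across_periods(per_day, k = 3)
  expect_true("flip" %in% sh2$up)
  expect_false("flip" %in% sh2$down)
})

test_that("Venn summaries match a brute-force membership tally", {
  two <- venn_summary(list(s1 = "a", s2 = "b"))
  expect_equal(two$regions$count[two$regions$pattern == "10"], 1)
  expect_equal(two$regions$count[two$regions$pattern == "01"], 1)
  expect_equal(two$regions$count[two$regions$pattern == "11"], 0)

  four <- venn_summary(rep(list(sprintf("g%d", 1:7)), 4))
  expect_equal(four$all_intersection, 7)
  expect_equal(four$union, 7)

  set.seed(33)
  pool <- sprintf("g%02d", 1:30)
  for (i in 1:25) {
    sets <- lapply(1:3, function(j) sample(pool, sample(3:15, 1)))
    vs <- venn_summary(sets)
    oracle <- venn_brute(sets)
    for (pat in names(oracle))
      expect_equal(vs$regions$count[vs$regions$pattern == pat],
                   unname(c(oracle[pat])))
    expect_equal(sum(vs$regions$count), vs$union)
  }
  expect_error(venn_summary(rep(list("a"), 6)), "upset")
  expect_identical(nrow(venn_summary(rep(list("a"), 6),
                                     upset = TRUE)$regions), 63L)
})
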