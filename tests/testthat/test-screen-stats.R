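test_that("the rescue index reproduces worked examples and pooling arithmetic", {
  tr <- data.frame(n_scored = 8, n_crossed = 5)
  ct <- data.frame(n_scored = 8, n_crossed = 2)
  expect_equal(rescue_index(tr, ct), 2.5)
  expect_equal(rescue_index(ct, ct), 1.0)
  # hand-pooled counts: (12/24) / (6/24) = 2
  tr3 <- data.frame(n_scored = c(8, 8, 8), n_crossed = c(3, 5, 4))
  ct3 <- data.frame(n_scored = c(8, 8, 8), n_crossed = c(2, 2, 2))
  expect_equal(rescue_index(tr3, ct3), 2.0)
  expect_equal(rescue_index(tr3, ct3, method = "per_embryo"), 2.0)
  expect_error(rescue_index(data.frame(n_scored = 8, n_crossed = 9), ct),
               "n_crossed")
})

test_that("a zero control crossing fraction flags the index as undefined", {
  tr <- data.frame(n_scored = 8, n_crossed = 5)
  c0 <- data.frame(n_scored = 8, n_crossed = 0)
  expect_warning(ri <- rescue_index(tr, c0), "undefined")
  expect_true(is.na(ri))
  expect_match(attr(ri, "reason"), "zero")
})

test_that("the rescue index is invariant under scaling the embryo counts", {
  set.seed(7)
  for (i in 1:20) {
    tr <- data.frame(n_scored = rep(8, 6), n_crossed = sample(0:8, 6, TRUE))
    ct <- data.frame(n_scored = rep(8, 6), n_crossed = sample(1:8, 6, TRUE))
    k <- sample(2:5, 1)
    expect_equal(rescue_index(tr[rep(1:6, k), ], ct[rep(1:6, k), ]),
                 rescue_index(tr, ct))
  }
})

test_that("hit calling is inclusive at the threshold and monotone", {
  res <- data.frame(rescue_index = c(2.5, 2.49, 3.1, NA, 4.0),
                    excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  h <- call_hits(res)
  expect_equal(h$hit, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # monotone: raising RI never turns a hit into a non-hit
  ri <- sort(runif(50, 0, 5))
  hits <- call_hits(data.frame(rescue_index = ri))$hit
  expect_false(is.unsorted(hits))
})

test_that("toxicity exclusion partitions compounds and reports percentages", {
  rec <- data.frame(
    compound_id = sprintf("C%04d", 1:982),
    toxicity = c(rep("death", 47), rep("delayed", 22), rep("malformed", 13),
                 rep("none", 900)))
  ex <- exclude_toxic(rec)
  expect_equal(nrow(ex$kept), 900L)
  expect_equal(nrow(ex$kept) + nrow(ex$excluded), 982L)
  tot <- ex$summary[ex$summary$category == "total_excluded", ]
  expect_equal(tot$n_compounds, 82L)
  expect_equal(tot$percent, 100 * 82 / 982)
  # no toxic records
  ex0 <- exclude_toxic(data.frame(compound_id = "a", toxicity = "none"))
  expect_equal(nrow(ex0$excluded), 0L)
  # random flags still partition
  set.seed(1)
  recr <- data.frame(compound_id = sprintf("C%03d", 1:50),
                     toxicity = sample(c("none", "death", "delayed"), 50, TRUE))
  exr <- exclude_toxic(recr)
  expect_equal(nrow(exr$kept) + nrow(exr$excluded), 50L)
})

test_that("percent-of-control length follows the reported arithmetic", {
  expect_equal(percent_of_control(c(40, 42), c(40, 42)), 100)
  expect_equal(percent_of_control(47.331, 35.06), 135, tolerance = 1e-6)
  expect_warning(p0 <- percent_of_control(10, 0), "undefined")
  expect_true(is.na(p0))
  expect_error(percent_of_control(numeric(0), 1), "non-empty")
})

test_that("the normality gate selects parametric and non-parametric branches", {
  set.seed(10)
  g_norm <- list(ctrl = rnorm(50), trt = rnorm(50, 0.2))
  r1 <- compare_groups(g_norm)
  expect_equal(r1$gate, "parametric")
  expect_equal(r1$test, "Student t-test")
  g_log <- list(ctrl = rlnorm(50), trt = rlnorm(50))
  r2 <- compare_groups(g_log)
  expect_equal(r2$gate, "non-parametric")
  expect_equal(r2$test, "Mann-Whitney U")
  # three groups
  g3 <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 0.5))
  r3 <- compare_groups(g3, design = "vs-control")
  expect_match(r3$test, "Dunnett")
  expect_equal(nrow(r3$posthoc), 2L)
  r3t <- compare_groups(g3, design = "all-pairs")
  expect_match(r3t$test, "Tukey")
  expect_equal(nrow(r3t$posthoc), 3L)
  g3l <- list(a = rlnorm(30), b = rlnorm(30), c = rlnorm(30))
  r3d <- compare_groups(g3l)
  expect_match(r3d$test, "Dunn")
  expect_error(compare_groups(list(a = 1:2, b = 1:5)), "n >= 3")
})

test_that("the two-group parametric branch reproduces the textbook t-test", {
  a <- c(1, 2, 3); b <- c(2, 4, 5)
  r <- compare_groups(list(ctrl = a, trt = b))
  # hand-computed Student t with pooled SD
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  tt <- (mean(b) - mean(a)) / (sp * sqrt(2 / 3))
  p <- 2 * pt(-abs(tt), 4)
  expect_equal(r$p_value, p, tolerance = 1e-6)
  expect_equal(r$statistic, tt, tolerance = 1e-6)
})

test_that("Dunn's test matches hand-computed rank statistics", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- factor(rep(c("a", "b", "c"), each = 3), levels = c("a", "b", "c"))
  dn <- capscreen:::.dunn_test(vals, grp, cbind(c("b", "c"), c("a", "a")))
  # rank means 2, 5, 8; Var = N(N+1)/12 = 7.5; se = sqrt(7.5 * 2/3) = sqrt(5)
  expect_equal(dn$z, c(3 / sqrt(5), 6 / sqrt(5)), tolerance = 1e-8)
  expect_equal(dn$p_value,
               pmin(1, 2 * 2 * pnorm(-abs(c(3, 6) / sqrt(5)))),
               tolerance = 1e-8)
})

test_that("post-hoc power matches a Monte-Carlo oracle and is monotone", {
  expect_equal(posthoc_power(c(30, 30), c(1, 1), c(1, 1)), 0.05)
  set.seed(42)
  mc <- mc_power_ttest(30, 30, 1, reps = 50000)
  expect_lt(abs(posthoc_power(c(30, 30), c(0, 1), c(1, 1)) - mc), 0.01)
  # monotone in n and effect size
  p_n <- sapply(c(10, 20, 40, 80), function(n)
    posthoc_power(c(n, n), c(0, 0.5), c(1, 1)))
  expect_false(is.unsorted(p_n))
  p_d <- sapply(c(0.2, 0.5, 0.8, 1.2), function(d)
    posthoc_power(c(20, 20), c(0, d), c(1, 1)))
  expect_false(is.unsorted(p_d))
  expect_warning(pw <- posthoc_power(c(5, 5), c(1, 1), c(0, 0)), "zero")
  expect_true(is.na(pw))
  # k > 2: zero effect gives alpha
  expect_equal(posthoc_power(c(10, 10, 10), c(1, 1, 1), c(1, 1, 1)), 0.05)
})

test_that("compare_groups reports observed power alongside the tests", {
  set.seed(5)
  g <- list(ctrl = rnorm(30), trt = rnorm(30, 1))
  r <- compare_groups(g)
  expect_gt(r$power, 0.5)
  expect_lte(r$power, 1)
})
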