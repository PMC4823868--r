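test_that("js_distance hits its analytic values and bounds", {
  p <- rep(1 / 6, 6)
  expect_equal(js_distance(p, p), 0)
  e1 <- c(1, 0, 0, 0, 0, 0)
  e6 <- c(0, 0, 0, 0, 0, 1)
  expect_equal(js_distance(e1, e6), 1)
  # uniform vs delta over six tissues, base-2 closed form:
  # JSD = (1 - log2(7)/6 + log2(12/7)) / 2, distance = sqrt(JSD)
  closed <- sqrt(((1 - log2(7) / 6) + log2(12 / 7)) / 2)
  expect_equal(js_distance(p, e1), closed, tolerance = 1e-12)
  expect_equal(js_distance(p, e1), 0.809233, tolerance = 1e-5)

  expect_error(js_distance(c(0.5, 0.5), c(1, 0, 0)),
               class = "circscan_domain_error")
  expect_error(js_distance(c(0.5, 0.5), c(1.5, -0.5)),
               class = "circscan_domain_error")
})

test_that("js_distance is a metric on random simplex vectors", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    rp <- function() { v <- rexp(n); v / sum(v) }
    p <- rp(); q <- rp(); r <- rp()
    dpq <- js_distance(p, q)
    expect_equal(dpq, js_distance(q, p))
    expect_gte(dpq, 0)
    expect_lte(dpq, 1)
    expect_lte(js_distance(p, r), dpq + js_distance(q, r) + 1e-12)
  }
  expect_equal(js_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
})

test_that("specificity scores attain their bounds and are equivariant", {
  tissues <- c("brain", "colon", "heart", "liver", "lung", "stomach")
  m <- rbind(only_brain = c(8, 0, 0, 0, 0, 0),
             not_brain = c(0, 2, 2, 2, 2, 2),
             flat = rep(3, 6))
  colnames(m) <- tissues
  sp <- specificity_scores(m, tissues)
  expect_equal(sp$best$best_score[sp$best$circ_id == "only_brain"], 1)
  expect_equal(sp$best$best_tissue[sp$best$circ_id == "only_brain"], "brain")
  expect_equal(sp$scores["not_brain", "brain"], 0)

  perm <- c(3, 1, 2, 6, 4, 5)
  sp2 <- specificity_scores(m[, perm], tissues[perm])
  expect_equal(sp2$scores[, tissues], sp$scores[, tissues])
})

test_that("replicate columns are averaged per tissue before scoring", {
  m <- cbind(b1 = c(4, 0), b2 = c(8, 0), h1 = c(0, 2), h2 = c(0, 4))
  rownames(m) <- c("cb", "ch")
  sp <- specificity_scores(m, c("brain", "brain", "heart", "heart"))
  expect_equal(unname(sp$tissue_means["cb", ]), c(6, 0))
  expect_equal(sp$best$best_score, c(1, 1))
})

test_that("all-zero profiles are excluded and reported", {
  m <- rbind(a = c(1, 1), z = c(0, 0))
  sp <- specificity_scores(m, c("t1", "t2"))
  expect_equal(sp$excluded, "z")
  expect_false("z" %in% sp$best$circ_id)
})

test_that("the specificity filter combines score and expression floors", {
  tissues <- paste0("t", 1:4)
  set.seed(8)
  base <- matrix(rexp(40 * 4, 1), 40, 4,
                 dimnames = list(sprintf("bg%02d", 1:40), tissues))
  planted <- matrix(0, 2, 4, dimnames = list(c("sp1", "sp2"), tissues))
  planted["sp1", 1] <- 1000
  planted["sp2", 3] <- 800
  m <- rbind(base, planted)
  sp <- specificity_scores(m, tissues)
  kept <- specific_circ_filter(sp)
  expect_setequal(kept$circ_id, c("sp1", "sp2"))

  # degenerate thresholds keep every scored circRNA
  all_kept <- specific_circ_filter(sp, min_score = 0, level_rule = -Inf)
  expect_equal(nrow(all_kept), nrow(sp$best))

  # high score but level below the floor is dropped
  m2 <- rbind(base * 1000, tiny = c(0.001, 0, 0, 0))
  sp2 <- specificity_scores(m2, tissues)
  expect_false("tiny" %in% specific_circ_filter(sp2)$circ_id)
})

test_that("poisson cutoffs match a hand-computed CDF", {
  # independent oracle: sum the Poisson pmf terms directly
  cdf_below <- function(c, lambda) {
    sum(exp(-lambda) * lambda^(0:(c - 1)) / factorial(0:(c - 1)))
  }
  counts08 <- c(rep(0, 6), rep(2, 4))               # fitted lambda = 0.8
  expect_equal(poisson_cutoff(counts08), 4L)
  expect_gte(cdf_below(4, 0.8), 0.99)
  expect_lt(cdf_below(3, 0.8), 0.99)

  counts1 <- rep(1, 20)
  expect_equal(poisson_cutoff(counts1), 5L)
  expect_gte(cdf_below(5, 1), 0.99)
  expect_lt(cdf_below(4, 1), 0.99)

  expect_equal(poisson_cutoff(c(5, 3), retain = 0), 1L)
  expect_error(poisson_cutoff(c(0, 0)), class = "circscan_domain_error")
})

test_that("poisson cutoff is non-decreasing in lambda and retain", {
  lambdas <- seq(0.2, 6, by = 0.2)
  cuts <- vapply(lambdas, function(l) poisson_cutoff(rep(l, 5)), 1L)
  expect_true(all(diff(cuts) >= 0))
  retains <- c(0.5, 0.9, 0.99, 0.999)
  cuts2 <- vapply(retains, function(r) poisson_cutoff(rep(1.5, 5), retain = r), 1L)
  expect_true(all(diff(cuts2) >= 0))
})

test_that("condition-specific calls need reads in one condition only", {
  cc <- c(a = 5L, b = 5L, c = 0L, d = 3L)
  nc <- c(a = 0L, b = 1L, c = 4L, d = 0L)
  res <- condition_specific(cc, nc)
  expect_equal(res$cancer_specific, "a")   # b fails: normal reads present
  expect_equal(res$normal_specific, "c")   # d fails: below the cutoff
})

test_that("rank-sum enumeration matches its closed cases and wilcox.test", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$statistic, 0)
  expect_equal(rs$p.value, 0.1)   # 2 of the 20 labelings are as extreme

  same <- rank_sum_test(c(2, 2, 5), c(2, 5, 2))
  expect_equal(same$p.value, 1)

  set.seed(12)
  for (i in 1:10) {
    x <- round(rnorm(5), 3); y <- round(rnorm(6) + 0.5, 3)  # tie-free
    mine <- rank_sum_test(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic))
  }
})

test_that("two-sided rank-sum p is invariant under swapping the groups", {
  set.seed(13)
  for (i in 1:10) {
    x <- rpois(sample(3:6, 1), 4); y <- rpois(sample(3:6, 1), 6)
    expect_equal(rank_sum_test(x, y)$p.value, rank_sum_test(y, x)$p.value)
  }
})

test_that("the normal approximation tracks exact enumeration at n=12", {
  cases <- list(
    list(x = c(-3, 3.34, -3.02, -1.17, -1.33, 0.59),
         y = c(-1.18, 2.85, 0.37, 0.3, 1.58, 3.8)),          # p ~ 0.18
    list(x = c(-0.04, -1.8, 0.36, -2.17, -3.12, -1.63),
         y = c(0.32, 3.93, 1.38, 3.76, 2.49, -2.08)),        # p ~ 0.04
    list(x = c(-1.61, -0.93, 1.69, 3.74, -1.24, 5.34),
         y = c(2.84, -0.29, 1.02, 2.06, -2.59, 0.9)))        # p ~ 0.94
  for (cs in cases) {
    exact <- rank_sum_test(cs$x, cs$y)$p.value
    approx <- rank_sum_test(cs$x, cs$y, exact_max = 0)$p.value
    expect_lt(abs(exact - approx), 0.01)
  }
})

test_that("pearson correlation handles exact and null cases", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_error(pearson_cor(x, rep(3, 10)), class = "circscan_domain_error")

  set.seed(15)
  inside <- vapply(1:100, function(i) {
    abs(pearson_cor(rnorm(100), rnorm(100))$r) < 0.3
  }, TRUE)
  expect_gte(mean(inside), 0.95)
})

test_that("differential abundance detects a planted twofold shift", {
  set.seed(16)
  norm <- rexp(60, 1 / 5) + 1.5
  m <- cbind(N = norm, C = 2 * norm)
  rownames(m) <- sprintf("c%02d", 1:60)
  pairs <- data.frame(tissue = "liver", case = "C", control = "N",
                      stringsAsFactors = FALSE)
  res <- differential_abundance(m, pairs)
  expect_equal(res$direction, "up")
  expect_equal(res$median_log2fc, 1, tolerance = 0.01)
  expect_lt(res$p.value, 0.01)

  m2 <- cbind(N = norm, C = norm)
  res2 <- differential_abundance(m2, pairs)
  expect_equal(res2$median_log2fc, 0)
  expect_equal(res2$p.value, 1)

  # zero SRPBM in the control is guarded by the pseudo-value
  m3 <- cbind(N = c(x = 0, y = 5), C = c(x = 4, y = 5))
  res3 <- differential_abundance(m3, pairs)
  expect_true(is.finite(res3$median_log2fc))
})
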