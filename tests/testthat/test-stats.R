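test_that("Mann-Whitney exact p matches enumeration for separated samples", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)   # 2 * 1/choose(6,3)
  expect_equal(res$method, "exact")
})

test_that("identical tied samples give p = 1 under the approximation", {
  res <- mann_whitney(c(1, 2), c(1, 2))
  expect_equal(res$p_value, 1)
  expect_match(res$method, "tie")
})

test_that("exact Mann-Whitney agrees with brute-force permutation", {
  perm_p <- function(x, y) {
    n <- length(x); all_v <- c(x, y)
    u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    obs <- u_of(x, y)
    m <- length(all_v)
    combs <- utils::combn(m, n)
    mu <- n * length(y) / 2
    hits <- 0
    for (j in seq_len(ncol(combs))) {
      u <- u_of(all_v[combs[, j]], all_v[-combs[, j]])
      if (abs(u - mu) >= abs(obs - mu) - 1e-12) hits <- hits + 1
    }
    hits / ncol(combs)
  }
  set.seed(14)
  for (i in 1:12) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- round(rnorm(nx, 0, 10), 3); y <- round(rnorm(ny, 2, 10), 3)
    if (anyDuplicated(c(x, y))) next
    res <- mann_whitney(x, y)
    expect_equal(res$p_value, perm_p(x, y), tolerance = 1e-12,
                 label = sprintf("case %d", i))
  }
  expect_error(mann_whitney(numeric(), 1:3), "empty")
})

test_that("Spearman correlation hits the monotone extremes", {
  x <- c(2, 5, 9, 11, 20)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, -x^3)$rho, -1)
  set.seed(8)
  r <- spearman_rho(runif(1000), runif(1000))
  expect_lt(abs(r$rho), 0.1)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("two repeated measures force Greenhouse-Geisser epsilon of one", {
  set.seed(2)
  m <- matrix(rnorm(20), 10, 2)
  res <- rm_anova_gg(m, rep(c("a", "b"), each = 5))
  expect_equal(res$epsilon[res$effect == "measure"], 1)
})

test_that("uncorrected ANOVA is recovered when epsilon is one", {
  set.seed(6)
  m <- matrix(rnorm(24), 12, 2)
  g <- rep(c("a", "b"), each = 6)
  res <- rm_anova_gg(m, g)
  # with k = 2 the within test reduces to a paired comparison: check F via aov
  d <- data.frame(y = as.vector(m), subj = factor(rep(1:12, 2)),
                  meas = factor(rep(1:2, each = 12)), grp = factor(rep(g, 2)))
  av <- summary(stats::aov(y ~ grp * meas + Error(subj / meas), data = d))
  f_ref <- av[["Error: subj:meas"]][[1]]["meas", "F value"]
  expect_equal(res$statistic[res$effect == "measure"], f_ref,
               tolerance = 1e-10)
  f_grp <- av[["Error: subj"]][[1]]["grp", "F value"]
  expect_equal(res$statistic[res$effect == "group"], f_grp, tolerance = 1e-10)
})

test_that("group relabelling does not change any p-value", {
  set.seed(13)
  m <- matrix(rnorm(40), 10, 4)
  g1 <- rep(c("young", "elderly"), each = 5)
  g2 <- rep(c("zzz", "aaa"), each = 5)
  expect_equal(rm_anova_gg(m, g1)$p_value, rm_anova_gg(m, g2)$p_value)
  x <- rnorm(6); y <- rnorm(6)
  expect_equal(mann_whitney(x, y)$p_value, mann_whitney(y, x)$p_value)
})

test_that("a strong between-group shift is detected", {
  set.seed(23)
  k <- 5
  m <- matrix(rnorm(22 * k), 22, k)
  m[12:22, ] <- m[12:22, ] + 3          # 3 within-subject SDs
  g <- rep(c("young", "elderly"), c(11, 11))
  res <- rm_anova_gg(m, g)
  expect_lt(res$p_value[res$effect == "group"], 0.001)
})

test_that("log transform triggers only on non-normal samples", {
  set.seed(16)
  norm_sample <- rnorm(50)
  r1 <- log_transform_if_nonnormal(norm_sample)
  expect_false(r1$transformed)
  expect_identical(r1$values, norm_sample)

  logn <- exp(rnorm(50, 0, 1.5))
  r2 <- log_transform_if_nonnormal(logn)
  expect_true(r2$transformed)
  expect_equal(r2$values, log(logn))

  bad <- c(exp(rnorm(49, 0, 2)), 0)
  expect_error(log_transform_if_nonnormal(bad), "non-positive")
})
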