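test_that("rm_correlation removes between-subject offsets", {
  # opposed offsets, identical within-subject slopes -> r = 1, df = 3
  rc <- rm_correlation(x = c(1, 2, 3, 4, 5, 6),
                       y = c(11, 12, 13, 1, 2, 3),
                       subject = c("A", "A", "A", "B", "B", "B"))
  expect_equal(rc$r, 1)
  expect_equal(rc$df, 3L)

  # one subject: equals ordinary Pearson
  set.seed(4)
  x <- rnorm(20); y <- 0.6 * x + rnorm(20)
  rc1 <- rm_correlation(x, y, rep("A", 20))
  expect_equal(rc1$r, cor(x, y))
  expect_equal(rc1$df, 18L)
  expect_equal(rc1$p, cor.test(x, y)$p.value, tolerance = 1e-12)

  # invariance to per-subject additive offsets
  subj <- rep(c("A", "B", "C"), each = 7)
  x2 <- rnorm(21); y2 <- rnorm(21)
  off <- c(A = 0, B = 50, C = -30)
  rc_a <- rm_correlation(x2, y2, subj)
  rc_b <- rm_correlation(x2 + off[subj], y2 - 2 * off[subj], subj)
  expect_equal(rc_a$r, rc_b$r)
  expect_equal(rc_a$p, rc_b$p)
})

test_that("rm_correlation drops singleton subjects with a warning", {
  expect_warning(
    rc <- rm_correlation(c(1, 2, 3, 4, 9), c(1, 2, 3, 4, 2),
                         c("A", "A", "B", "B", "C")),
    "dropping")
  expect_equal(rc$n_subjects, 2L)
  expect_error(suppressWarnings(
    rm_correlation(c(1, 9), c(1, 2), c("A", "C"))), "observations")
})

test_that("spearman screen is invariant under monotone transforms", {
  set.seed(8)
  x <- rnorm(7)
  night <- data.frame(animal_id = paste0("p", 1:7), m1 = x)
  post <- data.frame(animal_id = paste0("p", 1:7),
                     up = exp(x), down = -x^3)
  sc <- spearman_screen(night, post)
  expect_equal(sc$rho[sc$post_metric == "up"], 1)
  expect_equal(sc$rho[sc$post_metric == "down"], -1)
  expect_true(all(sc$flag %in% c("significant", "trend", "ns")))
  expect_true(all(sc$p >= 0 & sc$p <= 1))
  # flags honour the 0.05 / 0.10 thresholds
  expect_identical(sc$flag, ifelse(sc$p <= 0.05, "significant",
                                   ifelse(sc$p <= 0.10, "trend", "ns")))
})

test_that("spearman screen skips constant metrics and needs 4 animals", {
  night <- data.frame(animal_id = paste0("p", 1:5), m1 = rnorm(5),
                      flat = rep(1, 5))
  post <- data.frame(animal_id = paste0("p", 1:5), y = rnorm(5))
  expect_warning(sc <- spearman_screen(night, post), "constant")
  expect_false("flat" %in% sc$night_metric)
  expect_error(spearman_screen(night[1:3, ], post[1:3, ]), "4 matched")
})

test_that("one-way ANOVA agrees with the pooled t-test identity", {
  set.seed(12)
  a <- rnorm(8, 100, 5); b <- rnorm(9, 110, 5)
  res <- diet_anova(c(a, b), rep(c("HS", "HF"), c(8, 9)))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  # identical groups: F = 0, p = 1
  g <- c(1, 2, 3)
  res0 <- diet_anova(c(g, g), rep(c("A", "B"), each = 3))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  expect_error(diet_anova(c(1, 2, 3), c("A", "A", "B")), "n >= 2")
})

test_that("ANOVA type-I error is calibrated at the nominal level", {
  set.seed(99)
  rej <- mean(replicate(500, {
    diet_anova(rnorm(16), rep(c("A", "B"), each = 8))$p <= 0.05
  }))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})

test_that("variance F-test matches hand values and var.test", {
  res <- variance_f_test(c(0, 2, 0, 2), c(0, 1, 0, 1))
  expect_equal(res$F, 4)  # (4/3) / (1/3)
  ref <- var.test(c(0, 2, 0, 2), c(0, 1, 0, 1))
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(variance_f_test(c(1, 5, 3), c(1, 5, 3))$F, 1)
  # reciprocal under argument swap
  set.seed(2)
  a <- rnorm(6); b <- rnorm(9, 0, 3)
  expect_equal(variance_f_test(a, b)$F, 1 / variance_f_test(b, a)$F)
  expect_equal(variance_f_test(a, b)$p, variance_f_test(b, a)$p,
               tolerance = 1e-12)
  expect_error(variance_f_test(a, c(2, 2, 2)), "zero variance")
})

test_that("PCA standardizes, decomposes and reconstructs", {
  set.seed(14)
  x <- rnorm(10)
  two <- data.frame(a = x, b = 3 * x + 5)        # perfectly correlated
  p2 <- pca_metrics(two)
  expect_equal(p2$explained[1], 1, tolerance = 1e-12)
  expect_equal(sum(p2$explained), 1)

  df <- as.data.frame(matrix(rnorm(60), ncol = 4))
  p <- pca_metrics(df)
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  z <- scale(as.matrix(df))
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, z, tolerance = 1e-9, ignore_attr = TRUE)

  df$flat <- 1
  expect_error(pca_metrics(df), "flat")
  expect_error(pca_metrics(df[1:2, 1:3]), ">= 3 rows")
})
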