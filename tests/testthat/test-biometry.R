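test_that("complete-case filtering reports each removal reason", {
  man <- generate_manifest(350, 11, 4, 3, seed = 5)
  kept <- suppressMessages(filter_complete(man))
  expect_equal(nrow(kept), 332)
  rem <- attr(kept, "removals")
  expect_equal(rem$n[rem$reason == "unrecorded"], 11)
  expect_equal(rem$n[rem$reason == "missing_weight"], 4)
  expect_equal(rem$n[rem$reason == "missing_body_size"], 3)

  # fully complete table passes through unchanged
  full <- generate_manifest(10, 0, 0, 0, seed = 6)
  expect_equal(nrow(suppressMessages(filter_complete(full))), 10)

  # one record missing only SC is removed as missing body size
  full$SC[4] <- NA
  kept2 <- suppressMessages(filter_complete(full))
  expect_equal(nrow(kept2), 9)
  expect_equal(attr(kept2, "removals")$n, c(0, 0, 1))
})

test_that("descriptive statistics are consistent with their definitions", {
  tab <- generate_trait_table(120, seed = 8)
  d <- describe_traits(tab)
  ewes_bw <- tab$BW[tab$sex == "female"]
  row <- d[d$trait == "BW" & d$sex == "female", ]
  expect_equal(row$mean, mean(ewes_bw))
  expect_equal(row$sd, stats::sd(ewes_bw))
  expect_equal(row$cv, 100 * stats::sd(ewes_bw) / mean(ewes_bw),
               tolerance = 1e-12)
  expect_equal(row$min, min(ewes_bw))
  expect_equal(row$max, max(ewes_bw))
  expect_equal(row$n, sum(tab$sex == "female"))
  # a constant column has zero SD and zero CV
  tab$SC <- 9
  d2 <- describe_traits(tab)
  expect_equal(d2$cv[d2$trait == "SC"], rep(0, 3))
})

test_that("spearman matches the rank formula, cor.test, and is monotone invariant", {
  expect_equal(spearman_test(1:10, 1:10)$rho, 1)
  expect_equal(spearman_test(1:10, 10:1)$rho, -1)
  withr::with_seed(31, {
    x <- stats::rnorm(20); y <- stats::rnorm(20)
    st <- spearman_test(x, y)
    # tie-free closed form: 1 - 6 sum(d^2) / (n (n^2-1))
    d <- rank(x) - rank(y)
    rho_closed <- 1 - 6 * sum(d^2) / (20 * (20^2 - 1))
    expect_equal(st$rho, rho_closed, tolerance = 1e-12)
    ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
    expect_equal(st$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(st$p, ref$p.value, tolerance = 1e-9)
    # invariance under strictly monotone transforms
    expect_equal(spearman_test(exp(x), y^3 + 5 * y)$rho,
                 spearman_test(x, y)$rho)
  })
  expect_warning(st0 <- spearman_test(rep(1, 5), 1:5), "constant")
  expect_true(is.na(st0$rho))
  expect_error(spearman_test(1:2, 1:2), "at least 3")
})

test_that("pairwise correlations carry significance stars", {
  tab <- generate_trait_table(150, seed = 12)
  cors <- trait_correlations(tab, traits = c("BW", "BSL", "CC"))
  expect_equal(nrow(cors), 3)
  strong <- cors[cors$trait1 == "BW" & cors$trait2 == "BSL", ]
  expect_gt(strong$rho, 0.3)
  expect_equal(strong$stars, "***")
  expect_s3_class(plot_correlations(tab, c("BW", "BSL", "CC")), "ggplot")
})

test_that("one-way ANOVA by sex behaves at both extremes", {
  # identical group means: F ~ 0
  tab0 <- tibble::tibble(sex = rep(c("male", "female"), each = 4),
                         HW = rep(c(60, 62, 64, 66), 2))
  a0 <- anova_by_sex(tab0, "HW")
  expect_lt(a0$F, 1e-20)
  # simulated flock: body weight differs strongly by sex
  hits <- 0
  for (s in 1:20) {
    tab <- generate_trait_table(332, seed = 500 + s)
    if (anova_by_sex(tab, "BW")$p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 19)
  expect_error(anova_by_sex(tab0[tab0$sex == "male", ], "HW"), "two non-empty")
})

test_that("OLS fitting recovers exact and noisy linear models", {
  # noise-free line
  df <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  fit <- suppressWarnings(ols_fit(df, "y", "x")) # perfect fit warns in summary.lm
  expect_equal(unname(stats::coef(fit$fit)), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(glance(fit)$mse, 0, tolerance = 1e-18)
  expect_equal(predict(fit, tibble::tibble(x = 20)), 41, tolerance = 1e-9)

  # duplicated predictor is dropped with a warning
  df$x2 <- df$x
  w <- testthat::capture_warnings(fit2 <- ols_fit(df, "y", c("x", "x2")))
  expect_true(any(grepl("collinear", w)))
  expect_equal(fit2$predictors, "x")

  # tidy() exposes the coefficient table
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$term, c("(Intercept)", "x"))
})

test_that("stepwise selection finds real structure and stops on noise", {
  withr::with_seed(41, {
    n <- 200
    x <- matrix(stats::rnorm(n * 6), n)
    colnames(x) <- paste0("v", 1:6)
    df <- tibble::as_tibble(x)
    df$BW <- 1.0 * df$v3 + stats::rnorm(n, 0, 1)
    path <- stepwise_bw(df, "BW", paste0("v", 1:6))
    expect_gte(nrow(path), 1)
    expect_equal(path$predictors[[1]], "v3") # true predictor enters first
    # R^2 non-decreasing along the path, adjusted R^2 never above R^2
    expect_true(all(diff(path$r.squared) >= -1e-12))
    expect_true(all(path$adj.r.squared <= path$r.squared + 1e-12))
  })

  # perfectly collinear pair with signal: exactly one of the pair enters
  withr::with_seed(43, {
    n <- 120
    z <- stats::rnorm(n)
    df <- tibble::tibble(a = z, b = z, BW = 2 * z + stats::rnorm(n, 0, 0.5))
    path <- stepwise_bw(df, "BW", c("a", "b"))
    expect_equal(length(path$predictors[[nrow(path)]]), 1)
  })

  # pure noise: usually nothing passes the entry test
  withr::with_seed(47, {
    empties <- 0
    for (s in 1:15) {
      n <- 150
      df <- tibble::tibble(a = stats::rnorm(n), b = stats::rnorm(n),
                           BW = stats::rnorm(n))
      p <- suppressMessages(stepwise_bw(df, "BW", c("a", "b")))
      if (nrow(p) == 0) empties <- empties + 1
    }
    expect_gte(empties, 11)
  })
  expect_error(stepwise_bw(tibble::tibble(a = 1:3, BW = 1:3), "BW", "a"),
               "need n >")
})

test_that("published weight equations predict the reported flock means", {
  pub <- published_weight_models()
  expect_equal(nrow(pub), 9)
  # ewe 3-predictor equation at the ewe trait means gives the ewe mean BW
  ewe_means <- tibble::tibble(BSL = 67.5, CC = 101.31, HH = 66.33)
  expect_lt(abs(predict_weight(ewe_means, "ewe-3") - 46.06), 0.1)
  # ram 1-predictor equation at the ram CC mean gives the ram mean BW
  expect_lt(abs(predict_weight(tibble::tibble(CC = 95.88), "ram-1") - 54.09) /
              54.09, 0.01)
  # all-zero traits return the intercept
  zero <- tibble::tibble(BSL = 0, CC = 0, HH = 0)
  expect_equal(predict_weight(zero, "ewe-3"), -92.49)
  expect_error(predict_weight(tibble::tibble(BSL = 60), "ewe-3"),
               "missing predictor")
  expect_error(predict_weight(ewe_means, "ewe-9"), "unknown model")
  # a fitted model predicts through the generic too
  tab <- generate_trait_table(150, seed = 3)
  fit <- ols_fit(tab, "BW", c("BSL", "CC"))
  expect_equal(predict_weight(tab[1:5, ], fit), predict(fit, tab[1:5, ]))
})

test_that("trait tables round-trip through CSV", {
  tab <- generate_trait_table(20, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trait_csv(tab, path)
  tab2 <- read_trait_csv(path)
  expect_equal(tab2$BW, tab$BW, tolerance = 1e-9)
  expect_equal(tab2$sex, tab$sex)
})
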