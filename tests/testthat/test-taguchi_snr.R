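test_that("larger-the-better S/N matches hand-evaluated cases", {
  expect_equal(round(snr_ltb(140.11), 2), 42.93)
  expect_equal(snr_ltb(c(100, 200)),
               -10 * log10((1e-4 + 2.5e-5) / 2))  # 42.04 dB
  expect_equal(snr_ltb(1), 0)
  expect_warning(v <- snr_ltb(-263.42), "sign")
  expect_equal(round(v, 2), 48.41)
  expect_error(snr_ltb(c(10, 0)), "zero")
  expect_error(snr_ltb(numeric(0)), "empty")
})

test_that("negative-measurement policies behave as documented", {
  suppressWarnings({
    expect_equal(snr_ltb(c(-5, 5), negative_policy = "literal"),
                 snr_ltb(c(5, 5)))
    expect_equal(snr_ltb(c(-5, 5), negative_policy = "exclude"),
                 snr_ltb(5))
    expect_equal(snr_ltb(c(-5, 5), negative_policy = "floor", eps = 1e-3),
                 snr_ltb(c(1e-3, 5)))
  })
})

test_that("S/N equivariance and monotonicity properties hold", {
  set.seed(21)
  for (i in 1:50) {
    y <- runif(sample(1:5, 1), 10, 500)
    c_ <- runif(1, 0.1, 20)
    expect_equal(snr_ltb(c_ * y), snr_ltb(y) + 20 * log10(c_))
  }
  # strictly increasing in each |y_i|
  y <- c(50, 120, 300)
  for (j in 1:3) {
    y2 <- y
    y2[j] <- y[j] * 1.1
    expect_gt(snr_ltb(y2), snr_ltb(y))
  }
})

test_that("moment approximation reproduces all nine tabulated biogas S/N cells", {
  rt <- load_run_table()
  approx <- snr_ltb_from_moments(rt$bgp_mean_ml_gvs, rt$bgp_sd)
  expect_true(all(abs(approx - rt$snr_bgp_db) <= 0.02))
  expect_equal(round(approx[1], 2), 44.34)
  expect_equal(round(approx[2], 2), 47.60)
  # zero-variance limit equals the single-measurement formula
  expect_equal(snr_ltb_from_moments(167.39, 0), 20 * log10(167.39))
  expect_error(snr_ltb_from_moments(-3, 1), "positive mean")
})

test_that("moment approximation stays within +/-0.02 dB of exact triplicate S/N at CV <= 12%", {
  set.seed(4)
  for (i in 1:200) {
    m <- runif(1, 20, 400)
    cv <- runif(1, 0, 0.12)
    y <- m + m * cv * scale(rnorm(3))[, 1]
    if (any(y <= 0)) next
    # the formula expects the n-denominator (population) SD
    s_pop <- sqrt(mean((y - mean(y))^2))
    expect_lt(abs(snr_ltb_from_moments(mean(y), s_pop) - snr_ltb(y)), 0.02)
  }
})

test_that("smaller-the-better and nominal-the-best follow their definitions", {
  expect_equal(snr_stb(1), 0)
  expect_equal(snr_stb(10), -20)
  # sample with mean 10, sd 1 -> 10*log10(100/1) = 20 dB
  y <- c(9, 10, 11)
  expect_equal(snr_ntb(y), 10 * log10(mean(y)^2 / var(y)))
  expect_equal(snr_ntb(c(9, 10, 11)), 20)
  expect_error(snr_ntb(c(5, 5)), "zero variance")
  expect_error(snr_ntb(3), "at least two")
})

test_that("level means equal a brute-force group-by oracle on random tables", {
  d <- build_l9()
  lev <- codigest:::design_levels(d)
  set.seed(33)
  for (i in 1:500) {
    snr <- data.frame(run_id = 1:9, y = rnorm(9, 40, 8))
    f <- sample(c("A", "B", "C", "D"), 1)
    l <- sample(1:3, 1)
    oracle <- mean(snr$y[lev[, paste0(f, "_level")] == l])
    expect_identical(level_mean_snr(snr, d, f, l, "y"), oracle)
  }
})

test_that("effects table reproduces the tabulated level means, ranges and ranks", {
  d <- build_l9()
  rt <- load_run_table()
  eff <- effects_table(snr_table(rt, source = "columns"), d)

  tab4 <- list(
    bgp = matrix(c(37.21, 41.45, 40.59,
                   44.96, 43.29, 31.00,
                   37.00, 43.53, 38.73,
                   44.43, 37.90, 36.92), 4, 3, byrow = TRUE),
    bmp = matrix(c(31.06, 35.22, 34.79,
                   38.84, 36.75, 25.49,
                   30.51, 37.96, 32.61,
                   38.53, 31.66, 30.88), 4, 3, byrow = TRUE),
    cods = matrix(c(39.34, 36.46, 37.25,
                    36.83, 35.52, 40.70,
                    37.43, 35.18, 40.44,
                    35.81, 36.27, 40.98), 4, 3, byrow = TRUE))
  ranks <- list(bgp = c(4, 1, 3, 2), bmp = c(4, 1, 3, 2),
                cods = c(4, 2, 1, 3))
  for (resp in names(tab4)) {
    sub <- eff[eff$response == resp, ]
    got <- as.matrix(sub[, c("level1", "level2", "level3")])
    expect_true(all(abs(got - tab4[[resp]]) <= 0.02),
                label = paste("level means for", resp))
    expect_equal(sub$rank, ranks[[resp]], label = paste("ranks for", resp))
    expect_true(all(sub$range >= 0))
    expect_setequal(sub$rank, 1:4)
    # best level attains the max level mean
    expect_equal(sub$best_level, unname(apply(got, 1, which.max)))
  }
})

test_that("balance identity: mean of 9 run S/N equals mean of any factor's level means", {
  d <- build_l9()
  set.seed(9)
  for (i in 1:20) {
    snr <- data.frame(run_id = 1:9, y = rnorm(9, 35, 6))
    eff <- effects_table(snr, d, responses = "y")
    overall <- mean(snr$y)
    for (f in c("A", "B", "C", "D")) {
      sub <- eff[eff$factor == f, ]
      expect_equal(mean(c(sub$level1, sub$level2, sub$level3)), overall)
    }
  }
})

test_that("constant S/N tables fall back to the documented tie-breaks", {
  d <- build_l9()
  snr <- data.frame(run_id = 1:9, y = rep(35, 9))
  eff <- effects_table(snr, d, responses = "y")
  expect_equal(eff$range, rep(0, 4))
  expect_equal(eff$rank, 1:4)          # factor order A < B < C < D
  expect_equal(eff$best_level, rep(1L, 4))
  opt <- optimal_formulation(eff, "y")
  expect_equal(attr(opt, "designation"), "A1B1C1D1")
})

test_that("per-response optima match the study's selections", {
  d <- build_l9()
  eff <- effects_table(snr_table(load_run_table()), d)
  expect_equal(attr(optimal_formulation(eff, "bgp"), "designation"),
               "A2B1C2D1")
  expect_equal(attr(optimal_formulation(eff, "bmp"), "designation"),
               "A2B1C2D1")
  expect_equal(attr(optimal_formulation(eff, "cods"), "designation"),
               "A1B3C3D3")
  expect_error(optimal_formulation(eff, "nope"), "not present")
})
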