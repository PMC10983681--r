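test_that("noiseless flat configuration reduces to the closed form", {
  cfg <- synthetic_config(n_months = 6, noise_sigma = 0, trend_slope = 0,
                          seasonal_indices = rep(1, 12))
  x <- simulate_donations(cfg)
  om <- x$value[x$node == "O_M"]
  expect_equal(om, rep(5265 * 0.54 * 0.54, 6))
  tot <- x$value[x$node == "Total"]
  expect_equal(tot, rep(5265, 6))
})

test_that("generator output is coherent, positive and deterministic", {
  x1 <- simulate_donations(seed = 99)
  x2 <- simulate_donations(seed = 99)
  expect_identical(x1, x2)
  expect_true(all(x1$value > 0))
  expect_true(is_coherent(x1, blood_hierarchy(), tol = 1e-9))
  expect_equal(nrow(x1), 144 * 11)
  # a different seed gives different noise
  expect_false(identical(x1$value, simulate_donations(seed = 100)$value))
})

test_that("donor-pool shares are recovered under default noise", {
  x <- simulate_donations(seed = 12)
  m <- tidyr::pivot_wider(x, names_from = node, values_from = value)
  m_share <- sum(m$M) / sum(m$Total)
  o_share <- sum(m$O_M + m$O_F) / sum(m$Total)
  expect_lt(abs(m_share - 0.54), 0.02)
  expect_lt(abs(o_share - 0.54), 0.02)
})

test_that("summary statistics preserve the group-size ordering", {
  x <- simulate_donations(seed = 6)
  sm <- donation_summary(x, spec = blood_hierarchy())
  means <- setNames(sm$mean, sm$node)
  for (g in c("M", "F")) {
    v <- means[paste0(c("O", "A", "B", "AB"), "_", g)]
    expect_true(all(diff(v) < 0),
                label = paste("O > A > B > AB for", g))
  }
  expect_identical(names(sm),
                   c("node", "n", "mean", "sd", "min", "max", "skew",
                     "kurtosis"))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(gender_shares = c(M = 0.6, F = 0.6)),
               class = "donorcast_error_config")
  expect_error(synthetic_config(seasonal_indices = rep(1.1, 12)),
               class = "donorcast_error_config")
  expect_error(synthetic_config(trend_slope = -0.01, n_months = 144),
               class = "donorcast_error_config")
})

test_that("a level shock scales the window exactly and keeps coherence", {
  spec <- blood_hierarchy()
  x <- simulate_donations(seed = 17)
  xs <- inject_shock(x, spec, start = "2017-01", duration = 6,
                     magnitude = 0.4)
  w <- xs$period >= as.Date("2017-01-01") & xs$period <= as.Date("2017-06-01")
  expect_equal(xs$value[w], 0.6 * x$value[w], tolerance = 1e-12)
  expect_equal(xs$value[!w], x$value[!w])
  expect_true(is_coherent(xs, spec, tol = 1e-9))

  expect_equal(inject_shock(x, spec, "2017-01", 6, magnitude = 0)$value,
               x$value)
  expect_error(inject_shock(x, spec, "2018-10", 6, magnitude = 0.4),
               class = "donorcast_error_range")
  expect_error(inject_shock(x, spec, "2017-01", 3, magnitude = 1),
               class = "donorcast_error_config")
})

test_that("linear recovery ramps the reduction back towards baseline", {
  spec <- blood_hierarchy()
  x <- simulate_donations(synthetic_config(n_months = 36), seed = 18)
  xs <- inject_shock(x, spec, start = "2008-01", duration = 4,
                     magnitude = 0.4, recovery = "linear")
  tot <- function(df, p) df$value[df$node == "Total" &
                                    df$period == as.Date(p)]
  ratio <- vapply(sprintf("2008-0%d-01", 1:4),
                  function(p) tot(xs, p) / tot(x, p), numeric(1))
  expect_equal(unname(ratio), c(0.6, 0.7, 0.8, 0.9), tolerance = 1e-12)
})

test_that("a shock unseen in training degrades forecast accuracy", {
  spec <- blood_hierarchy()
  cfg <- synthetic_config(n_months = 168)
  x <- simulate_donations(cfg, seed = 23)
  xs <- inject_shock(x, spec, start = "2020-04", duration = 9,
                     magnitude = 0.4)
  tot <- x$value[x$node == "Total"]
  tots <- xs$value[xs$node == "Total"]
  fit <- fit_hw(tot[1:159], seasonal = "multiplicative")
  fc <- forecast(fit, 9)
  expect_gt(mape(tots[160:168], fc), mape(tot[160:168], fc))
})
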