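test_that("mape follows its definition and guards its domain", {
  expect_equal(mape(c(7, 7, 7), c(7, 7, 7)), 0)
  expect_equal(mape(100, 90), 10)
  expect_equal(mape(c(100, 200), c(110, 180)), 10)
  # scale invariance and zero iff exact
  y <- c(120, 80, 95); f <- c(100, 90, 99)
  expect_equal(mape(3 * y, 3 * f), mape(y, f))
  expect_gt(mape(y, f), 0)
  expect_error(mape(c(1, 0), c(1, 1)),
               class = "donorcast_error_zero_actual")
  expect_error(mape(1:3, 1:2), class = "donorcast_error_argument")
})

test_that("published two-year totals reproduce the reported yearly MAPEs", {
  t5 <- nbsz_validation_totals()
  y2019 <- t5[format(t5$period, "%Y") == "2019", ]
  y2020 <- t5[format(t5$period, "%Y") == "2020", ]
  expect_equal(round(mape(y2019$actual, y2019$forecast), 2), 14.80)
  expect_equal(round(mape(y2020$actual, y2020$forecast), 2), 84.06)
})

test_that("accuracy table has the method-comparison shape and exact averages", {
  spec <- blood_hierarchy()
  x <- simulate_donations(synthetic_config(n_months = 60), seed = 8)
  spl <- split_history(x, holdout = 12)
  tab <- accuracy_table(spl$history, spl$holdout, spec,
                        base_models = "ets")
  expect_identical(tab$node, c(spec$nodes, "Average"))
  expect_identical(setdiff(names(tab), "node"),
                   paste0("ets_", c("bu", "tdfp", "tdha", "tdhp", "oc")))
  expect_true(all(vapply(tab[-1], is.numeric, logical(1))))
  expect_true(all(as.matrix(tab[-1]) >= 0))
  expect_true(all(is.finite(as.matrix(tab[-1]))))
  # Average row is the exact mean of the node rows
  nodes <- tab[tab$node != "Average", -1]
  expect_equal(unlist(tab[tab$node == "Average", -1]),
               colMeans(as.matrix(nodes)), tolerance = 1e-9)
  # bottom-node BU cells equal the unreconciled base-forecast MAPE
  base <- base_forecasts(spl$history, spec, h = 12, model = "ets")
  om <- tidyr::pivot_wider(spl$holdout, names_from = node,
                           values_from = value)
  for (b in c("A_M", "O_F")) {
    raw <- base$value[base$node == b]
    expect_equal(tab$ets_bu[tab$node == b], mape(om[[b]], raw),
                 tolerance = 1e-9)
  }
})

test_that("holdout chronology is enforced", {
  spec <- blood_hierarchy()
  x <- simulate_donations(synthetic_config(n_months = 48), seed = 8)
  spl <- split_history(x, holdout = 12)
  expect_error(accuracy_table(x, spl$holdout, spec, base_models = "ets"),
               class = "donorcast_error_chronology")
})

test_that("perfect forecasts give an all-zero accuracy column", {
  spec <- pair_spec()
  hist <- random_history(spec, 24, seed = 3)
  # inject base forecasts equal to the holdout by using bottom-up on actuals
  actual <- random_history(spec, 4, seed = 4)
  base <- actual |>
    dplyr::group_by(node) |>
    dplyr::mutate(step = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(node, step, value)
  rec <- reconcile_bottom_up(base, spec)
  m <- tidyr::pivot_wider(actual, names_from = node, values_from = value)
  for (nd in spec$nodes) {
    expect_equal(mape(m[[nd]], rec$value[rec$node == nd]), 0)
  }
})

test_that("select_best returns the minimum-average column with canonical ties", {
  one <- tibble::tibble(node = "Average", arima_bu = 5.5)
  expect_equal(select_best(one)$method, "bu")

  best <- select_best(nbsz_accuracy_averages())
  expect_equal(best$method, "tdfp")
  expect_equal(best$model, "arima")
  expect_equal(best$mape, 11.30)

  tied <- tibble::tibble(node = "Average", ets_oc = 2, arima_tdha = 2)
  expect_message(res <- select_best(tied), "Tie")
  expect_equal(res$method, "tdha")   # tdha precedes oc canonically
  expect_error(select_best(tibble::tibble(node = "Total", a_b = 1)),
               class = "donorcast_error_argument")
})

test_that("validate_holdout reports per-period APEs and yearly windows", {
  t5 <- nbsz_validation_totals()
  rep <- validate_holdout(
    dplyr::select(t5, period, node, value = forecast),
    dplyr::select(t5, period, node, value = actual), node = "Total")
  yearly <- mape_by_year(rep)
  expect_equal(round(yearly$mape[yearly$year == 2019], 2), 14.80)
  expect_equal(round(yearly$mape[yearly$year == 2020], 2), 84.06)
  expect_equal(nrow(rep), 24)
  expect_equal(attr(rep, "mape"), mean(rep$ape))

  # forecasts identical to actuals give all-zero APEs
  same <- validate_holdout(
    dplyr::select(t5, period, node, value = actual),
    dplyr::select(t5, period, node, value = actual), node = "Total")
  expect_equal(same$ape, rep(0, 24))
})
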