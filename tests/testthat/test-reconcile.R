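spec_blood <- blood_hierarchy()

test_that("bottom-up sums bottom forecasts and ignores upper ones", {
  base <- base_tbl(as.list(published_bottom_row()))
  out <- reconcile_bottom_up(base, spec_blood)
  val <- setNames(out$value, out$node)
  expect_equal(unname(val[c("M", "F", "Total")]), c(3665, 2877, 6542))
  expect_equal(unname(val[spec_blood$bottom]),
               unname(published_bottom_row()))

  # upper base forecasts, however wrong, do not matter
  base2 <- dplyr::bind_rows(
    base, tibble::tibble(node = "Total", step = 1, value = 1e6,
                         model = "test"))
  expect_equal(reconcile_bottom_up(base2, spec_blood)$value, out$value)

  ones <- base_tbl(setNames(as.list(rep(1, 8)), spec_blood$bottom))
  v1 <- setNames(reconcile_bottom_up(ones, spec_blood)$value,
                 spec_blood$nodes)
  expect_equal(unname(v1[c("Total", "M", "F")]), c(8, 4, 4))

  # idempotence: re-reconciling the output changes nothing
  again <- reconcile_bottom_up(out, spec_blood)
  expect_equal(again$value, out$value)

  expect_error(reconcile_bottom_up(base[-1, ], spec_blood),
               class = "donorcast_error_incomplete")
})

test_that("average historical proportions match a loop-and-average oracle", {
  spec <- pair_spec()
  # constant shares
  h1 <- aggregate_bottom(bottom_tbl(matrix(c(3, 3, 7, 7), ncol = 2),
                                    spec$bottom), spec)
  expect_equal(proportions_ahp(h1, spec)$proportion, c(0.3, 0.7))
  # swapped shares average out
  h2 <- aggregate_bottom(bottom_tbl(matrix(c(1, 3, 3, 1), ncol = 2),
                                    spec$bottom), spec)
  expect_equal(proportions_ahp(h2, spec)$proportion, c(0.5, 0.5))
  expect_equal(proportions_pha(h2, spec)$proportion, c(0.5, 0.5))

  # brute-force oracles on a random 24-month blood-hierarchy series
  hist <- random_history(spec_blood, 24, seed = 31)
  m <- tidyr::pivot_wider(hist, names_from = node, values_from = value)
  p_ahp <- proportions_ahp(hist, spec_blood)
  p_pha <- proportions_pha(hist, spec_blood)
  for (b in spec_blood$bottom) {
    oracle_ahp <- mean(m[[b]] / m[["Total"]])
    oracle_pha <- mean(m[[b]]) / mean(m[["Total"]])
    expect_equal(p_ahp$proportion[p_ahp$node == b], oracle_ahp,
                 tolerance = 1e-12)
    expect_equal(p_pha$proportion[p_pha$node == b], oracle_pha,
                 tolerance = 1e-12)
  }
  expect_equal(sum(p_ahp$proportion), 1, tolerance = 1e-9)
  expect_equal(sum(p_pha$proportion), 1, tolerance = 1e-9)
})

test_that("one huge month separates the two historical schemes", {
  spec <- pair_spec()
  vals <- matrix(c(10, 10, 1000, 10, 10, 10), ncol = 2)
  h <- aggregate_bottom(bottom_tbl(vals, spec$bottom), spec)
  ahp <- proportions_ahp(h, spec)$proportion
  pha <- proportions_pha(h, spec)$proportion
  expect_equal(pha, c(1020, 30) / 1050, tolerance = 1e-12)
  expect_equal(ahp[1], mean(c(0.5, 0.5, 1000 / 1010)), tolerance = 1e-12)
  expect_gt(max(abs(ahp - pha)), 0.01)
})

test_that("forecast proportions follow the ancestor-chain product", {
  # every node an only child -> proportion 1
  solo <- hierarchy_spec(list(Total = "X", X = "x1"))
  base1 <- base_tbl(list(Total = 9, X = 5, x1 = 3))
  p1 <- proportions_fp(base1, solo)
  expect_equal(p1$proportion, 1)

  # the published worked example: p_OF = (55/100) * (100/200) = 0.275
  base2 <- base_tbl(list(Total = 999, M = 100, F = 100,
                         A_M = 25, B_M = 25, AB_M = 25, O_M = 25,
                         A_F = 20, B_F = 15, AB_F = 10, O_F = 55))
  p2 <- proportions_fp(base2, spec_blood)
  expect_equal(p2$proportion[p2$node == "O_F"], 0.275)

  # per-step proportions always sum to one
  base3 <- random_base(spec_blood, h = 5, seed = 77)
  p3 <- proportions_fp(base3, spec_blood)
  sums <- tapply(p3$proportion, p3$step, sum)
  expect_equal(as.numeric(sums), rep(1, 5), tolerance = 1e-12)

  base0 <- base_tbl(list(Total = 10, M = 0, F = 0,
                         A_M = 0, B_M = 0, AB_M = 0, O_M = 0,
                         A_F = 1, B_F = 1, AB_F = 1, O_F = 1))
  expect_error(proportions_fp(base0, spec_blood),
               class = "donorcast_error_zero_total")
})

test_that("top-down splits the top forecast and conserves it", {
  pair4 <- paste0("x", 1:4)
  spec4 <- hierarchy_spec(list(Total = pair4))
  hist4 <- aggregate_bottom(
    bottom_tbl(matrix(c(540, 240, 180, 40), nrow = 1), pair4), spec4)
  p <- proportions_pha(hist4, spec4)
  out <- reconcile_top_down(1000, p, spec4)
  val <- setNames(out$value, out$node)
  expect_equal(unname(val[pair4]), c(540, 240, 180, 40))
  expect_equal(unname(val["Total"]), 1000)

  # concentrated proportions send everything to one node
  hist1 <- aggregate_bottom(bottom_tbl(matrix(c(10, 0, 0, 0), nrow = 1),
                                       pair4), spec4)
  pc <- proportions_pha(hist1, spec4)
  outc <- reconcile_top_down(c(100, 200), pc, spec4)
  expect_equal(outc$value[outc$node == "x1"], c(100, 200))

  # disaggregate then re-aggregate returns the top forecast exactly
  hist <- random_history(spec_blood, 12, seed = 9)
  top <- c(5000, 6000, 7000)
  out2 <- reconcile_top_down(top, proportions_ahp(hist, spec_blood),
                             spec_blood)
  expect_equal(out2$value[out2$node == "Total"], top)
})

test_that("optimal combination equals the hand-solved normal equations", {
  oc1 <- reconcile_oc(base_tbl(list(Total = 10, X = 6)), chain_spec())
  expect_equal(oc1$value, c(8, 8), tolerance = 1e-9)

  oc2 <- reconcile_oc(base_tbl(list(Total = 10, a = 4, b = 4)),
                      pair_spec())
  expect_equal(setNames(oc2$value, oc2$node),
               c(Total = 28 / 3, a = 14 / 3, b = 14 / 3),
               tolerance = 1e-9)
})

test_that("optimal combination is the projection onto the coherent space", {
  toys <- list(
    chain_spec(), pair_spec(),
    hierarchy_spec(list(Total = c("a", "b", "c"))),
    hierarchy_spec(list(Total = c("a", "b", "c", "d"))),
    hierarchy_spec(list(Total = c("A", "B"), A = c("a1", "a2"),
                        B = c("b1", "b2"))))
  for (ti in seq_along(toys)) {
    spec <- toys[[ti]]
    S <- summing_matrix(spec)
    for (r in 1:10) {
      base <- random_base(spec, h = 1, seed = 1000 * ti + r)
      out <- reconcile_oc(base, spec)
      yhat <- base$value[match(spec$nodes, base$node)]
      oracle <- as.numeric(pinv_projection(S, yhat))
      expect_equal(out$value, oracle, tolerance = 1e-9)
      # idempotence: projecting a second time changes nothing
      expect_equal(reconcile_oc(out, spec)$value, out$value,
                   tolerance = 1e-9)
    }
  }
})

test_that("coherent base forecasts pass through optimal combination", {
  base <- reconcile_bottom_up(base_tbl(as.list(published_bottom_row())),
                              spec_blood)
  out <- reconcile_oc(base, spec_blood)
  expect_equal(out$value, base$value, tolerance = 1e-9)
})

test_that("all schemes coincide when shares are constant everywhere", {
  spec <- pair_spec()
  hist <- aggregate_bottom(
    bottom_tbl(matrix(rep(c(30, 70), each = 6), ncol = 2), spec$bottom),
    spec)
  base <- base_tbl(list(Total = 100, a = 30, b = 70))
  p_fp <- proportions_fp(base, spec)
  expect_equal(proportions_ahp(hist, spec)$proportion, c(0.3, 0.7))
  expect_equal(proportions_pha(hist, spec)$proportion, c(0.3, 0.7))
  expect_equal(p_fp$proportion, c(0.3, 0.7))
})

test_that("the two AHP share conventions agree on the printed formula default", {
  hist <- random_history(spec_blood, 24, seed = 13)
  p_total <- proportions_ahp(hist, spec_blood, within = "total")
  p_parent <- proportions_ahp(hist, spec_blood, within = "parent")
  # both are valid proportion sets but differ in general
  expect_equal(sum(p_total$proportion), 1, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(p_total$proportion,
                                p_parent$proportion,
                                tolerance = 1e-6)))
})

test_that("every method yields coherent forecasts through the wrapper", {
  hist <- random_history(spec_blood, 36, seed = 21)
  base <- random_base(spec_blood, h = 4, seed = 22)
  for (mth in c("bu", "tdfp", "tdha", "tdhp", "oc")) {
    out <- reconcile(base, spec_blood, mth, history = hist)
    expect_true(is_coherent(out, spec_blood, tol = 1e-6),
                label = paste("coherent under", mth))
  }
  expect_error(reconcile(base, spec_blood, "tdha"),
               class = "donorcast_error_argument")
})
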