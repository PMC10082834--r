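test_that("percentage change from baseline is exact", {
  expect_identical(delta_metric(2, 2), 0)
  expect_equal(delta_metric(2, 1.6), -20)
  expect_equal(delta_metric(1, 1.3), 30)
  expect_error(delta_metric(0, 1), "positive")
  expect_error(delta_metric(-2, 1), "positive")
})

test_that("reciprocal changes compose as -100x/(100+x)", {
  for (x in c(-50, -15, -5, 10, 25, 80, 200)) {
    post <- 2 * (1 + x / 100)
    back <- delta_metric(post, 2)
    expect_equal(back, -100 * x / (100 + x), tolerance = 1e-10)
  }
})

test_that("EORTC classification matches the printed thresholds", {
  expect_identical(classify_eortc(30), "progressive")
  expect_identical(classify_eortc(0), "stable")
  expect_identical(classify_eortc(-20), "partial_response")
  # boundary values are assigned to stable (strict printed inequalities)
  expect_identical(classify_eortc(25), "stable")
  expect_identical(classify_eortc(-15), "stable")
  expect_identical(classify_eortc(25.0001), "progressive")
  expect_identical(classify_eortc(-15.0001), "partial_response")
  expect_error(classify_eortc(NaN), "finite")
})

test_that("classification is piecewise-constant and monotone", {
  grid <- seq(-90, 90, by = 0.5)
  lev <- c(partial_response = 1, stable = 2, progressive = 3)
  codes <- lev[vapply(grid, classify_eortc, character(1))]
  expect_true(all(diff(codes) >= 0))
  expect_identical(unname(range(codes)), c(1, 3))
})

test_that("assess combines the three deltas and classifies on SUV", {
  ph <- make_phantom(small_spec(radius = 2, suv = 2))
  mask <- segment_mtv(ph$image, small_bbox())
  met <- quantify(ph$image, mask)
  same <- assess(met, met)
  expect_identical(same$delta_suv, 0)
  expect_identical(same$delta_mtv, 0)
  expect_identical(same$delta_tlg, 0)
  expect_identical(same$category, "stable")

  half <- met
  half$tlg <- met$tlg / 2
  r <- assess(met, half)
  expect_identical(r$delta_tlg, -50)
})

test_that("a constructed +40% uptake pair is classified progressive", {
  pair <- make_response_pair(small_spec(radius = 2, suv = 2),
                             delta_suv_pct = 40)
  res <- run_pipeline(pair$pre$image, pair$post$image,
                      small_bbox(), small_bbox())
  expect_identical(res$response$category, "progressive")
  expect_gt(res$response$delta_suv, 25)
})

test_that("the group-comparison decision tree takes the printed branches", {
  set.seed(101)
  # normal, homoskedastic, 3 groups -> ANOVA + Holm-Sidak
  tbl <- data.frame(group = rep(c("mock", "proton", "proton_boron"), each = 8),
                    value = rnorm(24, mean = 5, sd = 1))
  res <- compare_groups(tbl)
  expect_identical(res$branch, "parametric")
  expect_match(res$test, "ANOVA")
  expect_identical(nrow(res$pairwise), 3L)
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw))

  # two normal groups -> Student t
  res2 <- compare_groups(tbl[tbl$group != "proton_boron", ])
  expect_identical(res2$branch, "parametric")
  expect_match(res2$test, "Student")

  # heavily skewed data -> Kruskal-Wallis
  skew <- data.frame(group = rep(c("a", "b"), each = 12),
                     value = c(exp(seq(-2, 4, length.out = 12)),
                               exp(seq(-2.5, 3.5, length.out = 12))))
  res3 <- compare_groups(skew)
  expect_identical(res3$branch, "nonparametric")
  expect_match(res3$test, "Kruskal")

  # a group of 2 observations cannot be tested for normality
  tiny <- data.frame(group = rep(c("a", "b"), c(2, 5)),
                     value = c(1.2, 1.4, rnorm(5)))
  expect_warning(res4 <- compare_groups(tiny), "fewer than 3")
  expect_identical(res4$branch, "nonparametric")
})

test_that("identical groups give a non-significant comparison on either branch", {
  v <- c(1.1, 1.9, 2.4, 3.2, 2.8, 1.5)
  tbl <- data.frame(group = rep(c("a", "b"), each = 6), value = c(v, v))
  res <- compare_groups(tbl)
  expect_gt(res$p_value, 0.9)
})

test_that("the null rejection rate sits near the nominal level", {
  set.seed(2024)
  n_rep <- 200
  p <- replicate(n_rep, {
    tbl <- data.frame(group = rep(c("a", "b"), each = 6), value = rnorm(12))
    suppressWarnings(compare_groups(tbl)$p_value)
  })
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.12)
})

test_that("Holm-Sidak adjustment matches a hand-computed step-down", {
  p <- c(0.01, 0.04, 0.30)
  adj <- petquant:::.holm_sidak(p)
  expect_equal(adj[1], 1 - (1 - 0.01)^3)
  expect_equal(adj[2], max(1 - (1 - 0.01)^3, 1 - (1 - 0.04)^2))
  expect_equal(adj[3], max(1 - (1 - 0.01)^3, 1 - (1 - 0.04)^2, 0.30))
  expect_true(all(petquant:::.holm_sidak(c(0.9, 0.95, 0.99)) <= 1))
})
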