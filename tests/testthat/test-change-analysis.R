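test_that("compare_epochs reports medians, IQRs and rank tests", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  cmp <- compare_epochs(x, x, quantity = "self")
  expect_equal(cmp$percent_change, 0)
  expect_lt(cmp$statistic, 1e-9)
  expect_equal(cmp$p_value, 1, tolerance = 1e-6)
  # shifted uniform sample: closed-form medians, oracle-checked statistic
  pre <- as.numeric(1:1000)
  post <- pre + 100
  cmp2 <- compare_epochs(pre, post)
  expect_equal(cmp2$median[["pre"]], 500.5)
  expect_equal(cmp2$median[["post"]], 600.5)
  expect_equal(cmp2$percent_change, 100 / 500.5 * 100, tolerance = 1e-9)
  expect_equal(cmp2$statistic, kw_oracle(pre, post), tolerance = 1e-9)
  expect_equal(cmp2$iqr[["pre"]], stats::IQR(pre))
  # degenerate pooled data: H = 0, p = 1, with a warning
  expect_warning(cmp3 <- compare_epochs(rep(2, 5), rep(2, 7)), "degenerate")
  expect_equal(cmp3$statistic, 0)
  expect_equal(cmp3$p_value, 1)
  expect_error(compare_epochs(numeric(0), 1:3), "empty")
})

test_that("the G-band medians give the reported percent change", {
  cmp <- compare_epochs(c(10.59), c(11.77), quantity = "g_intensity")
  expect_equal(round(cmp$percent_change, 1), 11.1)
})

test_that("the Kruskal-Wallis statistic equals a brute-force rank oracle", {
  # exhaustive enumeration of all two-group samples over {1, 2, 3}
  for (n1 in 2:3) for (n2 in 2:3) {
    combos <- expand.grid(rep(list(1:3), n1 + n2))
    for (i in seq_len(nrow(combos))) {
      v <- as.numeric(combos[i, ])
      a <- v[seq_len(n1)]; b <- v[n1 + seq_len(n2)]
      expected <- kw_oracle(a, b)
      if (!is.finite(expected)) next  # all values tied: degenerate
      got <- stats::kruskal.test(list(a, b))$statistic
      expect_equal(unname(got), expected, tolerance = 1e-9)
    }
  }
})

test_that("medians and IQRs are permutation invariant, change antisymmetric", {
  set.seed(15)
  pre <- rlnorm(200); post <- rlnorm(200) * 1.2
  c1 <- compare_epochs(pre, post)
  c2 <- compare_epochs(sample(pre), sample(post))
  expect_equal(c1$median, c2$median)
  expect_equal(c1$iqr, c2$iqr)
  expect_equal(c1$statistic, c2$statistic)
  # swapping epochs negates the change up to the changed denominator
  swapped <- compare_epochs(post, pre)
  expect_equal(swapped$percent_change,
               -c1$percent_change / (1 + c1$percent_change / 100),
               tolerance = 1e-9)
})

test_that("zonal summaries conserve pixels and match the global comparison", {
  set.seed(30)
  vals_pre <- matrix(rlnorm(60 * 50), 60, 50)
  vals_post <- vals_pre * 1.1
  mask <- matrix(0L, 60, 50)
  mask[sample(3000, 400)] <- mask_codes()["unlit"]
  gpre <- alan_grid(list(x = vals_pre), origin = c(0, 30000), mask = mask)
  gpost <- alan_grid(list(x = vals_post), origin = c(0, 30000), mask = mask)
  regions <- make_regions(7, gpre, seed = 21)
  tab <- zonal_summary(gpre, gpost, regions)
  expect_s3_class(tab, "region_change_table")
  # a disjoint partition conserves the valid pixel count
  expect_equal(sum(tab$n_pre), sum(mask == 0L))
  # a single region covering the grid reproduces the global medians
  whole <- make_regions(1, gpre, seed = 1)
  tw <- zonal_summary(gpre, gpost, whole)
  cmp <- compare_epochs(valid_values(gpre), valid_values(gpost))
  expect_equal(tw$pre, unname(cmp$median["pre"]))
  expect_equal(tw$post, unname(cmp$median["post"]))
  # a region with no valid pixels is flagged, not dropped
  mask2 <- mask
  inside <- mgcv::in.out(regions$polygons[[3]], alanrisk:::pixel_centers(gpre))
  mask2[matrix(inside, 60, 50)] <- mask_codes()["unlit"]
  gpre2 <- alan_grid(list(x = vals_pre), origin = c(0, 30000), mask = mask2)
  tab2 <- zonal_summary(gpre2, gpost, regions)
  expect_true(tab2$empty[3])
  expect_equal(nrow(tab2), 7L)
})

test_that("species ranges built with and without the LED shift separate", {
  # 38 synthetic ranges laid out without mutual overlap; ranges 1-3 are
  # constructed without the shift and must be exactly the ones showing
  # non-positive mean G/R change
  set.seed(12)
  base <- matrix(runif(120 * 120, 0.4, 0.6), 120, 120)
  g <- alan_grid(list(g_over_r = base), origin = c(0, 60000), res = 500)
  th <- seq(0, 2 * pi, length.out = 33)
  centers <- expand.grid(cx = seq(10, 110, length.out = 7)[1:7],
                         cy = seq(10, 110, length.out = 6))[1:38, ]
  polys <- lapply(seq_len(38), function(i) {
    a <- runif(1, 2.5, 6); b <- runif(1, 2.5, 6)
    cbind(centers$cx[i] * 500 + a * 500 * cos(th),
          (120 - centers$cy[i]) * 500 + b * 500 * sin(th))
  })
  ranges <- region_set(sprintf("species_%02d", 1:38), polys, mode = "ranges")
  ctr <- alanrisk:::pixel_centers(g)
  exempt <- rep(FALSE, 120 * 120)
  for (i in 1:3)
    exempt <- exempt | mgcv::in.out(ranges$polygons[[i]], ctr)
  shift <- matrix(ifelse(exempt, -0.02, 0.15), 120, 120)
  gpost <- alan_grid(list(g_over_r = base + shift), origin = c(0, 60000),
                     res = 500)
  tab <- zonal_summary(g, gpost, ranges, statistic = "mean")
  expect_equal(sum(tab$empty), 0L)
  nonpos <- tab$region[tab$change <= 0]
  expect_setequal(nonpos, c("species_01", "species_02", "species_03"))
})

test_that("distribution reports are complete and deterministic", {
  set.seed(8)
  pre <- rlnorm(500); post <- rlnorm(500) * 1.3
  cmp <- compare_epochs(pre, post, quantity = "q1")
  rep1 <- distribution_report(list(q1 = list(comparison = cmp, pre = pre,
                                             post = post)))
  expect_equal(nrow(rep1$table), 1L)
  expect_equal(sum(rep1$histograms$q1$counts_pre), length(pre))
  expect_equal(sum(rep1$histograms$q1$counts_post), length(post))
  rep2 <- distribution_report(list(q1 = list(comparison = cmp, pre = pre,
                                             post = post)))
  expect_identical(rep1, rep2)
  expect_error(distribution_report(list()), "at least one")
})
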