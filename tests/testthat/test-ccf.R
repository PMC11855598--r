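test_that("CCF inversion matches the forward VAF model", {
  expect_equal(as.numeric(compute_ccf(0.5, 1, 2, 2, 1)), 1.0)
  expect_equal(as.numeric(compute_ccf(0, 0.8, 3, 2, 1)), 0)
  # forward at CCF 0.6, purity 0.8, CN_t 3, m 2, then invert
  v <- expected_vaf(0.6, 0.8, 3, 2, 2)
  expect_equal(v, 0.342857142857, tolerance = 1e-10)
  expect_equal(as.numeric(compute_ccf(v, 0.8, 3, 2, 2)), 0.6, tolerance = 1e-12)
  # clipping at 1.2 with raw value preserved
  cc <- compute_ccf(0.9, 1, 2, 2, 1)
  expect_equal(as.numeric(cc), 1.2)
  expect_equal(attr(cc, "raw"), 1.8)
  expect_error(compute_ccf(0.5, 0, 2), "purity")
})

test_that("round-trip identity holds across the (ccf, m, cn, purity) grid", {
  grid <- expand.grid(ccf = seq(0.05, 1, by = 0.05),
                      purity = c(0.4, 0.87, 1),
                      cn_t = 1:4, m = 1:4)
  grid <- grid[grid$m <= grid$cn_t, ]
  v <- expected_vaf(grid$ccf, grid$purity, grid$cn_t, 2, grid$m)
  back <- as.numeric(compute_ccf(v, grid$purity, grid$cn_t, 2, grid$m))
  expect_lt(max(abs(back - grid$ccf)), 1e-9)
  # monotone in VAF (below the 1.2 clipping point)
  vv <- seq(0, 0.3, by = 0.01)
  expect_true(all(diff(as.numeric(compute_ccf(vv, 0.9, 3, 2, 1))) > 0))
})

test_that("multiplicity estimation is exact where identifiable", {
  expect_equal(estimate_multiplicity(0.5, 1, 2), 1L)
  expect_equal(estimate_multiplicity(0.99, 1, 2), 2L)
  # estimates round(m * CCF): recovery grid at depth 500
  set.seed(13)
  depth <- 500; purity <- 0.9
  cases <- rbind(
    expand.grid(m = 1L, ccf = seq(0.5, 1, 0.1), cn_t = 2:3),
    expand.grid(m = 1:3, ccf = c(0.85, 0.95, 1), cn_t = 3))
  cases <- cases[cases$m <= cases$cn_t, ]
  cases <- cases[rep(seq_len(nrow(cases)), 30), ]
  v <- expected_vaf(cases$ccf, purity, cases$cn_t, 2, cases$m)
  alt <- rbinom(nrow(cases), depth, v)
  m_hat <- estimate_multiplicity(alt / depth, purity, cases$cn_t)
  # for CCF >= 0.85 the rounded product m*CCF identifies m itself
  identifiable <- cases$ccf >= 0.85 | cases$m == 1
  expect_gte(mean((m_hat == cases$m)[identifiable & cases$ccf >= 0.8]), 0.95)
  expect_gte(mean((m_hat == cases$m)[cases$m == 1]), 0.95)
})

test_that("CCF intervals behave at the boundaries", {
  ci <- ccf_interval(200, 200, 1, 2)
  expect_gt(ci[, "lo"], 0.9)
  ci0 <- ccf_interval(0, 150, 0.9, 2)
  expect_equal(unname(ci0[, "lo"]), 0)
  expect_true(all(ci0[, "lo"] <= ci0[, "hi"]))
  expect_error(ccf_interval(1, 0, 0.9, 2), "depth")
})

test_that("clonality rule combines probability and CI criteria", {
  expect_equal(classify_clonal(0.6, 0.5), "clonal")
  expect_equal(classify_clonal(0.2, 0.92), "clonal")
  expect_equal(classify_clonal(0.01, 0.2), "subclonal")
  # vectorized over a table
  expect_equal(classify_clonal(c(0.9, 0.1), c(0.1, 0.95)),
               c("clonal", "clonal"))
})

test_that("ccf_table assembles estimates and respects purity lookup", {
  counts <- data.frame(variant_id = c("v1", "v1"), population = c("A", "B"),
                       alt = c(45, 0), depth = c(100, 120), cn_t = 2)
  tab <- ccf_table(counts, purity = c(A = 0.9, B = 0.9))
  expect_equal(nrow(tab), 2)
  expect_gt(tab$ccf[1], 0.8)
  expect_equal(tab$ccf[2], 0)
  expect_equal(tab$clonality[2], "subclonal")
  expect_error(ccf_table(counts, purity = c(A = 0.9)), "purity missing")
})

test_that("truncal-VAF purity estimator inverts the dilution model", {
  set.seed(5)
  purity <- 0.85
  v <- expected_vaf(1, purity, 2, 2, 1)
  vafs <- rbinom(400, 200, v) / 200
  expect_lt(abs(purity_from_truncal_vaf(vafs, 2) - purity), 0.03)
})
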