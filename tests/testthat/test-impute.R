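# independent per-window least-squares oracle for one replicate block
ols_impute_oracle <- function(block, slices, wb = 10, wf = 10, min_req = 3) {
  out <- block
  block_min <- min(block, na.rm = TRUE)
  for (i in seq_len(nrow(block))) {
    z <- block[i, ]
    for (k in which(is.na(z))) {
      s <- slices[k]
      w <- which(slices >= s - wb & slices <= s + wf & !is.na(z))
      if (length(w) > min_req) {
        fit <- stats::lm(v ~ sl, data = data.frame(v = z[w], sl = slices[w]))
        pred <- unname(stats::predict(fit, newdata = data.frame(sl = s)))
        if (pred >= block_min) out[i, k] <- pred
      }
    }
  }
  out
}

test_that("window OLS imputation matches an independent least-squares oracle", {
  # collinear points: [1,2,NA,4,5] -> exactly 3
  ann <- make_annotation(5)
  m <- named_matrix(c(1, 2, NA, 4, 5), 1, ann)
  got <- impute_by_distance(tbl_profile(m), ann)
  expect_equal(slicewise:::profile_matrix(got)[1, 3], 3)

  # noisy linear profiles with 20% masking, vs oracle to 1e-10
  set.seed(13)
  ann2 <- make_annotation(c(30, 30))
  m2 <- named_matrix(0, 12, ann2)
  for (i in 1:12) {
    m2[i, 1:30] <- 10 + 0.2 * i * (1:30) / 30 + stats::rnorm(30, 0, 0.3)
    m2[i, 31:60] <- 10 + 0.2 * i * (1:30) / 30 + stats::rnorm(30, 0, 0.3)
  }
  mask <- sample(length(m2), round(0.2 * length(m2)))
  m2[mask] <- NA
  got2 <- slicewise:::profile_matrix(
    impute_by_distance(tbl_profile(m2), ann2))
  for (r in c("R1", "R2")) {
    sel <- ann2$replicate == r
    oracle <- ols_impute_oracle(m2[, sel, drop = FALSE], ann2$slice[sel])
    expect_lt(max(abs(got2[, sel] - oracle), na.rm = TRUE), 1e-10)
    expect_identical(is.na(got2[, sel]), is.na(oracle))
  }

  # observed cells bit-identical
  expect_identical(got2[!is.na(m2)], m2[!is.na(m2)])
})

test_that("linear predictions never undershoot the replicate-block minimum", {
  # steep decreasing profile whose extrapolated line would cross the minimum
  ann <- make_annotation(12)
  m <- named_matrix(0, 2, ann)
  m[1, ] <- seq(10, 0.2, length.out = 12)
  m[1, 11] <- NA
  m[2, ] <- 5
  # make a window whose line predicts below min(block)
  m[1, 12] <- NA
  m[1, 1:10] <- seq(30, 3, length.out = 10)
  res <- slicewise:::profile_matrix(impute_by_distance(tbl_profile(m), ann))
  blk_min <- min(m, na.rm = TRUE)
  expect_true(all(res[!is.na(res)] >= blk_min - 1e-12))

  # strict inequality on window occupancy: exactly 3 points, min_req 3 -> no fit
  m3 <- named_matrix(NA_real_, 1, make_annotation(12))
  m3[1, c(1, 2, 3)] <- c(1, 2, 3)
  ann3 <- make_annotation(12)
  res3 <- slicewise:::profile_matrix(
    impute_by_distance(tbl_profile(m3), ann3, width_forward = 10,
                       width_backward = 10, min_data_required = 3,
                       fallback = "none"))
  expect_true(all(is.na(res3[1, 4:12])))
  # with 4 observed points the fit happens
  m4 <- m3; m4[1, 4] <- 4
  res4 <- slicewise:::profile_matrix(
    impute_by_distance(tbl_profile(m4), ann3, min_data_required = 3))
  expect_equal(res4[1, 5:11], 5:11, ignore_attr = TRUE)
  # slice 12 window [2, 22] holds only 3 observed points: strict bound, no fit
  expect_true(is.na(res4[1, 12]))
})

test_that("imputation recovers sigmoidal profiles within 2 sigma RMSE", {
  set.seed(14)
  ann <- make_annotation(40)
  sigma <- 0.3
  truth <- 10 + 4 * sigmoid01(seq(0, 1, length.out = 40))
  m <- named_matrix(rep(truth, each = 8), 8, ann)
  m <- m + stats::rnorm(length(m), 0, sigma)
  full <- m
  mask <- sample(length(m), round(0.2 * length(m)))
  m[mask] <- NA
  got <- slicewise:::profile_matrix(impute_by_distance(tbl_profile(m), ann))
  imp <- which(is.na(m) & !is.na(got))
  expect_gt(length(imp), 20)
  rmse <- sqrt(mean((got[imp] - full[imp])^2))
  expect_lt(rmse, 2 * sigma)
})

test_that("fallback and global downshift draws are seeded and per-sample", {
  set.seed(15)
  ann <- make_annotation(c(20, 20))
  m <- named_matrix(stats::rnorm(10 * 40, 15, 2), 10, ann)
  m[2, 1:18] <- NA   # too sparse for any window in replicate 1
  m[2, 19] <- 10; m[2, 20] <- 20  # wide observed range -> rich fallback pool
  prof <- tbl_profile(m)
  a <- impute_by_distance(prof, ann, fallback = "impute", seed = 99)
  b <- impute_by_distance(prof, ann, fallback = "impute", seed = 99)
  expect_identical(as.matrix(a[-1]), as.matrix(b[-1]))
  c2 <- impute_by_distance(prof, ann, fallback = "impute", seed = 100)
  expect_false(identical(as.matrix(a[-1]), as.matrix(c2[-1])))
  # non-fallback cells agree across seeds
  diff_cells <- which(as.matrix(a[-1]) != as.matrix(c2[-1]))
  expect_true(all(is.na(m[diff_cells])))

  # global downshift: no missing -> identity
  full <- tbl_profile(named_matrix(stats::rnorm(40, 15), 1, make_annotation(40)))
  expect_identical(as.matrix(global_downshift_impute(full, seed = 1)[-1]),
                   as.matrix(full[-1]))

  # one missing cell sits in the sample's low tail; same seed reproduces
  set.seed(16)
  ann1 <- make_annotation(2)
  m1 <- named_matrix(stats::rnorm(400, 0, 1), 200, ann1)
  m1[1, 1] <- NA
  g1 <- global_downshift_impute(tbl_profile(m1), seed = 7)
  g2 <- global_downshift_impute(tbl_profile(m1), seed = 7)
  expect_identical(as.matrix(g1[-1]), as.matrix(g2[-1]))
  v <- slicewise:::profile_matrix(g1)[1, 1]
  low <- m1[-1, 1][m1[-1, 1] < stats::quantile(m1[-1, 1], 0.05, na.rm = TRUE)]
  expect_lt(v, mean(low) + 3 * stats::sd(low) + 1e-9)
  expect_false(anyNA(as.matrix(g1[-1])))

  # two missing cells in different samples use their own sample's tail
  m2 <- named_matrix(c(stats::rnorm(200, 0, 1), stats::rnorm(200, 50, 1)), 200, ann1)
  m2[5, 1] <- NA; m2[6, 2] <- NA
  gv <- slicewise:::profile_matrix(global_downshift_impute(tbl_profile(m2), seed = 8))
  expect_lt(gv[5, 1], 10)
  expect_gt(gv[6, 2], 40)
})
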