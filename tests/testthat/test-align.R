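test_that("relative positions map each replicate onto [0, 1]", {
  ann <- tibble::tibble(sample_id = paste0("s", 1:10),
                        replicate = rep(c("A", "B"), each = 5),
                        slice = c(1:5, 3:7))
  out <- relative_positions(ann)
  expect_equal(out$perc[1:5], c(0, 0.25, 0.5, 0.75, 1))
  # translation invariance
  expect_equal(out$perc[6:10], c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(out$perc2, out$perc)

  # arithmetic oracle on random slice sets
  set.seed(21)
  for (i in 1:10) {
    sl <- sort(sample(1:100, 8))
    a <- tibble::tibble(sample_id = paste0("x", 1:8), replicate = "A",
                        slice = sl)
    expect_equal(relative_positions(a)$perc,
                 (sl - min(sl)) / (max(sl) - min(sl)))
  }

  single <- tibble::tibble(sample_id = "s", replicate = "A", slice = 3)
  expect_error(relative_positions(single), "single slice")
})

test_that("loess smoothing reproduces quadratics and refuses extrapolation", {
  x <- seq(0, 1, length.out = 40)
  y <- 2 - 3 * x + 1.5 * x^2
  g <- smooth_to_grid(y, x, grid_n = 500)
  grid <- seq(0, 1, length.out = 500)
  expect_lt(max(abs(g - (2 - 3 * grid + 1.5 * grid^2))), 1e-6)

  # constant profile -> constant grid
  gc <- smooth_to_grid(rep(4, 40), x, grid_n = 100)
  expect_lt(max(abs(gc - 4)), 1e-8)

  # no extrapolation outside the data range
  x_in <- seq(0.2, 0.8, length.out = 30)
  g_in <- smooth_to_grid(x_in^2, x_in, grid_n = 100)
  grid100 <- seq(0, 1, length.out = 100)
  expect_true(all(is.na(g_in[grid100 < 0.2 - 1e-9])))
  expect_true(all(is.na(g_in[grid100 > 0.8 + 1e-9])))
  expect_false(anyNA(g_in[grid100 >= 0.2 & grid100 <= 0.8]))

  expect_error(smooth_to_grid(c(1, 2, 3), c(0, 0.5, 1)), "at least 4")

  # noisy sigmoid stays near truth at interior points
  set.seed(22)
  xs <- seq(0, 1, length.out = 120)
  truth <- sigmoid01(xs, 0.5, 0.1)
  gn <- smooth_to_grid(truth + stats::rnorm(120, 0, 0.05), xs,
                       grid_n = 500, span = 0.3)
  interior <- grid <- seq(0, 1, length.out = 500)
  keep <- interior > 0.1 & interior < 0.9
  expect_lt(max(abs(gn[keep] - sigmoid01(interior[keep], 0.5, 0.1))), 0.08)
})

test_that("the lag scan recovers constructed shifts in the correct direction", {
  n <- 5000
  grid <- seq(0, 1, length.out = n)
  g1 <- sigmoid01(grid, 0.5, 0.06)

  # identical profiles: shift ~ 0 in both directions
  bs0 <- pairwise_best_shift(g1, g1)
  expect_true(all(bs0$shift <= 1 / (n - 1) + 1e-12))

  # g2 = g1 shifted right by 250 grid points -> "lo" direction, 250/5000
  g2 <- c(rep(g1[1], 250), g1[1:(n - 250)])
  bs <- pairwise_best_shift(g1, g2)
  lo <- bs[bs$direction == "lo", ]
  expect_lt(abs(lo$shift - 250 / n), 2.5 / n)
  expect_gt(lo$corr, 0.999)

  # antisymmetry: swapping the profiles swaps the winning direction
  bs_sw <- pairwise_best_shift(g2, g1)
  up_sw <- bs_sw[bs_sw$direction == "up", ]
  expect_lt(abs(up_sw$shift - 250 / n), 2.5 / n)
  expect_gte(up_sw$corr, lo$corr - 1e-6)

  # anti-correlated profiles report the negative correlation, unmasked
  g3 <- 1 - g1 + 0.05 * sin(20 * pi * grid)
  bs_neg <- pairwise_best_shift(g1, g3)
  expect_true(any(bs_neg$corr < 0, na.rm = TRUE))
})

test_that("median shifts are robust and applied around the reference", {
  sh <- tibble::tibble(
    protein_id = rep(c("m1", "m2", "m3"), each = 2),
    rep_a = "A", rep_b = "B",
    direction = rep(c("lo", "up"), 3),
    shift = c(0.1, 0, 0.1, 0, 0.4, 0.01),
    corr = 0.9, lag = -1
  )
  ann <- relative_positions(make_annotation(c(10, 10), reps = c("A", "B")))
  al <- median_shift_and_apply(sh, ann, "A")
  med_lo <- al$median_shifts$shift[al$median_shifts$direction == "lo"]
  expect_equal(med_lo, 0.1)  # median beats the 0.4 outlier
  b <- al$annotation[al$annotation$replicate == "B", ]
  expect_equal(b$perc2, b$perc - 0.1)  # "lo" wins -> pulled back
  a <- al$annotation[al$annotation$replicate == "A", ]
  expect_equal(a$perc2, a$perc)        # reference untouched

  expect_error(median_shift_and_apply(sh[1:2, ], ann, "A"), "3 marker")
  expect_error(median_shift_and_apply(sh, ann, "Z"), "reference replicate")
})

test_that("alignment recovers known replicate offsets end to end", {
  # three replicates with offsets (0, +0.05, -0.08); 5 clean sigmoid markers
  ns <- 100
  offs <- c(R1 = 0, R2 = 0.05, R3 = -0.08)
  centers <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  ann <- relative_positions(make_annotation(c(ns, ns, ns)))
  m <- t(sapply(centers, function(cc) {
    unlist(lapply(names(offs), function(r) {
      sigmoid01(seq(0, 1, length.out = ns) + offs[[r]], cc, 0.08)
    }))
  }))
  rownames(m) <- paste0("M", seq_along(centers))
  colnames(m) <- ann$sample_id
  sh <- estimate_marker_shifts(tbl_profile(m), ann, rownames(m), "R1",
                               grid_n = 5000, span = 0.3)
  al <- median_shift_and_apply(sh, ann, "R1")
  applied <- vapply(c("R2", "R3"), function(r) {
    sub <- al$annotation[al$annotation$replicate == r, ]
    unique(round(sub$perc2 - sub$perc, 9))[1]
  }, numeric(1))
  # offset +s evaluates archetypes at perc+s: features appear earlier,
  # so realignment must add +s back (and -s for negative offsets)
  expect_lt(abs(applied[["R2"]] - 0.05), 0.01)
  expect_lt(abs(applied[["R3"]] - (-0.08)), 0.01)
})

test_that("finalize yields per-replicate z-scores and exact [0, 1] ranging", {
  set.seed(23)
  ann <- relative_positions(make_annotation(c(12, 12)))
  m <- named_matrix(stats::rnorm(6 * 24, 10, 2), 6, ann)
  fin <- finalize_profiles(tbl_profile(m), ann)
  z <- slicewise:::profile_matrix(fin$z)
  zr <- slicewise:::profile_matrix(fin$zr)

  # brute-force two-step oracle
  for (r in c("R1", "R2")) {
    sel <- ann$replicate == r
    oracle <- t(scale(t(m[, sel])))
    expect_equal(z[, sel], oracle, ignore_attr = TRUE)
  }
  expect_true(all(apply(zr, 1, min) == 0))
  expect_true(all(apply(zr, 1, max) == 1))
  expect_true(all(zr >= 0 & zr <= 1))

  # single replicate: plain per-protein z-score
  ann1 <- relative_positions(make_annotation(12))
  m1 <- named_matrix(stats::rnorm(48, 5), 4, ann1)
  fin1 <- finalize_profiles(tbl_profile(m1), ann1)
  expect_equal(slicewise:::profile_matrix(fin1$z), t(scale(t(m1))),
               ignore_attr = TRUE)

  # zero-variance protein dropped with warning
  m2 <- m; m2[2, ann$replicate == "R1"] <- 3
  expect_warning(fin2 <- finalize_profiles(tbl_profile(m2), ann),
                 "zero variance")
  expect_false("P002" %in% fin2$z$protein_id)

  # columns ordered by (replicate, perc2)
  expect_equal(fin$annotation$sample_id,
               ann$sample_id[order(ann$replicate, ann$perc2)])
})
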