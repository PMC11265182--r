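test_that("design matrix rows encode the log-linear kurtosis model", {
  gt <- gradient_table(c(0, 1000, 2000, rep(c(1000, 2000), 28)),
                       rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0),
                             fibonacci_directions(56)))
  A <- dki_design_matrix(gt)
  expect_equal(dim(A), c(59L, 22L))
  # b0 row: intercept only
  expect_equal(A[1, ], c(1, rep(0, 21)), ignore_attr = TRUE)
  # axis direction kills cross terms: b=1000 along x
  row <- A[2, ]
  expect_equal(unname(row["dxx"]), -1000)
  expect_equal(unname(row[c("dyy", "dzz", "dxy", "dxz", "dyz")]), rep(0, 5))
  expect_equal(unname(row["u_xxxx"]), 1000^2 / 6)
  expect_equal(unname(row[paste0("u_", c("yyyy", "zzzz", "xxxy", "xxyy"))]),
               rep(0, 4))

  # the two-shell 113-measurement scheme is full rank
  expect_equal(qr(dki_design_matrix(default_gradients()))$rank, 22L)

  # single shell: underdetermined
  gt1 <- gradient_table(c(0, rep(1000, 56)),
                        rbind(c(0, 0, 0), fibonacci_directions(56)))
  expect_error(dki_design_matrix(gt1), "underdetermined")
})

test_that("noiseless signals are recovered exactly (OLS and WLS)", {
  gt <- paper_gtab()
  # isotropic, zero kurtosis
  y <- dki_signal(80, rep(1.1e-3, 3), NULL, gt)
  for (m in c("ols", "wls")) {
    f <- dki_fit(y, gt, method = m)
    co <- coef(f)
    expect_equal(unname(co[c("dxx", "dyy", "dzz")]), rep(1.1e-3, 3),
                 tolerance = 1e-10)
    expect_lt(max(abs(f$W)), 1e-8)          # single Gaussian => K ~ 0
    expect_equal(unname(co["s0"]), 80, tolerance = 1e-10)
  }
  # random draws: all 22 parameters back to ~machine precision
  set.seed(401)
  for (i in 1:20) {
    th <- random_tensors()
    y <- dki_signal(th$s0, th$D, th$W, gt)
    f <- dki_fit(y, gt, method = if (i %% 2) "ols" else "wls")
    expect_lt(max_rel_err(f$D[1, ], th$D), 1e-8)
    expect_lt(max_rel_err(f$W[1, ], th$W), 1e-8)
    expect_lt(abs(f$s0[1] / th$s0 - 1), 1e-8)
  }
})

test_that("predict/fit round-trips and residuals vanish on noiseless data", {
  gt <- paper_gtab()
  set.seed(402)
  th <- random_tensors()
  y <- dki_signal(th$s0, th$D, th$W, gt)
  f <- dki_fit(y, gt)
  expect_lt(max(abs(residuals(f))), 1e-7)
  expect_equal(drop(predict(f)), y, tolerance = 1e-9)
  # refitting the prediction reproduces the coefficients
  f2 <- dki_fit(drop(predict(f)), gt)
  expect_equal(coef(f2), coef(f), tolerance = 1e-9)
})

test_that("apparent-kurtosis convention rescales the tensor diagonal by md^2/Dii^2", {
  gt <- paper_gtab()
  # D = diag(1,2,3)e-3, Wxxxx = 0.6 => md = 2e-3, apparent kxxxx = 4 * 0.6
  y <- dki_signal(1, c(1, 2, 3) * 1e-3, c(0.6, 0.3, 0.2), gt)
  f <- dki_fit(y, gt)
  tens <- axis_metrics(f, "tensor")
  app <- axis_metrics(f, "apparent")
  expect_equal(tens$kxxxx[1, 1, 1], 0.6, tolerance = 1e-8)
  expect_equal(app$kxxxx[1, 1, 1], (2^2 / 1^2) * 0.6, tolerance = 1e-8)
  expect_equal(app$kyyyy[1, 1, 1], (2^2 / 2^2) * 0.3, tolerance = 1e-8)
  expect_equal(app$kzzzz[1, 1, 1], (2^2 / 3^2) * 0.2, tolerance = 1e-8)
  # conventions agree when kurtosis is isotropic in the apparent sense only
  # if D is isotropic: check identity convention returns raw W
  set.seed(403)
  th <- random_tensors()
  f2 <- dki_fit(dki_signal(th$s0, th$D, th$W, gt), gt)
  t2 <- axis_metrics(f2, "tensor")
  expect_equal(c(t2$kxxxx[1,1,1], t2$kyyyy[1,1,1], t2$kzzzz[1,1,1]),
               th$W[1:3], tolerance = 1e-7)
})

test_that("axis permutation of tensors and gradients permutes fitted metrics", {
  gt <- paper_gtab()
  set.seed(404)
  th <- random_tensors()
  y <- dki_signal(th$s0, th$D, th$W, gt)
  f1 <- dki_fit(y, gt)
  # relabel axes x->y->z->x by permuting the direction columns
  perm <- c(3L, 1L, 2L)   # new axis i reads old axis perm[i]
  gt_p <- gradient_table(gt$bvals, gt$bvecs[, perm])
  f2 <- dki_fit(y, gt_p)
  expect_equal(f2$D[1, c("dxx", "dyy", "dzz")],
               f1$D[1, c("dxx", "dyy", "dzz")][perm],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(f2$W[1, c("wxxxx", "wyyyy", "wzzzz")],
               f1$W[1, c("wxxxx", "wyyyy", "wzzzz")][perm],
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(f2$md[1], f1$md[1], tolerance = 1e-10)
})

test_that("crossing-fibre mixtures show positive kurtosis along the crossing axes", {
  gt <- paper_gtab()
  mix <- mixture_model(c(0.5, 0.5), list(c(0.3, 0.3, 1.7) * 1e-3,
                                         c(0.3, 1.7, 0.3) * 1e-3))
  f <- dki_fit(simulate_voxel(mix, gt), gt)
  app <- axis_metrics(f, "apparent")
  expect_gt(app$kyyyy[1, 1, 1], 0.5)
  expect_gt(app$kzzzz[1, 1, 1], 0.5)
  # the x axis sees identical compartments: far less kurtosis than y/z
  expect_lt(app$kxxxx[1, 1, 1], 0.5 * app$kzzzz[1, 1, 1])
})

test_that("volume fits equal independent voxel fits and QC flags propagate", {
  gt <- paper_gtab()
  spec <- phantom_spec(grid_shape = c(10L, 10L, 6L), box_width = 3L)
  ph <- build_phantom(spec)
  fit <- dki_fit(ph$dwi)
  # every proj_left voxel equals the single-voxel fit bitwise
  one <- dki_fit(simulate_voxel(spec$models$proj_left, gt), gt)
  sel <- which(fit$voxels[, 1] == 3 & fit$voxels[, 2] == 3 & fit$voxels[, 3] == 4)
  expect_gte(length(sel), 1L)
  expect_equal(fit$D[sel[1], ], one$D[1, ], tolerance = 1e-12)
  expect_equal(fit$W[sel[1], ], one$W[1, ], tolerance = 1e-12)

  expect_error(dki_fit(ph$dwi, mask = array(FALSE, dim(ph$dwi$data)[1:3])),
               "empty mask")

  # a voxel with nonpositive signal is flagged, not clamped
  bad <- ph$dwi
  bad$data[3, 3, 4, 5] <- -1
  fb <- dki_fit(bad)
  vb <- which(fb$voxels[, 1] == 3 & fb$voxels[, 2] == 3 & fb$voxels[, 3] == 4)
  expect_true(fb$flags$invalid_signal[vb])
  expect_false(fb$valid[vb])
  expect_true(all(is.na(fb$D[vb, ])))
  maps <- axis_metrics(fb)
  expect_true(is.nan(maps$dxx[3, 3, 4]))

  s <- summary(fit)
  expect_equal(s$n_valid, sum(fit$valid))
})

test_that("noisy fits are nearly unbiased for the diffusivity diagonal", {
  gt <- paper_gtab()
  set.seed(405)
  m <- explicit_model(c(1.0, 0.6, 1.6) * 1e-3, c(1.30, 0.80, 0.60), 100)
  sig <- simulate_voxel(m, gt)
  n <- 400
  S <- add_noise(matrix(rep(sig, each = n), n), snr = 30, s0_ref = 100)
  dwi <- dwi_volume(array(S, c(n, 1, 1, length(sig))), diag(4), gt)
  f <- dki_fit(dwi)
  expect_gt(mean(f$valid), 0.95)
  est <- colMeans(f$D[f$valid, c("dxx", "dyy", "dzz")])
  expect_lt(max_rel_err(est, c(1.0, 0.6, 1.6) * 1e-3), 0.015)
})
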