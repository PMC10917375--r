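test_that("HRF convolution: no events give zero, an impulse gives the HRF", {
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      trial_type = character(0))
  d0 <- build_design(rbind(empty, data.frame(onset = 10, duration = 0.125,
                                             trial_type = "Go")),
                     TR = 2, n_volumes = 40, microtime_dt = 0.125)
  # near-impulse event: regressor proportional to the sampled canonical HRF
  tt <- (0:39) * 2 - 10
  href <- ifelse(tt >= 0 & tt <= 32, canonical_hrf(pmax(tt, 0)), 0) *
    0.125  # boxcar area
  expect_gt(cor(d0$X[tt >= 0 & tt <= 32, "Go"], href[tt >= 0 & tt <= 32]),
            0.9999)

  d1 <- build_design(data.frame(onset = 5, duration = 2, trial_type = "Go"),
                     TR = 2, n_volumes = 30)
  expect_equal(ncol(d1$X), 1)
  d_none <- tryCatch(
    build_design(data.frame(onset = 1, duration = 1,
                            trial_type = c("Go"))[0, ],
                 TR = 2, n_volumes = 30),
    error = function(e) e
  )
  # an empty event table has no condition regressors to build
  expect_true(inherits(d_none, "error") || ncol(d_none$X) == 0)
})

test_that("cosine high-pass basis has floor(2T/cutoff)+1 columns", {
  expect_equal(ncol(dct_basis(300, 2, 128)), 10)  # 600 s at 1/128 Hz
  expect_equal(ncol(dct_basis(64, 2, 128)), 3)
  # first column is the constant
  expect_equal(diff(range(dct_basis(50, 2)[, 1])), 0)
})

test_that("OLS contrast matches the normal-equations oracle to 1e-10", {
  set.seed(11)
  ev <- data.frame(onset = c(10, 30, 50, 70), duration = 2,
                   trial_type = c("Go", "NoGo", "Go", "NoGo"))
  des <- build_design(ev, TR = 2, n_volumes = 60)
  Y <- matrix(rnorm(60 * 3), 60, 3)
  res <- fit_contrast(Y, des, c(Go = -1, NoGo = 1))
  # brute-force oracle: full design, normal equations, t by definition
  Xf <- cbind(des$X, des$nuisance)
  cw <- c(-1, 1, rep(0, ncol(des$nuisance)))
  XtXi <- solve(crossprod(Xf))
  for (j in 1:3) {
    beta <- XtXi %*% crossprod(Xf, Y[, j])
    r <- Y[, j] - Xf %*% beta
    df <- 60 - qr(Xf)$rank
    s2 <- sum(r^2) / df
    tj <- drop(crossprod(cw, beta)) / sqrt(s2 * drop(crossprod(cw, XtXi %*% cw)))
    expect_equal(res$table$t[j], tj, tolerance = 1e-10)
  }
  expect_equal(res$df, 60 - qr(Xf)$rank)
  # peak table sorted by t descending
  expect_true(all(diff(res$peaks$t) <= 0))
})

test_that("degenerate contrasts and perfect fits are flagged", {
  ev <- data.frame(onset = c(10, 30), duration = 2,
                   trial_type = c("Go", "NoGo"))
  des <- build_design(ev, TR = 2, n_volumes = 40)
  Y <- matrix(rnorm(40), 40, 1)
  expect_error(fit_contrast(Y, des, c(Go = 0, NoGo = 0)), "degenerate")
  # data exactly in the model span: zero residual variance
  Yexact <- des$X %*% c(2, -1)
  expect_error(fit_contrast(Yexact, des, c(Go = -1, NoGo = 1)), "degenerate")
})

test_that("second-level t-tests run one- and two-sample variants", {
  set.seed(3)
  con <- rnorm(20, 0.5)
  g1 <- group_ttest(con)
  expect_equal(g1$df, 19)
  expect_equal(g1$t, mean(con) / (sd(con) / sqrt(20)), tolerance = 1e-12)
  grp <- factor(rep(c("f", "m"), each = 10))
  g2 <- group_ttest(con, grp)
  expect_equal(g2$df, 18)
})

test_that("ROI definition: argmax within mask and sphere, deterministic ties", {
  # 5x5x5 grid
  coords <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4))
  mask <- rep(TRUE, nrow(coords))
  tmap <- rnorm(nrow(coords))
  # single-voxel mask -> that voxel
  single <- define_roi(tmap, coords, coords[, 1] == 2 & coords[, 2] == 2 &
                         coords[, 3] == 2,
                       group_peak = c(2, 2, 2), radius = 2)
  expect_equal(unname(single$peak), c(2, 2, 2))
  expect_error(define_roi(tmap, coords, rep(FALSE, 125), c(2, 2, 2)), "empty")

  # synthetic blob centered off the group peak but inside the radius
  blob_center <- c(3, 2, 2)
  d2 <- rowSums(sweep(coords, 2, blob_center, "-")^2)
  tmap_blob <- exp(-d2 / 2)
  roi <- define_roi(tmap_blob, coords, mask, group_peak = c(2, 2, 2),
                    radius = 2)
  expect_equal(unname(roi$peak), blob_center)
  expect_false(roi$fallback)

  # all-equal t: lexicographically smallest coordinate wins
  tie <- define_roi(rep(1, 125), coords, mask, group_peak = c(2, 2, 2),
                    radius = 1)
  cand <- coords[rowSums(sweep(coords, 2, c(2, 2, 2), "-")^2) <= 1, ]
  expect_equal(unname(tie$peak),
               unname(cand[do.call(order, as.data.frame(cand))[1], ]))

  # no suprathreshold voxel: fall back to group peak, flagged
  fb <- define_roi(rep(0, 125), coords, mask, group_peak = c(1, 1, 1),
                   radius = 2, threshold = 1)
  expect_true(fb$fallback)
  expect_equal(unname(fb$peak), c(1, 1, 1))
})

test_that("eigenvariate extraction: identity, sign, noise robustness, order", {
  set.seed(7)
  base <- sin(seq(0, 6 * pi, length.out = 120))
  # single voxel: the voxel's series (demeaned) up to the scaling convention
  one <- extract_timeseries(matrix(base + 5, ncol = 1))
  expect_equal(one, base - mean(base), tolerance = 1e-10)

  # many copies plus noise at SNR 5: eigenvariate tracks the clean signal
  Y <- sapply(1:30, function(i) base + rnorm(120, sd = sd(base) / 5))
  ev <- extract_timeseries(Y)
  expect_gt(cor(ev, base), 0.99)
  expect_gt(cor(ev, rowMeans(Y)), 0)          # sign convention
  expect_equal(sd(ev), sd(rowMeans(Y) - mean(rowMeans(Y))), tolerance = 1e-10)

  # invariance to voxel ordering
  perm <- sample(30)
  expect_equal(extract_timeseries(Y[, perm]), ev, tolerance = 1e-8)

  expect_error(extract_timeseries(matrix(1, 10, 3)), "zero-variance")
})

test_that("toy voxel pipeline recovers the embedded node signal", {
  # embed one node's simulated BOLD into a small voxel patch, define the ROI
  # from a NoGo>Go contrast and extract the eigenvariate
  tpl <- default_truth_template()
  par <- generate_paradigm(small_paradigm())
  ts <- simulate_bold(tpl, par$design)
  node <- ts$values[, "IFG"]
  coords <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4))
  blob <- exp(-rowSums(sweep(coords, 2, c(2, 2, 2), "-")^2) / 4)
  set.seed(8)
  Y <- outer(node, blob) + matrix(rnorm(length(node) * 125, sd = sd(node) / 2),
                                  length(node))
  ev_events <- par$trials[, c("onset", "duration", "trial_type", "run")]
  des <- build_design(ev_events, TR = 2, n_volumes = par$design$n_volumes,
                      n_runs = 1)
  con <- fit_contrast(Y, des, c(Go = -1, NoGo = 1))
  roi <- define_roi(con$table$t, coords, mask = blob > 0.05,
                    group_peak = c(2, 2, 2), radius = 2)
  extracted <- extract_timeseries(Y, roi)
  expect_gt(abs(cor(extracted, node)), 0.9)
})
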