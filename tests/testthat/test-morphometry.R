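# build a bare stack with Gaussian blobs at given voxel positions
blob_stack <- function(dims, centers, amps, sxy = 3, sz = 4) {
  stk <- array(0, dim = dims)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; cz <- centers[i, 3]
    for (k in seq_len(dims[3]))
      for (ix in seq_len(dims[1]))
        stk[ix, , k] <- stk[ix, , k] + amps[i] *
          exp(-((ix - 1 - cx)^2 + (seq_len(dims[2]) - 1 - cy)^2) / (2 * sxy^2) -
                (k - 1 - cz)^2 / (2 * sz^2))
  }
  stk
}

test_that("profile of a uniform stack is constant", {
  stk <- array(7, dim = c(20, 20, 15))
  pr <- extract_profile(stk, c(5, 5), morph_params(), 1, 0.5)
  expect_true(all(pr$intensity == 7))
  expect_equal(pr$z, (0:14) * 0.5)
  expect_true(all(diff(pr$z) > 0))
})

test_that("profile peaks at the blob depth (exhaustive slice-scan oracle)", {
  stk <- blob_stack(c(40, 40, 30), cbind(20, 20, 12), amps = 100)
  pr <- extract_profile(stk, c(20, 20), morph_params(), 1, 1)
  expect_equal(which.max(pr$intensity), which.max(oracle_slicewise_max(stk)))
  expect_equal(which.max(pr$intensity), 13L)  # slice index of z0 = 12
})

test_that("two axially stacked blobs yield two local maxima at their depths", {
  stk <- blob_stack(c(40, 40, 40), rbind(c(20, 20, 10), c(20, 20, 20)),
                    amps = c(100, 80), sz = 2)
  pr <- extract_profile(stk, c(20, 20), morph_params(), 1, 1)
  y <- pr$intensity
  loc_max <- which(diff(sign(diff(y))) == -2) + 1L
  expect_setequal(loc_max, c(11L, 21L))
})

test_that("ROI seeds outside the image raise a bounds error", {
  stk <- array(0, dim = c(20, 20, 5))
  expect_error(extract_profile(stk, c(50, 5), morph_params(), 1, 1),
               "outside")
})

test_that("re-centering recovers the locally maximal peak", {
  stk <- blob_stack(c(40, 40, 20), cbind(20, 20, 8), amps = 200)
  off_center <- extract_profile(stk, c(21, 20), morph_params(), 1, 1)
  expect_equal(max(off_center$intensity), 200, tolerance = 1e-8)
})

test_that("peak shape: spike is bell, flat top is plateau, zeros are flagged", {
  tri <- structure(list(roi_id = "a", glomerulus_id = 1,
                        z = 0:10 / 2, intensity = c(0:5, 4:0)),
                   class = "intensity_profile")
  expect_equal(classify_peak_shape(tri)$shape, "bell")

  flat <- structure(list(roi_id = "b", glomerulus_id = 1,
                         z = 0:9 / 2, intensity = c(1, 2, rep(9, 6), 2, 1)),
                    class = "intensity_profile")
  rec <- classify_peak_shape(flat)
  expect_equal(rec$shape, "plateau")
  expect_equal(rec$peak_value, 9)
  expect_equal(c(rec$top1, rec$top2, rec$top3), c(9, 9, 9))

  zeros <- structure(list(roi_id = "c", glomerulus_id = 1,
                          z = 0:4, intensity = rep(0, 5)),
                     class = "intensity_profile")
  expect_equal(classify_peak_shape(zeros)$shape, "no_signal")
  expect_error(classify_peak_shape(structure(
    list(roi_id = "d", glomerulus_id = 1, z = 0:1, intensity = c(1, 2)),
    class = "intensity_profile")), "3 samples")
})

test_that("saturated synthetic cells classify plateau; clean twins bell", {
  cfg <- sim_config("WT", imaging.n_glomeruli = 1L,
                    imaging.cells_per_glomerulus = 10L,
                    imaging.img_size_px = 128L,
                    imaging.deep_cell_fraction = 0,
                    imaging.plateau_artifact_fraction = 0.5)
  sim <- gen_image_stack(cfg, seed = 21)
  shapes <- vapply(seq_len(nrow(sim$rois)), function(i) {
    pr <- extract_profile(sim$stacks[[1]],
                          c(sim$rois$x_um[i], sim$rois$y_um[i]),
                          morph_params(), sim$pixel_size_um, sim$z_step_um,
                          roi_id = sim$rois$roi_id[i])
    classify_peak_shape(pr, baseline = "lower_quantile")$shape
  }, character(1))
  expect_equal(shapes == "plateau", sim$truth$is_plateau)
})

test_that("depth and range filters match the enumerated-window oracle", {
  mk <- function(z) data.frame(roi_id = paste0("r", seq_along(z)),
                               glomerulus_id = 1, peak_z = z,
                               peak_value = 100, shape = "bell",
                               top1 = 100, top2 = 90, top3 = 80,
                               stringsAsFactors = FALSE)
  out <- filter_peaks(mk(c(5, 8, 12, 30, 40)))
  expect_setequal(out$peak_z, c(5, 8, 12))

  all_close <- mk(c(10, 12, 20, 24))
  expect_equal(nrow(filter_peaks(all_close)), 4L)

  expect_warning(res <- filter_peaks(mk(36)), "no peaks survive")
  expect_equal(nrow(res), 0L)

  # plateau peaks are dropped before windowing
  p <- mk(c(5, 8, 30))
  p$shape[3] <- "plateau"
  expect_setequal(filter_peaks(p)$peak_z, c(5, 8))
})

test_that("gap split: degenerate separation, invariances, tie flagging", {
  sp <- split_bright_dim(c(10, 10, 10, 1, 1))
  expect_true(sp$accepted)
  expect_equal(sp$labels, c("bright", "bright", "bright", "dim", "dim"))
  expect_equal(sp$gap, 9)

  v <- c(3, 11, 1, 12, 10.5)
  fwd <- split_bright_dim(v)
  rev_ <- split_bright_dim(rev(v))
  expect_equal(fwd$labels, rev(rev_$labels))

  scaled <- split_bright_dim(v * 17.3)
  expect_equal(scaled$labels, fwd$labels)

  tie <- split_bright_dim(c(0, 1, 3, 4, 6))  # two equal maximal gaps
  expect_false(tie$accepted)
  expect_null(tie$labels)
  expect_false(split_bright_dim(c(5, 5, 5))$accepted)
  expect_error(split_bright_dim(7), "at least 2")
})

test_that("gap split separates two well-separated normal components", {
  set.seed(31)
  comp <- rep(c("dim", "bright"), c(20, 30))
  vals <- ifelse(comp == "dim", rnorm(50, 10, 1), rnorm(50, 20, 1))
  sp <- split_bright_dim(vals)
  expect_true(sp$accepted)
  expect_equal(sp$labels, comp)
  expect_equal(oracle_gap_split(vals)$labels, sp$labels)
})

test_that("glomerulus composition arithmetic and one-class edge", {
  calls <- data.frame(glomerulus_id = 1, roi_id = letters[1:5],
                      class = c("bright", "bright", "bright", "dim", "dim"),
                      max_value = c(90, 100, 110, 9, 11))
  comp <- summarize_glomerulus(calls)
  expect_equal(comp$pct_bright, 60)
  expect_equal(comp$pct_dim, 40)
  expect_equal(comp$pct_bright + comp$pct_dim, 100)
  expect_equal(comp$mean_bright, 100)
  expect_equal(comp$mean_dim, 10)

  allb <- summarize_glomerulus(calls[calls$class == "bright", ])
  expect_equal(allb$pct_bright, 100)
  expect_equal(allb$pct_dim, 0)
  expect_true(is.na(allb$mean_dim))
})

test_that("Welch t agrees with the closed-form oracle", {
  a <- c(1, 2, 3, 4)
  same <- welch_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  b <- a + 10
  w <- welch_t_test(a, b)
  ref <- stats::t.test(a, b, var.equal = FALSE)
  expect_equal(w$t, unname(ref$statistic))
  expect_equal(w$df, unname(ref$parameter))
  expect_equal(w$p, ref$p.value)

  set.seed(8)
  x <- rnorm(9); y <- rgamma(14, 2)
  w2 <- welch_t_test(x, y)
  ref2 <- stats::t.test(x, y, var.equal = FALSE)
  expect_equal(w2$p, ref2$p.value)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("labels are invariant to positive rescaling of the whole stack", {
  cfg <- sim_config("WT", imaging.n_glomeruli = 1L,
                    imaging.cells_per_glomerulus = 8L,
                    imaging.img_size_px = 128L, imaging.noise = FALSE)
  sim <- gen_image_stack(cfg, seed = 13)
  run <- function(stk) {
    m <- morphometry_pipeline(list(stk), sim$rois, sim$pixel_size_um,
                              sim$z_step_um)
    m$calls[order(m$calls$roi_id), c("roi_id", "class")]
  }
  expect_equal(run(sim$stacks[[1]]), run(sim$stacks[[1]] * 2.7))
})
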