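test_that("moment statistics match hand-computed cases", {
  expect_equal(unname(channel_stats(rep(2.5, 10))), c(2.5, 0, 3))
  s <- channel_stats(c(0, 0, 1, 1))
  expect_equal(unname(s), c(0.5, 0, 1))
  s2 <- channel_stats(c(0, 0, 0, 1))
  expect_equal(unname(s2["skewness"]), 2 / sqrt(3), tolerance = 1e-9)  # 1.1547
  expect_equal(unname(s2["kurtosis"]), 7 / 3, tolerance = 1e-9)        # 2.3333
  expect_error(channel_stats(numeric(0)), "empty")
})

test_that("moment statistics agree with the naive summation oracle", {
  withr::with_seed(21, {
    for (i in 1:25) {
      x <- switch(1 + i %% 3,
                  rnorm(50), runif(200, 0, 255), rexp(17))
      expect_equal(channel_stats(x), oracle_channel_stats(x), tolerance = 1e-9)
    }
  })
})

test_that("GLCM matches hand-enumerated 2x2 cases", {
  g1 <- compute_glcm(matrix(c(0, 255, 0, 255), 2, 2), Ng = 2)  # rows (0,0),(255,255)
  expect_equal(g1$p, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  g2 <- compute_glcm(matrix(c(0, 0, 255, 255), 2, 2), Ng = 2)  # rows (0,255),(0,255)
  expect_equal(g2$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  g3 <- compute_glcm(matrix(100, 3, 3), Ng = 4)
  expect_equal(sum(g3$p), 1)
  expect_equal(g3$p[2, 2], 1)  # single diagonal cell (level 1 of 0..3)
  expect_error(compute_glcm(matrix(1, 2, 2), mask = matrix(FALSE, 2, 2)), "empty")
  expect_error(compute_glcm(matrix(1, 1, 1), Ng = 2), "DegenerateGlcm")
})

test_that("GLCM and its metrics equal the brute-force oracle on random images", {
  withr::with_seed(33, {
    for (rep in 1:100) {
      gray <- matrix(runif(64, 0, 255), 8, 8)
      Ng <- c(2, 4, 8)[1 + rep %% 3]
      mask <- if (rep %% 4 == 0) matrix(runif(64) > 0.2, 8, 8) else NULL
      if (!is.null(mask) && !any(mask)) mask[1, ] <- TRUE
      g <- compute_glcm(gray, mask, Ng = Ng)
      expect_equal(g$p, oracle_glcm(gray, mask, Ng = Ng), tolerance = 1e-9)
      roi <- if (is.null(mask)) as.vector(gray) else gray[mask]
      expect_equal(glcm_metrics(g, roi), oracle_glcm_metrics(g$p, roi),
                   tolerance = 1e-9)
    }
  })
})

test_that("GLCM metrics match closed forms on tiny matrices", {
  diag2 <- structure(list(p = matrix(c(0.5, 0, 0, 0.5), 2, 2), Ng = 2L,
                          offset = c(0L, 1L), symmetric = TRUE),
                     class = "glcm_matrix")
  m <- glcm_metrics(diag2, c(0, 255))
  expect_equal(unname(m[c("contrast", "correlation", "energy",
                          "homogeneity", "entropy")]),
               c(0, 1, 0.5, 1, 1))
  off2 <- diag2; off2$p <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  m2 <- glcm_metrics(off2, c(0, 255))
  expect_equal(unname(m2[c("contrast", "correlation", "energy",
                           "homogeneity", "entropy")]),
               c(1, -1, 0.5, 0.5, 1))
  const <- diag2; const$p <- matrix(c(1, 0, 0, 0), 2, 2)
  m3 <- glcm_metrics(const, rep(10, 4))
  expect_equal(unname(m3[c("contrast", "correlation", "energy",
                           "homogeneity", "entropy", "intensity")]),
               c(0, 1, 1, 1, 0, 10))
})

test_that("metric ranges hold on random GLCMs", {
  withr::with_seed(5, {
    for (i in 1:20) {
      gray <- matrix(runif(256, 0, 255), 16, 16)
      g <- compute_glcm(gray, Ng = 8)
      m <- glcm_metrics(g, as.vector(gray))
      expect_gt(m[["energy"]], 0); expect_lte(m[["energy"]], 1)
      expect_gt(m[["homogeneity"]], 0); expect_lte(m[["homogeneity"]], 1)
      expect_gte(m[["entropy"]], 0); expect_lte(m[["entropy"]], 2 * log2(8))
      expect_gte(m[["correlation"]], -1); expect_lte(m[["correlation"]], 1)
    }
  })
})

test_that("feature vector has the 51-name schema with 45 moment entries", {
  m <- response_model()
  sim <- simulate_spot(m, noisy_scene(seed = 8L), 5)
  roi <- segment_spot(sim$image)
  fv <- extract_features(sim$image, roi)
  expect_length(fv, 51L)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_length(grep("_(mean|skew|kurt)$", names(fv)), 45L)
  expect_length(grep("^(glcm_|gray_intensity)", names(fv)), 6L)
})

test_that("constant-color ROI collapses to the degenerate moment values", {
  img <- array(rep(c(0.3, 0.5, 0.7), each = 36), dim = c(6, 6, 3))
  fv <- extract_features(img, matrix(TRUE, 6, 6))
  expect_true(all(abs(fv[grep("_skew$", names(fv))]) < 1e-9))
  expect_true(all(abs(fv[grep("_kurt$", names(fv))] - 3) < 1e-9))
})

test_that("moment features are invariant to ROI pixel ordering", {
  m <- response_model()
  sim <- simulate_spot(m, noisy_scene(seed = 13L), 5)
  roi <- segment_spot(sim$image)
  px <- extract_roi_pixels(sim$image, roi)
  st1 <- channel_stack(px)
  withr::with_seed(1, {
    st2 <- channel_stack(px[sample(nrow(px)), ])
  })
  for (ch in colnames(st1)[1:15]) {
    expect_equal(channel_stats(st1[, ch]), channel_stats(st2[, ch]),
                 tolerance = 1e-9)
  }
})
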