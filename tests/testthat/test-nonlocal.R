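test_that("extract_patch returns interior windows verbatim and reflects at borders", {
  cfg3 <- patch_config(3, 5)
  ramp <- matrix(1:25, 5, 5)
  expect_identical(extract_patch(ramp, c(3, 3), cfg3), ramp[2:4, 2:4])
  # constant image: constant patch anywhere
  expect_true(all(extract_patch(matrix(2, 5, 5), c(1, 5), cfg3) == 2))
  # corner patch is symmetric about the corner (reflection padding)
  corner <- extract_patch(ramp, c(1, 1), cfg3)
  expect_identical(corner[1, ], corner[2, ])
  expect_identical(corner[, 1], corner[, 2])
  expect_identical(corner[2:3, 2:3], ramp[1:2, 1:2])
  expect_error(extract_patch(ramp, c(0, 3), cfg3), class = "nchr_index_error")
  expect_error(patch_config(4, 21), class = "nchr_invalid_config")
  expect_error(patch_config(9, 7), class = "nchr_invalid_config")
})

test_that("neighbor indicator excludes exactly the self pixel and is symmetric", {
  expect_identical(neighbor_indicator(c(5, 5), c(5, 5)), 0L)
  expect_identical(neighbor_indicator(c(3, 7), c(3, 8)), 1L)
  pts <- expand.grid(r = 1:3, c = 1:3)
  for (a in seq_len(nrow(pts))) for (b in seq_len(nrow(pts))) {
    x <- as.integer(pts[a, ]); i <- as.integer(pts[b, ])
    expect_identical(neighbor_indicator(x, i), neighbor_indicator(i, x))
  }
})

test_that("James-Stein shrinkage factor follows the positive-part rule", {
  expect_equal(js_shrinkage_factor(100, 0.3, 441), 1 - 439 * 0.09 / 100,
               tolerance = 1e-14)
  expect_identical(js_shrinkage_factor(1, 0.3, 441), 0)   # clipped
  expect_identical(js_shrinkage_factor(5, 0, 441), 1)     # no shrinkage
  expect_identical(js_shrinkage_factor(0, 0.3, 441), 0)   # zero residual
  expect_error(js_shrinkage_factor(-1, 0.3, 9), class = "nchr_domain_error")
  expect_error(js_shrinkage_factor(1, 0.3, 2), class = "nchr_domain_error")
})

test_that("weight field matches the brute-force oracle in both modes", {
  cfg <- patch_config(3, 5)
  cur <- withr::with_seed(21L, matrix(runif(16 * 16), 16, 16))
  noi <- cur + withr::with_seed(22L, matrix(rnorm(16 * 16, 0, 0.4), 16, 16))
  for (mode in c("modified-js", "conventional")) {
    wf <- weight_field(cur, noi, 0.5, cfg, mode = mode)
    bf <- bf_weight_field(cur, noi, 0.5, 3, 5, mode = mode)
    expect_lt(max(abs(wf$w - bf)), 1e-10)
  }
  # neighborhood-count reading of the shrinkage dimension
  wf_n <- weight_field(cur, noi, 0.5, cfg, js_count = "neighborhood")
  bf_n <- bf_weight_field(cur, noi, 0.5, 3, 5, js_count = "neighborhood")
  expect_lt(max(abs(wf_n$w - bf_n)), 1e-10)
})

test_that("per-pair weights agree with the field and respect the bounds", {
  cfg <- patch_config(3, 5)
  cur <- withr::with_seed(31L, matrix(runif(10 * 10), 10, 10))
  noi <- cur + withr::with_seed(32L, matrix(rnorm(100, 0, 0.4), 10, 10))
  wf_m <- weight_field(cur, noi, 0.5, cfg, mode = "modified-js")
  wf_c <- weight_field(cur, noi, 0.5, cfg, mode = "conventional")
  for (px in c(1L, 23L, 55L, 100L)) {
    r <- (px - 1L) %% 10L + 1L; cc <- (px - 1L) %/% 10L + 1L
    for (dr in -2:2) for (dc in -2:2) {
      j <- (dc + 2L) * 5L + (dr + 2L) + 1L
      i <- c(r + dr, cc + dc)
      expect_equal(wf_m$w[px, j], nl_weight(cur, c(r, cc), i, 0.5, noi, cfg),
                   tolerance = 1e-12)
      wc <- if (dr == 0 && dc == 0) 0
            else conventional_nl_weight(cur, c(r, cc), i, 0.5, cfg)
      expect_equal(wf_c$w[px, j], wc, tolerance = 1e-12)
    }
  }
  # 0 <= modified <= conventional <= 1, self-weight exactly 0
  expect_true(all(wf_m$w >= 0))
  expect_true(all(wf_m$w <= wf_c$w + 1e-15))
  expect_true(all(wf_c$w <= 1))
  self_col <- (0 + 2L) * 5L + (0 + 2L) + 1L
  expect_true(all(wf_m$w[, self_col] == 0))
  expect_true(all(wf_c$w[, self_col] == 0))
  expect_error(nl_weight(cur, c(1, 1), c(1, 2), 0, noi, cfg),
               class = "nchr_domain_error")
})

test_that("conventional weights are symmetric; modified weights need not be", {
  cfg <- patch_config(3, 5)
  cur <- withr::with_seed(41L, matrix(runif(12 * 12), 12, 12))
  noi <- cur + withr::with_seed(42L, matrix(rnorm(144, 0, 0.4), 12, 12))
  pairs <- withr::with_seed(43L, cbind(
    r = sample(3:10, 20, replace = TRUE), c = sample(3:10, 20, replace = TRUE),
    dr = sample(-2:2, 20, replace = TRUE), dc = sample(-2:2, 20, replace = TRUE)
  ))
  for (k in seq_len(nrow(pairs))) {
    x <- pairs[k, c("r", "c")]
    i <- x + pairs[k, c("dr", "dc")]
    expect_equal(conventional_nl_weight(cur, x, i, 0.5, cfg),
                 conventional_nl_weight(cur, i, x, 0.5, cfg),
                 tolerance = 1e-13)
  }
})

test_that("penalty matches the brute-force oracle and vanishes when it should", {
  cfg <- patch_config(3, 5)
  img <- withr::with_seed(51L, matrix(runif(8 * 8), 8, 8))
  wf <- weight_field(img, img + 0.3, 0.5, cfg, mode = "conventional")
  rho <- nl_penalty(img, wf)
  rho_bf <- bf_penalty(img, wf$w, 3, 5)
  expect_lt(abs(rho - rho_bf) / rho_bf, 1e-8)
  # constant image: all patch differences vanish
  wf_const <- weight_field(matrix(1, 8, 8), matrix(1.2, 8, 8), 0.5, cfg,
                           mode = "conventional")
  expect_identical(nl_penalty(matrix(1, 8, 8), wf_const), 0)
  # all-zero weights (modified mode with zero residual): zero penalty
  wf0 <- weight_field(img, img, 0.5, cfg, mode = "modified-js")
  expect_true(all(wf0$w == 0))
  expect_identical(nl_penalty(img, wf0), 0)
})

test_that("penalty gradient matches finite differences and is linear in the image", {
  cfg <- patch_config(3, 5)
  img <- withr::with_seed(61L, matrix(runif(8 * 8), 8, 8))
  wf <- weight_field(img, img + 0.3, 0.5, cfg, mode = "conventional")
  g <- nl_penalty_gradient(img, wf)
  gbf <- bf_gradient(img, wf$w, 3, 5)
  expect_lt(max(abs(g - gbf)) / max(abs(gbf)), 1e-10)
  h <- 1e-5
  gfd <- matrix(0, 8, 8)
  for (r in 1:8) for (cc in 1:8) {
    p1 <- img; p1[r, cc] <- p1[r, cc] + h
    p2 <- img; p2[r, cc] <- p2[r, cc] - h
    gfd[r, cc] <- (nl_penalty(p1, wf) - nl_penalty(p2, wf)) / (2 * h)
  }
  expect_lt(max(abs(g - gfd)) / max(abs(gfd)), 1e-4)
  # constant image sits at the penalty minimum
  expect_true(all(nl_penalty_gradient(matrix(3, 8, 8), wf) == 0))
  # frozen weights make rho quadratic: gradient scales linearly
  expect_equal(nl_penalty_gradient(2.5 * img, wf), 2.5 * g, tolerance = 1e-10)
})

test_that("rho is non-increasing along a small frozen-weight gradient step", {
  cfg <- patch_config(3, 5)
  for (s in 1:5) {
    img <- withr::with_seed(70L + s, matrix(runif(10 * 10), 10, 10))
    wf <- weight_field(img, img + 0.3, 0.6, cfg, mode = "conventional")
    g <- nl_penalty_gradient(img, wf)
    step <- 1e-3 / max(abs(g))
    expect_lte(nl_penalty(img - step * g, wf), nl_penalty(img, wf) + 1e-12)
  }
})
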