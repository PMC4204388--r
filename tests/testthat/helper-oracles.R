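# Brute-force reference implementations used as independent oracles.
# Everything here is deliberately written as plain nested loops over the
# definitions, with no calls into the package's fast paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

bf_reflect <- function(i, n) {
  p <- (i - 1) %% (2 * n)
  ifelse(p >= n, 2 * n - 1 - p, p) + 1
}

bf_patch <- function(img, center, pr) {
  img[bf_reflect(center[1] + (-pr:pr), nrow(img)),
      bf_reflect(center[2] + (-pr:pr), ncol(img)), drop = FALSE]
}

# Weight matrix in the package's layout: rows = pixels (column-major),
# column j = offset (dr, dc) with j = (dc+nr)*neigh + (dr+nr) + 1.
bf_weight_field <- function(current, noisy, sigma, patch, neigh,
                            mode = "modified-js", js_count = "patch") {
  H <- nrow(current); W <- ncol(current)
  pr <- patch %/% 2; nr <- neigh %/% 2
  m <- if (js_count == "patch") patch^2 else neigh^2
  w <- matrix(0, H * W, neigh^2)
  for (cc in 1:W) for (r in 1:H) {
    px <- (cc - 1) * H + r
    if (mode == "modified-js") {
      res <- bf_patch(noisy, c(r, cc), pr) - bf_patch(current, c(r, cc), pr)
      rn <- sum(res^2)
      js <- if (rn > 0) max(0, 1 - (m - 2) * sigma^2 / rn) else 0
    } else js <- 1
    if (js == 0) next
    p_x <- bf_patch(current, c(r, cc), pr)
    for (dc in -nr:nr) for (dr in -nr:nr) {
      if (dr == 0 && dc == 0) next
      j <- (dc + nr) * neigh + (dr + nr) + 1
      p_i <- bf_patch(current, c(r + dr, cc + dc), pr)
      w[px, j] <- js * exp(-sum((p_x - p_i)^2) / (2 * sigma^2))
    }
  }
  w
}

bf_penalty <- function(image, w, patch, neigh) {
  H <- nrow(image); W <- ncol(image)
  pr <- patch %/% 2; nr <- neigh %/% 2
  acc <- 0
  for (cc in 1:W) for (r in 1:H) {
    px <- (cc - 1) * H + r
    p_x <- bf_patch(image, c(r, cc), pr)
    for (dc in -nr:nr) for (dr in -nr:nr) {
      if (dr == 0 && dc == 0) next
      j <- (dc + nr) * neigh + (dr + nr) + 1
      if (w[px, j] == 0) next
      p_i <- bf_patch(image, c(r + dr, cc + dc), pr)
      acc <- acc + w[px, j] * sum((p_x - p_i)^2)
    }
  }
  acc
}

# Analytic gradient by direct accumulation of every term's two pixels.
bf_gradient <- function(image, w, patch, neigh) {
  H <- nrow(image); W <- ncol(image)
  pr <- patch %/% 2; nr <- neigh %/% 2
  g <- matrix(0, H, W)
  for (cc in 1:W) for (r in 1:H) {
    px <- (cc - 1) * H + r
    for (dc in -nr:nr) for (dr in -nr:nr) {
      if (dr == 0 && dc == 0) next
      j <- (dc + nr) * neigh + (dr + nr) + 1
      wj <- w[px, j]
      if (wj == 0) next
      for (uc in -pr:pr) for (ur in -pr:pr) {
        a_r <- bf_reflect(r + ur, H); a_c <- bf_reflect(cc + uc, W)
        b_r <- bf_reflect(r + dr + ur, H); b_c <- bf_reflect(cc + dc + uc, W)
        d <- image[a_r, a_c] - image[b_r, b_c]
        g[a_r, a_c] <- g[a_r, a_c] + 2 * wj * d
        g[b_r, b_c] <- g[b_r, b_c] - 2 * wj * d
      }
    }
  }
  g
}

# One sigma level of the solver, replicated with the brute-force pieces and
# a numeric backtracking line search (penalty re-evaluated per trial step).
bf_descent_step <- function(current, noisy, sigma, patch, neigh,
                            lambda = 0.7, inner_iters = 5,
                            mode = "modified-js", js_count = "patch") {
  if (mode == "modified-js" && max(abs(noisy - current)) == 0)
    mode <- "conventional"
  w <- bf_weight_field(current, noisy, sigma, patch, neigh, mode, js_count)
  rho0 <- bf_penalty(current, w, patch, neigh)
  if (rho0 > 0) {
    for (k in seq_len(inner_iters)) {
      g <- bf_gradient(current, w, patch, neigh)
      gmax <- max(abs(g))
      if (gmax == 0) break
      step <- lambda / gmax
      accepted <- FALSE
      for (bt in 1:60) {
        cand <- current - step * g
        rho1 <- bf_penalty(cand, w, patch, neigh)
        if (rho1 <= rho0) { accepted <- TRUE; break }
        step <- step / 2
      }
      if (!accepted) break
      current <- cand
      rho0 <- rho1
    }
  }
  current
}

# Straight-line replication of the full reconstruction loop.
bf_reconstruct <- function(coeff, delta, sigmas, patch, neigh,
                           lambda = 0.7, inner_iters = 5, conv_tol = 1e-4,
                           mode = "modified-js", js_count = "patch") {
  N <- length(coeff)
  naive <- Re(fft(coeff, inverse = TRUE) / sqrt(N))
  current <- naive
  for (s in sigmas) {
    prev <- current
    current <- bf_descent_step(current, naive, s, patch, neigh,
                               lambda, inner_iters, mode, js_count)
    Fh <- fft(current) / sqrt(N)
    d <- Fh - coeff
    if (delta == 0) {
      Fh <- coeff
    } else {
      md <- Mod(d)
      Fh <- coeff + d * ifelse(md > delta, delta / md, 1)
    }
    current <- Re(fft(Fh, inverse = TRUE) / sqrt(N))
    rel <- sqrt(sum((current - prev)^2)) / sqrt(sum(prev^2))
    if (rel < conv_tol) break
  }
  current
}

# Small test fixtures -------------------------------------------------------

# Flat three-layer phantom spec usable down to 32x32.
small_phantom_spec <- function(height = 32L, width = 32L, seed = 1L,
                               wave_amplitude = 0) {
  phantom_spec(
    height = height, width = width,
    layer_tops = round(c(0.3, 0.55, 0.8) * height),
    layer_reflectivities = c(0.8, 0.3, 1.0),
    wave_amplitude = wave_amplitude, roi_margin = 2L, seed = seed
  )
}

# A measurement of a random smooth-ish image, no phantom machinery.
random_measurement <- function(H, W, noise_std = 0.05, delta = NULL,
                               seed = 1L) {
  img <- withr::with_seed(seed, {
    base <- matrix(rnorm(H * W), H, W)
    (base + base[c(2:H, H), ] + base[, c(2:W, W)]) / 3 + 1
  })
  coeff <- fft(img) / sqrt(H * W)
  if (noise_std > 0) {
    noise <- withr::with_seed(seed + 1000L, complex(
      real = rnorm(H * W, 0, noise_std / sqrt(2)),
      imaginary = rnorm(H * W, 0, noise_std / sqrt(2))
    ))
    coeff <- coeff + matrix(noise, H, W)
  }
  kspace_measurement(coeff, delta = delta %||% (3 * noise_std),
                     meta = list(noise_std = noise_std))
}
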