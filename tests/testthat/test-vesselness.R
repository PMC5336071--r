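test_that("gaussian_kernel is normalized, symmetric, with the right falloff", {
  for (s in c(0.8, 1, 2.3)) {
    k <- gaussian_kernel(s)
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_identical(k, rev(k))
    expect_equal(length(k), 2 * ceiling(3 * s) + 1)
  }
  k <- gaussian_kernel(1)
  c0 <- ceiling(3) + 1
  expect_equal(k[c0 + 1] / k[c0], exp(-0.5), tolerance = 1e-12)
  expect_error(gaussian_kernel(0), "positive")
  expect_error(gaussian_kernel(-2), "positive")
})

test_that("hessian responses vanish on constants and linear ramps", {
  const <- matrix(113, 20, 20)
  h <- hessian_at_scale(const, 1.5)
  expect_equal(max(abs(h$ixx)), 0)
  expect_equal(max(abs(h$ixy)), 0)
  expect_equal(max(abs(h$iyy)), 0)

  ramp <- matrix(rep(seq_len(40), each = 30), 30, 40)  # I(r,c) = c
  h <- hessian_at_scale(ramp, 2)
  interior <- 10:20
  expect_lt(max(abs(h$ixx[interior, interior])), 1e-8)
  expect_lt(max(abs(h$iyy[interior, interior])), 1e-8)
  expect_lt(max(abs(h$ixy[interior, interior])), 1e-8)
})

test_that("a vertical dark line produces the expected Hessian signature", {
  # dark vertical line of Gaussian cross-profile, sd w: at the centerline
  # ixx = contrast * sigma^2 * w... analytic convolution of two Gaussians:
  # response of gamma-normalized d2/dx2 at sigma on profile -A*exp(-x^2/2w^2)
  # is +A * sigma^2 * w / (sigma^2 + w^2)^(3/2) at x = 0.
  w <- 2; A <- 100; sig <- 2
  nc <- 41; nr <- 31; cc <- 21
  prof <- -A * exp(-((1:nc) - cc)^2 / (2 * w^2))
  img <- matrix(rep(200 + prof, each = nr), nr, nc)
  img <- round(pmin(pmax(img, 0), 255))
  h <- hessian_at_scale(img, sig)
  expected <- A * sig^2 * w / (sig^2 + w^2)^1.5
  got <- h$ixx[16, cc]
  expect_gt(got, 0)
  expect_equal(got, expected, tolerance = 0.1)
  expect_lt(abs(h$iyy[16, cc]), 0.1 * got)
  expect_lt(abs(h$ixy[16, cc]), 0.1 * got)
})

test_that("closed-form eigenanalysis handles canonical cases", {
  mk <- function(a, b, d) list(ixx = matrix(a, 1, 1), ixy = matrix(b, 1, 1),
                               iyy = matrix(d, 1, 1))
  e <- eigen_decompose(mk(2, 0, 0))
  expect_equal(e$lambda1[1, 1], 0)
  expect_equal(e$lambda2[1, 1], 2)
  expect_equal(abs(e$v2[1, 1, ]), c(1, 0))   # x axis

  e <- eigen_decompose(mk(0, 1, 0))
  expect_equal(sort(c(e$lambda1[1, 1], e$lambda2[1, 1])), c(-1, 1))
  expect_equal(abs(e$lambda1[1, 1]), abs(e$lambda2[1, 1]))

  e <- eigen_decompose(mk(5, 0, 5))          # isotropic: orthonormal basis
  expect_equal(e$v1[1, 1, ], c(1, 0))
  expect_equal(e$v2[1, 1, ], c(0, 1))
})

test_that("eigen field matches a dense symmetric eigensolver and its identities", {
  set.seed(101)
  n <- 1000
  a <- rnorm(n, sd = 5); b <- rnorm(n, sd = 5); d <- rnorm(n, sd = 5)
  h <- list(ixx = matrix(a, 1, n), ixy = matrix(b, 1, n), iyy = matrix(d, 1, n))
  e <- eigen_decompose(h)
  for (i in seq_len(n)) {
    ref <- eigen(matrix(c(a[i], b[i], b[i], d[i]), 2, 2), symmetric = TRUE)
    got <- c(e$lambda1[1, i], e$lambda2[1, i])
    expect_lt(max(abs(sort(got) - sort(ref$values))), 1e-9)
  }
  # ordering, trace, determinant, orthonormality on a random 64 x 64 field
  set.seed(102)
  hf <- list(ixx = matrix(rnorm(64^2), 64), ixy = matrix(rnorm(64^2), 64),
             iyy = matrix(rnorm(64^2), 64))
  ef <- eigen_decompose(hf)
  expect_true(all(abs(ef$lambda1) <= abs(ef$lambda2) + 1e-12))
  expect_lt(max(abs(ef$lambda1 + ef$lambda2 - (hf$ixx + hf$iyy))), 1e-6)
  expect_lt(max(abs(ef$lambda1 * ef$lambda2 - (hf$ixx * hf$iyy - hf$ixy^2))), 1e-6)
  dot <- ef$v1[, , 1] * ef$v2[, , 1] + ef$v1[, , 2] * ef$v2[, , 2]
  n1 <- ef$v1[, , 1]^2 + ef$v1[, , 2]^2
  expect_lt(max(abs(dot)), 1e-6)
  expect_lt(max(abs(n1 - 1)), 1e-6)
})

test_that("blobness ratio and structureness follow their closed forms", {
  expect_equal(blobness_ratio(0, 5), 0)
  expect_equal(blobness_ratio(3, 3), 1)
  expect_equal(blobness_ratio(1, 2), 0.5)
  expect_equal(blobness_ratio(1, 0), 0)     # guarded division
  expect_equal(structureness(0, 0), 0)
  expect_equal(structureness(3, 4), 5)
  expect_equal(structureness(-4, 3), structureness(3, 4))
})

test_that("single-scale vesselness matches Frangi's formula and polarity rule", {
  mk <- function(l1, l2) list(lambda1 = matrix(l1, 1, 1), lambda2 = matrix(l2, 1, 1))
  # negative lambda2 scores zero for dark vessels
  expect_equal(vesselness_at_scale(mk(0.1, -3), 0.5, 10)[1, 1], 0)
  # ideal line: lambda1 = 0, S >> c gives a score approaching 1
  expect_gt(vesselness_at_scale(mk(0, 1000), 0.5, 1)[1, 1], 0.999)
  # blob with lambda1 = lambda2 > 0: first factor is exp(-2) at beta = 0.5
  v <- vesselness_at_scale(mk(5, 5), 0.5, 1e-6)[1, 1]
  expect_equal(v, exp(-2), tolerance = 1e-6)
  # bright polarity inverts the sign condition
  expect_gt(vesselness_at_scale(mk(0, -1000), 0.5, 1, polarity = "bright")[1, 1], 0.999)
  expect_equal(vesselness_at_scale(mk(0, 1000), 0.5, 1, polarity = "bright")[1, 1], 0)
})

test_that("frangi output lies in [0,1), is zero on constants, suppresses bright ridges", {
  expect_true(all(frangi(matrix(128, 20, 30))$values == 0))
  img <- line_image()
  v <- frangi(img, vesselness_params(scales = c(1, 2, 3)))
  expect_true(all(v$values >= 0 & v$values < 1))
  expect_true(all(v$argmax_scale %in% c(1, 2, 3)))
  # bright line on dark background: lambda2 < 0 on the ridge, score 0 there
  bright <- 255 - img
  vb <- frangi(bright, vesselness_params(scales = c(1, 2, 3)))
  expect_equal(max(vb$values[21, 10:70]), 0)
  # ... unless polarity is flipped
  vb2 <- frangi(bright, vesselness_params(scales = c(1, 2, 3), polarity = "bright"))
  expect_gt(min(vb2$values[21, 10:70]), 0.5)
})

test_that("frangi selects the scale matching the line half-width", {
  for (w in c(2, 3)) {
    img <- line_image(half_width = w)
    v <- frangi(img, vesselness_params(scales = c(1, 1.5, 2, 2.5, 3, 4, 5)))
    sel <- v$argmax_scale[21, 15:65]
    # optimum for a Gaussian profile of sd w is sigma = sqrt(2) w; the
    # centerline argmax should concentrate in a band around w
    expect_true(median(sel) >= w && median(sel) <= 2 * w)
  }
})

test_that("frangi discriminates a line from an equal-contrast blob", {
  params <- vesselness_params(scales = c(1, 2, 3), c = 10)
  line <- line_image(half_width = 2)
  blob <- blob_image(sigma = 2)
  vl <- frangi(line, params)$values
  vb <- frangi(blob, params)$values
  expect_gt(mean(vl[21, 10:70]), vb[21, 21])
})

test_that("frangi is exactly equivariant under 90-degree rotation", {
  set.seed(5)
  imgs <- list(matrix(sample(0:255, 40 * 56, TRUE), 40, 56),
               line_image(half_width = 2))
  for (img in imgs) {
    v1 <- frangi(img)$values
    v2 <- frangi(rot90m(img))$values
    expect_identical(rot90m(v1), v2)
  }
})

test_that("gamma = 1 normalization keeps the centerline response scale-invariant", {
  # same line rendered at double width: response at double sigma within 10%
  img1 <- line_image(nr = 41, nc = 81, half_width = 2)
  img2 <- line_image(nr = 81, nc = 161, row = 41, half_width = 4)
  r1 <- frangi(img1, vesselness_params(scales = 2 * sqrt(2), c = 10))$values[21, 41]
  r2 <- frangi(img2, vesselness_params(scales = 4 * sqrt(2), c = 10))$values[41, 81]
  expect_equal(r1, r2, tolerance = 0.1)
})

test_that("vesselness_to_gray max-normalizes and keeps all-zero maps at zero", {
  z <- frangi(matrix(50, 10, 10))
  expect_true(all(vesselness_to_gray(z) == 0))
  v <- frangi(line_image(), vesselness_params(scales = c(1, 2, 3)))
  g <- vesselness_to_gray(v)
  expect_equal(max(g), 255)
  expect_true(all(g >= 0 & g <= 255 & g == round(g)))
})
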