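# sRGB -> Lab conversion and the CIEDE2000 formula

test_that("rgb_to_lab maps the gamut anchors and neutral gray correctly", {
  white <- rgb_to_lab(c(1, 1, 1))
  expect_equal(unname(white[1, "L"]), 100, tolerance = 1e-6)
  expect_lt(abs(white[1, "a"]), 1e-3)
  expect_lt(abs(white[1, "b"]), 1e-3)

  black <- rgb_to_lab(c(0, 0, 0))
  expect_equal(unname(black[1, ]), c(0, 0, 0), tolerance = 1e-9)

  # frozen from the reference sRGB/D65 conversion (grDevices::convertColor)
  gray <- rgb_to_lab(c(0.5, 0.5, 0.5))
  expect_equal(unname(gray[1, "L"]), 53.38897, tolerance = 1e-4)
  expect_lt(abs(gray[1, "a"]), 1e-3)
  expect_lt(abs(gray[1, "b"]), 1e-3)

  expect_error(rgb_to_lab(c(1.2, 0, 0)), "\\[0, 1\\]")
})

test_that("rgb_to_lab agrees with an independent reference conversion", {
  skip_if_not_installed("farver")
  set.seed(11)
  rgb <- matrix(runif(3000), ncol = 3)
  mine <- rgb_to_lab(rgb)
  ref <- as.matrix(farver::convert_colour(rgb * 255, from = "rgb", to = "lab"))
  dE <- ciede2000_distance(mine, ref)
  expect_lt(max(dE), 0.05)
})

test_that("lab_to_rgb inverts rgb_to_lab", {
  set.seed(12)
  rgb <- matrix(runif(300), ncol = 3)
  back <- lab_to_rgb(rgb_to_lab(rgb))
  expect_equal(unname(back), unname(rgb), tolerance = 1e-9)
})

test_that("chroma_hue handles achromatic, Pythagorean and axis cases", {
  ach <- chroma_hue(c(50, 0, 0))
  expect_equal(ach$C, 0)
  expect_equal(ach$h, 0)  # convention for achromatic colors

  pyth <- chroma_hue(c(50, 3, 4))
  expect_equal(pyth$C, 5)
  expect_equal(pyth$h, atan(4 / 3) * 180 / pi)

  axis <- chroma_hue(c(50, -1, 0))
  expect_equal(axis$C, 1)
  expect_equal(axis$h, 180)
})

test_that("ciede2000 reproduces the standard verification pairs to 1e-4", {
  vp <- ciede2000_reference_pairs()
  got <- ciede2000_distance(as.matrix(vp[, c("L1", "a1", "b1")]),
                            as.matrix(vp[, c("L2", "a2", "b2")]))
  expect_equal(got, vp$dE00, tolerance = 1e-4)
  # scalar interface agrees with the vectorized one
  one <- ciede2000(unlist(vp[7, c("L1", "a1", "b1")]),
                   unlist(vp[7, c("L2", "a2", "b2")]))
  expect_equal(one$dE00, vp$dE00[7], tolerance = 1e-4)
})

test_that("ciede2000 agrees with an independent implementation on random pairs", {
  skip_if_not_installed("farver")
  set.seed(21)
  ref <- cbind(runif(200, 0, 100), runif(200, -60, 60), runif(200, -60, 60))
  sam <- cbind(runif(200, 0, 100), runif(200, -60, 60), runif(200, -60, 60))
  mine <- ciede2000_distance(ref, sam)
  theirs <- diag(farver::compare_colour(ref, sam, from_space = "lab",
                                        method = "cie2000"))
  # farver carries slightly lower internal precision; 1e-4 is the agreement
  # level the verification set demands
  expect_lt(max(abs(mine - unname(theirs))), 1e-4)
})

test_that("ciede2000 is a symmetric metric with antisymmetric components", {
  set.seed(22)
  for (i in 1:50) {
    x <- c(runif(1, 0, 100), runif(2, -50, 50))
    y <- c(runif(1, 0, 100), runif(2, -50, 50))
    fwd <- ciede2000(x, y)
    rev <- ciede2000(y, x)
    expect_equal(fwd$dE00, rev$dE00, tolerance = 1e-12)
    expect_equal(fwd$dL_prime, -rev$dL_prime, tolerance = 1e-12)
    expect_equal(fwd$dC_prime, -rev$dC_prime, tolerance = 1e-12)
    expect_equal(fwd$dH_prime, -rev$dH_prime, tolerance = 1e-12)
    expect_gt(fwd$dE00, 0)
  }
  ident <- ciede2000(c(42, 26, 5), c(42, 26, 5))
  expect_identical(ident$dE00, 0)
  expect_identical(ident$dL_prime, 0)
  expect_identical(ident$dH_prime, 0)
})

test_that("achromatic pairs reduce to |dL| / (kL * S_L)", {
  set.seed(23)
  for (i in 1:20) {
    L1 <- runif(1, 0, 100); L2 <- runif(1, 0, 100)
    res <- ciede2000(c(L1, 0, 0), c(L2, 0, 0))
    Lbar <- (L1 + L2) / 2
    SL <- 1 + 0.015 * (Lbar - 50)^2 / sqrt(20 + (Lbar - 50)^2)
    expect_equal(res$dE00, abs(L2 - L1) / SL, tolerance = 1e-10)
  }
})

test_that("intermediate terms respect their defined ranges", {
  set.seed(24)
  ref <- cbind(runif(300, 0, 100), runif(300, -80, 80), runif(300, -80, 80))
  sam <- cbind(runif(300, 0, 100), runif(300, -80, 80), runif(300, -80, 80))
  for (i in seq_len(50)) {
    r <- ciede2000(ref[i, ], sam[i, ])
    expect_gte(r$G, 0); expect_lte(r$G, 0.5)
    expect_gte(r$S_L, 1)
    expect_gte(r$S_C, 1)
    expect_gt(r$S_H, 0)
    expect_gte(r$dE00, 0)
  }
})

test_that("parametric coefficients scale their components and must be positive", {
  res1 <- ciede2000(c(40, 20, 5), c(45, 22, 3))
  res2 <- ciede2000(c(40, 20, 5), c(45, 22, 3), k = c(kL = 2, kC = 1, kH = 1))
  expect_lt(res2$dE00, res1$dE00)
  expect_error(ciede2000(c(40, 20, 5), c(45, 22, 3), k = c(0, 1, 1)),
               "strictly positive")
})
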