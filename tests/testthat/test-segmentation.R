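# tongue extraction, the four-region partition, and region color summaries

test_that("a solid rectangle partitions into the analytic band areas", {
  mask <- matrix(FALSE, 120, 120)
  mask[11:110, 11:110] <- TRUE  # 100 x 100 tongue
  part <- partition_regions(mask, partition_ratios(edge = 0.15,
                                                   posterior = 0.2,
                                                   apex = 0.2))
  sizes <- region_sizes(part)
  expect_equal(unname(sizes["posterior"]), 20 * 100)
  expect_equal(unname(sizes["apex"]), 20 * 100)
  expect_equal(unname(sizes["edge"]), 60 * 2 * 15)
  expect_equal(unname(sizes["middle"]), 60 * 70)
})

test_that("the four regions exactly partition any mask", {
  set.seed(31)
  for (i in 1:50) {
    mask <- random_ellipse_mask()
    part <- partition_regions(mask)
    labs <- part$labels
    # brute force per pixel: every mask pixel exactly one region, every
    # background pixel label 0
    expect_true(all(labs[mask] %in% 1:4))
    expect_true(all(labs[!mask] == 0L))
    expect_equal(sum(region_sizes(part)), sum(mask))
    expect_true(all(region_sizes(part) > 0))
  }
})

test_that("the partition ignores content outside the mask and is deterministic", {
  set.seed(32)
  mask <- random_ellipse_mask()
  p1 <- partition_regions(mask)
  p2 <- partition_regions(mask)
  expect_identical(p1$labels, p2$labels)
})

test_that("degenerate masks are rejected", {
  expect_error(partition_regions(matrix(FALSE, 10, 10)), "empty mask")
  tiny <- matrix(FALSE, 10, 10); tiny[5, 5] <- TRUE
  expect_error(partition_regions(tiny), "too small")
  expect_error(partition_ratios(posterior = 0.6, apex = 0.5), "< 1")
  expect_error(partition_ratios(edge = 0), "\\(0, 1\\)")
})

test_that("segment_tongue recovers a known synthetic mask", {
  fx <- flat_tongue_image()
  mask <- segment_tongue(fx$image)
  expect_gte(mask_jaccard(mask, fx$mask), 0.95)
})

test_that("segment_tongue attains Jaccard >= 0.95 on 20 seeded noisy renders", {
  for (r in 1:20) {
    g <- generate_tongue_image(pixel_noise_sd = 2, seed = 300 + r,
                               mask = superellipse_mask(90, 70))
    got <- segment_tongue(g$image)
    expect_gte(mask_jaccard(got, g$mask), 0.95)
  }
})

test_that("segment_tongue errors on an all-black image and saturates on all-tongue", {
  black <- tongue_image(array(0, c(20, 20, 3)))
  expect_error(segment_tongue(black), "no tongue found")

  rgb <- lab_to_rgb(c(43, 27, 5.3), clip = TRUE)
  full <- tongue_image(array(rep(rgb, each = 400), c(20, 20, 3)))
  expect_true(all(segment_tongue(full)))
})

test_that("region_mean_lab averages exactly and permutation-invariantly", {
  fx <- flat_tongue_image(lab = c(42, 26, 5))
  part <- partition_regions(fx$mask)
  got <- region_mean_lab(fx$image, part, "edge")
  # uniform region: the mean is the (gamut round-tripped) color itself
  expect_equal(unname(got[1, ]), c(42, 26, 5), tolerance = 0.01)

  # two known pixels: channel-wise midpoint of their Lab values
  px <- rbind(c(0.6, 0.3, 0.3), c(0.4, 0.2, 0.25))
  img <- tongue_image(array(c(px[, 1], px[, 2], px[, 3]), c(2, 1, 3)))
  mask <- matrix(TRUE, 2, 1)
  labs <- rgb_to_lab(px)
  part2 <- structure(list(labels = matrix(c(1L, 1L), 2, 1),
                          levels = c("background", "edge", "posterior",
                                     "middle", "apex"),
                          ratios = partition_ratios()),
                     class = "region_partition")
  got2 <- region_mean_lab(img, part2, "edge")
  expect_equal(unname(got2[1, ]), unname(colMeans(labs)), tolerance = 1e-9)

  expect_error(region_mean_lab(fx$image, part, "nothere"), "unknown region")
})

test_that("region means recover the generating color within the standard error", {
  hits <- 0L
  n_rep <- 30
  for (r in 1:n_rep) {
    g <- generate_tongue_image(region_colors = default_region_colors(),
                               pixel_noise_sd = 2, seed = 400 + r)
    got <- region_mean_lab(g$image, g$partition, "edge")
    n <- region_sizes(g$partition)[["edge"]]
    ok <- all(abs(got[1, ] - default_region_colors()$edge) <= 3 * 2 / sqrt(n))
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("label PNG round-trips the partition", {
  g <- generate_tongue_image(pixel_noise_sd = 0, mask = superellipse_mask(60, 50))
  path <- tempfile(fileext = ".png")
  write_label_png(g$partition, path)
  expect_identical(read_label_png(path), g$partition$labels)
})
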