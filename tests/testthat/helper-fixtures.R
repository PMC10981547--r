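# shared fixture builders: everything is generated in code at test time

# a random elliptical mask guaranteed large enough to populate all four
# partition regions
random_ellipse_mask <- function(height = 60, width = 50) {
  cy <- runif(1, 0.4, 0.6) * height
  cx <- runif(1, 0.4, 0.6) * width
  ay <- runif(1, 0.3, 0.45) * height
  ax <- runif(1, 0.3, 0.45) * width
  y <- (seq_len(height) - cy) / ay
  x <- (seq_len(width) - cx) / ax
  outer(y^2, x^2, "+") <= 1
}

# a uniform-color image with a rectangular "tongue" painted on a dark
# background; returns the image and its ground-truth mask
flat_tongue_image <- function(lab = c(43, 27, 5.3), height = 40, width = 30,
                              rows = 5:36, cols = 4:27) {
  bg <- c(0.08, 0.08, 0.10)
  px <- matrix(rep(bg, each = height * width), ncol = 3)
  mask <- matrix(FALSE, height, width)
  mask[rows, cols] <- TRUE
  rgb <- lab_to_rgb(lab, clip = TRUE)
  px[c(mask), ] <- matrix(rep(rgb, each = sum(mask)), ncol = 3)
  list(image = tongue_image(array(px, c(height, width, 3))), mask = mask)
}

table2_pairs <- function() tongue_cohort_lab()
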