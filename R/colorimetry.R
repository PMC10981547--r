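# Device-independent color math: sRGB -> CIE L*a*b* and the CIEDE2000
# color-difference formula. Everything downstream (region color summaries,
# position comparisons, the synthetic generator) is built on these.

# sRGB -> XYZ matrices (linear RGB in columns X, Y, Z rows) and reference
# whites. D65 is the native sRGB white; D50 uses the ICC Bradford-adapted
# matrix.
.white_points <- list(
  D65 = list(
    M = matrix(c(
      0.4124564, 0.3575761, 0.1804375,
      0.2126729, 0.7151522, 0.0721750,
      0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE),
    white = c(X = 0.95047, Y = 1.00000, Z = 1.08883)
  ),
  D50 = list(
    M = matrix(c(
      0.4360747, 0.3850649, 0.1430804,
      0.2225045, 0.7168786, 0.0606169,
      0.0139322, 0.0971045, 0.7141733), nrow = 3, byrow = TRUE),
    white = c(X = 0.96422, Y = 1.00000, Z = 0.82521)
  )
)

.as_color_matrix <- function(x, what = "color") {
  if (is.null(dim(x))) {
    if (length(x) != 3L)
      stop(what, " must be a length-3 vector or an n x 3 matrix", call. = FALSE)
    x <- matrix(as.numeric(x), nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L)
      stop(what, " must have 3 columns", call. = FALSE)
    storage.mode(x) <- "double"
  }
  x
}

#' Convert sRGB colors to CIE L*a*b*
#'
#' Implements the standard chain sRGB (gamma-companded, channels in `[0, 1]`)
#' -> linear RGB -> CIE XYZ -> CIE L*a*b*. The default reference white is
#' D65 with the 2-degree observer, the native white of the sRGB encoding and
#' the universal default for consumer-camera RGB; D50 (ICC, Bradford-adapted
#' matrix) is available as an alternative.
#'
#' @param rgb A length-3 numeric vector `(r, g, b)` or an n x 3 matrix, all
#'   channels in `[0, 1]` (divide 8-bit values by 255 first; the image
#'   readers in this package do this on read).
#' @param white_point `"D65"` (default) or `"D50"`.
#' @return An n x 3 matrix with columns `L`, `a`, `b` (`L` in `[0, 100]`);
#'   a single input vector returns a 1 x 3 matrix.
#' @examples
#' rgb_to_lab(c(1, 1, 1))      # reference white: L = 100, a = b = 0
#' rgb_to_lab(c(0.5, 0.5, 0.5))  # neutral gray
#' @export
rgb_to_lab <- function(rgb, white_point = c("D65", "D50")) {
  white_point <- match.arg(white_point)
  rgb <- .as_color_matrix(rgb, "rgb")
  if (anyNA(rgb) || any(rgb < 0 | rgb > 1))
    stop("rgb channels must lie in [0, 1]", call. = FALSE)
  wp <- .white_points[[white_point]]
  # inverse sRGB companding
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(wp$M)
  xyz_n <- sweep(xyz, 2L, wp$white, "/")
  eps <- (6 / 29)^3
  f <- ifelse(xyz_n > eps, xyz_n^(1 / 3), xyz_n / (3 * (6 / 29)^2) + 4 / 29)
  lab <- cbind(
    L = 116 * f[, 2L] - 16,
    a = 500 * (f[, 1L] - f[, 2L]),
    b = 200 * (f[, 2L] - f[, 3L])
  )
  lab
}

#' Convert CIE L*a*b* colors to sRGB
#'
#' Inverse of [rgb_to_lab()]. Colors outside the sRGB gamut produce channel
#' values outside `[0, 1]`; set `clip = TRUE` to clamp them (the number of
#' clamped channels is returned in the `"clipped"` attribute).
#'
#' @param lab A length-3 numeric vector `(L, a, b)` or an n x 3 matrix.
#' @param white_point `"D65"` (default) or `"D50"`.
#' @param clip Clamp out-of-gamut channels into `[0, 1]`?
#' @return An n x 3 matrix with columns `r`, `g`, `b`; attribute `"clipped"`
#'   counts clamped channels when `clip = TRUE`.
#' @export
lab_to_rgb <- function(lab, white_point = c("D65", "D50"), clip = FALSE) {
  white_point <- match.arg(white_point)
  lab <- .as_color_matrix(lab, "lab")
  wp <- .white_points[[white_point]]
  fy <- (lab[, 1L] + 16) / 116
  fx <- fy + lab[, 2L] / 500
  fz <- fy - lab[, 3L] / 200
  f <- cbind(fx, fy, fz)
  delta <- 6 / 29
  t <- ifelse(f > delta, f^3, 3 * delta^2 * (f - 4 / 29))
  xyz <- sweep(t, 2L, wp$white, "*")
  lin <- xyz %*% t(solve(wp$M))
  rgb <- ifelse(lin <= 0.0031308, 12.92 * lin,
                1.055 * sign(lin) * abs(lin)^(1 / 2.4) - 0.055)
  colnames(rgb) <- c("r", "g", "b")
  if (clip) {
    n_clip <- sum(rgb < 0 | rgb > 1)
    rgb <- pmin(pmax(rgb, 0), 1)
    attr(rgb, "clipped") <- n_clip
  }
  rgb
}

#' Is a L*a*b* color inside the sRGB gamut?
#'
#' @param lab A length-3 vector or n x 3 matrix of L*a*b* colors.
#' @param white_point Reference white passed to [lab_to_rgb()].
#' @param tol Channel tolerance outside `[0, 1]` still counted as in gamut.
#' @return Logical vector, one element per color.
#' @export
lab_in_gamut <- function(lab, white_point = "D65", tol = 1e-9) {
  rgb <- lab_to_rgb(lab, white_point = white_point)
  apply(rgb, 1L, function(ch) all(ch >= -tol & ch <= 1 + tol))
}

#' Chroma and hue angle of a L*a*b* color
#'
#' Chroma is `C = sqrt(a^2 + b^2)`; the hue angle `h` is the four-quadrant
#' angle of `(a, b)` in degrees, mapped to `[0, 360)`. An achromatic color
#' (`a = b = 0`) has `C = 0` and, by convention, `h = 0`.
#'
#' @param lab A length-3 vector or n x 3 matrix of L*a*b* colors.
#' @return A data.frame with columns `C` and `h`.
#' @examples
#' chroma_hue(c(50, 3, 4))  # C = 5, h = atan(4/3) in degrees
#' @export
chroma_hue <- function(lab) {
  lab <- .as_color_matrix(lab, "lab")
  C <- sqrt(lab[, 2L]^2 + lab[, 3L]^2)
  h <- atan2(lab[, 3L], lab[, 2L]) * 180 / pi
  h <- ifelse(h < 0, h + 360, h)
  h[C == 0] <- 0
  data.frame(C = C, h = h)
}

.deg_sin <- function(x) sin(x * pi / 180)
.deg_cos <- function(x) cos(x * pi / 180)

# Vectorized CIEDE2000 core. ref and sam are n x 3 Lab matrices; returns a
# data.frame of dE00 and every intermediate term, one row per pair. Hue
# handling follows the published implementation notes: the 360-degree
# wraparound in both the hue difference and the mean hue, and zeroed hue
# terms when either primed chroma vanishes.
.ciede2000_terms <- function(ref, sam, kL = 1, kC = 1, kH = 1) {
  L1 <- ref[, 1L]; a1 <- ref[, 2L]; b1 <- ref[, 3L]
  L2 <- sam[, 1L]; a2 <- sam[, 2L]; b2 <- sam[, 3L]

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  C_bar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(C_bar^7 / (C_bar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)

  h1p <- atan2(b1, a1p) * 180 / pi; h1p <- ifelse(h1p < 0, h1p + 360, h1p)
  h2p <- atan2(b2, a2p) * 180 / pi; h2p <- ifelse(h2p < 0, h2p + 360, h2p)
  h1p[C1p == 0] <- 0
  h2p[C2p == 0] <- 0

  dLp <- L2 - L1
  dCp <- C2p - C1p

  chroma_prod <- C1p * C2p
  dhp <- h2p - h1p
  dhp <- ifelse(dhp > 180, dhp - 360, ifelse(dhp < -180, dhp + 360, dhp))
  dhp[chroma_prod == 0] <- 0
  dHp <- 2 * sqrt(chroma_prod) * .deg_sin(dhp / 2)

  L_bar <- (L1 + L2) / 2
  Cp_bar <- (C1p + C2p) / 2
  h_sum <- h1p + h2p
  h_bar <- ifelse(abs(h1p - h2p) <= 180, h_sum / 2,
                  ifelse(h_sum < 360, (h_sum + 360) / 2, (h_sum - 360) / 2))
  h_bar <- ifelse(chroma_prod == 0, h_sum, h_bar)

  T_fac <- 1 - 0.17 * .deg_cos(h_bar - 30) + 0.24 * .deg_cos(2 * h_bar) +
    0.32 * .deg_cos(3 * h_bar + 6) - 0.20 * .deg_cos(4 * h_bar - 63)
  d_theta <- 30 * exp(-((h_bar - 275) / 25)^2)
  R_C <- 2 * sqrt(Cp_bar^7 / (Cp_bar^7 + 25^7))
  S_L <- 1 + 0.015 * (L_bar - 50)^2 / sqrt(20 + (L_bar - 50)^2)
  S_C <- 1 + 0.045 * Cp_bar
  S_H <- 1 + 0.015 * Cp_bar * T_fac
  R_T <- -.deg_sin(2 * d_theta) * R_C

  tL <- dLp / (kL * S_L)
  tC <- dCp / (kC * S_C)
  tH <- dHp / (kH * S_H)
  dE00 <- sqrt(tL^2 + tC^2 + tH^2 + R_T * tC * tH)

  data.frame(
    dE00 = dE00, dL_prime = dLp, dC_prime = dCp, dH_prime = dHp,
    S_L = S_L, S_C = S_C, S_H = S_H, R_T = R_T, G = G, T = T_fac,
    L_bar = L_bar, C_bar_prime = Cp_bar, h_bar_prime = h_bar
  )
}

#' CIEDE2000 color difference between two L*a*b* colors
#'
#' Computes the complete CIEDE2000 color difference \eqn{\Delta E_{00}}
#' between a reference and a sample color, including the G rescaling of the
#' a* axis, the primed chroma/hue coordinates, the mean-hue wraparound
#' rules, the hue-dependent factor T, the weighting functions
#' \eqn{S_L, S_C, S_H}, and the chroma-hue rotation term \eqn{R_T}.
#' Signed component differences are sample minus reference; in the position
#' analysis the sitting measurement is the reference and supine the sample,
#' so \eqn{\Delta L'} etc. read supine minus sitting.
#'
#' @param reference,sample Length-3 `(L, a, b)` vectors.
#' @param k Parametric coefficients, a named numeric vector
#'   `c(kL = 1, kC = 1, kH = 1)`; all must be strictly positive. The tongue
#'   analysis uses the 1:1:1 default throughout.
#' @return An object of class `"ciede2000"`: a list with `dE00`, the signed
#'   components `dL_prime`, `dC_prime`, `dH_prime`, the weighting functions
#'   `S_L`, `S_C`, `S_H`, the rotation term `R_T`, the a*-rescaling factor
#'   `G`, the hue factor `T`, and the parametric coefficients used.
#' @examples
#' d <- ciede2000(c(36.0, 23.9, 2.4), c(43.5, 25.1, 5.3))
#' round(d$dE00, 1)
#' @export
ciede2000 <- function(reference, sample, k = c(kL = 1, kC = 1, kH = 1)) {
  ref <- .as_color_matrix(reference, "reference")
  sam <- .as_color_matrix(sample, "sample")
  if (nrow(ref) != 1L || nrow(sam) != 1L)
    stop("ciede2000() takes single colors; use ciede2000_distance() for many pairs",
         call. = FALSE)
  k <- .check_k(k)
  terms <- .ciede2000_terms(ref, sam, k[["kL"]], k[["kC"]], k[["kH"]])
  out <- as.list(terms[1L, , drop = TRUE])
  out$k <- k
  class(out) <- "ciede2000"
  out
}

.check_k <- function(k) {
  if (is.null(names(k))) names(k) <- c("kL", "kC", "kH")[seq_along(k)]
  k <- k[c("kL", "kC", "kH")]
  if (anyNA(k) || any(k <= 0))
    stop("parametric coefficients kL, kC, kH must all be strictly positive",
         call. = FALSE)
  k
}

#' Vectorized CIEDE2000 distances
#'
#' @param reference,sample n x 3 matrices of L*a*b* colors, paired by row.
#' @param k Parametric coefficients as in [ciede2000()].
#' @return Numeric vector of \eqn{\Delta E_{00}} values, one per row.
#' @export
ciede2000_distance <- function(reference, sample, k = c(kL = 1, kC = 1, kH = 1)) {
  ref <- .as_color_matrix(reference, "reference")
  sam <- .as_color_matrix(sample, "sample")
  if (nrow(ref) != nrow(sam))
    stop("reference and sample must have the same number of rows", call. = FALSE)
  k <- .check_k(k)
  .ciede2000_terms(ref, sam, k[["kL"]], k[["kC"]], k[["kH"]])$dE00
}

#' @export
print.ciede2000 <- function(x, ...) {
  cat(sprintf("CIEDE2000 color difference: dE00 = %.2f\n", x$dE00))
  cat(sprintf("  dL' = %.2f  dC' = %.2f  dH' = %.2f\n",
              x$dL_prime, x$dC_prime, x$dH_prime))
  cat(sprintf("  S_L = %.3f  S_C = %.3f  S_H = %.3f  R_T = %.3f  G = %.4f\n",
              x$S_L, x$S_C, x$S_H, x$R_T, x$G))
  invisible(x)
}
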