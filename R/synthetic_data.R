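# Synthetic stand-in for the calibrated tongue-imaging rig and the patient
# cohort: paired tongue images (or bare region colors) with known ground
# truth, and biometric tables with a controllable association between a
# covariate and the true positional color shift.
#
# Shift magnitudes are specified in dE00 units so the generator's dial is
# the same scale the analysis measures; the Lab displacement realizing a
# requested magnitude is found by one-dimensional root-finding along a
# random direction.

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Default baseline region colors (sitting position)
#'
#' The edge default is a typical light-red tongue edge; middle and
#' posterior are paler and yellower (tongue coating), the apex slightly
#' redder.
#'
#' @return Named list of L*a*b* triples for edge, posterior, middle, apex.
#' @export
default_region_colors <- function() {
  list(edge      = c(43.0, 27.0, 5.3),
       posterior = c(46.0, 19.0, 9.0),
       middle    = c(48.0, 21.0, 8.0),
       apex      = c(44.0, 29.0, 6.0))
}

#' Specification of a synthetic paired cohort
#'
#' Defaults describe the study conditions the package analyses: 18
#' patients, per-patient true color shifts drawn from a lognormal whose
#' median (2.34) and spread place about 78% of shifts below the AT = 4.1
#' acceptability threshold, Gaussian pixel noise of sigma = 2 Lab units,
#' and baseline region colors typical of light-red tongues.
#'
#' @param n_patients Number of patients (>= 1).
#' @param region_colors Named list of baseline sitting L*a*b* colors for
#'   edge, posterior, middle, apex.
#' @param shift_meanlog,shift_sdlog Parameters of the lognormal from which
#'   per-patient true dE00 shift magnitudes are drawn.
#' @param direction_bias `"none"` (uniform directions on the Lab unit
#'   sphere) or `"lightness"` (directions biased toward the L* axis; the
#'   largest observed positional differences are lightness-dominated).
#' @param pixel_noise_sd Gaussian sigma per Lab channel added per pixel when
#'   rendering images.
#' @param association Optional `list(covariate =, slope =, noise_sd =,
#'   intercept =)` making that biometric column
#'   `intercept + slope * true_dE00 + N(0, noise_sd)`.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `"cohort_spec"` list.
#' @export
cohort_spec <- function(n_patients = 18,
                        region_colors = default_region_colors(),
                        shift_meanlog = log(2.34), shift_sdlog = 0.73,
                        direction_bias = c("none", "lightness"),
                        pixel_noise_sd = 2,
                        association = NULL,
                        seed = 20170501) {
  direction_bias <- match.arg(direction_bias)
  stopifnot(n_patients >= 1, pixel_noise_sd >= 0)
  if (!is.null(association))
    stopifnot(all(c("covariate", "slope", "noise_sd") %in% names(association)))
  structure(list(n_patients = as.integer(n_patients),
                 region_colors = region_colors,
                 shift_meanlog = shift_meanlog, shift_sdlog = shift_sdlog,
                 direction_bias = direction_bias,
                 pixel_noise_sd = pixel_noise_sd,
                 association = association, seed = seed),
            class = "cohort_spec")
}

#' Standard deviation of the spec's true shift distribution
#' @param spec A [cohort_spec()].
#' @return The analytic lognormal standard deviation of true dE00 shifts.
#' @export
shift_sd <- function(spec) {
  s2 <- spec$shift_sdlog^2
  sqrt(exp(2 * spec$shift_meanlog + s2) * (exp(s2) - 1))
}

#' Association slope yielding a target population correlation
#'
#' For covariate `= intercept + slope * dE00 + N(0, noise_sd)` the
#' population Pearson correlation with the true dE00 is
#' `slope * sd_shift / sqrt(slope^2 * sd_shift^2 + noise_sd^2)`; this
#' inverts that relation.
#'
#' @param r Target population correlation in `(-1, 1)`, non-zero.
#' @param noise_sd Covariate noise standard deviation.
#' @param sd_shift Standard deviation of the true shifts ([shift_sd()]).
#' @return The slope.
#' @export
slope_for_r <- function(r, noise_sd, sd_shift) {
  stopifnot(abs(r) < 1, r != 0, noise_sd > 0, sd_shift > 0)
  r * noise_sd / (sd_shift * sqrt(1 - r^2))
}

#' Superellipse tongue mask
#'
#' A vertically elongated superellipse (`|x/rx|^p + |y/ry|^p <= 1`),
#' apex at the bottom, root at the top — the canonical photographed tongue
#' outline.
#'
#' @param height,width Image dimensions in pixels.
#' @param rx,ry Semi-axes as fractions of the half-width / half-height.
#' @param p Superellipse exponent (2 = ellipse; larger = squarer).
#' @return Logical height x width matrix.
#' @export
superellipse_mask <- function(height = 180, width = 140,
                              rx = 0.78, ry = 0.92, p = 2.5) {
  cy <- (height + 1) / 2; cx <- (width + 1) / 2
  ay <- ry * height / 2; ax <- rx * width / 2
  y <- abs((seq_len(height) - cy) / ay)
  x <- abs((seq_len(width) - cx) / ax)
  outer(y^p, x^p, "+") <= 1
}

#' Render a synthetic tongue image with known region colors
#'
#' Each region's pixels are the region's L*a*b* color plus independent
#' Gaussian noise per channel, converted to sRGB; the background is a fixed
#' dark neutral. Deterministic for a fixed seed. Region colors that fall
#' outside the sRGB gamut raise an error naming the region; per-pixel noise
#' excursions are clipped to the gamut and counted.
#'
#' @param region_colors Named list of L*a*b* triples for edge, posterior,
#'   middle, apex.
#' @param pixel_noise_sd Gaussian sigma per Lab channel (0 = noiseless).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param mask Logical tongue mask (default [superellipse_mask()]).
#' @param ratios [partition_ratios()] used for the painted partition.
#' @param background sRGB background color.
#' @param position,subject_id Metadata for the returned image.
#' @return List: `image` (a `"tongue_image"`), `mask`, `partition`,
#'   `clipped` (count of gamut-clipped channels).
#' @export
generate_tongue_image <- function(region_colors = default_region_colors(),
                                  pixel_noise_sd = 2, seed = NULL,
                                  mask = superellipse_mask(),
                                  ratios = partition_ratios(),
                                  background = c(0.08, 0.08, 0.10),
                                  position = "sitting",
                                  subject_id = NA_character_) {
  .with_seed(seed, {
    for (rg in names(region_colors))
      if (!lab_in_gamut(region_colors[[rg]]))
        stop("region color out of sRGB gamut: ", rg, call. = FALSE)
    partition <- partition_regions(mask, ratios)
    h <- nrow(mask); w <- ncol(mask)
    px <- matrix(rep(background, each = h * w), ncol = 3L)
    clipped <- 0L
    for (rg in names(region_colors)) {
      sel <- which(partition$labels == .region_code(rg))
      if (!length(sel)) next
      lab <- matrix(rep(region_colors[[rg]], each = length(sel)), ncol = 3L)
      if (pixel_noise_sd > 0)
        lab <- lab + matrix(stats::rnorm(3L * length(sel), 0, pixel_noise_sd),
                            ncol = 3L)
      rgb <- lab_to_rgb(lab, clip = TRUE)
      clipped <- clipped + attr(rgb, "clipped")
      px[sel, ] <- rgb
    }
    img <- tongue_image(array(px, dim = c(h, w, 3L)), subject_id = subject_id,
                        position = position)
    list(image = img, mask = mask, partition = partition, clipped = clipped)
  })
}

#' Lab displacement realizing a requested CIEDE2000 magnitude
#'
#' Scales a direction vector so that the displaced color sits at exactly
#' the requested dE00 from the base color, by bracketed root-finding on the
#' scale factor ([stats::uniroot()], tolerance 1e-8). Errors if the
#' required displacement leaves the sRGB gamut (unsatisfiable shift).
#'
#' @param base Length-3 L*a*b* base color.
#' @param direction Length-3 direction (need not be normalized).
#' @param target_dE00 Requested magnitude (> 0).
#' @return The displaced L*a*b* color (length-3 vector).
#' @export
shift_by_dE00 <- function(base, direction, target_dE00) {
  stopifnot(target_dE00 > 0)
  u <- direction / sqrt(sum(direction^2))
  f <- function(t) ciede2000_distance(matrix(base, 1), matrix(base + t * u, 1)) -
    target_dE00
  hi <- max(1, target_dE00)
  while (f(hi) < 0 && hi < 512) hi <- hi * 2
  if (f(hi) < 0) stop("unsatisfiable shift: target dE00 out of reach",
                      call. = FALSE)
  t_star <- stats::uniroot(f, c(0, hi), tol = 1e-8)$root
  shifted <- base + t_star * u
  if (!lab_in_gamut(shifted))
    stop("unsatisfiable shift: displaced color leaves the sRGB gamut",
         call. = FALSE)
  shifted
}

.random_direction <- function(bias) {
  u <- stats::rnorm(3L)
  if (bias == "lightness") u[1L] <- 3 * u[1L]
  u / sqrt(sum(u^2))
}

# one draw of plausible outpatient biometrics (before any association
# overwrite); rates and moments follow an elderly Kampo outpatient profile
.draw_biometrics <- function(id) {
  data.frame(
    patient_id = id,
    age = round(min(max(stats::rnorm(1, 71, 13), 20), 95)),
    sex = sample(c("M", "F"), 1L, prob = c(7, 11)),
    bmi = round(stats::rnorm(1, 24.3, 3.5), 1),
    smoking = sample(c("yes", "no"), 1L, prob = c(8, 10)),
    cvd_drug = sample(c("yes", "no"), 1L, prob = c(7, 11)),
    sbp = round(stats::rnorm(1, 130, 20)),
    dbp = round(stats::rnorm(1, 73, 12)),
    tg = round(stats::rlnorm(1, log(110), 0.45)),
    hdl_c = round(stats::rnorm(1, 58, 14)),
    ldl_c = round(stats::rnorm(1, 130, 35)),
    hba1c = round(stats::rnorm(1, 6.1, 0.8), 1),
    fpg = round(stats::rnorm(1, 117, 25))
  )
}

#' Generate a paired synthetic cohort with ground truth
#'
#' For each patient a true shift magnitude is drawn from the spec's
#' lognormal, a random direction chosen, and the supine edge color placed
#' at exactly that dE00 from the sitting baseline ([shift_by_dE00()]); all
#' region colors are displaced by the same Lab vector. Biometrics are drawn
#' per patient, with the association covariate (if any) rewritten as
#' `intercept + slope * true_dE00 + noise`. Ground truth (colors, shifts,
#' per-patient dE00) is recorded before any rendering noise.
#'
#' @param spec A [cohort_spec()].
#' @param render_images Render PNG-ready image pairs? When `FALSE` (the
#'   default) the cohort is generated at the color level, which is what the
#'   statistical recovery studies need; rendering is exercised separately.
#' @param mask,ratios Passed to [generate_tongue_image()] when rendering.
#' @return List with `truth` (data.frame: patient_id, sitting/supine edge
#'   Lab, `true_dE00`), `biometrics` (data.frame), `images` (list of
#'   per-patient `list(sitting =, supine =)` render results, or `NULL`),
#'   and `spec`.
#' @export
generate_paired_cohort <- function(spec = cohort_spec(),
                                   render_images = FALSE,
                                   mask = superellipse_mask(),
                                   ratios = partition_ratios()) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_patients
    targets <- stats::rlnorm(n, spec$shift_meanlog, spec$shift_sdlog)
    truth <- vector("list", n)
    bio <- vector("list", n)
    images <- if (render_images) vector("list", n) else NULL
    base <- spec$region_colors
    for (i in seq_len(n)) {
      # achievability of a magnitude depends on the direction (the gamut is
      # anisotropic around the base color), so an unreachable draw redraws
      # the direction rather than failing the patient; only a magnitude no
      # direction can realize is an error
      sup_edge <- NULL
      for (try in 1:25) {
        u <- .random_direction(spec$direction_bias)
        sup_edge <- tryCatch(shift_by_dE00(base$edge, u, targets[i]),
                             error = function(e) NULL)
        if (!is.null(sup_edge)) break
      }
      if (is.null(sup_edge))
        stop("unsatisfiable shift for patient ", i,
             ": dE00 = ", signif(targets[i], 3),
             " is not realizable inside the sRGB gamut", call. = FALSE)
      delta <- sup_edge - base$edge
      truth[[i]] <- data.frame(
        patient_id = i,
        L_sit = base$edge[1], a_sit = base$edge[2], b_sit = base$edge[3],
        L_sup = sup_edge[1], a_sup = sup_edge[2], b_sup = sup_edge[3],
        true_dE00 = targets[i])
      bio[[i]] <- .draw_biometrics(i)
      if (render_images) {
        sup_colors <- lapply(base, function(cl) cl + delta)
        images[[i]] <- list(
          sitting = generate_tongue_image(base, spec$pixel_noise_sd,
                                          seed = NULL, mask = mask,
                                          ratios = ratios,
                                          position = "sitting",
                                          subject_id = as.character(i)),
          supine = generate_tongue_image(sup_colors, spec$pixel_noise_sd,
                                         seed = NULL, mask = mask,
                                         ratios = ratios,
                                         position = "supine",
                                         subject_id = as.character(i)))
      }
    }
    truth <- do.call(rbind, truth)
    bio <- do.call(rbind, bio)
    if (!is.null(spec$association)) {
      a <- spec$association
      intercept <- if (!is.null(a$intercept)) a$intercept
        else mean(bio[[a$covariate]])
      bio[[a$covariate]] <- intercept + a$slope * truth$true_dE00 +
        stats::rnorm(n, 0, a$noise_sd)
    }
    list(truth = truth, biometrics = bio, images = images, spec = spec)
  })
}
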