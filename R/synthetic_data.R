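#' Specification of a synthetic dark-field worm scene
#'
#' Declarative description of a ground-truthed scene: a worm-shaped bright
#' capsule (a sinusoidal centerline swept with a disk) on a dark noisy
#' background, optionally carrying rim-bright circular lipid droplets,
#' discrete bright puncta (lysosome-related organelles), multiplicative
#' vignetting, and a Poisson-Gaussian camera noise model (shot noise with
#' variance proportional to signal, plus additive read noise). Everything
#' the pipeline measures is recoverable in closed form from the returned
#' ground truth in the noiseless limit.
#'
#' @param frame `c(rows, cols)` of the raster; default `c(160, 160)`.
#' @param amplitude_px,wavelength_px Sinusoid amplitude and wavelength of
#'   the body centerline, in pixels.
#' @param half_width_px Capsule half-width (body radius), px.
#' @param span_px Horizontal extent of the centerline, px (`NULL`: frame
#'   width minus margins).
#' @param body_base_intensity Body intensity before droplets/puncta (a.u.).
#' @param background_mean,background_sd Background level and its Gaussian
#'   spread (a.u.).
#' @param droplet_count,droplet_radius_range,droplet_rim_gain,droplet_interior_gain
#'   Lipid-droplet layer: number of disks, radius range (px), rim
#'   brightness as a multiple of the interior increment, and the interior
#'   intensity increment (a.u.). Droplet edges render brighter than their
#'   interiors, as lipid droplets do under dark field.
#' @param droplet_density_target If non-`NULL`, overrides `droplet_count`:
#'   the number of droplets is chosen (with stochastic rounding, so the
#'   expectation is exact) to bring the body's noiseless scattering
#'   density to this value (a.u./px), using the realized body area and the
#'   closed-form expected per-droplet contribution.
#' @param droplet_min_sep Minimum center-to-center droplet distance in px;
#'   `NULL` (default) keeps droplet interiors disjoint, `0` places them
#'   freely (droplet intensity is additive either way).
#' @param puncta_count,puncta_intensity,puncta_radius Discrete bright
#'   puncta (LRO-like): count, added intensity (a.u.), radius (px).
#' @param vignette Multiplicative radial falloff coefficient in `[0, 1)`:
#'   intensity at the frame corner is reduced by this fraction.
#' @param shot_noise_gain Variance of shot noise per unit signal (0 = off).
#' @param read_noise_sd Additive Gaussian read noise SD (a.u.).
#' @param pixel_size_um Physical pixel size (um); default 1.
#' @param intensity_gain Overall multiplicative gain applied to the whole
#'   noiseless scene (emulates objective/illumination throughput).
#' @param seed Mandatory integer seed; the same seed yields a bit-identical
#'   scene.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(frame = c(160L, 160L),
                       amplitude_px = 12, wavelength_px = 90,
                       half_width_px = 8, span_px = NULL,
                       body_base_intensity = 40,
                       background_mean = 5, background_sd = 1.5,
                       droplet_count = 0L, droplet_radius_range = c(2, 3),
                       droplet_rim_gain = 1.5, droplet_interior_gain = 30,
                       droplet_density_target = NULL, droplet_min_sep = NULL,
                       puncta_count = 0L, puncta_intensity = 120,
                       puncta_radius = 1.5,
                       vignette = 0, shot_noise_gain = 0, read_noise_sd = 0,
                       pixel_size_um = 1, intensity_gain = 1, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (any(c(body_base_intensity, background_mean, background_sd,
            droplet_interior_gain, puncta_intensity) < 0))
    stop("intensities must be >= 0", call. = FALSE)
  if (vignette < 0 || vignette >= 1)
    stop("`vignette` must be in [0, 1)", call. = FALSE)
  structure(as.list(environment()), class = "scene_spec")
}

# stamp value into disk(s) of radius r at integer centers (n x 2, 1-based)
stamp_disks <- function(canvas, centers, r, value, add = TRUE) {
  ri <- ceiling(r)
  off <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  off <- off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
  nr <- nrow(canvas); nc <- ncol(canvas)
  for (i in seq_len(nrow(centers))) {
    rr <- centers[i, 1] + off$dr; cc <- centers[i, 2] + off$dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    ij <- cbind(rr[ok], cc[ok])
    if (add) canvas[ij] <- canvas[ij] + value else canvas[ij] <- value
  }
  canvas
}

# sample k points among candidate pixels (n x 2) with pairwise separation
# >= min_sep; errors if impossible within the candidate budget
sample_separated <- function(candidates, k, min_sep) {
  if (k == 0L) return(candidates[0, , drop = FALSE])
  if (k > nrow(candidates))
    stop(sprintf("could not place %d features among %d candidate pixels",
                 k, nrow(candidates)), call. = FALSE)
  if (min_sep <= 1)
    return(candidates[sample(nrow(candidates), k), , drop = FALSE])
  ord <- sample(nrow(candidates))
  acc <- matrix(0, 0, 2)
  for (i in ord) {
    p <- candidates[i, , drop = FALSE]
    if (nrow(acc) == 0L ||
        all((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2 >= min_sep^2)) {
      acc <- rbind(acc, p)
      if (nrow(acc) == k) return(acc)
    }
  }
  stop(sprintf("could not place %d disjoint features (placed %d); ",
               k, nrow(acc)), "enlarge the frame or reduce the count",
       call. = FALSE)
}

#' Render a synthetic scene with ground truth
#'
#' Deterministic given `spec$seed`. Compositing order: background, body,
#' droplets (interior then rim), puncta, overall gain, camera noise, then
#' vignette last. With no droplets, puncta, noise or vignette the
#' scattering density over the true body mask equals
#' `body_base_intensity * intensity_gain` exactly.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (a [worm_image()]) and `truth` (list:
#'   `body_mask`, `droplet_centers`, `droplet_radii`, `puncta_centers`,
#'   `latent_fat`, `arc_length_um`, `centerline`). Centers are 1-based
#'   `(row, col)` matrix rows.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, render_scene_impl(spec))
}

render_scene_impl <- function(spec) {
  nr <- spec$frame[1]; nc <- spec$frame[2]
  margin <- spec$half_width_px + 2
  span <- if (is.null(spec$span_px)) nc - 2 * margin else spec$span_px
  if (span < 4) stop("frame too small for the body", call. = FALSE)
  xs <- seq(0, span, by = 0.25)
  rowc <- nr / 2 + spec$amplitude_px * sin(2 * pi * xs / spec$wavelength_px)
  colc <- margin + xs
  if (any(rowc - spec$half_width_px < 0) || any(rowc + spec$half_width_px > nr - 1) ||
      any(colc - spec$half_width_px < 0) || any(colc + spec$half_width_px > nc - 1))
    stop("body does not fit in the frame", call. = FALSE)
  # body mask: capsule = centerline swept with a disk of radius half_width
  body <- matrix(FALSE, nr, nc)
  body <- stamp_disks(body, cbind(round(rowc) + 1L, round(colc) + 1L),
                      spec$half_width_px, TRUE, add = FALSE)
  # analytic arc length of the centerline
  dydx <- 2 * pi * spec$amplitude_px / spec$wavelength_px *
    cos(2 * pi * xs / spec$wavelength_px)
  arc <- sum(sqrt(1 + ((dydx[-1] + dydx[-length(dydx)]) / 2)^2) * diff(xs))

  scene <- matrix(pmax(0, stats::rnorm(nr * nc, spec$background_mean,
                                       spec$background_sd)), nr, nc)
  scene[body] <- spec$body_base_intensity

  # droplets: disks fully inside the body, rim brighter than interior
  dmap <- EBImage::distmap(body * 1)
  droplet_centers <- matrix(0, 0, 2); droplet_radii <- numeric(0)
  n_droplets <- spec$droplet_count
  if (!is.null(spec$droplet_density_target)) {
    unit <- droplet_unit_sum(spec$droplet_radius_range, spec$droplet_rim_gain,
                             spec$droplet_interior_gain)
    x <- (spec$droplet_density_target - spec$body_base_intensity) *
      sum(body) / unit
    if (x < 0) stop("droplet_density_target below body_base_intensity",
                    call. = FALSE)
    # stochastic rounding: the expected noiseless density hits the target
    # even when one droplet is a coarse intensity quantum
    n_droplets <- as.integer(floor(x) + stats::rbinom(1L, 1L, x - floor(x)))
  }
  if (n_droplets > 0L) {
    rmax <- spec$droplet_radius_range[2]
    elig <- which(dmap > rmax + 1, arr.ind = TRUE)
    # default: interiors disjoint (rims may touch; stamping is additive so
    # the total added intensity is exact regardless)
    min_sep <- if (is.null(spec$droplet_min_sep)) 2 * rmax + 1
               else spec$droplet_min_sep
    droplet_centers <- sample_separated(elig, n_droplets, min_sep)
    droplet_radii <- stats::runif(n_droplets,
                                  spec$droplet_radius_range[1],
                                  spec$droplet_radius_range[2])
    for (i in seq_len(n_droplets)) {
      r <- droplet_radii[i]; ctr <- droplet_centers[i, , drop = FALSE]
      scene <- stamp_disks(scene, ctr, r, spec$droplet_interior_gain)
      # rim: annulus between r and r+1, brighter than the interior
      rimval <- spec$droplet_rim_gain * spec$droplet_interior_gain
      full <- stamp_disks(matrix(0, nr, nc), ctr, r + 1, rimval)
      inner <- stamp_disks(matrix(0, nr, nc), ctr, r, rimval)
      scene <- scene + (full - inner)
    }
  }

  puncta_centers <- matrix(0, 0, 2)
  if (spec$puncta_count > 0L) {
    elig <- which(dmap > spec$puncta_radius, arr.ind = TRUE)
    puncta_centers <- sample_separated(elig, spec$puncta_count,
                                       2 * spec$puncta_radius + 1)
    scene <- stamp_disks(scene, puncta_centers, spec$puncta_radius,
                         spec$puncta_intensity)
  }

  # gain-free expected density over the body: the scene's latent truth
  noiseless_density <- mean(scene[body])
  scene <- scene * spec$intensity_gain
  if (spec$shot_noise_gain > 0)
    scene <- scene + stats::rnorm(nr * nc, 0,
                                  sqrt(spec$shot_noise_gain * pmax(scene, 0)))
  if (spec$read_noise_sd > 0)
    scene <- scene + stats::rnorm(nr * nc, 0, spec$read_noise_sd)
  scene <- pmax(scene, 0)
  if (spec$vignette > 0) {
    rr <- (seq_len(nr) - (nr + 1) / 2); cc <- (seq_len(nc) - (nc + 1) / 2)
    r2 <- outer(rr^2, cc^2, `+`)
    scene <- scene * (1 - spec$vignette * r2 / max(r2))
  }
  img <- worm_image(scene, bit_depth = 16L, modality = "darkfield",
                    pixel_size_um = spec$pixel_size_um, ingest = FALSE)
  list(image = img,
       truth = list(body_mask = body,
                    droplet_centers = droplet_centers,
                    droplet_radii = droplet_radii,
                    puncta_centers = puncta_centers,
                    latent_fat = n_droplets * spec$droplet_interior_gain,
                    noiseless_density = noiseless_density,
                    area_px = sum(body),
                    arc_length_um = arc * spec$pixel_size_um,
                    centerline = cbind(rowc, colc)))
}

#' Render a fluorescence counterpart of a dark-field scene
#'
#' Draws a Nile Red-like channel over the same body: puncta either at
#' exactly the dark-field puncta positions (`coincident = TRUE`, emulating
#' L1 larvae whose scattering comes from the stained lysosome-related
#' organelles) or at freshly sampled independent positions
#' (`coincident = FALSE`, the no-colocalization null).
#'
#' @param scene Output of [render_scene()].
#' @param spec The [scene_spec()] used for the scene.
#' @param coincident Reuse the dark-field puncta centers?
#' @param seed Seed for the independent placement and the channel noise.
#' @return A [worm_image()] with modality `"fluor_red"`.
#' @export
render_fluorescence <- function(scene, spec, coincident = TRUE, seed) {
  stopifnot(inherits(spec, "scene_spec"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  withr::with_seed(seed, {
    nr <- spec$frame[1]; nc <- spec$frame[2]
    body <- scene$truth$body_mask
    img <- matrix(pmax(0, stats::rnorm(nr * nc, spec$background_mean,
                                       spec$background_sd)), nr, nc)
    img[body] <- spec$body_base_intensity * 0.25   # dim autofluorescence
    centers <- if (coincident) {
      scene$truth$puncta_centers
    } else if (spec$puncta_count > 0L) {
      dmap <- EBImage::distmap(body * 1)
      elig <- which(dmap > spec$puncta_radius, arr.ind = TRUE)
      sample_separated(elig, spec$puncta_count, 2 * spec$puncta_radius + 1)
    } else matrix(0, 0, 2)
    if (nrow(centers))
      img <- stamp_disks(img, centers, spec$puncta_radius,
                         spec$puncta_intensity)
    if (spec$read_noise_sd > 0)
      img <- pmax(img + stats::rnorm(nr * nc, 0, spec$read_noise_sd), 0)
    worm_image(img, bit_depth = 16L, modality = "fluor_red",
               pixel_size_um = spec$pixel_size_um, ingest = FALSE)
  })
}

#' Render a synthetic calibration phantom
#'
#' A flat scattering field at `mean_level` with Gaussian noise and a dark
#' scratch mark at the center; a synthetic stand-in for a physical
#' scattering phantom. The returned [phantom_record()] uses an annulus
#' that excludes the mark, so its mean tracks `mean_level` closely.
#'
#' @param mean_level Field intensity (a.u.), > 0.
#' @param frame `c(rows, cols)`; default `c(128, 128)`.
#' @param noise_sd Gaussian pixel noise SD; default `0.01 * mean_level`.
#' @param mark_radius Scratch radius in px.
#' @param session_id Session label stored on the record.
#' @param seed Mandatory integer seed.
#' @return List with `image` and `record` (a [phantom_record()]).
#' @export
render_phantom <- function(mean_level, frame = c(128L, 128L),
                           noise_sd = 0.01 * mean_level, mark_radius = 3,
                           session_id = NULL, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (mean_level <= 0) stop("`mean_level` must be > 0", call. = FALSE)
  withr::with_seed(seed, {
    nr <- frame[1]; nc <- frame[2]
    img <- matrix(pmax(0, stats::rnorm(nr * nc, mean_level, noise_sd)), nr, nc)
    ctr <- c(floor(nr / 2), floor(nc / 2))          # 0-based mark center
    img <- stamp_disks(img, matrix(ctr + 1L, 1), mark_radius,
                       mean_level * 0.2, add = FALSE)
    frame_img <- worm_image(img, bit_depth = 16L, modality = "darkfield",
                            meta = list(session_id = session_id),
                            ingest = FALSE)
    rec <- phantom_record(frame_img, mark_center = ctr,
                          roi_inner_px = mark_radius + 2, roi_outer_px = 25,
                          session_id = session_id)
    list(image = frame_img, record = rec)
  })
}

#' Generate a synthetic cross-modality validation study
#'
#' Emulates the split-cohort design used to validate scattering density
#' against ORO staining: per condition a latent fat level is drawn, then
#' two *disjoint* sets of worms are measured -- one by dark-field
#' scattering, one by ORO staining (staining requires fixation, so the same
#' worm can never provide both). Each worm's measurement is
#' `gain * mu_condition * (1 + eps)` with `eps ~ Normal(0, noise_cv)`.
#'
#' Defaults mirror the published study shape: 23 conditions spanning a
#' 3-fold latent-fat range with about 15 worms per condition per modality.
#'
#' @param n_conditions Number of conditions (>= 3); default 23.
#' @param worms_per_condition Worms per condition per modality (>= 2);
#'   default 15.
#' @param latent_fat_range `c(lo, hi)` of latent fat levels; default
#'   `c(1, 3)`.
#' @param scatter_gain,oro_gain Measurement gain per latent unit.
#' @param noise_cv Per-worm coefficient of variation (>= 0); default 0.10.
#' @param seed Mandatory integer seed.
#' @return List of data frames `scatter` and `oro` (`condition`,
#'   `worm_id`, `density`) and `truth` (`condition`, `latent_fat`).
#' @export
generate_validation_study <- function(n_conditions = 23L,
                                      worms_per_condition = 15L,
                                      latent_fat_range = c(1, 3),
                                      scatter_gain = 1, oro_gain = 1,
                                      noise_cv = 0.10, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (n_conditions < 3L) stop("need >= 3 conditions", call. = FALSE)
  if (worms_per_condition < 2L) stop("need >= 2 worms per condition", call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  withr::with_seed(seed, {
    mu <- stats::runif(n_conditions, latent_fat_range[1], latent_fat_range[2])
    conds <- sprintf("cond_%02d", seq_len(n_conditions))
    draw <- function(gain, tag) {
      do.call(rbind, lapply(seq_len(n_conditions), function(i) {
        eps <- stats::rnorm(worms_per_condition, 0, noise_cv)
        data.frame(condition = conds[i],
                   worm_id = sprintf("%s_%s_w%02d", conds[i], tag,
                                     seq_len(worms_per_condition)),
                   density = pmax(0, gain * mu[i] * (1 + eps)),
                   stringsAsFactors = FALSE)
      }))
    }
    list(scatter = draw(scatter_gain, "df"),
         oro = draw(oro_gain, "oro"),
         truth = data.frame(condition = conds, latent_fat = mu,
                            stringsAsFactors = FALSE))
  })
}

#' Fit a generated (or measured) validation study
#'
#' Convenience wrapper: per-condition [cohort_summary()] of both
#' modalities, then [validation_fit()] of ORO means on scattering means.
#'
#' @param scatter,oro Data frames with `condition` and `density`.
#' @return A `validation_fit`.
#' @export
fit_validation_study <- function(scatter, oro) {
  conds <- intersect(unique(scatter$condition), unique(oro$condition))
  sc <- lapply(conds, function(cd)
    cohort_summary(scatter$density[scatter$condition == cd], cd))
  or <- lapply(conds, function(cd)
    cohort_summary(oro$density[oro$condition == cd], cd))
  validation_fit(sc, or)
}

# expected summed intensity added by one droplet (interior + rim), averaged
# over the radius range on the pixel grid; exact quadrature over the
# piecewise-constant pixel-count function
droplet_unit_sum <- function(radius_range, rim_gain, interior_gain) {
  npix <- function(r) {
    ri <- ceiling(r)
    off <- expand.grid(dr = -ri:ri, dc = -ri:ri)
    sum(off$dr^2 + off$dc^2 <= r^2)
  }
  rs <- seq(radius_range[1], radius_range[2], length.out = 41)
  mean(vapply(rs, function(r)
    npix(r) * interior_gain + (npix(r + 1) - npix(r)) * rim_gain * interior_gain,
    numeric(1)))
}

#' Generate a two-objective developmental time course
#'
#' Renders full scenes for synchronized cohorts culled at each profile
#' timepoint. Early timepoints are "imaged" through a simulated
#' high-magnification objective (fine pixel size), late ones through a
#' low-magnification objective (coarser pixels and different light
#' throughput); the shared timepoint is rendered through both, providing
#' the stitching anchor.
#'
#' `profile$latent_fat` is the target gain-free scattering density
#' (a.u./px) of the body at each timepoint: the generator converts it to a
#' droplet count using the closed-form expected per-droplet contribution,
#' so programmed fold-changes in `latent_fat` appear as matching
#' fold-changes in measured density. Each record's `truth$noiseless_density`
#' stores the realized gain-free density for exact comparisons.
#'
#' @param profile Data frame with increasing `timepoint_hr`, `latent_fat`
#'   (target density, a.u./px) and `length_um`.
#' @param worms_per_point Worms rendered per timepoint per objective.
#' @param shared_t Timepoint imaged through both objectives.
#' @param px_a,px_b Pixel sizes (um) of the two objectives (a = high mag,
#'   used for `t <= shared_t`; b = low mag, `t >= shared_t`).
#' @param gain_b Relative intensity gain of objective b (throughput
#'   mismatch the stitching must absorb).
#' @param frame Frame size for all scenes.
#' @param body_base_intensity Body intensity before droplets; must be
#'   below every `latent_fat` target.
#' @param droplet_interior_gain Intensity increment of a droplet interior.
#' @param noise List overriding noise fields of the scene spec.
#' @param seed Mandatory integer seed.
#' @return List of records, each `list(image, truth, timepoint_hr,
#'   objective, worm_id)`, plus attribute `profile`.
#' @export
generate_timecourse <- function(profile, worms_per_point = 12L, shared_t = 31,
                                px_a = 1, px_b = 2, gain_b = 0.55,
                                frame = c(176L, 176L),
                                body_base_intensity = 12,
                                droplet_interior_gain = 100,
                                noise = list(background_sd = 1,
                                             shot_noise_gain = 0.5,
                                             read_noise_sd = 1),
                                seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(all(c("timepoint_hr", "latent_fat", "length_um") %in% names(profile)))
  if (is.unsorted(profile$timepoint_hr, strictly = TRUE))
    stop("profile times must be increasing", call. = FALSE)
  if (any(profile$latent_fat <= body_base_intensity))
    stop("latent_fat targets must exceed body_base_intensity", call. = FALSE)
  radius_range <- c(1.5, 2)
  records <- list()
  rseed <- withr::with_seed(seed, sample.int(2^31 - 2, 1))
  k <- 0L
  for (i in seq_len(nrow(profile))) {
    t <- profile$timepoint_hr[i]
    objs <- c(if (t <= shared_t) "40x", if (t >= shared_t) "20x")
    for (obj in objs) {
      px <- if (obj == "40x") px_a else px_b
      gain <- if (obj == "40x") 1 else gain_b
      len_px <- profile$length_um[i] / px
      hw <- max(4, round(len_px / 14))
      if (len_px + 2 * (hw + 2) > frame[2])
        stop(sprintf("worm of %g um does not fit the %s frame",
                     profile$length_um[i], obj), call. = FALSE)
      amp <- max(2, round(hw / 2))
      # span chosen so the centerline arc length matches the programmed
      # body length (gentle sinusoid: first-order curvature correction)
      span <- len_px / (1 + 0.25 * (2 * pi * amp / len_px)^2 / 2)
      for (w in seq_len(worms_per_point)) {
        k <- k + 1L
        sp <- scene_spec(
          frame = frame, amplitude_px = amp,
          wavelength_px = span, half_width_px = hw, span_px = span,
          body_base_intensity = body_base_intensity,
          background_mean = 2, background_sd = noise$background_sd,
          droplet_density_target = profile$latent_fat[i],
          droplet_min_sep = 0,
          droplet_radius_range = radius_range, droplet_rim_gain = 1.5,
          droplet_interior_gain = droplet_interior_gain,
          shot_noise_gain = noise$shot_noise_gain,
          read_noise_sd = noise$read_noise_sd,
          pixel_size_um = px, intensity_gain = gain,
          seed = (rseed + 7L * k) %% (2^31 - 1))
        sc <- render_scene(sp)
        sc$image$meta$timepoint_hr <- t
        sc$image$meta$objective <- obj
        records[[k]] <- list(image = sc$image, truth = sc$truth,
                             timepoint_hr = t, objective = obj,
                             worm_id = sprintf("t%g_%s_w%d", t, obj, w))
      }
    }
  }
  attr(records, "profile") <- profile
  records
}

#' Generate a synthetic paired fasting cohort
#'
#' Emulates re-imaging the same worms after a period of fasting: each worm
#' has a latent baseline density, loses a stochastic fraction of it during
#' the fast, and both imaging sessions add independent multiplicative
#' measurement noise. With losses well above the measurement noise every
#' worm shows a decrease; with zero loss the sign of the measured change
#' is a coin flip.
#'
#' @param n_worms Number of worms; default 55.
#' @param baseline_density Mean baseline density (a.u./px).
#' @param baseline_cv Between-worm CV of the baseline.
#' @param loss_range `c(lo, hi)` fraction of density lost per worm
#'   (uniform); default `c(0.10, 0.40)`. Use `c(0, 0)` for a null cohort.
#' @param noise_cv Per-measurement CV; default 0.02.
#' @param seed Mandatory integer seed.
#' @return List of data frames `before` and `after` (`worm_id`,
#'   `density`) and `truth` (`worm_id`, `loss_fraction`).
#' @export
generate_fasting_cohort <- function(n_worms = 55L, baseline_density = 50,
                                    baseline_cv = 0.20,
                                    loss_range = c(0.10, 0.40),
                                    noise_cv = 0.02, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  withr::with_seed(seed, {
    ids <- sprintf("worm_%02d", seq_len(n_worms))
    base <- baseline_density * (1 + stats::rnorm(n_worms, 0, baseline_cv))
    base <- pmax(base, 0.1 * baseline_density)
    loss <- stats::runif(n_worms, loss_range[1], loss_range[2])
    before <- base * (1 + stats::rnorm(n_worms, 0, noise_cv))
    after <- base * (1 - loss) * (1 + stats::rnorm(n_worms, 0, noise_cv))
    list(before = data.frame(worm_id = ids, density = before,
                             stringsAsFactors = FALSE),
         after = data.frame(worm_id = ids, density = after,
                            stringsAsFactors = FALSE),
         truth = data.frame(worm_id = ids, loss_fraction = loss,
                            stringsAsFactors = FALSE))
  })
}

#' Measure a generated time course into a density series
#'
#' Segments each rendered frame at the objective's threshold, measures the
#' scattering density of the largest worm, and returns the long series
#' data frame that [stitch_objectives()] and [normalize_to_baseline()]
#' consume, together with per-timepoint mean measured worm lengths.
#'
#' @param records Output of [generate_timecourse()].
#' @param thresholds Named vector of per-objective segmentation thresholds
#'   (a.u.), e.g. `c("40x" = 6, "20x" = 3.5)`; a single unnamed value is
#'   used for all objectives.
#' @param min_area_px Minimum component area.
#' @return List: `series` (columns `timepoint_hr`, `density`, `objective`,
#'   `worm_id`), `lengths` (`timepoint_hr`, `mean_length_um`), `truth`
#'   (`timepoint_hr`, `mean_noiseless_density`).
#' @export
measure_timecourse <- function(records, thresholds = c("40x" = 6, "20x" = 3.8),
                               min_area_px = 200L) {
  rows <- lapply(records, function(rec) {
    thr <- if (is.null(names(thresholds))) thresholds[1]
           else thresholds[[rec$objective]]
    masks <- segment_worms(rec$image, thr, min_area_px = min_area_px,
                           max_worms = 1L)
    if (!length(masks)) return(NULL)
    d <- scattering_density(rec$image, masks[[1]])
    # open the mask before skeletonizing: boundary noise fuzz would grow
    # spurs and zigzags that inflate the geodesic length
    smooth <- EBImage::opening(masks[[1]]$mask * 1,
                               EBImage::makeBrush(3, "box")) > 0
    data.frame(timepoint_hr = rec$timepoint_hr, density = d$density,
               objective = rec$objective, worm_id = rec$worm_id,
               length_um = worm_length(smooth, rec$image$pixel_size_um),
               truth_density = rec$truth$noiseless_density,
               stringsAsFactors = FALSE)
  })
  series <- do.call(rbind, rows)
  ts <- sort(unique(series$timepoint_hr))
  per_t <- function(col) vapply(ts, function(t)
    mean(series[[col]][abs(series$timepoint_hr - t) < 1e-9]), numeric(1))
  list(series = series[c("timepoint_hr", "density", "objective", "worm_id")],
       lengths = data.frame(timepoint_hr = ts,
                            mean_length_um = per_t("length_um")),
       truth = data.frame(timepoint_hr = ts,
                          mean_noiseless_density = per_t("truth_density")))
}
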