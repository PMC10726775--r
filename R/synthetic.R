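# Synthetic data: parametric body-outline templates, pain-drawing cohorts
# with controllable group effects, and noisy scan renders with ground truth.
# All generators are pure functions of (configuration, seed).

#' Parametric synthetic body-outline template
#'
#' Builds a deterministic body silhouette (composed ellipses, strips and a
#' piecewise-linear torso) with frontal and dorsal views side by side on one
#' sheet, three corner fiducial discs, and named anatomical regions
#' (`abdomen`, `chest`, `legs` on the frontal view; `back`, `dorsal_legs` on
#' the dorsal view) used by [sample_cohort()].
#'
#' The `female` and `sexless` variants differ in shoulder and chest width and
#' in the gap between the legs, but share the torso geometry from the waist
#' to the hips, so the drawable area of the abdomen/hip band is identical
#' across variants — pain in the region most relevant for endometriosis is
#' drawn on equal canvas in both.
#'
#' The default size approximates an A4 sheet at 150 dpi.
#'
#' @param sex_label `"female"` or `"sexless"`.
#' @param width,height raster size in pixels; at least 200 x 200.
#' @param fiducial_radius marker disc radius in pixels; default scales with
#'   the sheet width (about 3 mm at 150 dpi).
#' @param template_id identifier; default derived from the arguments.
#' @return a [body_template()].
#' @export
make_template <- function(sex_label = c("female", "sexless"),
                          width = 1240, height = 1754,
                          fiducial_radius = NULL, template_id = NULL) {
  sex_label <- match.arg(sex_label)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 200L || height < 200L)
    stopf("make_template: size %dx%d too small for the body layout (min 200x200)",
          height, width)
  if (is.null(fiducial_radius)) fiducial_radius <- max(3, round(width / 124))
  if (is.null(template_id))
    template_id <- sprintf("synthetic-%s-%dx%d", sex_label, width, height)
  h <- height; w <- width
  rowm <- matrix(seq_len(h), h, w)
  colm <- matrix(seq_len(w), h, w, byrow = TRUE)

  # sex-dependent proportions (fractions of sheet width/height)
  shoulder_hw <- if (sex_label == "sexless") 0.095 else 0.085
  chest_hw    <- if (sex_label == "sexless") 0.083 else 0.088
  waist_hw    <- 0.062   # shared below here: abdomen band matched across sexes
  hip_hw      <- 0.085
  leg_gap     <- if (sex_label == "sexless") 0.010 else 0.006

  silhouette <- function(cx) {
    m <- matrix(FALSE, h, w)
    # head
    m <- m | (((rowm - 0.117 * h) / (0.037 * h))^2 +
                ((colm - cx) / (0.030 * w))^2 <= 1)
    # neck
    m <- m | (rowm >= 0.150 * h & rowm <= 0.185 * h & abs(colm - cx) <= 0.015 * w)
    # torso: piecewise-linear halfwidth from neck to crotch
    ctrl_r <- round(c(0.180, 0.205, 0.270, 0.400, 0.500, 0.530) * h)
    ctrl_hw <- c(0.020, shoulder_hw, chest_hw, waist_hw, hip_hw, 0.080) * w
    hw <- rep(0, h)
    rr <- ctrl_r[1]:ctrl_r[6]
    hw[rr] <- stats::approx(ctrl_r, ctrl_hw, xout = rr)$y
    m <- m | (abs(colm - cx) <= hw[pmin(pmax(rowm, 1L), h)] & rowm >= ctrl_r[1] &
                rowm <= ctrl_r[6])
    # arms: vertical strips clear of the torso
    arm_off <- (shoulder_hw + 0.035) * w
    m <- m | (rowm >= 0.210 * h & rowm <= 0.500 * h &
                (abs(colm - (cx - arm_off)) <= 0.016 * w |
                   abs(colm - (cx + arm_off)) <= 0.016 * w))
    # legs: tapering strips with a sex-dependent inner gap
    in_leg_rows <- rowm >= 0.530 * h & rowm <= 0.920 * h
    taper <- hip_hw * w + (rowm - 0.530 * h) / (0.390 * h) *
      (0.045 * w - hip_hw * w)
    off <- abs(colm - cx)
    m <- m | (in_leg_rows & off >= leg_gap * w & off <= taper)
    m
  }

  cx1 <- round(0.27 * w); cx2 <- round(0.73 * w)
  mask <- silhouette(cx1) | silhouette(cx2)

  # margin wide enough that a few degrees of page rotation on the scanner
  # bed cannot push a corner marker off the captured area
  marg <- max(2 * fiducial_radius + 2, round(0.06 * min(h, w)))
  fid <- rbind(c(marg, marg), c(marg, w - marg), c(h - marg, marg))

  rect <- function(r0, c0, r1, c1)
    c(max(1L, round(r0)), max(1L, round(c0)), min(h, round(r1)), min(w, round(c1)))
  regions <- list(
    abdomen = rect(0.400 * h, cx1 - hip_hw * w, 0.500 * h, cx1 + hip_hw * w),
    chest = rect(0.215 * h, cx1 - chest_hw * w, 0.330 * h, cx1 + chest_hw * w),
    legs = rect(0.560 * h, cx1 - hip_hw * w, 0.900 * h, cx1 + hip_hw * w),
    back = rect(0.280 * h, cx2 - hip_hw * w, 0.500 * h, cx2 + hip_hw * w),
    dorsal_legs = rect(0.560 * h, cx2 - hip_hw * w, 0.900 * h, cx2 + hip_hw * w))

  body_template(template_id, mask, fid, sex_label = sex_label,
                views = list(frontal = c(1L, 1L, h, w %/% 2L),
                             dorsal = c(1L, w %/% 2L + 1L, h, w)),
                fiducial_radius = fiducial_radius, regions = regions)
}

#' Cohort generator configuration
#'
#' Describes a two-group synthetic cohort of pain drawings. Defaults emulate
#' the study scale this package is built around: 24 drawings on the sexless
#' template and 26 on the female one, total marked areas lognormal on the
#' log10 scale (mean 3.3, sd 0.35 — matching observed log10 pixel-count
#' summaries) truncated to \[500, 20000\] pixels (the floor reflects the
#' smallest blotch a 1 mm fiber pen plausibly produces at 150 dpi), 1-4 pain
#' blobs per drawing, and region weights concentrated on the abdomen and
#' lower back, where endometriosis pain clusters.
#'
#' @param n_a,n_b group sizes.
#' @param blob_count integer vector of possible blob counts per drawing
#'   (sampled uniformly).
#' @param area_log10_mean,area_log10_sd lognormal parameters of the total
#'   target area per drawing, on the log10 scale.
#' @param area_range truncation bounds (pixels) for the target area.
#' @param area_scale multiplier applied to sampled areas and bounds; use
#'   `(dpi/150)^2` when generating on a reduced-resolution template.
#' @param region_weights named nonnegative weights over template regions for
#'   blob placement (normalized internally).
#' @param pen_radius pen-tip radius in pixels used to regularize blob
#'   boundaries (morphological closing/opening); about 0.3 mm at 150 dpi.
#'   Scale with resolution, 0 disables smoothing.
#' @param min_blob_area smallest area a single blob may be asked to have;
#'   blob counts are capped so each blob stays above it.
#' @param effect group-B modification: `"none"`, `"area_shift"` (areas
#'   multiplied by `area_multiplier`) or `"region_shift"` (group B placed by
#'   `region_weights_b`).
#' @param area_multiplier multiplier for `effect = "area_shift"`.
#' @param region_weights_b weights for group B under `effect = "region_shift"`.
#' @param group_labels labels for the two groups.
#' @param seed optional RNG seed making [sample_cohort()] reproducible.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_a = 24, n_b = 26, blob_count = 1:4,
                          area_log10_mean = 3.3, area_log10_sd = 0.35,
                          area_range = c(500, 20000), area_scale = 1,
                          region_weights = c(abdomen = 0.55, back = 0.25,
                                             legs = 0.12, chest = 0.08),
                          pen_radius = 2L, min_blob_area = 150L,
                          effect = c("none", "area_shift", "region_shift"),
                          area_multiplier = 1.5, region_weights_b = NULL,
                          group_labels = c("sexless", "female"), seed = NULL) {
  effect <- match.arg(effect)
  if (n_a < 1 || n_b < 1) stopf("cohort_config: group sizes must be >= 1")
  if (any(region_weights < 0) || sum(region_weights) <= 0)
    stopf("cohort_config: region weights must be nonnegative with positive sum")
  if (effect == "region_shift" && is.null(region_weights_b))
    stopf("cohort_config: region_shift requires region_weights_b")
  if (!is.null(region_weights_b) &&
      (any(region_weights_b < 0) || sum(region_weights_b) <= 0))
    stopf("cohort_config: region_weights_b must be nonnegative with positive sum")
  structure(list(n_a = as.integer(n_a), n_b = as.integer(n_b),
                 blob_count = as.integer(blob_count),
                 area_log10_mean = area_log10_mean,
                 area_log10_sd = area_log10_sd,
                 area_range = area_range, area_scale = area_scale,
                 pen_radius = as.integer(pen_radius),
                 min_blob_area = as.integer(min_blob_area),
                 region_weights = region_weights / sum(region_weights),
                 effect = effect, area_multiplier = area_multiplier,
                 region_weights_b = if (!is.null(region_weights_b))
                   region_weights_b / sum(region_weights_b),
                 group_labels = group_labels, seed = seed),
            class = "cohort_config")
}

# Morphological smoothing of a marked region at pen scale: closing then
# opening with a disc, restricted to `allowed`. A 1 mm fiber pen cannot
# produce features below its tip width, so raw Eden-growth raggedness is
# regularized to the pen's resolution. Operates on the bounding box only.
#' @noRd
smooth_mask <- function(marks, allowed, radius = 2L) {
  idx <- which(marks)
  if (length(idx) == 0L) return(marks)
  h <- nrow(marks)
  rr <- range(((idx - 1L) %% h) + 1L)
  cc <- range(((idx - 1L) %/% h) + 1L)
  pad <- 2L * radius + 1L
  r0 <- max(1L, rr[1] - pad); r1 <- min(h, rr[2] + pad)
  c0 <- max(1L, cc[1] - pad); c1 <- min(ncol(marks), cc[2] + pad)
  sub <- marks[r0:r1, c0:c1, drop = FALSE]
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  shift_or <- function(m, erode = FALSE) {
    out <- matrix(erode, nrow(m), ncol(m))
    nr <- nrow(m); nc <- ncol(m)
    for (k in seq_len(nrow(offs))) {
      dr <- offs$dr[k]; dc <- offs$dc[k]
      src_r <- max(1L, 1L - dr):min(nr, nr - dr)
      src_c <- max(1L, 1L - dc):min(nc, nc - dc)
      piece <- m[src_r + dr, src_c + dc, drop = FALSE]
      if (erode) out[src_r, src_c] <- out[src_r, src_c] & piece
      else out[src_r, src_c] <- out[src_r, src_c] | piece
    }
    if (erode) {
      # off-edge neighbourhood counts as background
      border <- matrix(TRUE, nr, nc)
      border[(radius + 1L):(nr - radius), (radius + 1L):(nc - radius)] <- FALSE
      out[border] <- FALSE
    }
    out
  }
  closed <- shift_or(shift_or(sub), erode = TRUE)
  opened <- shift_or(shift_or(closed, erode = TRUE))
  marks[r0:r1, c0:c1] <- opened & allowed[r0:r1, c0:c1]
  marks
}

# Adjust a marked region to an exact pixel count by Eden growth (add random
# allowed boundary pixels) or reverse-Eden shrinkage (remove random boundary
# pixels), so smoothing preserves the sampled target area exactly.
#' @noRd
adjust_area <- function(marks, allowed, target) {
  n <- sum(marks)
  h <- nrow(marks); n_px <- length(marks)
  if (n < target) {
    idx <- which(marks)
    nbrs <- function(px) {
      r <- ((px - 1L) %% h) + 1L
      c(if (length(px)) px[r > 1L] - 1L, px[r < h] + 1L,
        px[px > h] - h, px[px <= n_px - h] + h)
    }
    frontier <- unique(nbrs(idx))
    frontier <- frontier[allowed[frontier] & !marks[frontier]]
    while (n < target && length(frontier) > 0L) {
      j <- sample.int(length(frontier), 1L)
      px <- frontier[j]
      frontier <- frontier[-j]
      if (marks[px]) next
      marks[px] <- TRUE
      n <- n + 1L
      nb <- nbrs(px)
      nb <- nb[allowed[nb] & !marks[nb]]
      frontier <- c(frontier, nb[!nb %in% frontier])
    }
  } else if (n > target) {
    # controlled erosion: peel boundary pixels with the fewest marked
    # neighbours first (random tie-break), preserving smoothness
    m <- matrix(0L, h + 2L, ncol(marks) + 2L)
    while (n > target) {
      edge <- which(mask_edge(marks))
      if (length(edge) == 0L) break
      m[] <- 0L
      m[2:(h + 1L), 2:(ncol(marks) + 1L)] <- marks * 1L
      er <- ((edge - 1L) %% h) + 2L
      ec <- ((edge - 1L) %/% h) + 2L
      hh <- h + 2L
      lin <- (ec - 1L) * hh + er
      nbc <- m[lin - 1L] + m[lin + 1L] + m[lin - hh] + m[lin + hh] +
        m[lin - hh - 1L] + m[lin - hh + 1L] + m[lin + hh - 1L] + m[lin + hh + 1L]
      k <- min(n - target, max(1L, length(edge) %/% 4L))
      drop <- edge[order(nbc, stats::runif(length(edge)))[seq_len(k)]]
      marks[drop] <- FALSE
      n <- n - k
    }
  }
  marks
}

# Eden-style blob growth: starting from a seed pixel, repeatedly convert a
# uniformly chosen frontier pixel (4-neighbour of the blob, inside `allowed`)
# into a blob pixel until the target area is reached or the frontier empties.
#' @noRd
grow_blob <- function(allowed, seed_idx, target_area) {
  h <- nrow(allowed)
  n_px <- length(allowed)
  in_set <- logical(n_px)            # in blob or frontier
  blob <- integer(target_area)
  n_blob <- 0L
  frontier <- integer(max(64L, 4L * target_area))
  frontier[1L] <- seed_idx
  flen <- 1L
  in_set[seed_idx] <- TRUE
  while (n_blob < target_area && flen > 0L) {
    j <- sample.int(flen, 1L)
    px <- frontier[j]
    frontier[j] <- frontier[flen]
    flen <- flen - 1L
    n_blob <- n_blob + 1L
    blob[n_blob] <- px
    r <- ((px - 1L) %% h) + 1L
    nb <- c(if (r > 1L) px - 1L, if (r < h) px + 1L,
            if (px > h) px - h, if (px <= n_px - h) px + h)
    nb <- nb[allowed[nb] & !in_set[nb]]
    if (length(nb)) {
      if (flen + length(nb) > length(frontier))
        frontier <- c(frontier, integer(length(frontier)))
      frontier[flen + seq_along(nb)] <- nb
      flen <- flen + length(nb)
      in_set[nb] <- TRUE
    }
  }
  blob[seq_len(n_blob)]
}

#' @noRd
region_pixels <- function(template, region_name) {
  r <- template$regions[[region_name]]
  if (is.null(r)) stopf("template '%s' has no region '%s'",
                        template$template_id, region_name)
  h <- template$height
  sub <- template$outline_mask[r[1]:r[3], r[2]:r[4], drop = FALSE]
  idx <- which(sub)
  sub_h <- r[3] - r[1] + 1L
  rr <- ((idx - 1L) %% sub_h) + r[1]
  cc <- ((idx - 1L) %/% sub_h) + r[2]
  (cc - 1L) * h + rr
}

#' @noRd
sample_one_drawing <- function(template, weights, target_area, n_blobs,
                               pen_radius = 2L, min_blob_area = 150L) {
  h <- template$height; w <- template$width
  marks <- matrix(FALSE, h, w)
  # a blob below ~min_blob_area px would be smaller than a few pen widths
  n_blobs <- max(1L, min(n_blobs, target_area %/% min_blob_area))
  prop <- stats::runif(n_blobs, 0.5, 1.5)
  blob_areas <- pmax(25L, as.integer(round(target_area * prop / sum(prop))))
  capped <- FALSE
  region_px <- lapply(names(weights), function(nm) region_pixels(template, nm))
  names(region_px) <- names(weights)
  for (a in blob_areas) {
    nm <- sample(names(weights), 1L, prob = weights)
    cand <- region_px[[nm]]
    if (length(cand) == 0L) cand <- which(template$outline_mask)
    seed_px <- cand[sample.int(length(cand), 1L)]
    blob <- grow_blob(template$outline_mask, seed_px, a)
    if (length(blob) < a) capped <- TRUE
    marks[blob] <- TRUE
  }
  # regularize at pen scale, then restore the sampled area exactly
  if (pen_radius > 0L) {
    sm <- smooth_mask(marks, template$outline_mask, pen_radius)
    if (any(sm)) marks <- sm  # tiny blobs can vanish under opening; keep raw
    if (!capped) marks <- adjust_area(marks, template$outline_mask, target_area)
    if (sum(marks) < target_area) capped <- TRUE
  }
  list(marks = marks, capped = capped)
}

#' Generate a synthetic two-group pain-drawing cohort
#'
#' Draws each subject's total marked area and blob count from the
#' configuration, places blob seeds in template regions by the region
#' weights, grows each blob by random boundary dilation inside the outline,
#' and applies the configured group-B effect. Ground truth (targets, blob
#' counts, capping) is retained for validation. With a fixed `config$seed`
#' the cohort is fully reproducible.
#'
#' @param template_a,template_b [body_template()] for groups A and B (may be
#'   the same object).
#' @param config a [cohort_config()].
#' @return list with `drawings` (list of [pain_drawing()], group A then B),
#'   `truth` (data.frame of per-drawing ground truth) and `config`.
#' @export
sample_cohort <- function(template_a, template_b, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  labs <- config$group_labels
  prefixes <- toupper(substr(labs, 1, 1))
  if (prefixes[1] == prefixes[2]) prefixes <- c("A", "B")
  with_seed(config$seed, {
    rng <- config$area_range * config$area_scale
    draw_area <- function(mult = 1) {
      a <- 10^stats::rnorm(1, config$area_log10_mean, config$area_log10_sd)
      as.integer(round(min(max(a * config$area_scale * mult, rng[1]), rng[2])))
    }
    wA <- config$region_weights
    wB <- switch(config$effect,
                 region_shift = config$region_weights_b,
                 config$region_weights)
    multB <- if (config$effect == "area_shift") config$area_multiplier else 1
    drawings <- vector("list", config$n_a + config$n_b)
    truth <- vector("list", config$n_a + config$n_b)
    k <- 0L
    n_capped <- 0L
    for (g in 1:2) {
      tpl <- if (g == 1L) template_a else template_b
      wts <- if (g == 1L) wA else wB
      mult <- if (g == 1L) 1 else multB
      n_g <- if (g == 1L) config$n_a else config$n_b
      for (i in seq_len(n_g)) {
        k <- k + 1L
        target <- draw_area(mult)
        n_blobs <- if (length(config$blob_count) == 1L) config$blob_count
        else sample(config$blob_count, 1L)
        one <- sample_one_drawing(tpl, wts, target, n_blobs,
                                  pen_radius = config$pen_radius,
                                  min_blob_area = config$min_blob_area)
        if (one$capped) n_capped <- n_capped + 1L
        id <- sprintf("%s_%d", prefixes[g], i)
        drawings[[k]] <- pain_drawing(
          id, tpl, one$marks, labs[g],
          provenance = list(kind = "synthetic", seed = config$seed))
        truth[[k]] <- data.frame(
          drawing_id = id, group = labs[g], template_id = tpl$template_id,
          target_area = target, n_marked = sum(one$marks),
          n_blobs = n_blobs, capped = one$capped)
      }
    }
    if (n_capped > 0L)
      warnf("sample_cohort: %d drawing(s) capped below target area (region exhausted)",
            n_capped)
    list(drawings = drawings, truth = do.call(rbind, truth), config = config)
  })
}

#' Scan-noise configuration
#'
#' Perturbations applied by [render_scan()]: a random rigid-plus-scale page
#' placement and pixel-level intensity noise. Defaults model a benign flatbed
#' scan: rotation up to 3 degrees, translation up to 10 px, scale jitter up
#' to 2%, Gaussian intensity noise with sd 8 (on the 0-255 scale), 0.1%
#' salt-and-pepper pixels and 1% pen dropout (white gaps inside pen strokes).
#'
#' @param rotation_deg,translation_px,scale_jitter half-ranges of the uniform
#'   placement perturbations.
#' @param intensity_sd Gaussian intensity noise sd (0-255 scale).
#' @param salt_pepper fraction of pixels forced to pure black/white.
#' @param pen_dropout fraction of mark pixels left unrendered.
#' @param seed optional RNG seed.
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(rotation_deg = 3, translation_px = 10,
                         scale_jitter = 0.02, intensity_sd = 8,
                         salt_pepper = 0.001, pen_dropout = 0.01,
                         seed = NULL) {
  stopifnot(rotation_deg >= 0, translation_px >= 0, scale_jitter >= 0,
            intensity_sd >= 0, salt_pepper >= 0, salt_pepper <= 1,
            pen_dropout >= 0, pen_dropout <= 1)
  structure(list(rotation_deg = rotation_deg, translation_px = translation_px,
                 scale_jitter = scale_jitter, intensity_sd = intensity_sd,
                 salt_pepper = salt_pepper, pen_dropout = pen_dropout,
                 seed = seed),
            class = "noise_config")
}

#' Noise-free scan configuration
#'
#' Convenience: a [noise_config()] with every perturbation set to zero, so
#' [render_scan()] produces the template-coordinate image unchanged.
#' @return a `noise_config`.
#' @export
noise_none <- function() noise_config(0, 0, 0, 0, 0, 0)

#' Render a pain drawing as a synthetic grayscale scan
#'
#' Produces the page image a flatbed scanner would deliver: white background,
#' the body outline as a gray (160) contour, black fiducial discs (20) and
#' near-black pen marks (25), placed on the page under a random
#' rotation/translation/scale drawn from the noise configuration, then
#' corrupted with pen dropout, Gaussian intensity noise and salt-and-pepper
#' speckle. The exact scan-to-template affine transform that was applied is
#' returned as ground truth for registration tests.
#'
#' @param drawing a [pain_drawing()].
#' @param template the matching [body_template()].
#' @param noise a [noise_config()].
#' @param seed optional seed (defaults to `noise$seed`).
#' @return an object of class `scan_image`: list with `pixels` (numeric
#'   matrix, 0-255, 0 = black), `true_affine` (2x3 scan-to-template map),
#'   `drawing_id`, `template_id`.
#' @export
render_scan <- function(drawing, template, noise = noise_config(),
                        seed = noise$seed) {
  stopifnot(inherits(drawing, "pain_drawing"), inherits(template, "body_template"))
  if (!identical(drawing$template_id, template$template_id))
    stopf("render_scan: drawing/template mismatch")
  h <- template$height; w <- template$width
  with_seed(seed, {
    theta <- stats::runif(1, -noise$rotation_deg, noise$rotation_deg) * pi / 180
    tr <- stats::runif(2, -noise$translation_px, noise$translation_px)
    s <- 1 + stats::runif(1, -noise$scale_jitter, noise$scale_jitter)
    ctr <- c((h + 1) / 2, (w + 1) / 2)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    # forward map template -> scan: q = s R (p - ctr) + ctr + tr
    fwd <- cbind(s * R, -s * R %*% ctr + ctr + tr)
    scan2tpl <- affine_invert(fwd)

    # compose the ideal page in template coordinates
    base <- matrix(250, h, w)
    edge <- mask_edge(template$outline_mask)
    edge2 <- mask_edge(template$outline_mask & !edge)
    base[edge | edge2] <- 160
    mark_idx <- which(drawing$marks)
    if (noise$pen_dropout > 0 && length(mark_idx)) {
      keep <- stats::runif(length(mark_idx)) >= noise$pen_dropout
      mark_idx <- mark_idx[keep]
    }
    base[mark_idx] <- 25
    for (i in 1:3)
      base[disc_indices(h, w, template$fiducials[i, 1], template$fiducials[i, 2],
                        template$fiducial_radius)] <- 20

    # sample the page at each scan pixel; a scanner sensor integrates over
    # the pixel footprint, so average a 2x2 subpixel grid (anti-aliasing --
    # this is what makes subpixel fiducial localization possible downstream)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    scan <- matrix(0, h, w)
    for (o_r in c(-0.25, 0.25)) for (o_c in c(-0.25, 0.25)) {
      p <- affine_apply(scan2tpl, rows + o_r, cols + o_c)
      pr <- round(p$row); pc <- round(p$col)
      inb <- pr >= 1 & pr <= h & pc >= 1 & pc <= w
      sub <- matrix(255, h, w)
      sub[inb] <- base[(pc[inb] - 1) * h + pr[inb]]
      scan <- scan + sub
    }
    scan <- scan / 4

    if (noise$intensity_sd > 0)
      scan <- scan + stats::rnorm(length(scan), 0, noise$intensity_sd)
    if (noise$salt_pepper > 0) {
      n_sp <- round(noise$salt_pepper * length(scan))
      if (n_sp > 0) {
        idx <- sample.int(length(scan), n_sp)
        half <- seq_len(n_sp) <= n_sp / 2
        scan[idx[half]] <- 0
        scan[idx[!half]] <- 255
      }
    }
    scan <- pmin(pmax(scan, 0), 255)
    structure(list(pixels = scan, true_affine = scan2tpl,
                   drawing_id = drawing$drawing_id,
                   template_id = template$template_id,
                   noise = noise, seed = seed),
              class = "scan_image")
  })
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("Scan image (%d x %d) of drawing '%s' on template '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$drawing_id, x$template_id))
  invisible(x)
}
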