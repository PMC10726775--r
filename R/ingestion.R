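# Scan ingestion: fiducial detection, affine registration to the template,
# mark binarization and clipping.
#
# Intensity conventions (0-255 scale, 0 = black): the body outline is printed
# gray (around 160), fiducial discs and fiber-pen marks are near-black
# (below 40). The default mark threshold of 80 therefore captures pen ink
# while leaving the printed outline unmarked; both thresholds are
# configurable.

#' @noRd
scan_pixels <- function(scan) {
  px <- if (inherits(scan, "scan_image")) scan$pixels else scan
  if (!is.matrix(px) || !is.numeric(px))
    stopf("scan must be a numeric intensity matrix or a scan_image")
  px
}

#' Detect the three fiducial markers on a scanned sheet
#'
#' Thresholds the scan, labels 8-connected dark components, keeps those whose
#' area lies within \[0.5, 2\] times the expected marker area, and selects the
#' candidate triple whose pairwise-distance pattern best matches the
#' template's fiducial triad. The returned centroids are ordered to match the
#' template fiducial order.
#'
#' @param scan a `scan_image` or numeric intensity matrix (0-255).
#' @param template the [body_template()] the sheet was printed from.
#' @param expected_area_px expected marker area in pixels; defaults to the
#'   area of the template's fiducial disc.
#' @param fiducial_threshold intensity below which a pixel counts as marker
#'   ink.
#' @param match_tol maximum acceptable relative mismatch between detected and
#'   template pairwise distances.
#' @return numeric 3 x 2 matrix of (row, col) centroids in scan coordinates.
#' @export
detect_fiducials <- function(scan, template, expected_area_px = NULL,
                             fiducial_threshold = 80, match_tol = 0.05) {
  px <- scan_pixels(scan)
  if (is.null(expected_area_px))
    expected_area_px <- pi * template$fiducial_radius^2
  dark <- px < fiducial_threshold
  comp <- label_components(dark)
  if (comp$n == 0L)
    stopf("detect_fiducials: fewer than 3 candidate blobs (page has no dark ink)")
  areas <- tabulate(comp$label, comp$n)
  cand <- which(areas >= 0.5 * expected_area_px & areas <= 2 * expected_area_px)
  if (length(cand) < 3L)
    stopf("detect_fiducials: fewer than 3 candidate blobs of plausible marker area (%d found)",
          length(cand))
  h <- nrow(px); n_px <- length(px)
  # darkness-weighted centroid over the component plus a 1-pixel ring: the
  # anti-aliased marker edge carries the subpixel position information
  weighted_centroid <- function(lab) {
    idx <- comp$pixels[comp$label == lab]
    ring <- c(idx, idx - 1L, idx + 1L, idx - h, idx + h,
              idx - h - 1L, idx - h + 1L, idx + h - 1L, idx + h + 1L)
    ring <- unique(ring[ring >= 1L & ring <= n_px])
    wgt <- pmax(0, 230 - px[ring])
    rr <- ((ring - 1L) %% h) + 1L
    cc <- ((ring - 1L) %/% h) + 1L
    c(sum(wgt * rr), sum(wgt * cc)) / sum(wgt)
  }
  cents <- t(vapply(cand, weighted_centroid, numeric(2)))

  pair_d <- function(p) c(
    sqrt(sum((p[1, ] - p[2, ])^2)),
    sqrt(sum((p[1, ] - p[3, ])^2)),
    sqrt(sum((p[2, ] - p[3, ])^2)))
  d_tpl <- pair_d(template$fiducials)
  perms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                  ncol = 3, byrow = TRUE)
  combos <- utils::combn(nrow(cents), 3)
  best <- list(score = Inf); second <- Inf
  for (k in seq_len(ncol(combos))) {
    trip <- cents[combos[, k], , drop = FALSE]
    sc_k <- Inf; perm_k <- NULL
    for (p in seq_len(nrow(perms))) {
      sc <- sum(abs(pair_d(trip[perms[p, ], , drop = FALSE]) - d_tpl)) / sum(d_tpl)
      if (sc < sc_k) { sc_k <- sc; perm_k <- perms[p, ] }
    }
    if (sc_k < best$score) {
      second <- best$score
      best <- list(score = sc_k, points = trip[perm_k, , drop = FALSE])
    } else if (sc_k < second) second <- sc_k
  }
  if (best$score > match_tol)
    stopf("detect_fiducials: no candidate triple matches the template triad (best mismatch %.3f > %.3f)",
          best$score, match_tol)
  if (second <= match_tol && second - best$score < 0.005)
    stopf("detect_fiducials: ambiguous fiducials (two triples match within tolerance)")
  unname(best$points)
}

#' Register a scan to template coordinates
#'
#' Solves the affine map sending the three detected fiducial centroids to the
#' template fiducials. Three non-collinear point correspondences determine an
#' affine map exactly, so the residual (maximum distance between mapped and
#' template fiducials) is zero up to numerical tolerance by construction; it
#' is reported for diagnostics and checked downstream.
#'
#' @param detected 3 x 2 matrix of detected (row, col) centroids in scan
#'   coordinates, ordered like the template fiducials (as returned by
#'   [detect_fiducials()]).
#' @param template the [body_template()].
#' @return an object of class `registration_result`: `affine` (2x3
#'   scan-to-template map), `residual` (px), `detected_fiducials`.
#' @export
register_scan <- function(detected, template) {
  detected <- as.matrix(detected)
  if (!all(dim(detected) == c(3L, 2L)))
    stopf("register_scan: detected must be a 3x2 (row, col) matrix")
  if (abs(triangle_area2(detected)) < 1e-9)
    stopf("register_scan: detected fiducials are collinear")
  A <- affine_from_points(detected, template$fiducials)
  affine_invert(A)  # errors if degenerate
  mapped <- affine_apply(A, detected[, 1], detected[, 2])
  residual <- max(sqrt((mapped$row - template$fiducials[, 1])^2 +
                         (mapped$col - template$fiducials[, 2])^2))
  structure(list(affine = A, residual = residual, detected_fiducials = detected),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("Registration: residual %.2e px; affine scan->template\n", x$residual))
  print(round(x$affine, 4))
  invisible(x)
}

#' Extract pen marks from a registered scan
#'
#' Resamples the scan at every drawable template pixel (nearest-neighbour per
#' sub-pixel sample point, preserving the binary character of pen ink) and
#' decides whether the pixel is a pain mark. A pixel qualifies only when it
#' lies inside the body outline and outside the fiducial exclusion zones
#' (discs of 1.5 times the marker radius — a marker can never be pain).
#'
#' Two decision rules are available. The default `rule = "coverage"`
#' estimates the ink coverage of the pixel from the mean resampled intensity,
#' linearly between `white_level` (blank paper) and `ink_level` (solid pen),
#' and marks the pixel when coverage is at least 1/2; this places the
#' recovered boundary at the 50% ink line and is unbiased under the sub-pixel
#' blur that printing and scanning introduce. `rule = "strict"` marks the
#' pixel when the majority of sub-pixel samples fall below `mark_threshold`
#' (intensity 80 by default: black pen, below 40, is captured while the gray
#' printed outline, around 160, is not); it is the conservative choice for
#' hard-binarized input. Under either rule the gray outline stays unmarked.
#' Isolated single marked pixels are removed as scanner speckle unless
#' `despeckle = FALSE`.
#'
#' @param scan a `scan_image` or numeric intensity matrix.
#' @param registration a [register_scan()] result; refused with a diagnostic
#'   when its residual exceeds `residual_tol`.
#' @param template the [body_template()].
#' @param drawing_id,group_label identity of the resulting drawing.
#' @param mark_threshold intensity below which a sample counts as ink under
#'   `rule = "strict"`.
#' @param rule boundary decision rule, see Details.
#' @param ink_level,white_level reference intensities of solid pen ink and
#'   blank paper for `rule = "coverage"`.
#' @param residual_tol maximum acceptable registration residual (px).
#' @param despeckle drop isolated single marked pixels.
#' @param supersample number of sub-pixel sample points per template pixel
#'   (1, 4 or 5); more points suppress the half-pixel boundary jitter of the
#'   two rasterization rounds.
#' @return a [pain_drawing()] with provenance kind `"scan"`.
#' @export
extract_marks <- function(scan, registration, template,
                          drawing_id = "scan", group_label = "unknown",
                          mark_threshold = 80, rule = c("coverage", "strict"),
                          ink_level = 25, white_level = 250,
                          residual_tol = 2, despeckle = TRUE, supersample = 5) {
  rule <- match.arg(rule)
  stopifnot(inherits(registration, "registration_result"))
  px <- scan_pixels(scan)
  if (registration$residual > residual_tol)
    stopf("extract_marks: registration residual %.2f px exceeds tolerance %.2f px; refusing to extract",
          registration$residual, residual_tol)
  h <- template$height; w <- template$width
  tpl2scan <- affine_invert(registration$affine)
  allowed <- template$outline_mask
  excl <- integer(0)
  for (i in 1:3)
    excl <- c(excl, disc_indices(h, w, template$fiducials[i, 1],
                                 template$fiducials[i, 2],
                                 1.5 * template$fiducial_radius))
  allowed[excl] <- FALSE
  idx <- which(allowed)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  offs <- switch(as.character(supersample),
                 "1" = cbind(0, 0),
                 "4" = cbind(c(-0.25, -0.25, 0.25, 0.25),
                             c(-0.25, 0.25, -0.25, 0.25)),
                 "5" = cbind(c(0, -1, -1, 1, 1) / 3, c(0, -1, 1, -1, 1) / 3),
                 stopf("supersample must be 1, 4 or 5"))
  acc <- numeric(length(idx))
  for (k in seq_len(nrow(offs))) {
    q <- affine_apply(tpl2scan, rr + offs[k, 1], cc + offs[k, 2])
    qr <- round(q$row); qc <- round(q$col)
    inb <- qr >= 1 & qr <= nrow(px) & qc >= 1 & qc <= ncol(px)
    val <- rep(white_level, length(idx))
    val[inb] <- px[(qc[inb] - 1) * nrow(px) + qr[inb]]
    acc <- acc + if (rule == "coverage")
      pmin(pmax((white_level - val) / (white_level - ink_level), 0), 1)
    else as.numeric(val < mark_threshold)
  }
  marked <- acc * 2 >= nrow(offs)
  marks <- matrix(FALSE, h, w)
  marks[idx[marked]] <- TRUE
  if (despeckle) marks <- despeckle_mask(marks)
  if (inherits(scan, "scan_image") && identical(drawing_id, "scan"))
    drawing_id <- scan$drawing_id %||% "scan"
  pain_drawing(drawing_id, template, marks, group_label,
               provenance = list(kind = "scan",
                                 residual = registration$residual))
}

#' Ingest a scanned sheet into a pain drawing
#'
#' Convenience wrapper chaining [detect_fiducials()], [register_scan()] and
#' [extract_marks()].
#'
#' @inheritParams extract_marks
#' @inheritParams detect_fiducials
#' @param verbose log detected fiducials, residual and mark count to stderr.
#' @return a [pain_drawing()]; the `registration_result` is attached as
#'   attribute `"registration"`.
#' @export
ingest_scan <- function(scan, template, drawing_id = "scan",
                        group_label = "unknown", mark_threshold = 80,
                        fiducial_threshold = 80, residual_tol = 2,
                        despeckle = TRUE, verbose = FALSE) {
  det <- detect_fiducials(scan, template, fiducial_threshold = fiducial_threshold)
  reg <- register_scan(det, template)
  d <- extract_marks(scan, reg, template, drawing_id = drawing_id,
                     group_label = group_label, mark_threshold = mark_threshold,
                     residual_tol = residual_tol, despeckle = despeckle)
  if (verbose)
    message(sprintf("ingest: fiducials (%s); residual %.2e px; n_marked %d",
                    paste(sprintf("%.1f,%.1f", det[, 1], det[, 2]), collapse = "; "),
                    reg$residual, d$n_marked))
  attr(d, "registration") <- reg
  d
}
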