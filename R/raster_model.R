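# Core data types: body templates, pain drawings, pain profiles, and their
# file formats (PNG mask + JSON metadata for templates, run-length JSON for
# pain extents).

#' Body-outline template
#'
#' A `body_template` describes the raster domain every pain drawing lives on:
#' the drawable region (a binary human-body-outline mask), three fiducial
#' markers used to register scanned sheets, and the layout of the frontal and
#' dorsal views on the sheet. Frontal and dorsal views share one raster (one
#' A4 sheet); all statistics treat the sheet as a single pixel domain.
#'
#' @param template_id character scalar identifying the template.
#' @param outline_mask logical matrix; `TRUE` marks pixels inside a body
#'   outline, i.e. drawable.
#' @param fiducials numeric 3 x 2 matrix of (row, col) marker centres in
#'   template coordinates (1-based). Markers must lie outside the outline and
#'   must not be collinear.
#' @param sex_label one of `"female"`, `"sexless"`, `"other"`.
#' @param views named list with elements `frontal` and `dorsal`, each an
#'   integer vector `c(r0, c0, r1, c1)` giving a 1-based inclusive rectangle.
#'   The two extents must be disjoint.
#' @param fiducial_radius marker disc radius in pixels (used for rendering and
#'   for the exclusion zone during mark extraction).
#' @param regions optional named list of 1-based inclusive rectangles naming
#'   anatomical sub-regions (e.g. `abdomen`, `back`, `legs`) used by the
#'   synthetic cohort generator.
#' @return an object of class `body_template`.
#' @seealso [make_template()] for a parametric synthetic template,
#'   [load_template()] / [write_template()] for file I/O.
#' @export
body_template <- function(template_id, outline_mask, fiducials,
                          sex_label = c("female", "sexless", "other"),
                          views, fiducial_radius = 10, regions = list()) {
  sex_label <- match.arg(sex_label)
  if (!is.logical(outline_mask) || !is.matrix(outline_mask))
    stopf("outline_mask must be a logical matrix")
  fiducials <- as.matrix(fiducials)
  tpl <- structure(
    list(template_id = as.character(template_id),
         width = ncol(outline_mask), height = nrow(outline_mask),
         outline_mask = outline_mask, fiducials = fiducials,
         sex_label = sex_label, views = views,
         fiducial_radius = as.numeric(fiducial_radius), regions = regions),
    class = "body_template")
  validate_template(tpl)
}

#' @noRd
validate_template <- function(tpl) {
  m <- tpl$outline_mask
  if (!any(m)) stopf("template '%s': outline mask is empty", tpl$template_id)
  f <- tpl$fiducials
  if (!is.matrix(f) || nrow(f) != 3L || ncol(f) != 2L)
    stopf("template '%s': exactly 3 fiducials (row, col) are required, got %s",
          tpl$template_id, paste(dim(f), collapse = "x"))
  if (abs(triangle_area2(f)) <= 1e-9)
    stopf("template '%s': fiducials are collinear", tpl$template_id)
  ri <- round(f[, 1]); ci <- round(f[, 2])
  if (any(ri < 1 | ri > tpl$height | ci < 1 | ci > tpl$width))
    stopf("template '%s': fiducial outside raster bounds", tpl$template_id)
  if (any(m[cbind(ri, ci)]))
    stopf("template '%s': fiducial lies inside the body outline", tpl$template_id)
  v <- tpl$views
  if (!all(c("frontal", "dorsal") %in% names(v)))
    stopf("template '%s': views must name 'frontal' and 'dorsal'", tpl$template_id)
  if (rects_overlap(v$frontal, v$dorsal))
    stopf("template '%s': frontal and dorsal extents overlap", tpl$template_id)
  tpl
}

#' @noRd
rects_overlap <- function(a, b) {
  a[1] <= b[3] && b[1] <= a[3] && a[2] <= b[4] && b[2] <= a[4]
}

#' @export
print.body_template <- function(x, ...) {
  cat(sprintf("Body template '%s' (%s): %d x %d px, %d drawable px (%.1f%%)\n",
              x$template_id, x$sex_label, x$height, x$width,
              sum(x$outline_mask), 100 * mean(x$outline_mask)))
  cat(sprintf("  fiducials at (%s), radius %.0f px\n",
              paste(sprintf("%.0f,%.0f", x$fiducials[, 1], x$fiducials[, 2]),
                    collapse = "), ("), x$fiducial_radius))
  invisible(x)
}

#' Pain drawing
#'
#' A `pain_drawing` is one subject's binary raster of marked (painful) pixels,
#' tied to a [body_template()]. Every marked pixel must lie inside the
#' template's drawable outline; with `clip = TRUE` outside marks are removed
#' with a warning instead of raising an error (the behaviour used when reading
#' files and ingesting scans). Drawings with no marked pixel are legal but
#' flagged via `is_empty`; they take part in profiles and pixel counts.
#'
#' @param drawing_id character scalar, e.g. `"F_21"` (group letter + number).
#' @param template a [body_template()].
#' @param marks logical matrix with the template's dimensions.
#' @param group_label character scalar naming the subject's group.
#' @param provenance list describing where the drawing came from; element
#'   `kind` is one of `"scan"`, `"json"`, `"synthetic"`.
#' @param clip drop marks outside the outline (with a warning) instead of
#'   raising an error.
#' @return an object of class `pain_drawing`.
#' @export
pain_drawing <- function(drawing_id, template, marks, group_label,
                         provenance = list(kind = "synthetic"), clip = FALSE) {
  stopifnot(inherits(template, "body_template"))
  if (!is.logical(marks) || !identical(dim(marks), dim(template$outline_mask)))
    stopf("marks must be a logical matrix with the template's dimensions")
  outside <- marks & !template$outline_mask
  n_out <- sum(outside)
  if (n_out > 0L) {
    if (!clip)
      stopf("drawing '%s': %d marked pixel(s) outside the body outline",
            drawing_id, n_out)
    warnf("drawing '%s': clipped %d marked pixel(s) outside the body outline",
          drawing_id, n_out)
    marks <- marks & template$outline_mask
  }
  structure(
    list(drawing_id = as.character(drawing_id),
         template_id = template$template_id,
         group_label = as.character(group_label),
         marks = marks, n_marked = sum(marks),
         is_empty = !any(marks), provenance = provenance),
    class = "pain_drawing")
}

#' @export
print.pain_drawing <- function(x, ...) {
  cat(sprintf("Pain drawing '%s' (group %s, template %s): %d marked px%s [%s]\n",
              x$drawing_id, x$group_label, x$template_id, x$n_marked,
              if (x$is_empty) " (EMPTY)" else "", x$provenance$kind %||% "?"))
  invisible(x)
}

# --- run-length encoding ---------------------------------------------------

# Encode a logical matrix as per-row runs, 0-based, rows top-down and runs
# left-to-right. Returns a data.frame(row, col, len).
#' @noRd
marks_to_runs <- function(marks) {
  idx <- which(t(marks))  # row-major order
  if (length(idx) == 0L)
    return(data.frame(row = integer(0), col = integer(0), len = integer(0)))
  w <- ncol(marks)
  r <- (idx - 1L) %/% w
  c0 <- (idx - 1L) %% w
  brk <- c(TRUE, diff(idx) != 1L | diff(r) != 0L)
  starts <- which(brk)
  lens <- diff(c(starts, length(idx) + 1L))
  data.frame(row = r[starts], col = c0[starts], len = as.integer(lens))
}

#' @noRd
runs_to_marks <- function(runs, height, width) {
  marks <- matrix(FALSE, height, width)
  if (nrow(runs) == 0L) return(marks)
  if (any(runs$len < 1L)) stopf("malformed run: length < 1")
  if (any(runs$row < 0L | runs$row >= height))
    stopf("malformed run: row outside raster bounds")
  if (any(runs$col < 0L | runs$col + runs$len > width))
    stopf("malformed run: extends past raster bounds")
  for (i in seq_len(nrow(runs))) {
    cc <- runs$col[i] + seq_len(runs$len[i])  # 0-based col + 1..len -> 1-based
    marks[runs$row[i] + 1L, cc] <- TRUE
  }
  marks
}

#' Write a pain drawing to a pain-extent JSON file
#'
#' Serializes the marked pixels as per-row run-length encoding under the
#' `paindraw-extent-1` schema. Coordinates in the file are 0-based with the
#' origin at the top-left. Output is deterministic: keys are emitted in sorted
#' order and integers are written without decoration, so two writes of the
#' same drawing are byte-identical.
#'
#' @param drawing a [pain_drawing()].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @seealso [read_pain_json()]
#' @export
write_pain_json <- function(drawing, path) {
  stopifnot(inherits(drawing, "pain_drawing"))
  runs <- marks_to_runs(drawing$marks)
  run_list <- lapply(seq_len(nrow(runs)), function(i)
    list(col = runs$col[i], len = runs$len[i], row = runs$row[i]))
  obj <- list(
    drawing_id = drawing$drawing_id,
    group_label = drawing$group_label,
    height = nrow(drawing$marks),
    n_marked = drawing$n_marked,
    runs = run_list,
    schema = "paindraw-extent-1",
    template_id = drawing$template_id,
    width = ncol(drawing$marks))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a pain drawing from a pain-extent JSON file
#'
#' Reconstructs the binary marks raster from its run-length encoding and
#' validates it against the template: the schema tag and template id must
#' match, runs must stay inside the raster, and any marked pixel outside the
#' body outline is dropped with a warning (the clipping contract).
#'
#' @param path path to a file written by [write_pain_json()].
#' @param template the [body_template()] the drawing belongs to.
#' @return a [pain_drawing()] with provenance kind `"json"`.
#' @export
read_pain_json <- function(path, template) {
  stopifnot(inherits(template, "body_template"))
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!identical(obj$schema, "paindraw-extent-1"))
    stopf("'%s': not a paindraw-extent-1 file", path)
  if (!identical(obj$template_id, template$template_id))
    stopf("'%s': template mismatch (file '%s', expected '%s')",
          path, obj$template_id, template$template_id)
  if (obj$height != template$height || obj$width != template$width)
    stopf("'%s': raster size %dx%d does not match template %dx%d",
          path, obj$height, obj$width, template$height, template$width)
  runs <- if (length(obj$runs) == 0L)
    data.frame(row = integer(0), col = integer(0), len = integer(0))
  else as.data.frame(obj$runs)
  marks <- runs_to_marks(runs, obj$height, obj$width)
  if (!is.null(obj$n_marked) && obj$n_marked != sum(marks))
    warnf("'%s': n_marked field (%d) disagrees with runs (%d)",
          path, obj$n_marked, sum(marks))
  pain_drawing(obj$drawing_id, template, marks, obj$group_label,
               provenance = list(kind = "json", source = path), clip = TRUE)
}

# --- template I/O ----------------------------------------------------------

#' Write a template to disk as a PNG mask plus JSON metadata
#'
#' The mask is an 8-bit grayscale PNG (0 = outside, 255 = inside the body
#' outline); the metadata JSON stores the template id, sex label, fiducials
#' and view extents using 0-based coordinates and half-open rectangles.
#'
#' @param template a [body_template()].
#' @param mask_png,meta_json output file paths.
#' @return `meta_json`, invisibly.
#' @export
write_template <- function(template, mask_png, meta_json) {
  stopifnot(inherits(template, "body_template"))
  png::writePNG(template$outline_mask * 1, mask_png)
  rect_out <- function(r) c(r[1] - 1L, r[2] - 1L, r[3], r[4])  # to 0-based half-open
  meta <- list(
    template_id = template$template_id,
    sex_label = template$sex_label,
    fiducials = unname(lapply(seq_len(3), function(i)
      c(template$fiducials[i, 1] - 1, template$fiducials[i, 2] - 1))),
    fiducial_radius = template$fiducial_radius,
    views = lapply(template$views, rect_out),
    regions = lapply(template$regions, rect_out))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), meta_json)
  invisible(meta_json)
}

#' Load a template from a PNG mask and JSON metadata
#'
#' @param mask_png single-channel 8-bit PNG, 0 = outside, nonzero = inside.
#' @param meta_json metadata file as written by [write_template()].
#' @return a validated [body_template()].
#' @export
load_template <- function(mask_png, meta_json) {
  if (!file.exists(mask_png)) stopf("template mask not found: %s", mask_png)
  if (!file.exists(meta_json)) stopf("template metadata not found: %s", meta_json)
  img <- png::readPNG(mask_png)
  if (length(dim(img)) != 2L)
    stopf("'%s': template mask must be single-channel grayscale", mask_png)
  mask <- img > 0.5
  meta <- jsonlite::fromJSON(meta_json)
  fid <- meta$fiducials
  if (is.list(fid)) fid <- do.call(rbind, fid)
  fid <- as.matrix(fid)
  if (is.null(fid) || nrow(fid) != 3L || ncol(fid) != 2L)
    stopf("'%s': exactly 3 fiducials are required", meta_json)
  rect_in <- function(r) c(r[1] + 1L, r[2] + 1L, r[3], r[4])  # to 1-based inclusive
  body_template(meta$template_id, mask, fid + 1,
                sex_label = meta$sex_label,
                views = lapply(meta$views, rect_in),
                fiducial_radius = meta$fiducial_radius %||% 10,
                regions = lapply(meta$regions %||% list(), rect_in))
}
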