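# Fixtures built in code: a hand-sized template whose geometry is easy to
# reason about, plus small drawing constructors.

# 24 x 20 template: a 14 x 10 rectangular "body" (rows 7..20, cols 6..15)
# with corner fiducials well outside it. Frontal = left half of the sheet,
# dorsal = right half; the body straddles both so each view owns part of it.
tiny_template <- function() {
  mask <- matrix(FALSE, 24, 20)
  mask[7:20, 6:15] <- TRUE
  body_template(
    "tiny", mask,
    fiducials = rbind(c(2, 2), c(2, 19), c(22, 2)),
    sex_label = "other",
    views = list(frontal = c(1L, 1L, 24L, 10L), dorsal = c(1L, 11L, 24L, 20L)),
    fiducial_radius = 1,
    regions = list(left = c(7L, 6L, 20L, 10L), right = c(7L, 11L, 20L, 15L)))
}

# drawing from explicit (row, col) mark positions
tiny_drawing <- function(template, pts, id = "T_1", group = "g") {
  marks <- matrix(FALSE, template$height, template$width)
  if (length(pts)) marks[do.call(rbind, pts)] <- TRUE
  pain_drawing(id, template, marks, group)
}

# random drawing: each drawable pixel marked independently with prob p
rand_drawing <- function(template, p = 0.3, id = "R_1", group = "g") {
  marks <- matrix(FALSE, template$height, template$width)
  inside <- which(template$outline_mask)
  marks[inside[stats::runif(length(inside)) < p]] <- TRUE
  pain_drawing(id, template, marks, group)
}

# reduced-resolution study template + matching cohort configuration, for
# simulation-heavy tests; scale = linear fraction of the 150 dpi default
small_study_template <- function(sex = "sexless", scale = 0.2) {
  make_template(sex, round(1240 * scale), round(1754 * scale))
}

small_cohort_config <- function(scale = 0.2, ...) {
  cohort_config(area_scale = scale^2,
                pen_radius = max(1L, as.integer(round(2 * scale))),
                min_blob_area = max(4L, as.integer(round(150 * scale^2))),
                ...)
}

# independent brute-force Ruzicka: direct translation of the definition
brute_ruzicka <- function(x, y) {
  s_min <- 0; s_max <- 0
  for (i in seq_along(x)) {
    s_min <- s_min + min(x[i], y[i])
    s_max <- s_max + max(x[i], y[i])
  }
  if (s_max == 0) 1 else s_min / s_max
}
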