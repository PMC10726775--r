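# Pain profiles, the Ruzicka similarity index, pairwise similarity matrices
# and their within/between-group summaries.

#' Ruzicka similarity index
#'
#' \eqn{RZI(x, y) = \sum_i \min(x_i, y_i) / \sum_i \max(x_i, y_i)} for
#' nonnegative vectors or rasters of identical shape: 0 means disjoint
#' support, 1 means identical. On binary inputs this reduces to the Jaccard
#' index \eqn{|x \cap y| / |x \cup y|}; on pain profiles (per-pixel marking
#' proportions) it is its weighted generalization, comparing only where at
#' least one side marked rather than over all pixels.
#'
#' If both inputs are all-zero the index is defined here as 1 (two empty
#' drawings are identical), with a warning; this keeps the permutation test
#' total on degenerate cohorts.
#'
#' @param x,y nonnegative numeric (or logical) vectors/matrices, same shape.
#' @return a number in \[0, 1\].
#' @export
ruzicka <- function(x, y) {
  if (!identical(dim(x) %||% length(x), dim(y) %||% length(y)))
    stopf("ruzicka: inputs must have identical shape")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("ruzicka: inputs must have identical shape")
  if (anyNA(x) || anyNA(y)) stopf("ruzicka: inputs must not contain NA")
  if (any(x < 0) || any(y < 0)) stopf("ruzicka: inputs must be nonnegative")
  smax <- sum(pmax(x, y))
  if (smax == 0) {
    warnf("ruzicka: both inputs are all-zero; returning 1 by convention")
    return(1)
  }
  sum(pmin(x, y)) / smax
}

#' Group pain profile
#'
#' For a set of pain drawings sharing one template, the profile records for
#' each pixel the proportion of drawings in which that pixel was marked.
#' Values are `k/n` with integer `k`, 0 outside the body outline.
#'
#' @param drawings non-empty list of [pain_drawing()] objects on one template.
#' @return an object of class `pain_profile` with fields `template_id`,
#'   `proportions` (numeric matrix in \[0, 1\]) and `n` (group size).
#' @export
build_profile <- function(drawings) {
  if (length(drawings) == 0L) stopf("build_profile: empty drawing set")
  stopifnot(all(vapply(drawings, inherits, logical(1), "pain_drawing")))
  tid <- unique(vapply(drawings, function(d) d$template_id, character(1)))
  if (length(tid) != 1L)
    stopf("build_profile: drawings mix templates (%s)", paste(tid, collapse = ", "))
  n <- length(drawings)
  counts <- Reduce(`+`, lapply(drawings, function(d) d$marks * 1L))
  structure(list(template_id = tid, proportions = counts / n, n = n),
            class = "pain_profile")
}

#' @export
print.pain_profile <- function(x, ...) {
  nz <- sum(x$proportions > 0)
  cat(sprintf("Pain profile (template %s, n = %d): %d pixels marked by >=1 drawing, max proportion %.3f\n",
              x$template_id, x$n, nz, if (nz) max(x$proportions) else 0))
  invisible(x)
}

#' Pairwise Ruzicka similarity matrix of a cohort
#'
#' Computes the RZI between the binary marks of every pair of drawings. Rows
#' and columns are ordered as one group block then the other, so the matrix
#' quadrants correspond to within-group (diagonal blocks) and between-group
#' (off-diagonal blocks) pairs.
#'
#' @param drawings list of [pain_drawing()] on one template (at least 2).
#' @param groups optional character vector of length 2 fixing the group block
#'   order; defaults to order of first appearance.
#' @return an object of class `rzi_matrix`: list with `values` (symmetric
#'   numeric matrix with drawing ids as dimnames), `drawing_ids`,
#'   `group_labels`.
#' @export
pairwise_similarity <- function(drawings, groups = NULL) {
  if (length(drawings) < 2L) stopf("pairwise_similarity: need at least 2 drawings")
  if (length(unique(lapply(drawings, function(d) dim(d$marks)))) != 1L)
    stopf("pairwise_similarity: drawings mix raster sizes")
  labs <- vapply(drawings, function(d) d$group_label, character(1))
  if (is.null(groups)) groups <- unique(labs)
  ord <- order(match(labs, groups))
  drawings <- drawings[ord]; labs <- labs[ord]
  ids <- vapply(drawings, function(d) d$drawing_id, character(1))
  n <- length(drawings)
  # binary rasters: RZI reduces to Jaccard on the mark index sets, computed
  # set-wise rather than over the full raster
  sets <- lapply(drawings, function(d) which(d$marks))
  sizes <- lengths(sets)
  v <- diag(1, n)
  n_empty_pairs <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    inter <- sum(duplicated(c(sets[[i]], sets[[j]])))
    uni <- sizes[i] + sizes[j] - inter
    r <- if (uni == 0L) { n_empty_pairs <- n_empty_pairs + 1L; 1 } else inter / uni
    v[i, j] <- v[j, i] <- r
  }
  if (n_empty_pairs > 0L)
    warnf("pairwise_similarity: %d pair(s) of empty drawings scored 1 by convention",
          n_empty_pairs)
  dimnames(v) <- list(ids, ids)
  structure(list(values = v, drawing_ids = ids, group_labels = labs),
            class = "rzi_matrix")
}

#' @export
print.rzi_matrix <- function(x, ...) {
  off <- x$values[lower.tri(x$values)]
  cat(sprintf("Pairwise RZI matrix: %d drawings (%s); off-diagonal RZI %.3f-%.3f, median %.3f\n",
              length(x$drawing_ids),
              paste(sprintf("%s n=%d", names(table(x$group_labels)),
                            as.integer(table(x$group_labels))), collapse = ", "),
              min(off), max(off), stats::median(off)))
  invisible(x)
}

#' Within- and between-group similarity summaries
#'
#' Splits the off-diagonal pairwise RZI values into the three pair classes —
#' within the first group, within the second group, and between groups — and
#' reports min, max, mean, median and sample SD for each (each unordered pair
#' counted once). A group with fewer than 2 members has no within-group pairs;
#' its statistics are reported as `NA`.
#'
#' @param m an [pairwise_similarity()] result.
#' @return an object of class `rzi_group_summary`: list with `stats` (one row
#'   per pair class) and `values` (the underlying RZI value sets).
#' @export
summarize_groups <- function(m) {
  stopifnot(inherits(m, "rzi_matrix"))
  groups <- unique(m$group_labels)
  if (length(groups) != 2L)
    stopf("summarize_groups: exactly 2 group labels required, got %d", length(groups))
  v <- m$values
  idx_a <- which(m$group_labels == groups[1])
  idx_b <- which(m$group_labels == groups[2])
  pick_within <- function(idx) {
    if (length(idx) < 2L) return(NULL)
    sub <- v[idx, idx, drop = FALSE]
    sub[lower.tri(sub)]
  }
  vals <- list(
    within_a = pick_within(idx_a),
    within_b = pick_within(idx_b),
    between = as.vector(v[idx_a, idx_b, drop = FALSE]))
  names(vals) <- c(paste0("within_", groups[1]), paste0("within_", groups[2]),
                   "between")
  stat_row <- function(x) {
    if (is.null(x) || length(x) == 0L)
      return(data.frame(n_pairs = 0L, min = NA_real_, max = NA_real_,
                        mean = NA_real_, median = NA_real_, sd = NA_real_))
    data.frame(n_pairs = length(x), min = min(x), max = max(x),
               mean = mean(x), median = stats::median(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_)
  }
  stats_df <- do.call(rbind, lapply(vals, stat_row))
  stats_df <- cbind(pair_class = names(vals), stats_df)
  rownames(stats_df) <- NULL
  structure(list(stats = stats_df, values = vals, groups = groups),
            class = "rzi_group_summary")
}

#' @export
print.rzi_group_summary <- function(x, ...) {
  cat("Pairwise RZI by pair class:\n")
  df <- x$stats
  df[-1] <- lapply(df[-1], function(v) if (is.numeric(v)) round(v, 3) else v)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export a similarity heatmap
#'
#' Renders the pairwise matrix as a log10-scaled heatmap (zeros floored at
#' 1e-3 before taking logs), rows/columns in group-block order with the first
#' group's block in the top-left quadrant, as in the standard nearest-neighbour
#' display of pain-drawing cohorts.
#'
#' @param m an [pairwise_similarity()] result.
#' @param path output PNG path.
#' @param floor lower clamp applied before the log transform.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(m, path, floor = 1e-3) {
  stopifnot(inherits(m, "rzi_matrix"))
  v <- log10(pmax(m$values, floor))
  n <- nrow(v)
  grDevices::png(path, width = 800, height = 800)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  # flip rows so drawing 1 appears in the top-left corner
  graphics::image(seq_len(n), seq_len(n), t(v[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "drawing", ylab = "drawing", axes = FALSE,
                  main = "Pairwise RZI (log10, floored at 1e-3)")
  graphics::axis(1, at = seq_len(n), labels = m$drawing_ids, las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(m$drawing_ids), las = 2, cex.axis = 0.6)
  n_a <- sum(m$group_labels == m$group_labels[1])
  graphics::abline(v = n_a + 0.5, h = n - n_a + 0.5, lwd = 2)
  invisible(path)
}

#' Export pair-class boxplots
#'
#' Boxplots of the RZI value sets for the three pair classes produced by
#' [summarize_groups()].
#'
#' @param summary an `rzi_group_summary`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
export_boxplots <- function(summary, path) {
  stopifnot(inherits(summary, "rzi_group_summary"))
  vals <- summary$values[!vapply(summary$values, is.null, logical(1))]
  grDevices::png(path, width = 600, height = 500)
  on.exit(grDevices::dev.off())
  graphics::boxplot(vals, ylab = "Ruzicka similarity index", las = 1,
                    main = "Pairwise RZI by pair class")
  invisible(path)
}
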