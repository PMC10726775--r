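test_that("ruzicka matches hand-evaluated and brute-force values", {
  # sum(min)/sum(max) = (0.5 + 0 + 0.5) / (1 + 0 + 1)
  expect_equal(ruzicka(c(1, 0, 0.5), c(0.5, 0, 1)), 0.5)
  expect_equal(ruzicka(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ruzicka(c(1, 0), c(0, 2)), 0)
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:20, 1)
    x <- stats::runif(n, 0, 2) * stats::rbinom(n, 1, 0.7)
    y <- stats::runif(n, 0, 2) * stats::rbinom(n, 1, 0.7)
    expect_equal(ruzicka(x, y), brute_ruzicka(x, y), tolerance = 1e-12)
  }
})

test_that("ruzicka reduces to the Jaccard index on binary inputs", {
  set.seed(12)
  for (i in 1:50) {
    x <- stats::rbinom(25, 1, 0.4)
    y <- stats::rbinom(25, 1, 0.4)
    if (sum(x | y) == 0) next
    jaccard <- sum(x & y) / sum(x | y)
    expect_identical(ruzicka(x, y), jaccard)
  }
})

test_that("ruzicka is symmetric, bounded, and monotone under mark edits", {
  set.seed(13)
  for (i in 1:30) {
    n <- 30
    x <- stats::runif(n) * stats::rbinom(n, 1, 0.5)
    y <- stats::runif(n) * stats::rbinom(n, 1, 0.5)
    r <- ruzicka(x, y)
    expect_identical(r, ruzicka(y, x))
    expect_gte(r, 0); expect_lte(r, 1)
    # adding a commonly-marked pixel never decreases similarity
    z <- stats::runif(1, 0.1, 1)
    expect_gte(ruzicka(c(x, z), c(y, z)), r - 1e-12)
    # adding a one-sided pixel never increases it
    expect_lte(ruzicka(c(x, z), c(y, 0)), r + 1e-12)
  }
})

test_that("two all-zero inputs give RZI 1 with a warning; invalid input errors", {
  expect_warning(r <- ruzicka(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(r, 1)
  expect_error(ruzicka(c(-1, 0), c(0, 0)), "nonnegative")
  expect_error(ruzicka(c(1, 2), c(1, 2, 3)), "shape")
  expect_error(ruzicka(matrix(1, 2, 2), matrix(1, 4, 1)), "shape")
})

test_that("build_profile computes per-pixel marking proportions", {
  tpl <- tiny_template()
  d1 <- tiny_drawing(tpl, list(c(8, 7), c(8, 8)), id = "a")
  d2 <- tiny_drawing(tpl, list(c(8, 7), c(10, 10)), id = "b")
  # n = 1: the profile is the drawing's 0/1 raster
  p1 <- build_profile(list(d1))
  expect_identical(p1$proportions, d1$marks * 1 / 1)
  expect_equal(p1$n, 1)
  # a pixel marked by exactly one of two drawings has proportion 0.5
  p <- build_profile(list(d1, d2))
  expect_equal(p$proportions[8, 7], 1)
  expect_equal(p$proportions[8, 8], 0.5)
  expect_equal(p$proportions[10, 10], 0.5)
  # idempotence: n identical drawings reproduce the drawing
  pn <- build_profile(list(d1, d1, d1))
  expect_identical(pn$proportions, d1$marks * 1)
  # mass conservation: sum(proportions) * n = total marks
  expect_equal(sum(p$proportions) * p$n, d1$n_marked + d2$n_marked)
})

test_that("build_profile rejects empty sets and mixed templates", {
  tpl <- tiny_template()
  tpl2 <- tiny_template(); tpl2$template_id <- "tiny2"
  d1 <- tiny_drawing(tpl, list(c(8, 7)))
  d2 <- tiny_drawing(tpl2, list(c(8, 7)))
  expect_error(build_profile(list()), "empty")
  expect_error(build_profile(list(d1, d2)), "mix templates")
})

test_that("pairwise similarity matches a brute-force per-pixel oracle", {
  tpl <- tiny_template()
  set.seed(21)
  drawings <- c(
    lapply(1:4, function(i) rand_drawing(tpl, 0.3, sprintf("A_%d", i), "ga")),
    lapply(1:3, function(i) rand_drawing(tpl, 0.3, sprintf("B_%d", i), "gb")))
  m <- pairwise_similarity(drawings, groups = c("ga", "gb"))
  expect_true(isSymmetric(m$values))
  expect_identical(m$drawing_ids, c(paste0("A_", 1:4), paste0("B_", 1:3)))
  for (i in 1:7) for (j in 1:7) {
    expect_equal(m$values[i, j],
                 brute_ruzicka(as.numeric(drawings[[i]]$marks),
                               as.numeric(drawings[[j]]$marks)),
                 tolerance = 1e-12)
  }
})

test_that("pairwise similarity handles identical and disjoint cohorts", {
  tpl <- tiny_template()
  d <- tiny_drawing(tpl, list(c(8, 7), c(8, 8)))
  same <- lapply(1:3, function(i) tiny_drawing(tpl, list(c(8, 7), c(8, 8)),
                                               sprintf("S_%d", i)))
  m <- pairwise_similarity(same)
  expect_true(all(m$values == 1))
  dis <- list(tiny_drawing(tpl, list(c(8, 7)), "D_1"),
              tiny_drawing(tpl, list(c(12, 12)), "D_2"))
  m2 <- pairwise_similarity(dis)
  expect_equal(m2$values[1, 2], 0)
  expect_equal(diag(m2$values), c(1, 1), ignore_attr = TRUE)
})

test_that("group summaries split pairs into the three classes correctly", {
  tpl <- tiny_template()
  a_pts <- list(c(8, 7), c(8, 8))
  b_pts <- list(c(15, 12), c(15, 13))
  drawings <- c(
    lapply(1:3, function(i) tiny_drawing(tpl, a_pts, sprintf("A_%d", i), "ga")),
    lapply(1:4, function(i) tiny_drawing(tpl, b_pts, sprintf("B_%d", i), "gb")))
  s <- summarize_groups(pairwise_similarity(drawings, groups = c("ga", "gb")))
  st <- s$stats
  expect_equal(st$n_pairs, c(3 * 2 / 2, 4 * 3 / 2, 3 * 4))
  expect_equal(st$mean[st$pair_class == "within_ga"], 1)
  expect_equal(st$mean[st$pair_class == "within_gb"], 1)
  expect_equal(st$mean[st$pair_class == "between"], 0)
})

test_that("duplicating one cohort into both groups gives identical class value sets", {
  tpl <- tiny_template()
  set.seed(31)
  base <- lapply(1:4, function(i) rand_drawing(tpl, 0.3, sprintf("X_%d", i)))
  dup <- c(
    lapply(seq_along(base), function(i)
      pain_drawing(sprintf("P_%d", i), tpl, base[[i]]$marks, "g1")),
    lapply(seq_along(base), function(i)
      pain_drawing(sprintf("Q_%d", i), tpl, base[[i]]$marks, "g2")))
  s <- summarize_groups(pairwise_similarity(dup, groups = c("g1", "g2")))
  expect_equal(sort(s$values$within_g1), sort(s$values$within_g2))
  # between-class values contain each within-class value (pairs i != j) plus
  # the self-pairs (RZI 1)
  expect_true(all(s$values$within_g1 %in% s$values$between))
})

test_that("group summaries match brute-force recomputation on a random cohort", {
  tpl <- tiny_template()
  set.seed(41)
  drawings <- c(
    lapply(1:4, function(i) rand_drawing(tpl, 0.4, sprintf("A_%d", i), "ga")),
    lapply(1:3, function(i) rand_drawing(tpl, 0.4, sprintf("B_%d", i), "gb")))
  m <- pairwise_similarity(drawings, groups = c("ga", "gb"))
  s <- summarize_groups(m)
  rz <- function(i, j) brute_ruzicka(as.numeric(drawings[[i]]$marks),
                                     as.numeric(drawings[[j]]$marks))
  within_a <- unlist(lapply(1:3, function(i)
    lapply((i + 1):4, function(j) rz(i, j))))
  between <- unlist(lapply(1:4, function(i) lapply(5:7, function(j) rz(i, j))))
  st <- s$stats
  expect_equal(st$mean[1], mean(within_a))
  expect_equal(st$sd[1], stats::sd(within_a))
  expect_equal(st$median[3], stats::median(between))
  expect_equal(sort(s$values$between), sort(between))
})

test_that("a group with fewer than 2 members reports missing within-group stats", {
  tpl <- tiny_template()
  drawings <- list(tiny_drawing(tpl, list(c(8, 7)), "A_1", "ga"),
                   tiny_drawing(tpl, list(c(8, 8)), "B_1", "gb"),
                   tiny_drawing(tpl, list(c(9, 8)), "B_2", "gb"))
  s <- summarize_groups(pairwise_similarity(drawings, groups = c("ga", "gb")))
  expect_equal(s$stats$n_pairs[1], 0)
  expect_true(is.na(s$stats$mean[1]))
  expect_equal(s$stats$n_pairs[2], 1)
})

test_that("heatmap and boxplot export produce files, including degenerate inputs", {
  tpl <- tiny_template()
  same <- lapply(1:2, function(i) tiny_drawing(tpl, list(c(8, 7)),
                                               sprintf("S_%d", i), "ga"))
  dis <- lapply(1:2, function(i) tiny_drawing(tpl, list(c(12 + i, 12)),
                                              sprintf("D_%d", i), "gb"))
  m <- pairwise_similarity(c(same, dis), groups = c("ga", "gb"))
  expect_true(any(m$values == 0))  # zero entries must render at the floor
  hm <- withr::local_tempfile(fileext = ".png")
  bp <- withr::local_tempfile(fileext = ".png")
  export_heatmap(m, hm)
  export_boxplots(summarize_groups(m), bp)
  expect_gt(file.size(hm), 0)
  expect_gt(file.size(bp), 0)
})
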