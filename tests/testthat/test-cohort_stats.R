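test_that("Fisher exact reproduces published odds ratios and exact CIs to 3 decimals", {
  # outline-suitability question: rows sexless/female, cols yes/no
  q1 <- fisher_exact_2x2(contingency_table(rbind(c(21, 2), c(22, 3)),
                                           c("sexless", "female"), c("yes", "no")))
  expect_equal(round(q1$odds_ratio, 3), 1.421)
  expect_equal(round(q1$ci, 3), c(0.147, 18.613))
  expect_equal(q1$p_value, 1, tolerance = 1e-6)
  # perceived-sexlessness question
  q2 <- fisher_exact_2x2(contingency_table(rbind(c(14, 8), c(9, 16)),
                                           c("sexless", "female"), c("yes", "no")))
  expect_equal(round(q2$odds_ratio, 3), 3.033)
  expect_equal(round(q2$ci, 3), c(0.815, 12.151))
  expect_equal(round(q2$p_value, 3), 0.082)
  # importance question (no-opinion dropped), rows female/sexless
  q4 <- fisher_exact_2x2(contingency_table(rbind(c(11, 9), c(14, 9)),
                                           c("female", "sexless"),
                                           c("important", "unimportant")))
  expect_equal(round(q4$odds_ratio, 3), 0.790)
  expect_equal(round(q4$ci, 3), c(0.197, 3.130))
  expect_equal(round(q4$p_value, 3), 0.763)
})

test_that("Fisher exact respects table-symmetry invariances", {
  set.seed(71)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 8) + 1, 2, 2)
    base <- fisher_exact_2x2(tab)
    # simultaneous row and column swap leaves everything unchanged
    both <- fisher_exact_2x2(tab[2:1, 2:1])
    expect_equal(both$odds_ratio, base$odds_ratio, tolerance = 1e-9)
    expect_equal(both$ci, base$ci, tolerance = 1e-9)
    expect_equal(both$p_value, base$p_value, tolerance = 1e-12)
    # row swap inverts the odds ratio and mirrors the CI
    rows <- fisher_exact_2x2(tab[2:1, ])
    expect_equal(rows$odds_ratio, 1 / base$odds_ratio, tolerance = 1e-9)
    expect_equal(rows$ci, rev(1 / base$ci), tolerance = 1e-9)
    expect_equal(rows$p_value, base$p_value, tolerance = 1e-12)
  }
})

test_that("Fisher exact handles no-association and degenerate tables", {
  same <- fisher_exact_2x2(rbind(c(7, 3), c(7, 3)))
  expect_equal(same$p_value, 1)
  expect_equal(same$odds_ratio, 1, tolerance = 0.05)
  degen <- fisher_exact_2x2(rbind(c(0, 0), c(5, 3)))
  expect_equal(degen$p_value, 1)
  expect_true(is.na(degen$odds_ratio))
  expect_error(fisher_exact_2x2(rbind(c(1, 2, 3), c(4, 5, 6))), "2x2")
})

test_that("chi-squared on the sex-recognition feature table reproduces the published p", {
  q3 <- contingency_table(
    rbind(c(6, 5, 5, 5, 6, 5, 10, 14, 3), c(3, 2, 0, 2, 2, 0, 8, 12, 1)),
    c("sexless", "female"),
    c("head", "shoulders", "arms", "legs", "buttocks", "abdomen",
      "waist", "chest", "feet"))
  expect_warning(res <- chi_squared_table(q3), "expected cell")
  expect_equal(res$df, 8)
  expect_equal(round(res$p_value, 4), 0.3964)
})

test_that("chi-squared handles identical rows, hand oracle, and zero columns", {
  same <- suppressWarnings(chi_squared_table(rbind(c(5, 5, 5), c(5, 5, 5))))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # 2x2 hand computation of sum (O-E)^2 / E
  tab <- rbind(c(10, 20), c(30, 15))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(suppressWarnings(chi_squared_table(tab))$statistic,
               sum((tab - e)^2 / e))
  expect_warning(res <- chi_squared_table(rbind(c(5, 0, 7), c(3, 0, 2))),
                 "zero total")
  expect_equal(res$df, 1)
})

test_that("Welch t-test matches the textbook formula and handles identical samples", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(81)
  a <- stats::rnorm(12, 30, 9); b <- stats::rnorm(9, 28, 7)
  res <- welch_t(a, b)
  # independent evaluation of the Welch statistic and Satterthwaite df
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("pixel counts: log10 summaries match hand computation", {
  tpl <- tiny_template()
  mk <- function(n, id, grp) {
    pts <- lapply(seq_len(n), function(k)
      c(7 + (k - 1) %% 14, 6 + (k - 1) %/% 14))
    tiny_drawing(tpl, pts, id, grp)
  }
  a <- list(mk(10, "A_1", "ga"), mk(100, "A_2", "ga"))
  b <- list(mk(10, "B_1", "gb"), mk(100, "B_2", "gb"))
  s <- pixel_count_comparison(a, b, labels = c("ga", "gb"))
  expect_equal(s$counts$n_marked, c(10, 100, 10, 100))
  expect_equal(s$log10_stats$mean, c(1.5, 1.5))
  expect_equal(s$log10_stats$sd, rep(stats::sd(c(1, 2)), 2))
  # identical multisets: no group difference detectable
  expect_equal(s$rank_sum$p_value, 1, tolerance = 0.05)
  expect_equal(s$t_test$p_value, 1)
})

test_that("the rank-sum statistic matches a brute-force midrank computation", {
  tpl <- tiny_template()
  set.seed(91)
  mk_rand <- function(id, grp) rand_drawing(tpl, stats::runif(1, 0.05, 0.6), id, grp)
  for (rep in 1:5) {
    a <- lapply(1:6, function(i) mk_rand(sprintf("A_%d", i), "ga"))
    b <- lapply(1:8, function(i) mk_rand(sprintf("B_%d", i), "gb"))
    s <- suppressWarnings(pixel_count_comparison(a, b))
    ca <- vapply(a, function(d) d$n_marked, numeric(1))
    cb <- vapply(b, function(d) d$n_marked, numeric(1))
    la <- log10(ca[ca > 0]); lb <- log10(cb[cb > 0])
    ranks <- rank(c(la, lb))  # midranks for ties
    W_brute <- sum(ranks[seq_along(la)]) - length(la) * (length(la) + 1) / 2
    expect_equal(s$rank_sum$W, W_brute)
  }
})

test_that("zero-count drawings are excluded from log10 analyses with a warning", {
  tpl <- tiny_template()
  a <- list(tiny_drawing(tpl, list(c(8, 7)), "A_1", "ga"),
            tiny_drawing(tpl, list(), "A_2", "ga"),
            tiny_drawing(tpl, list(c(9, 7), c(9, 8)), "A_3", "ga"))
  b <- list(tiny_drawing(tpl, list(c(8, 8)), "B_1", "gb"),
            tiny_drawing(tpl, list(c(8, 9), c(9, 9)), "B_2", "gb"))
  expect_warning(s <- pixel_count_comparison(a, b), "0 marked pixels")
  expect_equal(s$log10_stats$n, c(2L, 2L))
  expect_equal(sum(s$counts$n_marked == 0), 1)
  expect_true(is.na(s$counts$log10_count[2]))
})

test_that("the questionnaire suite reproduces published percentages and drops non-responses", {
  q <- endometriosis_questionnaire()
  expect_named(q, c("q1_suitability", "q2_sexless", "q3_features",
                    "q4_importance", "q5_disturbance"))
  s <- questionnaire_summary(q)
  p1 <- s$q1_suitability$percentages
  expect_equal(p1$percent[p1$group == "overall" & p1$response == "yes"], 89.58)
  p2 <- s$q2_sexless$percentages
  expect_equal(p2$percent[p2$group == "sexless" & p2$response == "yes"], 63.64)
  # q4/q5 drop the no-opinion column and fall back to Fisher on the remainder
  expect_true(s$q4_importance$dropped_no_opinion)
  expect_identical(s$q4_importance$test$method, "fisher")
  expect_equal(round(s$q4_importance$test$fisher_flipped$odds_ratio, 3), 0.790)
  expect_identical(s$q3_features$test$method, "chi_squared")
  expect_equal(round(s$q3_features$test$chi_squared$p_value, 4), 0.3964)
})

test_that("a table left empty after dropping non-responses skips its test", {
  tab <- contingency_table(rbind(c(0, 0, 6), c(0, 0, 4)),
                           c("ga", "gb"), c("yes", "no", "no_opinion"))
  s <- questionnaire_summary(list(q = tab))
  expect_true(s$q$test$skipped)
  expect_match(s$q$test$message, "skipped")
})

test_that("age comparisons run a Welch test on the informative response groups", {
  q <- endometriosis_questionnaire()["q4_importance"]
  ages <- list(q4_importance = list(important = c(31, 28, 35, 27, 29),
                                    unimportant = c(26, 30, 24, 31),
                                    no_opinion = c(40, 18)))
  s <- questionnaire_summary(q, ages = ages)
  at <- s$q4_importance$age_test
  expect_identical(at$groups, c("important", "unimportant"))
  ref <- stats::t.test(ages$q4_importance$important, ages$q4_importance$unimportant)
  expect_equal(at$p_value, ref$p.value)
})

test_that("contingency CSV blocks round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#table demo", ",yes,no", "ga,3,4", "gb,5,6", "",
               "#table wide", ",a,b,c", "ga,1,2,3", "gb,4,5,6"), path)
  tabs <- read_contingency_csv(path)
  expect_named(tabs, c("demo", "wide"))
  expect_equal(unname(tabs$demo$counts), rbind(c(3L, 4L), c(5L, 6L)))
  expect_identical(colnames(tabs$wide$counts), c("a", "b", "c"))
  report <- withr::local_tempfile(fileext = ".csv")
  write_questionnaire_report(questionnaire_summary(tabs), report)
  expect_true(file.exists(report))
  got <- utils::read.csv(report)
  expect_true(all(c("percentage", "test") %in% got$kind))
})
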