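# Agreement metrics and the grouped comparison report.

test_that("MAD and MAPE behave on identities and simple vectors", {
  a <- mv(letters[1:4], c(1, 2, 3, 4))
  b <- mv(letters[1:4], c(1.1, 2, 3, 3.8))
  expect_equal(mean_abs_deviation(a, a), 0)
  expect_equal(mean_abs_deviation(a, b), mean(c(0.1, 0, 0, 0.2)))
  expect_equal(mean_abs_pct_error(a, a), 0)
  expect_error(mean_abs_deviation(a, mv(letters[2:5], 1:4)),
               class = "epwave_alignment_error")
  z <- mv(letters[1:4], c(0, 2, 3, 4))
  expect_error(mean_abs_pct_error(a, z, zero_policy = "error"),
               class = "epwave_domain_error")
  expect_equal(suppressMessages(mean_abs_pct_error(a, z, "skip")),
               mean(abs(c(2 - 2, 3 - 3, 4 - 4)) / c(2, 3, 4)))
})

test_that("MAD/MAPE invariances hold", {
  set.seed(3)
  obs <- mv(letters[1:8], runif(8, 1, 5))
  exp_ <- mv(letters[1:8], runif(8, 1, 5))
  # permutation invariance: reorder both vectors consistently
  perm <- sample(8)
  obs_p <- mv(obs$labels[perm], obs$values[perm])
  exp_p <- mv(exp_$labels[perm], exp_$values[perm])
  expect_equal(mean_abs_deviation(obs_p, exp_p),
               mean_abs_deviation(obs, exp_))
  expect_equal(mean_abs_pct_error(obs_p, exp_p),
               mean_abs_pct_error(obs, exp_))
  # translation leaves MAD unchanged
  shift <- mv(obs$labels, obs$values + 7)
  exp_s <- mv(exp_$labels, exp_$values + 7)
  expect_equal(mean_abs_deviation(shift, exp_s),
               mean_abs_deviation(obs, exp_))
  # MAPE(obs, exp) == MAD(obs/exp, ones) for positive expected
  ratio <- mv(obs$labels, obs$values / exp_$values)
  ones <- mv(obs$labels, rep(1, 8))
  expect_equal(mean_abs_pct_error(obs, exp_), mean_abs_deviation(ratio, ones))
})

test_that("Pearson r covers the identity and antipodal cases", {
  x <- mv(letters[1:5], c(-2, -1, 0, 1, 2))
  expect_equal(pearson_r(x, x), 1)
  neg <- mv(letters[1:5], -x$values)
  expect_equal(pearson_r(neg, x), -1)
  expect_error(pearson_r(mv(letters[1:2], 1:2), mv(letters[1:2], 1:2)),
               class = "epwave_parameter_error")
  flat <- mv(letters[1:5], rep(1, 5))
  expect_error(pearson_r(flat, x), class = "epwave_degenerate_error")
})

test_that("ICC(A,1) matches the ANOVA oracle and penalizes offsets", {
  subj <- sprintf("s%d", 1:4)
  same <- list(mv(subj, 1:4), mv(subj, 1:4), mv(subj, 1:4))
  expect_equal(icc_agreement(same), 1)
  # constant shift between raters: absolute agreement collapses
  shifted <- list(mv(subj, 1:4), mv(subj, 1:4 + 100))
  val <- icc_agreement(shifted)
  expect_lt(val, 0.01)
  expect_equal(val, icc_oracle(cbind(1:4, 1:4 + 100)), tolerance = 1e-12)
  # independent noise raters against the aov decomposition
  set.seed(99)
  m <- matrix(rnorm(30), nrow = 10)
  raters <- lapply(seq_len(ncol(m)), function(j) mv(sprintf("s%d", 1:10), m[, j]))
  got <- icc_agreement(raters)
  expect_equal(got, icc_oracle(m), tolerance = 1e-9)
  expect_gt(got, -1)
  expect_lte(got, 1)
  expect_error(icc_agreement(list(mv(subj, 1:4))),
               class = "epwave_parameter_error")
  expect_error(icc_agreement(list(mv(subj, 1:4), mv(rev(subj), 1:4))),
               class = "epwave_alignment_error")
})

test_that("the reference readings reproduce the published summary metrics", {
  rep_ <- reference_time_report <- local({
    df <- phase1_reference_tables()$time_domain
    expected <- mv(df$label, df$expected)
    raters <- list(examiner1 = mv(df$label, df$examiner1),
                   examiner2 = mv(df$label, df$examiner2),
                   examiner3 = mv(df$label, df$examiner3))
    build_phase1_report(expected, raters, split(df$label, df$group))
  })
  s <- rep_$summary
  pick <- function(g, r, col) s[s$group == g & s$rater == r, col]
  # marking rows: 11 values per rater
  expect_equal(pick("marking", "examiner1", "n"), 11)
  expect_equal(round(pick("marking", "examiner1", "mad"), 4), 0.0009)
  expect_equal(round(pick("marking", "examiner1", "mape"), 4), 0.0012)
  expect_equal(pick("marking", "examiner3", "mad"), 0)
  expect_equal(pick("marking", "examiner3", "mape"), 0)
  # calculation rows: 9 values per rater
  expect_equal(pick("calculation", "examiner1", "n"), 9)
  expect_equal(round(pick("calculation", "examiner1", "mad"), 4), 0.1111)
  expect_equal(round(pick("calculation", "examiner1", "mape"), 4), 0.0094)
  expect_equal(round(pick("calculation", "examiner3", "mad"), 4), 0.0100)
  expect_equal(round(pick("calculation", "examiner3", "mape"), 4), 0.0037)
  # automatic marking correlates perfectly with the expectation
  expect_equal(round(pick("calculation", "examiner3", "pearson_r"), 3), 1)
})

test_that("grouped report validates its partition", {
  exp_ <- mv(letters[1:4], 1:4)
  rat <- list(r1 = mv(letters[1:4], 1:4))
  expect_error(build_phase1_report(exp_, rat,
                                   list(g1 = c("a", "b"), g2 = c("b", "c", "d"))),
               class = "epwave_parameter_error")     # overlap
  expect_error(build_phase1_report(exp_, rat, list(g1 = c("a", "b"))),
               class = "epwave_parameter_error")     # not covering
  expect_warning(
    out <- build_phase1_report(exp_, rat,
                               list(g1 = letters[1:4], g2 = character(0))),
    "empty group")
  expect_equal(unique(out$summary$group), "g1")
  # single rater identical to the expectation: identity metrics
  expect_equal(out$summary$mad, 0)
  expect_equal(out$summary$mape, 0)
  expect_equal(out$summary$pearson_r, 1)
})
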