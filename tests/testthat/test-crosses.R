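test_that("lethal biallelic mosaicism selects the expected surviving sex", {
  # Y-linked Cas9 x homozygous gRNA mother: transheterozygous sons die
  y <- enumerate_f1(cross_design("hom", "Y"), penetrance = 1)
  expect_equal(sum(y$surv_prob[y$sex == "F"]), 1)
  expect_false(attr(y, "all_lethal"))
  # X-linked Cas9: all daughters inherit Cas9 and die -> males only
  x <- enumerate_f1(cross_design("hom", "X"), penetrance = 1)
  expect_equal(sum(x$surv_prob[x$sex == "M"]), 1)
  # autosomal homozygous Cas9: every offspring is transheterozygous -> none survive
  a <- enumerate_f1(cross_design("hom", "autosomal"), penetrance = 1)
  expect_true(attr(a, "all_lethal"))
  expect_equal(sum(a$surv_prob), 0)
  # wild-type father, heterozygous mother: four classes at 1/4
  wt <- enumerate_f1(cross_design("het", "none"))
  expect_equal(wt$surv_prob, rep(0.25, 4))
  # maternal Cas9 carryover kills gRNA+ offspring of both sexes
  mat <- enumerate_f1(cross_design("het", "none", maternal_cas9 = TRUE))
  expect_equal(sum(mat$surv_prob[mat$grna]), 0)
})

test_that("partial penetrance leaves proportional escapers", {
  for (pen in c(0, 0.5, 0.98)) {
    cls <- enumerate_f1(cross_design("het", "Y"), penetrance = pen)
    expect_equal(sum(cls$surv_prob), 1)
    lethal_w <- 0.25 * (1 - pen)
    expect_equal(cls$surv_prob[cls$lethal], lethal_w / (0.75 + lethal_w))
  }
  # penetrance 0 reduces to the Mendelian distribution
  expect_equal(enumerate_f1(cross_design("het", "Y"), 0)$surv_prob, rep(0.25, 4))
})

test_that("chi-squared goodness of fit matches hand and reference computation", {
  expect_equal(chisq_gof(c(25, 25, 25, 25))$statistic, 0)
  expect_equal(chisq_gof(c(10, 20))$statistic, 10 / 3)
  # agreement with the standard implementation on an arbitrary case
  obs <- c(37, 12, 44, 28); pr <- c(0.3, 0.1, 0.4, 0.2)
  g <- chisq_gof(obs, pr)
  ref <- suppressWarnings(stats::chisq.test(obs, p = pr))
  expect_equal(g$statistic, unname(ref$statistic))
  expect_equal(g$df, unname(ref$parameter))
  expect_equal(g$p_value, unname(ref$p.value))
  # invariance under class relabeling
  perm <- c(3, 1, 4, 2)
  expect_equal(chisq_gof(obs[perm], pr[perm])$statistic, g$statistic)
  # zero expected with nonzero observed must be merged explicitly
  expect_error(chisq_gof(c(5, 5), c(1, 0)), "merge classes")
  expect_error(chisq_gof(c(0, 0)), "positive")
})

test_that("published cross statistics are recovered from the printed counts", {
  rep_ <- reproduce_cross_tables()
  expect_true(all(rep_$agrees))
  get <- function(tab, line) rep_$statistic[rep_$table == tab & rep_$line == line]
  expect_equal(round(get("table2", "SGyA"), 1), 159.5)
  expect_equal(round(get("table2", "Autosomal"), 1), 432.2)
  expect_equal(round(get("table3", "SGyA"), 1), 311.3)
  expect_equal(get("table3", "X-Cas9"), 200)
  # significance calls match the published table footnotes
  expect_gt(rep_$p_value[rep_$table == "table2" & rep_$line == "WT"], 0.95)
  expect_lt(max(rep_$p_value[rep_$line != "WT"]), 0.001)
})

test_that("inheritance fractions convert to homing rates with clamping", {
  h <- homing_rate_from_inheritance(c(0.5, 1.0, 0.653, 0.69, 0.4))
  expect_equal(h$homing_rate, c(0, 1, 0.306, 0.38, 0))
  expect_identical(h$clamped, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_error(homing_rate_from_inheritance(1.2))
})

test_that("penetrance MLE inverts exact-expectation counts", {
  cross <- cross_design("het", "Y")
  # construct counts at the exact survivor expectations for penetrance 0.8
  n <- 4000
  cls <- enumerate_f1(cross, 0.8)
  obs <- round(cls$surv_prob * n)
  est <- estimate_penetrance(obs, cross)
  expect_equal(est$penetrance, 0.8, tolerance = 0.01)
  expect_true(est$se > 0)
  expect_error(estimate_penetrance(c(10, 10, 10, 10), cross_design("het", "none")),
               "no lethal class")
})
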