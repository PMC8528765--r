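test_that("catalog has the documented structure and cut-offs", {
  expect_length(get_scale("ASC_TA")$items, 11)
  expect_length(get_scale("ASC_SS")$items, 11)
  expect_length(get_scale("ASC_MO")$items, 9)
  expect_length(get_scale("ASC_LE")$items, 9)
  expect_length(get_scale("ASQ_concealing")$items, 8)
  expect_length(get_scale("ASQ_tolerating")$items, 5)
  expect_length(get_scale("ASQ_adjusting")$items, 7)
  expect_equal(get_scale("ASC_TA")$domain_cutoff, 39)
  expect_equal(get_scale("ASC_SS")$domain_cutoff, 23)
  expect_equal(get_scale("ASC_MO")$domain_cutoff, 32)
  expect_equal(get_scale("ASC_LE")$domain_cutoff, 23)
  # ASQ cut-offs derived as archival mean - 1 SD at load time
  expect_equal(get_scale("ASQ_concealing")$domain_cutoff, 2.27, tolerance = 1e-12)
  expect_equal(get_scale("ASQ_tolerating")$domain_cutoff, 2.29, tolerance = 1e-12)
  expect_equal(get_scale("ASQ_adjusting")$domain_cutoff, 1.70, tolerance = 1e-12)
  expect_error(get_scale("nope"), "unknown scale")
})

test_that("reversal recoding reflects endpoints, fixes the midpoint, and is an involution", {
  ta <- get_scale("ASC_TA")
  rev_item <- ta$reversed[1]
  plain <- setdiff(ta$items, ta$reversed)[1]
  r <- resp_df(c(rev_item, rev_item, plain), c(5, 3, 2))
  out <- recode_reversed(r, ta)
  expect_equal(out$value, c(1, 3, 2))
  # involution on the full 1-5 range
  full <- resp_df(rep(rev_item, 5), 1:5)
  expect_equal(recode_reversed(recode_reversed(full, ta), ta)$value, 1:5)
  # missingness preserved, unknown items rejected
  na_in <- resp_df(rev_item, NA_real_)
  expect_true(is.na(recode_reversed(na_in, ta)$value))
  expect_error(recode_reversed(resp_df(99, 3), ta), "unknown item")
})

test_that("score_scale aggregates per catalog rule and applies the >80% rule", {
  le <- get_scale("ASC_LE")
  s <- score_scale(const_resp(le, 2), le)
  expect_true(s$valid)
  expect_equal(s$value, 18)

  tol <- get_scale("ASQ_tolerating")
  s2 <- score_scale(resp_df(tol$items, 1:5), tol)
  expect_equal(s2$value, 3.0)

  # 8 of 11 observed: 8/11 <= 0.80 -> invalid
  ta <- get_scale("ASC_TA")
  r <- const_resp(ta, 3)
  r$value[1:3] <- NA
  s3 <- score_scale(r, ta)
  expect_false(s3$valid)
  expect_true(is.na(s3$value))

  # 10 of 11 observed: imputation with the observed mean; sum = mean * k
  r2 <- const_resp(ta, 4)
  r2$value[1] <- NA
  s4 <- score_scale(r2, ta)
  expect_true(s4$valid)
  expect_equal(s4$value, 44)
})

test_that("imputation never changes the mean of the observed items", {
  ta <- get_scale("ASC_TA")
  set.seed(42)
  for (i in 1:20) {
    v <- sample(1:5, 11, replace = TRUE)
    miss <- sample(11, sample(0:2, 1))
    v[miss] <- NA
    s <- score_scale(resp_df(ta$items, v), ta)
    expect_equal(s$value / 11, mean(v, na.rm = TRUE))
  }
})

test_that("domain_flag is inclusive and direction-aware", {
  ta <- get_scale("ASC_TA")
  mk <- function(value, scale) structure(
    list(scale = scale$name, value = value, n_observed = length(scale$items),
         n_items = length(scale$items), valid = TRUE), class = "scale_score")
  expect_true(domain_flag(mk(39, ta), ta))
  expect_false(domain_flag(mk(40, ta), ta))
  mo <- get_scale("ASC_MO")
  expect_false(domain_flag(mk(33, mo), mo))
  con <- get_scale("ASQ_concealing")
  expect_true(domain_flag(mk(2.27, con), con))
  # invalid score surfaces as missing
  bad <- mk(10, ta); bad$valid <- FALSE
  expect_true(is.na(domain_flag(bad, ta)))
})

test_that("domain_flag is monotone: lowering recoded responses never clears a flag", {
  ss <- get_scale("ASC_SS")
  set.seed(7)
  for (i in 1:25) {
    v <- sample(1:5, 11, replace = TRUE)
    s1 <- score_scale(resp_df(ss$items, v), ss)
    j <- sample(11, 1)
    v2 <- v; v2[j] <- max(1, v2[j] - sample(1:3, 1))
    s2 <- score_scale(resp_df(ss$items, v2), ss)
    if (isTRUE(domain_flag(s1, ss))) expect_true(domain_flag(s2, ss))
  }
})

test_that("item_flags respects cut-off, direction and missingness", {
  mo <- get_scale("ASC_MO")
  r <- resp_df(mo$items[1:3], c(1, 2, 3))
  expect_equal(item_flags(r, mo), mo$items[1:2])
  expect_length(item_flags(const_resp(mo, 5), mo), 0)
  # missing never flagged
  r$value[1] <- NA
  expect_equal(item_flags(r, mo), mo$items[2])
  # OQ risk item: at-or-above direction with cut-off 3
  oq <- get_scale("OQ_total")
  expect_equal(item_flags(resp_df(5L, 3), oq, cutoff = 3,
                          direction = "at_or_above"), 5L)
})

test_that("ASQ cut-off construction is mean - 1 SD with n-1 denominator", {
  # two-point samples with exact moments m +/- s/sqrt(2)
  mk <- function(m, s) c(m - s / sqrt(2), m + s / sqrt(2))
  cuts <- compute_asq_cutoffs(list(concealing = mk(3.01, 0.74),
                                   tolerating = mk(2.97, 0.68),
                                   adjusting = mk(2.45, 0.75)))
  expect_equal(round(unname(cuts), 2), c(2.27, 2.29, 1.70))
  # constant sample: SD 0, cut-off equals the constant
  expect_equal(unname(compute_asq_cutoffs(list(x = rep(2.5, 4)))), 2.5)
  expect_error(compute_asq_cutoffs(list(x = 1)), "at least 2")
})

test_that("risk assessment combines the three indicator items", {
  r0 <- risk_assessment(0, 1, 1)
  expect_equal(r0$severity, 0L)
  expect_false(r0$flag)
  r1 <- risk_assessment(2, 1, 1)
  expect_equal(r1$severity, 1L)
  expect_true(r1$flag)
  expect_true(r1$immediate)
  r2 <- risk_assessment(1, 3, 3)
  expect_equal(r2$severity, 2L)
  expect_true(r2$flag)
  expect_false(r2$immediate)
  # all three missing -> undefined
  rna <- risk_assessment(NA, NA, NA)
  expect_true(is.na(rna$severity) && is.na(rna$flag))
  # partial missingness: observed items still count
  rp <- risk_assessment(NA, 4, NA)
  expect_equal(rp$severity, 1L)
  expect_true(rp$flag)
})
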