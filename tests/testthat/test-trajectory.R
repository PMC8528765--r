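# Nearest-neighbour engine: slope fitting, neighbour ranking against a
# brute-force oracle, growth-model recovery, and boundary arithmetic.

test_that("fit_patient_slope matches closed-form OLS on ln(session)", {
  expect_equal(fit_patient_slope(rep(1.4, 6)), 0)
  s <- 1:8
  expect_equal(fit_patient_slope(2 - 0.5 * log(s), s), -0.5, tolerance = 1e-12)
  # frozen closed-form oracle: y=(1.8,1.2,0.9,0.7) at s=1..4
  y <- c(1.8, 1.2, 0.9, 0.7); x <- log(1:4)
  oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit_patient_slope(y, 1:4), oracle)
  expect_equal(round(oracle, 6), -0.796737)  # frozen from the formula above
  expect_true(is.na(fit_patient_slope(c(1, 2))))
})

test_that("reference pool records intake, totals, slopes and improving flags", {
  pool <- toy_pool(a = c(2, 2.2, 1.5), b = c(-0.4, 0.1, -0.2), T = c(10, 8, 12))
  expect_equal(pool$patients$intake, c(2, 2.2, 1.5))
  expect_equal(pool$patients$total_sessions, c(10L, 8L, 12L))
  expect_equal(pool$patients$slope, c(-0.4, 0.1, -0.2), tolerance = 1e-10)
  expect_equal(pool$patients$improving, c(TRUE, FALSE, TRUE))
})

test_that("neighbour selection matches exhaustive distance enumeration", {
  set.seed(31)
  # 5-patient toy pool with noisy trajectories, query over sessions 1-6
  scores <- do.call(rbind, lapply(1:5, function(i) {
    s <- 1:12
    data.frame(id = i, session = s,
               hscl = 2 - 0.3 * log(s) + rnorm(12, 0, 0.15) - 0.05 * i)
  }))
  pool <- as_reference_pool(scores)
  query <- data.frame(session = 1:6, hscl = 2 - 0.3 * log(1:6))
  got <- select_neighbors(query, pool, k = 3)
  # brute force over all improving pool members
  dist <- sapply(1:5, function(i) {
    y <- scores$hscl[scores$id == i][1:6]
    sqrt(mean((y - query$hscl)^2))
  })
  elig <- which(pool$patients$improving)
  want <- elig[order(dist[elig], elig)][1:3]
  expect_equal(as.integer(got), want)
  expect_equal(attr(got, "distances"), sort(dist[elig])[1:3], tolerance = 1e-12)
})

test_that("identical query ranks first with distance zero; k = pool returns all", {
  pool <- toy_pool(a = c(2, 1.8, 1.6, 2.1), b = rep(-0.3, 4), T = rep(10, 4))
  query <- data.frame(session = 1:6, hscl = 1.8 - 0.3 * log(1:6))
  got <- select_neighbors(query, pool, k = 4)
  expect_equal(as.integer(got)[1], 2L)
  expect_equal(attr(got, "distances")[1], 0)
  expect_length(got, 4)
  # ties broken by archival id: duplicate of patient 1's curve
  pool2 <- toy_pool(a = c(2, 2), b = c(-0.3, -0.3), T = c(10, 10))
  got2 <- select_neighbors(data.frame(session = 1:6, hscl = 2 - 0.3 * log(1:6)),
                           pool2, k = 2)
  expect_equal(as.integer(got2), c(1L, 2L))
  # short-pool exclusion: archival patients lacking a required session drop out
  pool3 <- toy_pool(a = c(2, 2), b = c(-0.3, -0.3), T = c(4, 10))
  expect_warning(
    got3 <- select_neighbors(data.frame(session = 1:6, hscl = rep(1.5, 6)),
                             pool3, k = 2),
    "eligible")
  expect_equal(as.integer(got3), 2L)
})

test_that("shrinking the candidate pool never shortens selected distances", {
  set.seed(77)
  scores <- do.call(rbind, lapply(1:30, function(i)
    data.frame(id = i, session = 1:10,
               hscl = 2 - 0.3 * log(1:10) + rnorm(10, 0, 0.2))))
  pool_big <- as_reference_pool(scores)
  pool_small <- as_reference_pool(scores[scores$id <= 15, ])
  query <- data.frame(session = 1:6, hscl = 1.9 - 0.25 * log(1:6))
  d_big <- attr(select_neighbors(query, pool_big, k = 5), "distances")
  d_small <- attr(select_neighbors(query, pool_small, k = 5), "distances")
  expect_true(all(d_big <= d_small + 1e-12))
})

test_that("expected model recovers noise-free coefficients and degenerates to OLS", {
  # neighbours generated exactly from known betas
  b <- c(2.0, -0.4, 0.01, 0.005)  # intercept, lns, T, lns:T
  scores <- do.call(rbind, lapply(1:8, function(i) {
    T <- 8 + i
    s <- seq_len(T)
    data.frame(id = i, session = s,
               hscl = b[1] + b[2] * log(s) + b[3] * T + b[4] * log(s) * T)
  }))
  pool <- as_reference_pool(scores)
  m <- suppressWarnings(fit_expected_model(pool, 1:8))
  expect_equal(unname(m$coef), b, tolerance = 1e-6)
  # no between-patient variance beyond T: mixed fit agrees with pooled OLS
  set.seed(55)
  scores_n <- scores
  scores_n$hscl <- scores_n$hscl + rnorm(nrow(scores_n), 0, 0.1)
  pool_n <- as_reference_pool(scores_n)
  m_n <- suppressWarnings(fit_expected_model(pool_n, 1:8))
  d <- pool_n$scores
  d$total <- pool_n$patients$total_sessions[match(d$id, pool_n$patients$id)]
  ols <- lm(hscl ~ log(session) * total, data = d)
  expect_equal(unname(m_n$coef), unname(coef(ols)), tolerance = 1e-2)
  # single shared T: T terms dropped with a warning
  scores2 <- do.call(rbind, lapply(1:4, function(i)
    data.frame(id = i, session = 1:10, hscl = 2 - 0.3 * log(1:10) + 0.1 * i)))
  pool2 <- as_reference_pool(scores2)
  expect_warning(m2 <- fit_expected_model(pool2, 1:4), "total-session")
  expect_false(m2$has_T)
  expect_equal(unname(m2$coef[2]), -0.3, tolerance = 1e-8)
})

test_that("mixed-model coefficient CIs cover generating values", {
  hits <- 0
  for (r in 1:60) {
    set.seed(400 + r)
    tau <- 0.25; sig <- 0.2
    scores <- do.call(rbind, lapply(1:40, function(i) {
      T <- sample(8:20, 1)
      s <- seq_len(T)
      data.frame(id = i, session = s,
                 hscl = 2 - 0.35 * log(s) + 0.004 * T + rnorm(1, 0, tau) +
                   rnorm(T, 0, sig))
    }))
    pool <- as_reference_pool(scores)
    m <- suppressWarnings(fit_expected_model(pool, 1:40))
    est <- m$coef[["lns"]]; se <- sqrt(m$vcov["lns", "lns"])
    hits <- hits + (abs(est - (-0.35)) <= 1.96 * se)
  }
  expect_gte(hits / 60, 0.90)
})

test_that("boundary arithmetic: upper = expected + z(.95) * SE", {
  # SE = 0 -> upper equals expected
  m0 <- manual_etr(c(1.2, -0.3), has_T = FALSE)
  bd <- boundary(m0, 10, 20)
  expect_equal(bd$upper, bd$expected)
  # expected 1.00, SE 0.20 -> upper 1.329 (normal-quantile oracle)
  m1 <- manual_etr(c(1.0, 0), sigma2 = 0.04, has_T = FALSE)
  b1 <- boundary(m1, 10, 20)  # lns coefficient is 0, so expected = 1
  expect_equal(b1$expected, 1.0)
  expect_equal(b1$upper, 1 + qnorm(0.95) * 0.2, tolerance = 1e-12)
  expect_equal(round(b1$upper, 3), 1.329)
  # upper non-decreasing in SE at fixed expected
  uppers <- sapply(c(0.01, 0.04, 0.09, 0.25), function(s2)
    boundary(manual_etr(c(1, 0), sigma2 = s2, has_T = FALSE), 10, 20)$upper)
  expect_true(all(diff(uppers) > 0))
  # window enforced
  expect_error(boundary(m0, 5, 20), "sessions 6-30")
  expect_error(boundary(m0, 31, 20), "sessions 6-30")
})

test_that("dynamic boundary: determinism, single-neighbour pool, coverage of on-curve patients", {
  pool <- toy_pool(a = seq(1.6, 2.2, length.out = 12), b = rep(-0.3, 12),
                   T = rep(20, 12))
  hist <- data.frame(session = 1:12, hscl = 1.9 - 0.3 * log(1:12))
  fb1 <- suppressWarnings(dynamic_boundary_sequence(hist, pool, k = 6))
  fb2 <- suppressWarnings(dynamic_boundary_sequence(hist, pool, k = 6))
  expect_identical(as.data.frame(fb1), as.data.frame(fb2))
  expect_equal(fb1$session, 6:12)
  # a patient tracking the pool's curve never exceeds the boundary
  expect_true(all(fb1$observed <= fb1$upper))
  # single archival patient: expected curve equals that patient's fitted curve
  pool1 <- toy_pool(a = 2, b = -0.3, T = 20)
  fb <- suppressWarnings(dynamic_boundary_sequence(
    data.frame(session = 1:8, hscl = 2 - 0.3 * log(1:8)), pool1, k = 5))
  expect_equal(fb$expected, 2 - 0.3 * log(6:8), tolerance = 1e-8)
})
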