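# Generator contracts: determinism, noise-free limits, battery pattern,
# multilevel structure recovery, and the configured group difference in
# treatment length.

test_that("same seed gives identical pools and cohorts", {
  cfg <- cohort_config(n_patients = 15L, n_therapists = 5L, archival_n = 40L)
  p1 <- generate_archival(cfg, seed = 11)
  p2 <- generate_archival(cfg, seed = 11)
  expect_identical(p1$scores, p2$scores)
  c1 <- generate_cohort(cfg, seed = 11)
  c2 <- generate_cohort(cfg, seed = 11)
  expect_identical(c1$sessions, c2$sessions)
  expect_identical(c1$truth, c2$truth)
  expect_false(identical(generate_cohort(cfg, seed = 12)$sessions, c1$sessions))
})

test_that("noise-free archival trajectories equal the fixed-effect curve exactly", {
  cfg <- cohort_config(archival_n = 10L, n_therapists = 3L,
                       sigma_therapist = 0, sigma_patient = 0,
                       sigma_residual = 0, frac_nonimproving = 0)
  pool <- generate_archival(cfg, seed = 2)
  b <- cfg$beta
  for (i in 1:10) {
    tr <- pool$scores[pool$scores$id == i, ]
    T <- max(tr$session)
    mu <- b[["intercept"]] + b[["total_sessions"]] * T +
      (b[["log_session"]] + b[["interaction"]] * T) * log(tr$session)
    expect_equal(tr$hscl, pmin(pmax(mu, 0), 3), tolerance = 1e-12)
  }
  # improving flag: effective slopes are negative at these T
  expect_true(all(pool$patients$improving[pool$patients$total_sessions >= 3]))
})

test_that("flat generating slope yields near-zero mean fitted slopes", {
  cfg <- cohort_config(archival_n = 300L,
                       beta = c(intercept = 1.5, log_session = 0,
                                total_sessions = 0, interaction = 0),
                       frac_nonimproving = 0)
  pool <- generate_archival(cfg, seed = 4)
  sl <- pool$patients$slope[!is.na(pool$patients$slope)]
  # Monte-Carlo error band: SE of the mean slope
  expect_lt(abs(mean(sl)), 3 * sd(sl) / sqrt(length(sl)))
})

test_that("battery pattern is exactly {1, 5, 10, 15, ...}", {
  cfg <- small_config()
  coh <- generate_cohort(cfg, seed = 9)
  bat <- unique(coh$sessions[coh$sessions$instrument %in% c("ASC", "ASQ", "OQ30"),
                             c("patient_id", "session")])
  for (pid in unique(bat$patient_id)) {
    T <- coh$truth$total_sessions[coh$truth$patient_id == pid]
    want <- c(1, seq(5, 30, by = 5))
    expect_equal(sort(bat$session[bat$patient_id == pid]), want[want <= T])
  }
  # item responses are in range
  hs <- coh$sessions[coh$sessions$instrument == "HSCL11", "value"]
  expect_true(all(hs %in% 0:3))
  ba <- coh$sessions[coh$sessions$instrument != "HSCL11", "value"]
  expect_true(all(ba %in% 1:5))
})

test_that("zero NOT prevalence means no deterioration anywhere", {
  cfg <- cohort_config(n_patients = 25L, n_therapists = 5L,
                       not_prevalence = 0)
  coh <- generate_cohort(cfg, seed = 3)
  expect_true(all(coh$truth$latent_status == "OT_latent"))
  expect_true(all(is.na(coh$truth$onset_session)))
})

test_that("marginal HSCL mean tracks the fixed-effect curve", {
  cfg <- cohort_config(n_patients = 400L, n_therapists = 20L,
                       not_prevalence = 0)
  coh <- generate_cohort(cfg, seed = 21)
  lat <- merge(coh$latent, coh$truth[, c("patient_id", "total_sessions")])
  b <- cfg$beta
  for (s in c(1, 5, 10)) {
    sub <- lat[lat$session == s, ]
    mu <- b[["intercept"]] + b[["total_sessions"]] * sub$total_sessions +
      (b[["log_session"]] + b[["interaction"]] * sub$total_sessions) * log(s)
    tot_sd <- sqrt(cfg$sigma_therapist^2 + cfg$sigma_patient^2 +
                     cfg$sigma_residual^2)
    expect_lt(abs(mean(sub$hscl_latent - mu)),
              4 * tot_sd / sqrt(nrow(sub)) + 0.01)  # 0.01 for [0,3] clamping
  }
})

test_that("variance components are recovered from the archival pool", {
  cfg <- cohort_config()   # archival_n = 1234, 65 therapists
  est <- sapply(1:3, function(i) {
    pool <- generate_archival(cfg, seed = 100 + i)
    d <- pool$scores
    d$total <- pool$patients$total_sessions[match(d$id, pool$patients$id)]
    d$lns <- log(d$session)
    fit <- suppressWarnings(suppressMessages(lme4::lmer(
      hscl ~ lns * total + (1 | id) + (1 | therapist_id), data = d,
      REML = TRUE)))
    vc <- lme4::VarCorr(fit)
    c(pat = unname(vc$id[1, 1]), ther = unname(vc$therapist_id[1, 1]))
  })
  expect_equal(mean(est["pat", ]), cfg$sigma_patient^2, tolerance = 0.20)
  expect_equal(mean(est["ther", ]), cfg$sigma_therapist^2, tolerance = 0.20)
})

test_that("treatment-length group difference matches its configured target", {
  cfg <- small_config(n_patients = 150L)
  target <- cohens_d(cfg$sessions_ot[["mean"]], cfg$sessions_ot[["sd"]], 273,
                     cfg$sessions_not[["mean"]], cfg$sessions_not[["sd"]], 140)
  ds <- sapply(1:20, function(i) {
    tr <- generate_cohort(cfg, seed = 200 + i)$truth
    ot <- tr$total_sessions[tr$latent_status == "OT_latent"]
    nt <- tr$total_sessions[tr$latent_status == "NOT_latent"]
    cohens_d(mean(ot), sd(ot), length(ot), mean(nt), sd(nt), length(nt))
  })
  expect_lt(abs(mean(ds) - target), 0.15)
})

test_that("continuous validation mode puts the latent score in every item", {
  cfg <- cohort_config(n_patients = 5L, n_therapists = 2L)
  coh <- generate_cohort(cfg, seed = 6, discretize = FALSE)
  sc <- score_cohort(coh$sessions)
  m <- merge(sc$hscl, coh$latent, by = c("patient_id", "session"))
  expect_equal(m$hscl, m$hscl_latent, tolerance = 1e-12)
})
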