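pair <- behavioral_model_pair(n_partner_slots = 3)
ctx <- ms_context(pair$culture)

test_that("predictive likelihoods separate the behavioural models", {
  p_share_c <- predictive_likelihood(pair$culture, "share", ctx)
  p_share_e <- predictive_likelihood(pair$ego, "share", ctx)
  expect_gt(p_share_c, p_share_e)
  p_conceal_c <- predictive_likelihood(pair$culture, "conceal", ctx)
  p_conceal_e <- predictive_likelihood(pair$ego, "conceal", ctx)
  expect_lt(p_conceal_c, p_conceal_e)
  expect_gt(p_share_c, 0); expect_gt(p_conceal_c, 0)
  expect_error(predictive_likelihood(pair$culture, "fly", ctx), "legal set")
})

test_that("identical models assign equal probability to any action", {
  twin <- behavioral_model_pair(n_partner_slots = 3)
  twin$ego <- twin$culture
  for (a in c("forage", "share", "conceal")) {
    cmp <- accumulate_delta_F(new_model_comparison("x"), a, ctx, twin)
    expect_equal(cmp$delta_F, 0, tolerance = 1e-12)
  }
  expect_equal(delta_G(twin$culture, twin$culture, ctx), 0,
               tolerance = 1e-12)
})

test_that("evidence accumulates additively into the log odds", {
  cmp <- new_model_comparison("adam", delta_G = 0)
  cmp1 <- accumulate_delta_F(cmp, "share", ctx, pair)
  cmp2 <- accumulate_delta_F(cmp1, "share", ctx, pair)
  expect_equal(cmp2$delta_F, 2 * cmp1$delta_F, tolerance = 1e-12)
  expect_equal(cmp2$n_evidence, 2L)
  expect_equal(cmp2$log_odds, cmp2$delta_F + cmp2$delta_G, tolerance = 1e-12)
  expect_equal(cmp2$posterior, 1 / (1 + exp(-cmp2$log_odds)),
               tolerance = 1e-12)
})

test_that("model posterior is the logistic of the log odds, capped", {
  cmp <- new_model_comparison("x")
  expect_equal(unname(model_posterior(cmp)["cultural"]), 0.5)
  cmp$delta_F <- log(2)
  expect_equal(unname(model_posterior(cmp)["cultural"]), 2 / 3,
               tolerance = 1e-12)
  cmp$delta_F <- 1e6
  expect_equal(unname(model_posterior(cmp)["cultural"]), 1,
               tolerance = 1e-12)
  cmp$delta_F <- -1e6
  expect_equal(unname(model_posterior(cmp)["cultural"]), 0,
               tolerance = 1e-12)
})

test_that("violation detection honours threshold and hysteresis", {
  walk <- function(ps, theta = 0.5, h = 0.1, armed = FALSE) {
    cmp <- new_model_comparison("t")
    cmp$armed <- armed
    n <- 0L
    for (p in ps) {
      cmp$delta_F <- log(p / (1 - p))
      dv <- detect_violation(cmp, "o", 1L, theta, h)
      cmp <- dv$cmp
      if (!is.null(dv$declaration)) n <- n + 1L
    }
    n
  }
  expect_equal(walk(c(0.9, 0.8)), 0L)           # stays above threshold
  expect_equal(walk(c(0.7, 0.3)), 1L)           # one crossing
  expect_equal(walk(c(0.7, 0.3, 0.4, 0.3)), 1L) # no re-arm below theta+h
  # oscillation around the threshold under wide hysteresis: one total
  expect_equal(walk(c(0.45, 0.55, 0.45), h = 0.2, armed = TRUE), 1L)
  expect_equal(walk(c(0.8, 0.3, 0.8, 0.3)), 2L) # full re-arm allows another
})

test_that("the sign of accumulated evidence recovers the generator", {
  set.seed(31)
  n_seq <- 40L
  hits <- c(culture = 0L, ego = 0L)
  for (k in seq_len(n_seq)) {
    for (gen in c("culture", "ego")) {
      acts <- sample_actions(pair[[gen]], ctx, 20L)
      dF <- sum(vapply(acts, function(a) {
        log(predictive_likelihood(pair$culture, a, ctx)) -
          log(predictive_likelihood(pair$ego, a, ctx))
      }, numeric(1)))
      ok <- if (gen == "culture") dF > 0 else dF < 0
      hits[gen] <- hits[gen] + ok
    }
  }
  expect_gte(hits[["culture"]] / n_seq, 0.8)
  expect_gte(hits[["ego"]] / n_seq, 0.8)
})

test_that("typing confidence under cultural actors grows with evidence", {
  set.seed(32)
  mean_p <- vapply(c(2L, 6L, 20L), function(len) {
    mean(vapply(1:60, function(k) {
      acts <- sample_actions(pair$culture, ctx, len)
      cmp <- new_model_comparison("t")
      for (a in acts) cmp <- accumulate_delta_F(cmp, a, ctx, pair)
      cmp$posterior
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_p) >= -1e-9))
})
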