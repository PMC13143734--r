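test_that("normalize maps non-negative vectors to categoricals", {
  expect_equal(normalize(c(2, 2)), c(0.5, 0.5))
  expect_equal(normalize(c(1, 0, 0)), c(1, 0, 0))
  expect_equal(normalize(c(9, 1)), c(0.9, 0.1))
  expect_error(normalize(c(0, 0)), "degenerate")
  expect_error(normalize(c(-1, 2)), "non-negative")
})

test_that("dirichlet expectation normalizes count columns and rejects zeros", {
  expect_equal(dirichlet_expectation(c(1, 1)), c(0.5, 0.5))
  expect_equal(dirichlet_expectation(matrix(c(3, 1), 2, 1)),
               matrix(c(0.75, 0.25), 2, 1))
  counts <- array(c(3, 1, 0, 2), dim = c(2, 2))
  out <- dirichlet_expectation(counts)
  expect_equal(colSums(matrix(out, 2)), c(1, 1))
  expect_error(dirichlet_expectation(matrix(c(0, 0, 1, 1), 2)),
               "degenerate")
})

test_that("agent versions have the specified level structure", {
  m1 <- make_agent_model("V1", tiny_spec())
  expect_length(m1$levels, 1L)
  m2 <- make_agent_model("V2", foraging_model_spec(3, 2),
                         prior_strength = 5)
  expect_length(m2$levels, 2L)
  expect_equal(m2$levels[[2]]$type_labels, c("in-group", "out-group"))
  expect_length(m2$levels[[2]]$D2, 2L)
  m3 <- make_agent_model("V3", foraging_model_spec(3, 2))
  expect_length(m3$levels, 1L)
  expect_true(m3$expandable)
})

test_that("configurable typing schemas are honoured", {
  spec <- foraging_model_spec(3, 2)
  spec$type_labels <- c("Sage", "Citizen", "Soldier")
  spec$alpha <- 0.4
  m <- make_agent_model("V2", spec)
  expect_equal(m$levels[[2]]$type_labels, c("Sage", "Citizen", "Soldier"))
  expect_equal(ncol(m$levels[[2]]$M), 3L)
})

test_that("validation errors name the offending field", {
  spec <- foraging_model_spec(3, 2)
  spec$alpha <- 1.3
  expect_error(make_agent_model("V2", spec), "alpha")
  spec2 <- foraging_model_spec(3, 2)
  spec2$policies <- spec2$policies[0, , drop = FALSE]
  expect_error(make_agent_model("V1", spec2), "polic")
  spec3 <- tiny_spec()
  spec3$A$o[] <- 0
  expect_error(make_agent_model("V1", spec3), "non-normalizable")
  spec4 <- tiny_spec()
  spec4$gamma_policy <- -1
  expect_error(make_agent_model("V1", spec4), "gamma_policy")
})

test_that("serialized configs round-trip field-identically", {
  m <- make_agent_model("V2", foraging_model_spec(3, 2, "cultural"))
  j1 <- jsonlite::toJSON(agent_model_dump(m), digits = NA,
                         auto_unbox = FALSE)
  m2 <- agent_model_load(jsonlite::fromJSON(j1, simplifyVector = FALSE))
  j2 <- jsonlite::toJSON(agent_model_dump(m2), digits = NA,
                         auto_unbox = FALSE)
  expect_identical(as.character(j1), as.character(j2))
})

test_that("every stochastic array in random configs passes the validator", {
  set.seed(11)
  for (k in 1:100) {
    spec <- foraging_model_spec(
      n_partner_slots = sample(2:5, 1), n_signals = sample(1:3, 1),
      preferences = sample(c("ego", "cultural"), 1),
      horizon = sample(1:2, 1))
    # perturb arrays with positive noise; construction must renormalize
    spec$A <- lapply(spec$A, function(a) a + stats::runif(length(a), 0, 0.1))
    ver <- sample(c("V1", "V2", "V3"), 1)
    if (ver == "V2") spec$alpha <- stats::runif(1)
    m <- make_agent_model(ver, spec)
    expect_true(validate_agent_model(m))
  }
})
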