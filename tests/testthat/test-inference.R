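test_that("single-factor inference matches exact Bayes and textbook cases", {
  A <- list(array(c(0.8, 0.2, 0.2, 0.8), dim = c(2, 2)))
  q <- infer_states(1L, list(c(0.5, 0.5)), A)
  expect_equal(q[[1]], c(0.8, 0.2))
  expect_equal(attr(q, "evidence"), 0.5)

  ident <- list(array(diag(3), dim = c(3, 3)))
  q2 <- infer_states(2L, list(c(0.2, 0.5, 0.3)), ident)
  expect_equal(q2[[1]], c(0, 1, 0))

  A0 <- list(array(c(0, 1, 0.7, 0.3), dim = c(2, 2)))
  expect_error(infer_states(1L, list(c(1, 0)), A0), "impossible observation")
})

test_that("oracle equivalence on random one-factor models", {
  set.seed(21)
  for (k in 1:100) {
    mdl <- rand_one_factor(n_mod = sample(1:2, 1))
    q <- infer_states(mdl$obs, mdl$prior, mdl$A)
    # brute-force enumeration oracle
    lik <- rep(1, mdl$ns)
    for (m in seq_along(mdl$A)) lik <- lik * mdl$A[[m]][mdl$obs[m], ]
    post <- lik * mdl$prior[[1]]
    ev <- sum(post)
    expect_equal(q[[1]], post / ev, tolerance = 1e-9)
    fr <- free_energy(q, mdl$obs,
                      structure(list(version = "V1",
                                     levels = list(list(A = mdl$A,
                                                        D = mdl$prior))),
                                class = "agent_model"))
    expect_equal(fr$total, -log(ev), tolerance = 1e-9)
  }
})

test_that("free-energy report decomposition sums to the total", {
  set.seed(22)
  for (k in 1:50) {
    mdl <- rand_two_factor()
    q <- infer_states(mdl$obs, mdl$prior, mdl$A)
    fr <- free_energy(q, mdl$obs,
                      structure(list(version = "V1",
                                     levels = list(list(A = mdl$A,
                                                        D = mdl$prior))),
                                class = "agent_model"),
                      q_level2 = c(0.7, 0.3), prior_level2 = c(0.5, 0.5),
                      q_alpha = c(0.6, 0.4), prior_alpha = c(0.5, 0.5))
    expect_equal(fr$total,
                 -fr$accuracy + sum(fr$complexity) + fr$transcendental,
                 tolerance = 1e-9)
    expect_gte(fr$complexity[["level2"]], 0)
    expect_gte(fr$transcendental, 0)
  }
  # q = prior: complexity exactly zero; deterministic matching likelihood:
  # total F exactly zero
  A <- list(array(c(1, 0, 0, 1), dim = c(2, 2)))
  mm <- structure(list(version = "V1",
                       levels = list(list(A = A, D = list(c(1, 0))))),
                  class = "agent_model")
  fr0 <- free_energy(list(c(1, 0)), 1L, mm)
  expect_identical(fr0$complexity[["level1"]], 0)
  expect_equal(fr0$total, 0)
})

test_that("damped mean-field descent never increases free energy", {
  set.seed(23)
  for (k in 1:100) {
    mdl <- rand_two_factor(n1 = sample(2:4, 1), n2 = sample(2:4, 1))
    mdl$obs <- vapply(mdl$A, function(a) sample.int(dim(a)[1L], 1L),
                      integer(1))
    q <- infer_states(mdl$obs, mdl$prior, mdl$A, track = TRUE)
    traj <- attr(q, "trajectory")
    Fs <- vapply(traj, mf_free_energy, numeric(1),
                 obs = mdl$obs, A = mdl$A, prior = mdl$prior)
    expect_true(all(diff(Fs) <= 1e-10))
  }
})

test_that("expected free energy boundary cases and split identity", {
  # predicted outcomes equal to preferences with deterministic A: G = 0
  m <- make_agent_model("V1", tiny_spec())
  ev <- expected_free_energy(1L, m, list(c(0.5, 0.5)))
  expect_equal(ev$G, 0, tolerance = 1e-12)

  # delta prediction against uniform preferences: risk = ln 2
  ev2 <- expected_free_energy(1L, m, list(c(1, 0)))
  expect_equal(ev2$risk, log(2), tolerance = 1e-12)
  expect_equal(ev2$ambiguity, 0, tolerance = 1e-12)

  # uniform likelihood columns: ambiguity = ln 2 per step for any belief
  spec <- tiny_spec()
  spec$A$o <- array(0.5, dim = c(2, 2))
  m3 <- make_agent_model("V1", spec)
  for (b in list(c(1, 0), c(0.3, 0.7))) {
    ev3 <- expected_free_energy(1L, m3, list(b))
    expect_equal(ev3$ambiguity, log(2), tolerance = 1e-12)
  }

  # split identity on random models: naive enumeration oracle vs G
  set.seed(24)
  for (k in 1:100) {
    ns <- sample(2:3, 2, replace = TRUE); no <- sample(2:3, 1)
    spec <- list(factor_sizes = ns, modality_sizes = no,
                 A = list(normalize_cols_arr(array(
                   stats::rgamma(no * prod(ns), 1) + 0.05,
                   dim = c(no, ns)))),
                 B = list(rand_B(ns[1], 2), rand_B(ns[2], 2)),
                 C = list(stats::rnorm(no)),
                 D = list(normalize(stats::runif(ns[1]) + 0.1),
                          normalize(stats::runif(ns[2]) + 0.1)),
                 policies = matrix(c(1L, 2L, 2L, 1L), 2, 2))
    m4 <- make_agent_model("V1", spec)
    bel <- list(normalize(stats::runif(ns[1]) + 0.05),
                normalize(stats::runif(ns[2]) + 0.05))
    pol <- m4$policies[sample(1:2, 1), ]
    got <- expected_free_energy(pol, m4, bel)
    orc <- efe_enumeration_oracle(pol, m4, bel)
    expect_equal(got$G, orc, tolerance = 1e-9)
    expect_equal(got$G, got$risk + got$ambiguity, tolerance = 1e-9)
    expect_gte(got$risk, -1e-12)
    expect_gte(got$ambiguity, -1e-12)
  }
})

test_that("policy posterior weights habits against expected free energy", {
  expect_equal(policy_posterior(c(1, 1), c(0.5, 0.5), 3), c(0.5, 0.5))
  expect_equal(policy_posterior(c(0, log(2)), c(0.5, 0.5), 1),
               c(2 / 3, 1 / 3))
  # temperature limit: gamma -> 0 recovers the habit prior
  expect_equal(policy_posterior(c(0, 5), c(0.7, 0.3), 1e-12), c(0.7, 0.3),
               tolerance = 1e-9)
})

test_that("action selection is deterministic under argmax and seeded sampling", {
  pol <- matrix(c(1L, 2L), 2, 1)
  a <- select_action(c(1, 0), pol, mode = "argmax")
  expect_equal(as.integer(a), 1L)
  a2 <- select_action(c(0.5, 0.5), pol, mode = "argmax")
  expect_equal(as.integer(a2), 1L)   # lowest-index tie break
  set.seed(5); s1 <- select_action(c(0.3, 0.7), pol, mode = "sample")
  set.seed(5); s2 <- select_action(c(0.3, 0.7), pol, mode = "sample")
  expect_identical(s1, s2)
})

test_that("likelihood and habit learning accumulate as stated", {
  counts <- array(1, dim = c(2, 2))
  expect_identical(update_likelihood(counts, list(c(0.5, 0.5)), 1L, 0),
                   counts)
  c2 <- update_likelihood(counts, list(c(1, 0)), 1L, 1)
  expect_equal(c2[1, 1], 2); expect_equal(sum(c2), 5)
  c3 <- update_likelihood(counts, list(c(0.5, 0.5)), 2L, 2)
  expect_equal(c3[2, ], c(2, 2))
  expect_equal(update_habits(c(1, 1), c(0.25, 0.75), 4), c(2, 4))
  expect_identical(update_habits(c(1, 1), c(1, 0), 0), c(1, 1))
})

test_that("precision posterior follows the free-energy-weighted prior", {
  expect_equal(as.numeric(infer_alpha(c(0, 1), c(1, 1), c(0.5, 0.5))),
               c(0.5, 0.5))
  post <- infer_alpha(c(0, 1), c(0, log(2)), c(0.5, 0.5))
  expect_equal(as.numeric(post), c(2 / 3, 1 / 3))
  expect_equal(attr(post, "transcendental"),
               kl_div(c(2 / 3, 1 / 3), c(0.5, 0.5)))
  delta <- infer_alpha(c(0, 0.5, 1), c(5, 0, 9), c(0, 1, 0))
  expect_equal(as.numeric(delta), c(0, 1, 0))
  expect_error(infer_alpha(c(0, 1), c(1, 2, 3), c(0.5, 0.5)), "length")
})
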