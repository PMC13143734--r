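test_that("cooperative harvest follows the stated yield rule", {
  cfg <- world_config(2, y0 = 1, coop_c = 0.5)
  h1 <- harvest_yield(1, 10, cfg)
  expect_equal(h1$yield, 1); expect_equal(h1$stock, 9)
  h2 <- harvest_yield(2, 10, cfg)
  expect_equal(h2$yield, 1.5); expect_equal(h2$stock, 7)
  h0 <- harvest_yield(3, 0, cfg)
  expect_equal(h0$yield, 0)
  # depletion-limited: yield capped by the per-capita stock
  h3 <- harvest_yield(4, 2, cfg)
  expect_equal(h3$yield, 0.5); expect_equal(h3$stock, 0)
})

test_that("regeneration relaxes stock toward the cap", {
  expect_equal(regenerate(4, 0, 10), 4)
  expect_equal(regenerate(10, 0.7, 10), 10)
  expect_equal(regenerate(5, 0.5, 10), 7.5)
})

test_that("world config validates its ranges", {
  expect_error(world_config(1), "n_agents")
  expect_error(world_config(4, regen = 1.5), "regen")
  expect_error(world_config(4, stranger_rate = -0.1), "stranger_rate")
  expect_error(world_config(4, gamma_att = -1), "gamma_att")
})

test_that("sharing splits inventory over co-located agents' satiety", {
  cfg <- world_config(3, n_patches = 1L, satiety_decay_every = 0L)
  st <- init_world_state(cfg)
  st$tick <- 1L
  st$inventory[1] <- 2
  st$satiety[] <- 0
  st <- apply_actions(st, list(list(type = "share"), idle_action(),
                               idle_action()), cfg)
  expect_equal(st$satiety, c(2 / 3, 2 / 3, 2 / 3))
  expect_equal(st$inventory[1], 0)
  # two co-located agents, inventory 2: each satiety pool +1
  st2 <- init_world_state(world_config(2, n_patches = 1L))
  st2$tick <- 1L; st2$inventory[2] <- 2; st2$satiety[] <- 0
  st2 <- apply_actions(st2, list(idle_action(), list(type = "share")),
                       world_config(2, n_patches = 1L))
  expect_equal(st2$satiety, c(1, 1))
})

test_that("sanctions confiscate, banish and raise every observer's alpha", {
  cfg <- world_config(4, confiscate = TRUE, banish_ticks = 10L,
                      alpha_increment = 0.2, conceal_lookback = 5L)
  st <- init_world_state(cfg, alpha0 = c(0.5, 0.9, 0.5, 0.5))
  st$tick <- 3L
  st$last_conceal[2] <- 2L
  st$inventory[2] <- 1.5
  p_target <- st$patch[2]
  stock_before <- st$stocks[p_target]
  st$pending_decl <- list(list(declarer = 1L, target = 2L, tick = 3L))
  st <- apply_sanctions(st, cfg)
  expect_equal(st$inventory[2], 0)
  expect_equal(st$stocks[p_target], stock_before + 1.5)
  expect_equal(st$banished_until[2], 13L)
  expect_true(is.na(st$patch[2]))
  expect_equal(st$alpha_eff, c(0.7, 0.9, 0.7, 0.7))  # cap at 1 honoured
  expect_equal(sum(vapply(st$events, function(e) e$type == "sanction",
                          logical(1))), 1L)
})

test_that("false declarations sanction nothing but are logged", {
  cfg <- world_config(3, conceal_lookback = 5L)
  st <- init_world_state(cfg)
  st$tick <- 50L   # any old concealment is outside the lookback
  st$pending_decl <- list(list(declarer = 1L, target = 2L, tick = 50L))
  alpha_before <- st$alpha_eff
  st <- apply_sanctions(st, cfg)
  expect_equal(st$banished_until[2], 0L)
  expect_equal(st$alpha_eff, alpha_before)
  expect_true(any(vapply(st$events, function(e) {
    e$type == "false_declaration"
  }, logical(1))))
})

test_that("consensus threshold gates sanctions", {
  cfg <- world_config(4, consensus_k = 2L, conceal_lookback = 5L)
  st <- init_world_state(cfg)
  st$tick <- 3L; st$last_conceal[2] <- 2L
  st$pending_decl <- list(list(declarer = 1L, target = 2L, tick = 3L))
  st1 <- apply_sanctions(st, cfg)
  expect_equal(st1$banished_until[2], 0L)  # one declarer is not enough
  st$pending_decl <- list(list(declarer = 1L, target = 2L, tick = 3L),
                          list(declarer = 3L, target = 2L, tick = 3L))
  st2 <- apply_sanctions(st, cfg)
  expect_gt(st2$banished_until[2], 0L)
})

test_that("attention-biased partner choice follows the softmax weights", {
  cfg <- world_config(4, stranger_rate = 0, gamma_att = 6, f_min = 1L)
  fam <- matrix(5L, 4, 4)
  typing <- matrix(NA_real_, 4, 4)
  typing[1, ] <- c(NA, 0.99, 0.5, 0.5)
  set.seed(51)
  draws <- replicate(1000, choose_partner(1L, 2:4, fam, typing, cfg))
  freq <- tabulate(draws, 4)[2] / 1000
  w <- exp(6 * c(0.99, 0.5, 0.5)); expected <- w[1] / sum(w)
  expect_gt(freq, 0.85)
  expect_equal(freq, expected, tolerance = 0.05)
  # gamma_att = 0: uniform choice among familiar candidates
  cfg0 <- world_config(4, stranger_rate = 0, gamma_att = 0, f_min = 1L)
  set.seed(52)
  d0 <- replicate(900, choose_partner(1L, 2:4, fam, typing, cfg0))
  expect_true(all(abs(tabulate(d0, 4)[2:4] / 900 - 1 / 3) < 0.06))
  # stranger_rate = 1: uniform over non-familiar candidates
  cfg1 <- world_config(4, stranger_rate = 1, gamma_att = 6, f_min = 10L)
  set.seed(53)
  d1 <- replicate(900, choose_partner(1L, 2:4, fam, typing, cfg1))
  expect_true(all(abs(tabulate(d1, 4)[2:4] / 900 - 1 / 3) < 0.06))
})

test_that("a no-op tick leaves the world unchanged except the clock", {
  cfg <- world_config(3, regen = 0, encounter_rate = 0,
                      satiety_decay_every = 0L)
  st <- init_world_state(cfg)
  sw <- step_world(st, replicate(3, idle_action(), simplify = FALSE), cfg)
  expect_equal(sw$state$tick, 1L)
  expect_equal(sw$state$stocks, st$stocks)
  expect_equal(sw$state$satiety, st$satiety)
  expect_equal(sw$state$inventory, st$inventory)
})

test_that("a lone forager's satiety follows the closed-form recurrence", {
  cfg <- world_config(2, n_patches = 2L, regen = 0, encounter_rate = 0,
                      satiety_decay_every = 3L, y0 = 1, coop_c = 0.5)
  st <- init_world_state(cfg)
  forage_all <- list(list(type = "forage"), idle_action())
  sat <- st$satiety[1]; stock <- st$stocks[1]
  for (t in 1:10) {
    sw <- step_world(st, forage_all, cfg)
    st <- sw$state
    y <- min(stock, cfg$y0)           # oracle recurrence
    sat <- min(sat + y, cfg$satiety_max)
    stock <- stock - y
    if (t %% 3 == 0) sat <- max(sat - 1, 0)
    expect_equal(st$satiety[1], sat, tolerance = 1e-12)
    expect_equal(st$stocks[1], stock, tolerance = 1e-12)
  }
})

test_that("banished agents take no world actions until return", {
  config <- load_scenario("adam-apple")
  tr <- run_simulation(config, seed = 1)
  sanction_tick <- tr$events$tick[tr$events$type == "sanction"][1]
  after <- tr$events[tr$events$tick > sanction_tick &
                       tr$events$actor == "adam" & !is.na(tr$events$actor), ]
  expect_false(any(after$type %in% c("forage", "share", "conceal",
                                     "declaration", "signal")))
  acts <- tr$actions[tr$actions$agent == "adam" &
                       tr$actions$tick > sanction_tick, "action"]
  expect_true(all(acts == "idle"))
})

test_that("unknown scenario names list the available fixtures", {
  expect_error(load_scenario("nope"), "adam-apple")
  cfgm <- load_scenario("adam-apple")
  expect_s3_class(cfgm$world, "world_config")
  expect_equal(cfgm$world$p_detect, 1)
  expect_equal(length(cfgm$agents), 4L)
})
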