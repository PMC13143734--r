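test_that("polarization index matches closed forms", {
  expect_equal(polarization_index(c(0.4, 0.4, 0.4)), 0)
  expect_equal(polarization_index(c(0, 0, 1, 1)), 1)
  expect_equal(polarization_index(c(0, 0.5, 1)), 2 * sqrt(1 / 6))
  expect_error(polarization_index(0.5), "at least 2")
})

test_that("mean polarization averages per-trial indices", {
  expect_equal(mean_polarization(list(c(0, 1)))$mean, 1)
  mp <- mean_polarization(list(c(0, 1), c(0.5, 0.5)))
  expect_equal(mp$mean, 0.5)
  expect_equal(mp$S, 2L)
  ten <- mean_polarization(rep(list(c(0.2, 0.8)), 10))
  expect_equal(ten$mean, polarization_index(c(0.2, 0.8)), tolerance = 1e-12)
  expect_error(mean_polarization(list()), "empty")
})

fake_trace_events <- function(symbol, group, valence = NULL) {
  n <- length(symbol)
  if (is.null(valence)) valence <- rep(2L, n)
  list(events = data.frame(tick = seq_len(n), type = "signal",
                           actor = "a", target = NA_character_,
                           amount = NA_real_, symbol = symbol,
                           group = group, valence = valence,
                           reason = NA_character_))
}

test_that("signal mutual information matches closed forms", {
  # perfect binary correspondence with uniform marginals: 1 bit
  tr <- fake_trace_events(rep(c(1L, 2L), 20), rep(c("A", "B"), 20))
  expect_equal(signal_mutual_information(tr, "sender-group"), 1)
  # independence: 0 bits
  tr2 <- fake_trace_events(rep(c(1L, 2L, 1L, 2L), 10),
                           rep(c("A", "A", "B", "B"), 10))
  expect_equal(signal_mutual_information(tr2, "sender-group"), 0)
  # single repeated symbol: 0 bits
  tr3 <- fake_trace_events(rep(1L, 10), rep(c("A", "B"), 5))
  expect_equal(signal_mutual_information(tr3, "sender-group"), 0)
  expect_error(signal_mutual_information(fake_trace_events(1L, "A"),
                                         window = c(5, 6)), "no signal")
})

test_that("fitness summary equals the hand summation", {
  lp <- log(softmax(c(-2, 0, 2)))
  obs <- data.frame(tick = 1:3, agent = "a", satiety_bin = c(1L, 2L, 3L),
                    yield_bin = 2L, partner = NA_character_,
                    partner_action = "none", signal = 0L, declared = FALSE)
  obs2 <- obs; obs2$agent <- "b"
  tr <- list(observations = rbind(obs, obs2), ids = c("a", "b"),
             groups = c("g1", "g2"),
             config = list(agents = list(list(controller = "V1"),
                                         list(controller = "cooperator"))))
  fit <- fitness_summary(tr)
  expect_equal(fit$per_agent$fitness,
               rep(lp[1] + lp[2] + lp[3], 2))
  expect_equal(unname(fit$per_group), rep(lp[1] + lp[2] + lp[3], 2))
  # identical observation streams give identical fitness
  expect_equal(fit$per_agent$fitness[1], fit$per_agent$fitness[2])
})

test_that("seeded runs are bit-identical and T = 0 yields an empty trace", {
  cfg <- focal_config("V2", T = 15L, watch = TRUE)
  t1 <- run_simulation(cfg, seed = 7)
  t2 <- run_simulation(cfg, seed = 7)
  expect_identical(t1$actions, t2$actions)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$comparisons, t2$comparisons)
  expect_identical(t1$free_energy, t2$free_energy)
  t0 <- run_simulation(focal_config("V1", T = 0L), seed = 1)
  expect_null(t0$actions)
  expect_equal(t0$ticks, 0L)
})

test_that("trace files are valid JSON lines with a header manifest", {
  tr <- run_simulation(focal_config("V1", T = 5L), seed = 3)
  path <- tempfile(fileext = ".jsonl")
  write_trace(tr, path)
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  expect_equal(recs[[1]]$kind, "header")
  expect_equal(recs[[1]]$seed, 3L)
  expect_equal(recs[[1]]$index_base, 1L)
  kinds <- vapply(recs, `[[`, character(1), "kind")
  expect_true(all(c("action", "event") %in% kinds))
  unlink(path)
})

test_that("parameter sweeps cover the value-seed cross product", {
  cfg <- focal_config("V1", T = 5L)
  out <- run_sweep(cfg, "world.stranger_rate", c(0.2, 0.8), seeds = 1:2)
  expect_equal(nrow(out), 4L)
  expect_setequal(unique(out$value), c(0.2, 0.8))
  expect_error(run_sweep(cfg, "world.stranger_rate", numeric(0), 1),
               "empty")
  expect_error(run_sweep(cfg, "world.not_a_field.x", 1, 1), "unresolvable")
  csv <- tempfile(fileext = ".csv")
  run_sweep(cfg, "experiment.T", c(3L), seeds = 1L, out_csv = csv)
  expect_true(startsWith(readLines(csv, n = 1), "#"))
  unlink(csv)
})

test_that("config YAML round-trips through write and read", {
  config <- load_scenario("adam-apple")
  path <- tempfile(fileext = ".yaml")
  write_config_yaml(config, path)
  back <- read_config_yaml(path)
  expect_equal(back$world$p_detect, config$world$p_detect)
  expect_equal(length(back$agents), length(config$agents))
  expect_equal(nrow(back$experiment$pairing_script),
               nrow(config$experiment$pairing_script))
  t1 <- run_simulation(config, seed = 2)
  t2 <- run_simulation(back, seed = 2)
  expect_identical(t1$events, t2$events)
  unlink(path)
})

test_that("typing alignment scores the best permutation", {
  typing <- list(a = c(0.9, 0.1), b = c(0.8, 0.2), c = c(0.1, 0.9))
  truth <- c(a = "coop", b = "coop", c = "def")
  expect_equal(typing_alignment(typing, truth), 1)
  flipped <- list(a = c(0.1, 0.9), b = c(0.2, 0.8), c = c(0.9, 0.1))
  expect_equal(typing_alignment(flipped, truth), 1)  # label-permutation safe
  expect_true(is.na(typing_alignment(typing["a"], truth)))
})
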