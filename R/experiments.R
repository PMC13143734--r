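# Closed-loop simulation harness: world plus a mixed population of
# controllers (inference agents V1/V2/V3, scripted behavioural profiles,
# lightweight watchers), trace assembly, and the metrics the prediction
# harnesses consume. Metrics are computed post-hoc from traces only.

COOPERATOR_SHARE_P <- 0.9
DEFECTOR_CONCEAL_P <- 0.5

obs_action_map <- c(cooperate = "share", defect = "forage",
                    conceal = "conceal")

# convert a world observation bundle to model outcome indices
world_obs_to_model <- function(wobs, slot, n_signals) {
  c(satiety_obs = wobs$satiety_bin,
    yield_obs = wobs$yield_bin,
    partner_id_obs = slot,
    partner_action_obs = match(wobs$partner_action, partner_moves()),
    signal_obs = if (wobs$signal > 0L) wobs$signal else n_signals + 1L,
    declaration_obs = if (isTRUE(wobs$declared)) 2L else 1L)
}

#' Run a closed-loop multi-agent simulation
#'
#' Steps the world and every agent for `T` ticks and assembles a complete
#' trace: actions, observations, events, free-energy reports, running model
#' comparisons of every watcher, per-agent effective alpha, and
#' structure-learning events. Identical `config` and `seed` give a
#' bit-identical trace.
#'
#' @param config List with sections `world` (arguments of [world_config()]),
#'   `agents` (one list per agent: `id`, `controller` in
#'   `"V1" "V2" "V3" "cooperator" "defector" "observer" "scripted"`,
#'   optional `group`, `alpha`, `preferences`, `watch`, `type_labels`,
#'   `horizon`, `policy_actions`), and `experiment` (`T`, `mode`, `theta`,
#'   `hysteresis`, optional `pairing_script` and `action_script` data
#'   frames).
#' @param seed Integer seed for all randomness.
#' @return Object of class `trace`.
#' @export
run_simulation <- function(config, seed = 1L) {
  set.seed(as.integer(seed))
  cfg <- if (inherits(config$world, "world_config")) config$world
         else do.call(world_config, config$world)
  acfg <- config$agents
  N <- cfg$n_agents
  if (length(acfg) != N) {
    stop("config validation: agents section must list exactly n_agents (",
         N, ") entries", call. = FALSE)
  }
  excfg <- config$experiment %||% list()
  TT <- as.integer(excfg$T %||% 50L)
  mode <- excfg$mode %||% "sample"
  theta <- excfg$theta %||% 0.5
  hyst <- excfg$hysteresis %||% 0.1
  pairing_script <- excfg$pairing_script
  action_script <- excfg$action_script

  ids <- vapply(seq_len(N), function(i) acfg[[i]]$id %||% paste0("agent-", i),
                character(1))
  groups <- vapply(seq_len(N), function(i) acfg[[i]]$group %||% "band-A",
                   character(1))
  alpha0 <- vapply(seq_len(N), function(i) as.numeric(acfg[[i]]$alpha %||% 0.5),
                   numeric(1))
  state <- init_world_state(cfg, groups, alpha0)

  # behavioural model pair shared by all watchers: per-action log evidence
  # ratios and the prior log-odds term are context constants here
  bm <- behavioral_model_pair(n_partner_slots = min(N, 4L),
                              n_signals = cfg$n_signals)
  ctx <- ms_context(bm$culture)
  lr <- vapply(c("forage", "share", "conceal"), function(a) {
    log(predictive_likelihood(bm$culture, a, ctx)) -
      log(predictive_likelihood(bm$ego, a, ctx))
  }, numeric(1))
  dG <- delta_G(bm$culture, bm$ego, ctx)

  agents <- vector("list", N)
  for (i in seq_len(N)) {
    a <- acfg[[i]]
    ctrl <- a$controller %||% "cooperator"
    ag <- list(ctrl = ctrl, id = ids[i],
               watch = isTRUE(a$watch) || ctrl == "observer",
               comparisons = list())
    if (ctrl %in% c("V1", "V2", "V3")) {
      spec <- foraging_model_spec(
        n_partner_slots = min(N, a$n_partner_slots %||% 4L),
        n_signals = cfg$n_signals,
        preferences = a$preferences %||% "cultural",
        horizon = a$horizon %||% 2L,
        policy_actions = a$policy_actions %||% c("forage", "share", "conceal"))
      spec$type_labels <- a$type_labels %||% c("in-group", "out-group")
      spec$alpha <- a$alpha %||% 0.5
      spec$expansion_K <- a$expansion_K %||% 2L
      ag$model <- make_agent_model(ctrl, spec)
      ag$astate <- init_agent_state(ag$model, alpha_eff = alpha0[i])
    }
    agents[[i]] <- ag
  }

  # column-wise accumulators (amortized growth)
  acc <- new.env(parent = emptyenv())
  acc_init <- function(name, proto, n0 = 256L) {
    assign(name, list(n = 0L, cols = lapply(proto, function(p) {
      rep(p, n0)
    })), envir = acc)
  }
  acc_push <- function(name, row) {
    a <- get(name, envir = acc)
    n <- a$n + 1L
    if (n > length(a$cols[[1L]])) {
      a$cols <- lapply(a$cols, function(col) c(col, rep(col[1L][NA],
                                                        length(col))))
    }
    for (k in seq_along(row)) a$cols[[k]][n] <- row[[k]]
    a$n <- n
    assign(name, a, envir = acc)
  }
  acc_df <- function(name) {
    a <- get(name, envir = acc)
    if (a$n == 0L) return(NULL)
    as.data.frame(lapply(a$cols, function(col) col[seq_len(a$n)]))
  }
  acc_init("actions", list(tick = NA_integer_, agent = NA_character_,
                           action = NA_character_), TT * N)
  acc_init("obs", list(tick = NA_integer_, agent = NA_character_,
                       satiety_bin = NA_integer_, yield_bin = NA_integer_,
                       partner = NA_character_,
                       partner_action = NA_character_, signal = NA_integer_,
                       declared = NA), TT * N)
  acc_init("fe", list(tick = NA_integer_, agent = NA_character_,
                      total = NA_real_, accuracy = NA_real_,
                      complexity1 = NA_real_, complexity2 = NA_real_,
                      transcendental = NA_real_))
  acc_init("cmp", list(tick = NA_integer_, observer = NA_character_,
                       target = NA_character_, delta_F = NA_real_,
                       delta_G = NA_real_, log_odds = NA_real_,
                       posterior = NA_real_, n_evidence = NA_integer_))
  acc_init("exp", list(tick = NA_integer_, agent = NA_character_,
                       K = NA_integer_))
  acc_init("alpha", list(tick = NA_integer_, agent = NA_character_,
                         alpha_eff = NA_real_), TT * N)
  typing_mat <- matrix(NA_real_, N, N)

  wobs <- vector("list", N)

  scripted_action <- function(i, t) {
    if (!is.null(action_script)) {
      hit <- action_script[action_script$agent == ids[i] &
                             action_script$tick == t, , drop = FALSE]
      if (nrow(hit) > 0L) {
        r <- hit[1L, ]
        tgt <- if ("target" %in% names(r) && !is.na(r$target)) {
          match(r$target, ids)
        } else NA_integer_
        sym <- if ("symbol" %in% names(r) && !is.na(r$symbol)) r$symbol
               else NA_integer_
        return(list(type = as.character(r$action), target = tgt,
                    symbol = sym))
      }
    }
    list(type = "forage")
  }

  for (t in seq_len(TT)) {
    actions <- vector("list", N)
    for (i in seq_len(N)) {
      if (!(state$tick + 1L > state$banished_until[i])) {
        actions[[i]] <- idle_action()
        next
      }
      ag <- agents[[i]]
      oi <- wobs[[i]]
      act <- NULL

      # watcher update: score the partner's observed action, maybe declare
      if (ag$watch && !is.null(oi) && !is.na(oi$partner_id) &&
          oi$partner_action %in% names(obs_action_map)) {
        tgt <- oi$partner_id
        key <- ids[tgt]
        cmp <- ag$comparisons[[key]] %||% new_model_comparison(key, dG)
        cmp$delta_F <- cmp$delta_F + lr[[obs_action_map[[oi$partner_action]]]]
        cmp$n_evidence <- cmp$n_evidence + 1L
        cmp$log_odds <- cmp$delta_F + cmp$delta_G
        cmp$posterior <- logistic_capped(cmp$log_odds)
        dv <- detect_violation(cmp, declarer_id = ids[i], tick = t,
                               theta_deviant = theta, hysteresis = hyst)
        cmp <- dv$cmp
        ag$comparisons[[key]] <- cmp
        typing_mat[i, tgt] <- cmp$posterior
        acc_push("cmp", list(t, ids[i], key, cmp$delta_F, cmp$delta_G,
                             cmp$log_odds, cmp$posterior, cmp$n_evidence))
        if (!is.null(dv$declaration)) {
          act <- list(type = "declare", target = tgt)
        }
      }

      if (is.null(act)) {
        act <- switch(ag$ctrl,
          cooperator = if (stats::runif(1) < COOPERATOR_SHARE_P) {
            list(type = "share")
          } else list(type = "forage"),
          defector = if (stats::runif(1) < DEFECTOR_CONCEAL_P) {
            list(type = "conceal")
          } else list(type = "forage"),
          observer = list(type = "forage"),
          scripted = scripted_action(i, t),
          { # inference controllers
            if (is.null(oi)) list(type = "forage") else {
              pid_chr <- if (is.na(oi$partner_id)) NA_character_
                         else ids[oi$partner_id]
              sl <- slot_for_partner(ag$astate, pid_chr,
                                     ag$model$levels[[1L]]$factor_sizes[["partner_id"]])
              ag$astate <- sl$state
              mobs <- world_obs_to_model(oi, sl$slot, cfg$n_signals)
              ag$astate$alpha_eff <- state$alpha_eff[i]
              expanded_before <- length(ag$model$levels)
              st <- step_agent(ag$model, mobs, ag$astate,
                               partner_id = pid_chr, mode = mode)
              ag$model <- st$model; ag$astate <- st$state
              if (length(ag$model$levels) > expanded_before) {
                acc_push("exp", list(t, ids[i],
                  length(ag$model$levels[[2L]]$type_labels)))
              }
              acc_push("fe", list(t, ids[i], st$report$total,
                                  st$report$accuracy,
                                  st$report$complexity[[1L]],
                                  st$report$complexity[[2L]],
                                  st$report$transcendental))
              aname <- ag$model$actions[st$action]
              if (startsWith(aname, "signal_")) {
                list(type = "signal",
                     symbol = as.integer(sub("signal_", "", aname)))
              } else if (aname == "declare") {
                if (is.na(oi$partner_id)) list(type = "forage")
                else list(type = "declare", target = oi$partner_id)
              } else list(type = aname)
            }
          })
      }
      agents[[i]] <- ag
      actions[[i]] <- act
    }

    pov <- NULL
    if (!is.null(pairing_script)) {
      hit <- pairing_script[pairing_script$tick == t, , drop = FALSE]
      if (nrow(hit) > 0L) {
        pov <- cbind(match(hit$a, ids), match(hit$b, ids))
      }
    }
    sw <- step_world(state, actions, cfg, typing = typing_mat,
                     pairing_override = pov)
    state <- sw$state
    wobs <- sw$obs

    for (i in seq_len(N)) {
      acc_push("actions", list(t, ids[i], state$executed[i] %||% "idle"))
      if (!is.null(wobs[[i]])) {
        o <- wobs[[i]]
        acc_push("obs", list(t, ids[i], o$satiety_bin, o$yield_bin,
                             if (is.na(o$partner_id)) NA_character_
                             else ids[o$partner_id],
                             o$partner_action, o$signal, o$declared))
      }
      acc_push("alpha", list(t, ids[i], state$alpha_eff[i]))
    }
  }

  events <- events_to_df(state$events, ids)
  out <- list(seed = as.integer(seed), config = config, ticks = TT,
              ids = ids, groups = groups,
              actions = acc_df("actions"),
              observations = acc_df("obs"),
              free_energy = acc_df("fe"),
              comparisons = acc_df("cmp"),
              expansions = acc_df("exp"),
              alpha = acc_df("alpha"),
              events = events,
              final_state = state, agents = agents)
  class(out) <- "trace"
  out
}

events_to_df <- function(events, ids) {
  get <- function(e, f, default) if (is.null(e[[f]])) default else e[[f]]
  n <- length(events)
  df <- data.frame(
    tick = vapply(events, function(e) as.integer(e$tick), integer(1)),
    type = vapply(events, function(e) e$type, character(1)),
    actor = vapply(events, function(e) {
      a <- get(e, "actor", NA_integer_)
      if (is.na(a)) NA_character_ else ids[a]
    }, character(1)),
    target = vapply(events, function(e) {
      a <- get(e, "target", NA_integer_)
      if (is.na(a)) NA_character_ else ids[a]
    }, character(1)),
    amount = vapply(events, function(e) as.numeric(get(e, "amount",
                                                       NA_real_)),
                    numeric(1)),
    symbol = vapply(events, function(e) as.integer(get(e, "symbol",
                                                       NA_integer_)),
                    integer(1)),
    group = vapply(events, function(e) get(e, "group", NA_character_),
                   character(1)),
    valence = vapply(events, function(e) as.integer(get(e, "valence",
                                                        NA_integer_)),
                     integer(1)),
    reason = vapply(events, function(e) get(e, "reason", NA_character_),
                    character(1)))
  if (n == 0L) df <- df[0L, ]
  df
}

#' @export
print.trace <- function(x, ...) {
  cat("<trace> (indices 1-based)", x$ticks, "ticks,", length(x$ids),
      "agents; events:", nrow(x$events),
      "; declarations:", sum(x$events$type == "declaration"), "\n")
  invisible(x)
}

#' Write a trace as JSON lines
#'
#' One record per line with a `kind` field
#' (`action|observation|event|free-energy|comparison|alpha|expansion`),
#' schema-stable, so any figure can be recomputed from the file alone.
#'
#' @param trace A `trace`.
#' @param path Output file path.
#' @return `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- list(kind = "header", schema = "transcend-trace-1",
                 index_base = 1L, seed = trace$seed, ticks = trace$ticks,
                 agents = as.list(trace$ids))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  emit <- function(df, kind) {
    if (is.null(df) || nrow(df) == 0L) return(invisible())
    for (r in seq_len(nrow(df))) {
      rec <- c(list(kind = kind), as.list(df[r, ]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  na = "null"), con)
    }
  }
  emit(trace$actions, "action")
  emit(trace$observations, "observation")
  emit(trace$events, "event")
  emit(trace$free_energy, "free-energy")
  emit(trace$comparisons, "comparison")
  emit(trace$expansions, "expansion")
  invisible(path)
}

#' Polarization index of a belief vector
#'
#' Twice the population standard deviation of scalar beliefs in `[0, 1]`:
#' 0 at consensus, 1 when the population splits evenly between the extremes.
#'
#' @param beliefs Numeric vector in `[0, 1]`, length >= 2.
#' @return Scalar in `[0, 1]`.
#' @export
polarization_index <- function(beliefs) {
  if (length(beliefs) < 2L) {
    stop("polarization_index: need at least 2 beliefs", call. = FALSE)
  }
  2 * sqrt(mean((beliefs - mean(beliefs))^2))
}

#' Mean polarization over simulation trials
#'
#' @param trials List of per-trial belief vectors.
#' @return List with `rho` (per-trial indices), `S` and `mean`.
#' @export
mean_polarization <- function(trials) {
  if (length(trials) == 0L) stop("mean_polarization: empty trial list",
                                 call. = FALSE)
  rho <- vapply(trials, polarization_index, numeric(1))
  list(rho = rho, S = length(rho), mean = mean(rho))
}

#' Per-observer belief scalars from a trace
#'
#' Each watcher's scalar belief summarizes its final P(cultural) over the
#' targets it has watched. With `weight = "evidence"` (default) each
#' target's final posterior is weighted by the number of observations the
#' watcher collected on it — the attention-weighted reading of "watched",
#' through which attention bias can shape the opinion an agent forms.
#' `weight = "target"` is the unweighted mean over scored targets.
#'
#' @param trace A `trace`.
#' @param weight `"evidence"` or `"target"`.
#' @return Named numeric vector (one entry per observer with comparisons).
#' @export
belief_scalars <- function(trace, weight = c("evidence", "target")) {
  weight <- match.arg(weight)
  cmp <- trace$comparisons
  if (is.null(cmp) || nrow(cmp) == 0L) return(numeric(0))
  out <- c()
  for (o in unique(cmp$observer)) {
    sub <- cmp[cmp$observer == o, ]
    per_target <- do.call(rbind, lapply(split(sub, sub$target), function(d) {
      k <- which.max(d$tick)
      data.frame(p = d$posterior[k], n = d$n_evidence[k])
    }))
    out[o] <- if (weight == "evidence") {
      sum(per_target$p * per_target$n) / sum(per_target$n)
    } else mean(per_target$p)
  }
  out
}

# plug-in mutual information of a 2-way contingency table, in bits
mi_plugin <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  unname(mi)
}

#' Mutual information between signal symbols and a sender label
#'
#' Plug-in estimate over the signal events of a tick window, in bits.
#' `"sender-group"` uses the sender's group tag, `"sender-valence"` the
#' sender's satiety level at emission (low versus not-low) — a direct
#' indication of internal state. Computed per window to expose signal
#' migration from valence toward group identity.
#'
#' @param trace A `trace`.
#' @param label `"sender-group"` or `"sender-valence"`.
#' @param window Optional `c(from, to)` tick range.
#' @return MI in bits.
#' @export
signal_mutual_information <- function(trace,
                                      label = c("sender-group",
                                                "sender-valence"),
                                      window = NULL) {
  label <- match.arg(label)
  ev <- trace$events
  sig <- ev[ev$type == "signal", , drop = FALSE]
  if (!is.null(window)) {
    sig <- sig[sig$tick >= window[1L] & sig$tick <= window[2L], , drop = FALSE]
  }
  if (nrow(sig) == 0L) stop("signal_mutual_information: no signal events ",
                            "in window", call. = FALSE)
  lab <- if (label == "sender-group") sig$group else (sig$valence <= 1L)
  mi_plugin(sig$symbol, lab)
}

#' Cumulative preference fitness per agent and group
#'
#' Fitness is the sum over ticks of the log preference probability assigned
#' to the realized satiety observation, under the stated preference vector
#' (the common currency across agent versions). Deterministic given the
#' trace.
#'
#' @param trace A `trace`.
#' @param C_satiety Log-preference vector over the 3 satiety bins.
#' @return List with `per_agent` (data frame: agent, group, controller,
#'   fitness, ticks) and `per_group` means.
#' @export
fitness_summary <- function(trace, C_satiety = c(-2, 0, 2)) {
  lp <- log(softmax(C_satiety))
  ob <- trace$observations
  ctrl <- vapply(trace$config$agents, function(a) {
    a$controller %||% "cooperator"
  }, character(1))
  names(ctrl) <- trace$ids
  per <- do.call(rbind, lapply(split(ob, ob$agent), function(d) {
    data.frame(agent = d$agent[1L], fitness = sum(lp[d$satiety_bin]),
               ticks = nrow(d))
  }))
  per$group <- trace$groups[match(per$agent, trace$ids)]
  per$controller <- ctrl[per$agent]
  grp <- vapply(split(per$fitness, per$group), mean, numeric(1))
  list(per_agent = per[, c("agent", "group", "controller", "fitness",
                           "ticks")],
       per_group = grp)
}

# set a value at a dotted path ("world.gamma_att") inside a nested config
modify_path <- function(node, keys, value) {
  k <- keys[1L]
  if (length(keys) == 1L) {
    node[[k]] <- value
    return(node)
  }
  if (is.null(node[[k]])) stop("sweep: unresolvable parameter path",
                               call. = FALSE)
  node[[k]] <- modify_path(node[[k]], keys[-1L], value)
  node
}

#' Sweep one configuration parameter over values and seeds
#'
#' Runs the cross-product of `values` and `seeds`, one summary row each:
#' mean fitness, belief polarization over watchers, declaration count, and
#' the signal-MI endpoints of the run.
#'
#' @param config Simulation config (see [run_simulation()]).
#' @param param_path Dotted path into the config, e.g. `"world.gamma_att"`.
#' @param values Values to assign at the path.
#' @param seeds Integer seeds.
#' @param out_csv Optional path; when given, the summary table is written as
#'   CSV with a comment header naming the parameter and seeds.
#' @return Data frame with one row per (value, seed).
#' @export
run_sweep <- function(config, param_path, values, seeds, out_csv = NULL) {
  if (length(values) == 0L) stop("run_sweep: empty value list", call. = FALSE)
  rows <- list()
  for (v in values) {
    cfg_v <- modify_path(config, strsplit(param_path, ".",
                                          fixed = TRUE)[[1L]], v)
    for (s in seeds) {
      tr <- run_simulation(cfg_v, seed = s)
      fit <- fitness_summary(tr)
      bs <- belief_scalars(tr)
      rho <- if (length(bs) >= 2L) polarization_index(bs) else NA_real_
      n_decl <- sum(tr$events$type == "declaration")
      mi_g <- tryCatch(signal_mutual_information(tr, "sender-group"),
                       error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        param = param_path, value = v, seed = s,
        mean_fitness = mean(fit$per_agent$fitness),
        polarization = rho, n_declarations = n_decl, mi_group = mi_g)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) {
    con <- file(out_csv, "wt")
    writeLines(paste0("# sweep ", param_path, " over [",
                      paste(values, collapse = ", "), "], seeds [",
                      paste(seeds, collapse = ", "), "]"), con)
    utils::write.csv(out, con, row.names = FALSE)
    close(con)
  }
  out
}

#' Best-permutation alignment of typing beliefs with ground-truth labels
#'
#' Assigns each partner its maximum-posterior type and scores the agreement
#' with the true partner labels under the best permutation of type indices.
#'
#' @param typing Named list of categorical typing posteriors (per partner).
#' @param truth Named vector of true labels for the same partners.
#' @return Accuracy in `[0, 1]`, or `NA` if fewer than 2 scored partners.
#' @export
typing_alignment <- function(typing, truth) {
  common <- intersect(names(typing), names(truth))
  if (length(common) < 2L) return(NA_real_)
  assign <- vapply(typing[common], which.max, integer(1))
  K <- max(assign, 2L)
  true_f <- as.integer(factor(truth[common]))
  perms <- permutations_of(seq_len(max(K, max(true_f))))
  best <- 0
  for (p in perms) {
    acc <- mean(p[assign] == true_f)
    best <- max(best, acc)
  }
  best
}

permutations_of <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}
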