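# The generative process: a patch-based foraging world with cooperative
# yields, signalling, concealment, public declarations, sanctions
# (confiscation and banishment) and stranger-encounter scheduling. All
# randomness flows through R's global RNG so a seeded run is bit-identical
# on rerun. Indices are 1-based, as everywhere in this package.

#' Construct and validate a world configuration
#'
#' @param n_agents Number of agents (>= 2).
#' @param n_patches Number of resource patches (>= 1).
#' @param patch_init,patch_cap Initial stock and carrying capacity per patch.
#' @param regen Regeneration rate r in `[0, 1]`: stock relaxes toward the cap
#'   by `r * (cap - stock)` per tick.
#' @param y0 Base per-forager yield.
#' @param coop_c Cooperation coefficient c >= 0: per-forager yield scales as
#'   `y0 * (1 + c * (n - 1))` when n foragers work a patch together.
#' @param n_signals Signal alphabet size.
#' @param stranger_rate Probability an encounter partner is drawn among
#'   non-familiar agents.
#' @param gamma_att Attention bias >= 0: familiar partners are drawn with
#'   probability proportional to `exp(gamma_att * P(cultural))`.
#' @param p_detect Probability a co-located observer detects a concealment.
#' @param confiscate Whether sanctions confiscate the target's inventory.
#' @param banish_ticks Banishment duration in ticks (0 disables).
#' @param alpha_increment Increase of every observer's effective alpha per
#'   consumed declaration (capped at 1).
#' @param consensus_k Number of concurring declarations required before a
#'   sanction fires.
#' @param f_min Co-located tick count above which a pair counts as familiar.
#' @param satiety_decay_every Ticks between one-unit satiety decays.
#' @param satiety_max Satiety ceiling in units.
#' @param encounter_rate Per-tick probability an agent seeks a partner
#'   (values < 1 give sparse encounter regimes).
#' @param conceal_lookback Ticks during which a concealment can still be
#'   verified by a declaration.
#' @return Object of class `world_config`.
#' @export
world_config <- function(n_agents, n_patches = 2L, patch_init = 10,
                         patch_cap = 10, regen = 0.1, y0 = 1, coop_c = 0.5,
                         n_signals = 2L, stranger_rate = 0.2, gamma_att = 0,
                         p_detect = 0.5, confiscate = TRUE,
                         banish_ticks = 20L, alpha_increment = 0.1,
                         consensus_k = 1L, f_min = 3L,
                         satiety_decay_every = 5L, satiety_max = 6,
                         encounter_rate = 1, conceal_lookback = 10L) {
  cfg <- list(n_agents = as.integer(n_agents), n_patches = as.integer(n_patches),
              patch_init = patch_init, patch_cap = patch_cap, regen = regen,
              y0 = y0, coop_c = coop_c, n_signals = as.integer(n_signals),
              stranger_rate = stranger_rate, gamma_att = gamma_att,
              p_detect = p_detect, confiscate = isTRUE(confiscate),
              banish_ticks = as.integer(banish_ticks),
              alpha_increment = alpha_increment,
              consensus_k = as.integer(consensus_k), f_min = as.integer(f_min),
              satiety_decay_every = as.integer(satiety_decay_every),
              satiety_max = satiety_max, encounter_rate = encounter_rate,
              conceal_lookback = as.integer(conceal_lookback))
  with(cfg, {
    if (n_agents < 2L) stop("n_agents: must be >= 2", call. = FALSE)
    if (n_patches < 1L) stop("n_patches: must be >= 1", call. = FALSE)
    if (regen < 0 || regen > 1) stop("regen: must lie in [0, 1]", call. = FALSE)
    if (coop_c < 0) stop("coop_c: must be >= 0", call. = FALSE)
    if (stranger_rate < 0 || stranger_rate > 1) {
      stop("stranger_rate: must lie in [0, 1]", call. = FALSE)
    }
    if (gamma_att < 0) stop("gamma_att: must be >= 0", call. = FALSE)
    if (p_detect < 0 || p_detect > 1) stop("p_detect: must lie in [0, 1]",
                                           call. = FALSE)
    if (banish_ticks < 0L) stop("banish_ticks: must be >= 0", call. = FALSE)
    if (alpha_increment < 0) stop("alpha_increment: must be >= 0",
                                  call. = FALSE)
    if (encounter_rate < 0 || encounter_rate > 1) {
      stop("encounter_rate: must lie in [0, 1]", call. = FALSE)
    }
  })
  class(cfg) <- "world_config"
  cfg
}

#' Initialize a world state
#'
#' @param cfg A `world_config`.
#' @param groups Character vector of group tags (recycled to `n_agents`).
#' @param alpha0 Starting effective alpha per agent (recycled).
#' @return Object of class `world_state`.
#' @export
init_world_state <- function(cfg, groups = "band-A", alpha0 = 0.5) {
  N <- cfg$n_agents
  st <- list(tick = 0L,
             stocks = rep(cfg$patch_init, cfg$n_patches),
             patch = ((seq_len(N) - 1L) %% cfg$n_patches) + 1L,
             inventory = numeric(N),
             satiety = rep(3, N),
             banished_until = rep(0L, N),
             group = rep_len(groups, N),
             alpha_eff = rep_len(alpha0, N),
             familiarity = matrix(0L, N, N),
             partner = rep(NA_integer_, N),
             last_conceal = rep(-1000000L, N),
             consumed_cum = 0, regen_cum = 0,
             pending_decl = list(),
             events = list())
  st$initial_total <- sum(st$stocks) + sum(st$inventory)
  class(st) <- "world_state"
  st
}

is_active <- function(state, i = NULL) {
  act <- state$tick > state$banished_until
  if (is.null(i)) act else act[i]
}

add_event <- function(state, type, actor = NA_integer_,
                      target = NA_integer_, ...) {
  state$events[[length(state$events) + 1L]] <-
    list(tick = state$tick, type = type, actor = actor, target = target, ...)
  state
}

#' Pair active agents for this tick
#'
#' Each participating agent (per `encounter_rate`) is matched: with
#' probability `stranger_rate` a uniformly random non-familiar partner,
#' otherwise a familiar partner drawn with probability proportional to
#' `exp(gamma_att * P(cultural))` — confirmation-biased attention. Pairings
#' are symmetric; an odd agent forages alone. Paired partners are
#' co-located for the tick.
#'
#' @param state A `world_state`.
#' @param typing N x N matrix of P(cultural) estimates (row = observer);
#'   `NA` entries count as 0.5. `NULL` for uniform.
#' @param cfg A `world_config`.
#' @return Updated state (fields `partner`, `patch`, `familiarity`).
#' @export
schedule_encounters <- function(state, typing = NULL, cfg) {
  N <- cfg$n_agents
  state$partner <- rep(NA_integer_, N)
  active <- which(is_active(state))
  if (length(active) < 2L) return(state)
  joins <- stats::runif(length(active)) < cfg$encounter_rate
  pool <- active[joins]
  if (length(pool) < 2L) return(state)
  ord <- sample(pool)
  unpaired <- rep(TRUE, N)
  unpaired[setdiff(seq_len(N), pool)] <- FALSE
  for (i in ord) {
    if (!unpaired[i]) next
    cand <- setdiff(which(unpaired), i)
    if (length(cand) == 0L) break
    j <- choose_partner(i, cand, state$familiarity, typing, cfg)
    state$partner[i] <- j; state$partner[j] <- i
    unpaired[i] <- FALSE; unpaired[j] <- FALSE
    state$patch[j] <- state$patch[i]
    state$familiarity[i, j] <- state$familiarity[i, j] + 1L
    state$familiarity[j, i] <- state$familiarity[j, i] + 1L
  }
  state
}

#' Draw one encounter partner for an agent
#'
#' The sampling kernel behind [schedule_encounters()]: with probability
#' `stranger_rate` a uniform draw among non-familiar candidates (falling
#' back to all candidates), otherwise a draw among familiar candidates
#' (same fallback) weighted by `exp(gamma_att * P(cultural))`, with
#' unscored candidates counted at 0.5.
#'
#' @param i Chooser index.
#' @param cand Candidate partner indices.
#' @param familiarity Co-location count matrix.
#' @param typing P(cultural) matrix (row = observer) or `NULL`.
#' @param cfg A `world_config`.
#' @return One index from `cand`.
#' @export
choose_partner <- function(i, cand, familiarity, typing, cfg) {
  fam <- cand[familiarity[i, cand] >= cfg$f_min]
  nonfam <- setdiff(cand, fam)
  use_stranger <- stats::runif(1) < cfg$stranger_rate
  pool <- if (use_stranger) {
    if (length(nonfam) > 0L) nonfam else cand
  } else {
    if (length(fam) > 0L) fam else cand
  }
  w <- rep(1, length(pool))
  if (!use_stranger && cfg$gamma_att > 0 && !is.null(typing)) {
    p <- typing[i, pool]
    p[is.na(p)] <- 0.5
    w <- exp(cfg$gamma_att * p)
  }
  if (length(pool) == 1L) pool
  else pool[sample.int(length(pool), 1L, prob = w)]
}

#' Per-forager yield from a patch
#'
#' `yield = min(stock / n, y0 * (1 + c * (n - 1)))`: cooperation raises the
#' per-capita yield until the patch cannot support it.
#'
#' @param n_foragers Number of extractors (>= 1).
#' @param stock Current patch stock (>= 0).
#' @param cfg A `world_config` (uses `y0` and `coop_c`).
#' @return List with `yield` (per forager) and `stock` (after extraction).
#' @export
harvest_yield <- function(n_foragers, stock, cfg) {
  stopifnot(n_foragers >= 1L, stock >= 0)
  y <- min(stock / n_foragers, cfg$y0 * (1 + cfg$coop_c * (n_foragers - 1)))
  list(yield = y, stock = stock - n_foragers * y)
}

#' Patch regeneration toward the carrying capacity
#'
#' @param stock Current stock (vectorized).
#' @param r Regeneration rate in `[0, 1]`.
#' @param cap Carrying capacity.
#' @return `min(cap, stock + r * (cap - stock))`.
#' @export
regenerate <- function(stock, r, cap) {
  stopifnot(r >= 0, r <= 1)
  pmin(cap, stock + r * (cap - stock))
}

# an action is a list(type = ..., target = int, symbol = int, patch = int)
idle_action <- function() list(type = "idle")

#' Apply one tick's actions to the world
#'
#' Forage and conceal extract from the agent's patch under the cooperative
#' yield rule; forage feeds the agent directly, conceal diverts the yield to
#' private inventory (world-true, detectable by co-located observers).
#' Share distributes the sharer's inventory evenly over all co-located
#' active agents' satiety. Signals are heard by co-located agents; declare
#' enqueues a declaration for [apply_sanctions()]. Illegal actions (e.g. by
#' banished agents) are rejected and logged; the simulation never aborts
#' mid-run.
#'
#' @param state A `world_state` (after [schedule_encounters()]).
#' @param actions List of N action lists (`list(type, target, symbol, patch)`).
#' @param cfg A `world_config`.
#' @return Updated state; executed action types are recorded in
#'   `state$executed` and all effects in the event log.
#' @export
apply_actions <- function(state, actions, cfg) {
  N <- cfg$n_agents
  executed <- rep("idle", N)
  legal <- function(i, type) {
    if (!is_active(state, i)) return(type %in% c("move", "idle"))
    TRUE
  }
  # legality screen
  for (i in seq_len(N)) {
    a <- actions[[i]] %||% idle_action()
    if (is.null(a$type)) a$type <- "idle"
    if (!legal(i, a$type)) {
      state <- add_event(state, "rejected", actor = i, reason = a$type)
      actions[[i]] <- idle_action()
    } else actions[[i]] <- a
  }
  types <- vapply(actions, function(a) a$type, character(1))

  # extraction, patch by patch
  extractors <- which(types %in% c("forage", "conceal") & is_active(state))
  for (p in sort(unique(state$patch[extractors]))) {
    who <- extractors[state$patch[extractors] == p]
    h <- harvest_yield(length(who), state$stocks[p], cfg)
    state$stocks[p] <- h$stock
    for (i in who) {
      if (types[i] == "forage") {
        state$satiety[i] <- min(state$satiety[i] + h$yield, cfg$satiety_max)
        state$consumed_cum <- state$consumed_cum + h$yield
        state <- add_event(state, "forage", actor = i, amount = h$yield)
      } else {
        state$inventory[i] <- state$inventory[i] + h$yield
        state$last_conceal[i] <- state$tick
        state <- add_event(state, "conceal", actor = i, amount = h$yield)
      }
      executed[i] <- types[i]
    }
  }

  for (i in which(types == "share" & is_active(state))) {
    co <- which(state$patch == state$patch[i] & is_active(state))
    amount <- state$inventory[i]
    if (amount > 0 && length(co) > 0L) {
      per <- amount / length(co)
      state$satiety[co] <- pmin(state$satiety[co] + per, cfg$satiety_max)
      state$consumed_cum <- state$consumed_cum + amount
      state$inventory[i] <- 0
    }
    state <- add_event(state, "share", actor = i, amount = amount)
    executed[i] <- "share"
  }

  for (i in which(startsWith(types, "signal") & is_active(state))) {
    k <- actions[[i]]$symbol %||% 1L
    state <- add_event(state, "signal", actor = i, symbol = as.integer(k),
                       group = state$group[i],
                       valence = satiety_bin(state$satiety[i]))
    executed[i] <- "signal"
  }

  for (i in which(types == "declare" & is_active(state))) {
    tgt <- actions[[i]]$target
    if (is.null(tgt) || is.na(tgt)) {
      state <- add_event(state, "rejected", actor = i, reason = "declare-no-target")
      next
    }
    state$pending_decl[[length(state$pending_decl) + 1L]] <-
      list(declarer = i, target = as.integer(tgt), tick = state$tick)
    state <- add_event(state, "declaration", actor = i,
                       target = as.integer(tgt))
    executed[i] <- "declare"
  }

  for (i in which(types == "move")) {
    p <- actions[[i]]$patch %||% (state$patch[i] %% cfg$n_patches + 1L)
    if (is_active(state, i)) state$patch[i] <- as.integer(p)
    executed[i] <- "move"
  }

  state$executed <- executed
  state
}

#' Consume pending declarations and apply sanctions
#'
#' A target with at least `consensus_k` distinct declarers is sanctioned if
#' its concealment is world-true (a conceal within `conceal_lookback`
#' ticks): inventory confiscated back to the patch (if configured),
#' banishment set, and every other active agent's effective alpha raised by
#' `alpha_increment` (capped at 1) — the declaration makes cultural
#' expectations dominate in the audience. Declarations against innocents
#' are logged as false declarations and apply no sanction.
#'
#' @param state A `world_state`.
#' @param cfg A `world_config`.
#' @return Updated state.
#' @export
apply_sanctions <- function(state, cfg) {
  if (length(state$pending_decl) == 0L) return(state)
  targets <- vapply(state$pending_decl, function(d) d$target, integer(1))
  declarers <- vapply(state$pending_decl, function(d) d$declarer, integer(1))
  for (tgt in unique(targets)) {
    who <- unique(declarers[targets == tgt])
    if (length(who) < cfg$consensus_k) next
    guilty <- (state$tick - state$last_conceal[tgt]) <= cfg$conceal_lookback
    if (!guilty) {
      state <- add_event(state, "false_declaration", actor = who[1L],
                         target = tgt)
      next
    }
    if (cfg$confiscate && state$inventory[tgt] > 0) {
      p <- state$patch[tgt]
      if (is.na(p)) p <- 1L
      state$stocks[p] <- state$stocks[p] + state$inventory[tgt]
      state$inventory[tgt] <- 0
    }
    if (cfg$banish_ticks > 0L) {
      state$banished_until[tgt] <- state$tick + cfg$banish_ticks
      state$patch[tgt] <- NA_integer_
      if (!is.na(state$partner[tgt])) {
        state$partner[state$partner[tgt]] <- NA_integer_
        state$partner[tgt] <- NA_integer_
      }
    }
    observers <- setdiff(which(is_active(state)), tgt)
    state$alpha_eff[observers] <-
      pmin(1, state$alpha_eff[observers] + cfg$alpha_increment)
    state <- add_event(state, "sanction", actor = who[1L], target = tgt,
                       n_declarers = length(who))
  }
  state$pending_decl <- list()
  state
}

satiety_bin <- function(units) 1L + (units >= 2) + (units >= 5)
stock_bin <- function(stock, cap) 1L + (stock >= cap / 3) + (stock >= 2 * cap / 3)

# world-level observation synthesis; model-facing index conversion happens
# in the simulation loop
synthesize_observations <- function(state, cfg) {
  N <- cfg$n_agents
  tick_events <- Filter(function(e) e$tick == state$tick, state$events)
  any_decl <- any(vapply(tick_events, function(e) e$type == "declaration",
                         logical(1)))
  obs <- vector("list", N)
  for (i in seq_len(N)) {
    if (!is_active(state, i)) next
    j <- state$partner[i]
    pact <- "none"; psig <- 0L; pid <- NA_integer_; pgroup <- NA_character_
    if (!is.na(j) && is_active(state, j)) {
      pid <- j; pgroup <- state$group[j]
      ex <- state$executed[j]
      pact <- switch(ex,
        share = "cooperate",
        forage = "defect",
        conceal = if (stats::runif(1) < cfg$p_detect) "conceal" else "defect",
        "none")
      if (ex == "signal") {
        sig_ev <- Filter(function(e) e$type == "signal" && e$actor == j,
                         tick_events)
        if (length(sig_ev) > 0L) psig <- sig_ev[[1L]]$symbol
      }
    }
    obs[[i]] <- list(
      satiety_bin = satiety_bin(state$satiety[i]),
      yield_bin = stock_bin(state$stocks[state$patch[i]], cfg$patch_cap),
      partner_id = pid, partner_group = pgroup,
      partner_action = pact, signal = psig,
      declared = any_decl)
  }
  obs
}

#' Advance the world by one tick
#'
#' Order: encounter scheduling, action application, sanction processing,
#' satiety decay, regeneration, observation synthesis. Total resource
#' (stocks + inventories + cumulative consumed satiety units) is invariant
#' up to regeneration inflow.
#'
#' @param state A `world_state`.
#' @param actions List of N action lists (one per agent; banished agents'
#'   submissions are ignored).
#' @param cfg A `world_config`.
#' @param typing Optional N x N P(cultural) matrix for attention-biased
#'   pairing.
#' @param pairing_override Optional 2-column matrix of forced pairs for this
#'   tick.
#' @return List `(state, obs)`; `obs` is a list of per-agent world-level
#'   observation bundles (`NULL` for banished agents).
#' @export
step_world <- function(state, actions, cfg, typing = NULL,
                       pairing_override = NULL) {
  state$tick <- state$tick + 1L
  state <- schedule_encounters(state, typing, cfg)
  if (!is.null(pairing_override) && nrow(pairing_override) > 0L) {
    for (r in seq_len(nrow(pairing_override))) {
      a <- pairing_override[r, 1L]; b <- pairing_override[r, 2L]
      if (!is_active(state, a) || !is_active(state, b)) next
      old_a <- state$partner[a]; old_b <- state$partner[b]
      if (!is.na(old_a) && old_a != b) state$partner[old_a] <- NA_integer_
      if (!is.na(old_b) && old_b != a) state$partner[old_b] <- NA_integer_
      state$partner[a] <- b; state$partner[b] <- a
      state$patch[b] <- state$patch[a]
      state$familiarity[a, b] <- state$familiarity[a, b] + 1L
      state$familiarity[b, a] <- state$familiarity[b, a] + 1L
    }
  }
  state <- apply_actions(state, actions, cfg)
  state <- apply_sanctions(state, cfg)
  if (cfg$satiety_decay_every > 0L &&
      state$tick %% cfg$satiety_decay_every == 0L) {
    act <- is_active(state)
    state$satiety[act] <- pmax(state$satiety[act] - 1, 0)
  }
  before <- sum(state$stocks)
  state$stocks <- regenerate(state$stocks, cfg$regen, cfg$patch_cap)
  state$regen_cum <- state$regen_cum + (sum(state$stocks) - before)
  obs <- synthesize_observations(state, cfg)
  list(state = state, obs = obs)
}

#' Resource-conservation bookkeeping error
#'
#' @param state A `world_state`.
#' @return Absolute deviation of
#'   `stocks + inventories + consumed - initial - regenerated` from zero.
#' @export
world_conservation_error <- function(state) {
  abs(sum(state$stocks) + sum(state$inventory) + state$consumed_cum -
        state$initial_total - state$regen_cum)
}
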