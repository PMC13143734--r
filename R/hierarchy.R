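# Two-level message passing. Level 1 is the world-facing POMDP; level 2
# holds a categorical typing factor over the current partner. Ascending
# messages are soft (posterior-weighted) summaries of the level-1 posterior;
# descending messages are empirical priors over one level-1 factor, blended
# with the bottom-up belief by the cultural precision alpha.

#' Ascend a level-1 posterior to a level-2 soft observation
#'
#' Applies the summary map linearly to the posterior of the linked level-1
#' factor and renormalizes, keeping level-1 uncertainty instead of sampling
#' a hard outcome.
#'
#' @param level1_posterior Categorical over the linked level-1 factor.
#' @param summary_map Matrix (summary categories x level-1 states) whose
#'   columns are categorical.
#' @return Categorical soft-observation vector over summary categories.
#' @export
ascend <- function(level1_posterior, summary_map) {
  if (ncol(summary_map) != length(level1_posterior)) {
    stop("ascend: summary_map shape mismatch", call. = FALSE)
  }
  normalize(as.vector(summary_map %*% level1_posterior))
}

# level-2 perception from a soft observation: expected log-likelihood update
infer_type_from_message <- function(message, A2, prior2) {
  ll <- as.vector(crossprod(log(pmax(A2, 1e-300)), message))
  softmax(log(pmax(prior2, 1e-300)) + ll)
}

#' Log-linear blend of a base prior with a top-down prediction
#'
#' `out propto exp((1 - alpha) ln base + alpha ln top)`. At `alpha = 0` the
#' base prior is reproduced exactly; at `alpha = 1` the top-down prediction
#' dominates. Zero entries of the top-down prediction where the base is
#' positive are floored at 1e-12 before the blend.
#'
#' @param base,top Categorical vectors on the same support.
#' @param alpha Real in `[0, 1]`.
#' @return Categorical vector.
#' @export
blend_log_linear <- function(base, top, alpha) {
  stopifnot(length(base) == length(top))
  if (alpha < 0 || alpha > 1) stop("alpha: must lie in [0, 1]", call. = FALSE)
  if (alpha == 0) return(base)
  top[top <= 0 & base > 0] <- 1e-12
  if (alpha == 1) return(normalize(top))
  w <- exp((1 - alpha) * log(pmax(base, 1e-300)) +
           alpha * log(pmax(top, 1e-300)))
  w[base <= 0 & top <= 0] <- 0
  normalize(w)
}

#' Descending empirical prior from the typing posterior
#'
#' The link array maps the level-2 typing posterior to a prediction over the
#' linked level-1 factor; that prediction is blended log-linearly with the
#' base prior under the precision gain alpha.
#'
#' @param level2_posterior Categorical over types.
#' @param link Link matrix M (level-1 states x types), columns categorical.
#' @param base_prior Categorical base prior over the linked level-1 factor.
#' @param alpha Cultural precision in `[0, 1]`.
#' @return List of class `descending_prior`: `prior` (the blended
#'   categorical), `top_down` (the raw prediction) and `alpha`.
#' @export
descend <- function(level2_posterior, link, base_prior, alpha) {
  if (ncol(link) != length(level2_posterior)) {
    stop("descend: link shape mismatch", call. = FALSE)
  }
  top <- as.vector(link %*% level2_posterior)
  out <- list(prior = blend_log_linear(base_prior, top, alpha),
              top_down = normalize(top), alpha = alpha)
  class(out) <- "descending_prior"
  out
}

#' Initialize the runtime state of an inference agent
#'
#' @param model An `agent_model`.
#' @param alpha_eff Starting effective precision (defaults to the model's
#'   configured alpha, or 0 for single-level agents).
#' @return A mutable-state list threaded through [step_agent()].
#' @export
init_agent_state <- function(model, alpha_eff = NULL) {
  l1 <- model$levels[[1L]]
  has_l2 <- length(model$levels) > 1L
  if (is.null(alpha_eff)) {
    alpha_eff <- if (has_l2) model$levels[[2L]]$alpha else 0
  }
  list(tick = 0L,
       prior1 = l1$D,
       belief1 = l1$D,
       typing = list(),          # per-partner-id level-2 posteriors
       slot_map = character(0),  # world ids occupying identity slots
       alpha_eff = alpha_eff,
       f_history = new_model_history(W = 50L),
       surprisal = numeric(0),   # partner-action surprisal ring buffer
       move_counts = NULL,       # per-partner observed-move counts (V3)
       last_policy = NA_integer_)
}

# map a world partner id to an identity-slot index; new ids take the first
# free slot, overflow lands on the final ("stranger") slot
slot_for_partner <- function(state, partner_id, n_slots) {
  if (is.na(partner_id) || partner_id == "") return(list(slot = n_slots,
                                                         state = state))
  i <- match(partner_id, state$slot_map)
  if (!is.na(i)) return(list(slot = i, state = state))
  if (length(state$slot_map) < n_slots - 1L) {
    state$slot_map <- c(state$slot_map, partner_id)
    return(list(slot = length(state$slot_map), state = state))
  }
  list(slot = n_slots, state = state)
}

#' Run one full perception-action cycle for an agent
#'
#' Level-1 perception, ascending message, level-2 typing update (two-level
#' agents only), descending alpha-blended prior, expected-free-energy policy
#' evaluation under that blended belief, action selection, Dirichlet
#' learning, and bookkeeping for structure learning (V3). A V1 agent skips
#' the ascend/descend stages entirely, and a two-level agent with
#' `alpha = 0` follows the identical level-1 path.
#'
#' @param model An `agent_model`.
#' @param obs Named integer vector of outcome indices per modality.
#' @param state Runtime state from [init_agent_state()].
#' @param partner_id World identifier of the current partner (`NA` if
#'   foraging alone); used to key typing beliefs.
#' @param mode Action selection mode, `"sample"` or `"argmax"`.
#' @param learn_modalities Modalities whose likelihood counts are updated.
#' @return List with `action` (control index), `state`, `model` (updated
#'   counts / possible V3 expansion) and `report` (a `free_energy_report`).
#' @export
step_agent <- function(model, obs, state, partner_id = NA_character_,
                       mode = "sample",
                       learn_modalities = "partner_action_obs") {
  l1 <- model$levels[[1L]]
  obs <- as.integer(unlist(obs))
  has_l2 <- length(model$levels) > 1L

  # predictive surprisal of the partner-action channel, recorded before the
  # update; this is the channel structure learning listens to
  pa <- match("partner_action_obs", names(l1$modality_sizes))
  if (!is.na(pa)) {
    none_idx <- l1$modality_sizes[pa]
    if (obs[pa] != none_idx) {
      Amat <- matrix(l1$A[[pa]], nrow = dim(l1$A[[pa]])[1L])
      p_pred <- sum(Amat[obs[pa], ] * as.vector(outer_joint(state$prior1)))
      state$surprisal <- c(utils::tail(state$surprisal, 49L),
                           -log(max(p_pred, 1e-300)))
    }
  }

  q1 <- tryCatch(infer_states(obs, state$prior1, l1$A),
                 error = function(e) stop("agent step failed at tick ",
                                          state$tick + 1L, ": ",
                                          conditionMessage(e), call. = FALSE))
  report <- free_energy(q1, obs, model,
                        top_down = list(prior = state$prior1))
  state$f_history <- push_history(state$f_history, report$total)

  belief_eff <- q1
  if (has_l2) {
    l2 <- model$levels[[2L]]
    tf <- l2$target_factor
    prior2 <- if (!is.na(partner_id) && !is.null(state$typing[[partner_id]])) {
      state$typing[[partner_id]]
    } else l2$D2
    if (state$tick %% l2$k_timescale == 0L) {
      msg <- ascend(q1[[tf]], l2$summary_map)
      q2 <- infer_type_from_message(msg, l2$A2, prior2)
    } else q2 <- prior2
    if (!is.na(partner_id)) state$typing[[partner_id]] <- q2
    dp <- descend(q2, l2$M, q1[[tf]], state$alpha_eff)
    belief_eff[[tf]] <- dp$prior
  }

  evals <- evaluate_policies_with_belief(model, belief_eff)
  action <- select_action(evals$posterior, model$policies, mode = mode)
  state$last_policy <- attr(action, "policy")

  # learning
  if (model$eta_a > 0) {
    for (mname in learn_modalities) {
      mi <- match(mname, names(l1$modality_sizes))
      if (is.na(mi)) next
      model$levels[[1L]]$pA[[mi]] <-
        update_likelihood(model$levels[[1L]]$pA[[mi]], q1, obs[mi],
                          model$eta_a)
      model$levels[[1L]]$A[[mi]] <-
        dirichlet_expectation(model$levels[[1L]]$pA[[mi]])
    }
  }
  if (model$eta_e > 0) {
    model$levels[[1L]]$pE <- update_habits(model$levels[[1L]]$pE,
                                           evals$posterior, model$eta_e)
    model$levels[[1L]]$E <- dirichlet_expectation(model$levels[[1L]]$pE)
  }

  # V3 bookkeeping: per-partner move statistics and expansion trigger
  if (model$version == "V3" && !has_l2 && !is.na(pa)) {
    if (is.null(state$move_counts)) state$move_counts <- list()
    if (!is.na(partner_id) && obs[pa] != l1$modality_sizes[pa]) {
      mc <- state$move_counts[[partner_id]] %||% rep(0, l1$modality_sizes[pa])
      mc[obs[pa]] <- mc[obs[pa]] + 1
      state$move_counts[[partner_id]] <- mc
    }
    if (model$expandable &&
        failure_detected(state$f_history, eps = 0.01, cooldown = 100L) &&
        length(state$surprisal) >= 50L &&
        mean(state$surprisal) >= surprise_floor()) {
      model <- expand_typing_factor(model, K = model$expansion_K,
                                    move_counts = state$move_counts)
      state$f_history$last_expansion <- state$tick
      # seed typing beliefs from accumulated per-partner statistics
      l2 <- model$levels[[2L]]
      for (pid in names(state$move_counts)) {
        mc <- state$move_counts[[pid]]
        if (sum(mc) >= 3) {
          state$typing[[pid]] <-
            infer_type_from_message(normalize(mc), l2$A2, l2$D2)
        }
      }
    }
  }

  # roll the effective belief forward as the next tick's prior
  u <- as.integer(action)
  state$prior1 <- lapply(seq_along(belief_eff), function(f) {
    normalize(as.vector(l1$B[[f]][, , u] %*% belief_eff[[f]]))
  })
  names(state$prior1) <- names(l1$D)
  state$belief1 <- q1
  state$tick <- state$tick + 1L

  list(action = u, state = state, model = model, report = report,
       policy_posterior = evals$posterior)
}

# policy evaluation given an externally blended belief: lean inner loop
# (per-call precomputation of flattened likelihoods, preference
# distributions and entropy vectors; step-1 results cached per action since
# open-loop policies share prefixes)
evaluate_policies_with_belief <- function(model, belief) {
  l1 <- model$levels[[1L]]
  Amat <- lapply(l1$A, function(a) matrix(a, nrow = dim(a)[1L]))
  Hs <- lapply(Amat, function(m) colSums(-xlogx(m)))
  Cdist <- lapply(l1$C, softmax)
  score <- function(qs) {
    qj <- as.vector(outer_joint(qs))
    g <- 0
    for (m in seq_along(Amat)) {
      o_pred <- as.vector(Amat[[m]] %*% qj)
      g <- g + kl_div(o_pred, Cdist[[m]]) + sum(qj * Hs[[m]])
    }
    g
  }
  roll <- function(qs, u) {
    lapply(seq_along(qs), function(f) as.vector(l1$B[[f]][, , u] %*% qs[[f]]))
  }
  pol <- model$policies
  step1 <- list()
  G <- numeric(nrow(pol))
  for (p in seq_len(nrow(pol))) {
    u1 <- pol[p, 1L]
    key <- as.character(u1)
    if (is.null(step1[[key]])) {
      qs1 <- roll(belief, u1)
      step1[[key]] <- list(qs = qs1, g = score(qs1))
    }
    s1 <- step1[[key]]
    g <- s1$g
    qs <- s1$qs
    if (ncol(pol) > 1L) {
      for (tt in 2L:ncol(pol)) {
        qs <- roll(qs, pol[p, tt])
        g <- g + score(qs)
      }
    }
    G[p] <- g
  }
  list(G = G,
       posterior = policy_posterior(G, l1$E, model$gamma_policy))
}
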