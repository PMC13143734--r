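# Transcendental model selection: score an observed agent's actions under a
# cultural behavioural model (deep preferences: sharing and standing matter)
# versus an egocentric one (own satiety only), accumulate the log evidence
# ratio, and emit violation declarations when the typing posterior collapses.
#
# log-odds = dF + dG: dF accumulates ln P(o|m_culture) - ln P(o|m_ego) over
# observed actions; dG = G(m_ego) - G(m_culture) encodes prior model odds
# under P(m) propto exp(-G(m)), so the model with lower expected free energy
# in context is a-priori more probable. (The source convention equates
# ln P(m) - ln P(m') with G(m) - G(m'); under P(m) propto exp(-G(m)) those
# two differ by a sign, and this package keeps the convention that lower G
# means higher prior probability.)

LOG_ODDS_CAP <- 50

#' Build the cultural / egocentric behavioural model pair
#'
#' Both models share likelihoods and transitions and differ only in
#' preferences: the cultural model prefers seeing cooperation and not being
#' declared, the egocentric model cares about its own satiety alone. They
#' act over single-action policies so their action probabilities are
#' directly comparable.
#'
#' @param n_partner_slots,n_signals Sizes passed to [foraging_model_spec()].
#' @param actions Character vector of scoreable actions.
#' @return List with elements `culture` and `ego`, both `agent_model`s.
#' @export
behavioral_model_pair <- function(n_partner_slots = 4L, n_signals = 2L,
                                  actions = c("forage", "share", "conceal")) {
  mk <- function(pref) {
    m <- make_agent_model("V1", foraging_model_spec(
      n_partner_slots, n_signals, preferences = pref, horizon = 1L,
      policy_actions = actions))
    attr(m, "role") <- if (pref == "cultural") "culture" else "ego"
    m
  }
  list(culture = mk("cultural"), ego = mk("ego"))
}

#' Default scoring context for model comparison
#'
#' @param model Either behavioural model (shared structure).
#' @param belief Optional per-factor belief describing the observed agent's
#'   situation; defaults to the model's state prior.
#' @param alpha Precision with which the cultural model's typing expectation
#'   (cooperative partner) is blended into its planning belief.
#' @return List of class `ms_context`.
#' @export
ms_context <- function(model, belief = NULL, alpha = 0) {
  list(belief = belief %||% model$levels[[1L]]$D, alpha = alpha)
}

# softmax action distribution of a behavioural model in context
action_distribution <- function(m, context) {
  belief <- context$belief
  if (!is.null(context$alpha) && context$alpha > 0 &&
      identical(attr(m, "role"), "culture")) {
    tf <- match("partner_move", names(m$levels[[1L]]$factor_sizes))
    if (!is.na(tf)) {
      coop <- c(0.7, 0.1, 0.05, 0.15)
      belief[[tf]] <- blend_log_linear(belief[[tf]], coop, context$alpha)
    }
  }
  ev <- evaluate_policies_with_belief(m, belief)
  acts <- m$policies[, 1L]
  stats::setNames(as.numeric(ev$posterior), m$actions[acts])
}

#' Probability a behavioural model assigns to an observed action
#'
#' @param m An `agent_model` from [behavioral_model_pair()].
#' @param observed_action Action name or control index.
#' @param context An `ms_context`.
#' @return Strictly positive probability (floored at 1e-12).
#' @export
predictive_likelihood <- function(m, observed_action, context = ms_context(m)) {
  p <- action_distribution(m, context)
  key <- if (is.numeric(observed_action)) m$actions[observed_action]
         else as.character(observed_action)
  if (is.na(key) || !key %in% names(p)) {
    stop("predictive_likelihood: action '", observed_action,
         "' is not in the context's legal set", call. = FALSE)
  }
  max(unname(p[key]), 1e-12)
}

#' Create an empty model-comparison record for a watched agent
#'
#' @param target_id Identifier of the watched agent.
#' @param delta_G Prior log-odds term from [delta_G()] (added once).
#' @return Object of class `model_comparison` with running `delta_F`,
#'   `log_odds`, `posterior` (P(cultural)), `n_evidence`, and the hysteresis
#'   arming flag used by [detect_violation()].
#' @export
new_model_comparison <- function(target_id, delta_G = 0) {
  cmp <- list(target = target_id, delta_F = 0, delta_G = delta_G,
              n_evidence = 0L, armed = FALSE, declared = FALSE)
  cmp$log_odds <- cmp$delta_F + cmp$delta_G
  cmp$posterior <- logistic_capped(cmp$log_odds)
  class(cmp) <- "model_comparison"
  cmp
}

logistic_capped <- function(x) {
  x <- max(min(x, LOG_ODDS_CAP), -LOG_ODDS_CAP)
  1 / (1 + exp(-x))
}

#' Accumulate one observation's evidence into a model comparison
#'
#' Adds `ln P(o | m_culture) - ln P(o | m_ego)` to the running `delta_F`,
#' increments the evidence count and refreshes the log-odds and posterior.
#'
#' @param cmp A `model_comparison`.
#' @param observed_action Action name or index.
#' @param context An `ms_context`.
#' @param models Pair from [behavioral_model_pair()].
#' @return Updated `model_comparison`.
#' @export
accumulate_delta_F <- function(cmp, observed_action, context, models) {
  pc <- predictive_likelihood(models$culture, observed_action, context)
  pe <- predictive_likelihood(models$ego, observed_action, context)
  cmp$delta_F <- cmp$delta_F + (log(pc) - log(pe))
  cmp$n_evidence <- cmp$n_evidence + 1L
  cmp$log_odds <- cmp$delta_F + cmp$delta_G
  cmp$posterior <- logistic_capped(cmp$log_odds)
  cmp
}

#' Prior log-odds between the behavioural models in a context
#'
#' Aggregates each model's expected free energy over its action set with a
#' softmin at the policy temperature, and returns
#' `G(m_ego) - G(m_culture)`: the model with lower expected free energy
#' receives higher prior probability.
#'
#' @param m_culture,m_ego The behavioural models.
#' @param context An `ms_context`.
#' @return Real prior log-odds.
#' @export
delta_G <- function(m_culture, m_ego, context = ms_context(m_culture)) {
  agg <- function(m) {
    ev <- evaluate_policies_with_belief(m, context$belief)
    g <- m$gamma_policy
    x <- -g * ev$G
    M <- max(x)
    -(M + log(sum(exp(x - M)))) / g
  }
  agg(m_ego) - agg(m_culture)
}

#' Typing belief implied by a model comparison
#'
#' `P(cultural) = logistic(delta_F + delta_G)` with the log-odds capped at
#' +/-50 for numeric safety.
#'
#' @param cmp A `model_comparison`.
#' @return Named categorical `c(cultural = p, egocentric = 1 - p)`.
#' @export
model_posterior <- function(cmp) {
  p <- logistic_capped(cmp$delta_F + cmp$delta_G)
  c(cultural = p, egocentric = 1 - p)
}

#' Threshold crossing with hysteresis: emit a violation declaration
#'
#' A declaration is emitted exactly when P(cultural) falls below
#' `theta_deviant` having previously reached at least
#' `theta_deviant + hysteresis` (the armed condition); the comparison then
#' dis-arms until the posterior recovers above the arming level, so an
#' oscillation around the threshold yields a single declaration.
#'
#' @param cmp A `model_comparison` (carries the armed flag).
#' @param declarer_id,tick Provenance recorded on the declaration.
#' @param theta_deviant Threshold in (0, 1), default 0.5.
#' @param hysteresis Arming margin, default 0.1.
#' @return List `(declaration, cmp)`; `declaration` is `NULL` or a list
#'   `(declarer, target, tick, evidence)` snapshotting the comparison.
#' @export
detect_violation <- function(cmp, declarer_id = NA_character_, tick = NA_integer_,
                             theta_deviant = 0.5, hysteresis = 0.1) {
  stopifnot(theta_deviant > 0, theta_deviant < 1)
  p <- unname(model_posterior(cmp)["cultural"])
  decl <- NULL
  if (!cmp$armed && p >= theta_deviant + hysteresis) cmp$armed <- TRUE
  else if (cmp$armed && p < theta_deviant) {
    decl <- list(declarer = declarer_id, target = cmp$target, tick = tick,
                 evidence = list(delta_F = cmp$delta_F, delta_G = cmp$delta_G,
                                 log_odds = cmp$log_odds,
                                 posterior = p, n_evidence = cmp$n_evidence))
    cmp$armed <- FALSE
  }
  list(declaration = decl, cmp = cmp)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> target", x$target,
      "| dF", format(x$delta_F, digits = 4),
      "| dG", format(x$delta_G, digits = 4),
      "| P(cultural)", format(x$posterior, digits = 4),
      "| n =", x$n_evidence, "\n")
  invisible(x)
}
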