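# Single-level active-inference computations: perception (state posteriors),
# the variational free energy with its accuracy / complexity / transcendental
# decomposition, expected free energy with the pragmatic (risk) and epistemic
# (ambiguity) split, policy selection and Dirichlet learning updates.
# Natural logarithms throughout; only the metrics module converts to bits.

# outer product of per-factor beliefs -> joint array over the factor grid
outer_joint <- function(qs) {
  out <- qs[[1L]]
  if (length(qs) > 1L) for (g in 2L:length(qs)) out <- outer(out, qs[[g]])
  array(out, dim = vapply(qs, length, integer(1)))
}

# joint likelihood P(o | s1..sF) of a fixed observation bundle: elementwise
# product over modalities of the observed outcome's slice of each A array
joint_likelihood <- function(obs, A) {
  lik <- NULL
  for (m in seq_along(A)) {
    d <- dim(A[[m]])
    slice <- array(matrix(A[[m]], nrow = d[1L])[obs[[m]], ], dim = d[-1L])
    lik <- if (is.null(lik)) slice else lik * slice
  }
  lik
}

# sum_{s_{-f}} X(s) * prod_{g != f} q_g(s_g), leaving a vector over factor f
contract_except <- function(X, qs, f) {
  d <- dim(X)
  Xf <- matrix(aperm(X, c(f, seq_along(d)[-f])), nrow = d[f])
  as.vector(Xf %*% as.vector(outer_joint(qs[-f])))
}

#' Infer the level-1 state posterior from an observation bundle
#'
#' Exact Bayes for a single state factor; for several factors a damped
#' mean-field fixed point on the factorized posterior (damping 0.5,
#' tolerance 1e-8, at most 64 sweeps).
#'
#' @param obs Integer vector (or list) of outcome indices, one per modality.
#' @param prior List of per-factor categorical priors (a `BeliefState`).
#' @param A List of likelihood arrays, one per modality.
#' @param damping,tol,max_iter Mean-field iteration controls.
#' @param track When `TRUE`, attach the sequence of mean-field iterates as
#'   attribute `"trajectory"` (for descent diagnostics).
#' @return List of per-factor categorical posteriors, with attributes
#'   `evidence` (exact marginal likelihood for one factor, `NA` otherwise)
#'   and `iters`.
#' @export
infer_states <- function(obs, prior, A, damping = 0.5, tol = 1e-8,
                         max_iter = 64L, track = FALSE) {
  obs <- as.integer(unlist(obs))
  for (m in seq_along(A)) {
    if (obs[m] < 1L || obs[m] > dim(A[[m]])[1L]) {
      stop("infer_states: observation index out of range for modality ", m,
           call. = FALSE)
    }
  }
  lik <- joint_likelihood(obs, A)
  fsizes <- vapply(prior, length, integer(1))
  if (length(prior) == 1L) {
    w <- as.vector(lik) * prior[[1L]]
    ev <- sum(w)
    if (ev <= 0) stop("impossible observation: zero marginal likelihood",
                      call. = FALSE)
    q <- list(w / ev)
    attr(q, "evidence") <- ev
    attr(q, "iters") <- 0L
    return(q)
  }
  # mean-field: q_f propto exp(E_{q_-f}[ln lik] + ln prior_f); the permuted
  # log-likelihood views are fixed across iterations, so build them once
  loglik <- log(pmax(lik, 1e-300))
  dim(loglik) <- fsizes
  nf <- length(fsizes)
  views <- lapply(seq_len(nf), function(f) {
    matrix(aperm(loglik, c(f, seq_len(nf)[-f])), nrow = fsizes[f])
  })
  logprior <- lapply(prior, function(p) log(pmax(p, 1e-300)))
  q <- prior
  ev_check <- sum(outer_joint(prior) * lik)
  if (ev_check <= 0) stop("impossible observation: zero marginal likelihood",
                          call. = FALSE)
  iters <- 0L
  trajectory <- if (track) list(q) else NULL
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (f in seq_len(nf)) {
      w <- as.vector(outer_joint(q[-f]))
      q_new <- softmax(as.vector(views[[f]] %*% w) + logprior[[f]])
      q_new <- damping * q_new + (1 - damping) * q[[f]]
      delta <- max(delta, max(abs(q_new - q[[f]])))
      q[[f]] <- q_new
    }
    if (track) trajectory[[length(trajectory) + 1L]] <- q
    iters <- it
    if (delta < tol) break
  }
  attr(q, "evidence") <- NA_real_
  attr(q, "iters") <- iters
  if (track) attr(q, "trajectory") <- trajectory
  q
}

#' Variational free energy with its hierarchical decomposition
#'
#' Evaluates `F = -accuracy + complexity(level 1) + complexity(level 2) +
#' transcendental` at a given posterior. Accuracy is the expected
#' log-likelihood of the observations; each level's complexity is the KL
#' divergence of that level's posterior from its (possibly top-down) prior;
#' the transcendental term is the KL of the precision posterior from its
#' prior and is 0 when alpha is a fixed scalar. For a one-level agent the
#' higher-order and transcendental entries are 0, and at the exact
#' single-factor posterior the total equals `-ln(evidence)`.
#'
#' @param q List of per-factor categorical posteriors (level 1).
#' @param obs Integer outcome indices per modality.
#' @param model An `agent_model` (its level-1 `A` and `D` are used).
#' @param top_down Optional descending prior (from [descend()]) replacing the
#'   base prior `D`; a list of per-factor categoricals under `$prior`.
#' @param q_level2,prior_level2 Optional level-2 typing posterior/prior.
#' @param q_alpha,prior_alpha Optional precision posterior/prior over an
#'   alpha grid (see [infer_alpha()]).
#' @return Object of class `free_energy_report`: a list with `total`,
#'   `accuracy`, `complexity` (one entry per level) and `transcendental`.
#' @export
free_energy <- function(q, obs, model, top_down = NULL,
                        q_level2 = NULL, prior_level2 = NULL,
                        q_alpha = NULL, prior_alpha = NULL) {
  l1 <- model$levels[[1L]]
  obs <- as.integer(unlist(obs))
  prior <- if (!is.null(top_down)) top_down$prior else l1$D
  lik <- joint_likelihood(obs, l1$A)
  qj <- outer_joint(q)
  pos <- qj > 0
  if (any(pos & (lik <= 0))) {
    accuracy <- -Inf
  } else {
    accuracy <- sum(qj[pos] * log(lik[pos]))
  }
  c1 <- sum(mapply(kl_div, q, prior))
  c2 <- if (!is.null(q_level2)) kl_div(q_level2, prior_level2) else 0
  trans <- if (!is.null(q_alpha)) kl_div(q_alpha, prior_alpha) else 0
  rep <- list(total = -accuracy + c1 + c2 + trans,
              accuracy = accuracy,
              complexity = c(level1 = c1, level2 = c2),
              transcendental = trans)
  class(rep) <- "free_energy_report"
  rep
}

#' @export
print.free_energy_report <- function(x, ...) {
  cat("<free_energy_report> (nats; indices 1-based)\n",
      " total:", format(x$total), "\n",
      " accuracy:", format(x$accuracy), "\n",
      " complexity:", paste(format(x$complexity), collapse = " + "), "\n",
      " transcendental:", format(x$transcendental), "\n")
  invisible(x)
}

# per-modality outcome-entropy vectors over the joint state grid (ambiguity)
modality_entropies <- function(A) {
  lapply(A, function(a) {
    m <- matrix(a, nrow = dim(a)[1L])
    colSums(-xlogx(m))
  })
}

#' Expected free energy of one open-loop policy
#'
#' Rolls the belief forward through `B` for each action of the policy and
#' accumulates, per step, risk (KL of the predicted outcome distribution
#' from the preference distribution `softmax(C)`, the pragmatic term) and
#' ambiguity (expected outcome entropy of `A` under the predicted states,
#' the epistemic term). `G = risk + ambiguity` summed over the horizon.
#'
#' @param policy Integer vector of action indices.
#' @param model An `agent_model`.
#' @param belief List of per-factor categorical beliefs at the current tick.
#' @return List with `G`, `risk`, `ambiguity` and the per-step breakdown.
#' @export
expected_free_energy <- function(policy, model, belief) {
  l1 <- model$levels[[1L]]
  Hs <- modality_entropies(l1$A)
  Cdist <- lapply(l1$C, softmax)
  qs <- belief
  risk <- 0; ambiguity <- 0
  steps <- data.frame(step = seq_along(policy), risk = NA_real_,
                      ambiguity = NA_real_)
  for (t in seq_along(policy)) {
    u <- policy[t]
    qs <- lapply(seq_along(qs), function(f) {
      as.vector(l1$B[[f]][, , u] %*% qs[[f]])
    })
    qj <- as.vector(outer_joint(qs))
    r_t <- 0; a_t <- 0
    for (m in seq_along(l1$A)) {
      Amat <- matrix(l1$A[[m]], nrow = dim(l1$A[[m]])[1L])
      o_pred <- as.vector(Amat %*% qj)
      r_t <- r_t + kl_div(o_pred, Cdist[[m]])
      a_t <- a_t + sum(qj * Hs[[m]])
    }
    risk <- risk + r_t; ambiguity <- ambiguity + a_t
    steps$risk[t] <- r_t; steps$ambiguity[t] <- a_t
  }
  list(G = risk + ambiguity, risk = risk, ambiguity = ambiguity,
       steps = steps)
}

#' Evaluate every policy in the model's policy set
#'
#' @param model An `agent_model`.
#' @param belief Per-factor categorical beliefs.
#' @return Data frame with one row per policy: `G`, `risk`, `ambiguity`,
#'   and `posterior` from [policy_posterior()].
#' @export
evaluate_policies <- function(model, belief) {
  evals <- lapply(seq_len(nrow(model$policies)), function(p) {
    expected_free_energy(model$policies[p, ], model, belief)
  })
  out <- data.frame(policy = seq_along(evals),
                    G = vapply(evals, `[[`, numeric(1), "G"),
                    risk = vapply(evals, `[[`, numeric(1), "risk"),
                    ambiguity = vapply(evals, `[[`, numeric(1), "ambiguity"))
  out$posterior <- policy_posterior(out$G, model$levels[[1L]]$E,
                                    model$gamma_policy)
  out
}

#' Policy posterior from expected free energies and the habit prior
#'
#' `q(pi) propto E(pi) * exp(-gamma_policy * G(pi))`.
#'
#' @param G Numeric vector of expected free energies.
#' @param E Habit prior (categorical over policies).
#' @param gamma_policy Inverse temperature, > 0.
#' @return Categorical vector over policies.
#' @export
policy_posterior <- function(G, E, gamma_policy) {
  stopifnot(length(G) == length(E), gamma_policy > 0)
  softmax(log(pmax(E, 1e-300)) - gamma_policy * G)
}

#' Select a control index from the policy posterior
#'
#' `argmax` is deterministic with a lowest-index tie-break; `sample` draws
#' from the posterior using R's global RNG stream, so it is reproducible
#' under `set.seed()`.
#'
#' @param policy_post Categorical vector over policies.
#' @param policies Integer matrix of open-loop policies (rows).
#' @param mode `"sample"` or `"argmax"`.
#' @return The first control index of the chosen policy, with the chosen
#'   policy row index in attribute `"policy"`.
#' @export
select_action <- function(policy_post, policies,
                          mode = c("sample", "argmax")) {
  mode <- match.arg(mode)
  validate_categorical(policy_post)
  p <- if (mode == "argmax") which.max(policy_post)
       else sample.int(length(policy_post), 1L, prob = policy_post)
  a <- policies[p, 1L]
  attr(a, "policy") <- p
  a
}

#' Dirichlet likelihood update from one observation
#'
#' Adds `eta_a * q(s)` to the observed outcome's row of the counts for one
#' modality; all other rows are unchanged.
#'
#' @param counts Dirichlet count array for one modality (outcome first).
#' @param q Per-factor categorical beliefs.
#' @param obs Observed outcome index for this modality.
#' @param eta_a Learning rate, >= 0.
#' @return Updated count array.
#' @export
update_likelihood <- function(counts, q, obs, eta_a) {
  stopifnot(eta_a >= 0)
  if (eta_a == 0) return(counts)
  d <- dim(counts)
  m <- matrix(counts, nrow = d[1L])
  m[obs, ] <- m[obs, ] + eta_a * as.vector(outer_joint(q))
  array(m, dim = d)
}

#' Habit update from the policy posterior
#'
#' @param e_counts Dirichlet counts over policies.
#' @param policy_post Categorical over policies.
#' @param eta_e Learning rate, >= 0.
#' @return Updated counts.
#' @export
update_habits <- function(e_counts, policy_post, eta_e) {
  stopifnot(eta_e >= 0, length(e_counts) == length(policy_post))
  e_counts + eta_e * policy_post
}

#' Posterior over the precision alpha on a discrete grid
#'
#' Opt-in inference of the cultural precision: given the free energy
#' obtained under each candidate alpha, the posterior is
#' `q(alpha) propto prior(alpha) * exp(-F(alpha))`. The KL of this posterior
#' from its prior is the transcendental term of the free-energy report.
#'
#' @param grid Numeric vector of candidate alpha values in `[0, 1]`.
#' @param per_alpha_F Numeric vector of free energies, one per grid point.
#' @param prior_alpha Categorical prior over the grid.
#' @return Categorical posterior over the grid, with the transcendental KL
#'   in attribute `"transcendental"`.
#' @export
infer_alpha <- function(grid, per_alpha_F, prior_alpha) {
  if (length(grid) != length(per_alpha_F)) {
    stop("infer_alpha: grid and per_alpha_F lengths differ", call. = FALSE)
  }
  validate_categorical(prior_alpha)
  post <- softmax(log(pmax(prior_alpha, 1e-300)) - per_alpha_F)
  attr(post, "transcendental") <- kl_div(post, prior_alpha)
  post
}
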