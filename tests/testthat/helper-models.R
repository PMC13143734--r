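# Fixture builders used across the suite. Everything is generated in code;
# sizes are kept tiny so property loops stay fast.

# random one-factor, possibly multi-modality likelihood model
rand_one_factor <- function(ns = sample(2:5, 1), no = sample(2:4, 1),
                            n_mod = 1L) {
  A <- lapply(seq_len(n_mod), function(m) {
    a <- matrix(stats::rgamma(no * ns, 1) + 0.05, no, ns)
    a <- sweep(a, 2, colSums(a), "/")
    array(a, dim = c(no, ns))
  })
  prior <- list(normalize(stats::rgamma(ns, 1) + 0.05))
  obs <- vapply(A, function(a) sample.int(dim(a)[1L], 1L), integer(1))
  list(A = A, prior = prior, obs = obs, ns = ns)
}

# random two-factor model for mean-field checks
rand_two_factor <- function(n1 = 3L, n2 = 3L, no = 3L, n_mod = 2L) {
  A <- lapply(seq_len(n_mod), function(m) {
    a <- matrix(stats::rgamma(no * n1 * n2, 1) + 0.05, no)
    a <- sweep(a, 2, colSums(a), "/")
    array(a, dim = c(no, n1, n2))
  })
  prior <- list(normalize(stats::rgamma(n1, 1) + 0.05),
                normalize(stats::rgamma(n2, 1) + 0.05))
  obs <- rep(1L, n_mod)
  list(A = A, prior = prior, obs = obs)
}

# minimal 2-state / 2-outcome agent spec (1 factor, 1 modality, 2 actions)
tiny_spec <- function(n_actions = 2L, horizon = 1L) {
  B <- array(0, dim = c(2, 2, n_actions))
  for (u in seq_len(n_actions)) B[, , u] <- diag(2)
  list(factor_sizes = c(s = 2L), modality_sizes = c(o = 2L),
       actions = paste0("u", seq_len(n_actions)),
       A = list(o = array(diag(2), dim = c(2L, 2L))),
       B = list(s = B),
       C = list(o = c(0, 0)),
       D = list(s = c(0.5, 0.5)),
       policies = matrix(seq_len(n_actions), ncol = horizon,
                         nrow = n_actions))
}

# mean-field free energy of a factorized belief (independent oracle form)
mf_free_energy <- function(q, obs, A, prior) {
  lik <- Reduce(`*`, lapply(seq_along(A), function(m) {
    d <- dim(A[[m]])
    array(matrix(A[[m]], nrow = d[1L])[obs[m], ], dim = d[-1L])
  }))
  qj <- Reduce(function(a, b) outer(a, b), q)
  acc <- sum(qj[qj > 0] * log(lik[qj > 0]))
  acc <- if (any(qj > 0 & lik <= 0)) -Inf else acc
  -acc + sum(mapply(kl_div, q, prior))
}

# small simulation config with a focal inference agent among scripted peers
focal_config <- function(version = "V1", alpha = 0.5, T = 30L,
                         n_coop = 2L, n_def = 1L, stranger_rate = 0.5,
                         watch = FALSE) {
  agents <- c(list(list(id = "focal", controller = version,
                        group = "band-A", preferences = "cultural",
                        alpha = alpha, watch = watch)),
              lapply(seq_len(n_coop), function(i) {
                list(id = paste0("coop-", i), controller = "cooperator",
                     group = "band-B")
              }),
              lapply(seq_len(n_def), function(i) {
                list(id = paste0("def-", i), controller = "defector",
                     group = "band-B")
              }))
  list(world = list(n_agents = length(agents), n_patches = 2L,
                    stranger_rate = stranger_rate, p_detect = 1,
                    banish_ticks = 0L),
       agents = agents,
       experiment = list(T = T))
}

# sample an action sequence from a behavioural model's action distribution
sample_actions <- function(model, context, n) {
  p <- vapply(c("forage", "share", "conceal"), function(a) {
    predictive_likelihood(model, a, context)
  }, numeric(1))
  p <- p / sum(p)
  sample(names(p), n, replace = TRUE, prob = p)
}

# column-normalize an A-like array along the outcome dimension
normalize_cols_arr <- function(a) {
  d <- dim(a)
  m <- matrix(a, nrow = d[1L])
  array(sweep(m, 2, colSums(m), "/"), dim = d)
}

# random transition array (next x current x action), columns categorical
rand_B <- function(n, n_act) {
  B <- array(stats::rgamma(n * n * n_act, 1) + 0.05, dim = c(n, n, n_act))
  for (u in seq_len(n_act)) {
    B[, , u] <- sweep(B[, , u, drop = FALSE][, , 1], 2,
                      colSums(B[, , u, drop = FALSE][, , 1]), "/")
  }
  B
}

# naive enumeration oracle for expected free energy (risk + ambiguity),
# independent of the vectorized implementation path
efe_enumeration_oracle <- function(policy, model, belief) {
  l1 <- model$levels[[1L]]
  qs <- belief
  G <- 0
  for (u in policy) {
    qs <- lapply(seq_along(qs), function(f) {
      as.vector(l1$B[[f]][, , u] %*% qs[[f]])
    })
    grid <- as.matrix(expand.grid(lapply(qs, seq_along)))
    p_joint <- apply(grid, 1, function(s) {
      prod(mapply(function(q, si) q[si], qs, s))
    })
    for (m in seq_along(l1$A)) {
      No <- dim(l1$A[[m]])[1L]
      qo <- numeric(No)
      amb <- 0
      for (r in seq_len(nrow(grid))) {
        col <- vapply(seq_len(No), function(o) {
          do.call(`[`, c(list(l1$A[[m]]), list(o), as.list(grid[r, ])))
        }, numeric(1))
        qo <- qo + p_joint[r] * col
        amb <- amb - p_joint[r] * sum(col[col > 0] * log(col[col > 0]))
      }
      Cd <- softmax(l1$C[[m]])
      G <- G + sum(qo[qo > 0] * (log(qo[qo > 0]) - log(Cd[qo > 0]))) + amb
    }
  }
  G
}
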