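# V3 mechanics: detect persistent failure of free-energy reduction, expand
# the model with a typing factor seeded from the agent's own partner
# statistics, and evaluate pruning proposals by analytic Bayesian model
# reduction over Dirichlet normalizers.

#' Create a free-energy history ring buffer
#'
#' @param W Window length (>= 2).
#' @return Object of class `model_history`: values seen so far (at most W),
#'   the total tick count `n`, and the tick of the last expansion.
#' @export
new_model_history <- function(W = 50L) {
  stopifnot(W >= 2L)
  structure(list(values = numeric(0), W = as.integer(W), n = 0L,
                 last_expansion = 0L),
            class = "model_history")
}

#' Push a per-tick total free energy into the history
#'
#' @param history A `model_history`.
#' @param f Total free energy at this tick (nats).
#' @return Updated history (buffer trimmed to the last W values).
#' @export
push_history <- function(history, f) {
  history$values <- utils::tail(c(history$values, f), history$W)
  history$n <- history$n + 1L
  history
}

#' Has free-energy reduction stalled?
#'
#' True iff the buffer is full, the drop from the first half's mean to the
#' second half's mean is below `eps`, and at least `cooldown` ticks have
#' passed since the last expansion (or since the start, for a fresh agent).
#'
#' @param history A `model_history`.
#' @param eps Minimum mean reduction still counted as progress (nats).
#' @param cooldown Minimum ticks between expansions.
#' @return Logical.
#' @export
failure_detected <- function(history, eps = 0.01, cooldown = 100L) {
  v <- history$values
  W <- history$W
  if (length(v) < W) return(FALSE)
  if (history$n - history$last_expansion < cooldown) return(FALSE)
  h <- W %/% 2L
  drop <- mean(v[seq_len(h)]) - mean(v[(W - h + 1L):W])
  drop < eps
}

#' Residual-surprise floor for triggering expansion
#'
#' Expansion requires not only stalled free-energy reduction but residual,
#' unexplainable surprise on the partner-action channel. The floor is the
#' midpoint between the irreducible per-observation surprisal of a single
#' consistent behavioural profile and that of an even two-profile mixture,
#' under the default observation noise: about 0.77 versus 1.22 nats, hence
#' 1.0 nats. A homogeneous population, once learned, sits well below the
#' floor; an unmodelled mixture sits above it.
#'
#' @return Numeric scalar (nats).
#' @export
surprise_floor <- function() 1.0

#' Expand a one-level V3 agent with a typing factor
#'
#' Adds a level-2 factor with K type states. The link array M (and the
#' level-2 likelihood, initialized equal to it) is drawn from Dirichlet
#' distributions centred on the agent's accumulated per-partner outcome
#' statistics: partners with enough observations are grouped into K
#' behavioural clusters and each cluster's mean move distribution becomes a
#' column's Dirichlet mean. With fresh statistics the columns are
#' near-symmetric. Level-1 arrays are untouched. Uses R's global RNG stream.
#'
#' @param model A one-level V3 `agent_model`.
#' @param K Number of type states (>= 2).
#' @param move_counts Named list (per partner id) of observed-move count
#'   vectors, as gathered by [step_agent()].
#' @param concentration Total Dirichlet concentration per column.
#' @param alpha Precision assigned to the new level (defaults 0.6).
#' @return The expanded two-level `agent_model`.
#' @export
expand_typing_factor <- function(model, K = 2L, move_counts = list(),
                                 concentration = 100, alpha = 0.6) {
  if (length(model$levels) > 1L) {
    stop("expand_typing_factor: model already has a typing level",
         call. = FALSE)
  }
  if (model$version != "V3") {
    stop("expand_typing_factor: only V3 agents self-expand", call. = FALSE)
  }
  K <- as.integer(K)
  stopifnot(K >= 2L)
  l1 <- model$levels[[1L]]
  tf <- match("partner_move", names(l1$factor_sizes))
  if (is.na(tf)) tf <- 1L
  nt <- l1$factor_sizes[tf]

  informative <- Filter(function(x) sum(x) >= 3, move_counts)
  centers <- matrix(1 / nt, nt, K)
  if (length(informative) >= K) {
    dists <- t(vapply(informative, function(x) normalize(x + 0.1),
                      numeric(nt)))
    # order partners by their first-category (cooperate) share and split
    # into K quantile groups: a deterministic, scale-free clustering
    ord <- order(dists[, 1L])
    grp <- cut(seq_along(ord), breaks = K, labels = FALSE)
    for (k in seq_len(K)) {
      centers[, K - k + 1L] <- colMeans(dists[ord[grp == k], , drop = FALSE])
    }
  }
  M <- vapply(seq_len(K), function(k) {
    normalize(stats::rgamma(nt, shape = concentration *
                                  pmax(centers[, k], 0.02)))
  }, numeric(nt))

  l2 <- list(n = 2L, type_labels = model$type_labels %||%
               paste0("type-", seq_len(K)),
             alpha = alpha, M = M, A2 = M, summary_map = diag(nt),
             D2 = rep(1 / K, K), target_factor = tf, k_timescale = 1L)
  if (length(l2$type_labels) != K) l2$type_labels <- paste0("type-",
                                                            seq_len(K))
  model$levels[[2L]] <- l2
  model$type_labels <- l2$type_labels
  model
}

log_multivariate_beta <- function(a) sum(lgamma(a)) - lgamma(sum(a))

#' Bayesian model reduction over Dirichlet counts
#'
#' Analytic log-evidence difference of a reduced model relative to the full
#' model, from Dirichlet normalizers alone: with data counts
#' `n = full_counts - full_prior`, the difference is
#' `sum_cols [ln B(a_r + n) - ln B(a_r)] - sum_cols [ln B(a_f + n) - ln B(a_f)]`.
#' A `merge_map` pools the data of merged columns so that one type explains
#' them jointly. Positive values favour the reduction.
#'
#' @param full_counts Posterior Dirichlet counts of the full model
#'   (outcomes x columns).
#' @param reduced_prior Prior counts of the reduced model, congruent in
#'   shape (merged columns carry identical entries).
#' @param full_prior Prior counts of the full model; defaults to all ones.
#' @param merge_map Optional integer vector assigning each full column to a
#'   reduced group.
#' @return Log-evidence difference (reduced minus full), in nats.
#' @export
reduce_model <- function(full_counts, reduced_prior, full_prior = NULL,
                         merge_map = NULL) {
  fc <- as.matrix(full_counts)
  rp <- as.matrix(reduced_prior)
  if (!identical(dim(fc), dim(rp))) {
    stop("reduce_model: shapes are not congruent", call. = FALSE)
  }
  fp <- if (is.null(full_prior)) matrix(1, nrow(fc), ncol(fc))
        else as.matrix(full_prior)
  if (!identical(dim(fc), dim(fp))) {
    stop("reduce_model: full_prior shape mismatch", call. = FALSE)
  }
  n <- fc - fp
  if (any(n < -1e-9)) {
    stop("reduce_model: full_counts must dominate full_prior", call. = FALSE)
  }
  n[n < 0] <- 0
  le_full <- sum(vapply(seq_len(ncol(fc)), function(j) {
    log_multivariate_beta(fp[, j] + n[, j]) - log_multivariate_beta(fp[, j])
  }, numeric(1)))
  groups <- if (is.null(merge_map)) seq_len(ncol(fc)) else as.integer(merge_map)
  le_red <- 0
  for (g in unique(groups)) {
    cols <- which(groups == g)
    ng <- rowSums(n[, cols, drop = FALSE])
    ag <- rp[, cols[1L]]
    le_red <- le_red + log_multivariate_beta(ag + ng) -
      log_multivariate_beta(ag)
  }
  le_red - le_full
}
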