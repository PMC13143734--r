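# Generative-model construction and validation.
#
# An agent model is a plain list (class "agent_model") so that it survives a
# JSON round trip. Level 1 is the world-facing POMDP: likelihoods A (one array
# per modality, outcome index first, then one dimension per state factor),
# transitions B (one array per factor, next x current x action), log-preferences
# C, state priors D, habit prior E over policies, and Dirichlet counts pA/pE
# from which A and E are re-derived after learning. Level 2 (V2, or V3 after
# expansion) carries a single categorical typing factor whose link array M
# predicts one level-1 factor top-down.

#' Primitive world actions
#'
#' The fixed, ordered action alphabet shared by agents and the world:
#' forage, share, conceal, one signal action per symbol, declare, move.
#'
#' @param n_signals Number of signal symbols (>= 1).
#' @return Character vector of action names; positions are the control
#'   indices used everywhere else (1-based, as all indices in this package).
#' @export
world_actions <- function(n_signals = 2L) {
  c("forage", "share", "conceal",
    paste0("signal_", seq_len(n_signals)), "declare", "move")
}

#' Names of the partner-move states / partner-action outcomes
#' @return Character vector `c("cooperate", "defect", "conceal", "none")`.
#' @export
partner_moves <- function() c("cooperate", "defect", "conceal", "none")

# sticky drift matrix on an ordered factor: p_up/p_down mass to the
# neighbouring bin, remainder stays (clamped at the ends)
drift_matrix <- function(n, p_up = 0, p_down = 0) {
  B <- diag(n) * (1 - p_up - p_down)
  for (s in seq_len(n)) {
    up <- min(s + 1L, n); dn <- max(s - 1L, 1L)
    B[up, s] <- B[up, s] + p_up
    B[dn, s] <- B[dn, s] + p_down
  }
  B
}

sticky_matrix <- function(n, stay = 0.9) {
  if (n == 1L) return(matrix(1, 1, 1))
  matrix((1 - stay) / (n - 1), n, n) + diag(n) * (stay - (1 - stay) / (n - 1))
}

# A-array builder: fill array(No, fsizes) from fun(row of joint state indices)
# returning a categorical over outcomes
build_A <- function(No, fsizes, fun) {
  grid <- as.matrix(expand.grid(lapply(fsizes, seq_len)))
  A <- array(0, dim = c(No, fsizes))
  Amat <- matrix(0, No, nrow(grid))
  for (j in seq_len(nrow(grid))) Amat[, j] <- fun(grid[j, ])
  A[] <- Amat
  A
}

noisy_id <- function(n, p = 0.9) {
  m <- matrix((1 - p) / (n - 1), n, n)
  if (n == 1L) return(matrix(1, 1, 1))
  diag(m) <- p
  m
}

#' Default specification for the world-facing foraging model
#'
#' Builds the configuration mapping consumed by [make_agent_model()]: the
#' smallest discrete model that supports cooperative foraging, signalling,
#' concealment and declaration observations.
#'
#' Level-1 state factors: own satiety (3 bins), current-patch stock (3 bins),
#' partner identity (one slot per known agent plus a stranger slot),
#' partner's last move (cooperate / defect / conceal / none), and own social
#' standing (good / suspect) through which concealment raises the predicted
#' probability of being declared. Modalities: satiety, patch yield, partner
#' identity, partner action, heard signal, declaration.
#'
#' @param n_partner_slots Number of identity slots including the stranger
#'   slot (>= 2).
#' @param n_signals Signal alphabet size.
#' @param preferences `"ego"` (own satiety only) or `"cultural"` (additionally
#'   prefers seeing cooperation and not being declared).
#' @param horizon Policy horizon H.
#' @param policy_actions Character subset of [world_actions()] from which
#'   open-loop policies are enumerated.
#' @return A named list usable as the `spec` argument of [make_agent_model()].
#' @export
foraging_model_spec <- function(n_partner_slots = 4L, n_signals = 2L,
                                preferences = c("cultural", "ego"),
                                horizon = 2L,
                                policy_actions = c("forage", "share", "conceal")) {
  preferences <- match.arg(preferences)
  P <- as.integer(n_partner_slots)
  stopifnot(P >= 2L, n_signals >= 1L)
  acts <- world_actions(n_signals)
  fsizes <- c(satiety = 3L, stock = 3L, partner_id = P,
              partner_move = 4L, standing = 2L)
  msizes <- c(satiety_obs = 3L, yield_obs = 3L, partner_id_obs = P,
              partner_action_obs = 4L, signal_obs = n_signals + 1L,
              declaration_obs = 2L)

  A <- list(
    satiety_obs = build_A(3L, fsizes, function(s) noisy_id(3, 0.9)[, s[1]]),
    yield_obs = build_A(3L, fsizes, function(s) noisy_id(3, 0.9)[, s[2]]),
    partner_id_obs = build_A(P, fsizes, function(s) noisy_id(P, 0.95)[, s[3]]),
    partner_action_obs = build_A(4L, fsizes, function(s) noisy_id(4, 0.85)[, s[4]]),
    signal_obs = build_A(n_signals + 1L, fsizes, function(s) {
      # valence-linked default: cooperative partners tend to emit symbol 1,
      # uncooperative ones symbol 2 (if present); absent partner emits nothing
      v <- rep(0.1 / n_signals, n_signals + 1L)
      move <- s[4]
      if (move == 4L) { v[] <- 0.05 / n_signals; v[n_signals + 1L] <- 0.95 }
      else if (move == 1L) { v[1L] <- 0.6; v[n_signals + 1L] <- 1 - 0.6 - sum(v[seq_len(n_signals)][-1L]) }
      else { k <- min(2L, n_signals); v[k] <- 0.6; v[n_signals + 1L] <- 1 - 0.6 - sum(v[seq_len(n_signals)][-k]) }
      v / sum(v)
    }),
    declaration_obs = build_A(2L, fsizes, function(s) {
      p_decl <- if (s[5] == 2L) 0.4 else 0.02
      c(1 - p_decl, p_decl)
    })
  )

  n_act <- length(acts)
  mk_B <- function(per_action) {
    n <- nrow(per_action[[1]])
    B <- array(0, dim = c(n, n, n_act))
    for (u in seq_len(n_act)) B[, , u] <- per_action[[acts[u]]]
    B
  }
  same_for_all <- function(m) stats::setNames(rep(list(m), n_act), acts)

  # own satiety: foraging feeds, concealing feeds a little less surely,
  # sharing gives food away, everything else decays slowly
  sat_default <- drift_matrix(3, p_down = 0.2)
  B_sat <- same_for_all(sat_default)
  B_sat$forage <- drift_matrix(3, p_up = 0.8)
  B_sat$conceal <- drift_matrix(3, p_up = 0.6)
  B_sat$share <- drift_matrix(3, p_down = 0.5)

  # patch stock: depleted by extraction, slowly regenerating otherwise
  stock_default <- drift_matrix(3, p_up = 0.1)
  B_stock <- same_for_all(stock_default)
  B_stock$forage <- drift_matrix(3, p_down = 0.5)
  B_stock$conceal <- drift_matrix(3, p_down = 0.5)

  B_id <- same_for_all(sticky_matrix(P, 0.9))

  # partner's move: reciprocity under sharing, defensiveness after concealing
  move_default <- sticky_matrix(4, 0.7)
  B_move <- same_for_all(move_default)
  B_move$share <- matrix(c(0.70, 0.10, 0.05, 0.15), 4, 4)
  B_move$conceal <- matrix(c(0.10, 0.55, 0.20, 0.15), 4, 4)

  # social standing: concealing is risky, sharing restores
  stand_default <- sticky_matrix(2, 0.95)
  B_stand <- same_for_all(stand_default)
  B_stand$conceal <- matrix(c(0.4, 0.6, 0.05, 0.95), 2, 2)
  B_stand$share <- matrix(c(0.95, 0.05, 0.6, 0.4), 2, 2)

  B <- list(satiety = mk_B(B_sat), stock = mk_B(B_stock),
            partner_id = mk_B(B_id), partner_move = mk_B(B_move),
            standing = mk_B(B_stand))

  C <- list(satiety_obs = c(-2, 0, 2), yield_obs = rep(0, 3),
            partner_id_obs = rep(0, P), partner_action_obs = rep(0, 4),
            signal_obs = rep(0, n_signals + 1L), declaration_obs = c(0, 0))
  if (preferences == "cultural") {
    C$partner_action_obs <- c(2, -1, -2, 0)
    C$declaration_obs <- c(0, -4)
    C$satiety_obs <- c(-1, 0, 1)
  }

  D <- list(satiety = c(0.2, 0.6, 0.2), stock = c(0.2, 0.3, 0.5),
            partner_id = rep(1 / P, P), partner_move = c(0.25, 0.25, 0.1, 0.4),
            standing = c(0.9, 0.1))

  pol_idx <- match(policy_actions, acts)
  if (anyNA(pol_idx)) stop("policy_actions: unknown action name", call. = FALSE)
  policies <- as.matrix(expand.grid(rep(list(pol_idx), horizon)))
  colnames(policies) <- NULL

  list(factor_sizes = fsizes, modality_sizes = msizes, actions = acts,
       A = A, B = B, C = C, D = D,
       policies = policies, gamma_policy = 2, eta_a = 1, eta_e = 0.1,
       preferences = preferences)
}

# default level-2 spec: typing factor over `labels`, linked to the level-1
# partner_move factor; in-group types are expected to cooperate
default_level2_spec <- function(labels = c("in-group", "out-group"),
                                alpha = 0.5) {
  K <- length(labels)
  M <- matrix(0, 4L, K)
  for (k in seq_len(K)) {
    # alternate cooperative / uncooperative profiles across the label list
    M[, k] <- if (k %% 2L == 1L) c(0.70, 0.10, 0.05, 0.15)
              else c(0.10, 0.45, 0.30, 0.15)
  }
  list(type_labels = labels, alpha = alpha,
       M = M, A2 = M, summary_map = diag(4L),
       D2 = rep(1 / K, K), target_factor = "partner_move", k_timescale = 1L)
}

#' Expected likelihood / habit under Dirichlet counts
#'
#' Column-wise mean of the Dirichlet distribution over each conditional
#' categorical: counts normalized along the outcome dimension (the first
#' array dimension), or along the whole vector for habit counts.
#'
#' @param counts Strictly positive array (outcome index first) or vector.
#' @return Array or vector of the same shape whose outcome-columns sum to 1.
#' @export
dirichlet_expectation <- function(counts) {
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("dirichlet counts must be finite and non-negative", call. = FALSE)
  }
  if (is.null(dim(counts))) {
    if (sum(counts) <= 0) stop("degenerate distribution: zero count column",
                               call. = FALSE)
    return(counts / sum(counts))
  }
  d <- dim(counts)
  m <- matrix(counts, nrow = d[1L])
  cs <- colSums(m)
  if (any(cs <= 0)) stop("degenerate distribution: zero count column",
                         call. = FALSE)
  out <- sweep(m, 2L, cs, "/")
  array(out, dim = d)
}

DIRICHLET_FLOOR <- 1e-3

#' Construct and validate an agent model
#'
#' Builds a V1 (single-level), V2 (two-level, fixed typing factor) or V3
#' (single-level, expandable through structure learning) agent from a
#' configuration mapping such as the one produced by
#' [foraging_model_spec()]. All stochastic arrays are normalized and checked;
#' Dirichlet counts are initialized from the arrays (scaled by
#' `prior_strength`) with a strictly positive floor so that likelihood
#' learning stays well-defined after sparse evidence.
#'
#' @param version `"V1"`, `"V2"` or `"V3"`.
#' @param spec Configuration mapping (see [foraging_model_spec()]); for V2 it
#'   must include `type_labels` (length >= 2) and `alpha` in `[0, 1]`, or a
#'   full `level2` sub-list.
#' @param prior_strength Total pseudo-count per likelihood column used to
#'   initialize Dirichlet counts.
#' @return An object of class `agent_model`.
#' @export
make_agent_model <- function(version = c("V1", "V2", "V3"), spec,
                             prior_strength = 10) {
  version <- match.arg(version)
  req <- c("factor_sizes", "modality_sizes", "A", "B", "C", "D", "policies")
  for (f in req) if (is.null(spec[[f]])) {
    stop("make_agent_model: missing field '", f, "'", call. = FALSE)
  }
  fsizes <- vapply(spec$factor_sizes, as.integer, integer(1))
  msizes <- vapply(spec$modality_sizes, as.integer, integer(1))
  if (any(fsizes < 1L)) stop("factor_sizes: all sizes must be >= 1",
                             call. = FALSE)
  if (any(msizes < 1L)) stop("modality_sizes: all sizes must be >= 1",
                             call. = FALSE)

  A <- lapply(spec$A, function(a) {
    a <- as_sized_array(a)
    normalize_columns(a)
  })
  for (m in seq_along(A)) {
    dm <- dim(A[[m]])
    if (dm[1L] != msizes[m] || !identical(unname(dm[-1L]), unname(fsizes))) {
      stop("A[", names(msizes)[m] %||% m, "]: shape mismatch with ",
           "modality/factor sizes", call. = FALSE)
    }
  }
  B <- lapply(spec$B, function(b) {
    b <- as_sized_array(b)
    if (length(dim(b)) != 3L) stop("B: each factor array must be 3-d ",
                                   "(next x current x action)", call. = FALSE)
    for (u in seq_len(dim(b)[3L])) b[, , u] <- normalize_columns(b[, , u, drop = FALSE])
    b
  })
  for (f in seq_along(B)) {
    db <- dim(B[[f]])
    if (db[1L] != fsizes[f] || db[2L] != fsizes[f]) {
      stop("B[", names(fsizes)[f] %||% f, "]: shape mismatch", call. = FALSE)
    }
  }
  C <- lapply(spec$C, as.numeric)
  for (m in seq_along(C)) {
    if (length(C[[m]]) != msizes[m] || any(!is.finite(C[[m]]))) {
      stop("C[", names(msizes)[m] %||% m, "]: must be finite and match ",
           "modality size", call. = FALSE)
    }
  }
  D <- lapply(spec$D, function(d) normalize(as.numeric(d)))
  for (f in seq_along(D)) {
    if (length(D[[f]]) != fsizes[f]) stop("D[", f, "]: length mismatch",
                                          call. = FALSE)
  }

  policies <- as.matrix(spec$policies)
  storage.mode(policies) <- "integer"
  if (nrow(policies) < 1L) stop("policies: policy set must be non-empty",
                                call. = FALSE)
  n_act <- dim(B[[1L]])[3L]
  if (any(policies < 1L) || any(policies > n_act)) {
    stop("policies: action index out of range", call. = FALSE)
  }
  E <- spec$E %||% rep(1 / nrow(policies), nrow(policies))
  E <- normalize(as.numeric(E))
  if (length(E) != nrow(policies)) stop("E: length must equal policy count",
                                        call. = FALSE)

  gamma_policy <- as.numeric(spec$gamma_policy %||% 2)
  if (!is.finite(gamma_policy) || gamma_policy <= 0) {
    stop("gamma_policy: must be > 0", call. = FALSE)
  }
  eta_a <- as.numeric(spec$eta_a %||% 1)
  eta_e <- as.numeric(spec$eta_e %||% 0.1)
  if (eta_a < 0 || eta_e < 0) stop("learning rates eta_a/eta_e must be >= 0",
                                   call. = FALSE)

  pA <- lapply(A, function(a) pmax(a * prior_strength, DIRICHLET_FLOOR))
  pE <- pmax(E * prior_strength, DIRICHLET_FLOOR)

  level1 <- list(n = 1L, factor_sizes = fsizes, modality_sizes = msizes,
                 A = A, B = B, C = C, D = D, E = E, pA = pA, pE = pE)

  level2 <- NULL
  if (version == "V2") {
    l2spec <- spec$level2 %||% default_level2_spec(
      labels = spec$type_labels %||% c("in-group", "out-group"),
      alpha = spec$alpha %||% 0.5)
    level2 <- validate_level2(l2spec, fsizes)
  } else if (!is.null(spec$alpha)) {
    a <- as.numeric(spec$alpha)
    if (!is.finite(a) || a < 0 || a > 1) {
      stop("alpha: must lie in [0, 1]", call. = FALSE)
    }
  }

  model <- list(version = version,
                levels = if (is.null(level2)) list(level1)
                         else list(level1, level2),
                policies = policies, gamma_policy = gamma_policy,
                eta_a = eta_a, eta_e = eta_e,
                actions = spec$actions %||% paste0("u", seq_len(n_act)),
                expandable = identical(version, "V3"),
                expansion_K = as.integer(spec$expansion_K %||% 2L),
                type_labels = if (!is.null(level2)) level2$type_labels
                              else spec$type_labels)
  class(model) <- "agent_model"
  validate_agent_model(model)
  model
}

validate_level2 <- function(l2, fsizes) {
  labels <- l2$type_labels
  if (is.null(labels) || length(labels) < 2L) {
    stop("type_labels: V2 requires >= 2 type labels", call. = FALSE)
  }
  alpha <- as.numeric(l2$alpha)
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha: must lie in [0, 1]", call. = FALSE)
  }
  K <- length(labels)
  target <- l2$target_factor %||% "partner_move"
  tf <- if (is.character(target)) match(target, names(fsizes))
        else as.integer(target)
  if (is.na(tf)) stop("level2$target_factor: unknown level-1 factor",
                      call. = FALSE)
  nt <- unname(fsizes[tf])
  M <- as_sized_array(l2$M); dim(M) <- c(nt, K)
  M <- apply(M, 2L, normalize)
  A2 <- as_sized_array(l2$A2 %||% M)
  S <- nrow(as.matrix(A2))
  A2 <- apply(matrix(A2, S), 2L, normalize)
  if (ncol(A2) != K) stop("level2$A2: column count must equal type count",
                          call. = FALSE)
  smap <- as_sized_array(l2$summary_map %||% diag(nt))
  smap <- matrix(smap, nrow = S)
  if (ncol(smap) != nt) stop("level2$summary_map: must map the target ",
                             "factor's states to summary categories",
                             call. = FALSE)
  smap <- apply(smap, 2L, normalize)
  D2 <- normalize(as.numeric(l2$D2 %||% rep(1, K)))
  if (length(D2) != K) stop("level2$D2: length mismatch", call. = FALSE)
  list(n = 2L, type_labels = as.character(labels), alpha = alpha,
       M = M, A2 = A2, summary_map = smap, D2 = D2,
       target_factor = tf,
       k_timescale = as.integer(l2$k_timescale %||% 1L))
}

# normalize the outcome dimension (first) of an A-like array
normalize_columns <- function(a) {
  d <- dim(a)
  m <- matrix(a, nrow = d[1L])
  cs <- colSums(m)
  if (any(!is.finite(m)) || any(m < 0) || any(cs <= 0)) {
    stop("non-normalizable array: columns must be non-negative with a ",
         "positive sum", call. = FALSE)
  }
  array(sweep(m, 2L, cs, "/"), dim = d)
}

as_sized_array <- function(x) {
  if (is.list(x)) x <- simplify_nested(x)
  x
}

# rebuild an array from the nested-list form produced by JSON serialization
simplify_nested <- function(x) {
  if (!is.list(x)) return(as.numeric(x))
  parts <- lapply(x, simplify_nested)
  arr <- simplify2array(parts)
  arr
}

#' Recursively validate every stochastic array of an agent model
#'
#' Checks categorical invariants on each likelihood column, each transition
#' column, each prior, the habit prior, strict positivity of Dirichlet
#' counts, and level-2 link/summary arrays when present.
#'
#' @param model An `agent_model`.
#' @return `TRUE` invisibly; errors on the first violation.
#' @export
validate_agent_model <- function(model) {
  l1 <- model$levels[[1L]]
  for (m in seq_along(l1$A)) {
    cols <- matrix(l1$A[[m]], nrow = dim(l1$A[[m]])[1L])
    apply(cols, 2L, validate_categorical)
    if (any(l1$pA[[m]] <= 0)) stop("pA: counts must be strictly positive",
                                   call. = FALSE)
  }
  for (f in seq_along(l1$B)) {
    b <- l1$B[[f]]
    for (u in seq_len(dim(b)[3L])) apply(b[, , u, drop = FALSE], 2L,
                                         validate_categorical)
  }
  lapply(l1$D, validate_categorical)
  validate_categorical(l1$E)
  if (any(l1$pE <= 0)) stop("pE: counts must be strictly positive",
                            call. = FALSE)
  if (length(model$levels) > 1L) {
    l2 <- model$levels[[2L]]
    apply(l2$M, 2L, validate_categorical)
    apply(l2$A2, 2L, validate_categorical)
    apply(l2$summary_map, 2L, validate_categorical)
    validate_categorical(l2$D2)
    if (l2$alpha < 0 || l2$alpha > 1) stop("alpha out of [0, 1]",
                                           call. = FALSE)
  }
  n_versions_ok <- switch(model$version,
    V1 = length(model$levels) == 1L,
    V2 = length(model$levels) == 2L,
    V3 = TRUE)
  if (!n_versions_ok) stop("level count inconsistent with version",
                           call. = FALSE)
  invisible(TRUE)
}

#' @export
print.agent_model <- function(x, ...) {
  cat("<agent_model> version", x$version,
      "| levels:", length(x$levels),
      "| factors:", paste(x$levels[[1]]$factor_sizes, collapse = "x"),
      "| policies:", nrow(x$policies),
      "(indices: 1-based)\n")
  if (length(x$levels) > 1L) {
    cat("  level 2: types [", paste(x$levels[[2]]$type_labels,
                                    collapse = ", "),
        "], alpha =", x$levels[[2]]$alpha, "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an agent model to a JSON-ready list
#'
#' Arrays become nested lists with their shapes and label lists included, so
#' a dump can be re-loaded with [agent_model_load()] and rebuilt
#' field-identically.
#'
#' @param model An `agent_model`.
#' @return A plain list; pass to `jsonlite::toJSON(..., digits = NA)`.
#' @export
agent_model_dump <- function(model) {
  l1 <- model$levels[[1L]]
  arr_out <- function(a) list(dim = as.integer(dim(a) %||% length(a)),
                              data = as.numeric(a))
  out <- list(
    index_base = 1L,
    version = model$version,
    actions = model$actions,
    factor_sizes = as.list(l1$factor_sizes),
    modality_sizes = as.list(l1$modality_sizes),
    A = lapply(l1$A, arr_out), B = lapply(l1$B, arr_out),
    C = lapply(l1$C, as.numeric), D = lapply(l1$D, as.numeric),
    E = as.numeric(l1$E),
    pA = lapply(l1$pA, arr_out), pE = as.numeric(l1$pE),
    policies = arr_out(model$policies),
    gamma_policy = model$gamma_policy,
    eta_a = model$eta_a, eta_e = model$eta_e,
    expansion_K = model$expansion_K)
  if (length(model$levels) > 1L) {
    l2 <- model$levels[[2L]]
    out$level2 <- list(type_labels = l2$type_labels, alpha = l2$alpha,
                       M = arr_out(l2$M), A2 = arr_out(l2$A2),
                       summary_map = arr_out(l2$summary_map),
                       D2 = as.numeric(l2$D2),
                       target_factor = l2$target_factor,
                       k_timescale = l2$k_timescale)
  }
  out
}

#' Rebuild an agent model from a dump
#'
#' @param dump List produced by [agent_model_dump()] (possibly after a JSON
#'   round trip).
#' @return An `agent_model`.
#' @export
agent_model_load <- function(dump) {
  arr_in <- function(x) {
    a <- as.numeric(unlist(x$data))
    d <- as.integer(unlist(x$dim))
    if (length(d) > 1L) dim(a) <- d
    a
  }
  spec <- list(factor_sizes = unlist(dump$factor_sizes),
               modality_sizes = unlist(dump$modality_sizes),
               actions = unlist(dump$actions),
               A = lapply(dump$A, arr_in), B = lapply(dump$B, arr_in),
               C = lapply(dump$C, function(x) as.numeric(unlist(x))),
               D = lapply(dump$D, function(x) as.numeric(unlist(x))),
               E = as.numeric(unlist(dump$E)),
               policies = matrix(arr_in(dump$policies),
                                 nrow = unlist(dump$policies$dim)[1L]),
               gamma_policy = dump$gamma_policy,
               eta_a = dump$eta_a, eta_e = dump$eta_e,
               expansion_K = dump$expansion_K)
  if (!is.null(dump$level2)) {
    l2 <- dump$level2
    spec$level2 <- list(type_labels = unlist(l2$type_labels),
                        alpha = l2$alpha, M = arr_in(l2$M),
                        A2 = arr_in(l2$A2),
                        summary_map = arr_in(l2$summary_map),
                        D2 = as.numeric(unlist(l2$D2)),
                        target_factor = unlist(l2$target_factor),
                        k_timescale = l2$k_timescale)
  }
  model <- make_agent_model(unlist(dump$version), spec)
  # restore learned counts exactly (make_agent_model re-initializes them)
  model$levels[[1L]]$pA <- mapply(function(a, tmpl) {
    arr <- arr_in(a); dim(arr) <- dim(tmpl); arr
  }, dump$pA, model$levels[[1L]]$pA, SIMPLIFY = FALSE)
  model$levels[[1L]]$pE <- as.numeric(unlist(dump$pE))
  model
}
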