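## TD(lambda) learning of linear value-function weights over a basis set,
## with one-step-lookahead action values and softmax action selection.
## run_trial() is the readable reference implementation; td_train() (Rcpp)
## runs the same protocol -- identical arithmetic and random-draw order --
## for batch experiments.

#' Agent hyperparameters
#'
#' @param alpha learning rate in `[0, 1]` (fractional step size thanks to
#'   row L2 normalization of the basis).
#' @param gamma discount factor in `(0, 1]`; see [scaled_discount()] for the
#'   per-world scaling rule.
#' @param lambda eligibility-trace decay in `[0, 1]` (default 0.9).
#' @param beta softmax inverse temperature, `>= 0` (default 80).
#' @param max_steps trial length cap in actions (default 500).
#' @return An `agent_config` list.
#' @export
agent_config <- function(alpha, gamma, lambda = 0.9, beta = 80,
                         max_steps = 500L) {
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0, lambda <= 1,
            gamma > 0, gamma <= 1, beta >= 0, max_steps >= 1)
  structure(list(alpha = alpha, gamma = gamma, lambda = lambda,
                 beta = beta, max_steps = as.integer(max_steps)),
            class = "agent_config")
}

#' Fresh agent state
#'
#' @param n number of basis functions.
#' @return List with zero weight vector `w` and eligibility vector `e`.
#' @export
agent_state <- function(n) {
  list(w = numeric(n), e = numeric(n))
}

#' Linear value estimate
#'
#' @param w weight vector.
#' @param phi_row basis activation row for a state.
#' @return The inner product `sum(w * phi_row)`.
#' @export
value_estimate <- function(w, phi_row) {
  if (length(w) != length(phi_row)) stop("weight/basis length mismatch")
  sum(w * phi_row)
}

#' One TD(lambda) update
#'
#' `delta = r + gamma * V(s') - V(s)` with `V(s') := 0` when the transition
#' is terminal; accumulating traces `e <- gamma * lambda * e + phi(s)`; then
#' `w <- w + alpha * delta * e`.
#'
#' @param agent an [agent_state()].
#' @param cfg an [agent_config()].
#' @param phi_s basis row of the state being updated.
#' @param r reward credited to this update.
#' @param phi_next basis row of the successor state (ignored when
#'   `terminal`).
#' @param terminal logical; `TRUE` zeroes the bootstrap target.
#' @return The updated agent state, with the TD error in `$delta`.
#' @export
td_update <- function(agent, cfg, phi_s, r, phi_next, terminal = FALSE) {
  if (!all(is.finite(phi_s)) || !is.finite(r))
    stop("non-finite inputs to td_update")
  v_s <- value_estimate(agent$w, phi_s)
  v_next <- if (terminal) 0 else value_estimate(agent$w, phi_next)
  delta <- r + cfg$gamma * v_next - v_s
  agent$e <- cfg$gamma * cfg$lambda * agent$e + phi_s
  agent$w <- agent$w + cfg$alpha * delta * agent$e
  agent$delta <- delta
  agent
}

#' One-step-lookahead action values
#'
#' The transition model of a gridworld is transparent, so the value of an
#' action is the estimated value of the neighboring state it leads to.
#' Unavailable actions (walls, grid edge) are absent from the result.
#'
#' @param gw a `grid_world`.
#' @param basis a `basis_set` over `gw`.
#' @param w weight vector.
#' @param s non-terminal state index.
#' @return Named numeric vector of `Q(s, a)` over available actions.
#' @export
q_values <- function(gw, basis, w, s) {
  nb <- neighbors_matrix(gw)[s, ]
  avail <- !is.na(nb)
  # plain sum() so the arithmetic matches the compiled engine bit-for-bit
  q <- vapply(nb[avail], function(t) sum(basis$Phi[t, ] * w), numeric(1))
  setNames(q, ACTIONS[avail])
}

#' Sample an action from a softmax policy
#'
#' Probabilities proportional to `exp(beta * Q)` over the available actions,
#' numerically stabilized by max subtraction.  Consumes exactly one uniform
#' draw from the R random stream.
#'
#' @param q_map named Q-value vector (see [q_values()]).
#' @param beta inverse temperature.
#' @return One action name.
#' @export
softmax_policy <- function(q_map, beta) {
  if (!length(q_map)) stop("no available actions")
  ex <- exp(beta * (q_map - max(q_map)))
  u <- runif(1) * sum(ex)
  acc <- 0
  for (i in seq_along(ex)) {
    acc <- acc + ex[[i]]
    if (u <= acc) return(names(q_map)[i])
  }
  names(q_map)[length(q_map)]
}

#' Softmax choice probabilities
#' @inheritParams softmax_policy
#' @return Named probability vector.
#' @export
softmax_probs <- function(q_map, beta) {
  ex <- exp(beta * (q_map - max(q_map)))
  ex / sum(ex)
}

#' Per-world discount scaling
#'
#' Environments of different size span different goal distances; to keep
#' the learned value range comparable the discount is set to
#' `gamma = 0.9^(d / c)`, so that `gamma^c = 0.9^d` is constant across
#' worlds sharing the reference distance `d`.
#'
#' @param d reference distance (the smallest `c` across the worlds under
#'   comparison), in states.
#' @param c this world's maximum geodesic distance from any state to the
#'   goal, in states.
#' @return The discount factor `0.9^(d/c)`.
#' @export
scaled_discount <- function(d, c) {
  stopifnot(d > 0, c > 0)
  0.9^(d / c)
}

# states from which the goal is reachable (the goal's connected component),
# goal excluded: the default pool of start states
start_states <- function(gw) {
  A <- adjacency_matrix(gw)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)$membership
  setdiff(which(comp == comp[gw$goal]), gw$goal)
}

# maximum geodesic distance from any reachable state to the goal
max_goal_distance <- function(gw) {
  g <- igraph::graph_from_adjacency_matrix(adjacency_matrix(gw),
                                           mode = "undirected")
  d <- igraph::distances(g, v = gw$goal)
  max(d[is.finite(d)])
}

#' Run one learning trial
#'
#' The agent starts at a random non-goal state (uniform over the goal's
#' connected component), picks actions by softmax over one-step-lookahead Q
#' values, and performs a TD(lambda) update at every step.  Rewards follow
#' the visiting convention: a state's reward is credited when the agent is
#' at that state, so every non-goal step carries reward 0 and bootstraps the
#' successor's learned value; on arriving at the goal a final terminal
#' update (reward `gw$reward`, bootstrap 0) is applied, driving `V(goal)` toward
#' the goal reward.  The trial ends at the (absorbing) goal or after
#' `max_steps` actions.  Eligibility traces are reset at trial start.
#'
#' @param gw a `grid_world`.
#' @param basis a `basis_set` over `gw`.
#' @param agent an [agent_state()] (weights persist across trials).
#' @param cfg an [agent_config()].
#' @param start optional fixed start state; by default drawn uniformly.
#' @param starts optional pool of candidate start states.
#' @return List with `steps` (actions taken), `agent` (updated state),
#'   `trajectory` (visited states, start first).
#' @export
run_trial <- function(gw, basis, agent, cfg, start = NULL, starts = NULL) {
  if (is.null(starts)) starts <- start_states(gw)
  if (is.null(start)) {
    u <- runif(1)
    start <- starts[1L + floor(u * length(starts))]
  }
  agent$e <- numeric(length(agent$e))
  s <- start
  traj <- s
  steps <- 0L
  while (steps < cfg$max_steps) {
    q <- q_values(gw, basis, agent$w, s)
    a <- softmax_policy(q, cfg$beta)
    s_next <- gw_step(gw, s, a)$state
    steps <- steps + 1L
    agent <- td_update(agent, cfg, basis$Phi[s, ], 0, basis$Phi[s_next, ],
                       terminal = FALSE)
    s <- s_next
    traj <- c(traj, s)
    if (s == gw$goal) {
      agent <- td_update(agent, cfg, basis$Phi[s, ], gw$reward,
                         basis$Phi[s, ], terminal = TRUE)
      break
    }
  }
  list(steps = steps, agent = agent, trajectory = traj)
}

#' Batch TD(lambda) training (compiled engine)
#'
#' Trains `n_runs` independent agents for `n_trials` trials each, following
#' exactly the [run_trial()] protocol (same update rule, same random-draw
#' order), in compiled code.  Fully reproducible: the R random stream is
#' used, so `set.seed()` before the call (or the `seed` argument) fixes all
#' trajectories.
#'
#' @param gw a `grid_world`.
#' @param basis a `basis_set` over `gw`.
#' @param cfg an [agent_config()].
#' @param n_runs number of independent agents.
#' @param n_trials trials per agent.
#' @param seed optional integer seed applied before simulation.
#' @param starts optional candidate start states (default: the goal's
#'   component, goal excluded).
#' @return List with `steps` (`n_runs` x `n_trials` integer matrix) and
#'   `weights` (`n_runs` x `N` matrix of final weights).
#' @export
td_train <- function(gw, basis, cfg, n_runs, n_trials, seed = NULL,
                     starts = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(starts)) starts <- start_states(gw)
  nb <- neighbors_matrix(gw)
  nb0 <- nb; nb0[is.na(nb0)] <- 0L
  res <- td_train_cpp(t(basis$Phi), nb0 - 1L, gw$goal - 1L, gw$reward,
                      as.integer(starts - 1L), as.integer(n_runs),
                      as.integer(n_trials), cfg$alpha, cfg$lambda,
                      cfg$gamma, cfg$beta, cfg$max_steps)
  res
}
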