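## Independent oracles, deliberately implemented with different algorithms
## and data structures than the package code they check.

# breadth-first-search shortest-path distances from one source over an
# adjacency matrix (queue-based; the package uses igraph's all-pairs code)
bfs_distances <- function(A, source) {
  M <- nrow(A)
  dist <- rep(Inf, M)
  dist[source] <- 0
  queue <- source
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(A[v, ] == 1)
    new <- nb[!is.finite(dist[nb])]
    dist[new] <- dist[v] + 1
    queue <- c(queue, new)
  }
  dist
}

bfs_all_pairs <- function(A) {
  t(vapply(seq_len(nrow(A)), function(s) bfs_distances(A, s),
           numeric(nrow(A))))
}

# classic tabular TD(lambda): V- and e-tables indexed by state, no basis
# matrix anywhere.  `steps` is a data.frame with columns s, r, s_next,
# terminal, new_episode (TRUE resets the trace before the update).
tabular_td_oracle <- function(steps, M, alpha, gamma, lambda) {
  V <- numeric(M)
  e <- numeric(M)
  for (i in seq_len(nrow(steps))) {
    if (steps$new_episode[i]) e[] <- 0
    s <- steps$s[i]
    v_next <- if (steps$terminal[i]) 0 else V[steps$s_next[i]]
    delta <- steps$r[i] + gamma * v_next - V[s]
    e <- gamma * lambda * e
    e[s] <- e[s] + 1
    V <- V + alpha * delta * e
  }
  V
}

# a fixed wall-respecting random walk with episode restarts, used as the
# shared trajectory for TD equivalence checks
make_fixed_trajectory <- function(gw, n_steps, seed) {
  set.seed(seed)
  starts <- Filter(function(s) length(available_actions(gw, s)) > 0,
                   setdiff(seq_len(n_states(gw)), gw$goal))
  s <- sample(starts, 1)
  out <- vector("list", n_steps)
  new_ep <- TRUE
  for (i in seq_len(n_steps)) {
    a <- sample(available_actions(gw, s), 1)
    tr <- gw_step(gw, s, a)
    out[[i]] <- data.frame(s = s, r = 0, s_next = tr$state,
                           terminal = FALSE, new_episode = new_ep)
    new_ep <- FALSE
    s <- tr$state
    if (tr$terminal) {
      # final terminal update at the goal, then a fresh episode
      out[[i]] <- rbind(out[[i]],
                        data.frame(s = s, r = gw$reward, s_next = s,
                                   terminal = TRUE, new_episode = FALSE))
      s <- sample(starts, 1)
      new_ep <- TRUE
    }
  }
  do.call(rbind, out)
}

# run the package's td_update over an arbitrary basis along a trajectory
run_td_along <- function(steps, basis, cfg) {
  ag <- agent_state(ncol(basis$Phi))
  for (i in seq_len(nrow(steps))) {
    if (steps$new_episode[i]) ag$e[] <- 0
    ag <- td_update(ag, cfg, basis$Phi[steps$s[i], ], steps$r[i],
                    basis$Phi[steps$s_next[i], ], steps$terminal[i])
  }
  ag
}

expect_no_ci_overlap <- function(lower_curve, higher_curve, trials = NULL) {
  a <- curve_window_stats(lower_curve, trials)
  b <- curve_window_stats(higher_curve, trials)
  expect_lt(a$hi, b$lo)
}
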