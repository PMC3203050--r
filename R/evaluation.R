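## Ground-truth values, learning-rate calibration, learning-curve
## experiments over the fixture worlds, and signed value-bleed errors at
## walls.

#' Ground-truth value map by dynamic programming
#'
#' Value iteration for the optimal (greedy) policy under the package's
#' reward convention: the goal is absorbing with `V(goal) = reward`, every
#' other state satisfies `V(s) = gamma * max_a V(next(s, a))`.  On a
#' corridor this gives the closed form `V(s) = gamma^dist(s, goal) * reward`.
#' States from which the goal is unreachable keep value 0.
#'
#' @param gw a `grid_world`.
#' @param gamma discount factor.
#' @param tol stop when the largest update is below this.
#' @return A `value_map`: list with `values` (length `M`), `reference =
#'   "ground_truth"`, and `gamma`.
#' @export
ground_truth_dp <- function(gw, gamma, tol = 1e-10) {
  M <- n_states(gw)
  nb <- neighbors_matrix(gw)
  V <- numeric(M)
  V[gw$goal] <- gw$reward
  repeat {
    Vn <- matrix(-Inf, M, 4)
    for (a in 1:4) {
      ok <- !is.na(nb[, a])
      Vn[ok, a] <- V[nb[ok, a]]
    }
    best <- apply(Vn, 1, max)
    best[!is.finite(best)] <- 0        # isolated cells
    Vnew <- gamma * best
    Vnew[gw$goal] <- gw$reward
    if (max(abs(Vnew - V)) < tol) break
    V <- Vnew
  }
  new_value_map(Vnew, "ground_truth", gamma)
}

new_value_map <- function(values, reference, gamma = NA_real_) {
  structure(list(values = values, reference = reference, gamma = gamma),
            class = "value_map")
}

#' Value map from learned weights
#'
#' @param basis a `basis_set`.
#' @param w a weight vector (length `N`) or a runs x `N` matrix, in which
#'   case per-state values are averaged over runs.
#' @return A `value_map` with `reference = "learned"`.
#' @export
value_map_from_weights <- function(basis, w) {
  if (is.matrix(w)) {
    vals <- as.numeric(basis$Phi %*% colMeans(w))
  } else {
    vals <- as.numeric(basis$Phi %*% w)
  }
  new_value_map(vals, "learned")
}

#' Bellman residual of a value map
#'
#' Maximum absolute self-consistency error of `V` under the greedy policy.
#'
#' @param vm a `value_map`.
#' @param gw the world.
#' @param gamma discount.
#' @return Scalar residual; small for a converged [ground_truth_dp()] map.
#' @export
bellman_residual <- function(vm, gw, gamma) {
  nb <- neighbors_matrix(gw)
  V <- vm$values
  resid <- 0
  for (s in seq_len(n_states(gw))) {
    if (s == gw$goal) {
      resid <- max(resid, abs(V[s] - gw$reward))
    } else {
      tgt <- nb[s, !is.na(nb[s, ])]
      v <- if (length(tgt)) gamma * max(V[tgt]) else 0
      resid <- max(resid, abs(V[s] - v))
    }
  }
  resid
}

#' Reference goal distance across the fixture suite
#'
#' The per-world discount is `0.9^(d/c)` ([scaled_discount()]) with `c` the
#' world's own maximum geodesic distance to goal and `d` the smallest such
#' `c` across the six fixture worlds, so every fixture spans the same value
#' range.
#'
#' @return Integer distance `d` (cached after the first call).
#' @export
reference_distance <- function() {
  if (!is.null(.navbasis_cache$ref_d)) return(.navbasis_cache$ref_d)
  d <- min(vapply(fixture_names(),
                  function(nm) max_goal_distance(make_fixture(nm)),
                  numeric(1)))
  .navbasis_cache$ref_d <- d
  d
}

#' Discount factor for a world
#'
#' @param gw a `grid_world`.
#' @param d_ref reference distance (default [reference_distance()]).
#' @param rule `"goal"` (maximum geodesic distance from any state to the
#'   goal; default) or `"diameter"` (maximum distance between any pair of
#'   states) as the world's characteristic distance `c`.
#' @return `scaled_discount(d_ref, c)`.
#' @export
discount_for_world <- function(gw, d_ref = reference_distance(),
                               rule = c("goal", "diameter")) {
  rule <- match.arg(rule)
  cc <- if (rule == "goal") {
    max_goal_distance(gw)
  } else {
    D <- geodesic_distances(adjacency_matrix(gw))$values
    max(D[is.finite(D)])
  }
  scaled_discount(d_ref, cc)
}

#' Calibrated learning rates for the fixture presets
#'
#' Per-condition learning rates chosen by [grid_search_alpha()] over the 21
#' point grid `{0, 0.05, ..., 1}` to minimize the mean number of steps to
#' termination over 50 trials (100 runs per grid point); the calibration
#' settings are documented in the package vignette.
#'
#' @return A tibble with `preset`, `family`, `metric`, `alpha`.
#' @export
preset_alphas <- function() {
  tibble::tribble(
    ~preset,              ~family,   ~metric,      ~alpha,
    "open_field_20",      "tabular", "euclidean",  0.70,
    "open_field_20",      "place",   "euclidean",  0.15,
    "open_field_20",      "grid",    "euclidean",  0.15,
    "open_field_20",      "place",   "geodesic",   0.10,
    "open_field_20",      "grid",    "geodesic",   0.20,
    "simple_barrier_20",  "tabular", "euclidean",  0.65,
    "simple_barrier_20",  "place",   "euclidean",  0.10,
    "simple_barrier_20",  "grid",    "euclidean",  0.15,
    "simple_barrier_20",  "place",   "geodesic",   0.15,
    "simple_barrier_20",  "grid",    "geodesic",   0.15,
    "narrow_aperture_20", "tabular", "euclidean",  0.65,
    "narrow_aperture_20", "place",   "euclidean",  0.05,
    "narrow_aperture_20", "grid",    "euclidean",  0.05,
    "narrow_aperture_20", "place",   "geodesic",   0.05,
    "narrow_aperture_20", "grid",    "geodesic",   0.10)
}

lookup_alpha <- function(preset, family, metric) {
  tab <- preset_alphas()
  metric <- if (family == "tabular") "euclidean" else metric
  hit <- tab[tab$preset == preset & tab$family == family &
               tab$metric == metric, ]
  if (!nrow(hit)) stop(sprintf("no calibrated alpha for %s/%s/%s",
                               preset, family, metric))
  hit$alpha[[1]]
}

#' Learning-rate grid search
#'
#' Runs the full training protocol at every grid point (same seed each, so
#' the comparison is paired) and returns the learning rate minimizing the
#' mean number of steps to termination over the whole training window.
#'
#' @param gw a `grid_world` (or fixture name).
#' @param family,metric basis family and metric tag.
#' @param alphas candidate learning rates in `[0, 1]`.
#' @param n_runs,n_trials runs per grid point and trials per run.
#' @param seed integer seed, reused at every grid point.
#' @param lambda,beta,max_steps remaining [agent_config()] fields.
#' @return List with `best_alpha` and `results` (a tibble of `alpha`,
#'   `mean_steps`).
#' @export
grid_search_alpha <- function(gw, family = "tabular", metric = "euclidean",
                              alphas = seq(0, 1, by = 0.05),
                              n_runs = 100, n_trials = 50, seed = 1,
                              lambda = 0.9, beta = 80, max_steps = 500L) {
  stopifnot(length(alphas) >= 1, all(alphas >= 0 & alphas <= 1))
  if (is.character(gw)) gw <- make_fixture(gw)
  basis <- build_basis(gw, family, metric)
  gamma <- discount_for_world(gw)
  ms <- vapply(alphas, function(a) {
    cfg <- agent_config(alpha = a, gamma = gamma, lambda = lambda,
                        beta = beta, max_steps = max_steps)
    res <- td_train(gw, basis, cfg, n_runs, n_trials, seed = seed)
    mean(res$steps)
  }, numeric(1))
  list(best_alpha = alphas[which.min(ms)],
       results = tibble::tibble(alpha = alphas, mean_steps = ms))
}

#' Run a learning-curve experiment
#'
#' Trains `n_runs` independent agents on a fixture world and aggregates the
#' per-trial steps-to-goal into a learning curve with normal-approximation
#' 95% confidence intervals.
#'
#' @param preset a fixture name (see [fixture_names()]) or a `grid_world`.
#' @param basis_family `"tabular"`, `"place"` or `"grid"`.
#' @param metric_tag `"euclidean"` or `"geodesic"`.
#' @param n_runs,n_trials number of independent agents and trials each.
#' @param seed integer seed.
#' @param alpha learning rate; by default looked up in [preset_alphas()].
#' @param lambda,beta,max_steps remaining [agent_config()] fields.
#' @return A `learning_curve` tibble (`trial`, `mean_steps`,
#'   `ci_halfwidth`, `n_runs`) carrying the per-run steps matrix, final
#'   mean value map, basis and resolved configuration as attributes.
#' @export
run_experiment <- function(preset, basis_family = "tabular",
                           metric_tag = "euclidean",
                           n_runs = 500, n_trials = 50, seed = 1,
                           alpha = NULL, lambda = 0.9, beta = 80,
                           max_steps = 500L) {
  preset_name <- if (is.character(preset)) preset else "custom"
  gw <- if (is.character(preset)) make_fixture(preset) else preset
  if (is.null(alpha)) alpha <- lookup_alpha(preset_name, basis_family, metric_tag)
  basis <- build_basis(gw, basis_family, metric_tag)
  gamma <- discount_for_world(gw)
  cfg <- agent_config(alpha = alpha, gamma = gamma, lambda = lambda,
                      beta = beta, max_steps = max_steps)
  res <- td_train(gw, basis, cfg, n_runs, n_trials, seed = seed)
  steps <- res$steps
  curve <- tibble::tibble(
    trial = seq_len(n_trials),
    mean_steps = colMeans(steps),
    ci_halfwidth = qnorm(0.975) * apply(steps, 2, sd) / sqrt(n_runs),
    n_runs = n_runs)
  config <- list(preset = preset_name, family = basis_family,
                 metric = metric_tag, alpha = alpha, gamma = gamma,
                 lambda = lambda, beta = beta, max_steps = max_steps,
                 n_runs = n_runs, n_trials = n_trials, seed = seed)
  structure(curve,
            steps = steps,
            mean_values = value_map_from_weights(basis, res$weights),
            config = config,
            class = c("learning_curve", class(curve)))
}

#' Mean and CI of steps-to-goal over a trial window
#'
#' Averages each run's steps over the given trials, then reports the mean
#' and a 95% normal-approximation confidence interval over runs -- the
#' statistic used for curve-ordering comparisons.
#'
#' @param curve a `learning_curve` from [run_experiment()].
#' @param trials integer vector of trials to average (default: all).
#' @return A one-row tibble: `mean`, `lo`, `hi`, `n_runs`.
#' @export
curve_window_stats <- function(curve, trials = NULL) {
  steps <- attr(curve, "steps")
  if (is.null(trials)) trials <- seq_len(ncol(steps))
  per_run <- rowMeans(steps[, trials, drop = FALSE])
  m <- mean(per_run)
  hw <- qnorm(0.975) * sd(per_run) / sqrt(length(per_run))
  tibble::tibble(mean = m, lo = m - hw, hi = m + hw, n_runs = length(per_run))
}

#' @export
glance.learning_curve <- function(x, ...) {
  cfg <- attr(x, "config")
  dplyr::bind_cols(tibble::as_tibble(cfg[c("preset", "family", "metric",
                                           "alpha", "gamma", "lambda",
                                           "beta", "n_runs", "n_trials")]),
                   curve_window_stats(x)[, c("mean", "lo", "hi")])
}

#' Plot a learning curve
#' @param object a `learning_curve`.
#' @param ... unused.
#' @return A ggplot of mean steps per trial with the 95% CI ribbon.
#' @export
autoplot.learning_curve <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trial, y = .data$mean_steps)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_steps - .data$ci_halfwidth,
                                      ymax = .data$mean_steps + .data$ci_halfwidth),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trial", y = "mean steps to goal",
                  title = sprintf("%s / %s (%s)", cfg$preset, cfg$family,
                                  cfg$metric)) +
    ggplot2::theme_minimal()
}

#' Tidy a value map
#' @param x a `value_map`.
#' @param gw the world it lives on.
#' @param ... unused.
#' @return Tibble with `state`, `x`, `y`, `value`, `reference`.
#' @export
tidy.value_map <- function(x, gw, ...) {
  xy <- cell_xy(gw, seq_along(x$values))
  tibble::tibble(state = seq_along(x$values), x = xy[, 1], y = xy[, 2],
                 value = x$values, reference = x$reference)
}

#' Plot a value map
#' @param object a `value_map`.
#' @param gw the world it lives on.
#' @param ... unused.
#' @return A ggplot heat map (dark = low, light = high) with walls drawn.
#' @export
autoplot.value_map <- function(object, gw, ...) {
  df <- tidy.value_map(object, gw)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_segment(data = wall_segments(gw),
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "red", linewidth = 1.2, inherit.aes = FALSE) +
    ggplot2::coord_equal() + ggplot2::theme_minimal()
}

#' Signed value error on the two sides of each wall
#'
#' For every cell adjacent to a blocked edge, the signed error
#' `learned - truth` is averaged separately over cells on the goal-nearer
#' side of their wall and cells on the goal-farther side (sides classified
#' by geodesic distance to the goal).  Euclidean bases overgeneralize
#' across walls: value is overrepresented on the far side (positive
#' far-side error) and underrepresented on the near side.
#'
#' @param learned a `value_map` with learned values.
#' @param truth a `value_map` from [ground_truth_dp()].
#' @param gw the common world.
#' @return A one-row tibble: `near_side_error`, `far_side_error`, `n_near`,
#'   `n_far`.  A world without walls yields an empty (zero-row) tibble with
#'   a warning.
#' @export
wall_bleed_metric <- function(learned, truth, gw) {
  if (!nrow(gw$blocked)) {
    warning("world has no walls; wall bleed is undefined")
    return(tibble::tibble(near_side_error = numeric(0),
                          far_side_error = numeric(0),
                          n_near = integer(0), n_far = integer(0)))
  }
  g <- igraph::graph_from_adjacency_matrix(adjacency_matrix(gw),
                                           mode = "undirected")
  dist_goal <- as.numeric(igraph::distances(g, v = gw$goal))
  near <- integer(0); far <- integer(0)
  for (k in seq_len(nrow(gw$blocked))) {
    i <- gw$blocked[k, 1]; j <- gw$blocked[k, 2]
    if (dist_goal[i] == dist_goal[j]) next    # tie: no near/far side
    if (dist_goal[i] < dist_goal[j]) { near <- c(near, i); far <- c(far, j) }
    else { near <- c(near, j); far <- c(far, i) }
  }
  near <- unique(near); far <- unique(far)
  err <- learned$values - truth$values
  tibble::tibble(near_side_error = mean(err[near]),
                 far_side_error = mean(err[far]),
                 n_near = length(near), n_far = length(far))
}
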