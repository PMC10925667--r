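#' Mean concentration M = (1/N) sum_i theta_i
#'
#' The fraction of the network occupied by the substance; under pure
#' diffusion it is conserved, under reaction-diffusion it can grow to 1
#' (full invasion) or shrink to 0 (extinction).
#'
#' @param theta non-empty concentration vector.
#' @return scalar mean.
#' @export
mean_concentration <- function(theta) {
  if (length(theta) == 0) stop("theta must be non-empty", call. = FALSE)
  mean(theta)
}

#' Count of nodes strictly above a concentration threshold
#'
#' `N(theta_c) = sum_i Heaviside(theta_i - theta_c)` with the convention
#' `Heaviside(x) = 0` for `x <= 0`: a node exactly at the threshold is NOT
#' counted.
#'
#' @param theta concentration vector.
#' @param theta_c threshold, `>= 0`.
#' @return integer count.
#' @export
count_above <- function(theta, theta_c) {
  if (theta_c < 0) stop("theta_c must be non-negative", call. = FALSE)
  sum(theta > theta_c)
}

#' Large-time node count under pure diffusion (closed form)
#'
#' Pure diffusion on a connected graph spreads any initial mass uniformly, so
#' every node ends at `theta0_total / n`. The long-time count of nodes above
#' `theta_c` is therefore all-or-nothing: `n` if `theta0_total / n > theta_c`,
#' else 0 (the boundary case counts as 0, matching the strict Heaviside).
#' Used as an analytic oracle against the numerical integrator.
#'
#' @param theta0_total total initial concentration (sum over nodes).
#' @param n number of nodes, `>= 1`.
#' @param theta_c threshold.
#' @return `n` or `0`.
#' @export
diffusion_limit_count <- function(theta0_total, n, theta_c) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (theta0_total / n > theta_c) n else 0L
}

#' Observable time series of a trajectory
#'
#' @param traj a `trajectory` from [integrate_dynamics()].
#' @param theta_c threshold for the node count.
#' @return data.frame with columns `time`, `M`, `N_above`; the threshold used
#'   is attached as attribute `"theta_c"`.
#' @export
observable_series <- function(traj, theta_c) {
  stopifnot(inherits(traj, "trajectory"))
  out <- data.frame(
    time = traj$times,
    M = rowMeans(traj$states),
    N_above = apply(traj$states, 1, count_above, theta_c = theta_c)
  )
  attr(out, "theta_c") <- theta_c
  out
}

#' Classify the outcome of a trajectory
#'
#' Operationalises the asymptotic regimes: *invaded* -- every node above
#' `theta_c` and within `tol_invaded` of carrying capacity 1; *extinct* --
#' mean concentration at or below `tol_extinct`; *stalled* -- anything else
#' (e.g. a sub-threshold state frozen by the neutral Allee clamp). When the
#' graph is supplied, convergence is additionally checked via the stopping
#' rule `max_i |dtheta_i/dt| < deriv_tol`; a trajectory that has not converged
#' carries `converged = FALSE` rather than a hard label.
#'
#' @param traj a `trajectory`.
#' @param theta_c threshold concentration.
#' @param tol_extinct extinction tolerance on the final mean (default 1e-6).
#' @param tol_invaded invasion tolerance on distance to carrying capacity
#'   (default 1e-3).
#' @param g optionally the [binary_graph()] the trajectory was run on, to
#'   evaluate the stopping rule at the final state.
#' @param deriv_tol stopping-rule tolerance on the max derivative.
#' @return object of class `outcome`: list with `label` (one of `"invaded"`,
#'   `"extinct"`, `"stalled"`), `final_M`, `final_N_above`, `t_converged`
#'   (final time), `converged` (logical, `NA` when `g` is absent).
#' @export
classify_outcome <- function(traj, theta_c, tol_extinct = 1e-6,
                             tol_invaded = 1e-3, g = NULL,
                             deriv_tol = 1e-10) {
  stopifnot(inherits(traj, "trajectory"))
  final <- traj$states[nrow(traj$states), ]
  n <- length(final)
  M <- mean_concentration(final)
  Nab <- count_above(final, theta_c)
  label <- if (Nab == n && min(final) >= 1 - tol_invaded) "invaded"
           else if (M <= tol_extinct) "extinct"
           else "stalled"
  converged <- NA
  if (!is.null(g)) {
    dmax <- max(abs(rd_rhs(g, traj$config$reaction, traj$config$w, final)))
    converged <- dmax < deriv_tol
  }
  structure(list(label = label, final_M = M, final_N_above = Nab,
                 t_converged = traj$times[length(traj$times)],
                 converged = converged),
            class = "outcome")
}

#' @exportS3Method base::print
print.outcome <- function(x, ...) {
  cat(sprintf("<outcome> %s (M = %g, N_above = %d, t = %g%s)\n",
              x$label, x$final_M, x$final_N_above, x$t_converged,
              if (isFALSE(x$converged)) ", NOT converged" else ""))
  invisible(x)
}

# Chunked integration until the asymptotic outcome is decided.
#
# Two phase-line facts allow early exits (graph diffusion obeys a maximum
# principle, so max(theta) cannot increase while the reaction is off or
# negative):
#  * neutral Allee with every node at or below theta_c: the reaction is off
#    everywhere and stays off; the state relaxes diffusively toward the
#    sub-threshold uniform mean => stalled (or extinct if the mean is tiny).
#  * strong Allee with every node below theta_c: the reaction is strictly
#    negative wherever theta > 0, total mass decays to zero => extinct.
run_to_outcome <- function(g, config, theta0, theta_c = config$reaction$theta_c,
                           tol_extinct = 1e-6, tol_invaded = 1e-3,
                           deriv_tol = 1e-10, t_block = 5, t_max_total = 400) {
  stopifnot(inherits(g, "binary_graph"), inherits(config, "simulation_config"))
  theta <- theta0
  t_now <- 0
  kind <- config$reaction$kind
  n <- length(g$k)
  block_cfg <- simulation_config(w = config$w, reaction = config$reaction,
                                 t_max = t_block, dt = t_block,
                                 method = config$method,
                                 euler_dt = config$euler_dt,
                                 clip_negative = config$clip_negative,
                                 rtol = config$rtol, atol = config$atol)
  decide <- function(theta, converged) {
    M <- mean(theta)
    label <- if (count_above(theta, theta_c) == n &&
                 min(theta) >= 1 - tol_invaded) "invaded"
             else if (M <= tol_extinct) "extinct"
             else "stalled"
    list(label = label, final_state = theta, final_M = M,
         final_N_above = count_above(theta, theta_c),
         t_end = t_now, converged = converged)
  }
  repeat {
    if (min(theta) >= 1 - tol_invaded && count_above(theta, theta_c) == n)
      return(decide(theta, TRUE))
    if (mean(theta) <= tol_extinct)
      return(decide(theta, TRUE))
    if (kind == "neutral_allee" && max(theta) <= theta_c)
      return(decide(theta, TRUE))
    if (kind == "strong_allee" && max(theta) < theta_c)
      return(modifyList(decide(theta, TRUE), list(label = "extinct")))
    dmax <- max(abs(rd_rhs(g, config$reaction, config$w, theta)))
    if (dmax < deriv_tol) return(decide(theta, TRUE))
    if (t_now >= t_max_total) return(decide(theta, FALSE))
    tr <- integrate_dynamics(g, block_cfg, theta)
    theta <- tr$states[nrow(tr$states), ]
    t_now <- t_now + t_block
  }
}

#' Asymptotic outcome of a point-seeded simulation
#'
#' Integrates in blocks until the outcome is decided (full invasion,
#' extinction, a frozen sub-threshold state, or a vanishing derivative) and
#' classifies it. This is the workhorse behind [invasion_value()].
#'
#' @param g a [binary_graph()].
#' @param config a [simulation_config()]; its `t_max`/`dt` are ignored in
#'   favour of the block schedule.
#' @param seed_node seed node index (1-based).
#' @param theta0 initial concentration at the seed.
#' @param ... passed to the internal driver (`theta_c`, `tol_extinct`,
#'   `tol_invaded`, `deriv_tol`, `t_block`, `t_max_total`).
#' @return list with `label`, `final_state`, `final_M`, `final_N_above`,
#'   `t_end`, `converged`.
#' @export
seed_outcome <- function(g, config, seed_node, theta0, ...) {
  run_to_outcome(g, config, point_seed(length(g$k), seed_node, theta0), ...)
}

#' Invasion value of a seed node by bisection
#'
#' The invasion value is the minimal initial concentration `theta0` injected
#' into a single node above which the dynamics asymptotically invade the
#' whole graph (`M -> 1`, all nodes above `theta_c`). It has no closed form;
#' it is found by bisection on `theta0`, relying on outcome monotonicity
#' (invaded at `theta0` implies invaded at any larger `theta0`), which is
#' checked at the bracket ends.
#'
#' @param g a [binary_graph()].
#' @param config a [simulation_config()] fixing `w` and the reaction.
#' @param seed_node seed node index (1-based).
#' @param bracket `c(lo, hi)`: `lo` must fail to invade and `hi` must invade.
#'   Default `c(theta_c / 10, 1)`.
#' @param tol bracket width at which bisection stops (default 1e-4).
#' @param ... passed on to [seed_outcome()] (e.g. `t_max_total`).
#' @return scalar midpoint of the final bracket, with attributes `bracket`
#'   (the final `c(lo, hi)`) and `n_sim` (number of simulations run).
#' @export
invasion_value <- function(g, config, seed_node,
                           bracket = c(config$reaction$theta_c / 10, 1),
                           tol = 1e-4, ...) {
  lo <- bracket[1]; hi <- bracket[2]
  if (!(lo >= 0 && hi > lo)) stop("bracket must satisfy 0 <= lo < hi",
                                  call. = FALSE)
  n_sim <- 0L
  outcome_at <- function(th) {
    n_sim <<- n_sim + 1L
    seed_outcome(g, config, seed_node, th, ...)$label
  }
  if (lo > 0 && outcome_at(lo) == "invaded")
    stop(sprintf(
      "invalid bracket: theta0 = %g already invades; widen the bracket downward",
      lo), call. = FALSE)
  if (outcome_at(hi) != "invaded")
    stop(sprintf(
      "invalid bracket: theta0 = %g does not invade; widen the bracket upward",
      hi), call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (outcome_at(mid) == "invaded") hi <- mid else lo <- mid
  }
  structure((lo + hi) / 2, bracket = c(lo, hi), n_sim = n_sim)
}

#' Scan seed concentrations for invasion outcomes
#'
#' Runs [seed_outcome()] for every combination of seed node and initial
#' concentration and tabulates the outcome labels. Useful for mapping where
#' the invasion value lies before bisecting, and for comparing seed locations
#' (hub versus pendant) on the same grid.
#'
#' @param g a [binary_graph()].
#' @param config a [simulation_config()].
#' @param seed_nodes vector of node indices (1-based).
#' @param theta0_grid vector of initial concentrations.
#' @param ... passed to [seed_outcome()].
#' @return data.frame with columns `seed_node`, `theta0`, `label`, `final_M`,
#'   `final_N_above`, `t_end`, `converged`.
#' @export
invasion_scan <- function(g, config, seed_nodes, theta0_grid, ...) {
  rows <- list()
  for (sn in seed_nodes) for (th in theta0_grid) {
    o <- seed_outcome(g, config, sn, th, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      seed_node = sn, theta0 = th, label = o$label, final_M = o$final_M,
      final_N_above = o$final_N_above, t_end = o$t_end,
      converged = o$converged)
  }
  do.call(rbind, rows)
}
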