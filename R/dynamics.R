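#' Simulation configuration
#'
#' @param w diffusion rate, `>= 0` (per unit time; time units are arbitrary).
#' @param reaction a [reaction_spec()]; use kind `"none"` for pure diffusion.
#' @param t_max end time of the simulation, `> 0`.
#' @param dt output sampling interval, `> 0`.
#' @param method integration scheme: `"rk45"` (adaptive Dormand-Prince,
#'   default), `"euler"` (fixed-step explicit Euler), or `"expm"` (exact
#'   heat-kernel solution; valid only for reaction kind `"none"`).
#' @param euler_dt internal step for the Euler scheme. Automatically reduced
#'   (with a warning) if it violates the explicit-scheme stability bound
#'   `0.5 / (w k_max + r sup|g'|)`.
#' @param clip_negative clip transient negative concentrations (a
#'   discretisation artefact) to zero. Default `TRUE`.
#' @param rtol,atol relative and absolute tolerances for the adaptive scheme.
#'   The absolute tolerance defaults well below the Allee threshold scale
#'   `theta_c = 0.001` so that threshold-crossing classification is reliable.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(w = 1, reaction = reaction_spec("logistic"),
                              t_max = 10, dt = 0.1,
                              method = c("rk45", "euler", "expm"),
                              euler_dt = 1e-3, clip_negative = TRUE,
                              rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  stopifnot(inherits(reaction, "reaction_spec"))
  if (!is.numeric(w) || length(w) != 1 || !is.finite(w) || w < 0)
    stop("w must be a single non-negative number", call. = FALSE)
  if (t_max <= 0 || dt <= 0 || euler_dt <= 0)
    stop("t_max, dt and euler_dt must be positive", call. = FALSE)
  if (method == "expm" && reaction$kind != "none")
    stop("method 'expm' solves pure diffusion only; set reaction kind 'none'",
         call. = FALSE)
  structure(list(w = w, reaction = reaction, t_max = t_max, dt = dt,
                 method = method, euler_dt = euler_dt,
                 clip_negative = clip_negative, rtol = rtol, atol = atol),
            class = "simulation_config")
}

#' Point-seed initial condition
#'
#' An empty network except for concentration `theta0` injected into a single
#' node: `theta_j(0) = theta0 * delta_{ij}`. Models a focal injury or a
#' localised onset of pathology in one brain region.
#'
#' @param n number of nodes.
#' @param node seed node index (1-based).
#' @param theta0 initial concentration at the seed, `> 0`.
#' @return numeric vector of length `n`.
#' @export
point_seed <- function(n, node, theta0) {
  if (node < 1 || node > n || node != round(node))
    stop("node must be an integer in 1..", n, call. = FALSE)
  if (!is.numeric(theta0) || theta0 <= 0)
    stop("theta0 must be positive", call. = FALSE)
  theta <- numeric(n)
  theta[node] <- theta0
  theta
}

# Symmetric eigendecomposition of L, cached per call site.
laplacian_eigen <- function(L) {
  e <- eigen(L, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors)
}

#' Closed-form network diffusion via the heat kernel
#'
#' Evaluates `theta(t) = expm(w L t) theta(0)`, the exact solution of the
#' network diffusion equation `theta' = w L theta`, through the symmetric
#' eigendecomposition of `L`. Total concentration is conserved exactly (the
#' all-ones vector spans the kernel of `L`).
#'
#' @param L graph Laplacian from [graph_laplacian()] (or any symmetric
#'   negative-semidefinite matrix).
#' @param theta0 initial concentration vector.
#' @param w diffusion rate.
#' @param t a single time `>= 0`, or a vector of times.
#' @param eig optional precomputed `eigen(L, symmetric = TRUE)`-style list
#'   (fields `values`, `vectors`) to reuse across many calls.
#' @return for scalar `t`, a vector of length N; for vector `t`, a
#'   `length(t)` x N matrix with one row per time.
#' @export
diffuse_closed_form <- function(L, theta0, w, t, eig = NULL) {
  if (length(theta0) != nrow(L))
    stop("theta0 length (", length(theta0), ") does not match L (",
         nrow(L), ")", call. = FALSE)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (is.null(eig)) eig <- laplacian_eigen(L)
  proj <- drop(crossprod(eig$vectors, theta0))   # coordinates in eigenbasis
  out <- vapply(t, function(tt) {
    if (tt == 0) return(as.numeric(theta0))      # exact identity at t = 0
    drop(eig$vectors %*% (exp(w * eig$values * tt) * proj))
  }, numeric(length(theta0)))
  if (length(t) == 1) drop(out) else t(out)
}

#' Right-hand side of the reaction-diffusion equation on a graph
#'
#' `dtheta_i/dt = w (sum_j A_ij theta_j - k_i theta_i) + r g(theta_i)`:
#' diffusive exchange along the edges plus the local reaction inside each
#' node.
#'
#' @param g a [binary_graph()].
#' @param spec a [reaction_spec()].
#' @param w diffusion rate.
#' @param theta concentration vector.
#' @return derivative vector of the same length.
#' @export
rd_rhs <- function(g, spec, w, theta) {
  stopifnot(inherits(g, "binary_graph"))
  if (length(theta) != length(g$k))
    stop("theta length does not match the graph", call. = FALSE)
  w * (drop(g$A %*% theta) - g$k * theta) + reaction_rate(spec, theta)
}

# Stability bound for the explicit Euler scheme: dt <= 0.5 / (w k_max + r G')
# with G' an upper bound on |g'| over [0, 1].
euler_stable_dt <- function(g, config) {
  sp <- config$reaction
  gp <- switch(sp$kind,
               none = 0,
               logistic = 1,
               strong_allee = 1 + sp$theta_c,
               neutral_allee = 1 + sp$theta_c)
  denom <- config$w * max(g$k, 0) + sp$r * gp
  if (denom <= 0) Inf else 0.5 / denom
}

#' Integrate reaction-diffusion dynamics on a graph
#'
#' Integrates `theta' = w L theta + r g(theta)` from `theta0`, sampling the
#' state at `0, dt, 2 dt, ..., t_max`.
#'
#' Methods: `"rk45"` delegates to an adaptive embedded Dormand-Prince scheme
#' (deSolve), `"euler"` is a fixed-step explicit scheme with internal step
#' `euler_dt` (reduced automatically if it violates the stability bound), and
#' `"expm"` evaluates the exact heat-kernel solution (pure diffusion only).
#'
#' @param g a [binary_graph()].
#' @param config a [simulation_config()].
#' @param theta0 initial concentration vector (length = number of nodes).
#' @return object of class `trajectory`: list with `times` (ascending, from
#'   0), `states` (a `length(times)` x N matrix, one row per time point),
#'   `config`, `labels`, and `graph_info` provenance.
#' @examples
#' g <- make_small_fixtures()$P2
#' cfg <- simulation_config(w = 1, reaction = reaction_spec("none"),
#'                          t_max = 2, dt = 0.5, method = "expm")
#' tr <- integrate_dynamics(g, cfg, point_seed(2, 1, 1))
#' rowSums(tr$states)  # conserved
#' @export
integrate_dynamics <- function(g, config, theta0) {
  stopifnot(inherits(g, "binary_graph"), inherits(config, "simulation_config"))
  n <- length(g$k)
  if (length(theta0) != n)
    stop("theta0 length (", length(theta0), ") does not match the graph (",
         n, " nodes)", call. = FALSE)
  times <- seq(0, config$t_max, by = config$dt)
  if (times[length(times)] < config$t_max)
    times <- c(times, config$t_max)
  states <- switch(config$method,
    expm  = integrate_expm(g, config, theta0, times),
    euler = integrate_euler(g, config, theta0, times),
    rk45  = integrate_rk45(g, config, theta0, times))
  if (any(!is.finite(states)))
    stop("non-finite state encountered during integration (method ",
         config$method, "); reduce the step size or check the inputs",
         call. = FALSE)
  if (config$clip_negative) states[states < 0] <- 0
  structure(list(times = times, states = states, config = config,
                 labels = g$labels,
                 graph_info = list(n_nodes = n, n_links = sum(g$k) / 2,
                                   threshold_used = g$threshold_used)),
            class = "trajectory")
}

integrate_expm <- function(g, config, theta0, times) {
  eig <- laplacian_eigen(graph_laplacian(g))
  st <- diffuse_closed_form(graph_laplacian(g), theta0, config$w, times,
                            eig = eig)
  if (is.null(dim(st))) st <- matrix(st, nrow = length(times))
  st[1, ] <- theta0   # t = 0 is the identity, exactly
  st
}

integrate_euler <- function(g, config, theta0, times) {
  h <- config$euler_dt
  h_stab <- euler_stable_dt(g, config)
  if (h > h_stab) {
    warning(sprintf(
      "euler_dt = %g exceeds the stability bound %g; reducing the step",
      h, h_stab), call. = FALSE)
    h <- h_stab
  }
  As <- Matrix::Matrix(g$A, sparse = TRUE)
  k <- g$k; w <- config$w; sp <- config$reaction
  clip <- config$clip_negative
  states <- matrix(NA_real_, length(times), length(theta0))
  states[1, ] <- theta <- theta0
  for (j in seq_along(times)[-1]) {
    span <- times[j] - times[j - 1]
    m <- max(1L, ceiling(span / h))
    hh <- span / m
    for (s in seq_len(m)) {
      theta <- theta + hh * (w * (as.numeric(As %*% theta) - k * theta) +
                               reaction_rate(sp, theta))
      if (clip) theta[theta < 0] <- 0
    }
    states[j, ] <- theta
  }
  states
}

integrate_rk45 <- function(g, config, theta0, times) {
  As <- Matrix::Matrix(g$A, sparse = TRUE)
  k <- g$k; w <- config$w; sp <- config$reaction
  rhs <- function(t, y, parms) {
    list(w * (as.numeric(As %*% y) - k * y) + reaction_rate(sp, y))
  }
  # start below the explicit stability step: the cubic reaction overflows if
  # the first trial step is as large as the output interval
  hini <- min(config$dt, euler_stable_dt(g, config))
  sol <- deSolve::ode(y = theta0, times = times, func = rhs, parms = NULL,
                      method = "ode45", rtol = config$rtol, atol = config$atol,
                      hini = hini, maxsteps = 1e5)
  unname(as.matrix(sol)[, -1, drop = FALSE])
}

#' @exportS3Method base::print
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d nodes, %d time points on [0, %g], method %s, reaction %s\n",
    ncol(x$states), length(x$times), max(x$times), x$config$method,
    x$config$reaction$kind))
  invisible(x)
}
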