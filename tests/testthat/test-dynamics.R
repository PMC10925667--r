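test_that("point seeds put theta0 on one node and nothing elsewhere", {
  expect_equal(point_seed(3, 2, 0.1), c(0, 0.1, 0))
  expect_equal(point_seed(1, 1, 1), 1)
  expect_equal(sum(point_seed(379, 53, 0.1)), 0.1)
  expect_error(point_seed(3, 4, 0.1), "1..3")
  expect_error(point_seed(3, 1, 0), "positive")
})

test_that("the heat-kernel solution matches the two-node analytic form", {
  L <- graph_laplacian(make_small_fixtures()$P2)
  th0 <- c(1, 0)
  expect_identical(diffuse_closed_form(L, th0, 1, 0), th0)
  for (t in c(0.1, 0.7, 2)) {
    # eigenvalues of the 2-node Laplacian are {0, -2}
    expect_equal(diffuse_closed_form(L, th0, 1, t),
                 c((1 + exp(-2 * t)) / 2, (1 - exp(-2 * t)) / 2))
  }
  # vectorised times, one row per time point
  out <- diffuse_closed_form(L, th0, 1, c(0, 1))
  expect_equal(dim(out), c(2, 2))
})

test_that("heat-kernel diffusion conserves mass and flattens to theta0/N", {
  fx <- make_small_fixtures()
  for (g in fx[c("K3", "S4", "random_20")]) {
    n <- length(g$k)
    th0 <- point_seed(n, 1, 0.7)
    L <- graph_laplacian(g)
    short <- diffuse_closed_form(L, th0, 1, 1.5)
    expect_lt(abs(sum(short) - 0.7) / 0.7, 1e-12)
    long <- diffuse_closed_form(L, th0, 1, 200)
    expect_lt(max(abs(long - 0.7 / n)), 1e-6)
  }
})

test_that("the reaction-diffusion RHS matches hand-computed cases", {
  fx <- make_small_fixtures()
  # uniform carrying capacity is a fixed point for every reaction
  for (kind in c("logistic", "strong_allee", "neutral_allee", "none")) {
    rhs <- rd_rhs(fx$K3, reaction_spec(kind), 1, rep(1, 3))
    expect_equal(rhs, c(0, 0, 0))
  }
  # isolated node: pure logistic reaction
  isolated <- binary_graph(matrix(0, 1, 1))
  expect_equal(rd_rhs(isolated, reaction_spec("logistic"), 1, 0.5), 0.25)
  # pure flux along a single edge
  expect_equal(rd_rhs(fx$P2, reaction_spec("none"), 1, c(1, 0)), c(-1, 1))
})

test_that("all integration methods conserve mass under pure diffusion", {
  fx <- make_small_fixtures()
  for (g in fx[c("K3", "random_20", "hub_pendant_20")]) {
    n <- length(g$k)
    th0 <- point_seed(n, 1, 0.4)
    for (method in c("euler", "rk45", "expm")) {
      cfg <- simulation_config(w = 1, reaction = reaction_spec("none"),
                               t_max = 5, dt = 0.5, method = method,
                               euler_dt = 1e-3)
      tr <- integrate_dynamics(g, cfg, th0)
      expect_equal(tr$times[1], 0)
      expect_equal(tr$states[1, ], th0)
      expect_lt(max(abs(rowSums(tr$states) - 0.4)) / 0.4, 1e-9)
    }
  }
})

test_that("euler, rk45 and expm agree on pure diffusion", {
  set.seed(91)
  for (rep in 1:3) {
    repeat {
      A <- random_adjacency(sample(5:50, 1), 0.2)
      if (uf_connected(A)) break
    }
    g <- binary_graph(A)
    th0 <- stats::runif(nrow(A))
    states <- lapply(c("euler", "rk45", "expm"), function(m) {
      cfg <- simulation_config(w = 1, reaction = reaction_spec("none"),
                               t_max = 5, dt = 1, method = m,
                               euler_dt = 5e-5)
      integrate_dynamics(g, cfg, th0)$states
    })
    expect_lt(max(abs(states[[1]] - states[[3]])), 1e-5)
    expect_lt(max(abs(states[[2]] - states[[3]])), 1e-5)
  }
})

test_that("rk45 matches a brute-force Euler oracle on reaction-diffusion", {
  fx <- make_small_fixtures()
  cases <- list(list(g = fx$hub_pendant_20, kind = "logistic", th0 = 0.1),
                list(g = fx$random_20, kind = "neutral_allee", th0 = 0.3))
  for (cs in cases) {
    n <- length(cs$g$k)
    th0 <- point_seed(n, 1, cs$th0)
    cfg <- simulation_config(w = 1, reaction = reaction_spec(cs$kind,
                                                            theta_c = 0.001),
                             t_max = 3, dt = 3, method = "rk45")
    got <- integrate_dynamics(cs$g, cfg, th0)$states[2, ]
    want <- euler_oracle(cs$g$A, th0, w = 1, r = 1, kind = cs$kind,
                         theta_c = 0.001, t_max = 3, h = 1e-4)
    expect_lt(max(abs(got - want)), 1e-4)
  }
})

test_that("trajectories stay inside [0, 1] up to numerical tolerance", {
  fx <- make_small_fixtures()
  for (kind in c("logistic", "strong_allee", "neutral_allee")) {
    cfg_raw <- simulation_config(w = 1, reaction = reaction_spec(kind),
                                 t_max = 10, dt = 0.5, clip_negative = FALSE)
    tr <- integrate_dynamics(fx$hub_pendant_20, cfg_raw,
                             point_seed(20, 1, 0.9))
    expect_gt(min(tr$states), -1e-6)
    expect_lt(max(tr$states), 1 + 1e-6)
    cfg_clip <- simulation_config(w = 1, reaction = reaction_spec(kind),
                                  t_max = 10, dt = 0.5, clip_negative = TRUE)
    trc <- integrate_dynamics(fx$hub_pendant_20, cfg_clip,
                              point_seed(20, 1, 0.9))
    expect_gte(min(trc$states), 0)
  }
})

test_that("uniform 0 and uniform 1 are stationary for every reaction", {
  g <- make_small_fixtures()$random_20
  for (kind in c("logistic", "strong_allee", "neutral_allee")) {
    cfg <- simulation_config(w = 1, reaction = reaction_spec(kind),
                             t_max = 5, dt = 5)
    for (u in c(0, 1)) {
      tr <- integrate_dynamics(g, cfg, rep(u, 20))
      expect_equal(tr$states[2, ], rep(u, 20), tolerance = 1e-12)
    }
  }
})

test_that("diffusion flattens to theta0/N while logistic invades fully", {
  g <- make_small_fixtures()$random_20
  th0 <- point_seed(20, 3, 0.1)
  cfg_d <- simulation_config(w = 1, reaction = reaction_spec("none"),
                             t_max = 80, dt = 80)
  end_d <- integrate_dynamics(g, cfg_d, th0)$states[2, ]
  expect_lt(max(abs(end_d - 0.1 / 20)), 1e-6)
  cfg_l <- simulation_config(w = 1, reaction = reaction_spec("logistic"),
                             t_max = 80, dt = 80)
  end_l <- integrate_dynamics(g, cfg_l, th0)$states[2, ]
  expect_lt(max(abs(end_l - 1)), 1e-3)
})

test_that("an unstable Euler step is reduced with a warning", {
  g <- make_small_fixtures()$S4
  cfg <- simulation_config(w = 5, reaction = reaction_spec("logistic"),
                           t_max = 2, dt = 1, method = "euler",
                           euler_dt = 0.5)
  expect_warning(tr <- integrate_dynamics(g, cfg, point_seed(5, 1, 0.5)),
                 "stability")
  expect_true(all(is.finite(tr$states)))
})

test_that("expm is refused when a reaction term is active", {
  expect_error(simulation_config(reaction = reaction_spec("logistic"),
                                 method = "expm"),
               "pure diffusion")
})
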