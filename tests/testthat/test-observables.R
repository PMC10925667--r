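test_that("mean concentration is the arithmetic mean", {
  expect_equal(mean_concentration(rep(1, 7)), 1)
  expect_equal(mean_concentration(point_seed(379, 53, 0.1)), 0.1 / 379)
  expect_equal(mean_concentration(c(0.2, 0.4, 0.6)), 0.4)
  expect_error(mean_concentration(numeric(0)), "non-empty")
})

test_that("count_above uses the strict Heaviside convention", {
  tc <- 0.001
  expect_equal(count_above(rep(tc, 3), tc), 0)      # Theta(0) = 0
  expect_equal(count_above(rep(1, 10), tc), 10)
  expect_equal(count_above(c(0.0005, 0.002, 0.5), tc), 2)
  expect_equal(count_above(c(-1, 0, 0.5, 2), 0), 2) # positives only
})

test_that("the diffusion-limit count is all-or-nothing at theta0/N vs theta_c", {
  expect_equal(diffusion_limit_count(0.5, 379, 0.001), 379)
  expect_equal(diffusion_limit_count(0.1, 379, 0.001), 0)
  # boundary theta0/N == theta_c falls on the zero side
  expect_equal(diffusion_limit_count(0.379, 379, 0.001), 0)
  expect_equal(diffusion_limit_count(1e-9, 5, 0), 5)
})

test_that("observable series tracks M and N_above along a trajectory", {
  g <- make_small_fixtures()$K3
  cfg <- simulation_config(w = 1, reaction = reaction_spec("none"),
                           t_max = 1, dt = 0.5)
  tr <- integrate_dynamics(g, cfg, c(0.9, 0, 0))
  ser <- observable_series(tr, 0.001)
  expect_named(ser, c("time", "M", "N_above"))
  expect_equal(ser$time, tr$times)
  expect_equal(ser$M, rowMeans(tr$states))
  expect_equal(ser$N_above[1], 1)
  expect_equal(ser$N_above[nrow(ser)], 3)
})

test_that("long-time diffusion N_above matches the closed-form oracle", {
  g <- make_small_fixtures()$random_20
  cfg <- simulation_config(w = 1, reaction = reaction_spec("none"),
                           t_max = 150, dt = 150)
  for (th0 in c(0.1, 0.01)) {   # 0.1/20 > 1e-3, 0.01/20 < 1e-3
    final <- integrate_dynamics(g, cfg, point_seed(20, 1, th0))$states[2, ]
    expect_equal(count_above(final, 0.001),
                 diffusion_limit_count(th0, 20, 0.001))
  }
})

test_that("M is constant in time under pure diffusion", {
  g <- make_small_fixtures()$hub_pendant_20
  cfg <- simulation_config(w = 1, reaction = reaction_spec("none"),
                           t_max = 10, dt = 0.5)
  ser <- observable_series(integrate_dynamics(g, cfg, point_seed(20, 5, 0.3)),
                           0.001)
  expect_lt(max(abs(ser$M - 0.3 / 20)) / (0.3 / 20), 1e-9)
})

test_that("outcomes are classified as invaded, extinct or stalled", {
  g <- make_small_fixtures()$random_20
  # logistic from any positive seed invades
  cfg_l <- simulation_config(w = 1, reaction = reaction_spec("logistic"),
                             t_max = 60, dt = 60)
  tr <- integrate_dynamics(g, cfg_l, point_seed(20, 1, 0.05))
  oc <- classify_outcome(tr, 0.001, g = g)
  expect_equal(oc$label, "invaded")
  expect_equal(oc$final_N_above, 20)
  # strong Allee from a sub-threshold uniform start goes extinct
  cfg_s <- simulation_config(w = 1,
                             reaction = reaction_spec("strong_allee",
                                                      theta_c = 0.01),
                             t_max = 4000, dt = 2000)
  trs <- integrate_dynamics(g, cfg_s, rep(0.005, 20))
  expect_equal(classify_outcome(trs, 0.01)$label, "extinct")
  # neutral Allee below threshold with no diffusion freezes exactly
  cfg_n <- simulation_config(w = 0,
                             reaction = reaction_spec("neutral_allee",
                                                      theta_c = 0.001),
                             t_max = 5, dt = 5)
  trn <- integrate_dynamics(g, cfg_n, rep(0.0005, 20))
  ocn <- classify_outcome(trn, 0.001, g = g)
  expect_equal(ocn$label, "stalled")
  expect_true(ocn$converged)
  expect_equal(trn$states[2, ], rep(0.0005, 20))
})

test_that("the isolated-node neutral-Allee invasion value is theta_c", {
  lone <- binary_graph(matrix(0, 1, 1))
  cfg <- simulation_config(w = 1, reaction = reaction_spec("neutral_allee",
                                                           theta_c = 0.001))
  iv <- invasion_value(lone, cfg, 1, bracket = c(1e-4, 1), tol = 1e-4,
                       t_max_total = 5000)
  expect_lt(abs(iv - 0.001), 2e-4)
})

test_that("logistic invasion value collapses to the lower bracket edge", {
  g <- make_small_fixtures()$random_20
  cfg <- simulation_config(w = 1, reaction = reaction_spec("logistic"))
  iv <- invasion_value(g, cfg, 1, bracket = c(0, 0.1), tol = 1e-3)
  expect_lt(iv, 1e-3)
})

test_that("invalid brackets are reported with a widening hint", {
  g <- make_small_fixtures()$random_20
  cfg <- simulation_config(w = 1, reaction = reaction_spec("logistic"))
  expect_error(invasion_value(g, cfg, 1, bracket = c(0.1, 0.5)),
               "widen the bracket downward")
  cfg_n <- simulation_config(w = 1, reaction = reaction_spec("neutral_allee",
                                                             theta_c = 0.2))
  expect_error(invasion_value(g, cfg_n, 1, bracket = c(1e-4, 1e-3)),
               "widen the bracket upward")
})

test_that("invasion is monotone in theta0 on the shipped fixtures", {
  g <- make_small_fixtures()$hub_pendant_20
  grid <- c(0.003, 0.01, 0.03, 0.1, 0.3, 1)
  for (kind in c("logistic", "strong_allee", "neutral_allee")) {
    cfg <- simulation_config(w = 1, reaction = reaction_spec(kind,
                                                             theta_c = 0.001))
    scan <- invasion_scan(g, cfg, seed_nodes = 20, theta0_grid = grid,
                          t_max_total = 600)
    invaded <- scan$label == "invaded"
    # once invaded, larger seeds stay invaded
    expect_true(all(diff(invaded) >= 0),
                info = paste(kind, paste(scan$label, collapse = ",")))
  }
})
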