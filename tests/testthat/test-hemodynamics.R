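single_tube_profile <- function(L_px = 100, r_px = 1, px = 0.01) {
  nodes <- data.frame(id = 1:2, row = c(0, 0), col = c(0, L_px))
  make_profile(list(make_segment(c(0, 0), c(0, L_px), r_px, 1L, 2L)),
               nodes, px_size = px)
}

test_that("Poiseuille resistance and series/parallel composition are exact", {
  net <- build_flow_network(single_tube_profile(), mu = 0.035)
  expect_equal(net$edges$R_hyd, 8 * 0.035 * 1 / (pi * 0.01^4), tolerance = 1e-12)

  # two identical edges in series: total resistance doubles
  nodes <- data.frame(id = 1:3, row = c(0, 0, 0), col = c(0, 50, 100))
  series <- make_profile(list(make_segment(c(0, 0), c(0, 50), 1, 1L, 2L),
                              make_segment(c(0, 50), c(0, 100), 1, 2L, 3L)),
                         nodes, 0.01)
  ns <- build_flow_network(series)
  wf <- inlet_waveform("constant", T = 16L, peak = 1)
  sol <- solve_network(ns, wf)
  expect_equal(unname(sol$P[1L, 1L]), sum(ns$edges$R_hyd) * 1, tolerance = 1e-9)
  expect_equal(sum(ns$edges$R_hyd), 2 * ns$edges$R_hyd[1L])

  # two identical edges in parallel: conductances add
  nodesp <- data.frame(id = 1:4, row = c(0, 0, -10, 10), col = c(0, 40, 80, 80))
  par <- make_profile(list(make_segment(c(0, 0), c(0, 40), 2, 1L, 2L),
                           make_segment(c(0, 40), c(-10, 80), 1, 2L, 3L),
                           make_segment(c(0, 40), c(10, 80), 1, 2L, 4L)),
                      nodesp, 0.01)
  np <- build_flow_network(par)
  solp <- solve_network(np, wf)
  r_branch <- np$edges$R_hyd[2L]
  expect_equal(np$edges$R_hyd[3L], r_branch, tolerance = 1e-9)
  # pressure at the junction = Q * R_parallel = Q * r_branch / 2
  expect_equal(solp$node_pressure[2L, 1L], r_branch / 2, tolerance = 1e-6)
})

test_that("network construction validates structure", {
  nodes <- data.frame(id = 1:4, row = c(0, 0, 5, 5), col = c(0, 10, 50, 60))
  disc <- make_profile(list(make_segment(c(0, 0), c(0, 10), 1, 1L, 2L),
                            make_segment(c(5, 50), c(5, 60), 1, 3L, 4L)),
                       nodes, 0.01)
  expect_error(build_flow_network(disc), "disconnected")
  expect_error(build_flow_network(single_tube_profile(), inlet = 99L),
               "degree-1")
  expect_error(build_flow_network(single_tube_profile(px = 0)), "positive")
  # inlet defaults to the thickest terminal
  prof <- y_profile(parent_r = 5, daughter_r = 2, px_size = 0.01)
  expect_equal(build_flow_network(prof)$inlet, 1L)
})

test_that("waveform sampling: argmax, constancy, pulse volume", {
  wf <- inlet_waveform("halfsine", T = 20L, period = 1, peak = 2)
  expect_equal(which.max(wf$q), 10L)  # tie at 10/11 resolved to the earlier
  expect_equal(max(wf$q), 2 * sin(pi * 9.5 / 20))
  cst <- inlet_waveform("constant", T = 8L, peak = 3)
  expect_true(all(cst$q == 3))
  wf100 <- inlet_waveform("halfsine", T = 100L, period = 0.8, peak = 1.5)
  vol <- sum(wf100$q) * 0.8 / 100
  expect_lt(abs(vol - 2 * 1.5 * 0.8 / pi) / (2 * 1.5 * 0.8 / pi), 0.01)
  expect_error(inlet_waveform(T = 1L), "T >= 2")
  expect_error(inlet_waveform(peak = 0), "positive")
})

test_that("single tube obeys dP = Q * R to machine precision", {
  net <- build_flow_network(single_tube_profile())
  wf <- inlet_waveform(T = 32L, peak = 0.02)
  sol <- solve_network(net, wf)
  expect_lt(max(abs(sol$P[1L, ] - wf$q * net$edges$R_hyd)) /
              max(wf$q * net$edges$R_hyd), 1e-9)
  expect_equal(unname(sol$Q[2L, ]), wf$q, tolerance = 1e-12)
})

test_that("a symmetric bifurcation splits flow exactly in half", {
  prof <- y_profile(parent_r = 3, daughter_r = 1.5, px_size = 0.01)
  # make daughters geometrically identical
  prof$segments[[3L]] <- make_segment(c(50, 50), c(70, 80), 1.5, 2L, 4L)
  prof$segments[[2L]] <- make_segment(c(50, 50), c(30, 80), 1.5, 2L, 3L)
  sol <- solve_network(build_flow_network(prof), inlet_waveform(T = 16L, peak = 1))
  expect_equal(unname(sol$Q[2L, ]), unname(sol$Q[3L, ]), tolerance = 1e-9)
  expect_equal(unname(sol$Q[2L, 8L]), sol$waveform$q[8L] / 2, tolerance = 1e-9)
})

test_that("random trees match the independent solver and conserve mass", {
  for (s in 1:5) {
    prof <- random_tree_profile(levels = 3L, seed = s)
    net <- build_flow_network(prof)
    wf <- inlet_waveform(T = 16L, peak = 1.5)
    sol <- solve_network(net, wf)
    expect_lte(hemo_mass_residual(sol), 1e-9)
    q_or <- oracle_network_flows(net, wf$q[8L])
    expect_lt(max(abs(sol$edge_flow[, 8L] - q_or)) / max(abs(q_or)), 1e-9)
    # pressure decreases from inlet toward every outlet
    expect_true(all(sol$node_pressure[match(net$inlet, net$nodes$id), 8L] >=
                      sol$node_pressure[, 8L] - 1e-9))
    expect_true(all(sol$node_pressure[, 8L] >= net$outlet_pressure - 1e-9))
  }
})

test_that("viscosity and radius scalings follow the Poiseuille law", {
  prof <- single_tube_profile()
  n1 <- build_flow_network(prof, mu = 0.035)
  n2 <- build_flow_network(prof, mu = 0.070)
  expect_equal(n2$edges$R_hyd, 2 * n1$edges$R_hyd, tolerance = 1e-12)
  half <- single_tube_profile(r_px = 0.5)
  nh <- build_flow_network(half, mu = 0.035)
  expect_equal(nh$edges$R_hyd, 16 * n1$edges$R_hyd, tolerance = 1e-12)
})

test_that("feature extraction emits the documented schema and count", {
  sol <- solve_network(build_flow_network(single_tube_profile()),
                       inlet_waveform(T = 32L, peak = 0.01))
  fv <- extract_hemo_features(sol)
  F <- 2L; T <- 32L
  expect_length(fv, 2L * F * T + 6L * F + 2L + T)
  # the series + summary block alone counts 140 at F=2, T=32
  block <- sum(grepl("^(Q|P)_", names(fv)))
  expect_equal(block, 140L)
  expect_equal(unname(fv["Qmax_Time"]), sol$waveform$t[which.max(sol$waveform$q)])
  expect_equal(unname(fv["Qmax_Time_from_cm"]), unname(fv["Qmax_Time"]))
  expect_equal(unname(fv["Step_10_mean"]), mean(sol$Q[, 10L]))
  expect_equal(unname(fv["Q_max_inlet"]), max(sol$waveform$q))
  # constant waveform: argmax tie broken to the earliest step
  solc <- solve_network(build_flow_network(single_tube_profile()),
                        inlet_waveform("constant", T = 16L, peak = 1))
  fvc <- extract_hemo_features(solc)
  expect_equal(unname(fvc["Qmax_Time"]), solc$waveform$t[1L])
  short <- solve_network(build_flow_network(single_tube_profile()),
                         inlet_waveform(T = 12L, peak = 1))
  expect_error(extract_hemo_features(short), "13")
})
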