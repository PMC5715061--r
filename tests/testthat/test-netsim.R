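test_that("sampled edge densities match the configured probabilities", {
  set.seed(11)
  cfg <- sim_config()
  net <- build_synaptic_network(cfg)
  expect_equal(net$n_nodes, 250)
  comm <- net$community
  st <- net$structure
  expect_true(all(diag(st) == 0))
  expect_true(all(net$weights[st == 0] == 0))
  expect_equal(length(comm), 250)

  # binomial 3-sd bands around the configured densities
  within_pairs <- outer(comm, comm, "==") & row(st) != col(st)
  n_within <- sum(within_pairs)
  tol_w <- 3 * sqrt(0.35 * 0.65 / n_within)
  expect_lt(abs(mean(st[within_pairs]) - 0.35), tol_w)

  hub_out <- matrix(comm == net$hub_community, 250, 250, byrow = TRUE) &
    matrix(comm != net$hub_community, 250, 250)
  tol_h <- 3 * sqrt(0.20 * 0.80 / sum(hub_out))
  expect_lt(abs(mean(st[hub_out]) - 0.20), tol_h)

  between <- outer(comm, comm, "!=") & !hub_out
  tol_b <- 3 * sqrt(0.05 * 0.95 / sum(between))
  expect_lt(abs(mean(st[between]) - 0.05), tol_b)

  # hub community's ground-truth out-of-community out-degree dominates
  outdeg <- vapply(1:5, function(g) {
    src <- comm == g
    sum(st[!src, src]) / sum(src)
  }, numeric(1))
  expect_true(all(outdeg[net$hub_community] > outdeg[-net$hub_community]))
})

test_that("degenerate densities give block-diagonal structure", {
  set.seed(2)
  cfg <- sim_config(n_communities = 3, community_size = 4,
                    within_density = 1, between_density = 0,
                    hub_out_density = 0)
  net <- build_synaptic_network(cfg)
  comm <- net$community
  same <- outer(comm, comm, "==") & row(net$structure) != col(net$structure)
  expect_true(all(net$structure[same] == 1))
  expect_true(all(net$structure[!same & row(net$structure) != col(net$structure)] == 0))
})

test_that("weights follow the 1/sqrt(in-degree) scaling rule", {
  set.seed(5)
  cfg <- sim_config()
  net <- build_synaptic_network(cfg)
  K <- rowSums(net$structure)
  i <- which.max(K)
  w <- net$weights[i, net$structure[i, ] == 1]
  # row mean within 4 se of 1/sqrt(K_i)
  expect_lt(abs(mean(w) - 1 / sqrt(K[i])), 4 * 0.2 / sqrt(K[i]) / sqrt(K[i]))
})

test_that("network generation is reproducible from the seed", {
  cfg <- sim_config()
  set.seed(99); a <- build_synaptic_network(cfg)
  set.seed(99); b <- build_synaptic_network(cfg)
  expect_identical(a$weights, b$weights)
})

test_that("task designs draw disjoint stimulation sets inside the hub", {
  set.seed(3)
  cfg <- sim_config()
  net <- build_synaptic_network(cfg)
  des <- task_design(net, cfg)
  expect_equal(dim(des$stim_sets), c(12, 4))
  expect_equal(anyDuplicated(as.vector(des$stim_sets)), 0L)
  expect_true(all(net$community[des$stim_sets] == net$hub_community))
  expect_equal(as.integer(table(des$schedule$condition)), rep(32L, 4))
  # non-overlapping blocks
  sch <- des$schedule[order(des$schedule$onset_s), ]
  expect_true(all(diff(sch$onset_s) >= sch$duration_s[-nrow(sch)]))
})

test_that("a too-small hub community is a configuration error", {
  set.seed(4)
  cfg <- sim_config(n_communities = 5, community_size = 10)
  net <- build_synaptic_network(cfg)
  expect_error(task_design(net, cfg), "hub community has 10 nodes")
})

test_that("zero weights and zero input stay at the fixed point", {
  cfg <- sim_config(noise_sd = 0, burn_in = 0)
  ts <- simulate_dynamics(matrix(0, 4, 4), cfg, duration = 1)
  expect_true(all(ts$data == 0))
})

test_that("uncoupled node with constant input converges to the root of the drift", {
  cfg <- sim_config(s = 0.5, g = 0, noise_sd = 0, burn_in = 0, tau = 10,
                    dt = 10)
  I <- 0.3
  ts <- simulate_dynamics(matrix(0, 1, 1), cfg,
                          input = matrix(I, 1, 500), duration = 5)
  # independent root-finder on -x + s*tanh(x) + I = 0
  root <- uniroot(function(x) -x + 0.5 * tanh(x) + I, c(-5, 5),
                  tol = 1e-12)$root
  expect_lt(abs(ts$data[1, 500] - root), 1e-6)
})

test_that("simulation aborts with a diagnostic when the state diverges", {
  cfg <- sim_config(noise_sd = 0, burn_in = 0, s = 1, g = 1,
                    balanced_coupling = FALSE, tau = 1, dt = 10)
  # dt >> tau with strong positive input makes the explicit scheme blow up
  expect_error(
    simulate_dynamics(matrix(50, 2, 2) - diag(50, 2), cfg,
                      input = matrix(1e4, 2, 1000), duration = 10),
    "non-finite at integration step")
})

test_that("trajectories at study-scale parameters remain bounded", {
  set.seed(21)
  cfg <- sim_config()
  net <- build_synaptic_network(cfg)
  ts <- simulate_dynamics(net, cfg, duration = 60)
  expect_true(all(is.finite(ts$data)))
  expect_lt(max(abs(ts$data)), 50)
})

test_that("midpoint and Heun schemes agree on summary statistics at dt = 10 ms", {
  set.seed(31)
  cfg <- sim_config(n_communities = 2, community_size = 20)
  net <- build_synaptic_network(cfg)
  set.seed(77)
  a <- simulate_dynamics(net, cfg, duration = 60, method = "midpoint")
  set.seed(77)
  b <- simulate_dynamics(net, cfg, duration = 60, method = "heun")
  # same noise stream, same order of accuracy: close moments
  expect_lt(abs(sd(a$data) - sd(b$data)) / sd(a$data), 0.1)
  ca <- cor(colMeans(a$data[net$community == 1, ]),
            colMeans(a$data[net$community == 2, ]))
  cb <- cor(colMeans(b$data[net$community == 1, ]),
            colMeans(b$data[net$community == 2, ]))
  expect_lt(abs(ca - cb), 0.15)
})

test_that("BOLD conversion matches direct double-gamma evaluation on an impulse", {
  dt <- 0.1
  n_steps <- 400
  impulse <- matrix(0, 2, n_steps)
  impulse[1, 1] <- 1
  neural <- timeseries_matrix(impulse, sampling_interval = dt, kind = "neural")
  bold <- to_bold(neural, tr = 1)
  expect_equal(ncol(bold$data), 40)
  # independent closed-form double-gamma (peak-normalized like the package)
  dg <- function(t) {
    h <- t^5 * exp(-t) / gamma(6) - t^15 * exp(-t) / gamma(16) / 6
    grid <- seq(0, 32, by = 0.01)
    h / max(grid^5 * exp(-grid) / gamma(6) -
              grid^15 * exp(-grid) / gamma(16) / 6)
  }
  m <- seq_len(32)
  t_sampled <- (m * 10 - 1) * dt   # last fine sample of each TR
  expect_equal(bold$data[1, m], dg(t_sampled), tolerance = 1e-10)
  # beyond the 32 s kernel support the response is truncated to zero
  expect_true(all(abs(bold$data[1, 33:40]) < 1e-3))
  expect_true(all(bold$data[2, ] == 0))
})

test_that("BOLD conversion is linear and rejects incompatible sampling", {
  set.seed(8)
  a <- timeseries_matrix(matrix(rnorm(300), 3), 0.1, "neural")
  b <- timeseries_matrix(matrix(rnorm(300), 3), 0.1, "neural")
  ab <- timeseries_matrix(a$data + b$data, 0.1, "neural")
  expect_equal(to_bold(ab, 1)$data, to_bold(a, 1)$data + to_bold(b, 1)$data,
               tolerance = 1e-12)
  expect_error(to_bold(a, 0.25), "multiple of the neural sampling interval")
})

test_that("a simulated subject is reproducible and correctly laid out", {
  cfg <- sim_config(community_size = 15, n_stim_nodes = 3,
                    rest_duration = 30, blocks_per_condition = 2,
                    block_duration = 5, inter_block_interval = 5)
  a <- simulate_subject(cfg, seed = 123)
  b <- simulate_subject(cfg, seed = 123)
  expect_identical(a$rest$data, b$rest$data)
  expect_identical(a$task$data, b$task$data)
  expect_equal(ncol(a$rest$data), 30)
  expect_equal(ncol(a$task$data), a$design$run_duration)
  expect_equal(nrow(a$schedule), 8)
  expect_s3_class(a$rest, "timeseries_matrix")
  expect_equal(a$rest$kind, "bold")
})

test_that("null stimulation leaves task statistics at rest levels", {
  cfg <- sim_config(community_size = 15, n_stim_nodes = 3,
                    rest_duration = 60, blocks_per_condition = 3,
                    block_duration = 5, inter_block_interval = 5,
                    stim_amplitude = 0)
  subj <- simulate_subject(cfg, seed = 9)
  v_rest <- apply(subj$rest$data, 1, var)
  v_task <- apply(subj$task$data, 1, var)
  # paired comparison of per-node variances: no systematic difference
  tt <- t.test(log(v_task) - log(v_rest))
  expect_gt(tt$p.value, 0.01)
})
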