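#' Simulation configuration
#'
#' Bundles all parameters of the ground-truth network simulator: the
#' community-structured synaptic topology, the firing-rate dynamics, the
#' rest/task driving inputs, and the hemodynamic forward model. Defaults are
#' the validation-study conditions: 5 communities of 50 nodes, within-density
#' 0.35, between-density 0.05, hub out-of-community density 0.20, Gaussian
#' synaptic weights with mean 1/sqrt(K) and sd 0.2/sqrt(K) (K = realized
#' in-degree), local and global coupling s = g = 1, time constant 10 ms,
#' integration step 10 ms, unit-variance Gaussian noise, 600 s rest runs,
#' four task conditions each stimulating a distinct 12-node hub subset.
#'
#' @param n_communities number of network communities.
#' @param community_size nodes per community.
#' @param within_density probability of a directed edge within a community.
#' @param between_density probability of a directed edge between communities.
#' @param hub_out_density probability of a directed edge from a hub-community
#'   node to a node outside the hub community.
#' @param weight_mean_scale,weight_sd_scale numerators of the synaptic weight
#'   mean and sd before division by sqrt(in-degree).
#' @param s local (recurrent) coupling, unitless.
#' @param g global coupling, unitless. The default 0.3 keeps the balanced
#'   network's community modes in the stable near-critical fluctuation
#'   regime (stability requires g below the reciprocal of the leading
#'   community eigenvalue, about 0.35 at the default topology).
#' @param tau node time constant, ms.
#' @param dt integration step, ms.
#' @param noise_sd standard deviation of the spontaneous Gaussian input.
#' @param rest_duration rest-run length in seconds.
#' @param tr BOLD sampling interval in seconds.
#' @param n_conditions number of task conditions.
#' @param n_stim_nodes hub nodes stimulated per condition.
#' @param stim_amplitude constant stimulation added to each stimulated node
#'   during a task block (same units as the noise input).
#' @param blocks_per_condition task miniblocks per condition; the default
#'   (32, giving 128 miniblocks over four conditions) mirrors the miniblock
#'   count of the task paradigm the simulation emulates.
#' @param block_duration miniblock stimulation duration, seconds.
#' @param inter_block_interval rest gap after each miniblock, seconds.
#' @param burn_in initial transient discarded from every run, seconds.
#' @param balanced_coupling when `TRUE`, the synaptic drive to each node is
#'   balanced by a nonselective inhibitory feedback equal to the node's
#'   total in-weight times the network-mean activation, so recurrent
#'   excitation transmits fluctuations rather than pinning the network at a
#'   saturated operating point.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_communities = 5, community_size = 50,
                       within_density = 0.35, between_density = 0.05,
                       hub_out_density = 0.20,
                       weight_mean_scale = 1.0, weight_sd_scale = 0.2,
                       s = 1.0, g = 0.3, tau = 10, dt = 10, noise_sd = 1.0,
                       rest_duration = 600, tr = 1,
                       n_conditions = 4, n_stim_nodes = 12,
                       stim_amplitude = 0.5, blocks_per_condition = 32,
                       block_duration = 10, inter_block_interval = 10,
                       burn_in = 10, balanced_coupling = TRUE) {
  cfg <- list(n_communities = n_communities, community_size = community_size,
              within_density = within_density,
              between_density = between_density,
              hub_out_density = hub_out_density,
              weight_mean_scale = weight_mean_scale,
              weight_sd_scale = weight_sd_scale,
              s = s, g = g, tau = tau, dt = dt, noise_sd = noise_sd,
              rest_duration = rest_duration, tr = tr,
              n_conditions = n_conditions, n_stim_nodes = n_stim_nodes,
              stim_amplitude = stim_amplitude,
              blocks_per_condition = blocks_per_condition,
              block_duration = block_duration,
              inter_block_interval = inter_block_interval,
              burn_in = burn_in, balanced_coupling = balanced_coupling)
  dens <- c(within_density, between_density, hub_out_density)
  if (any(dens < 0 | dens > 1))
    stop("edge densities must lie in [0, 1]")
  if (dt <= 0 || tau <= 0) stop("dt and tau must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  topology : %d communities x %d nodes; densities %.2f within / %.2f between / %.2f hub-out\n",
              x$n_communities, x$community_size, x$within_density,
              x$between_density, x$hub_out_density))
  cat(sprintf("  weights  : N(%.2f/sqrt(K), %.2f/sqrt(K)) on in-edges\n",
              x$weight_mean_scale, x$weight_sd_scale))
  cat(sprintf("  dynamics : s=%.2g g=%.2g tau=%g ms, RK2 dt=%g ms, noise sd %.2g\n",
              x$s, x$g, x$tau, x$dt, x$noise_sd))
  cat(sprintf("  task     : %d conditions x %d blocks x %g s (amp %.2g), %d hub nodes each\n",
              x$n_conditions, x$blocks_per_condition, x$block_duration,
              x$stim_amplitude, x$n_stim_nodes))
  invisible(x)
}

#' Build a community-structured synaptic network with one hub community
#'
#' Samples a directed binary structure independently per ordered node pair
#' (no self-connections): within-community pairs connect with probability
#' `within_density`, between-community pairs with `between_density`, except
#' that edges whose source lies in the designated hub community and whose
#' target lies outside it connect with `hub_out_density`. Gaussian synaptic
#' weights are then drawn on existing edges with mean
#' `weight_mean_scale/sqrt(K_i)` and sd `weight_sd_scale/sqrt(K_i)`, where
#' `K_i` is node i's realized in-degree, so total synaptic input scales with
#' the number of inputs.
#'
#' `weights[i, j]` is the weight of the edge j -> i (receiver rows), matching
#' the dynamics in [simulate_dynamics()].
#'
#' @param config a [sim_config()].
#' @param hub_community index of the community designated as the hub.
#' @return an object of class `synaptic_network` with elements `weights`,
#'   `structure`, `community` (integer label per node), `hub_community`,
#'   `n_nodes`.
#' @export
build_synaptic_network <- function(config = sim_config(), hub_community = 1L) {
  n_c <- config$n_communities
  sz <- config$community_size
  n <- n_c * sz
  if (hub_community < 1 || hub_community > n_c)
    stop("hub_community out of range")
  community <- rep(seq_len(n_c), each = sz)

  same <- outer(community, community, "==")
  src_hub <- matrix(community == hub_community, n, n, byrow = TRUE)
  tgt_hub <- matrix(community == hub_community, n, n)
  p <- matrix(config$between_density, n, n)
  p[src_hub & !tgt_hub] <- config$hub_out_density
  p[same] <- config$within_density
  structure_mat <- matrix(rbinom(n * n, 1L, as.vector(p)), n, n)
  diag(structure_mat) <- 0L

  K <- rowSums(structure_mat)           # realized in-degree per receiver
  weights <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (K[i] == 0L) next
    j <- which(structure_mat[i, ] == 1L)
    weights[i, j] <- rnorm(K[i],
                           mean = config$weight_mean_scale / sqrt(K[i]),
                           sd = config$weight_sd_scale / sqrt(K[i]))
  }
  structure(list(weights = weights, structure = structure_mat,
                 community = community,
                 hub_community = as.integer(hub_community), n_nodes = n),
            class = "synaptic_network")
}

#' @export
print.synaptic_network <- function(x, ...) {
  cat(sprintf("Synaptic network: %d nodes, %d communities (hub = %d), %d edges (density %.3f)\n",
              x$n_nodes, length(unique(x$community)), x$hub_community,
              sum(x$structure), mean(x$structure[row(x$structure) != col(x$structure)])))
  invisible(x)
}

#' Draw a task design stimulating disjoint hub-node ensembles
#'
#' Assigns each task condition a distinct, pairwise-disjoint set of
#' `n_stim_nodes` nodes drawn at random from the hub community, and lays out
#' an interleaved miniblock schedule: `blocks_per_condition` blocks per
#' condition of `block_duration` seconds, separated by
#' `inter_block_interval` seconds of rest, with condition order randomized
#' within each cycle of all conditions so every condition appears once per
#' cycle.
#'
#' @param network a `synaptic_network`.
#' @param config a [sim_config()].
#' @return an object of class `task_design` with `stim_sets` (node-index
#'   matrix, one column per condition), `schedule` (data frame: block,
#'   condition, onset_s, duration_s), `amplitude`, and the run duration.
#' @export
task_design <- function(network, config = sim_config()) {
  hub_nodes <- which(network$community == network$hub_community)
  need <- config$n_conditions * config$n_stim_nodes
  if (length(hub_nodes) < need)
    stop(sprintf("hub community has %d nodes; %d conditions x %d stimulated nodes need %d",
                 length(hub_nodes), config$n_conditions,
                 config$n_stim_nodes, need))
  picked <- sample(hub_nodes, need)
  stim_sets <- matrix(picked, nrow = config$n_stim_nodes,
                      ncol = config$n_conditions)

  n_cycles <- config$blocks_per_condition
  cond_seq <- unlist(lapply(seq_len(n_cycles),
                            function(i) sample.int(config$n_conditions)))
  n_blocks <- length(cond_seq)
  period <- config$block_duration + config$inter_block_interval
  schedule <- data.frame(block = seq_len(n_blocks),
                         condition = cond_seq,
                         onset_s = (seq_len(n_blocks) - 1) * period,
                         duration_s = config$block_duration)
  structure(list(stim_sets = stim_sets, schedule = schedule,
                 amplitude = config$stim_amplitude,
                 run_duration = n_blocks * period),
            class = "task_design")
}

#' Node-by-timepoint time-series container
#'
#' @param data numeric matrix, nodes in rows, timepoints in columns.
#' @param sampling_interval seconds between consecutive columns.
#' @param kind `"neural"` or `"bold"`.
#' @return an object of class `timeseries_matrix`.
#' @export
timeseries_matrix <- function(data, sampling_interval,
                              kind = c("neural", "bold")) {
  kind <- match.arg(kind)
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("time series contains non-finite values")
  if (sampling_interval <= 0) stop("sampling_interval must be positive")
  structure(list(data = data, sampling_interval = sampling_interval,
                 kind = kind), class = "timeseries_matrix")
}

#' @export
print.timeseries_matrix <- function(x, ...) {
  cat(sprintf("%s time series: %d nodes x %d timepoints @ %g s\n",
              x$kind, nrow(x$data), ncol(x$data), x$sampling_interval))
  invisible(x)
}

#' Simulate firing-rate network dynamics
#'
#' Integrates, per node i,
#' `tau * dx_i/dt = -x_i + s*phi(x_i) + g * sum_j W_ij phi(x_j) + I_i(t)`
#' with `phi = tanh`, by the explicit midpoint (second-order Runge-Kutta)
#' method at step `config$dt`. The input `I_i(t)` is a fresh Gaussian draw
#' (sd `config$noise_sd`) per node per step, held constant across the two
#' stage evaluations, plus any scheduled task stimulation or user-supplied
#' input. The initial state is zero and the first `config$burn_in` seconds
#' are discarded.
#'
#' @param network a `synaptic_network` (or a bare weight matrix).
#' @param config a [sim_config()].
#' @param input `NULL` for spontaneous activity only, a `task_design` whose
#'   schedule adds constant-amplitude stimulation to the condition's nodes,
#'   or a dense node-by-timestep matrix of external input (aligned to the
#'   post-burn-in grid).
#' @param duration run length in seconds (excluding burn-in); must be a
#'   multiple of `config$dt`.
#' @param method integration scheme, `"midpoint"` (default) or `"heun"`.
#' @return a `timeseries_matrix` of kind `"neural"` sampled every `dt`.
#' @export
simulate_dynamics <- function(network, config = sim_config(), input = NULL,
                              duration = config$rest_duration,
                              method = c("midpoint", "heun")) {
  method <- match.arg(method)
  W <- if (inherits(network, "synaptic_network")) network$weights else as.matrix(network)
  n <- nrow(W)
  dt_s <- config$dt / 1000
  n_steps <- round(duration / dt_s)
  if (abs(n_steps * dt_s - duration) > 1e-9)
    stop("duration must be a multiple of the integration step")
  burn_steps <- round(config$burn_in / dt_s)
  total <- n_steps + burn_steps

  stim_cond <- integer(0)
  stim_nodes <- matrix(integer(0), 0, 0)
  stim_amp <- 0
  ext <- matrix(numeric(0), 0, 0)
  if (inherits(input, "task_design")) {
    step_t <- (seq_len(total) - 1 - burn_steps) * dt_s   # time at step start
    stim_cond <- integer(total)
    for (b in seq_len(nrow(input$schedule))) {
      on <- input$schedule$onset_s[b]
      idx <- step_t >= on & step_t < on + input$schedule$duration_s[b]
      stim_cond[idx] <- input$schedule$condition[b]
    }
    stim_nodes <- input$stim_sets
    storage.mode(stim_nodes) <- "integer"
    stim_amp <- input$amplitude
  } else if (is.matrix(input)) {
    if (nrow(input) != n || ncol(input) != n_steps)
      stop(sprintf("input matrix must be %d x %d (nodes x steps)", n, n_steps))
    ext <- cbind(matrix(0, n, burn_steps), input)
  } else if (!is.null(input)) {
    stop("input must be NULL, a task_design, or a node-by-step matrix")
  }

  integrator <- if (method == "midpoint") rk2_integrate else rk2_integrate_heun
  x <- integrator(W, rep(0, n), config$s, config$g, config$tau, config$dt,
                  as.integer(total), config$noise_sd,
                  as.integer(stim_cond), stim_nodes, stim_amp, ext,
                  as.integer(burn_steps), isTRUE(config$balanced_coupling))
  timeseries_matrix(x, sampling_interval = dt_s, kind = "neural")
}

#' Canonical double-gamma hemodynamic response function
#'
#' The conventional parameterization of the canonical HRF: a gamma density
#' peaking near `peak_delay` seconds minus a `1/ratio`-scaled undershoot
#' gamma peaking near `undershoot_delay` seconds, normalized to unit peak.
#'
#' @param t times in seconds at which to evaluate the kernel.
#' @param peak_delay,undershoot_delay response and undershoot delays (s).
#' @param peak_disp,undershoot_disp dispersions (s).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return numeric vector of HRF values (peak 1).
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1, ratio = 6) {
  h <- dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    dgamma(t, shape = undershoot_delay / undershoot_disp,
           scale = undershoot_disp) / ratio
  h[t < 0] <- 0
  grid <- seq(0, 32, by = 0.01)
  peak <- max(dgamma(grid, shape = peak_delay / peak_disp, scale = peak_disp) -
                dgamma(grid, shape = undershoot_delay / undershoot_disp,
                       scale = undershoot_disp) / ratio)
  h / peak
}

#' Convert neural activity to BOLD
#'
#' Convolves each node's neural time series with the canonical double-gamma
#' HRF sampled at the neural rate (32 s support), then decimates to one
#' sample per `tr`, taking the last convolved sample of each TR interval.
#'
#' @param neural a `timeseries_matrix` of kind `"neural"`.
#' @param tr output sampling interval in seconds; must be a multiple of the
#'   neural sampling interval.
#' @param hrf_length kernel support in seconds.
#' @return a `timeseries_matrix` of kind `"bold"` with `duration/tr` columns.
#' @export
to_bold <- function(neural, tr = 1, hrf_length = 32) {
  stopifnot(inherits(neural, "timeseries_matrix"))
  dt <- neural$sampling_interval
  factor <- tr / dt
  if (abs(factor - round(factor)) > 1e-8)
    stop("tr must be a multiple of the neural sampling interval")
  factor <- as.integer(round(factor))
  h <- canonical_hrf(seq(0, hrf_length, by = dt))
  bold <- convolve_decimate(neural$data, h, factor)
  timeseries_matrix(bold, sampling_interval = tr, kind = "bold")
}

#' Simulate one subject's rest and task sessions
#'
#' Builds a fresh synaptic network and task design, simulates a spontaneous
#' (rest) run and a task run in which scheduled miniblocks add
#' constant-amplitude stimulation to the condition's hub nodes on top of the
#' noise, and converts both to BOLD at `config$tr`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed making the whole subject reproducible.
#' @param hub_community community index designated as the hub.
#' @param keep_neural keep the raw neural time series (large) in the result.
#' @return an object of class `subject_run`: `network`, `design` (a
#'   `task_design`), `rest` and `task` (`timeseries_matrix`, kind bold),
#'   `schedule` (the block design table), `seed`.
#' @export
simulate_subject <- function(config = sim_config(), seed = NULL,
                             hub_community = 1L, keep_neural = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  network <- build_synaptic_network(config, hub_community)
  design <- task_design(network, config)
  rest_neural <- simulate_dynamics(network, config, input = NULL,
                                   duration = config$rest_duration)
  task_neural <- simulate_dynamics(network, config, input = design,
                                   duration = design$run_duration)
  out <- list(network = network, design = design,
              rest = to_bold(rest_neural, config$tr),
              task = to_bold(task_neural, config$tr),
              schedule = design$schedule, seed = seed, config = config)
  if (keep_neural) {
    out$rest_neural <- rest_neural
    out$task_neural <- task_neural
  }
  structure(out, class = "subject_run")
}

#' @export
print.subject_run <- function(x, ...) {
  cat(sprintf("Simulated subject (seed %s): rest %d x %d, task %d x %d BOLD samples, %d miniblocks\n",
              format(x$seed), nrow(x$rest$data), ncol(x$rest$data),
              nrow(x$task$data), ncol(x$task$data), nrow(x$schedule)))
  invisible(x)
}
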