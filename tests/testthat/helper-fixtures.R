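# Shared fixtures, built once per test run. Sizes are kept small; the
# acceptance tests use study-scale runs.

fx <- new.env(parent = emptyenv())

fixture_config <- function() {
  if (is.null(fx$cfg)) fx$cfg <- maze_config()
  fx$cfg
}

# one small late-regime day (depletion-aware agent)
fixture_sim <- function() {
  if (is.null(fx$sim)) {
    fx$sim <- simulate_agent(fixture_config(),
                             agent_params(depletion_factor = 0.8,
                                          decay = 0.05),
                             n_sessions = 2L, trials_per_session = 250L,
                             seed = 421L)
  }
  fx$sim
}

# matching 40-neuron population with fine grid
fixture_pop <- function() {
  if (is.null(fx$pop)) {
    sim <- fixture_sim()
    spec <- make_coding_spec(n_neurons = 40L, seed = 422L)
    fx$spec <- spec
    fx$pop <- generate_population(sim$trials, sim$trace, spec, seed = 423L,
                                  fine_grid = TRUE)
  }
  fx$pop
}

fixture_spec <- function() {
  fixture_pop()
  fx$spec
}

# progression-level decoder set on the fixture population
fixture_decoder <- function() {
  if (is.null(fx$decoder)) {
    design <- assign_bins_and_groups(fixture_pop(), "progression")
    fx$decoder <- train_decoders_cv(design, seed = 424L)
  }
  fx$decoder
}

# hand-built trial table: patch sequence given as dest patches, ports
# chosen consistently; timing synthetic
toy_trials <- function(dest_patches, rewards = NULL, session = 1L) {
  n <- length(dest_patches)
  if (is.null(rewards)) rewards <- rep(0L, n)
  dest_port <- integer(n)
  origin_port <- integer(n)
  origin_patch <- integer(n)
  cur_port <- 2L * dest_patches[1L] - 1L  # start in first patch
  cur_patch <- dest_patches[1L]
  for (i in seq_len(n)) {
    p <- dest_patches[i]
    if (p == cur_patch) {
      dp <- partner_port(cur_port)
    } else {
      dp <- 2L * p - 1L
    }
    origin_port[i] <- cur_port
    origin_patch[i] <- cur_patch
    dest_port[i] <- dp
    cur_port <- dp
    cur_patch <- p
  }
  t_start <- (seq_len(n) - 1L) * 10
  data.frame(
    day = 1L, session = session, trial = seq_len(n),
    origin_port = origin_port, dest_port = dest_port,
    origin_patch = origin_patch, dest_patch = dest_patches,
    is_switch = origin_patch != dest_patches,
    reward = rewards, effective_p = 0.5,
    t_start = t_start, t_poke = t_start + 3, t_end = t_start + 8
  )
}
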