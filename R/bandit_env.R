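#' Maze configuration for the three-patch, six-port spatial bandit
#'
#' The maze holds three Y-shaped foraging patches, each ending in two reward
#' ports (ports \code{2p - 1} and \code{2p} belong to patch \code{p}). Every
#' port carries a nominal reward probability drawn from \{0.2, 0.5, 0.8\}.
#' Repeated within-patch alternation multiplies the effective probability of
#' a port by \code{discount} on each re-visit; probabilities are restored to
#' nominal when the animal switches patch.
#'
#' @param nominal_p numeric vector of six per-port nominal reward
#'   probabilities, each in \{0.2, 0.5, 0.8\}. Exactly one patch must attain
#'   the highest mean probability, and no patch may hold the pair (0.8, 0.8).
#' @param discount per-revisit multiplicative depletion factor in (0, 1].
#' @param seed optional integer recorded for provenance (set by
#'   [sample_port_assignment()]).
#' @return An object of class \code{maze_config}: a list with
#'   \code{nominal_p}, \code{discount}, \code{patch_of_port},
#'   \code{left_neighbor} (cyclic patch receiving the turn bias: 1 to 2,
#'   2 to 3, 3 to 1), and \code{seed}.
#' @seealso [sample_port_assignment()], [effective_p()], [step_trial()]
#' @export
maze_config <- function(nominal_p = c(0.5, 0.8, 0.2, 0.5, 0.2, 0.2),
                        discount = 0.8, seed = NA_integer_) {
  stopifnot(length(nominal_p) == 6L, is.numeric(nominal_p))
  if (!all(nominal_p %in% c(0.2, 0.5, 0.8))) {
    stop("nominal_p values must come from {0.2, 0.5, 0.8}")
  }
  if (!(is.numeric(discount) && length(discount) == 1L &&
        discount > 0 && discount <= 1)) {
    stop("discount must lie in (0, 1]")
  }
  patch_of_port <- rep(1:3, each = 2L)
  patch_means <- vapply(1:3, function(p) mean(nominal_p[patch_of_port == p]),
                        numeric(1))
  if (sum(patch_means == max(patch_means)) != 1L) {
    stop("exactly one patch must attain the highest mean nominal p")
  }
  for (p in 1:3) {
    if (all(nominal_p[patch_of_port == p] == 0.8)) {
      stop("no patch may hold the nominal pair (0.8, 0.8)")
    }
  }
  structure(
    list(
      nominal_p = as.numeric(nominal_p),
      discount = discount,
      patch_of_port = patch_of_port,
      left_neighbor = c(2L, 3L, 1L),
      seed = seed
    ),
    class = "maze_config"
  )
}

#' @export
print.maze_config <- function(x, ...) {
  cat("Maze configuration (3 patches, 6 ports)\n")
  for (p in 1:3) {
    ports <- which(x$patch_of_port == p)
    cat(sprintf("  patch %d: ports %d/%d  p(R) = %.1f / %.1f\n",
                p, ports[1], ports[2],
                x$nominal_p[ports[1]], x$nominal_p[ports[2]]))
  }
  cat(sprintf("  per-revisit discount: %.2f\n", x$discount))
  invisible(x)
}

#' Ports belonging to one patch
#' @param config a [maze_config()].
#' @param patch patch identifier (1-3).
#' @return Integer vector of the two port identifiers.
#' @export
ports_of_patch <- function(config, patch) {
  which(config$patch_of_port == patch)
}

#' Partner port within the same patch
#' @param port port identifier (1-6).
#' @return The other port of the same patch.
#' @export
partner_port <- function(port) {
  as.integer(port + ifelse(port %% 2L == 1L, 1L, -1L))
}

#' Sample a nominal reward-probability assignment
#'
#' Draws a uniform sample from all assignments of \{0.2, 0.5, 0.8\} to the
#' six ports that satisfy the maze invariants: no patch holds (0.8, 0.8) and
#' exactly one patch attains the highest mean nominal probability.
#'
#' @param rng_seed integer seed; the same seed always yields the same
#'   assignment.
#' @param discount per-revisit depletion factor passed through to the config.
#' @return A [maze_config()].
#' @export
sample_port_assignment <- function(rng_seed, discount = 0.8) {
  stopifnot(is.numeric(rng_seed), length(rng_seed) == 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(rng_seed))
  levels <- c(0.2, 0.5, 0.8)
  repeat {
    p <- sample(levels, 6L, replace = TRUE)
    cfg <- tryCatch(
      maze_config(p, discount = discount, seed = as.integer(rng_seed)),
      error = function(e) NULL
    )
    if (!is.null(cfg)) return(cfg)
  }
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Fresh environment state
#'
#' Tracks the environment side of the depletion bookkeeping: per-port counts
#' of visits already made during the current patch occupancy, the last port
#' occupied, and the current patch. Visit counts are zero for every port
#' outside the current patch.
#'
#' @param start_port optional port at which the session begins. When given,
#'   the placement counts as a first visit (so a later return to that port
#'   within the same occupancy is a depleted re-visit).
#' @param config a [maze_config()] (required when \code{start_port} is set).
#' @return An object of class \code{env_state}.
#' @export
env_state <- function(start_port = NULL, config = NULL) {
  st <- structure(
    list(revisit_count = integer(6), last_port = NA_integer_,
         current_patch = NA_integer_),
    class = "env_state"
  )
  if (!is.null(start_port)) {
    stopifnot(!is.null(config))
    st$revisit_count[start_port] <- 1L
    st$last_port <- as.integer(start_port)
    st$current_patch <- config$patch_of_port[start_port]
  }
  st
}

#' Effective reward probability of a port
#'
#' Consecutive visits to the same port are never rewarded. Otherwise the
#' nominal probability is discounted once per within-occupancy visit already
#' made to that port: \code{nominal_p * discount^k}.
#'
#' @param config a [maze_config()].
#' @param state an [env_state()].
#' @param port port identifier (1-6).
#' @return Probability in [0, 1].
#' @export
effective_p <- function(config, state, port) {
  if (!(is.numeric(port) || is.integer(port)) || length(port) != 1L ||
      is.na(port) || port < 1 || port > 6) {
    stop("unknown port identifier: ", port)
  }
  port <- as.integer(port)
  if (!is.na(state$last_port) && port == state$last_port) return(0)
  config$nominal_p[port] * config$discount^state$revisit_count[port]
}

#' Advance the environment by one trial
#'
#' Draws the reward outcome Bernoulli(effective p) for the chosen port and
#' applies the depletion-repletion bookkeeping: a patch switch resets the
#' departed patch's visit counters (repletion is instantaneous), and the
#' chosen port's counter is incremented. Uses the current R random stream;
#' seed the caller for reproducibility.
#'
#' @param config a [maze_config()].
#' @param state an [env_state()].
#' @param chosen_port destination port; must differ from \code{state$last_port}.
#' @param force_p optional probability overriding the effective p (used in
#'   tests of degenerate outcomes).
#' @return A list with \code{record} (origin/destination ports and patches,
#'   switch flag, reward, effective p) and the updated \code{state}.
#' @export
step_trial <- function(config, state, chosen_port, force_p = NULL) {
  chosen_port <- as.integer(chosen_port)
  if (!is.na(state$last_port) && chosen_port == state$last_port) {
    stop("protocol violation: a trial must end at a different port")
  }
  p_eff <- if (is.null(force_p)) effective_p(config, state, chosen_port)
           else force_p
  reward <- stats::rbinom(1L, 1L, p_eff)
  dest_patch <- config$patch_of_port[chosen_port]
  origin_port <- state$last_port
  origin_patch <- state$current_patch
  is_switch <- !is.na(origin_patch) && dest_patch != origin_patch
  if (is_switch) {
    state$revisit_count[ports_of_patch(config, origin_patch)] <- 0L
  }
  state$revisit_count[chosen_port] <- state$revisit_count[chosen_port] + 1L
  state$last_port <- chosen_port
  state$current_patch <- dest_patch
  record <- list(
    origin_port = origin_port, dest_port = chosen_port,
    origin_patch = origin_patch, dest_patch = dest_patch,
    is_switch = is_switch, reward = reward, effective_p = p_eff
  )
  list(record = record, state = state)
}

#' Draw trial timing
#'
#' Run durations are log-normal with configurable medians (stay vs switch
#' trials take different typical times); the pause at the chosen port lasts
#' longer after reward than after omission, mirroring consumption versus a
#' brief check.
#'
#' @param is_switch logical, switch trial?
#' @param reward 0/1 outcome.
#' @param timing list of timing parameters (see [timing_defaults()]).
#' @return A list with \code{run} and \code{pause} durations in seconds.
#' @keywords internal
draw_timing <- function(is_switch, reward, timing = timing_defaults()) {
  med <- if (is_switch) timing$run_median_switch else timing$run_median_stay
  run <- stats::rlnorm(1L, meanlog = log(med), sdlog = timing$run_sdlog)
  pause <- if (reward == 1L) timing$pause_reward else timing$pause_omission
  list(run = run, pause = pause)
}

#' Default trial-timing parameters (seconds)
#'
#' Median run time 3 s on stay trials and 4.5 s on switch trials
#' (log-normal, sdlog 0.2); pause 5 s after reward and 0.8 s after omission.
#' These place the pre-move window (-0.8 to +0.2 s around movement
#' initiation) inside the pause on both outcomes.
#'
#' @return Named list of timing parameters.
#' @export
timing_defaults <- function() {
  list(run_median_stay = 3, run_median_switch = 4.5, run_sdlog = 0.2,
       pause_reward = 5, pause_omission = 0.8)
}

#' Serialize a maze configuration to JSON
#' @param config a [maze_config()].
#' @param path output file path.
#' @export
write_maze_config <- function(config, path) {
  obj <- list(nominal_p = config$nominal_p, discount = config$discount,
              patch_of_port = config$patch_of_port,
              left_neighbor = config$left_neighbor, seed = config$seed)
  write_json_atomic(obj, path)
  invisible(path)
}

#' Read a maze configuration from JSON
#' @param path JSON file written by [write_maze_config()].
#' @return A [maze_config()].
#' @export
read_maze_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- maze_config(obj$nominal_p, discount = obj$discount,
                     seed = if (is.null(obj$seed)) NA_integer_
                            else as.integer(obj$seed))
  cfg
}
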