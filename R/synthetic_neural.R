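#' Stay-journey identity of an ordered port pair
#'
#' The six within-patch ordered port pairs define the stay journeys:
#' journey \code{2 * (patch - 1) + 1} runs odd port to even port, journey
#' \code{2 * (patch - 1) + 2} runs even to odd.
#'
#' @param origin_port,dest_port ports of one within-patch traversal.
#' @return Integer journey id in 1..6.
#' @export
journey_id <- function(origin_port, dest_port) {
  patch <- (origin_port + 1L) %/% 2L
  as.integer(2L * (patch - 1L) + ifelse(origin_port %% 2L == 1L, 1L, 2L))
}

#' Action (turn direction) of a stay journey
#' @param journey journey id in 1..6.
#' @return 1 for odd-to-even journeys ("left"), 2 for even-to-odd ("right").
#' @export
journey_action <- function(journey) {
  ifelse(journey %% 2L == 1L, 1L, 2L)
}

#' Patch of a stay journey
#' @param journey journey id in 1..6.
#' @return Patch id in 1..3.
#' @export
journey_patch <- function(journey) {
  as.integer((journey + 1L) %/% 2L)
}

.n_bins_run <- 8L
.n_bins_out <- 3L
.n_bins <- 11L

#' Build a synthetic population coding specification
#'
#' Each neuron gets a baseline log-rate, a smooth goal-progress tuning bump
#' (with mild per-journey amplitude modulation, so task-structure coding has
#' journey-by-progression detail), and a value-gain profile over the 11
#' progression bins whose sharing follows the neuron's generality class:
#' \emph{progression} shares one profile across all journeys, \emph{action}
#' draws one per turn direction, \emph{patch} one per patch, \emph{journey}
#' one per journey, and \emph{none} carries zero gain. Gains multiply the
#' trialwise switch value on the log-rate scale, i.e., value acts as a
#' multiplicative gain on task-structure coding.
#'
#' @param n_neurons number of neurons.
#' @param class_mix named proportions over
#'   \code{c("progression","action","patch","journey","none")}; must sum
#'   to 1.
#' @param gain_scale nonnegative scale of value-gain amplitudes.
#' @param seed integer seed (spec is deterministic given the seed).
#' @param value_transition logical; when TRUE the value encoded during the
#'   outcome bins interpolates from the current trial's switch value (bin 9)
#'   to the next trial's (bin 11), linking successive trials.
#' @param rate_cap maximum instantaneous rate (Hz).
#' @return Object of class \code{coding_spec}.
#' @export
make_coding_spec <- function(n_neurons = 100L,
                             class_mix = c(progression = 0.3, action = 0.2,
                                           patch = 0.2, journey = 0.2,
                                           none = 0.1),
                             gain_scale = 0.5, seed = 1L,
                             value_transition = TRUE, rate_cap = 200) {
  if (gain_scale < 0) stop("gain_scale must be >= 0")
  classes <- c("progression", "action", "patch", "journey", "none")
  mix <- stats::setNames(rep(0, 5L), classes)
  mix[names(class_mix)] <- class_mix
  if (abs(sum(mix) - 1) > 1e-8) stop("class_mix proportions must sum to 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  # deterministic balanced assignment, remainder sampled
  n_each <- floor(mix * n_neurons)
  cls <- rep(classes, times = n_each)
  if (length(cls) < n_neurons) {
    cls <- c(cls, sample(classes, n_neurons - length(cls),
                         replace = TRUE, prob = pmax(mix, 1e-12)))
  }
  cls <- sample(cls)
  bump <- function(center, width, amp) {
    amp * exp(-((1:.n_bins) - center)^2 / (2 * width^2))
  }
  neurons <- lapply(seq_len(n_neurons), function(i) {
    class_i <- cls[i]
    baseline <- log(stats::runif(1, 2, 12))
    t_center <- stats::runif(1, 1, .n_bins)
    t_width <- stats::runif(1, 0.8, 2.5)
    t_amp <- stats::runif(1, 0.5, 1.5)
    jmod <- stats::runif(6, 0.7, 1.3)
    n_groups <- switch(class_i, progression = 1L, action = 2L,
                       patch = 3L, journey = 6L, none = 0L)
    gain <- matrix(0, .n_bins, 6L)
    g_center <- g_width <- g_amp <- numeric(0)
    if (n_groups > 0L && gain_scale > 0) {
      g_center <- stats::runif(n_groups, 1, .n_bins)
      g_width <- stats::runif(n_groups, 2, 4)
      g_amp <- gain_scale * stats::runif(n_groups, 0.5, 1.5) *
        sample(c(-1, 1), n_groups, replace = TRUE)
      group_of_journey <- switch(class_i,
        progression = rep(1L, 6L),
        action = journey_action(1:6),
        patch = journey_patch(1:6),
        journey = 1:6)
      for (j in 1:6) {
        g <- group_of_journey[j]
        gain[, j] <- bump(g_center[g], g_width[g], g_amp[g])
      }
    }
    list(class = class_i, baseline = baseline,
         tuning = list(center = t_center, width = t_width, amp = t_amp,
                       jmod = jmod),
         gain = gain,
         gain_params = list(center = g_center, width = g_width,
                            amp = g_amp))
  })
  structure(list(neurons = neurons, n_neurons = n_neurons,
                 gain_scale = gain_scale, seed = as.integer(seed),
                 value_transition = value_transition, rate_cap = rate_cap),
            class = "coding_spec")
}

#' @export
print.coding_spec <- function(x, ...) {
  cls <- vapply(x$neurons, `[[`, character(1), "class")
  cat(sprintf("Coding spec: %d neurons, gain scale %.3g, transition %s\n",
              x$n_neurons, x$gain_scale, x$value_transition))
  print(table(factor(cls, levels = c("progression", "action", "patch",
                                     "journey", "none"))))
  invisible(x)
}

# tuning evaluated at a continuous bin coordinate (1..11); x and journey
# may be vectors of equal length (journey recycled if scalar)
.tuning_at <- function(neuron, x, journey) {
  tn <- neuron$tuning
  tn$amp * tn$jmod[journey] * exp(-(x - tn$center)^2 / (2 * tn$width^2))
}

.gain_at <- function(neuron, x, journey) {
  gp <- neuron$gain_params
  if (length(gp$amp) == 0L) return(rep(0, length(x)))
  group_of_journey <- switch(neuron$class,
    progression = rep(1L, 6L),
    action = journey_action(1:6),
    patch = journey_patch(1:6),
    journey = 1:6,
    none = rep(1L, 6L))
  g <- group_of_journey[journey]
  gp$amp[g] * exp(-(x - gp$center[g])^2 / (2 * gp$width[g]^2))
}

# per-trial bin-resolved journey, value, and duration scaffolding
.population_scaffold <- function(trials, trace, spec) {
  n <- nrow(trials)
  stay_j <- ifelse(trials$is_switch, NA_integer_,
                   journey_id(trials$origin_port, trials$dest_port))
  origin_j <- journey_id(trials$origin_port, partner_port(trials$origin_port))
  dest_j <- journey_id(partner_port(trials$dest_port), trials$dest_port)
  J <- matrix(NA_integer_, n, .n_bins)
  for (b in 1:.n_bins) {
    J[, b] <- ifelse(!trials$is_switch, stay_j,
                     ifelse(b <= 4L, origin_j, dest_j))
  }
  sv <- trace$switch_value
  sv_arr <- if (!is.null(trace$switch_value_arrival)) {
    trace$switch_value_arrival
  } else {
    sv
  }
  sess <- paste(trials$day, trials$session)
  sv_next <- c(sv[-1L], NA_real_)
  sv_next[sess != c(sess[-1L], "")] <- NA_real_
  sv_next_f <- ifelse(is.na(sv_next), sv_arr, sv_next)
  # encoded value timeline: origin-referenced switch value over the first
  # path segment, arrival-referenced value after the choice point, and
  # (with the transition flag) a linear hand-off to the next trial's value
  # across the outcome bins
  V <- cbind(matrix(sv, n, 4L), matrix(sv_arr, n, .n_bins - 4L))
  if (spec$value_transition) {
    V[, 10L] <- (sv_arr + sv_next_f) / 2
    V[, 11L] <- sv_next_f
  }
  run_dur <- trials$t_poke - trials$t_start
  pause_dur <- trials$t_end - trials$t_poke
  D <- cbind(matrix(run_dur / .n_bins_run, n, .n_bins_run),
             matrix(pause_dur / .n_bins_out, n, .n_bins_out))
  list(J = J, V = V, D = D, sv = sv, sv_arr = sv_arr, sv_next = sv_next,
       sv_next_f = sv_next_f, stay_j = stay_j, origin_j = origin_j,
       dest_j = dest_j)
}

#' Generate a Poisson spiking population from a simulated day
#'
#' For every (trial, progression bin, neuron) the log-rate is baseline +
#' task-structure tuning + value gain x switch value; spike counts are
#' Poisson with exposure equal to the bin duration. The run period is
#' normalized time split into 8 equal bins, and the outcome (pause) period
#' into 3 bins. Switch trials use the origin journey's tuning over bins 1-4
#' (first path segment) and the destination journey's over bins 5-11, with
#' the origin-patch-referenced switch value throughout. When the spec's
#' transition flag is on, the outcome-period value interpolates from the
#' current trial's switch value (bin 9) to the next trial's (bin 11).
#'
#' @param trials simulated trial table.
#' @param trace matching [value_trace()] trace (supplies switch values).
#' @param spec a [make_coding_spec()].
#' @param seed integer seed; counts are bit-reproducible given the seed.
#' @param fine_grid logical; also generate a 50-sample normalized-time grid
#'   of rates and counts per trial (with absolute timestamps) for the
#'   geometry analyses.
#' @return Object of class \code{binned_population}: \code{counts}
#'   (trial x bin x neuron), \code{durations} (trial x bin), \code{labels}
#'   (per-trial condition labels incl. current/next switch value), and
#'   optionally \code{fine} (counts, rates, times, durations on the fine
#'   grid).
#' @export
generate_population <- function(trials, trace, spec, seed = 1L,
                                fine_grid = TRUE) {
  if (is.null(trace) || is.null(trace$switch_value)) {
    stop("missing value trace")
  }
  stopifnot(nrow(trials) == nrow(trace))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- nrow(trials)
  N <- spec$n_neurons
  sc <- .population_scaffold(trials, trace, spec)
  B <- matrix(rep(1:.n_bins, each = n), n, .n_bins)
  idx <- cbind(c(B), c(sc$J))
  counts <- array(0L, c(n, .n_bins, N))
  rates <- array(NA_real_, c(n, .n_bins, N))
  for (k in seq_len(N)) {
    nr <- spec$neurons[[k]]
    tun <- vapply(1:6, function(j) .tuning_at(nr, 1:.n_bins, j),
                  numeric(.n_bins))
    lam <- nr$baseline + tun[idx] + nr$gain[idx] * c(sc$V)
    r <- pmin(exp(lam), spec$rate_cap)
    counts[, , k] <- matrix(stats::rpois(n * .n_bins, r * c(sc$D)),
                            n, .n_bins)
    rates[, , k] <- matrix(r, n, .n_bins)
  }
  labels <- data.frame(
    trial_id = seq_len(n),
    day = trials$day, session = trials$session, trial = trials$trial,
    journey = sc$stay_j,
    origin_journey = sc$origin_j, dest_journey = sc$dest_j,
    action = ifelse(is.na(sc$stay_j), NA_integer_,
                    journey_action(sc$stay_j)),
    patch = trials$dest_patch, origin_patch = trials$origin_patch,
    is_switch = trials$is_switch, reward = trials$reward,
    sv_current = sc$sv, sv_arrival = sc$sv_arr, sv_next = sc$sv_next,
    t_start = trials$t_start, t_poke = trials$t_poke, t_end = trials$t_end
  )
  fine <- NULL
  if (fine_grid) {
    fine <- .generate_fine_grid(trials, sc, spec)
  }
  structure(list(counts = counts, rates = rates, durations = sc$D,
                 labels = labels, fine = fine,
                 meta = list(n_neurons = N, gain_scale = spec$gain_scale,
                             value_transition = spec$value_transition,
                             seed = as.integer(seed))),
            class = "binned_population")
}

# 50-sample grid per trial with absolute timestamps: 36 samples uniform
# over the run period (normalized progression x in [0.5, 8.5]) and 14
# samples uniform in real time over the pause. During the pause the
# progression coordinate is anchored to time-before-movement-initiation
# over a fixed 0.8 s span (x ramps 8.5 -> 11.5 across the final 0.8 s,
# clamped at 8.5 earlier), so the pre-move window carries the same
# task-structure coordinate after rewards (long pauses) and omissions
# (short pauses).
.generate_fine_grid <- function(trials, sc, spec, n_fine = 50L,
                                pre_move_span = 0.8) {
  n <- nrow(trials)
  N <- spec$n_neurons
  u <- (seq_len(n_fine) - 0.5) / n_fine
  in_run <- u < .n_bins_run / .n_bins
  n_run <- sum(in_run)
  n_pause <- n_fine - n_run
  run_dur <- trials$t_poke - trials$t_start
  pause_dur <- trials$t_end - trials$t_poke
  times <- matrix(NA_real_, n, n_fine)
  durs <- matrix(NA_real_, n, n_fine)
  frac_run <- u[in_run] / (.n_bins_run / .n_bins)
  frac_pause <- (u[!in_run] - .n_bins_run / .n_bins) / (.n_bins_out / .n_bins)
  times[, in_run] <- trials$t_start + outer(run_dur, frac_run)
  times[, !in_run] <- trials$t_poke + outer(pause_dur, frac_pause)
  durs[, in_run] <- matrix(run_dur / n_run, n, n_run)
  durs[, !in_run] <- matrix(pause_dur / n_pause, n, n_pause)
  # progression coordinate per sample
  Xf <- matrix(NA_real_, n, n_fine)
  Xf[, in_run] <- matrix(.n_bins_run * frac_run + 0.5, n, n_run,
                         byrow = TRUE)
  to_end <- trials$t_end - times[, !in_run, drop = FALSE]
  Xf[, !in_run] <- 11.5 - .n_bins_out * pmin(to_end, pre_move_span) /
    pre_move_span
  # journey per sample: switch trials change tuning at the segment boundary
  Jf <- matrix(NA_integer_, n, n_fine)
  for (i in seq_len(n_fine)) {
    Jf[, i] <- ifelse(!trials$is_switch, sc$stay_j,
                      ifelse(Xf[, i] < 4.5, sc$origin_j, sc$dest_j))
  }
  Vf <- matrix(sc$sv_arr, n, n_fine)
  Vf[, in_run][Xf[, in_run] < 4.5] <-
    matrix(sc$sv, n, n_run)[Xf[, in_run] < 4.5]
  if (spec$value_transition) {
    w <- pmin(pmax((Xf - 9) / 2, 0), 1)
    Vf <- Vf * (1 - w) + matrix(sc$sv_next_f, n, n_fine) * w
  }
  counts <- array(0L, c(n, n_fine, N))
  rates <- array(NA_real_, c(n, n_fine, N))
  for (k in seq_len(N)) {
    nr <- spec$neurons[[k]]
    lam <- nr$baseline +
      .tuning_at(nr, c(Xf), c(Jf)) +
      .gain_at(nr, c(Xf), c(Jf)) * c(Vf)
    r <- pmin(exp(lam), spec$rate_cap)
    counts[, , k] <- matrix(stats::rpois(n * n_fine, r * c(durs)),
                            n, n_fine)
    rates[, , k] <- matrix(r, n, n_fine)
  }
  list(counts = counts, rates = rates, times = times, durations = durs,
       u = u, x = Xf, in_run = in_run)
}
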