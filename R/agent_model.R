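#' Agent parameter set for the Beta-Bernoulli foraging model
#'
#' The nine-parameter behavioral model combines a Beta-Bernoulli port
#' learner with a depletion estimate, forgetting, and a structured softmax
#' over patches (plus a port-stage softmax on switch trials).
#'
#' @param gamma weight in [0, 1] placed on the upcoming port when averaging
#'   the current patch's two port values.
#' @param depletion_factor multiplier in (0, 1] applied to the agent's
#'   per-port depletion estimate \code{d} at each within-occupancy re-visit;
#'   1 means depletion is ignored (pure recency-weighted learning).
#' @param decay forgetting rate in [0, 1): non-chosen ports' pseudo-counts
#'   relax toward 1 by \code{(x - 1) * (1 - decay) + 1} each trial.
#' @param beta_stay,beta_go inverse temperatures (>= 0) scaling the current
#'   patch's and the alternative patches' integrated values.
#' @param beta_port inverse temperature (>= 0) of the port-stage softmax on
#'   switch trials.
#' @param b_stay additive stay bias on the current patch's integrated value.
#' @param b_turn additive turn bias on the patch to the left of the current
#'   one (cyclic 1 to 2, 2 to 3, 3 to 1).
#' @return An object of class \code{agent_params} (named list).
#' @export
agent_params <- function(gamma = 0.5, depletion_factor = 0.8, decay = 0.1,
                         beta_stay = 5, beta_go = 5, beta_port = 3,
                         b_stay = 1, b_turn = 0) {
  p <- list(gamma = gamma, depletion_factor = depletion_factor,
            decay = decay, beta_stay = beta_stay, beta_go = beta_go,
            beta_port = beta_port, b_stay = b_stay, b_turn = b_turn)
  validate_agent_params(p)
  structure(p, class = "agent_params")
}

validate_agent_params <- function(p) {
  stopifnot(
    p$gamma >= 0, p$gamma <= 1,
    p$depletion_factor > 0, p$depletion_factor <= 1,
    p$decay >= 0, p$decay < 1,
    p$beta_stay >= 0, p$beta_go >= 0, p$beta_port >= 0,
    is.finite(p$b_stay), is.finite(p$b_turn)
  )
  invisible(p)
}

#' @export
print.agent_params <- function(x, ...) {
  cat("Agent parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %.4f\n", nm, x[[nm]]))
  invisible(x)
}

.param_names <- c("gamma", "depletion_factor", "decay", "beta_stay",
                  "beta_go", "beta_port", "b_stay", "b_turn")

# Transformed (unconstrained) parameter space: logit for unit-interval
# parameters, log for temperatures, identity for biases. The unit-interval
# bounds are attained only in the limit; optimizers work on theta.
.logit <- function(x) stats::qlogis(pmin(pmax(x, 1e-9), 1 - 1e-9))

#' Map natural-space parameters to the unconstrained fitting space
#' @param params an [agent_params()].
#' @return Named numeric vector of length 8.
#' @export
params_to_theta <- function(params) {
  c(gamma = .logit(params$gamma),
    depletion_factor = .logit(params$depletion_factor),
    decay = .logit(params$decay),
    beta_stay = log(max(params$beta_stay, 1e-9)),
    beta_go = log(max(params$beta_go, 1e-9)),
    beta_port = log(max(params$beta_port, 1e-9)),
    b_stay = params$b_stay,
    b_turn = params$b_turn)
}

#' Map unconstrained parameters back to natural space
#' @param theta numeric vector of length 8 (order: gamma, depletion_factor,
#'   decay, beta_stay, beta_go, beta_port, b_stay, b_turn).
#' @return An [agent_params()].
#' @export
theta_to_params <- function(theta) {
  agent_params(
    gamma = stats::plogis(theta[[1]]),
    depletion_factor = stats::plogis(theta[[2]]),
    decay = stats::plogis(theta[[3]]),
    beta_stay = exp(theta[[4]]),
    beta_go = exp(theta[[5]]),
    beta_port = exp(theta[[6]]),
    b_stay = theta[[7]],
    b_turn = theta[[8]]
  )
}

#' Fresh session belief
#'
#' Per-port Beta pseudo-counts alpha and beta initialized to 1, depletion
#' estimates d initialized to 1, and within-occupancy visit counters at 0.
#' Beliefs are re-initialized at the start of every session.
#'
#' @param n_ports number of ports (>= 2; the task uses 6).
#' @param start_port optional port occupied at session start; its placement
#'   counts as a first within-occupancy visit.
#' @return Object of class \code{belief} with fields \code{alpha},
#'   \code{beta}, \code{d}, \code{visits}, \code{current_patch}.
#' @export
init_session_belief <- function(n_ports = 6L, start_port = NULL) {
  if (n_ports < 2L) stop("n_ports must be at least 2")
  b <- structure(
    list(alpha = rep(1, n_ports), beta = rep(1, n_ports),
         d = rep(1, n_ports), visits = integer(n_ports),
         current_patch = NA_integer_),
    class = "belief"
  )
  if (!is.null(start_port)) {
    b$visits[start_port] <- 1L
    b$current_patch <- rep(1:3, each = 2L)[start_port]
  }
  b
}

#' One-step belief update
#'
#' Applies, in order: (i) on a patch switch, reset of all depletion
#' estimates and occupancy counters; (ii) on a within-occupancy re-visit to
#' the chosen port, multiplication of its depletion estimate by the
#' depletion factor; (iii) the outcome update on the chosen port - reward
#' increments alpha by 1; an omission increments beta by
#' \code{(1 - mu) / (1 / d - mu)} with \code{mu = (alpha + 1) / (alpha +
#' beta + 2)}, which reduces to +1 at d = 1 and to 0 as d tends to 0 (an
#' omission at a fully depleted port carries no information about the
#' underlying rate); (iv) forgetting of all non-chosen ports toward 1.
#'
#' @param belief a \code{belief}.
#' @param chosen_port visited port.
#' @param reward 0/1 outcome.
#' @param switched logical, did this trial change patch?
#' @param params an [agent_params()].
#' @param patch_of_port port-to-patch map (default task topology).
#' @return Updated \code{belief}.
#' @export
belief_update <- function(belief, chosen_port, reward, switched, params,
                          patch_of_port = rep(1:3, each = 2L)) {
  chosen_port <- as.integer(chosen_port)
  if (switched) {
    belief$d[] <- 1
    belief$visits[] <- 0L
  }
  if (belief$visits[chosen_port] >= 1L) {
    belief$d[chosen_port] <- belief$d[chosen_port] * params$depletion_factor
  }
  d <- belief$d[chosen_port]
  if (d <= 0) stop("corrupted belief state: d <= 0")
  if (reward == 1L) {
    belief$alpha[chosen_port] <- belief$alpha[chosen_port] + 1
  } else {
    a <- belief$alpha[chosen_port]
    b <- belief$beta[chosen_port]
    mu <- (a + 1) / (a + b + 2)
    if (mu >= 1 / d) stop("corrupted belief state: mu >= 1/d")
    belief$beta[chosen_port] <- b + (1 - mu) / (1 / d - mu)
  }
  keep <- seq_along(belief$alpha) != chosen_port
  belief$alpha[keep] <- (belief$alpha[keep] - 1) * (1 - params$decay) + 1
  belief$beta[keep] <- (belief$beta[keep] - 1) * (1 - params$decay) + 1
  belief$visits[chosen_port] <- belief$visits[chosen_port] + 1L
  belief$current_patch <- patch_of_port[chosen_port]
  belief
}

#' Expected port value under the current belief
#' @param belief a \code{belief}.
#' @return Numeric vector \code{alpha / (alpha + beta)} per port.
#' @export
port_q <- function(belief) {
  belief$alpha / (belief$alpha + belief$beta)
}

#' Port and patch values given the current position
#'
#' The current patch's value is a weighted average of its two ports:
#' \code{gamma * Q_upcoming + (1 - gamma) * Q_past}, where Q_past is the
#' occupied port's value and Q_upcoming is the partner port's value
#' multiplied by the depletion estimate that would apply on that visit
#' (prospective depletion). Alternative patches take the unweighted mean of
#' their two undepleted port values.
#'
#' @param belief a \code{belief}.
#' @param current_port occupied port.
#' @param params an [agent_params()].
#' @param config a [maze_config()] (topology only).
#' @return List with \code{q_port} (length 6) and \code{q_patch} (length 3).
#' @export
port_and_patch_values <- function(belief, current_port, params,
                                  config = maze_config()) {
  qp <- port_q(belief)
  cur_patch <- config$patch_of_port[current_port]
  partner <- partner_port(current_port)
  d_next <- if (belief$visits[partner] >= 1L) {
    belief$d[partner] * params$depletion_factor
  } else {
    1
  }
  q_up <- qp[partner] * d_next
  q_past <- qp[current_port]
  q_patch <- numeric(3)
  for (p in 1:3) {
    if (p == cur_patch) {
      q_patch[p] <- params$gamma * q_up + (1 - params$gamma) * q_past
    } else {
      q_patch[p] <- mean(qp[ports_of_patch(config, p)])
    }
  }
  list(q_port = qp, q_patch = q_patch)
}

#' Patch- and port-stage choice probabilities
#'
#' Integrated patch values: the current patch gets
#' \code{beta_stay * Q + b_stay}; the left neighbor of the current patch
#' gets \code{beta_go * Q + b_turn}; the remaining patch gets
#' \code{beta_go * Q}. Patch choice is a softmax over the three integrated
#' values. For each alternative patch, port choice on a switch is a second
#' softmax over \code{beta_port * Q_port} of its two ports.
#'
#' @param q_patch numeric length-3 patch values.
#' @param q_port numeric length-6 port values.
#' @param current_patch occupied patch.
#' @param params an [agent_params()].
#' @param config a [maze_config()].
#' @return List with \code{v_patch} (integrated values), \code{p_patch}
#'   (softmax probabilities summing to 1), and \code{p_port}, a 3 x 2 matrix
#'   whose row q holds the port probabilities within patch q (NA for the
#'   current patch).
#' @export
choice_probabilities <- function(q_patch, q_port, current_patch, params,
                                 config = maze_config()) {
  v <- params$beta_go * q_patch
  v[current_patch] <- params$beta_stay * q_patch[current_patch] + params$b_stay
  left <- config$left_neighbor[current_patch]
  v[left] <- v[left] + params$b_turn
  if (any(!is.finite(v))) stop("non-finite integrated patch value")
  p_patch <- softmax(v)
  p_port <- matrix(NA_real_, 3L, 2L)
  for (q in 1:3) {
    if (q == current_patch) next
    ports <- ports_of_patch(config, q)
    p_port[q, ] <- softmax(params$beta_port * q_port[ports])
  }
  list(v_patch = v, p_patch = p_patch, p_port = p_port)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Switch value of a trial
#'
#' The decision variable for leaving: the highest-valued alternative
#' patch's integrated value minus the current patch's integrated value
#' (biases included). With a sizeable stay bias the quantity is typically
#' negative; it is invariant to adding a constant to every patch value.
#'
#' @param v_patch numeric length-3 integrated patch values.
#' @param current_patch occupied patch.
#' @return Scalar switch value.
#' @export
switch_value <- function(v_patch, current_patch) {
  max(v_patch[-current_patch]) - v_patch[current_patch]
}

#' Per-trial value trace and choice likelihood (reference implementation)
#'
#' Replays a trial table through the learner: beliefs are re-initialized at
#' each session start (the first trial's origin port counts as occupied),
#' values and choice probabilities are computed from the pre-outcome belief,
#' and the belief is updated after each trial. Equivalent to the compiled
#' likelihood used by [fit_day()]; this version additionally returns the
#' full latent trace.
#'
#' @param trials trial table (see [simulate_agent()] for the schema).
#' @param params an [agent_params()].
#' @param config a [maze_config()].
#' @return List with \code{nll} (total negative log-likelihood: patch stage
#'   on every trial plus port stage on switch trials) and \code{trace}, a
#'   data frame keyed by (day, session, trial) holding per-port Q values,
#'   patch Q and integrated values, patch probabilities, the chosen-port
#'   probability on switch trials, and the switch value.
#' @export
value_trace <- function(trials, params, config = maze_config()) {
  if (nrow(trials) == 0L) stop("empty trial table")
  n <- nrow(trials)
  qport <- matrix(NA_real_, n, 6L)
  qpatch <- matrix(NA_real_, n, 3L)
  vpatch <- matrix(NA_real_, n, 3L)
  ppatch <- matrix(NA_real_, n, 3L)
  p_dest_port <- rep(NA_real_, n)
  sv <- numeric(n)
  sv_arr <- numeric(n)
  ll <- 0
  belief <- NULL
  sess_key <- paste(trials$day, trials$session)
  prev_key <- ""
  for (i in seq_len(n)) {
    if (sess_key[i] != prev_key) {
      belief <- init_session_belief(6L, start_port = trials$origin_port[i])
      prev_key <- sess_key[i]
    }
    cur_port <- trials$origin_port[i]
    cur_patch <- trials$origin_patch[i]
    vals <- port_and_patch_values(belief, cur_port, params, config)
    ch <- choice_probabilities(vals$q_patch, vals$q_port, cur_patch, params,
                               config)
    qport[i, ] <- vals$q_port
    qpatch[i, ] <- vals$q_patch
    vpatch[i, ] <- ch$v_patch
    ppatch[i, ] <- ch$p_patch
    sv[i] <- switch_value(ch$v_patch, cur_patch)
    dest_patch <- trials$dest_patch[i]
    ll <- ll + log(ch$p_patch[dest_patch])
    if (dest_patch != cur_patch) {
      ports <- ports_of_patch(config, dest_patch)
      j <- match(trials$dest_port[i], ports)
      p_dest_port[i] <- ch$p_port[dest_patch, j]
      ll <- ll + log(p_dest_port[i])
    }
    # arrival-referenced switch value: the same pre-outcome belief evaluated
    # from the destination port, with the patch-switch repletion (reset of
    # depletion estimates) already applied - the agent's valuation after
    # committing to the choice but before the outcome
    b2 <- belief
    if (dest_patch != cur_patch) {
      b2$d[] <- 1
      b2$visits[] <- 0L
    }
    vals2 <- port_and_patch_values(b2, trials$dest_port[i], params, config)
    ch2 <- choice_probabilities(vals2$q_patch, vals2$q_port, dest_patch,
                                params, config)
    sv_arr[i] <- switch_value(ch2$v_patch, dest_patch)
    belief <- belief_update(belief, trials$dest_port[i], trials$reward[i],
                            switched = dest_patch != cur_patch, params,
                            config$patch_of_port)
  }
  trace <- data.frame(
    day = trials$day, session = trials$session, trial = trials$trial,
    switch_value = sv, switch_value_arrival = sv_arr,
    p_dest_port = p_dest_port
  )
  colnames(qport) <- paste0("qport", 1:6)
  colnames(qpatch) <- paste0("qpatch", 1:3)
  colnames(vpatch) <- paste0("vpatch", 1:3)
  colnames(ppatch) <- paste0("ppatch", 1:3)
  trace <- cbind(trace, qport, qpatch, vpatch, ppatch)
  list(nll = -ll, trace = trace)
}

#' Negative log-likelihood of observed choices
#'
#' Sum over trials of the negative log patch-stage probability of the chosen
#' patch, plus the negative log port-stage probability of the chosen port on
#' switch trials. Uses the compiled likelihood.
#'
#' @param trials trial table (one day; sessions contiguous).
#' @param params an [agent_params()] or an unconstrained theta vector.
#' @param config a [maze_config()].
#' @return Finite scalar NLL.
#' @export
negative_log_likelihood <- function(trials, params, config = maze_config()) {
  if (nrow(trials) == 0L) stop("empty trial table")
  if (inherits(params, "agent_params")) {
    par <- unlist(params[.param_names])
  } else {
    par <- unlist(theta_to_params(params)[.param_names])
  }
  nll_trials_cpp(
    as.integer(trials$origin_port), as.integer(trials$dest_port),
    as.integer(trials$origin_patch), as.integer(trials$dest_patch),
    as.integer(trials$reward),
    as.integer(as.factor(paste(trials$day, trials$session))),
    as.numeric(par), as.integer(config$patch_of_port),
    as.integer(config$left_neighbor)
  )
}

#' Central-difference gradient of the NLL in transformed space
#' @param trials trial table.
#' @param theta unconstrained parameter vector.
#' @param config a [maze_config()].
#' @param h step size.
#' @return Numeric gradient of length 8.
#' @export
nll_gradient <- function(trials, theta, config = maze_config(), h = 1e-5) {
  vapply(seq_along(theta), function(k) {
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + h
    tm[k] <- tm[k] - h
    (negative_log_likelihood(trials, tp, config) -
       negative_log_likelihood(trials, tm, config)) / (2 * h)
  }, numeric(1))
}

# Fixed multi-start jitter: reproducible unconstrained-space offsets around
# the initialization, one row per restart.
.multistart_offsets <- function(n_starts) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(20260101L)
  offs <- matrix(stats::rnorm(8L * 16L, sd = 0.8), 16L, 8L)
  offs[1L, ] <- 0
  offs[seq_len(n_starts), , drop = FALSE]
}

#' Fit one day of choices by (penalized) maximum likelihood
#'
#' Minimizes the NLL (or the negative log posterior when a Gaussian prior on
#' the transformed parameters is supplied) with BFGS from several fixed
#' jittered starting points, and reports the transformed-space Hessian at
#' the optimum (the Laplace curvature used by [fit_hierarchical()]).
#'
#' @param trials one day of trials (>= 2).
#' @param config a [maze_config()].
#' @param init an [agent_params()] used as the central starting point.
#' @param prior optional list with numeric \code{mean} and \code{sd} of
#'   length 8 (transformed space); supplying it turns the fit into a MAP fit.
#' @param n_starts number of multi-starts (fixed jitter, max 16).
#' @param maxit BFGS iteration cap per start.
#' @return List with \code{params}, \code{theta}, \code{nll} (likelihood
#'   part only), \code{objective} (including any prior penalty),
#'   \code{hessian}, \code{converged}, and \code{n_trials}. Non-convergence
#'   is flagged, not raised.
#' @export
fit_day <- function(trials, config = maze_config(), init = agent_params(),
                    prior = NULL, n_starts = 5L, maxit = 400L) {
  if (nrow(trials) < 2L) stop("need at least 2 trials to fit")
  theta0 <- params_to_theta(init)
  obj <- function(theta) {
    val <- negative_log_likelihood(trials, theta, config)
    if (!is.null(prior)) {
      val <- val + sum((theta - prior$mean)^2 / (2 * prior$sd^2))
    }
    val
  }
  offs <- .multistart_offsets(n_starts)
  best <- NULL
  for (s in seq_len(nrow(offs))) {
    fit <- tryCatch(
      stats::optim(theta0 + offs[s, ], obj, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  hess <- tryCatch(stats::optimHess(best$par, obj), error = function(e) NULL)
  grad <- nll_gradient_obj(obj, best$par)
  list(
    params = theta_to_params(best$par),
    theta = stats::setNames(best$par, .param_names),
    nll = negative_log_likelihood(trials, best$par, config),
    objective = best$value,
    hessian = hess,
    converged = best$convergence == 0L && max(abs(grad)) < 1e-2,
    n_trials = nrow(trials)
  )
}

nll_gradient_obj <- function(obj, theta, h = 1e-5) {
  vapply(seq_along(theta), function(k) {
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + h
    tm[k] <- tm[k] - h
    (obj(tp) - obj(tm)) / (2 * h)
  }, numeric(1))
}

#' Hierarchical model fit across days (Laplace EM)
#'
#' Day-level transformed parameters are modeled as draws from a diagonal
#' Gaussian population prior. The E step computes per-day MAP estimates and
#' Laplace curvatures under the current prior; the M step updates the prior
#' mean to the average MAP estimate and the prior variance to the average of
#' squared deviations plus Laplace posterior variances. Iterates until the
#' prior mean moves less than \code{tol} (infinity norm) or \code{max_iter}
#' EM sweeps.
#'
#' @param days list of >= 2 per-day trial tables.
#' @param config a [maze_config()].
#' @param init central starting point for the first E step.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the prior-mean change.
#' @param n_starts multi-starts for the first E step (later sweeps warm-start
#'   from the previous MAP).
#' @return List with \code{day_params} (list of [agent_params()]),
#'   \code{day_theta} (matrix), \code{prior} (mean/sd), \code{nll} (summed
#'   day likelihood part), \code{converged}, \code{n_iter}, and
#'   \code{day_converged} flags.
#' @export
fit_hierarchical <- function(days, config = maze_config(),
                             init = agent_params(), max_iter = 200L,
                             tol = 1e-3, n_starts = 3L) {
  if (length(days) < 2L) {
    stop("fit_hierarchical needs >= 2 days; use fit_day for a single day")
  }
  n_days <- length(days)
  prior <- list(mean = params_to_theta(init), sd = rep(2, 8L))
  theta <- matrix(rep(prior$mean, n_days), n_days, 8L, byrow = TRUE)
  fits <- vector("list", n_days)
  n_iter <- 0L
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    for (j in seq_len(n_days)) {
      init_j <- if (iter == 1L) init else theta_to_params(theta[j, ])
      fits[[j]] <- fit_day(days[[j]], config, init = init_j, prior = prior,
                           n_starts = if (iter == 1L) n_starts else 1L)
      theta[j, ] <- fits[[j]]$theta
    }
    new_mean <- colMeans(theta)
    post_var <- t(vapply(fits, function(f) {
      v <- rep(NA_real_, 8L)
      if (!is.null(f$hessian)) {
        inv <- tryCatch(solve(f$hessian), error = function(e) NULL)
        if (!is.null(inv)) v <- pmax(diag(inv), 0)
      }
      ifelse(is.finite(v), v, 0)
    }, numeric(8L)))
    new_var <- colMeans(sweep(theta, 2L, new_mean)^2 + post_var)
    delta <- max(abs(new_mean - prior$mean))
    prior <- list(mean = new_mean, sd = sqrt(pmax(new_var, 1e-6)))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(
    day_params = lapply(seq_len(n_days), function(j) theta_to_params(theta[j, ])),
    day_theta = theta,
    prior = prior,
    nll = sum(vapply(fits, function(f) f$nll, numeric(1))),
    day_converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    converged = converged,
    n_iter = n_iter
  )
}

#' Simulate a closed-loop agent in the depleting bandit
#'
#' At each trial the agent computes patch values from its belief, samples a
#' patch (and a port when switching) from the choice model, the environment
#' draws the outcome under the depletion-repletion rule, and the belief is
#' updated. Sessions start at a uniformly sampled port with fresh beliefs
#' and a fresh environment. Trial timing is drawn from [timing_defaults()].
#'
#' @param config a [maze_config()].
#' @param params an [agent_params()].
#' @param n_sessions sessions per simulated day.
#' @param trials_per_session trials per session.
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @param day day label stored in the table.
#' @param timing timing parameter list.
#' @return List with \code{trials} (data frame: day, session, trial,
#'   origin/destination ports and patches, is_switch, reward, effective_p,
#'   t_start, t_poke, t_end) and \code{trace} (the latent [value_trace()]
#'   data frame for the same trials).
#' @export
simulate_agent <- function(config = maze_config(), params = agent_params(),
                           n_sessions = 5L, trials_per_session = 300L,
                           seed = 1L, day = 1L,
                           timing = timing_defaults()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  rows <- vector("list", n_sessions * trials_per_session)
  k <- 0L
  for (s in seq_len(n_sessions)) {
    start_port <- sample.int(6L, 1L)
    state <- env_state(start_port, config)
    belief <- init_session_belief(6L, start_port = start_port)
    t_clock <- 0
    for (i in seq_len(trials_per_session)) {
      cur_port <- state$last_port
      cur_patch <- state$current_patch
      vals <- port_and_patch_values(belief, cur_port, params, config)
      ch <- choice_probabilities(vals$q_patch, vals$q_port, cur_patch,
                                 params, config)
      dest_patch <- sample.int(3L, 1L, prob = ch$p_patch)
      if (dest_patch == cur_patch) {
        dest_port <- partner_port(cur_port)
      } else {
        ports <- ports_of_patch(config, dest_patch)
        dest_port <- ports[sample.int(2L, 1L, prob = ch$p_port[dest_patch, ])]
      }
      stp <- step_trial(config, state, dest_port)
      state <- stp$state
      rec <- stp$record
      tm <- draw_timing(rec$is_switch, rec$reward, timing)
      k <- k + 1L
      rows[[k]] <- data.frame(
        day = day, session = s, trial = i,
        origin_port = cur_port, dest_port = dest_port,
        origin_patch = cur_patch, dest_patch = dest_patch,
        is_switch = rec$is_switch, reward = rec$reward,
        effective_p = rec$effective_p,
        t_start = t_clock, t_poke = t_clock + tm$run,
        t_end = t_clock + tm$run + tm$pause
      )
      t_clock <- t_clock + tm$run + tm$pause
      belief <- belief_update(belief, dest_port, rec$reward,
                              switched = rec$is_switch, params,
                              config$patch_of_port)
    }
  }
  trials <- do.call(rbind, rows)
  tr <- value_trace(trials, params, config)
  list(trials = trials, trace = tr$trace)
}
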