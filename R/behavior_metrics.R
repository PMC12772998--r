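#' Behavioral foraging summary
#'
#' Computes the behavioral meta-learning signatures from a trial table:
#' per-trial reward rate, switch-targeting probabilities, the probability of
#' switching on the trial after a reward, bout lengths, and single-visit
#' episodes. A bout is a maximal run of consecutive trials within one patch
#' (computed within sessions); a single-visit episode is a bout of length 1.
#'
#' @param trials trial table with \code{day}, \code{session},
#'   \code{dest_patch}, \code{is_switch}, \code{reward}.
#' @param config a [maze_config()] identifying the high/medium/low patches
#'   by mean nominal p.
#' @return List of class \code{foraging_summary}: \code{reward_rate},
#'   \code{p_switch_to_high} (destination of a switch from a non-high patch
#'   is the high patch), \code{p_high_to_medium} (a switch out of the high
#'   patch targets the medium patch), \code{p_switch_after_reward} (next
#'   trial is a switch given this trial was rewarded),
#'   \code{p_switch_after_reward_stay} (the same, conditioning on rewarded
#'   stay trials), \code{bout_lengths} (data frame: day, session, patch,
#'   length, single_visit, rewarded), and \code{single_visit_episodes}.
#'   Switch-conditioned probabilities are NA (undefined) when no qualifying
#'   trials exist.
#' @export
summarize_foraging <- function(trials, config = maze_config()) {
  patch_means <- vapply(1:3, function(p) {
    mean(config$nominal_p[ports_of_patch(config, p)])
  }, numeric(1))
  high <- which.max(patch_means)
  medium <- order(patch_means, decreasing = TRUE)[2L]

  sess <- split(seq_len(nrow(trials)), paste(trials$day, trials$session))
  sess <- sess[order(vapply(sess, min, integer(1)))]

  bouts <- list()
  nxt_switch_num <- 0L
  nxt_switch_den <- 0L
  nxt_switch_stay_num <- 0L
  nxt_switch_stay_den <- 0L
  for (idx in sess) {
    pat <- trials$dest_patch[idx]
    r <- rle(pat)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bouts[[length(bouts) + 1L]] <- data.frame(
      day = trials$day[idx[1L]], session = trials$session[idx[1L]],
      patch = r$values, length = r$lengths,
      start_trial = trials$trial[idx[starts]],
      single_visit = r$lengths == 1L,
      rewarded = trials$reward[idx[starts]] == 1L
    )
    n <- length(idx)
    if (n >= 2L) {
      rew <- trials$reward[idx[-n]] == 1L
      nxt <- trials$is_switch[idx[-1L]]
      nxt_switch_num <- nxt_switch_num + sum(nxt[rew])
      nxt_switch_den <- nxt_switch_den + sum(rew)
      stay_rew <- rew & !trials$is_switch[idx[-n]]
      nxt_switch_stay_num <- nxt_switch_stay_num + sum(nxt[stay_rew])
      nxt_switch_stay_den <- nxt_switch_stay_den + sum(stay_rew)
    }
  }
  bouts <- do.call(rbind, bouts)

  sw <- trials[trials$is_switch %in% TRUE, , drop = FALSE]
  from_nonhigh <- sw[sw$origin_patch != high, , drop = FALSE]
  from_high <- sw[sw$origin_patch == high, , drop = FALSE]
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(
    reward_rate = mean(trials$reward),
    p_switch_to_high = ratio(sum(from_nonhigh$dest_patch == high),
                             nrow(from_nonhigh)),
    p_high_to_medium = ratio(sum(from_high$dest_patch == medium),
                             nrow(from_high)),
    p_switch_after_reward = ratio(nxt_switch_num, nxt_switch_den),
    p_switch_after_reward_stay = ratio(nxt_switch_stay_num,
                                       nxt_switch_stay_den),
    bout_lengths = bouts,
    single_visit_episodes = bouts[bouts$single_visit, , drop = FALSE],
    high_patch = high, medium_patch = medium,
    n_trials = nrow(trials)
  ), class = "foraging_summary")
}

#' Logistic regression of switch/stay on patch values
#'
#' Predicts single-trial switch (1) versus stay (0) decisions from the
#' current patch's integrated value and the maximum alternative-patch value,
#' with a logit link. Under a depletion-aware agent the current-patch
#' coefficient is negative and the alternative-patch coefficient positive.
#' Perfect separation is flagged and the coefficients re-estimated with a
#' light ridge penalty.
#'
#' @param trace a [value_trace()] trace data frame (columns
#'   \code{vpatch1..3}).
#' @param trials matching trial table (provides \code{origin_patch} and
#'   \code{is_switch}).
#' @return List of class \code{choice_regression} with \code{coefficients},
#'   \code{se}, \code{z}, \code{p_value}, \code{separation} flag, and
#'   \code{n}.
#' @export
choice_logistic <- function(trace, trials) {
  stopifnot(nrow(trace) == nrow(trials))
  v <- as.matrix(trace[, paste0("vpatch", 1:3)])
  cur <- trials$origin_patch
  v_current <- v[cbind(seq_len(nrow(v)), cur)]
  v_alt_max <- vapply(seq_len(nrow(v)), function(i) max(v[i, -cur[i]]),
                      numeric(1))
  y <- as.integer(trials$is_switch)
  if (stats::sd(v_current) == 0 || stats::sd(v_alt_max) == 0) {
    stop("constant predictor: choice regression is degenerate")
  }
  fit <- suppressWarnings(
    stats::glm(y ~ v_current + v_alt_max, family = stats::binomial())
  )
  mu <- stats::fitted(fit)
  separated <- any(mu > 1 - 1e-8 & y == 1L) && any(mu < 1e-8 & y == 0L) ||
    max(abs(stats::coef(fit)[-1L]), na.rm = TRUE) > 50
  if (separated) {
    # ridge refit stabilizes the estimates under separation
    x <- cbind(v_current, v_alt_max)
    rf <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                         lambda = 1e-2)
    co <- c(`(Intercept)` = as.numeric(rf$a0),
            v_current = as.numeric(rf$beta[1L]),
            v_alt_max = as.numeric(rf$beta[2L]))
    se <- rep(NA_real_, 3L)
  } else {
    sm <- summary(fit)$coefficients
    co <- sm[, "Estimate"]
    se <- sm[, "Std. Error"]
  }
  z <- co / se
  structure(list(
    coefficients = co, se = se, z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    separation = separated, n = length(y)
  ), class = "choice_regression")
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows of \code{data} with replacement and recomputes
#' \code{statistic}; returns the point estimate and the percentile 95\%
#' interval. Deterministic given the seed.
#'
#' @param statistic function of a data frame (or vector) returning a scalar.
#' @param data data frame or vector of resampling units (trials, or bouts
#'   where stated).
#' @param n_iter bootstrap iterations (default 10000; fewer than 100 warns).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return List with \code{estimate}, \code{ci} (length-2), \code{n_iter}.
#' @export
bootstrap_ci <- function(statistic, data, n_iter = 10000L, seed = 1L,
                         conf = 0.95) {
  if (n_iter < 100L) warning("n_iter < 100: interval will be unstable")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  pick <- function(idx) {
    if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
  }
  est <- statistic(data)
  stats_boot <- vapply(seq_len(n_iter), function(b) {
    statistic(pick(sample.int(n, n, replace = TRUE)))
  }, numeric(1))
  a <- (1 - conf) / 2
  list(estimate = est,
       ci = unname(stats::quantile(stats_boot, c(a, 1 - a), na.rm = TRUE)),
       n_iter = n_iter)
}

#' Pooled two-proportion Z test
#'
#' Compares two proportions (e.g., early- versus late-learning switch
#' probabilities) with the pooled-variance Z statistic.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @param alternative "two.sided", "greater" (p1 > p2), or "less".
#' @return List with \code{z}, \code{p_value}, \code{p1}, \code{p2}.
#' @export
prop_z_test <- function(x1, n1, x2, n2, alternative = "two.sided") {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(z = z, p_value = p, p1 = p1, p2 = p2)
}
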