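#' Proximity-to-switch groups
#'
#' For each stay trial, the number of visits remaining until the next patch
#' switch within the session (the switch trial itself counts as the final
#' visit): a bout A, A, A followed by a switch yields groups 3, 2, 1 for
#' the stays. Switch trials and stay trials after a session's last switch
#' get NA and are never assigned a training group. Groups deeper than
#' \code{cap} share the cap value.
#'
#' @param labels population labels (or a trial table with \code{day},
#'   \code{session}, \code{is_switch}).
#' @param cap largest distinct group (default 8).
#' @return Integer vector of groups (NA for switch trials and incomplete
#'   final bouts).
#' @export
proximity_groups <- function(labels, cap = 8L) {
  n <- nrow(labels)
  groups <- rep(NA_integer_, n)
  sess <- paste(labels$day, labels$session)
  for (s in unique(sess)) {
    idx <- which(sess == s)
    sw <- idx[labels$is_switch[idx]]
    for (i in idx) {
      if (labels$is_switch[i]) next
      nxt <- sw[sw > i]
      if (length(nxt) == 0L) next
      groups[i] <- min(nxt) - i
    }
  }
  pmin(groups, as.integer(cap))
}

#' Decoding design: bins, conditions, features, and CV groups
#'
#' Builds the per-level binning used by the value decoders. The
#' \emph{progression} level pools all stay trials and uses the full 11-bin
#' scheme (8 run + 3 outcome bins). The \emph{action}, \emph{patch}, and
#' \emph{journey} levels group trials by condition and use 8 run-time bins
#' per condition (16, 24, 48 bins in total). Features are
#' duration-normalized rates (count / bin duration). Switch trials are
#' labeled with their origin-side condition over bins 1-4 (first path
#' segment) and destination-side condition over bins 5 onward, and are
#' never assigned a training group.
#'
#' @param population a [generate_population()] result.
#' @param level one of "progression", "action", "patch", "journey".
#' @param cap proximity-group cap.
#' @return Object of class \code{decoding_design}.
#' @export
assign_bins_and_groups <- function(population, level = "progression",
                                   cap = 8L) {
  lv <- c("progression", "action", "patch", "journey")
  if (!level %in% lv) stop("unknown level: ", level)
  lab <- population$labels
  n <- nrow(lab)
  n_prog <- if (level == "progression") .n_bins else .n_bins_run
  jmat <- matrix(NA_integer_, n, n_prog)
  for (b in seq_len(n_prog)) {
    jmat[, b] <- ifelse(!lab$is_switch, lab$journey,
                        ifelse(b <= 4L, lab$origin_journey,
                               lab$dest_journey))
  }
  cond <- switch(level,
    progression = matrix(1L, n, n_prog),
    action = matrix(journey_action(jmat), n, n_prog),
    patch = matrix(journey_patch(jmat), n, n_prog),
    journey = jmat)
  n_cond <- switch(level, progression = 1L, action = 2L, patch = 3L,
                   journey = 6L)
  rates <- population$counts[, seq_len(n_prog), , drop = FALSE] /
    as.numeric(population$durations[, seq_len(n_prog)])
  structure(list(
    level = level, cap = as.integer(cap), n_prog = n_prog,
    n_cond = n_cond, n_bins = n_cond * n_prog,
    cond = cond, rates = rates,
    groups = proximity_groups(lab, cap),
    is_switch = lab$is_switch,
    values = lab$sv_current, values_next = lab$sv_next,
    labels = lab, subset = NULL
  ), class = "decoding_design")
}

#' Equalize training-set sizes across decoding levels
#'
#' Reduces every design's training pool (stay trials with a proximity
#' group) to the minimum shared count by seeded sampling without
#' replacement, stratified by proximity group (largest-remainder
#' allocation keeps group proportions within one trial).
#'
#' @param designs list of [assign_bins_and_groups()] results.
#' @param seed integer seed.
#' @return The designs with their \code{subset} field set.
#' @export
matched_subsample <- function(designs, seed = 1L) {
  if (length(designs) < 2L) stop("need at least 2 levels to match")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  pools <- lapply(designs, function(d) which(!is.na(d$groups)))
  m <- min(lengths(pools))
  lapply(designs, function(d) {
    pool <- which(!is.na(d$groups))
    g <- d$groups[pool]
    tab <- table(g)
    target <- m * as.numeric(tab) / length(pool)
    take <- floor(target)
    rem <- m - sum(take)
    if (rem > 0L) {
      extra <- order(target - take, decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1L
    }
    sel <- unlist(lapply(seq_along(tab), function(i) {
      cand <- pool[g == names(tab)[i]]
      sample(cand, min(take[i], length(cand)))
    }))
    d$subset <- sort(sel)
    d
  })
}

#' Train per-bin LASSO value decoders with structured cross-validation
#'
#' For each bin, a linear readout \code{V = b0 + sum_i b_i r_i} of the
#' switch value from the population rate vector is trained by LASSO with
#' leave-one-proximity-group-out cross-validation: each proximity group is
#' held out once, the model trains on all remaining groups' stay trials
#' (the L1 penalty is chosen by inner cross-validation on the training
#' rows), and the held-out group is decoded exclusively by that model.
#' Switch trials - and stay trials without a group - are never trained on
#' and are decoded by the average of the fold models. Per-bin held-out
#' variance explained is reported against the current trial's and the next
#' trial's switch value.
#'
#' @param design an [assign_bins_and_groups()] result.
#' @param seed integer seed (inner CV fold draws).
#' @param lambda optional fixed L1 penalty; NULL selects per fold by inner
#'   5-fold cross-validation.
#' @param inner_nfolds folds of the inner lambda search.
#' @return Object of class \code{decoder_set}: \code{weights} (neurons x
#'   bins, fold-averaged), \code{intercepts}, \code{decoded} (trials x
#'   progression-bin matrix of cross-validated decoded values), \code{r2}
#'   (per-bin data frame: held-out R-squared vs current and next value),
#'   \code{cv_record} (per bin and fold: held-out group and training trial
#'   ids), plus the design metadata.
#' @export
train_decoders_cv <- function(design, seed = 1L, lambda = NULL,
                              inner_nfolds = 5L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- length(design$values)
  N <- dim(design$rates)[3L]
  groups <- design$groups
  train_ok <- !is.na(groups) & !design$is_switch
  if (!is.null(design$subset)) {
    train_ok <- train_ok & seq_len(n) %in% design$subset
  }
  glv <- sort(unique(groups[train_ok]))
  if (length(glv) < 3L) stop("need at least 3 proximity groups")
  weights <- matrix(0, N, design$n_bins)
  intercepts <- numeric(design$n_bins)
  decoded <- matrix(NA_real_, n, design$n_prog)
  r2 <- data.frame(bin = seq_len(design$n_bins), cond = NA_integer_,
                   prog_bin = NA_integer_, r2_current = NA_real_,
                   r2_next = NA_real_, n_train = NA_integer_)
  cv_record <- vector("list", design$n_bins)
  dropped <- 0L
  for (bin_id in seq_len(design$n_bins)) {
    cnd <- (bin_id - 1L) %/% design$n_prog + 1L
    b <- (bin_id - 1L) %% design$n_prog + 1L
    in_bin <- design$cond[, b] == cnd
    tr_pool <- which(in_bin & train_ok)
    if (length(tr_pool) < 3L * length(glv)) next
    X <- design$rates[, b, , drop = FALSE]
    X <- matrix(X, n, N)
    keep <- which(apply(X[tr_pool, , drop = FALSE], 2L, stats::sd) > 0)
    if (length(keep) < N) dropped <- dropped + (N - length(keep))
    if (length(keep) < 2L) next
    y <- design$values
    fold_pred <- matrix(NA_real_, n, length(glv))
    W <- matrix(0, N, length(glv))
    b0 <- numeric(length(glv))
    rec <- vector("list", length(glv))
    for (gi in seq_along(glv)) {
      g <- glv[gi]
      train <- tr_pool[groups[tr_pool] != g]
      cvf <- glmnet::cv.glmnet(X[train, keep, drop = FALSE], y[train],
                               alpha = 1, nfolds = inner_nfolds)
      lam <- if (is.null(lambda)) cvf$lambda.min else lambda
      co <- as.numeric(stats::coef(cvf, s = lam))
      b0[gi] <- co[1L]
      W[keep, gi] <- co[-1L]
      eligible <- which(in_bin)
      fold_pred[eligible, gi] <- X[eligible, keep, drop = FALSE] %*%
        co[-1L] + co[1L]
      rec[[gi]] <- list(held_out_group = g, train_trials = train)
    }
    pred <- rowMeans(fold_pred, na.rm = TRUE)
    own <- which(in_bin & train_ok)
    pred[own] <- fold_pred[cbind(own, match(groups[own], glv))]
    decoded[in_bin, b] <- pred[in_bin]
    weights[, bin_id] <- rowMeans(W)
    intercepts[bin_id] <- mean(b0)
    eval_idx <- own
    ss <- function(yv, idx) {
      idx <- idx[!is.na(yv[idx]) & !is.na(pred[idx])]
      if (length(idx) < 3L) return(NA_real_)
      1 - sum((yv[idx] - pred[idx])^2) / sum((yv[idx] - mean(yv[idx]))^2)
    }
    r2$cond[bin_id] <- cnd
    r2$prog_bin[bin_id] <- b
    r2$r2_current[bin_id] <- ss(design$values, eval_idx)
    r2$r2_next[bin_id] <- ss(design$values_next, eval_idx)
    r2$n_train[bin_id] <- length(tr_pool)
    cv_record[[bin_id]] <- rec
  }
  if (dropped > 0L) {
    message(dropped, " zero-variance neuron columns dropped across bins")
  }
  structure(list(
    weights = weights, intercepts = intercepts, decoded = decoded,
    r2 = r2, cv_record = cv_record, level = design$level,
    n_prog = design$n_prog, groups = groups, is_switch = design$is_switch,
    values = design$values, values_next = design$values_next,
    labels = design$labels
  ), class = "decoder_set")
}

#' Audit the cross-validation record
#'
#' Verifies the two structural guarantees of the decoder training scheme:
#' no switch trial ever appears in a training split, and no stay trial is
#' decoded by a model whose training split contained it.
#'
#' @param decoder_set a [train_decoders_cv()] result.
#' @return List with \code{n_switch_in_training} and
#'   \code{n_self_decoding} (both must be 0) and \code{passed}.
#' @export
audit_cv <- function(decoder_set) {
  n_sw <- 0L
  n_self <- 0L
  sw_trials <- which(decoder_set$is_switch)
  for (rec in decoder_set$cv_record) {
    if (is.null(rec)) next
    for (fold in rec) {
      n_sw <- n_sw + sum(fold$train_trials %in% sw_trials)
      own <- which(decoder_set$groups == fold$held_out_group)
      n_self <- n_self + sum(own %in% fold$train_trials)
    }
  }
  list(n_switch_in_training = n_sw, n_self_decoding = n_self,
       passed = n_sw == 0L && n_self == 0L)
}

#' Per-trial decoded-value summaries
#'
#' Collapses the trials x bins decoded-value matrix (progression level) to
#' the per-trial scalars used by the meta-learning metrics: pre-choice
#' (mean of bins 1-4), post-choice (mean of bins 5-8), outcome (mean of
#' bins 9-11), and the bin-1 and bin-8 values.
#'
#' @param decoder_set a progression-level [train_decoders_cv()] result.
#' @return Data frame keyed by trial with the scalars plus trial labels.
#' @export
decoded_summary <- function(decoder_set) {
  if (decoder_set$n_prog != .n_bins) {
    stop("decoded summaries require the 11-bin progression-level decoder")
  }
  d <- decoder_set$decoded
  lab <- decoder_set$labels
  data.frame(
    trial_id = lab$trial_id, day = lab$day, session = lab$session,
    trial = lab$trial, is_switch = lab$is_switch, reward = lab$reward,
    patch = lab$patch, origin_patch = lab$origin_patch,
    pre = rowMeans(d[, 1:4, drop = FALSE]),
    post = rowMeans(d[, 5:8, drop = FALSE]),
    outcome = rowMeans(d[, 9:11, drop = FALSE]),
    bin1 = d[, 1L], bin8 = d[, 8L],
    sv_current = decoder_set$values, sv_next = decoder_set$values_next
  )
}

#' Compare per-bin decoding of current- versus next-trial value
#'
#' @param decoder_set a [train_decoders_cv()] result.
#' @return Data frame per bin with held-out R-squared against the current
#'   and the next trial's switch value and their difference.
#' @export
score_current_vs_next <- function(decoder_set) {
  out <- decoder_set$r2
  out$next_minus_current <- out$r2_next - out$r2_current
  out
}

.paired_metric_ci <- function(x, n_boot, seed) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_), n = 0L))
  }
  bc <- bootstrap_ci(mean, x, n_iter = n_boot, seed = seed)
  list(estimate = bc$estimate, ci = bc$ci, n = length(x))
}

#' Decoded-value meta-learning metrics
#'
#' Pure arithmetic on cross-validated decoded values around patch
#' transitions:
#' \itemize{
#'   \item \emph{neural value repletion}: switch-out pre-choice value minus
#'     the next switch-in (same patch) post-choice value;
#'   \item \emph{neural value depletion}: first-stay post-choice value
#'     minus the switch-in post-choice value, restricted to rewarded
#'     switch-ins;
#'   \item \emph{outcome effect}: outcome-period value minus the bin-8
#'     value of the same switch trial;
#'   \item \emph{neural value update}: bin-1 value of the first subsequent
#'     stay minus the bin-8 switch-in value;
#'   \item the outcome deltas: mean(metric | omission) minus
#'     mean(metric | reward).
#' }
#' Every metric is a difference, hence invariant to adding a constant to
#' all decoded values. Confidence intervals are percentile bootstraps over
#' the event pairs.
#'
#' @param decoded a [decoded_summary()] data frame.
#' @param n_boot bootstrap iterations.
#' @param seed integer seed.
#' @return List of class \code{metalearning_metrics}; each component has
#'   \code{estimate}, \code{ci}, \code{n}. A metric with no qualifying
#'   event pairs is NA with n = 0.
#' @export
metalearning_metrics <- function(decoded, n_boot = 10000L, seed = 1L) {
  d <- decoded
  n <- nrow(d)
  sess <- paste(d$day, d$session)
  sw <- which(d$is_switch)
  last_of_sess <- c(sess[-1L] != sess[-n], TRUE)

  # repletion: switch-out from P paired with the next switch-in to P
  repletion <- c()
  for (i in sw) {
    p <- d$origin_patch[i]
    nxt <- sw[sw > i & d$patch[sw] == p & sess[sw] == sess[i]]
    if (length(nxt) == 0L) next
    repletion <- c(repletion, d$pre[i] - d$post[min(nxt)])
  }

  # depletion: rewarded switch-in followed directly by a stay in the patch
  depletion <- c()
  update <- c()
  upd_reward <- c()
  out_eff <- c()
  out_reward <- c()
  for (i in sw) {
    if (i < n && !last_of_sess[i] && !d$is_switch[i + 1L]) {
      if (d$reward[i] == 1L) {
        depletion <- c(depletion, d$post[i + 1L] - d$post[i])
      }
      update <- c(update, d$bin1[i + 1L] - d$bin8[i])
      upd_reward <- c(upd_reward, d$reward[i])
    }
    out_eff <- c(out_eff, d$outcome[i] - d$bin8[i])
    out_reward <- c(out_reward, d$reward[i])
  }

  delta <- function(x, rew, sd_seed) {
    keep <- !is.na(x)
    x <- x[keep]; rew <- rew[keep]
    if (sum(rew == 1L) == 0L || sum(rew == 0L) == 0L) {
      return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_), n = 0L))
    }
    df <- data.frame(x = x, rew = rew)
    st <- function(dd) mean(dd$x[dd$rew == 0L]) - mean(dd$x[dd$rew == 1L])
    bc <- bootstrap_ci(st, df, n_iter = n_boot, seed = sd_seed)
    list(estimate = bc$estimate, ci = bc$ci, n = length(x))
  }

  structure(list(
    repletion = .paired_metric_ci(repletion, n_boot, seed),
    depletion = .paired_metric_ci(depletion, n_boot, seed + 1L),
    outcome_effect = .paired_metric_ci(out_eff, n_boot, seed + 2L),
    value_update = .paired_metric_ci(update, n_boot, seed + 3L),
    delta_outcome_effect = delta(out_eff, out_reward, seed + 4L),
    delta_value_update = delta(update, upd_reward, seed + 5L)
  ), class = "metalearning_metrics")
}

#' Single-visit episode analysis
#'
#' A single-visit episode is a switch into a patch followed immediately by
#' a switch out. For each episode the neural update is the switch-out
#' trial's bin-1 value minus the switch-in trial's bin-8 value, split by
#' the switch-in reward; switch-out pre-choice values are also compared
#' against same-patch stay-trial pre-choice values (rank-sum test).
#'
#' @param decoded a [decoded_summary()] data frame.
#' @return List with \code{episodes} (one row per episode: patch, reward,
#'   update, switch-out pre-choice value), \code{update_by_reward}
#'   (means), and \code{vs_stay} (rank-sum comparison of switch-out versus
#'   same-patch stay pre-choice values). Zero episodes yield an empty
#'   table.
#' @export
single_visit_analysis <- function(decoded) {
  d <- decoded
  n <- nrow(d)
  sess <- paste(d$day, d$session)
  rows <- list()
  for (i in which(d$is_switch)) {
    if (i >= n || sess[i + 1L] != sess[i]) next
    if (!d$is_switch[i + 1L]) next
    rows[[length(rows) + 1L]] <- data.frame(
      trial_id = d$trial_id[i], patch = d$patch[i], reward = d$reward[i],
      update = d$bin1[i + 1L] - d$bin8[i],
      switch_out_pre = d$pre[i + 1L]
    )
  }
  episodes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial_id = integer(0), patch = integer(0),
               reward = integer(0), update = numeric(0),
               switch_out_pre = numeric(0))
  upd <- c(rewarded = mean(episodes$update[episodes$reward == 1L]),
           unrewarded = mean(episodes$update[episodes$reward == 0L]))
  vs_stay <- NULL
  if (nrow(episodes) > 0L) {
    stay_pre <- d$pre[!d$is_switch & d$patch %in% unique(episodes$patch)]
    if (length(stay_pre) >= 3L) {
      wt <- suppressWarnings(
        stats::wilcox.test(episodes$switch_out_pre, stay_pre,
                           alternative = "greater")
      )
      vs_stay <- list(mean_switch_out = mean(episodes$switch_out_pre),
                      mean_stay = mean(stay_pre), p_value = wt$p.value)
    }
  }
  list(episodes = episodes, update_by_reward = upd, vs_stay = vs_stay)
}

# threshold maximizing overall accuracy for a monotone score
.best_threshold <- function(score, y) {
  ord <- order(score)
  ys <- y[ord]
  n <- length(ys)
  cum_stay <- cumsum(ys == 0L)
  cum_sw <- cumsum(ys == 1L)
  total_sw <- cum_sw[n]
  acc <- (c(0, cum_stay) + (total_sw - c(0, cum_sw))) / n
  k <- which.max(acc) - 1L
  ss <- score[ord]
  if (k == 0L) {
    ss[1L] - 1
  } else if (k == n) {
    ss[n] + 1
  } else {
    (ss[k] + ss[k + 1L]) / 2
  }
}

.balanced_accuracy <- function(score, y, thr) {
  pred <- as.integer(score > thr)
  sens <- mean(pred[y == 1L] == 1L)
  spec <- mean(pred[y == 0L] == 0L)
  (sens + spec) / 2
}

#' Predict switch/stay decisions from decoded pre-choice value
#'
#' Fits a single-predictor logistic model of switch (1) versus stay (0) on
#' the per-trial pre-choice decoded value, binarizes its predictions at the
#' threshold that maximizes overall accuracy, and reports balanced accuracy
#' (mean of switch sensitivity and stay specificity). The bootstrap
#' resamples trials with replacement, re-optimizing the threshold on each
#' resample.
#'
#' @param pre_values per-trial pre-choice decoded value.
#' @param is_switch logical/0-1 labels.
#' @param n_boot bootstrap iterations.
#' @param seed integer seed.
#' @return List with \code{balanced_accuracy}, \code{ci}, \code{sensitivity},
#'   \code{specificity}, \code{threshold}, \code{coefficients}, \code{n}.
#' @export
predict_decisions <- function(pre_values, is_switch, n_boot = 10000L,
                              seed = 1L) {
  keep <- !is.na(pre_values) & !is.na(is_switch)
  x <- pre_values[keep]
  y <- as.integer(is_switch[keep])
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  p <- stats::fitted(fit)
  thr <- .best_threshold(p, y)
  pred <- as.integer(p > thr)
  sens <- mean(pred[y == 1L] == 1L)
  spec <- mean(pred[y == 0L] == 0L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- length(y)
  bs <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2L) return(NA_real_)
    th <- .best_threshold(p[idx], y[idx])
    .balanced_accuracy(p[idx], y[idx], th)
  }, numeric(1))
  list(
    balanced_accuracy = (sens + spec) / 2,
    ci = unname(stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE)),
    sensitivity = sens, specificity = spec,
    threshold = thr, coefficients = stats::coef(fit), n = n
  )
}
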