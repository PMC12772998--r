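#' Gaussian-kernel smoothed single-trial rates on a trial-aligned window
#'
#' Estimates each neuron's firing rate on a regular grid of times relative
#' to each trial's movement initiation (the end of the pause at the origin
#' port, \code{t_start}), by Gaussian-kernel smoothing of the fine-grid
#' spike counts: rate(t) = sum_i K(t - t_i) c_i / sum_i K(t - t_i) d_i over
#' fine samples i of the trial and its within-session neighbors (so windows
#' reaching into the preceding outcome period are covered). Constant-rate
#' input is returned unchanged at interior samples.
#'
#' @param population a [generate_population()] result with a fine grid.
#' @param window numeric length-2 window (seconds) relative to trial
#'   initiation, e.g. \code{c(-0.8, 0.2)} for the pre-move window or
#'   \code{c(0, 3)} for the navigation window.
#' @param dt grid step (s).
#' @param kernel_sd Gaussian kernel width (s), default 0.05.
#' @param trials optional trial-id subset.
#' @return List of class \code{trial_states}: \code{states} array
#'   (trial x time x neuron; NA where no data falls under the kernel),
#'   \code{times} (relative grid), \code{trial_id}.
#' @export
trial_window_rates <- function(population, window = c(-0.8, 0.2),
                               dt = 0.05, kernel_sd = 0.05, trials = NULL) {
  fine <- population$fine
  if (is.null(fine)) stop("population was generated without a fine grid")
  lab <- population$labels
  if (is.null(trials)) trials <- lab$trial_id
  grid <- seq(window[1], window[2], by = dt)
  n_t <- length(trials)
  N <- population$meta$n_neurons
  states <- array(NA_real_, c(n_t, length(grid), N))
  sess <- paste(lab$day, lab$session)
  for (ti in seq_len(n_t)) {
    tr <- trials[ti]
    nb <- tr + (-1L:1L)
    nb <- nb[nb >= 1L & nb <= nrow(lab)]
    nb <- nb[sess[nb] == sess[tr]]
    tau <- as.numeric(t(fine$times[nb, , drop = FALSE]))
    dur <- as.numeric(t(fine$durations[nb, , drop = FALSE]))
    cnt <- matrix(aperm(fine$counts[nb, , , drop = FALSE], c(2L, 1L, 3L)),
                  nrow = length(tau), ncol = N)
    q <- lab$t_start[tr] + grid
    W <- exp(-outer(q, tau, "-")^2 / (2 * kernel_sd^2))
    denom <- as.numeric(W %*% dur)
    est <- (W %*% cnt) / denom
    est[denom < 1e-8, ] <- NA_real_
    states[ti, , ] <- est
  }
  structure(list(states = states, times = grid, trial_id = trials),
            class = "trial_states")
}

#' Condition-averaged population matrix
#'
#' Averages smoothed single-trial rates within conditions and stacks the
#' per-condition time courses into the (Conditions x Time) x Neurons matrix
#' used for subspace estimation. Conditions with zero trials are dropped
#' with a message.
#'
#' @param states a [trial_window_rates()] result.
#' @param conditions vector of condition labels, one per trial in
#'   \code{states} (NA trials are ignored).
#' @return List of class \code{condition_matrix}: \code{matrix}
#'   ((C x T) x N), \code{condition} and \code{time} per row.
#' @export
smooth_and_average <- function(states, conditions) {
  stopifnot(length(conditions) == dim(states$states)[1L])
  keep_lv <- unique(conditions[!is.na(conditions)])
  keep_lv <- keep_lv[order(keep_lv)]
  rows <- list()
  cond_out <- c()
  time_out <- c()
  for (lv in keep_lv) {
    sel <- which(!is.na(conditions) & conditions == lv)
    if (length(sel) == 0L) {
      message("condition ", lv, " has zero trials; dropped")
      next
    }
    avg <- apply(states$states[sel, , , drop = FALSE], c(2L, 3L), mean,
                 na.rm = TRUE)
    rows[[length(rows) + 1L]] <- avg
    cond_out <- c(cond_out, rep(lv, length(states$times)))
    time_out <- c(time_out, states$times)
  }
  structure(list(matrix = do.call(rbind, rows), condition = cond_out,
                 time = time_out),
            class = "condition_matrix")
}

#' Principal-component subspace of a condition-averaged matrix
#'
#' Column-centered PCA (no per-neuron variance scaling) of the
#' (Conditions x Time) x Neurons matrix, optionally restricted to a time
#' window. Loadings are orthonormal and eigenvalues non-increasing.
#'
#' @param cond_mat a [smooth_and_average()] result (or bare matrix).
#' @param window optional time window (relative seconds) selecting rows.
#' @param label source window label, e.g. "navigation" or "pre-move".
#' @return Object of class \code{subspace}: \code{mean}, \code{loadings}
#'   (neurons x components), \code{eigenvalues}, \code{var_explained},
#'   \code{label}.
#' @export
fit_subspace <- function(cond_mat, window = NULL, label = "navigation") {
  if (inherits(cond_mat, "condition_matrix")) {
    M <- cond_mat$matrix
    if (!is.null(window)) {
      sel <- cond_mat$time >= window[1] & cond_mat$time <= window[2]
      M <- M[sel, , drop = FALSE]
    }
  } else {
    M <- as.matrix(cond_mat)
  }
  M <- M[stats::complete.cases(M), , drop = FALSE]
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(mean = pc$center, loadings = pc$rotation,
                 eigenvalues = ev, var_explained = ev / sum(ev),
                 label = label),
            class = "subspace")
}

#' Project data into a fitted subspace
#'
#' Applies the stored centering and orthonormal loadings.
#'
#' @param subspace a [fit_subspace()] result.
#' @param data matrix (rows x neurons) or a \code{trial_states} array
#'   averaged over its window.
#' @param n_comp number of components to keep.
#' @return Matrix of projections (rows x components).
#' @export
project_subspace <- function(subspace, data, n_comp = NULL) {
  L <- subspace$loadings
  if (is.null(n_comp)) n_comp <- ncol(L)
  if (n_comp > ncol(L)) stop("more components requested than available")
  sweep(as.matrix(data), 2L, subspace$mean) %*% L[, seq_len(n_comp),
                                                  drop = FALSE]
}

#' Per-trial state at trial initiation
#'
#' Averages smoothed rates over the window (typically the pre-move window)
#' to one population vector per trial.
#'
#' @param states a [trial_window_rates()] result.
#' @return Matrix (trials x neurons).
#' @export
initiation_states <- function(states) {
  apply(states$states, c(1L, 3L), mean, na.rm = TRUE)
}

#' Cosine of the angle between post-reward and post-omission state shifts
#'
#' A single-trial neural-state shift is the vector between projected states
#' at initiation of two successive trials. Shifts are grouped by the
#' earlier trial's outcome; the cosine between the two mean shift vectors
#' (on the chosen component pair) measures whether reward and omission move
#' the population in opposite (-1) or aligned (+1) directions. The
#' confidence interval bootstraps single-trial shifts with replacement.
#'
#' @param proj matrix of projected states (trials x components), ordered as
#'   the trial table.
#' @param labels population labels (provides session keys, switch flags,
#'   rewards).
#' @param components integer pair of components to use.
#' @param n_boot bootstrap iterations.
#' @param seed integer seed.
#' @param within_bouts restrict to consecutive stay-trial pairs.
#' @return List with \code{cosine}, \code{ci}, \code{n_reward},
#'   \code{n_omission}, and the mean shift vectors.
#' @export
shift_cosine <- function(proj, labels, components = c(2L, 3L),
                         n_boot = 1000L, seed = 1L, within_bouts = TRUE) {
  n <- nrow(proj)
  sess <- paste(labels$day, labels$session)
  ok <- seq_len(n - 1L)
  ok <- ok[sess[ok] == sess[ok + 1L]]
  if (within_bouts) {
    ok <- ok[!labels$is_switch[ok] & !labels$is_switch[ok + 1L]]
  }
  ok <- ok[stats::complete.cases(proj[ok, components, drop = FALSE]) &
             stats::complete.cases(proj[ok + 1L, components, drop = FALSE])]
  shifts <- proj[ok + 1L, components, drop = FALSE] -
    proj[ok, components, drop = FALSE]
  outcome <- labels$reward[ok]
  if (sum(outcome == 1L) < 5L || sum(outcome == 0L) < 5L) {
    stop("fewer than 5 shifts in one outcome class")
  }
  cos_of <- function(idx_r, idx_o) {
    vr <- colMeans(shifts[idx_r, , drop = FALSE])
    vo <- colMeans(shifts[idx_o, , drop = FALSE])
    sum(vr * vo) / sqrt(sum(vr^2) * sum(vo^2))
  }
  i_r <- which(outcome == 1L)
  i_o <- which(outcome == 0L)
  est <- cos_of(i_r, i_o)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  bs <- vapply(seq_len(n_boot), function(b) {
    cos_of(sample(i_r, length(i_r), replace = TRUE),
           sample(i_o, length(i_o), replace = TRUE))
  }, numeric(1))
  list(cosine = est,
       ci = unname(stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE)),
       n_reward = length(i_r), n_omission = length(i_o),
       mean_shift_reward = colMeans(shifts[i_r, , drop = FALSE]),
       mean_shift_omission = colMeans(shifts[i_o, , drop = FALSE]))
}

#' Select the component pair carrying the proximity-value gradient
#'
#' Among candidate components, picks the two whose condition-averaged
#' projections correlate most strongly (by absolute Spearman rank
#' correlation) with the proximity-group order. Mirrors choosing the two
#' leading axes with salient value-related gradients.
#'
#' @param subspace a [fit_subspace()] result.
#' @param states a [trial_window_rates()] result (pre-move window).
#' @param groups per-trial proximity groups (small = close to switch).
#' @param candidates candidate component indices.
#' @return Integer vector of two component indices (decreasing |rho|),
#'   with the correlations as an attribute.
#' @export
select_value_components <- function(subspace, states, groups,
                                    candidates = 2:5) {
  init <- initiation_states(states)
  proj <- project_subspace(subspace, init)
  candidates <- candidates[candidates <= ncol(proj)]
  lv <- sort(unique(groups[!is.na(groups)]))
  if (length(lv) < 3L) stop("need at least 3 proximity groups")
  rho <- vapply(candidates, function(k) {
    m <- vapply(lv, function(g) mean(proj[groups %in% g, k], na.rm = TRUE),
                numeric(1))
    suppressWarnings(stats::cor(m, seq_along(lv), method = "spearman"))
  }, numeric(1))
  sel <- candidates[order(abs(rho), decreasing = TRUE)][1:2]
  attr(sel, "rho") <- stats::setNames(rho, candidates)
  sel
}

#' Alignment of a decoding axis with subspace components
#'
#' Cosine of the axis with each of the first three loading vectors, and
#' with the plane spanned by components 2 and 3 (the norm of the axis's
#' orthogonal projection onto that plane).
#'
#' @param subspace a [fit_subspace()] result.
#' @param axis decoder weight vector in neuron space.
#' @return List with \code{cos_pc} (components 1-3) and
#'   \code{plane_alignment} (components 2-3 plane).
#' @export
axis_alignment <- function(subspace, axis) {
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("zero-norm axis")
  a <- axis / nrm
  L <- subspace$loadings
  k <- min(3L, ncol(L))
  cos_pc <- vapply(seq_len(k), function(i) sum(a * L[, i]), numeric(1))
  plane <- if (ncol(L) >= 3L) {
    p <- L[, 2:3] %*% (t(L[, 2:3]) %*% a)
    sqrt(sum(p^2))
  } else {
    NA_real_
  }
  list(cos_pc = cos_pc, plane_alignment = plane)
}
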