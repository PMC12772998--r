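#' Poisson GLM design for single-neuron encoding analysis
#'
#' One row per (stay trial, run bin). The indicator block holds the 48
#' binary journey-by-progression predictors (each row activates exactly
#' one); the value block holds switch-value-by-bin interaction predictors at
#' the requested granularity: 8 (progression), 16 (action x progression),
#' 24 (patch x progression), 48 (journey x progression), or 0 ("none", the
#' reduced task-structure-only model). A log bin-duration offset makes
#' unequal bin exposures comparable.
#'
#' @param population a [generate_population()] result.
#' @param granularity one of "none", "progression", "action", "patch",
#'   "journey".
#' @return List of class \code{glm_design}: sparse model matrix \code{X},
#'   \code{offset}, \code{trial_id} and \code{bin} per row, \code{stay_idx}
#'   (trial ids used), and block sizes.
#' @export
build_design <- function(population, granularity = "journey") {
  lv <- c("none", "progression", "action", "patch", "journey")
  if (!granularity %in% lv) stop("unknown granularity: ", granularity)
  lab <- population$labels
  stay <- which(!lab$is_switch & !is.na(lab$journey))
  n_stay <- length(stay)
  nb <- .n_bins_run
  trial_id <- rep(lab$trial_id[stay], each = nb)
  journey <- rep(lab$journey[stay], each = nb)
  bin <- rep(seq_len(nb), times = n_stay)
  sv <- rep(lab$sv_current[stay], each = nb)
  rows <- seq_along(trial_id)
  ind_col <- (journey - 1L) * nb + bin
  n_val <- switch(granularity, none = 0L, progression = nb,
                  action = 2L * nb, patch = 3L * nb, journey = 6L * nb)
  if (n_val > 0L) {
    grp <- switch(granularity,
                  progression = rep(1L, length(journey)),
                  action = journey_action(journey),
                  patch = journey_patch(journey),
                  journey = journey)
    val_col <- 48L + (grp - 1L) * nb + bin
    X <- Matrix::sparseMatrix(
      i = c(rows, rows), j = c(ind_col, val_col),
      x = c(rep(1, length(rows)), sv),
      dims = c(length(rows), 48L + n_val)
    )
  } else {
    X <- Matrix::sparseMatrix(
      i = rows, j = ind_col, x = rep(1, length(rows)),
      dims = c(length(rows), 48L)
    )
  }
  dur <- t(population$durations[stay, seq_len(nb), drop = FALSE])
  structure(list(
    X = X, offset = log(as.numeric(dur)), trial_id = trial_id, bin = bin,
    stay_idx = lab$trial_id[stay], granularity = granularity,
    n_ind = 48L, n_val = n_val
  ), class = "glm_design")
}

#' Counts of one neuron aligned to a design
#' @param population a [generate_population()] result.
#' @param design a [build_design()] result.
#' @param neuron neuron index.
#' @return Integer vector of counts, one per design row.
#' @export
design_counts <- function(population, design, neuron) {
  cm <- population$counts[design$stay_idx, seq_len(.n_bins_run), neuron,
                          drop = FALSE]
  as.integer(t(matrix(cm, length(design$stay_idx), .n_bins_run)))
}

#' Poisson deviance
#' @param y observed counts.
#' @param mu predicted means.
#' @return Total deviance \code{2 * sum(y log(y / mu) - (y - mu))}.
#' @export
poisson_deviance <- function(y, mu) {
  mu <- pmax(mu, 1e-12)
  2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
}

#' Single penalized Poisson GLM fit
#'
#' L1-penalized fit via coordinate descent for \code{lambda > 0}; the
#' unpenalized case uses iteratively reweighted least squares directly.
#'
#' @param design a [build_design()].
#' @param y counts per row.
#' @param lambda L1 penalty (0 for unpenalized).
#' @param rows optional row subset to fit on.
#' @return List with \code{intercept}, \code{coef} (per design column), and
#'   \code{predict(newrows)} giving mean counts.
#' @export
fit_poisson_glm <- function(design, y, lambda = 0, rows = NULL) {
  if (is.null(rows)) rows <- seq_along(y)
  X <- design$X[rows, , drop = FALSE]
  off <- design$offset[rows]
  yy <- y[rows]
  if (lambda > 0) {
    fit <- glmnet::glmnet(X, yy, family = "poisson", offset = off,
                          lambda = lambda, standardize = TRUE)
    b0 <- as.numeric(fit$a0)
    be <- as.numeric(fit$beta)
  } else {
    keep <- which(Matrix::colSums(abs(X)) > 0)
    Xd <- as.matrix(X[, keep, drop = FALSE])
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, Xd), yy, family = stats::poisson(),
                     offset = off)
    )
    co <- fit$coefficients
    co[is.na(co)] <- 0
    b0 <- co[1L]
    be <- numeric(ncol(X))
    be[keep] <- co[-1L]
  }
  out <- list(intercept = b0, coef = be)
  out$predict <- function(newrows) {
    eta <- as.numeric(design$X[newrows, , drop = FALSE] %*% be) + b0 +
      design$offset[newrows]
    exp(eta)
  }
  out
}

#' Cross-validated penalized Poisson GLM for one neuron
#'
#' Repeated trial-level k-fold cross-validation. The L1 penalty is chosen
#' once per neuron-model by an inner cross-validation over a logarithmic
#' grid; each repeat then partitions trials into folds, fits the penalized
#' model on the training rows, and accumulates held-out deviance. The
#' repeat-level fraction of deviance explained is
#' \code{(D_null - D_model) / D_null}, with the null being a training-set
#' intercept-plus-offset model.
#'
#' @param design a [build_design()].
#' @param y counts per design row (one neuron).
#' @param n_folds folds per repeat (trial-level).
#' @param n_repeats repeats.
#' @param seed integer seed for the fold assignments.
#' @param lambda optional fixed penalty; when NULL it is selected by inner
#'   5-fold cross-validation.
#' @return List of class \code{glm_cv}: \code{fractions} (one held-out
#'   deviance fraction per repeat), \code{lambda}, \code{granularity},
#'   \code{flagged} (TRUE for an all-zero neuron, fractions defined as 0),
#'   and \code{coef} (full-data penalized fit).
#' @export
fit_poisson_glm_cv <- function(design, y, n_folds = 10L, n_repeats = 100L,
                               seed = 1L, lambda = NULL) {
  trials <- unique(design$trial_id)
  n_tr <- length(trials)
  if (n_tr < 2L * n_folds) stop("too few trials for ", n_folds, " folds")
  if (all(y == 0L)) {
    return(structure(list(
      fractions = rep(0, n_repeats), lambda = NA_real_,
      granularity = design$granularity, flagged = TRUE, coef = NULL
    ), class = "glm_cv"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (is.null(lambda)) {
    foldid_tr <- sample(rep_len(seq_len(5L), n_tr))
    foldid <- foldid_tr[match(design$trial_id, trials)]
    cvfit <- glmnet::cv.glmnet(design$X, y, family = "poisson",
                               offset = design$offset, foldid = foldid,
                               nlambda = 30L, standardize = TRUE)
    lambda <- cvfit$lambda.min
  }
  fractions <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    foldid_tr <- sample(rep_len(seq_len(n_folds), n_tr))
    foldid <- foldid_tr[match(design$trial_id, trials)]
    d_model <- 0
    d_null <- 0
    for (f in seq_len(n_folds)) {
      test <- which(foldid == f)
      train <- which(foldid != f)
      fit <- fit_poisson_glm(design, y, lambda = lambda, rows = train)
      mu <- fit$predict(test)
      r0 <- sum(y[train]) / sum(exp(design$offset[train]))
      mu0 <- r0 * exp(design$offset[test])
      d_model <- d_model + poisson_deviance(y[test], mu)
      d_null <- d_null + poisson_deviance(y[test], mu0)
    }
    fractions[r] <- if (d_null > 0) (d_null - d_model) / d_null else 0
  }
  full <- fit_poisson_glm(design, y, lambda = lambda)
  structure(list(
    fractions = fractions, lambda = lambda,
    granularity = design$granularity, flagged = FALSE,
    coef = list(intercept = full$intercept, beta = full$coef)
  ), class = "glm_cv")
}

#' Select the L1 penalty for one neuron by inner cross-validation
#'
#' Trial-grouped 5-fold cross-validation over glmnet's logarithmic lambda
#' grid. Used once per neuron (on the reduced, task-structure-only design)
#' so that all compared models share one penalty and differ only in their
#' value block.
#'
#' @param design a [build_design()] result.
#' @param y counts per design row.
#' @param seed integer seed.
#' @return Scalar penalty (lambda at minimal cross-validated deviance).
#' @export
choose_lambda <- function(design, y, seed = 1L) {
  if (all(y == 0L)) return(NA_real_)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  trials <- unique(design$trial_id)
  foldid_tr <- sample(rep_len(seq_len(5L), length(trials)))
  foldid <- foldid_tr[match(design$trial_id, trials)]
  cvfit <- glmnet::cv.glmnet(design$X, y, family = "poisson",
                             offset = design$offset, foldid = foldid,
                             nlambda = 30L, standardize = TRUE)
  cvfit$lambda.min
}

.parsimony_order <- c(progression = 1L, action = 2L, patch = 3L,
                      journey = 4L)

#' Categorize a neuron's value-coding generality
#'
#' A neuron is labeled "none" unless at least one value model explains a
#' significantly greater fraction of held-out deviance than the reduced
#' (no-value) model (one-sided rank-sum over repeat-level fractions, Holm
#' correction, p < 0.01). Otherwise the four value granularities are
#' compared pairwise (one-sided rank-sum, Holm across comparisons): if one
#' model significantly beats all others it wins; when several are
#' statistically indistinguishable at the top, the most parsimonious wins
#' (progression < action < patch < journey by parameter count; the
#' action/patch tie resolves toward action by fixed order).
#'
#' @param fits named list of [fit_poisson_glm_cv()] results (or bare
#'   \code{fractions} vectors) for "reduced", "progression", "action",
#'   "patch", "journey".
#' @param alpha_value significance level against the reduced model.
#' @param alpha_pair significance level for pairwise comparisons.
#' @return List with \code{category}, \code{p_value_vs_reduced} (min
#'   Holm-adjusted), \code{pairwise} (adjusted p matrix, row beats column),
#'   and \code{median_fractions}.
#' @export
categorize_value_generality <- function(fits, alpha_value = 0.01,
                                        alpha_pair = 0.05) {
  grans <- c("progression", "action", "patch", "journey")
  need <- c("reduced", grans)
  if (!all(need %in% names(fits))) {
    stop("missing granularity: ", paste(setdiff(need, names(fits)),
                                        collapse = ", "))
  }
  frac <- lapply(fits[need], function(f) {
    if (is.list(f)) f$fractions else f
  })
  p_red <- vapply(grans, function(g) {
    suppressWarnings(stats::wilcox.test(frac[[g]], frac$reduced,
                                        alternative = "greater"))$p.value
  }, numeric(1))
  p_red_adj <- stats::p.adjust(p_red, method = "holm")
  med <- vapply(frac, stats::median, numeric(1))
  if (min(p_red_adj) >= alpha_value) {
    return(list(category = "none", p_value_vs_reduced = min(p_red_adj),
                pairwise = NULL, median_fractions = med))
  }
  praw <- matrix(NA_real_, 4L, 4L, dimnames = list(grans, grans))
  for (a in grans) for (b in grans) {
    if (a == b) next
    praw[a, b] <- suppressWarnings(
      stats::wilcox.test(frac[[a]], frac[[b]],
                         alternative = "greater"))$p.value
  }
  padj <- praw
  padj[!is.na(praw)] <- stats::p.adjust(praw[!is.na(praw)], method = "holm")
  beats <- !is.na(padj) & padj < alpha_pair
  unbeaten <- grans[colSums(beats) == 0L]
  if (length(unbeaten) == 0L) unbeaten <- grans
  category <- unbeaten[which.min(.parsimony_order[unbeaten])]
  list(category = category, p_value_vs_reduced = min(p_red_adj),
       pairwise = padj, median_fractions = med)
}

#' Encoding analysis over a population
#'
#' Fits, for each requested neuron, the reduced (no-value) model and the
#' four value-granularity models on identical folds, then categorizes the
#' neuron's value-coding generality.
#'
#' @param population a [generate_population()] result.
#' @param neurons neuron indices (default all).
#' @param n_folds,n_repeats cross-validation settings.
#' @param seed integer seed.
#' @return Data frame with one row per neuron: assigned \code{category},
#'   the generative class when available, and median held-out deviance
#'   fractions per model.
#' @export
analyze_encoding <- function(population, neurons = NULL, n_folds = 10L,
                             n_repeats = 20L, seed = 1L) {
  if (is.null(neurons)) neurons <- seq_len(population$meta$n_neurons)
  grans <- c("progression", "action", "patch", "journey")
  designs <- c(
    list(reduced = build_design(population, "none")),
    stats::setNames(lapply(grans, build_design, population = population),
                    grans)
  )
  rows <- lapply(seq_along(neurons), function(i) {
    k <- neurons[i]
    y <- design_counts(population, designs$reduced, k)
    # one penalty per neuron, selected on the reduced model and shared by
    # every compared model so that only the value block differs
    lam <- choose_lambda(designs$reduced, y, seed = seed + k)
    fits <- lapply(designs, function(d) {
      fit_poisson_glm_cv(d, y, n_folds = n_folds, n_repeats = n_repeats,
                         seed = seed + k, lambda = lam)
    })
    cat_k <- categorize_value_generality(fits)
    data.frame(
      neuron = k,
      category = cat_k$category,
      p_value_vs_reduced = cat_k$p_value_vs_reduced,
      frac_reduced = cat_k$median_fractions[["reduced"]],
      frac_progression = cat_k$median_fractions[["progression"]],
      frac_action = cat_k$median_fractions[["action"]],
      frac_patch = cat_k$median_fractions[["patch"]],
      frac_journey = cat_k$median_fractions[["journey"]]
    )
  })
  do.call(rbind, rows)
}
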