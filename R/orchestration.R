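#' Atomic JSON write
#' @param x object to serialize.
#' @param path destination path.
#' @keywords internal
write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' Atomic CSV write
#' @param df data frame.
#' @param path destination path.
#' @keywords internal
write_csv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

.check_col <- function(df, col, checker, what) {
  if (!col %in% names(df)) stop("missing column: ", col)
  bad <- which(!checker(df[[col]]))
  if (length(bad) > 0L) {
    stop(sprintf("column '%s' %s (first offending row: %d)",
                 col, what, bad[1L]))
  }
  invisible(TRUE)
}

#' Validate a trial table against the schema
#'
#' Checks column presence, types, and ranges; violations name the
#' offending column and row.
#'
#' @param trials data frame to validate.
#' @return The validated table, invisibly.
#' @export
validate_trials <- function(trials) {
  int_ok <- function(x) !is.na(x) & x == round(x)
  .check_col(trials, "day", int_ok, "must be integer")
  .check_col(trials, "session", int_ok, "must be integer")
  .check_col(trials, "trial", int_ok, "must be integer")
  for (col in c("origin_port", "dest_port")) {
    .check_col(trials, col, function(x) int_ok(x) & x >= 1 & x <= 6,
               "must be a port id in 1..6")
  }
  for (col in c("origin_patch", "dest_patch")) {
    .check_col(trials, col, function(x) int_ok(x) & x >= 1 & x <= 3,
               "must be a patch id in 1..3")
  }
  .check_col(trials, "reward", function(x) x %in% c(0, 1),
             "must be 0 or 1")
  .check_col(trials, "is_switch", function(x) !is.na(as.logical(x)),
             "must be logical")
  .check_col(trials, "effective_p", function(x) !is.na(x) & x >= 0 & x <= 1,
             "must lie in [0, 1]")
  for (col in c("t_start", "t_poke", "t_end")) {
    .check_col(trials, col, function(x) is.finite(x), "must be finite")
  }
  bad <- which(!(trials$t_start < trials$t_poke &
                   trials$t_poke < trials$t_end))
  if (length(bad) > 0L) {
    stop("timing must satisfy t_start < t_poke < t_end (first offending row: ",
         bad[1L], ")")
  }
  bad <- which(trials$origin_port == trials$dest_port)
  if (length(bad) > 0L) {
    stop("dest_port must differ from origin_port (first offending row: ",
         bad[1L], ")")
  }
  invisible(trials)
}

#' Write a trial table (CSV, validated)
#' @param trials trial table.
#' @param path destination CSV path.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  write_csv_atomic(trials, path)
}

#' Read a trial table (CSV, validated)
#' @param path CSV path written by [write_trials()].
#' @return Validated trial data frame.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path)
  df$is_switch <- as.logical(df$is_switch)
  validate_trials(df)
  df
}

#' Write a binned population to long-format CSVs
#'
#' Emits \code{<stem>_counts.csv} (trial, bin, neuron, count, duration) and
#' \code{<stem>_labels.csv}. The fine grid is not serialized; regenerate it
#' with [generate_population()] under the stored seed.
#'
#' @param population a [generate_population()] result.
#' @param stem path stem (without suffix).
#' @export
write_population <- function(population, stem) {
  dm <- dim(population$counts)
  long <- data.frame(
    trial = rep(seq_len(dm[1L]), times = dm[2L] * dm[3L]),
    bin = rep(rep(seq_len(dm[2L]), each = dm[1L]), times = dm[3L]),
    neuron = rep(seq_len(dm[3L]), each = dm[1L] * dm[2L]),
    count = as.integer(population$counts),
    duration = rep(as.numeric(population$durations), times = dm[3L])
  )
  write_csv_atomic(long, paste0(stem, "_counts.csv"))
  write_csv_atomic(population$labels, paste0(stem, "_labels.csv"))
  invisible(stem)
}

#' Read a binned population from long-format CSVs
#' @param stem path stem used by [write_population()].
#' @return A \code{binned_population} (without fine grid or true rates).
#' @export
read_population <- function(stem) {
  long <- utils::read.csv(paste0(stem, "_counts.csv"))
  labels <- utils::read.csv(paste0(stem, "_labels.csv"))
  labels$is_switch <- as.logical(labels$is_switch)
  .check_col(long, "count", function(x) !is.na(x) & x >= 0 & x == round(x),
             "must be a nonnegative integer count")
  .check_col(long, "duration", function(x) !is.na(x) & x > 0,
             "must be a positive duration")
  .check_col(long, "bin", function(x) x >= 1 & x <= .n_bins,
             "must be a bin index in 1..11")
  n_tr <- max(long$trial)
  nb <- max(long$bin)
  N <- max(long$neuron)
  counts <- array(0L, c(n_tr, nb, N))
  counts[cbind(long$trial, long$bin, long$neuron)] <- long$count
  durations <- matrix(NA_real_, n_tr, nb)
  durations[cbind(long$trial, long$bin)] <- long$duration
  structure(list(counts = counts, rates = NULL, durations = durations,
                 labels = labels, fine = NULL,
                 meta = list(n_neurons = N, gain_scale = NA_real_,
                             value_transition = NA, seed = NA_integer_)),
            class = "binned_population")
}

#' Serialize a coding spec to JSON
#' @param spec a [make_coding_spec()].
#' @param path destination path.
#' @export
write_coding_spec <- function(spec, path) {
  obj <- list(
    n_neurons = spec$n_neurons, gain_scale = spec$gain_scale,
    seed = spec$seed, value_transition = spec$value_transition,
    rate_cap = spec$rate_cap,
    neurons = lapply(spec$neurons, function(nr) {
      list(class = nr$class, baseline = nr$baseline, tuning = nr$tuning,
           gain = as.numeric(nr$gain), gain_params = nr$gain_params)
    })
  )
  write_json_atomic(obj, path)
}

#' Read a coding spec from JSON
#' @param path file written by [write_coding_spec()].
#' @return A \code{coding_spec}.
#' @export
read_coding_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  neurons <- lapply(obj$neurons, function(nr) {
    list(
      class = nr$class,
      baseline = as.numeric(nr$baseline),
      tuning = list(center = as.numeric(nr$tuning$center),
                    width = as.numeric(nr$tuning$width),
                    amp = as.numeric(nr$tuning$amp),
                    jmod = num(nr$tuning$jmod)),
      gain = matrix(num(nr$gain), .n_bins, 6L),
      gain_params = list(center = num(nr$gain_params$center),
                         width = num(nr$gain_params$width),
                         amp = num(nr$gain_params$amp))
    )
  })
  structure(list(neurons = neurons, n_neurons = as.integer(obj$n_neurons),
                 gain_scale = as.numeric(obj$gain_scale),
                 seed = as.integer(obj$seed),
                 value_transition = isTRUE(obj$value_transition),
                 rate_cap = as.numeric(obj$rate_cap)),
            class = "coding_spec")
}

.stage_names <- c("simulate-behavior", "fit-behavior", "simulate-neurons",
                  "fit-glm", "geometry", "decode", "metrics")

#' Derive a stage seed from the base seed
#'
#' One global base seed fans out to per-stage seeds by a fixed counter
#' scheme (\code{base * 1000 + stage index}), so stages can be re-run in
#' isolation and still reproduce a full run.
#'
#' @param base_seed small integer base seed.
#' @param stage stage name (see [pipeline_config()]).
#' @return Integer seed.
#' @export
stage_seed <- function(base_seed, stage) {
  idx <- match(stage, .stage_names)
  if (is.na(idx)) stop("unknown stage: ", stage)
  as.integer(base_seed) * 1000L + idx
}

#' Default pipeline configuration
#'
#' Encodes the study-scale defaults: a 6-port maze with per-revisit
#' discount 0.8, 5 sessions of 300 trials per day, a 100-neuron synthetic
#' population, 11 decoder bins, and 10000 bootstrap iterations. Two agent
#' regimes are defined: \emph{early} (depletion-blind, factor 1) and
#' \emph{late} (rule-incorporating, factor equal to the environment's
#' discount).
#'
#' @param base_seed global base seed (fanned out per stage).
#' @param ... named overrides replacing top-level config entries.
#' @return Nested configuration list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(base_seed = 1L, ...) {
  cfg <- list(
    env = list(nominal_p = c(0.5, 0.8, 0.2, 0.5, 0.2, 0.2), discount = 0.8,
               sessions_per_day = 5L, trials_per_session = 300L),
    agent = list(
      early = list(gamma = 0.5, depletion_factor = 1.0, decay = 0.3,
                   beta_stay = 5, beta_go = 5, beta_port = 3,
                   b_stay = 1, b_turn = 0),
      late = list(gamma = 0.5, depletion_factor = 0.8, decay = 0.05,
                  beta_stay = 5, beta_go = 5, beta_port = 3,
                  b_stay = 1, b_turn = 0)
    ),
    neural = list(n_neurons = 100L,
                  class_mix = c(progression = 0.3, action = 0.2,
                                patch = 0.2, journey = 0.2, none = 0.1),
                  gain_scale = 0.5, value_transition = TRUE),
    analysis = list(cap = 8L, n_boot = 10000L, glm_folds = 10L,
                    glm_repeats = 20L, glm_neurons = NULL,
                    decoder_level = "progression", fit_starts = 5L),
    seeds = list(base = as.integer(base_seed))
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
  structure(cfg, class = "pipeline_config")
}

#' Hash of a configuration (stamped into every output)
#' @param config a [pipeline_config()].
#' @return md5 hex string of the canonical JSON serialization.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.require_upstream <- function(path, stage) {
  if (!file.exists(path)) {
    stop("missing upstream output for stage '", stage, "': ", path)
  }
  path
}

#' Run the end-to-end analysis pipeline
#'
#' Executes (a subset of) the stages simulate-behavior, fit-behavior,
#' simulate-neurons, fit-glm, geometry, decode, metrics, for both agent
#' regimes, writing every artifact into \code{out_dir} and a manifest JSON
#' listing stages, seeds, files, and the config hash. Stage subsets reuse
#' upstream outputs from \code{out_dir} and fail with an explicit message
#' when one is missing. Re-running with an identical configuration
#' reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run (in canonical order).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = .stage_names) {
  bad <- setdiff(stages, .stage_names)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .stage_names[.stage_names %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  hash <- config_hash(cfg)
  base <- cfg$seeds$base
  env_cfg <- maze_config(cfg$env$nominal_p, discount = cfg$env$discount)
  regimes <- names(cfg$agent)
  files <- list()
  state <- new.env(parent = emptyenv())

  path_of <- function(name) file.path(out_dir, name)
  get_trials <- function(rg) {
    key <- paste0("trials_", rg)
    if (!is.null(state[[key]])) return(state[[key]])
    p <- .require_upstream(path_of(paste0("trials_", rg, ".csv")),
                           "downstream")
    state[[key]] <- read_trials(p)
    state[[key]]
  }
  get_trace <- function(rg) {
    key <- paste0("trace_", rg)
    if (!is.null(state[[key]])) return(state[[key]])
    p <- .require_upstream(path_of(paste0("trace_", rg, ".csv")),
                           "downstream")
    state[[key]] <- utils::read.csv(p)
    state[[key]]
  }
  get_population <- function(rg, need_fine = FALSE) {
    key <- paste0("pop_", rg)
    if (!is.null(state[[key]])) {
      pop <- state[[key]]
      if (!need_fine || !is.null(pop$fine)) return(pop)
    }
    spec_path <- .require_upstream(path_of("coding_spec.json"),
                                   "downstream")
    spec <- read_coding_spec(spec_path)
    pop <- generate_population(get_trials(rg), get_trace(rg), spec,
                               seed = stage_seed(base, "simulate-neurons"),
                               fine_grid = TRUE)
    state[[key]] <- pop
    pop
  }

  for (st in stages) {
    if (st == "simulate-behavior") {
      for (rg in regimes) {
        sim <- simulate_agent(
          env_cfg, do.call(agent_params, cfg$agent[[rg]]),
          n_sessions = cfg$env$sessions_per_day,
          trials_per_session = cfg$env$trials_per_session,
          seed = stage_seed(base, st) + match(rg, regimes)
        )
        sim$trials$config_hash <- NULL
        write_trials(sim$trials, path_of(paste0("trials_", rg, ".csv")))
        write_csv_atomic(sim$trace, path_of(paste0("trace_", rg, ".csv")))
        state[[paste0("trials_", rg)]] <- sim$trials
        state[[paste0("trace_", rg)]] <- sim$trace
        files[[paste0("trials_", rg)]] <- paste0("trials_", rg, ".csv")
        files[[paste0("trace_", rg)]] <- paste0("trace_", rg, ".csv")
      }
    } else if (st == "fit-behavior") {
      for (rg in regimes) {
        trials <- get_trials(rg)
        fit <- fit_day(trials, env_cfg,
                       n_starts = cfg$analysis$fit_starts)
        out <- list(regime = rg, params = unclass(fit$params),
                    nll = fit$nll, converged = fit$converged,
                    n_trials = fit$n_trials, config_hash = hash)
        write_json_atomic(out, path_of(paste0("fit_", rg, ".json")))
        files[[paste0("fit_", rg)]] <- paste0("fit_", rg, ".json")
      }
    } else if (st == "simulate-neurons") {
      spec <- make_coding_spec(
        n_neurons = cfg$neural$n_neurons,
        class_mix = cfg$neural$class_mix,
        gain_scale = cfg$neural$gain_scale,
        seed = stage_seed(base, st),
        value_transition = cfg$neural$value_transition
      )
      write_coding_spec(spec, path_of("coding_spec.json"))
      files[["coding_spec"]] <- "coding_spec.json"
      for (rg in regimes) {
        pop <- generate_population(get_trials(rg), get_trace(rg), spec,
                                   seed = stage_seed(base, st),
                                   fine_grid = TRUE)
        state[[paste0("pop_", rg)]] <- pop
        write_population(pop, path_of(paste0("population_", rg)))
        files[[paste0("population_", rg)]] <-
          paste0("population_", rg, "_counts.csv")
      }
    } else if (st == "fit-glm") {
      for (rg in regimes) {
        pop <- get_population(rg)
        neurons <- cfg$analysis$glm_neurons
        res <- analyze_encoding(pop, neurons = neurons,
                                n_folds = cfg$analysis$glm_folds,
                                n_repeats = cfg$analysis$glm_repeats,
                                seed = stage_seed(base, st))
        res$config_hash <- hash
        write_csv_atomic(res, path_of(paste0("glm_", rg, ".csv")))
        files[[paste0("glm_", rg)]] <- paste0("glm_", rg, ".csv")
      }
    } else if (st == "geometry") {
      for (rg in regimes) {
        pop <- get_population(rg, need_fine = TRUE)
        geo <- regime_geometry(pop, cap = cfg$analysis$cap,
                               n_boot = min(cfg$analysis$n_boot, 2000L),
                               seed = stage_seed(base, st))
        out <- list(regime = rg, cosine = geo$shift$cosine,
                    ci = geo$shift$ci, components = geo$components,
                    var_explained = geo$subspace$var_explained[1:5],
                    config_hash = hash)
        write_json_atomic(out, path_of(paste0("geometry_", rg, ".json")))
        files[[paste0("geometry_", rg)]] <- paste0("geometry_", rg, ".json")
      }
    } else if (st == "decode") {
      for (rg in regimes) {
        pop <- get_population(rg)
        design <- assign_bins_and_groups(pop, cfg$analysis$decoder_level,
                                         cap = cfg$analysis$cap)
        ds <- train_decoders_cv(design, seed = stage_seed(base, st))
        state[[paste0("decoder_", rg)]] <- ds
        dec <- decoded_summary(ds)
        dec$config_hash <- hash
        write_csv_atomic(dec, path_of(paste0("decoded_", rg, ".csv")))
        write_csv_atomic(score_current_vs_next(ds),
                         path_of(paste0("decoder_r2_", rg, ".csv")))
        audit <- audit_cv(ds)
        write_json_atomic(c(audit, list(config_hash = hash)),
                          path_of(paste0("cv_audit_", rg, ".json")))
        files[[paste0("decoded_", rg)]] <- paste0("decoded_", rg, ".csv")
      }
    } else if (st == "metrics") {
      for (rg in regimes) {
        key <- paste0("decoder_", rg)
        dec <- if (!is.null(state[[key]])) {
          decoded_summary(state[[key]])
        } else {
          p <- .require_upstream(path_of(paste0("decoded_", rg, ".csv")),
                                 st)
          df <- utils::read.csv(p)
          df$is_switch <- as.logical(df$is_switch)
          df
        }
        mm <- metalearning_metrics(dec, n_boot = cfg$analysis$n_boot,
                                   seed = stage_seed(base, st))
        sv <- single_visit_analysis(dec)
        pd <- predict_decisions(dec$pre, dec$is_switch,
                                n_boot = cfg$analysis$n_boot,
                                seed = stage_seed(base, st))
        out <- list(regime = rg, metrics = lapply(unclass(mm), unclass),
                    single_visit_update = sv$update_by_reward,
                    balanced_accuracy = pd$balanced_accuracy,
                    accuracy_ci = pd$ci, config_hash = hash)
        write_json_atomic(out, path_of(paste0("metrics_", rg, ".json")))
        files[[paste0("metrics_", rg)]] <- paste0("metrics_", rg, ".json")
      }
    }
  }
  manifest <- list(
    stages = stages,
    config = unclass(cfg),
    config_hash = hash,
    seeds = stats::setNames(
      lapply(.stage_names, function(s) stage_seed(base, s)), .stage_names),
    files = files,
    package_version = as.character(utils::packageVersion("metaforage"))
  )
  write_json_atomic(manifest, path_of("manifest.json"))
  invisible(manifest)
}

#' Pre-move subspace geometry for one regime
#'
#' Convenience wrapper used by the pipeline and the direction analyses:
#' smooths the fine grid over the pre-move window, builds the
#' proximity-conditioned pre-move subspace, picks the component pair with
#' the strongest proximity-value gradient, and computes the post-outcome
#' shift cosine.
#'
#' @param population a [generate_population()] result with fine grid.
#' @param cap proximity cap.
#' @param n_boot bootstrap iterations for the cosine CI.
#' @param seed integer seed.
#' @return List with \code{subspace}, \code{components}, \code{shift},
#'   \code{proj} (per-trial initiation-state projections).
#' @export
regime_geometry <- function(population, cap = 8L, n_boot = 1000L,
                            seed = 1L) {
  states <- trial_window_rates(population, window = c(-0.8, 0.2))
  groups <- proximity_groups(population$labels, cap = cap)
  cm <- smooth_and_average(states, groups)
  sub <- fit_subspace(cm, label = "pre-move")
  comps <- tryCatch(
    select_value_components(sub, states, groups),
    error = function(e) c(2L, 3L)
  )
  init <- initiation_states(states)
  proj <- project_subspace(sub, init)
  shift <- shift_cosine(proj, population$labels, components = comps,
                        n_boot = n_boot, seed = seed)
  list(subspace = sub, components = comps, shift = shift, proj = proj)
}
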