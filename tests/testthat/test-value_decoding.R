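test_that("proximity groups count visits remaining until the switch", {
  tr <- toy_trials(c(1L, 1L, 1L, 2L, 2L, 1L, 1L))
  g <- proximity_groups(tr)
  # stays before the patch-2 switch: 3, 2, 1; switch trials NA;
  # the patch-2 stay precedes the switch back to patch 1 (group 1);
  # trailing stays after the last switch have no group
  expect_equal(g, c(3L, 2L, 1L, NA, 1L, NA, NA))
  expect_true(all(is.na(g[tr$is_switch])))
  capped <- proximity_groups(toy_trials(c(rep(1L, 12L), 2L)), cap = 8L)
  expect_equal(max(capped, na.rm = TRUE), 8L)
})

test_that("bin schemes match the decoder levels", {
  pop <- fixture_pop()
  expect_equal(assign_bins_and_groups(pop, "progression")$n_bins, 11L)
  expect_equal(assign_bins_and_groups(pop, "action")$n_bins, 16L)
  expect_equal(assign_bins_and_groups(pop, "patch")$n_bins, 24L)
  expect_equal(assign_bins_and_groups(pop, "journey")$n_bins, 48L)
  expect_error(assign_bins_and_groups(pop, "bins"), "unknown level")
})

test_that("matched subsampling equalizes and stratifies training pools", {
  pop <- fixture_pop()
  designs <- list(progression = assign_bins_and_groups(pop, "progression"),
                  journey = assign_bins_and_groups(pop, "journey"))
  # force different pool sizes by masking some groups in one design
  designs$journey$groups[seq_len(120L)] <- NA
  matched <- matched_subsample(designs, seed = 40L)
  n1 <- length(matched[[1L]]$subset)
  n2 <- length(matched[[2L]]$subset)
  expect_equal(n1, n2)
  m <- min(sum(!is.na(designs$progression$groups)),
           sum(!is.na(designs$journey$groups)))
  expect_equal(n1, m)
  # group proportions preserved within one trial of the target
  g_all <- table(designs$progression$groups)
  g_sub <- table(designs$progression$groups[matched[[1L]]$subset])
  expected <- m * as.numeric(g_all) / sum(g_all)
  expect_true(all(abs(as.numeric(g_sub) - expected) <= 1))
  expect_identical(matched_subsample(designs, seed = 40L)[[1L]]$subset,
                   matched[[1L]]$subset)
})

test_that("decoder cross-validation never leaks switch or own trials", {
  ds <- fixture_decoder()
  audit <- audit_cv(ds)
  expect_equal(audit$n_switch_in_training, 0L)
  expect_equal(audit$n_self_decoding, 0L)
  expect_true(audit$passed)
  # every stay trial with a group has a decoded value in every bin
  grouped <- which(!is.na(ds$groups))
  expect_false(anyNA(ds$decoded[grouped, ]))
})

test_that("decoders explain held-out variance at default gain, not at zero", {
  ds <- fixture_decoder()
  expect_gt(mean(ds$r2$r2_current[1:4]), 0.2)
  sim <- fixture_sim()
  spec0 <- make_coding_spec(40L, seed = 422L, gain_scale = 0)
  pop0 <- generate_population(sim$trials, sim$trace, spec0, seed = 423L,
                              fine_grid = FALSE)
  ds0 <- train_decoders_cv(assign_bins_and_groups(pop0, "progression"),
                           seed = 424L)
  expect_true(all(ds0$r2$r2_current <= 0.05))
})

test_that("decoded pre-choice value ramps toward the switch", {
  ds <- fixture_decoder()
  dec <- decoded_summary(ds)
  groups <- ds$groups
  lv <- sort(unique(groups[!is.na(groups)]))
  m <- vapply(lv, function(g) mean(dec$pre[which(groups == g)], na.rm = TRUE),
              numeric(1))
  # group counts down toward the switch: value must increase as the group
  # index decreases; include switch trials as the final step
  seq_vals <- c(rev(m), mean(dec$pre[dec$is_switch], na.rm = TRUE))
  rho <- stats::cor(seq_along(seq_vals), seq_vals, method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("outcome bins track the next trial's value when linked", {
  ds <- fixture_decoder()
  sc <- score_current_vs_next(ds)
  expect_gt(sc$next_minus_current[11L], 0)
  expect_gte(sc$r2_current[1L], sc$r2_next[1L])
  # ablation: with the transition flag off there is no outcome-bin
  # advantage for the next-trial value
  sim <- fixture_sim()
  spec_off <- make_coding_spec(40L, seed = 422L, value_transition = FALSE)
  pop_off <- generate_population(sim$trials, sim$trace, spec_off,
                                 seed = 423L, fine_grid = FALSE)
  ds_off <- train_decoders_cv(assign_bins_and_groups(pop_off, "progression"),
                              seed = 424L)
  sc_off <- score_current_vs_next(ds_off)
  expect_lt(sc_off$next_minus_current[11L], 0)
})

test_that("all generality levels decode value after matched subsampling", {
  pop <- fixture_pop()
  lvls <- c("progression", "action", "patch", "journey")
  designs <- stats::setNames(
    lapply(lvls, function(l) assign_bins_and_groups(pop, l)), lvls)
  matched <- matched_subsample(designs, seed = 45L)
  for (l in lvls) {
    # journey-level condition bins can leave < 3 observations per inner
    # fold; cv.glmnet handles this with ungrouped error estimates
    ds <- suppressWarnings(train_decoders_cv(matched[[l]], seed = 46L))
    r2 <- ds$r2$r2_current
    expect_gt(mean(r2, na.rm = TRUE), 0)
  }
})

test_that("meta-learning metrics are exact arithmetic on decoded values", {
  # constructed table: one switch-out / switch-in pair in patch 2
  d <- data.frame(
    trial_id = 1:6, day = 1L, session = 1L, trial = 1:6,
    is_switch = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    reward = c(1L, 1L, 1L, 1L, 0L, 1L),
    patch = c(2L, 3L, 3L, 2L, 2L, 2L),
    origin_patch = c(2L, 2L, 3L, 3L, 2L, 2L),
    pre = c(0, 0.4, 0, 0.1, 0, 0), post = c(0, 0.2, 0.5, -0.3, 0.1, 0),
    outcome = c(0, 0.3, 0, 0.2, 0, 0), bin1 = c(0, 0, 0.2, 0, 0.4, 0),
    bin8 = c(0, 0.1, 0, 0.15, 0, 0),
    sv_current = 0, sv_next = 0
  )
  mm <- metalearning_metrics(d, n_boot = 200L, seed = 1L)
  # switch-out from patch 2 at trial 2 (pre 0.4) pairs with switch-in to
  # patch 2 at trial 4 (post -0.3): repletion 0.7
  expect_equal(mm$repletion$estimate, 0.7)
  # rewarded switch-ins followed by stays: trials 2 and 4
  expect_equal(mm$depletion$estimate,
               mean(c(0.5 - 0.2, 0.1 - (-0.3))))
  expect_equal(mm$outcome_effect$estimate,
               mean(c(0.3 - 0.1, 0.2 - 0.15)))
  expect_equal(mm$value_update$estimate,
               mean(c(0.2 - 0.1, 0.4 - 0.15)))
  # adding a constant to every decoded value changes nothing
  d2 <- d
  for (col in c("pre", "post", "outcome", "bin1", "bin8")) {
    d2[[col]] <- d2[[col]] + 3.7
  }
  mm2 <- metalearning_metrics(d2, n_boot = 200L, seed = 1L)
  for (nm in names(mm)) {
    expect_equal(mm2[[nm]]$estimate, mm[[nm]]$estimate, tolerance = 1e-12)
  }
})

test_that("single-visit episodes are isolated and scored", {
  d <- data.frame(
    trial_id = 1:4, day = 1L, session = 1L, trial = 1:4,
    is_switch = c(FALSE, TRUE, TRUE, FALSE),
    reward = c(0L, 1L, 0L, 0L),
    patch = c(1L, 2L, 1L, 1L), origin_patch = c(1L, 1L, 2L, 1L),
    pre = c(0, 0, 0.6, 0), post = 0, outcome = 0,
    bin1 = c(0, 0, 0.25, 0), bin8 = c(0, 0.25, 0, 0),
    sv_current = 0, sv_next = 0
  )
  sv <- single_visit_analysis(d)
  expect_equal(nrow(sv$episodes), 1L)
  expect_equal(sv$episodes$update, 0)  # identical in/out values
  expect_equal(sv$episodes$reward, 1L)
  none <- single_visit_analysis(d[c(1L, 4L), ])
  expect_equal(nrow(none$episodes), 0L)
})

test_that("decision prediction is exact in degenerate regimes", {
  set.seed(41)
  # separable values
  y <- rep(c(0L, 1L), each = 50L)
  x <- c(rnorm(50, -2, 0.1), rnorm(50, 2, 0.1))
  pd <- predict_decisions(x, y, n_boot = 200L, seed = 2L)
  expect_equal(pd$balanced_accuracy, 1)
  # label shuffling returns chance with an interval covering 0.5
  xs <- rnorm(400)
  ys <- rbinom(400, 1L, 0.3)
  pd0 <- predict_decisions(xs, ys, n_boot = 500L, seed = 3L)
  expect_lt(pd0$ci[1L], 0.55)
  expect_gt(pd0$ci[2L], 0.45)
  expect_error(predict_decisions(x, rep(1L, 100L)), "single class")
})
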