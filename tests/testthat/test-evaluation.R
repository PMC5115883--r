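test_that("stratified splits hold out round(class * fraction) per class", {
  ds <- random_ds(110, 2, seed = 1)   # 86 below60 / 24 at_least_60
  sp <- stratified_splits(ds, 10, 0.2, seed = 4)
  for (s in sp) {
    expect_length(s$test, 22L)                        # 17 + 5
    expect_equal(sum(ds$target[s$test] == "below60"), 17L)
    expect_equal(sum(ds$target[s$test] == "at_least_60"), 5L)
    expect_length(intersect(s$train, s$test), 0L)
    expect_setequal(c(s$train, s$test), 1:110)
  }
  # different splits actually differ; same seed reproduces exactly
  expect_false(identical(sp[[1L]]$test, sp[[2L]]$test))
  expect_identical(stratified_splits(ds, 10, 0.2, seed = 4), sp)
  # unstratifiable setting rejected
  tiny <- random_ds(12, 1, n_pos = 11, seed = 2)
  expect_error(stratified_splits(tiny, 3, 0.2, seed = 1), "too small")
})

test_that("inner folds partition the subjects with class balance", {
  y <- factor(c(rep("below60", 68), rep("at_least_60", 20)),
              levels = c("below60", "at_least_60"))
  f <- stratified_folds(y, 2L, seed = 7)
  expect_setequal(unique(f), 1:2)
  expect_equal(as.vector(table(f, y)[, "at_least_60"]), c(10L, 10L))
  expect_equal(as.vector(table(f, y)[, "below60"]), c(34L, 34L))
})

test_that("F1 agrees with hand-computed confusion tables", {
  lev <- c("below60", "at_least_60")
  t1 <- factor(c("below60", "below60", "at_least_60"), levels = lev)
  expect_equal(f1_score(t1, t1), 1)
  # TP=2, FP=1, FN=1 for below60 on a 6-subject toy
  tr <- factor(rep(lev, each = 3), levels = lev)
  pr <- factor(c("below60", "below60", "at_least_60",
                 "below60", "at_least_60", "at_least_60"), levels = lev)
  expect_equal(f1_score(tr, pr, "below60"), 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(f1_score(tr, pr, "macro"),
               mean(c(f1_score(tr, pr, "below60"), f1_score(tr, pr, "at_least_60"))))
  # constant-majority prediction: minority F1 is 0, macro is half the majority F1
  maj <- factor(rep("below60", 6), levels = lev)
  f_b <- 2 * 3 / (2 * 3 + 3 + 0)
  expect_equal(f1_score(tr, maj), (f_b + 0) / 2)
  expect_equal(f1_score(tr, maj, "at_least_60"), 0)
  expect_error(f1_score(tr, maj, "micro"), "unknown")
})

test_that("inner model selection prefers the smallest C among ties", {
  ds <- random_ds(110, 2, seed = 5)
  cfg1 <- evaluation_config(c_grid = 1, seed = 3)
  # single-C grid short-circuits without fitting
  expect_equal(inner_select_C(ds, "local_1d", cfg1)$chosen_C, 1)
  # a noise dataset yields identical (fallback) scores across the grid,
  # so the smallest C must be returned
  cfg <- evaluation_config(c_grid = c(0.1, 1, 10), inner_repeats = 2L, seed = 3)
  sel <- suppressWarnings(inner_select_C(ds, "local_1d", cfg))
  if (length(unique(sel$mean_f1)) == 1L) expect_equal(sel$chosen_C, 0.1)
  expect_equal(names(sel$mean_f1), c("0.1", "1", "10"))
})

test_that("Jaccard stability reproduces worked pair values", {
  expect_equal(jaccard_stability(list(c("a", "b"), c("a", "b")))$mean, 1)
  expect_equal(jaccard_stability(list("a", "b"))$mean, 0)
  expect_equal(jaccard_stability(list(c("a", "b"), c("b", "c")))$mean, 1 / 3)
  expect_equal(jaccard_stability(list(character(), character()))$mean, 1)
  s <- jaccard_stability(list(c("a", "b"), c("b", "c"), c("a", "b")))
  expect_equal(s$mean, mean(c(1 / 3, 1, 1 / 3)))
  expect_equal(s$sd, sd(c(1 / 3, 1, 1 / 3)))
  expect_error(jaccard_stability(list("a")), "at least 2")
})

test_that("permutation p-values are add-one bounded and ordered correctly", {
  # direct check of the formula semantics on a fast configuration
  spec <- synthetic_spec(60, 4, class_sizes = c(45, 15),
                         planted_1d = list(list(var = 1, range = 1:5, prob = 0.95)))
  ds <- generate_dataset(spec, seed = 13)$dataset
  cfg <- evaluation_config(n_splits = 3, c_grid = 1, n_permutations = 19,
                           n_perm_splits = 2, seed = 11)
  pt <- permutation_test(ds, "local_1d", cfg, fixed_C = 1)
  expect_gte(pt$p_value, 1 / 20)
  expect_lte(pt$p_value, 1)
  expect_length(pt$permuted, 19L)
  expect_equal(pt$p_value, (1 + sum(pt$permuted >= pt$observed)) / 20)
  # an observed statistic below every permuted one gives p = 1
  pt_low <- permutation_test(ds, "local_1d", cfg, fixed_C = 1, observed = -Inf)
  expect_equal(pt_low$p_value, 1)
  # and above every permuted one gives the add-one floor
  pt_high <- permutation_test(ds, "local_1d", cfg, fixed_C = 1, observed = Inf)
  expect_equal(pt_high$p_value, 1 / 20)
})

test_that("the full protocol aggregates runs reproducibly with correct bookkeeping", {
  spec <- synthetic_spec(110, 8, class_sizes = c(86, 24),
    planted_1d = list(list(var = 1, range = 1:5, prob = 0.9),
                      list(var = 2, range = 6:10, prob = 0.9)))
  ds <- generate_dataset(spec, seed = 17)$dataset
  cfg <- evaluation_config(n_splits = 6, c_grid = 1, seed = 5)
  rep1 <- evaluate_model(ds, "local_1d", cfg)
  expect_s3_class(rep1, "evaluation_report")
  expect_equal(nrow(rep1$per_run), 6L)
  expect_equal(rep1$f1_mean, mean(rep1$per_run$f1))
  expect_equal(rep1$f1_sd, sd(rep1$per_run$f1))
  expect_equal(rep1$complexity_mean, mean(rep1$per_run$complexity))
  expect_equal(rep1$c_star, 1)
  expect_equal(rep1$stability_mean, jaccard_stability(rep1$feature_sets)$mean)
  expect_true(rep1$f1_mean > 0.5)   # strongly planted signal must be learnable

  # bit-reproducible under the same config
  rep2 <- evaluate_model(ds, "local_1d", cfg)
  expect_identical(rep1$per_run, rep2$per_run)
  expect_identical(rep1$feature_sets, rep2$feature_sets)

  # frequency tables: counts bounded by runs, planted variable dominates
  fr <- rep1$frequencies
  expect_true(all(fr$variable_frequency$frequency <= 6L))
  expect_true(all(c("bucket 0.16", "bucket 0.20") %in%
                    fr$variable_frequency$name[fr$variable_frequency$frequency >= 3L]))
  expect_true(all(fr$rule_frequency$frequency <= 6L))
  # 1D model: no interactions, but bin coverage present
  expect_equal(nrow(fr$interaction_frequency), 0L)
  expect_true(nrow(fr$bin_coverage) > 0L)
  expect_true(all(fr$bin_coverage$bin %in% 1:10))
})

test_that("interaction frequencies appear only for 2D rules", {
  spec <- synthetic_spec(110, 6, class_sizes = c(86, 24),
    planted_2d = list(list(vars = c(1L, 2L), prob = 0.9, balanced = FALSE)))
  ds <- generate_dataset(spec, seed = 23)$dataset
  cfg <- evaluation_config(n_splits = 4, c_grid = 1, seed = 2)
  rep <- evaluate_model(ds, "local_1and2d", cfg)
  fr <- rep$frequencies
  if (nrow(fr$interaction_frequency) > 0L) {
    expect_true(all(fr$interaction_frequency$frequency <= 4L))
    expect_true(all(fr$interaction_frequency$var1 < fr$interaction_frequency$var2))
    expect_true(all(fr$interaction_frequency$modality %in%
                      c("below60", "at_least_60")))
  }
  # the pair itself is found in at least one run (unbalanced plant shifts
  # margins, so chi2 screening sees both variables)
  pair_seen <- any(vapply(rep$models, function(m) {
    any(!is.na(m$rules$var2))
  }, TRUE))
  expect_true(pair_seen)
})

test_that("seed scoping leaves the caller's RNG stream untouched", {
  set.seed(123); a <- runif(2)
  set.seed(123); runif(1)
  invisible(with_seed(999, runif(10)))
  expect_equal(runif(1), a[2L])
  # sub-seed fan-out is deterministic and distinct
  s1 <- draw_subseeds(5, 10)
  expect_identical(s1, draw_subseeds(5, 10))
  expect_false(any(duplicated(s1)))
})
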