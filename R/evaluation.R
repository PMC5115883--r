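#' Evaluation protocol configuration
#'
#' Parameters of the repeated stratified-holdout protocol: 100 random 80/20
#' class-stratified splits; per split an inner cross-validation of 10 runs
#' of 2-fold (2 folds keep enough subjects of the minority class) to pick
#' the regularization coefficient C; the final models fix C to the most
#' frequent inner choice; significance by a label-permutation test.
#'
#' @param n_splits number of outer train/test splits (default 100).
#' @param test_fraction held-out fraction (default 0.2).
#' @param inner_repeats,inner_folds inner CV layout (default 10 x 2-fold).
#' @param c_grid candidate C values (default 10^(-3..2)).
#' @param n_permutations label permutations for the significance test.
#' @param n_perm_splits outer splits used per permutation (reduced-fidelity
#'   default 5; set to `n_splits` for the full protocol).
#' @param seed master seed; every split and permutation derives its own
#'   sub-seed from it.
#' @param f1_average `"macro"` or one of the modality names.
#' @param alpha,min_modality_size,min_z screening and mining thresholds
#'   passed to [build_model()].
#' @return an `evaluation_config` list.
#' @export
evaluation_config <- function(n_splits = 100L, test_fraction = 0.2,
                              inner_repeats = 10L, inner_folds = 2L,
                              c_grid = c(0.001, 0.01, 0.1, 1, 10, 100),
                              n_permutations = 1000L, n_perm_splits = 5L,
                              seed = 1L, f1_average = "macro",
                              alpha = 0.05, min_modality_size = 10,
                              min_z = 1.96) {
  stopifnot(test_fraction > 0, test_fraction < 1, length(c_grid) >= 1L,
            all(c_grid > 0), n_splits >= 1L)
  structure(list(n_splits = as.integer(n_splits), test_fraction = test_fraction,
                 inner_repeats = as.integer(inner_repeats),
                 inner_folds = as.integer(inner_folds),
                 c_grid = sort(c_grid), n_permutations = as.integer(n_permutations),
                 n_perm_splits = as.integer(n_perm_splits), seed = as.integer(seed),
                 f1_average = f1_average, alpha = alpha,
                 min_modality_size = min_modality_size, min_z = min_z),
            class = "evaluation_config")
}

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

draw_subseeds <- function(seed, n) with_seed(seed, sample.int(.Machine$integer.max - 1L, n))

#' Repeated stratified train/test splits
#'
#' Random splits preserving the class proportions: the per-class test count
#' is `round(class_size * test_fraction)`.
#'
#' @param ds a `discretized_dataset`.
#' @param n_splits number of independent splits.
#' @param test_fraction held-out fraction.
#' @param seed reproducibility seed.
#' @return list of `list(train, test)` integer index pairs.
#' @export
stratified_splits <- function(ds, n_splits, test_fraction, seed) {
  y <- ds$target
  cls <- levels(y)
  sizes <- table(y)
  n_test <- round(sizes * test_fraction)
  if (any(n_test < 1L) || any(n_test >= sizes)) {
    stop("a class is too small to stratify at test fraction ", test_fraction)
  }
  seeds <- draw_subseeds(seed, n_splits)
  lapply(seq_len(n_splits), function(i) {
    with_seed(seeds[i], {
      test <- unlist(lapply(cls, function(cl) {
        idx <- which(y == cl)
        sample(idx, n_test[[cl]])
      }))
      test <- sort(test)
      list(train = setdiff(seq_along(y), test), test = test)
    })
  })
}

# stratified k-fold partition of an index vector
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' F1 score
#'
#' Harmonic mean of precision and recall. `average = "macro"` reports the
#' unweighted mean of the per-modality F1 scores; naming a modality reports
#' that modality's F1. A modality with no predicted (or no achievable)
#' positives scores 0.
#'
#' @param truth,pred factors over the same modalities.
#' @param average `"macro"` or a modality name.
#' @return a number in `[0, 1]`.
#' @export
f1_score <- function(truth, pred, average = "macro") {
  lev <- levels(truth)
  pred <- factor(as.character(pred), levels = lev)
  per <- vapply(lev, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, 0)
  if (average == "macro") mean(per)
  else if (average %in% lev) per[[average]]
  else stop("unknown F1 average '", average, "'")
}

# fit every C on pre-selected features; returns per-C validation F1.
# screening and mining run once per fold -- only the fit depends on C
fit_grid_f1 <- function(train, val, model_type, config) {
  sel <- select_model_features(train, model_type, config$alpha,
                               config$min_modality_size, config$min_z)
  vapply(config$c_grid, function(C) {
    m <- suppressWarnings(fit_from_selection(train, sel, C))
    f1_score(val$target, predict(m, val), config$f1_average)
  }, 0)
}

#' Inner cross-validated choice of C
#'
#' For each C on the grid, the mean validation F1 over `inner_repeats` runs
#' of stratified `inner_folds`-fold cross-validation of the training set;
#' variable screening and rule mining are re-run inside every fold, so no
#' validation subject influences feature construction. The chosen C
#' maximizes mean F1, ties going to the smallest C.
#'
#' @param train a `discretized_dataset` (the training split).
#' @param model_type model type as in [build_model()].
#' @param config an [evaluation_config()].
#' @param seed seed for the fold draws.
#' @return list with `chosen_C` and `mean_f1` (named by C).
#' @export
inner_select_C <- function(train, model_type, config, seed = config$seed) {
  if (length(config$c_grid) == 1L) {
    return(list(chosen_C = config$c_grid,
                mean_f1 = stats::setNames(NA_real_, as.character(config$c_grid))))
  }
  fold_seeds <- draw_subseeds(seed, config$inner_repeats)
  scores <- matrix(0, nrow = 0L, ncol = length(config$c_grid))
  for (r in seq_len(config$inner_repeats)) {
    fold <- stratified_folds(train$target, config$inner_folds, fold_seeds[r])
    for (k in seq_len(config$inner_folds)) {
      tr <- subset_subjects(train, fold != k)
      va <- subset_subjects(train, fold == k)
      scores <- rbind(scores, fit_grid_f1(tr, va, model_type, config))
    }
  }
  mean_f1 <- colMeans(scores)
  names(mean_f1) <- as.character(config$c_grid)
  chosen <- config$c_grid[which.max(mean_f1)]   # which.max takes the first (smallest C) at ties
  list(chosen_C = chosen, mean_f1 = mean_f1)
}

model_feature_ids <- function(model) {
  if (model$model_type == "global") model$selected_variables
  else if (is.null(model$rules) || nrow(model$rules) == 0L) character()
  else rule_ids(model$rules)
}

#' Full evaluation of one model type
#'
#' The complete protocol: (pass 1) for each outer split, choose C by inner
#' cross-validation on the training set; fix `C*` to the most frequent
#' choice (smallest at ties); (pass 2) rebuild each split's model at `C*`,
#' score it on the held-out subjects, and aggregate F1, complexity,
#' selected-feature stability and frequency tables. Bit-reproducible for a
#' fixed seed.
#'
#' @param ds a `discretized_dataset`.
#' @param model_type model type as in [build_model()].
#' @param config an [evaluation_config()].
#' @param permutation_p optionally compute the permutation p-value as well
#'   (default FALSE; see [permutation_test()]).
#' @return an `evaluation_report` object.
#' @export
evaluate_model <- function(ds, model_type, config, permutation_p = FALSE) {
  splits <- stratified_splits(ds, config$n_splits, config$test_fraction, config$seed)
  inner_seeds <- draw_subseeds(config$seed + 1L, config$n_splits)

  chosen_Cs <- numeric(config$n_splits)
  for (i in seq_len(config$n_splits)) {
    train <- subset_subjects(ds, splits[[i]]$train)
    chosen_Cs[i] <- inner_select_C(train, model_type, config, inner_seeds[i])$chosen_C
  }
  tab <- table(chosen_Cs)
  modal <- names(tab)[tab == max(tab)]
  c_star <- min(as.numeric(modal))

  per_run <- vector("list", config$n_splits)
  feature_sets <- vector("list", config$n_splits)
  models <- vector("list", config$n_splits)
  for (i in seq_len(config$n_splits)) {
    train <- subset_subjects(ds, splits[[i]]$train)
    test <- subset_subjects(ds, splits[[i]]$test)
    m <- suppressWarnings(build_model(train, model_type, C = c_star,
                                      alpha = config$alpha,
                                      min_modality_size = config$min_modality_size,
                                      min_z = config$min_z))
    per_run[[i]] <- data.frame(
      run = i, f1 = f1_score(test$target, predict(m, test), config$f1_average),
      complexity = m$complexity, chosen_C = chosen_Cs[i])
    feature_sets[[i]] <- model_feature_ids(m)
    models[[i]] <- m
  }
  per_run <- do.call(rbind, per_run)
  stab <- jaccard_stability(feature_sets)

  report <- structure(
    list(model_type = model_type, config = config,
         per_run = per_run,
         f1_mean = mean(per_run$f1), f1_sd = stats::sd(per_run$f1),
         complexity_mean = mean(per_run$complexity),
         c_star = c_star, c_mode_freq = max(tab), c_table = tab,
         stability_mean = stab$mean, stability_sd = stab$sd,
         feature_sets = feature_sets,
         models = models,
         permutation_p = NA_real_),
    class = "evaluation_report"
  )
  report$frequencies <- feature_frequencies(report)
  if (isTRUE(permutation_p)) {
    report$permutation_p <- permutation_test(ds, model_type, config,
                                             fixed_C = c_star)$p_value
  }
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (", x$model_type, ", ", x$config$n_splits, " splits)\n", sep = "")
  cat(sprintf("  F1 %.2f +/- %.2f | complexity %.1f | C* = %g (freq %d) | stability %.2f +/- %.2f\n",
              x$f1_mean, x$f1_sd, x$complexity_mean, x$c_star, x$c_mode_freq,
              x$stability_mean, x$stability_sd))
  if (!is.na(x$permutation_p)) cat(sprintf("  permutation p = %.4g\n", x$permutation_p))
  invisible(x)
}

#' Label-permutation significance test
#'
#' Tests whether the model's predictive performance could arise with
#' randomly permuted outcomes. The statistic is the mean test F1 over
#' `n_perm_splits` stratified splits of the full pipeline (screening,
#' mining, fit at a fixed C); it is recomputed for `n_permutations` label
#' permutations, and the add-one p-value is
#' `(1 + #permuted >= observed) / (n_permutations + 1)`.
#'
#' @param ds a `discretized_dataset`.
#' @param model_type model type.
#' @param config an [evaluation_config()] (`n_permutations`,
#'   `n_perm_splits` and `seed` are used).
#' @param fixed_C the C used throughout (typically the `C*` of
#'   [evaluate_model()]; default 1).
#' @param observed optionally a pre-computed observed statistic; by default
#'   the same reduced statistic is computed on the unpermuted labels.
#' @return list with `p_value`, `observed`, `permuted` (vector of permuted
#'   statistics).
#' @export
permutation_test <- function(ds, model_type, config, fixed_C = 1,
                             observed = NULL) {
  stat <- function(d, seed) {
    splits <- stratified_splits(d, config$n_perm_splits, config$test_fraction, seed)
    mean(vapply(splits, function(sp) {
      m <- suppressWarnings(build_model(subset_subjects(d, sp$train), model_type,
                                        C = fixed_C, alpha = config$alpha,
                                        min_modality_size = config$min_modality_size,
                                        min_z = config$min_z))
      te <- subset_subjects(d, sp$test)
      f1_score(te$target, predict(m, te), config$f1_average)
    }, 0))
  }
  if (is.null(observed)) observed <- stat(ds, config$seed + 2L)
  perm_seeds <- draw_subseeds(config$seed + 3L, config$n_permutations)
  permuted <- vapply(seq_len(config$n_permutations), function(b) {
    dperm <- ds
    dperm$target <- with_seed(perm_seeds[b], sample(ds$target))
    stat(dperm, perm_seeds[b] + 1L)
  }, 0)
  p <- (1 + sum(permuted >= observed)) / (config$n_permutations + 1)
  list(p_value = p, observed = observed, permuted = permuted)
}

#' Jaccard stability of selected-feature sets
#'
#' Mean and standard deviation of the Jaccard similarity
#' `|A n B| / |A u B|` over all unordered pairs of runs. Feature identity is
#' the variable name for global models and the full
#' (variables, conditions, modality) triple for local models. Two empty
#' sets count as similarity 1.
#'
#' @param sets list of character vectors of feature identifiers (>= 2).
#' @return list with `mean` and `sd`.
#' @export
jaccard_stability <- function(sets) {
  if (length(sets) < 2L) stop("stability needs at least 2 runs")
  sims <- c()
  for (i in seq_len(length(sets) - 1L)) {
    for (j in (i + 1L):length(sets)) {
      a <- unique(sets[[i]]); b <- unique(sets[[j]])
      u <- length(union(a, b))
      sims <- c(sims, if (u == 0L) 1 else length(intersect(a, b)) / u)
    }
  }
  list(mean = mean(sims), sd = stats::sd(sims))
}

#' Feature, rule and interaction frequency tables
#'
#' The data behind the Results-style figures: how often each variable enters
#' a model over the runs; how often each exact rule recurs; in how many runs
#' each unordered variable pair interacts through a 2D rule, per modality; and
#' per-(modality, variable) bin-coverage maps counting, for every level
#' code, the number of (run, rule) occurrences covering it.
#'
#' @param report an `evaluation_report`.
#' @return list with data.frames `variable_frequency`, `rule_frequency`,
#'   `interaction_frequency`, `bin_coverage`.
#' @export
feature_frequencies <- function(report) {
  runs <- report$models
  n_runs <- length(runs)

  var_count <- list()
  rule_count <- list()
  inter_count <- list()
  bin_rows <- list()
  for (i in seq_len(n_runs)) {
    m <- runs[[i]]
    if (m$model_type == "global") {
      vars <- m$selected_variables
    } else if (!is.null(m$rules) && nrow(m$rules) > 0L) {
      r <- m$rules
      vars <- unique(c(r$var1, r$var2[!is.na(r$var2)]))
      ids <- rule_ids(r)
      for (id in ids) rule_count[[id]] <- (rule_count[[id]] %||% 0L) + 1L
      two_d <- which(!is.na(r$var2))
      keys <- unique(vapply(two_d, function(k) {
        pair <- paste(sort(c(r$var1[k], r$var2[k])), collapse = " & ")
        paste0(r$modality[k], "\r", pair)
      }, ""))
      for (key in keys) inter_count[[key]] <- (inter_count[[key]] %||% 0L) + 1L
      one_d <- which(is.na(r$var2))
      for (k in one_d) {
        bin_rows[[length(bin_rows) + 1L]] <- data.frame(
          modality = r$modality[k], variable = r$var1[k],
          bin = r$cond1[[k]], stringsAsFactors = FALSE)
      }
    } else {
      vars <- character()
    }
    for (v in vars) var_count[[v]] <- (var_count[[v]] %||% 0L) + 1L
  }

  to_df <- function(cnt) {
    if (length(cnt) == 0L) {
      return(data.frame(name = character(), frequency = integer()))
    }
    df <- data.frame(name = names(cnt), frequency = unlist(cnt), row.names = NULL,
                     stringsAsFactors = FALSE)
    df[order(-df$frequency, df$name), , drop = FALSE]
  }
  vf <- to_df(var_count)
  rf <- to_df(rule_count)

  inter <- if (length(inter_count) == 0L) {
    data.frame(modality = character(), var1 = character(), var2 = character(),
               frequency = integer())
  } else {
    parts <- strsplit(names(inter_count), "\r", fixed = TRUE)
    pairs <- strsplit(vapply(parts, `[`, "", 2L), " & ", fixed = TRUE)
    data.frame(modality = vapply(parts, `[`, "", 1L),
               var1 = vapply(pairs, `[`, "", 1L),
               var2 = vapply(pairs, `[`, "", 2L),
               frequency = unlist(inter_count), row.names = NULL,
               stringsAsFactors = FALSE)
  }

  bins <- if (length(bin_rows) == 0L) {
    data.frame(modality = character(), variable = character(), bin = integer(),
               frequency = integer())
  } else {
    all_bins <- do.call(rbind, bin_rows)
    agg <- stats::aggregate(list(frequency = rep(1L, nrow(all_bins))),
                            all_bins[c("modality", "variable", "bin")], sum)
    agg[order(agg$modality, agg$variable, agg$bin), , drop = FALSE]
  }

  list(variable_frequency = vf, rule_frequency = rf,
       interaction_frequency = inter[order(-inter$frequency), , drop = FALSE],
       bin_coverage = bins, n_runs = n_runs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
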