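test_that("1D condition enumeration matches the closed forms", {
  ord10 <- variable_meta("b", "ordinal", as.character(1:10))
  conds <- enumerate_conditions_1d(ord10)
  expect_length(conds, 55L)                       # k(k+1)/2
  # brute-force oracle: every contiguous range, each exactly once
  brute <- list()
  for (a in 1:10) for (b in a:10) brute[[length(brute) + 1L]] <- a:b
  expect_identical(conds, brute)

  expect_length(enumerate_conditions_1d(variable_meta("x", "ordinal", "1")), 1L)

  sex <- variable_meta("sex", "nominal", c("M", "F"), origin = "demographic")
  subsets <- enumerate_conditions_1d(sex)
  expect_length(subsets, 3L)
  expect_setequal(vapply(subsets, paste, "", collapse = ","), c("1", "2", "1,2"))

  wide <- variable_meta("eth", "nominal", letters[1:7], origin = "demographic")
  expect_error(enumerate_conditions_1d(wide), "pre-group")
})

test_that("candidate enumeration covers pairs exhaustively and deterministically", {
  metas <- lapply(1:3, function(j) variable_meta(paste0("v", j), "ordinal", as.character(1:10)))
  one_d <- enumerate_candidates(metas, 1L)
  expect_equal(nrow(one_d), 3L * 55L)
  two_d <- enumerate_candidates(metas[1:2], 2L)
  expect_equal(nrow(two_d), 55L * 55L)
  expect_true(all(two_d$var1 != two_d$var2))       # never paired with itself
  all3 <- enumerate_candidates(metas, 2L)
  expect_equal(nrow(all3), 3L * 55L^2)
  expect_identical(all3, enumerate_candidates(metas, 2L))  # deterministic
  expect_error(enumerate_candidates(metas[1L], 2L), "at least 2")
})

test_that("rule support equals per-subject condition evaluation", {
  vals <- rbind(c(1, 4), c(2, 5), c(3, 6), c(4, 1), c(5, 2), c(6, 3))
  ds <- make_ordinal_ds(vals, c(rep("below60", 4), rep("at_least_60", 2)), k = 6)
  # brute-force membership on the 6-subject fixture
  for (cond1 in list(1:2, 3:6, 2:4)) {
    for (cond2 in list(NULL, 1:3, 5:6)) {
      got <- if (is.null(cond2)) rule_support(ds, "v1", cond1)
             else rule_support(ds, "v1", cond1, "v2", cond2)
      manual <- which(vapply(seq_len(6), function(i) {
        vals[i, 1] %in% cond1 && (is.null(cond2) || vals[i, 2] %in% cond2)
      }, TRUE))
      expect_identical(got, manual)
    }
  }
  expect_length(rule_support(ds, "v1", 1:6), 6L)   # full range covers everyone
  expect_length(rule_support(ds, "v1", 1:3, "v2", 4:6), 3L)
  expect_error(rule_support(ds, "v1", 1:2, "v1", 3:4), "distinct")
})

test_that("z-score follows the one-proportion formula", {
  ds <- random_ds(110, 2, seed = 2)
  tgt <- as.character(ds$target)
  # whole population: p_r = p_0
  expect_equal(rule_z_score(1:110, "below60", ds), 0)
  # 20 subjects all below60: the hand-computed value
  sup <- which(tgt == "below60")[1:20]
  p0 <- 86 / 110
  expect_equal(rule_z_score(sup, "below60", ds),
               (1 - p0) / sqrt(p0 * (1 - p0) / 20), tolerance = 1e-12)
  expect_equal(round(rule_z_score(sup, "below60", ds), 2), 2.36)

  # enrichment for one modality is depletion for the other
  expect_lt(rule_z_score(sup, "at_least_60", ds), 0)

  # subject order never matters
  sh <- sample(sup)
  expect_equal(rule_z_score(sh, "below60", ds), rule_z_score(sup, "below60", ds))

  expect_error(rule_z_score(integer(), "below60", ds), "empty")
  ds_deg <- ds; ds_deg$target <- factor(rep("below60", 110), levels = c("below60", "at_least_60"))
  expect_error(rule_z_score(1:5, "below60", ds_deg), "degenerate|non-empty")
})

test_that("selection applies both thresholds inclusively and records quality", {
  # v1: below60 sits in bins 1..5, at_least_60 in bins 6..10
  vals <- cbind(c(rep(1:5, length.out = 86), rep(6:10, length.out = 24)))
  ds <- make_ordinal_ds(vals, ckd_target())
  kept <- select_significant(ds, dims = 1L)
  expect_true(nrow(kept) > 0L)
  expect_true(all(kept$modality_size >= 10))
  expect_true(all(kept$z >= 1.96))
  # coverage/modality_size recomputed independently for every kept rule
  for (i in seq_len(nrow(kept))) {
    sup <- rule_support(ds, kept$var1[i], kept$cond1[[i]])
    expect_equal(kept$coverage[i], length(sup))
    expect_equal(kept$modality_size[i], sum(ds$target[sup] == kept$modality[i]))
    expect_equal(kept$z[i], oracle_z(sup, kept$modality[i], ds$target), tolerance = 1e-12)
  }
  # thresholds are inclusive: a rule at exactly the cutoffs stays
  probe <- kept[which.min(kept$z), ]
  at_cut <- select_significant(ds, dims = 1L, min_z = probe$z,
                               min_modality_size = probe$modality_size)
  expect_true(rule_ids(probe) %in% rule_ids(at_cut))
  # raising either threshold past it drops it
  above <- select_significant(ds, dims = 1L, min_z = probe$z + 1e-9)
  expect_false(rule_ids(probe) %in% rule_ids(above))
  small <- select_significant(ds, dims = 1L, min_modality_size = 10)
  expect_true(all(small$modality_size >= 10))
  expect_error(select_significant(ds, min_z = -1), "positive")
})

test_that("minimization agrees with the exhaustive dominance oracle", {
  # the two-rule worked instances: nested ranges on one variable
  two <- random_rule_table(2, two_d = FALSE)
  two$cond1 <- list(2:4, 1:5); two$lo1 <- c(2L, 1L); two$hi1 <- c(4L, 5L)
  two$mask1 <- vapply(two$cond1, function(cd) sum(2^(cd - 1)), 0)
  two$var1 <- "v1"; two$var2 <- NA_character_; two$modality <- "below60"
  two$z <- c(2.0, 2.5)                       # inner weaker -> larger survives
  expect_equal(rule_ids(minimize_rules(two)), rule_ids(two[2L, ]))
  two$z <- c(2.5, 2.0)                       # inner stronger -> smaller survives
  expect_equal(rule_ids(minimize_rules(two)), rule_ids(two[1L, ]))
  two$z <- c(2.2, 2.2)                       # tie -> larger wins, no annihilation
  expect_equal(rule_ids(minimize_rules(two)), rule_ids(two[2L, ]))
  # incomparable: overlapping non-nested ranges stay untouched
  two$cond1 <- list(1:3, 2:5); two$lo1 <- c(1L, 2L); two$hi1 <- c(3L, 5L)
  two$mask1 <- vapply(two$cond1, function(cd) sum(2^(cd - 1)), 0)
  expect_equal(nrow(minimize_rules(two)), 2L)

  set.seed(42)
  for (rep in 1:40) {
    rt <- random_rule_table(sample(2:60, 1L))
    mine <- minimize_rules(rt)
    orac <- oracle_minimize(rt)
    expect_setequal(paste(rule_ids(mine), mine$z), paste(rule_ids(orac), orac$z))
    # idempotence and containment-freedom
    again <- minimize_rules(mine)
    expect_equal(nrow(again), nrow(mine))
  }
})

test_that("mined rulesets satisfy their provenance and find planted structure", {
  # a variable that separates the classes over fully occupied bins
  vals <- cbind(c(rep(1:3, length.out = 86), rep(4:10, length.out = 24)),
                rep(1:10, length.out = 110))
  ds <- make_ordinal_ds(vals, ckd_target())
  rs <- mine_rules(ds, dims = 1L)
  expect_s3_class(rs, "ruleset")
  expect_true(all(rs$rules$modality_size >= rs$provenance$min_modality_size))
  expect_true(all(rs$rules$z >= rs$provenance$min_z))
  ids <- rule_ids(rs$rules)
  expect_true("v1[1,2,3]->below60" %in% ids)

  # deterministic
  expect_identical(rule_ids(mine_rules(ds, dims = 1L)$rules), ids)

  # marginally-balanced planted interaction: invisible in 1D, found in 2D
  spec <- synthetic_spec(110, 6, class_sizes = c(86, 24),
                         planted_2d = list(list(vars = c(1L, 2L), prob = 0.9,
                                                balanced = TRUE)))
  gen <- generate_dataset(spec, seed = 8)
  r1 <- mine_rules(gen$dataset, dims = 1L)
  planted <- gen$ground_truth$planted_pairs[[1L]]
  expect_false(any(r1$rules$var1 %in% planted))
  r12 <- mine_rules(gen$dataset, dims = c(1L, 2L))
  hit <- !is.na(r12$rules$var2) &
    r12$rules$var1 %in% planted & r12$rules$var2 %in% planted
  expect_true(any(hit))
})

test_that("null data yields rare survivors at the default thresholds", {
  # label-shuffled noise: survivors should be in the z-threshold tail range
  set.seed(99)
  n_cand <- 0L; n_kept <- 0L
  for (r in 1:15) {
    ds <- random_ds(110, 4, seed = 1000 + r)
    kept <- select_significant(ds, dims = 1L)
    n_cand <- n_cand + 4L * 55L * 2L
    n_kept <- n_kept + nrow(kept)
  }
  # one-sided 1.96 tail is ~2.5% per candidate-modality test; correlated
  # candidates inflate the variance, so assert a generous band around it
  expect_lt(n_kept / n_cand, 0.08)
})

test_that("rulesets round-trip through JSONL", {
  vals <- cbind(c(rep(1:3, length.out = 86), rep(4:10, length.out = 24)),
                rep(c(1:5, 1:5), length.out = 110))
  ds <- make_ordinal_ds(vals, ckd_target())
  rs <- mine_rules(ds, dims = c(1L, 2L))
  p <- withr::local_tempfile(fileext = ".jsonl")
  write_ruleset(rs, p)
  back <- read_ruleset(p)
  expect_equal(rule_ids(back$rules), rule_ids(rs$rules))
  expect_equal(back$rules$z, rs$rules$z)
  expect_equal(back$rules$coverage, rs$rules$coverage)
  expect_equal(back$provenance$min_z, rs$provenance$min_z)
  # the human-readable rendering matches the published syntax
  txt <- format_rule(rs$rules[1L, ])
  expect_match(txt, "\\{variable: 'v1'; condition: bins? \\d")
})
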