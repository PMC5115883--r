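# shared fixtures and independent oracles

# quick ordinal dataset: n subjects, m variables with k levels, given target
make_ordinal_ds <- function(values, target, k = 10L,
                            modalities = c("below60", "at_least_60")) {
  values <- as.matrix(values)
  meta <- lapply(seq_len(ncol(values)), function(j) {
    variable_meta(paste0("v", j), "ordinal", as.character(1:k))
  })
  discretized_dataset(values, meta, target, modalities = modalities)
}

random_ds <- function(n, m, k = 10L, n_pos = round(n * 86 / 110), seed = 1L) {
  set.seed(seed)
  vals <- matrix(sample.int(k, n * m, replace = TRUE), n, m)
  tgt <- sample(c(rep("below60", n_pos), rep("at_least_60", n - n_pos)))
  make_ordinal_ds(vals, tgt, k)
}

# the 110-subject 86/24 target used throughout
ckd_target <- function() c(rep("below60", 86), rep("at_least_60", 24))

# --- independent oracles --------------------------------------------------

# z statistic computed directly from the definition, independent of the
# package's vectorized path
oracle_z <- function(support, modality, target) {
  p0 <- mean(target == modality)
  n_r <- length(support)
  p_r <- mean(target[support] == modality)
  (p_r - p0) / sqrt(p0 * (1 - p0) / n_r)
}

# exhaustive O(r^2) pairwise dominance filter over a rule table; containment
# computed set-wise from the condition lists, nothing shared with the
# package's mask/range machinery
oracle_minimize <- function(rules) {
  n <- nrow(rules)
  if (n == 0L) return(rules)
  contains <- function(i, j) {  # conditions of i strictly inside conditions of j?
    if (rules$modality[i] != rules$modality[j]) return(FALSE)
    if (!identical(rules$var1[i], rules$var1[j])) return(FALSE)
    if (!identical(is.na(rules$var2[i]), is.na(rules$var2[j]))) return(FALSE)
    if (!is.na(rules$var2[i]) && rules$var2[i] != rules$var2[j]) return(FALSE)
    a1 <- rules$cond1[[i]]; b1 <- rules$cond1[[j]]
    a2 <- rules$cond2[[i]]; b2 <- rules$cond2[[j]]
    sub1 <- all(a1 %in% b1); sub2 <- is.null(a2) || all(a2 %in% b2)
    eq <- setequal(a1, b1) && (is.null(a2) || setequal(a2, b2))
    sub1 && sub2 && !eq
  }
  removed <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (contains(i, j) && rules$z[j] >= rules$z[i]) removed[i] <- TRUE
      if (contains(j, i) && rules$z[j] > rules$z[i]) removed[i] <- TRUE
    }
  }
  out <- rules[!removed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random rule tables for dominance-oracle comparisons: ordinal ranges and
# nominal subsets over a few variables, one or two dimensions
random_rule_table <- function(n_rules, k = 6L, n_vars = 3L, two_d = TRUE) {
  vars <- paste0("v", seq_len(n_vars))
  rng <- function() { a <- sample.int(k, 1L); b <- sample(a:k, 1L); a:b }
  rows <- lapply(seq_len(n_rules), function(i) {
    v1 <- sample(vars, 1L)
    if (two_d && stats::runif(1) < 0.5) {
      v2 <- sample(setdiff(vars, v1), 1L)
      ord <- sort(c(v1, v2))
      list(var1 = ord[1L], cond1 = rng(), var2 = ord[2L], cond2 = rng(),
           modality = sample(c("below60", "at_least_60"), 1L))
    } else {
      list(var1 = v1, cond1 = rng(), var2 = NA_character_, cond2 = NULL,
           modality = sample(c("below60", "at_least_60"), 1L))
    }
  })
  df <- data.frame(
    var1 = vapply(rows, `[[`, "", "var1"),
    var2 = vapply(rows, function(r) r$var2, ""),
    modality = vapply(rows, `[[`, "", "modality"),
    coverage = NA_integer_, modality_size = NA_integer_,
    z = round(stats::runif(n_rules, 1.96, 6), 2),
    stringsAsFactors = FALSE)
  df$cond1 <- lapply(rows, `[[`, "cond1")
  df$cond2 <- lapply(rows, `[[`, "cond2")
  df$mask1 <- vapply(df$cond1, function(cd) sum(2^(cd - 1L)), 0)
  df$mask2 <- vapply(df$cond2, function(cd) if (is.null(cd)) 0 else sum(2^(cd - 1L)), 0)
  df$lo1 <- vapply(df$cond1, min, 0L); df$hi1 <- vapply(df$cond1, max, 0L)
  df$lo2 <- vapply(df$cond2, function(cd) if (is.null(cd)) 0L else min(cd), 0L)
  df$hi2 <- vapply(df$cond2, function(cd) if (is.null(cd)) 0L else max(cd), 0L)
  df$ord1 <- TRUE; df$ord2 <- TRUE
  df
}

# L2-penalized logistic objective in the package's parameterization,
# minimized numerically -- the brute-force fit oracle
oracle_l2_logistic <- function(x, t, C) {
  x <- as.matrix(x)
  obj <- function(b) {
    s <- drop(cbind(1, x) %*% b) * t
    C * sum(log1p(exp(-s))) + 0.5 * sum(b[-1L]^2)
  }
  fit <- stats::optim(rep(0, ncol(x) + 1L), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 2000))
  list(intercept = fit$par[1L], weights = fit$par[-1L], value = fit$value)
}

# canonical rule identity usable on both package rules and hand-built rows
sorted_ids <- function(rules) sort(rule_ids(rules))
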