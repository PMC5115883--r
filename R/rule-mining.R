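#' Enumerate all 1D conditions of a variable
#'
#' A condition is the elementary building block of a rule: for an ordinal
#' variable every contiguous range of level codes `[a, b]` (there are
#' `k(k+1)/2` of them for `k` levels); for a nominal variable every
#' non-empty subset of its categories. Nominal enumeration is guarded,
#' because the subset count grows as `2^k - 1`.
#'
#' @param meta a [variable_meta()].
#' @param max_nominal_levels refuse nominal variables with more levels than
#'   this (default 6); pre-group rare categories instead.
#' @return a list of integer vectors of level codes, in deterministic order
#'   (ordinal: lexicographic by `(a, b)`; nominal: increasing bitmask).
#' @export
enumerate_conditions_1d <- function(meta, max_nominal_levels = 6L) {
  k <- meta$n_levels
  if (meta$kind == "ordinal") {
    out <- vector("list", k * (k + 1L) / 2L)
    i <- 0L
    for (a in seq_len(k)) {
      for (b in a:k) {
        i <- i + 1L
        out[[i]] <- a:b
      }
    }
    out
  } else {
    if (k > max_nominal_levels) {
      stop("nominal variable '", meta$name, "' has ", k, " levels (limit ",
           max_nominal_levels, "); pre-group categories before mining")
    }
    lapply(seq_len(2L^k - 1L), function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) != 0L))
  }
}

#' Enumerate candidate rule conditions over a variable list
#'
#' Yields every 1D condition (dims = 1) or every pair of 1D conditions over
#' each unordered pair of distinct variables (dims = 2), in deterministic
#' order: variables in declared order, conditions as in
#' [enumerate_conditions_1d()]. A variable is never paired with itself.
#'
#' @param metas list of [variable_meta()].
#' @param dims 1 or 2.
#' @param max_nominal_levels nominal subset guard.
#' @return a data.frame with columns `var1`, `cond1` (list column of level
#'   codes) and, for dims = 2, `var2`, `cond2`.
#' @export
enumerate_candidates <- function(metas, dims = 1L, max_nominal_levels = 6L) {
  if (inherits(metas, "variable_meta")) metas <- list(metas)
  nm <- vapply(metas, `[[`, "", "name")
  conds <- lapply(metas, enumerate_conditions_1d, max_nominal_levels = max_nominal_levels)
  if (dims == 1L) {
    n_per <- lengths(conds)
    df <- data.frame(var1 = rep(nm, n_per), stringsAsFactors = FALSE)
    df$cond1 <- unlist(conds, recursive = FALSE)
    return(df)
  }
  if (dims != 2L) stop("dims must be 1 or 2")
  if (length(metas) < 2L) stop("2D enumeration needs at least 2 variables")
  pieces <- list()
  for (i in seq_len(length(metas) - 1L)) {
    for (j in (i + 1L):length(metas)) {
      ni <- length(conds[[i]]); nj <- length(conds[[j]])
      df <- data.frame(var1 = rep(nm[i], ni * nj), var2 = rep(nm[j], ni * nj),
                       stringsAsFactors = FALSE)
      df$cond1 <- rep(conds[[i]], each = nj)
      df$cond2 <- rep(conds[[j]], times = ni)
      pieces[[length(pieces) + 1L]] <- df
    }
  }
  do.call(rbind, pieces)
}

#' Subjects satisfying a conjunction of conditions
#'
#' The support of a rule; its 0/1 indicator over subjects is the "local
#' variable" used as a classifier feature.
#'
#' @param ds a `discretized_dataset`.
#' @param var1 variable name; `cond1` integer vector of admitted level codes.
#' @param var2,cond2 optional second condition on a distinct variable.
#' @return sorted integer vector of subject indices.
#' @export
rule_support <- function(ds, var1, cond1, var2 = NULL, cond2 = NULL) {
  sel <- ds$values[, var1] %in% cond1
  if (!is.null(var2)) {
    if (identical(var1, var2)) stop("the two conditions of a 2D rule must be on distinct variables")
    sel <- sel & ds$values[, var2] %in% cond2
  }
  which(sel)
}

#' One-proportion z-score of a rule
#'
#' Rule quality: compares the proportion of the target modality inside the
#' rule's support to the proportion in the whole population,
#' \deqn{z = (p_r - p_0) / \sqrt{p_0 (1 - p_0) / n_r}}
#' with \eqn{p_r} the modality proportion in the rule, \eqn{p_0} the
#' population proportion and \eqn{n_r} the support size. Positive when the
#' rule is enriched for the modality.
#'
#' @param support integer vector of subject indices (non-empty).
#' @param modality target modality the rule describes.
#' @param ds a `discretized_dataset`.
#' @return the z statistic.
#' @export
rule_z_score <- function(support, modality, ds) {
  if (length(support) == 0L) stop("rule support is empty")
  if (!modality %in% levels(ds$target)) stop("unknown modality '", modality, "'")
  p0 <- mean(ds$target == modality)
  if (p0 <= 0 || p0 >= 1) stop("degenerate target: modality proportion is 0 or 1")
  n_r <- length(support)
  p_r <- mean(ds$target[support] == modality)
  (p_r - p0) / sqrt(p0 * (1 - p0) / n_r)
}

# --- internal fast mining path -------------------------------------------
#
# Conditions are represented as bitmasks over level codes so that
# containment tests and support counting vectorize. For a variable pair the
# coverage of every condition pair is obtained in one step from the k1 x k2
# contingency table: C1 %*% T %*% t(C2), where C1, C2 stack the 0/1
# condition indicators.

cond_mask <- function(cond) {
  if (max(cond) > 31L) stop("variables with more than 31 levels are not supported for mining")
  sum(bitwShiftL(1L, cond - 1L))
}

cond_matrix <- function(conds, k) {
  C <- matrix(0, nrow = length(conds), ncol = k)
  for (i in seq_along(conds)) C[i, conds[[i]]] <- 1
  C
}

# annotate a rule block with the containment bookkeeping columns: bitmasks,
# range bounds and ordinal flags (ordinal conditions are contiguous, so
# (lo, hi) determines the set and containment is two comparisons)
annotate_conds <- function(df, conds1, conds2, ord1, ord2) {
  df$cond1 <- conds1
  df$cond2 <- if (is.null(conds2)) vector("list", nrow(df)) else conds2
  df$mask1 <- vapply(conds1, cond_mask, 0)
  df$mask2 <- if (is.null(conds2)) 0 else vapply(conds2, cond_mask, 0)
  df$lo1 <- vapply(conds1, min, 0L); df$hi1 <- vapply(conds1, max, 0L)
  df$lo2 <- if (is.null(conds2)) 0L else vapply(conds2, min, 0L)
  df$hi2 <- if (is.null(conds2)) 0L else vapply(conds2, max, 0L)
  df$ord1 <- ord1; df$ord2 <- ord2
  df
}

# score all 1D candidates of one variable for every modality at once
score_1d <- function(ds, var, conds, min_modality_size, min_z) {
  k <- ds$meta[[var]]$n_levels
  ord <- ds$meta[[var]]$kind == "ordinal"
  v <- ds$values[, var]
  C <- cond_matrix(conds, k)
  ct <- tabulate(v, nbins = k)
  cov <- as.vector(C %*% ct)
  out <- list()
  for (mod in levels(ds$target)) {
    cm <- tabulate(v[ds$target == mod], nbins = k)
    msz <- as.vector(C %*% cm)
    p0 <- mean(ds$target == mod)
    z <- ifelse(cov > 0, (msz / cov - p0) / sqrt(p0 * (1 - p0) / cov), -Inf)
    keep <- which(msz >= min_modality_size & z >= min_z)
    if (length(keep) > 0L) {
      df <- data.frame(var1 = var, var2 = NA_character_, modality = mod,
                       coverage = cov[keep], modality_size = msz[keep],
                       z = z[keep], stringsAsFactors = FALSE)
      out[[mod]] <- annotate_conds(df, conds[keep], NULL, ord, TRUE)
    }
  }
  out
}

# score all 2D candidates of one variable pair for every modality
score_2d <- function(ds, var_a, var_b, conds_a, conds_b,
                     min_modality_size, min_z) {
  ka <- ds$meta[[var_a]]$n_levels; kb <- ds$meta[[var_b]]$n_levels
  va <- ds$values[, var_a]; vb <- ds$values[, var_b]
  ord_a <- ds$meta[[var_a]]$kind == "ordinal"
  ord_b <- ds$meta[[var_b]]$kind == "ordinal"
  Ca <- cond_matrix(conds_a, ka); Cb <- cond_matrix(conds_b, kb)
  cross <- (va - 1L) * kb + vb
  Tall <- matrix(tabulate(cross, ka * kb), ka, kb, byrow = TRUE)
  COV <- Ca %*% Tall %*% t(Cb)
  out <- list()
  na <- length(conds_a); nb <- length(conds_b)
  for (mod in levels(ds$target)) {
    inmod <- ds$target == mod
    Tmod <- matrix(tabulate(cross[inmod], ka * kb), ka, kb, byrow = TRUE)
    MOD <- Ca %*% Tmod %*% t(Cb)
    p0 <- mean(inmod)
    Z <- matrix(-Inf, na, nb)
    pos <- COV > 0
    Z[pos] <- (MOD[pos] / COV[pos] - p0) / sqrt(p0 * (1 - p0) / COV[pos])
    keep <- which(MOD >= min_modality_size & Z >= min_z, arr.ind = TRUE)
    if (nrow(keep) > 0L) {
      ia <- keep[, 1L]; ib <- keep[, 2L]
      df <- data.frame(var1 = var_a, var2 = var_b, modality = mod,
                       coverage = COV[keep], modality_size = MOD[keep],
                       z = Z[keep], stringsAsFactors = FALSE)
      out[[mod]] <- annotate_conds(df, conds_a[ia], conds_b[ib], ord_a, ord_b)
    }
  }
  out
}

empty_rules <- function() {
  df <- data.frame(var1 = character(), var2 = character(), modality = character(),
                   coverage = integer(), modality_size = integer(), z = numeric(),
                   stringsAsFactors = FALSE)
  df$cond1 <- list(); df$cond2 <- list(); df$mask1 <- numeric(); df$mask2 <- numeric()
  df$lo1 <- integer(); df$hi1 <- integer(); df$lo2 <- integer(); df$hi2 <- integer()
  df$ord1 <- logical(); df$ord2 <- logical()
  df
}

#' Select significant candidate rules
#'
#' Scores every candidate against both target modalities and keeps those
#' with modality size at least `min_modality_size` and z-score at least
#' `min_z` (both thresholds inclusive). Each kept rule is annotated with its
#' coverage, modality size and z.
#'
#' @param ds a `discretized_dataset`.
#' @param variables variable names to mine over (default all).
#' @param dims integer vector, subset of `c(1, 2)`.
#' @param min_modality_size support threshold (default 10).
#' @param min_z z-score threshold (default 1.96, the two-sided 5% normal
#'   quantile).
#' @param max_nominal_levels nominal subset guard.
#' @return a rule data.frame (one row per kept rule) with list columns
#'   `cond1`, `cond2`.
#' @export
select_significant <- function(ds, variables = NULL, dims = c(1L, 2L),
                               min_modality_size = 10, min_z = 1.96,
                               max_nominal_levels = 6L) {
  if (min_modality_size <= 0 || min_z <= 0) stop("thresholds must be positive")
  if (is.null(variables)) variables <- names(ds$meta)
  stopifnot(all(variables %in% names(ds$meta)))
  conds <- lapply(ds$meta[variables], enumerate_conditions_1d,
                  max_nominal_levels = max_nominal_levels)
  pieces <- list()
  if (1L %in% dims) {
    for (v in variables) {
      pieces <- c(pieces, score_1d(ds, v, conds[[v]], min_modality_size, min_z))
    }
  }
  if (2L %in% dims && length(variables) >= 2L) {
    for (i in seq_len(length(variables) - 1L)) {
      for (j in (i + 1L):length(variables)) {
        pieces <- c(pieces, score_2d(ds, variables[i], variables[j],
                                     conds[[i]], conds[[j]],
                                     min_modality_size, min_z))
      }
    }
  }
  if (length(pieces) == 0L) return(empty_rules())
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Remove dominated rules (minimization)
#'
#' Redundancy removal between rules sharing the same variable set and
#' modality, where one rule's conditions contain the other's: a rule is
#' deleted when it is included in a strictly larger rule with a z-score at
#' least as high, or when it strictly covers a smaller rule with a strictly
#' higher z-score. The asymmetric tie rule (larger rule wins at equal z)
#' prevents nested equal-z rules from eliminating each other. Rules on
#' different variable sets, or of different dimension, are never compared.
#'
#' @param rules a rule data.frame as returned by [select_significant()].
#' @return the subset of undominated rules (idempotent).
#' @export
minimize_rules <- function(rules) {
  if (nrow(rules) == 0L) return(rules)
  grp <- paste(rules$modality, rules$var1, rules$var2, sep = "\r")
  keep <- logical(nrow(rules))
  # containment of condition i in condition j, [i, j]; ordinal conditions are
  # contiguous so two range comparisons suffice, nominal sets need bitmasks
  coord_sub <- function(ord, lo, hi, mask) {
    if (ord) {
      outer(lo, lo, ">=") & outer(hi, hi, "<=")
    } else {
      outer(mask, mask, function(a, b) bitwAnd(a, b) == a)
    }
  }
  for (g in split(seq_len(nrow(rules)), grp)) {
    z <- rules$z[g]
    ng <- length(g)
    if (ng == 1L) { keep[g] <- TRUE; next }
    sub <- coord_sub(rules$ord1[g[1L]], rules$lo1[g], rules$hi1[g], rules$mask1[g])
    if (!is.na(rules$var2[g[1L]])) {
      sub <- sub & coord_sub(rules$ord2[g[1L]], rules$lo2[g], rules$hi2[g], rules$mask2[g])
    }
    strict_sub <- sub & !(sub & t(sub))              # [i, j]: i strictly inside j
    z_row <- matrix(z, ng, ng)                       # z_i by row
    z_col <- matrix(z, ng, ng, byrow = TRUE)         # z_j by col
    dominated <- (strict_sub & (z_col >= z_row)) |        # larger j, z_j >= z_i
                 (t(strict_sub) & (z_col > z_row))        # smaller j, z_j > z_i
    keep[g] <- rowSums(dominated) == 0
  }
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine significant minimal rules
#'
#' The full mining pipeline for one dataset: exhaustive candidate
#' enumeration over the given variables, quality scoring against both target
#' modalities, threshold selection, and dominance minimization. Entirely
#' deterministic.
#'
#' @inheritParams select_significant
#' @return a `ruleset` object: list with `rules` (data.frame) and
#'   `provenance` (thresholds, variables, dims, dataset size).
#' @export
mine_rules <- function(ds, variables = NULL, dims = c(1L, 2L),
                       min_modality_size = 10, min_z = 1.96,
                       max_nominal_levels = 6L) {
  if (is.null(variables)) variables <- names(ds$meta)
  cand <- select_significant(ds, variables, dims, min_modality_size, min_z,
                             max_nominal_levels)
  rules <- minimize_rules(cand)
  structure(
    list(rules = rules,
         provenance = list(variables = variables, dims = sort(unique(as.integer(dims))),
                           min_modality_size = min_modality_size, min_z = min_z,
                           n_subjects = n_subjects(ds),
                           modalities = levels(ds$target),
                           n_candidates_kept = nrow(cand))),
    class = "ruleset"
  )
}

#' @export
print.ruleset <- function(x, ...) {
  cat("ruleset: ", nrow(x$rules), " rules (",
      paste(names(table(x$rules$modality)), table(x$rules$modality),
            sep = "=", collapse = ", "),
      "); thresholds: modality size >= ", x$provenance$min_modality_size,
      ", z >= ", x$provenance$min_z, "\n", sep = "")
  if (nrow(x$rules) > 0L) {
    for (i in seq_len(min(10L, nrow(x$rules)))) cat("  ", format_rule(x$rules[i, ]), "\n")
    if (nrow(x$rules) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' Render a rule in the conventional human-readable syntax
#'
#' e.g. `{variable: 'bucket 2.14'; condition: bins 1 to 4}` for an ordinal
#' range, a category list for nominal sets, joined with AND for 2D rules.
#'
#' @param rule a rule data.frame (one string is returned per row).
#' @param metas optional named list of [variable_meta()] to render nominal
#'   category labels instead of codes.
#' @return a character vector, one element per rule.
#' @export
format_rule <- function(rule, metas = NULL) {
  if (nrow(rule) != 1L) {
    return(vapply(seq_len(nrow(rule)),
                  function(i) format_rule(rule[i, ], metas), ""))
  }
  fmt1 <- function(var, cond) {
    m <- if (!is.null(metas) && var %in% names(metas)) metas[[var]] else NULL
    if (!is.null(m) && m$kind == "nominal") {
      cd <- paste0("{", paste(m$levels[cond], collapse = ", "), "}")
    } else if (length(cond) == 1L) {
      cd <- paste0("bin ", cond)
    } else {
      cd <- paste0("bins ", min(cond), " to ", max(cond))
    }
    paste0("variable: '", var, "'; condition: ", cd)
  }
  s <- fmt1(rule$var1, rule$cond1[[1L]])
  if (!is.na(rule$var2)) s <- paste0(s, " AND ", fmt1(rule$var2, rule$cond2[[1L]]))
  sprintf("{%s} -> %s (coverage %d, modality size %d, z %.2f)",
          s, rule$modality, rule$coverage, rule$modality_size, rule$z)
}

#' Canonical identifier of a rule (variables + exact conditions + modality)
#'
#' Used as the feature identity for Jaccard stability of local models.
#'
#' @param rules a rule data.frame.
#' @return character vector of identifiers.
#' @export
rule_ids <- function(rules) {
  if (nrow(rules) == 0L) return(character())
  vapply(seq_len(nrow(rules)), function(i) {
    s <- paste0(rules$var1[i], "[", paste(rules$cond1[[i]], collapse = ","), "]")
    if (!is.na(rules$var2[i])) {
      s <- paste0(s, "&", rules$var2[i], "[", paste(rules$cond2[[i]], collapse = ","), "]")
    }
    paste0(s, "->", rules$modality[i])
  }, "")
}

#' Write / read a ruleset as JSON lines
#'
#' One rule per line: variables, level-code conditions, modality, coverage,
#' modality size, z. The provenance is written as a leading header line with
#' a `"_provenance"` key.
#'
#' @param rs a `ruleset`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_ruleset <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(`_provenance` = rs$provenance), auto_unbox = TRUE), con)
  r <- rs$rules
  for (i in seq_len(nrow(r))) {
    rec <- list(var1 = r$var1[i], cond1 = r$cond1[[i]], modality = r$modality[i],
                coverage = r$coverage[i], modality_size = r$modality_size[i],
                z = r$z[i])
    if (!is.na(r$var2[i])) { rec$var2 <- r$var2[i]; rec$cond2 <- r$cond2[[i]] }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

# parse a serialized quality field: absent or "NA" means not recorded
# (e.g. planted ground-truth rules written before scoring)
read_num <- function(v, na) {
  if (is.null(v) || (length(v) == 1L && (is.na(v) || identical(v, "NA")))) return(na)
  if (is.integer(na)) as.integer(v) else as.numeric(v)
}

#' @rdname write_ruleset
#' @param path path to a JSONL ruleset file.
#' @export
read_ruleset <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty ruleset file")
  prov <- jsonlite::fromJSON(lines[1L])$`_provenance`
  rules <- empty_rules()
  if (length(lines) > 1L) {
    recs <- lapply(lines[-1L], jsonlite::fromJSON)
    rules <- data.frame(
      var1 = vapply(recs, `[[`, "", "var1"),
      var2 = vapply(recs, function(r) if (is.null(r$var2)) NA_character_ else r$var2, ""),
      modality = vapply(recs, `[[`, "", "modality"),
      coverage = vapply(recs, function(r) read_num(r$coverage, NA_integer_), 0L),
      modality_size = vapply(recs, function(r) read_num(r$modality_size, NA_integer_), 0L),
      z = vapply(recs, function(r) read_num(r$z, NA_real_), 0),
      stringsAsFactors = FALSE
    )
    rules$cond1 <- lapply(recs, function(r) as.integer(r$cond1))
    rules$cond2 <- lapply(recs, function(r) if (is.null(r$cond2)) NULL else as.integer(r$cond2))
    rules$mask1 <- vapply(rules$cond1, cond_mask, 0)
    rules$mask2 <- vapply(rules$cond2, function(cd) if (is.null(cd)) 0 else cond_mask(cd), 0)
    rules$lo1 <- vapply(rules$cond1, min, 0L); rules$hi1 <- vapply(rules$cond1, max, 0L)
    rules$lo2 <- vapply(rules$cond2, function(cd) if (is.null(cd)) 0L else min(cd), 0L)
    rules$hi2 <- vapply(rules$cond2, function(cd) if (is.null(cd)) 0L else max(cd), 0L)
    # kinds are not stored in the JSONL; bitmask containment is always valid
    rules$ord1 <- FALSE; rules$ord2 <- FALSE
  }
  structure(list(rules = rules, provenance = prov), class = "ruleset")
}
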