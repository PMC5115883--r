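#' Chi-squared variable screening with Bonferroni correction
#'
#' The global feature-selection step: for each variable, a chi-squared test
#' of independence between its occupied levels and the binary target;
#' variables with `p <= alpha / m` are kept, where `m` is the number of
#' tested (non-constant) variables. Constant variables are skipped, not
#' errors.
#'
#' @param ds a `discretized_dataset` (the training split).
#' @param alpha family-wise error level (default 0.05).
#' @param correction only `"bonferroni"` is implemented.
#' @return character vector of selected variable names (possibly empty), in
#'   declared variable order.
#' @export
chi2_select <- function(ds, alpha = 0.05, correction = "bonferroni") {
  if (!identical(correction, "bonferroni")) stop("only bonferroni correction is supported")
  y <- ds$target
  vals <- ds$values
  n <- nrow(vals); p <- ncol(vals); K <- max(vals)
  # level-by-class counts for every variable in one pass: linearize the
  # (level, variable) index and tabulate within each class
  off <- rep.int(K * (seq_len(p) - 1L), rep.int(n, p))
  lin <- as.vector(vals) + off
  in1 <- y == levels(y)[1L]
  c1 <- matrix(tabulate(lin[rep(in1, p)], K * p), K, p)
  c2 <- matrix(tabulate(lin[rep(!in1, p)], K * p), K, p)
  tot <- c1 + c2
  n1 <- sum(in1); n2 <- n - n1
  e1 <- tot * n1 / n; e2 <- tot * n2 / n
  term <- function(cc, ee) {
    t <- (cc - ee)^2 / ee
    t[ee == 0] <- 0   # unoccupied levels contribute nothing
    t
  }
  stat <- colSums(term(c1, e1) + term(c2, e2))
  occ <- colSums(tot > 0L)
  pvals <- ifelse(occ >= 2L,
                  stats::pchisq(stat, occ - 1L, lower.tail = FALSE),
                  NA_real_)
  m <- sum(!is.na(pvals))
  if (m == 0L) return(character())
  names(ds$meta)[!is.na(pvals) & pvals <= alpha / m]
}

#' Binary feature matrix of a set of rules
#'
#' Converts rules into the "local variables" the classifier consumes: one
#' 0/1 column per rule, entry 1 iff the subject satisfies all the rule's
#' conditions. Column order follows the rule table; column sums on the
#' mining data equal rule coverages.
#'
#' @param rules a rule data.frame (or a `ruleset`).
#' @param ds a `discretized_dataset`.
#' @return numeric matrix, subjects x rules, with rule identifiers as
#'   column names. Zero columns for an empty rule set.
#' @export
rules_to_features <- function(rules, ds) {
  if (inherits(rules, "ruleset")) rules <- rules$rules
  n <- n_subjects(ds)
  out <- matrix(0, n, nrow(rules))
  for (i in seq_len(nrow(rules))) {
    sel <- ds$values[, rules$var1[i]] %in% rules$cond1[[i]]
    if (!is.na(rules$var2[i])) sel <- sel & ds$values[, rules$var2[i]] %in% rules$cond2[[i]]
    out[sel, i] <- 1
  }
  colnames(out) <- rule_ids(rules)
  rownames(out) <- ds$subjects
  out
}

#' L2-penalized logistic regression
#'
#' Maximizes the L2-penalized binomial log-likelihood
#' \deqn{\min_{w,b} \; C \sum_i \log(1 + e^{-t_i (x_i^\top w + b)}) + \tfrac12 \|w\|^2}
#' with inverse regularization strength `C` (larger C = weaker penalty) and
#' an unpenalized intercept, by damped Newton iterations. Deterministic up
#' to the solver tolerance.
#'
#' @param x numeric feature matrix (subjects x features).
#' @param t vector of +1/-1 class labels (+1 = positive modality).
#' @param C inverse penalty strength, > 0.
#' @param tol convergence tolerance on the gradient max-norm (default 1e-8).
#' @param max_iter Newton iteration cap.
#' @return list with `intercept`, `weights`, `converged`, `objective`.
#' @export
fit_l2_logistic <- function(x, t, C, tol = 1e-8, max_iter = 200L) {
  if (C <= 0) stop("C must be positive")
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop("at least one feature is required")
  if (!all(t %in% c(-1, 1)) || length(unique(t)) < 2L) {
    stop("t must contain both +1 and -1 labels")
  }
  n <- nrow(x); p <- ncol(x)
  X <- cbind(1, x)
  pen <- c(0, rep(1, p))
  beta <- numeric(p + 1L)
  obj <- function(b) {
    s <- drop(X %*% b) * t
    C * sum(log1p(exp(-abs(s))) + pmax(-s, 0)) + 0.5 * sum(pen * b^2)
  }
  f <- obj(beta)
  for (it in seq_len(max_iter)) {
    s <- drop(X %*% beta)
    mu <- stats::plogis(s)                  # P(t = +1 | x)
    y01 <- (t + 1) / 2
    g <- C * drop(crossprod(X, mu - y01)) + pen * beta
    if (max(abs(g)) < tol) break
    wgt <- pmax(mu * (1 - mu), 1e-10)
    H <- C * crossprod(X, X * wgt) + diag(pen, p + 1L)
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8, p + 1L), g)
    })
    # backtracking line search keeps the damped Newton step monotone
    alpha <- 1
    repeat {
      cand <- beta - alpha * step
      fc <- obj(cand)
      if (fc <= f + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    beta <- cand
    f <- fc
  }
  list(intercept = beta[1L], weights = beta[-1L],
       converged = max(abs(g)) < tol, objective = f, n_iter = it)
}

# encode the raw variables of a global model: ordinal level codes as single
# numeric columns, nominal variables one-hot
encode_global <- function(ds, vars) {
  cols <- list()
  for (v in vars) {
    m <- ds$meta[[v]]
    if (m$kind == "ordinal") {
      cols[[v]] <- matrix(as.numeric(ds$values[, v]), ncol = 1L,
                          dimnames = list(NULL, v))
    } else {
      oh <- matrix(0, n_subjects(ds), m$n_levels,
                   dimnames = list(NULL, paste0(v, "=", m$levels)))
      oh[cbind(seq_len(n_subjects(ds)), ds$values[, v])] <- 1
      cols[[v]] <- oh
    }
  }
  do.call(cbind, cols)
}

#' Build a predictive model on a training dataset
#'
#' The three model types of the analysis:
#' \itemize{
#'   \item `global`: chi-squared/Bonferroni variable screening, then an
#'     L2-logistic fit on the raw selected variables (ordinal level codes as
#'     numeric columns, nominal one-hot).
#'   \item `local_1d`: the same screening, 1D rule mining restricted to the
#'     screened variables, then an L2-logistic fit on the binary rule
#'     features.
#'   \item `local_1and2d`: as `local_1d` with 2D rules added.
#' }
#' If screening (or mining) leaves no features, the model degrades to an
#' intercept-only majority-class predictor, with a warning.
#'
#' @param train a `discretized_dataset`.
#' @param model_type `"global"`, `"local_1d"` or `"local_1and2d"`.
#' @param C inverse regularization strength of the logistic fit.
#' @param alpha,min_modality_size,min_z screening and mining thresholds.
#' @param variables optional explicit variable list overriding the
#'   chi-squared screen (for mining experiments on known variables).
#' @return an `nmr_model` object with the selected features, weights,
#'   complexity (= number of features) and provenance.
#' @export
build_model <- function(train, model_type = c("global", "local_1d", "local_1and2d"),
                        C = 1, alpha = 0.05, min_modality_size = 10,
                        min_z = 1.96, variables = NULL) {
  model_type <- match.arg(model_type)
  sel <- select_model_features(train, model_type, alpha, min_modality_size,
                               min_z, variables)
  fit_from_selection(train, sel, C)
}

# the C-independent half of model building: variable screening, rule mining
# and feature construction. Shared across a regularization grid.
select_model_features <- function(train, model_type, alpha = 0.05,
                                  min_modality_size = 10, min_z = 1.96,
                                  variables = NULL) {
  selected_by <- if (is.null(variables)) "chi2" else "given"
  if (is.null(variables)) variables <- chi2_select(train, alpha)

  rules <- NULL
  if (length(variables) == 0L) {
    feats <- NULL
  } else if (model_type == "global") {
    feats <- encode_global(train, variables)
  } else {
    dims <- if (model_type == "local_1d") 1L else c(1L, 2L)
    rs <- mine_rules(train, variables, dims, min_modality_size, min_z)
    rules <- rs$rules
    feats <- if (nrow(rules) > 0L) rules_to_features(rules, train) else NULL
  }
  list(model_type = model_type, variables = variables, selected_by = selected_by,
       rules = rules, feats = feats)
}

fit_from_selection <- function(train, sel, C) {
  model_type <- sel$model_type
  variables <- sel$variables
  rules <- sel$rules
  feats <- sel$feats
  selected_by <- sel$selected_by
  positive <- levels(train$target)[1L]
  t <- ifelse(train$target == positive, 1, -1)

  sel_vars <- variables
  if (is.null(feats) || ncol(feats) == 0L) {
    warning("no features selected for ", model_type,
            " model; falling back to an intercept-only majority-class model")
    maj <- names(which.max(table(train$target)))
    fit <- list(intercept = if (maj == positive) 1 else -1, weights = numeric(0))
    feats <- matrix(0, n_subjects(train), 0L)
    sel_vars <- character()
    rules <- if (model_type == "global") NULL else empty_rules()
  } else {
    fit <- fit_l2_logistic(feats, t, C)
  }

  structure(
    list(model_type = model_type,
         positive = positive,
         modalities = levels(train$target),
         selected_variables = sel_vars,
         selected_by = selected_by,
         rules = rules,
         feature_names = colnames(feats),
         C = C,
         intercept = fit$intercept,
         weights = fit$weights,
         complexity = ncol(feats)),
    class = "nmr_model"
  )
}

#' @export
print.nmr_model <- function(x, ...) {
  cat("nmr_model (", x$model_type, "): complexity ", x$complexity,
      ", C = ", x$C, "\n", sep = "")
  cat("  positive modality:", x$positive, "\n")
  if (!is.null(x$rules)) cat("  rules:", nrow(x$rules), "\n")
  invisible(x)
}

# feature matrix of a fitted model on (possibly new) data
model_features <- function(model, ds) {
  if (model$complexity == 0L) return(matrix(0, n_subjects(ds), 0L))
  if (model$model_type == "global") {
    encode_global(ds, model$selected_variables)
  } else {
    rules_to_features(model$rules, ds)
  }
}

#' Predict modalities with a fitted model
#'
#' Rule features are recomputed on the new subjects from the stored
#' conditions; the predicted class is the positive modality when the
#' predicted probability is at least 0.5 (linear score at least 0).
#'
#' @param object an `nmr_model`.
#' @param ds a `discretized_dataset` with the model's variables.
#' @param type `"modality"` (default) or `"prob"`.
#' @param ... unused.
#' @export
predict.nmr_model <- function(object, ds, type = c("modality", "prob"), ...) {
  type <- match.arg(type)
  feats <- model_features(object, ds)
  score <- object$intercept + if (ncol(feats) > 0L) drop(feats %*% object$weights) else 0
  prob <- stats::plogis(score)
  if (type == "prob") return(prob)
  other <- setdiff(object$modalities, object$positive)
  factor(ifelse(prob >= 0.5, object$positive, other), levels = object$modalities)
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model an `nmr_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path) {
  obj <- unclass(model)
  if (!is.null(obj$rules)) {
    r <- obj$rules
    obj$rules <- lapply(seq_len(nrow(r)), function(i) {
      rec <- list(var1 = r$var1[i], cond1 = r$cond1[[i]], modality = r$modality[i],
                  coverage = r$coverage[i], modality_size = r$modality_size[i], z = r$z[i])
      if (!is.na(r$var2[i])) { rec$var2 <- r$var2[i]; rec$cond2 <- r$cond2[[i]] }
      rec
    })
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
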