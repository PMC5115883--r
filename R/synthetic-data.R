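#' Specification of a synthetic discretized cohort
#'
#' Describes a synthetic dataset with the statistical structure the mining
#' method assumes: a fixed class imbalance, independent uniform noise
#' buckets, planted 1D marginal shifts (one class enriched in a bin range,
#' the other class mirrored into the complement), and planted 2D
#' interactions. A marginally balanced 2D plant places one class in the
#' agreeing corners (low-low / high-high) and the other in the disagreeing
#' corners, so each variable's margin stays uniform in both classes and the
#' signal is invisible to 1D mining -- the property that makes the added
#' value of 2D rules testable. An unbalanced plant enriches a single corner
#' per class, which also shifts the margins.
#'
#' Defaults mirror the CKD cohort dimensions: 110 subjects, 184 ordinal
#' bucket variables in 10 bins, 86 below60 vs 24 at_least_60.
#'
#' @param n_subjects,n_buckets,n_bins cohort dimensions.
#' @param class_sizes named or ordered pair `(below60, at_least_60)`.
#' @param planted_1d list of `list(var, range, prob)`: bucket index,
#'   enriched bin range for the first modality, enrichment probability.
#' @param planted_2d list of `list(vars, prob, balanced)`: a pair of bucket
#'   indices, the corner-enrichment probability, and the marginal-balance
#'   flag. Plants must not share variables with each other or with 1D
#'   plants.
#' @param n_clinical number of extra clinical variables (0, 1 or 2): an
#'   age-like ordinal enriched in its upper bins for the first modality,
#'   then a binary nominal.
#' @param clinical_assoc enrichment probability of the clinical plants
#'   (0.5 = no association).
#' @param modalities modality names, first = below60-like (larger class by
#'   default).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 110L, n_buckets = 184L, n_bins = 10L,
                           class_sizes = c(86L, 24L),
                           planted_1d = list(), planted_2d = list(),
                           n_clinical = 0L, clinical_assoc = 0.6,
                           modalities = c("below60", "at_least_60")) {
  if (sum(class_sizes) != n_subjects) stop("class sizes must sum to n_subjects")
  used <- integer()
  for (p in planted_1d) {
    stopifnot(p$var >= 1L, p$var <= n_buckets, p$prob > 0, p$prob < 1,
              all(p$range >= 1L), all(p$range <= n_bins),
              length(p$range) < n_bins)
    used <- c(used, p$var)
  }
  for (p in planted_2d) {
    stopifnot(length(p$vars) == 2L, all(p$vars >= 1L), all(p$vars <= n_buckets),
              p$prob > 0, p$prob < 1)
    used <- c(used, p$vars)
  }
  if (anyDuplicated(used)) {
    stop("planted variables overlap; marginal-balance constraints are infeasible")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_buckets = as.integer(n_buckets), n_bins = as.integer(n_bins),
                 class_sizes = as.integer(class_sizes),
                 planted_1d = planted_1d, planted_2d = planted_2d,
                 n_clinical = as.integer(n_clinical),
                 clinical_assoc = clinical_assoc,
                 modalities = modalities),
            class = "synthetic_spec")
}

# uniform draw over a set of bins
rbin <- function(n, bins) if (length(bins) == 1L) rep(bins, n) else sample(bins, n, replace = TRUE)

#' Generate a synthetic discretized dataset with known ground truth
#'
#' Noise buckets are uniform over the bins independently of class; planted
#' variables follow the enrichment scheme of [synthetic_spec()]. The ground
#' truth lists the planted rules in rule-table form for recovery scoring.
#'
#' @param spec a [synthetic_spec()].
#' @param seed reproducibility seed.
#' @return list with `dataset` (a [discretized_dataset()]) and
#'   `ground_truth` (planted rule table, planted variable names, pairs).
#' @export
generate_dataset <- function(spec, seed = 1L) {
  with_seed(seed, {
    k <- spec$n_bins
    n <- spec$n_subjects
    mods <- spec$modalities
    target <- sample(rep(mods, spec$class_sizes))
    in1 <- target == mods[1L]

    vals <- matrix(0L, n, spec$n_buckets)
    for (j in seq_len(spec$n_buckets)) vals[, j] <- rbin(n, 1:k)

    low <- 1:(k %/% 2L); high <- (k %/% 2L + 1L):k

    gt_rows <- list()
    for (p in spec$planted_1d) {
      rng <- as.integer(p$range)
      comp <- setdiff(1:k, rng)
      draw <- function(idx, enriched_in) {
        m <- length(idx)
        inr <- stats::runif(m) < p$prob
        out <- integer(m)
        out[inr] <- rbin(sum(inr), if (enriched_in) rng else comp)
        out[!inr] <- rbin(sum(!inr), if (enriched_in) comp else rng)
        out
      }
      vals[in1, p$var] <- draw(which(in1), TRUE)
      vals[!in1, p$var] <- draw(which(!in1), FALSE)
      gt_rows[[length(gt_rows) + 1L]] <-
        list(var1 = bucket_var_name(p$var), cond1 = rng, var2 = NA_character_,
             cond2 = NULL, modality = mods[1L])
      gt_rows[[length(gt_rows) + 1L]] <-
        list(var1 = bucket_var_name(p$var), cond1 = comp, var2 = NA_character_,
             cond2 = NULL, modality = mods[2L])
    }

    for (p in spec$planted_2d) {
      va <- p$vars[1L]; vb <- p$vars[2L]
      corners_agree <- list(list(low, low), list(high, high))
      corners_disagree <- list(list(low, high), list(high, low))
      fill <- function(idx, corners) {
        for (i in idx) {
          if (stats::runif(1) < p$prob) {
            cr <- corners[[sample.int(length(corners), 1L)]]
            vals[i, va] <<- rbin(1L, cr[[1L]])
            vals[i, vb] <<- rbin(1L, cr[[2L]])
          } else {
            vals[i, va] <<- rbin(1L, 1:k)
            vals[i, vb] <<- rbin(1L, 1:k)
          }
        }
      }
      if (isTRUE(p$balanced)) {
        fill(which(in1), corners_agree)
        fill(which(!in1), corners_disagree)
      } else {
        fill(which(in1), list(list(low, low)))
        fill(which(!in1), list(list(high, high)))
      }
      gt_rows[[length(gt_rows) + 1L]] <-
        list(var1 = bucket_var_name(va), cond1 = low,
             var2 = bucket_var_name(vb), cond2 = low, modality = mods[1L])
      gt_rows[[length(gt_rows) + 1L]] <-
        list(var1 = bucket_var_name(va), cond1 = high,
             var2 = bucket_var_name(vb), cond2 = high,
             modality = if (isTRUE(p$balanced)) mods[1L] else mods[2L])
    }

    meta <- lapply(seq_len(spec$n_buckets), function(j) {
      variable_meta(bucket_var_name(j), "ordinal", as.character(1:k), "bucket")
    })

    if (spec$n_clinical >= 1L) {
      # age-like ordinal, upper bins enriched in the first modality
      upper <- high
      age <- integer(n)
      inup <- stats::runif(n) < spec$clinical_assoc
      age[in1 & inup] <- rbin(sum(in1 & inup), upper)
      age[in1 & !inup] <- rbin(sum(in1 & !inup), low)
      age[!in1 & inup] <- rbin(sum(!in1 & inup), low)
      age[!in1 & !inup] <- rbin(sum(!in1 & !inup), upper)
      vals <- cbind(vals, age)
      meta[[length(meta) + 1L]] <- variable_meta("Age", "ordinal",
                                                 as.character(1:k), "clinical")
    }
    if (spec$n_clinical >= 2L) {
      sex <- ifelse(stats::runif(n) < ifelse(in1, spec$clinical_assoc,
                                             1 - spec$clinical_assoc), 1L, 2L)
      vals <- cbind(vals, sex)
      meta[[length(meta) + 1L]] <- variable_meta("Sex", "nominal",
                                                 c("M", "F"), "demographic")
    }

    ds <- discretized_dataset(vals, meta, target, modalities = mods)

    gt <- if (length(gt_rows) == 0L) empty_rules() else {
      df <- data.frame(
        var1 = vapply(gt_rows, `[[`, "", "var1"),
        var2 = vapply(gt_rows, function(r) r$var2, ""),
        modality = vapply(gt_rows, `[[`, "", "modality"),
        coverage = NA_integer_, modality_size = NA_integer_, z = NA_real_,
        stringsAsFactors = FALSE)
      df$cond1 <- lapply(gt_rows, `[[`, "cond1")
      df$cond2 <- lapply(gt_rows, `[[`, "cond2")
      df$mask1 <- vapply(df$cond1, cond_mask, 0)
      df$mask2 <- vapply(df$cond2, function(cd) if (is.null(cd)) 0 else cond_mask(cd), 0)
      df
    }

    list(dataset = ds,
         ground_truth = list(
           rules = gt,
           planted_variables = vapply(spec$planted_1d, function(p) bucket_var_name(p$var), ""),
           planted_pairs = lapply(spec$planted_2d, function(p) bucket_var_name(p$vars))))
  })
}

bucket_var_name <- function(j) sprintf("bucket %.2f", 0.16 + 0.04 * (j - 1L))

#' Generate synthetic bucketed NMR spectra
#'
#' Smooth spectra as sums of Lorentzian peaks at known ppm positions with
#' class-dependent amplitudes plus multiplicative subject-level dilution and
#' additive baseline noise, for end-to-end exercise of the preprocessing
#' chain. Not a physical model of chemical shifts or J-coupling.
#'
#' @param n_subjects,class_sizes,modalities cohort layout (as in
#'   [synthetic_spec()]).
#' @param peaks list of `list(ppm, amp, ratio, gamma)`: peak position, base
#'   amplitude (first modality), amplitude ratio first/second modality, and
#'   half-width at half maximum in ppm (default 0.01). The default panel
#'   mimics a CKD-like urinary profile: several metabolite peaks depleted in
#'   the renal-failure class (ratio < 1), one elevated (ratio > 1), and
#'   non-differential background peaks.
#' @param ppm_step sampling step of the synthetic axis (default 0.005 ppm
#'   over 0 to 9.5 ppm).
#' @param noise_sd additive baseline noise standard deviation.
#' @param seed reproducibility seed.
#' @return list with `ppm` (axis), `signal` (subjects x points matrix,
#'   non-negative) and `target`.
#' @export
generate_spectra <- function(n_subjects = 110L, class_sizes = c(86L, 24L),
                             modalities = c("below60", "at_least_60"),
                             peaks = list(
                               list(ppm = 1.30, amp = 8, ratio = 0.5),
                               list(ppm = 2.50, amp = 6, ratio = 0.5),
                               list(ppm = 3.17, amp = 10, ratio = 0.4),
                               list(ppm = 3.57, amp = 7, ratio = 2.0),
                               list(ppm = 3.97, amp = 6, ratio = 0.5),
                               list(ppm = 7.20, amp = 4, ratio = 1.0)),
                             ppm_step = 0.005, noise_sd = 0.02, seed = 1L) {
  stopifnot(sum(class_sizes) == n_subjects)
  with_seed(seed, {
    ppm <- seq(0, 9.5, by = ppm_step)
    target <- factor(sample(rep(modalities, class_sizes)), levels = modalities)
    sig <- matrix(0, n_subjects, length(ppm))
    dilution <- exp(stats::rnorm(n_subjects, 0, 0.2))
    for (i in seq_len(n_subjects)) {
      s <- numeric(length(ppm))
      for (pk in peaks) {
        gamma <- pk$gamma %||% 0.01
        amp <- pk$amp * if (target[i] == modalities[1L]) 1 else 1 / pk$ratio
        amp <- amp * exp(stats::rnorm(1, 0, 0.1))
        s <- s + amp * gamma^2 / ((ppm - pk$ppm)^2 + gamma^2)
      }
      sig[i, ] <- pmax(dilution[i] * s + stats::rnorm(length(ppm), 0, noise_sd), 0)
    }
    rownames(sig) <- paste0("S", seq_len(n_subjects))
    list(ppm = ppm, signal = sig, target = target)
  })
}
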