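#' Variable metadata for a discretized dataset
#'
#' Describes one discretized explanatory variable: an ordinal variable (for
#' example a quantile-binned NMR bucket, with levels coded 1..k and a total
#' order) or a nominal variable (unordered categories such as sex or
#' ethnicity).
#'
#' @param name variable identifier (unique within a dataset).
#' @param kind `"ordinal"` or `"nominal"`.
#' @param levels ordered character vector of level labels; for ordinal
#'   variables these are the bin labels in increasing order (codes 1..k map
#'   onto them positionally), for nominal variables the category names.
#' @param origin data source tag, one of `"bucket"`, `"clinical"`,
#'   `"chemistry"`, `"pathology"`, `"demographic"`.
#' @return a `variable_meta` object (a named list).
#' @export
variable_meta <- function(name, kind = c("ordinal", "nominal"),
                          levels,
                          origin = c("bucket", "clinical", "chemistry",
                                     "pathology", "demographic")) {
  kind <- match.arg(kind)
  origin <- match.arg(origin)
  levels <- as.character(levels)
  if (length(levels) < 1L || anyDuplicated(levels)) {
    stop("variable '", name, "': levels must be a non-empty set of unique labels")
  }
  structure(
    list(name = as.character(name), kind = kind,
         n_levels = length(levels), levels = levels, origin = origin),
    class = "variable_meta"
  )
}

#' Discretized multi-source dataset
#'
#' The universe rules are mined over: a subjects-by-variables table of level
#' codes plus a binary target modality (in the CKD application, eGFR below
#' versus at least 60 ml/min/1.73m2).
#'
#' @param values integer matrix (subjects x variables) of level codes, each
#'   code in `1..n_levels` of its variable. Column names must match the
#'   metadata.
#' @param meta list of [variable_meta()] objects, one per column of `values`.
#' @param target factor (or coercible vector) of length `nrow(values)` with
#'   exactly two non-empty modalities.
#' @param subjects subject identifiers; defaults to rownames of `values` or
#'   `S1..Sn`.
#' @param modalities canonical modality order; the first modality is the one
#'   z-scores and models treat as the "positive" class by default.
#' @return a `discretized_dataset` object.
#' @export
discretized_dataset <- function(values, meta, target, subjects = NULL,
                                modalities = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(subjects)) {
    subjects <- rownames(values)
    if (is.null(subjects)) subjects <- paste0("S", seq_len(nrow(values)))
  }
  subjects <- as.character(subjects)
  if (inherits(meta, "variable_meta")) meta <- list(meta)
  names(meta) <- vapply(meta, `[[`, "", "name")
  if (anyDuplicated(names(meta))) {
    stop("duplicated variable names: ",
         paste(unique(names(meta)[duplicated(names(meta))]), collapse = ", "))
  }
  if (ncol(values) != length(meta)) {
    stop("values has ", ncol(values), " columns but metadata describes ",
         length(meta), " variables")
  }
  colnames(values) <- names(meta)
  rownames(values) <- subjects

  if (is.null(modalities)) {
    modalities <- if (is.factor(target)) levels(target) else sort(unique(as.character(target)))
  }
  if (length(modalities) != 2L) stop("target must have exactly 2 modalities")
  target <- factor(as.character(target), levels = modalities)
  if (anyNA(target)) stop("missing or unknown target modality for subjects: ",
                          paste(subjects[is.na(target)], collapse = ", "))
  if (any(table(target) == 0L)) stop("both target modalities must be non-empty")
  if (length(target) != nrow(values)) stop("target length does not match subject count")

  ds <- structure(
    list(subjects = subjects, meta = meta, values = values, target = target),
    class = "discretized_dataset"
  )
  validate_dataset(ds)
  ds
}

#' @export
print.discretized_dataset <- function(x, ...) {
  tt <- table(x$target)
  cat("discretized_dataset: ", length(x$subjects), " subjects x ",
      length(x$meta), " variables\n", sep = "")
  cat("  target: ", paste(names(tt), tt, sep = "=", collapse = " vs "), "\n", sep = "")
  kinds <- table(vapply(x$meta, `[[`, "", "kind"))
  cat("  variables:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# every code must be a valid level of its variable; NA codes are not allowed
# (imputation happens upstream, on the numeric table)
validate_dataset <- function(ds) {
  for (j in seq_along(ds$meta)) {
    m <- ds$meta[[j]]
    v <- ds$values[, j]
    bad <- which(is.na(v) | v < 1L | v > m$n_levels)
    if (length(bad) > 0L) {
      stop("invalid level code for variable '", m$name, "', subject '",
           ds$subjects[bad[1L]], "': ", ds$values[bad[1L], j],
           " (valid codes 1..", m$n_levels, ")")
    }
  }
  invisible(ds)
}

#' Number of subjects / variables
#' @param ds a `discretized_dataset`.
#' @export
n_subjects <- function(ds) length(ds$subjects)

#' @rdname n_subjects
#' @export
n_variables <- function(ds) length(ds$meta)

#' Subset a discretized dataset by subject index
#'
#' @param ds a `discretized_dataset`.
#' @param idx integer or logical subject index.
#' @return a `discretized_dataset` over the selected subjects.
#' @export
subset_subjects <- function(ds, idx) {
  structure(
    list(subjects = ds$subjects[idx], meta = ds$meta,
         values = ds$values[idx, , drop = FALSE],
         target = factor(ds$target[idx], levels = levels(ds$target))),
    class = "discretized_dataset"
  )
}

#' Read a discretized dataset from CSV
#'
#' Two layouts are supported. `"wide_csv"` is a single wide table: one row
#' per subject, a `subject` identifier column, one column per variable
#' holding level labels, and one target column; variable kinds come from a
#' metadata sidecar CSV. `"s1_csv"` mirrors a two-sheet spreadsheet deposit
#' (sheet 1 data, sheet 2 metadata) exported sheet-by-sheet to CSV, and is
#' parsed identically.
#'
#' The metadata table needs columns `name`, `kind`, `origin` and `levels`
#' (level labels joined with `|`, in order).
#'
#' @param data_path path to the data CSV.
#' @param meta_path path to the metadata CSV.
#' @param layout `"wide_csv"` or `"s1_csv"` (same parser; kept distinct so
#'   provenance of spreadsheet exports is explicit).
#' @param target_col name of the target column in the data table.
#' @param modalities canonical modality order for the target factor.
#' @return a validated [discretized_dataset()].
#' @export
read_dataset <- function(data_path, meta_path,
                         layout = c("wide_csv", "s1_csv"),
                         target_col = "target",
                         modalities = c("below60", "at_least_60")) {
  layout <- match.arg(layout)
  if (!file.exists(data_path)) stop("data file not found: ", data_path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  dat <- utils::read.csv(data_path, check.names = FALSE, colClasses = "character")
  md <- utils::read.csv(meta_path, check.names = FALSE, colClasses = "character")
  if (!target_col %in% names(dat)) stop("missing target column '", target_col, "'")
  needed <- c("name", "kind", "origin", "levels")
  if (!all(needed %in% names(md))) {
    stop("metadata must have columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(md$name)) {
    stop("duplicated variable names in metadata: ",
         paste(unique(md$name[duplicated(md$name)]), collapse = ", "))
  }
  subjects <- if ("subject" %in% names(dat)) dat$subject else paste0("S", seq_len(nrow(dat)))
  missing_vars <- setdiff(md$name, names(dat))
  if (length(missing_vars) > 0L) {
    stop("variables in metadata but not in data: ", paste(missing_vars, collapse = ", "))
  }
  meta <- lapply(seq_len(nrow(md)), function(i) {
    variable_meta(md$name[i], md$kind[i],
                  strsplit(md$levels[i], "|", fixed = TRUE)[[1L]],
                  md$origin[i])
  })
  values <- matrix(NA_integer_, nrow = nrow(dat), ncol = length(meta))
  for (j in seq_along(meta)) {
    m <- meta[[j]]
    lab <- dat[[m$name]]
    code <- match(lab, m$levels)
    if (anyNA(code)) {
      bad <- which(is.na(code))[1L]
      stop("unknown level '", lab[bad], "' for variable '", m$name,
           "', subject '", subjects[bad], "'")
    }
    values[, j] <- code
  }
  discretized_dataset(values, meta, dat[[target_col]], subjects, modalities)
}

#' Write a discretized dataset to CSV (wide layout + metadata sidecar)
#'
#' @param ds a `discretized_dataset`.
#' @param data_path,meta_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_dataset <- function(ds, data_path, meta_path) {
  lab <- as.data.frame(
    lapply(seq_along(ds$meta), function(j) ds$meta[[j]]$levels[ds$values[, j]]),
    col.names = names(ds$meta), check.names = FALSE, optional = TRUE
  )
  names(lab) <- names(ds$meta)
  out <- cbind(data.frame(subject = ds$subjects, check.names = FALSE),
               lab,
               data.frame(target = as.character(ds$target)))
  utils::write.csv(out, data_path, row.names = FALSE, quote = TRUE)
  md <- data.frame(
    name = vapply(ds$meta, `[[`, "", "name"),
    kind = vapply(ds$meta, `[[`, "", "kind"),
    n_levels = vapply(ds$meta, `[[`, 0L, "n_levels"),
    origin = vapply(ds$meta, `[[`, "", "origin"),
    levels = vapply(ds$meta, function(m) paste(m$levels, collapse = "|"), ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(md, meta_path, row.names = FALSE, quote = TRUE)
  invisible(c(data_path, meta_path))
}

#' Median imputation of a numeric table
#'
#' Replaces each missing entry by the per-variable median of the observed
#' values (midpoint of the two central order statistics for even counts, the
#' standard sample median). Imputation is applied to the numeric table before
#' discretization.
#'
#' @param x numeric matrix or data.frame, subjects x variables, possibly with
#'   `NA` entries.
#' @return the same table with every `NA` replaced; observed entries
#'   unchanged.
#' @export
impute_median <- function(x) {
  was_df <- is.data.frame(x)
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("impute_median expects a numeric table")
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (all(miss)) {
      nm <- colnames(m)[j]
      stop("variable ", if (is.null(nm)) j else paste0("'", nm, "'"),
           " has no observed values; cannot impute")
    }
    if (any(miss)) m[miss, j] <- stats::median(m[!miss, j])
  }
  if (was_df) as.data.frame(m) else m
}
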