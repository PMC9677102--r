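#' Construct a weight panel from a data.frame
#'
#' A `weight_panel` is the package's longitudinal container: one row per
#' child per examination, sorted by child and examination age, with the
#' analysis time scale `t` defined as years since each child's first
#' measurement (so `t = 0` at entry). Columns `child_id`, `sex`, `area`,
#' `exam_age`, `height`, `weight` are required; `bmi` is derived, and
#' `state`, `ahi`, `awi` are attached by [classify_status()] /
#' [compute_increments()] downstream.
#'
#' @param x data.frame with the required columns (ages in decimal years,
#'   height cm, weight kg).
#' @param complete_case Drop children that do not have the full number of
#'   examination waves (the maximum observed per child). Mirrors a
#'   complete-data design; default `TRUE`.
#' @param min_records Children with fewer records are dropped (transition
#'   analysis needs at least two observations). Default 2.
#' @return A `weight_panel` (data.frame subclass) with derived columns
#'   `t`, `bmi`, `initial_bmi`, and attributes `n_children` and `dropped`
#'   (a report of removed rows/children).
#' @export
weight_panel <- function(x, complete_case = TRUE, min_records = 2L) {
  req <- c("child_id", "sex", "area", "exam_age", "height", "weight")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols))
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x)
  x$child_id <- as.character(x$child_id)
  dropped <- list()

  ok <- is.finite(x$exam_age) & is.finite(x$height) & is.finite(x$weight) &
    x$height > 0 & x$weight > 0 &
    x$exam_age >= 3 & x$exam_age <= 20
  if (any(!ok)) {
    dropped$invalid_rows <- x[!ok, , drop = FALSE]
    x <- x[ok, , drop = FALSE]
  }
  if (!nrow(x)) stop("no valid records remain")

  x <- x[order(x$child_id, x$exam_age), ]
  dup <- stats::ave(x$exam_age, x$child_id,
                    FUN = function(a) duplicated(a)) > 0
  if (any(dup)) {
    bad <- unique(x$child_id[dup])
    stop("duplicate exam_age within child(ren): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }

  n_rec <- table(x$child_id)
  if (complete_case) {
    full <- max(n_rec)
    incomplete <- names(n_rec)[n_rec < full]
    if (length(incomplete)) {
      dropped$incomplete_children <- incomplete
      x <- x[!x$child_id %in% incomplete, , drop = FALSE]
    }
  } else {
    short <- names(n_rec)[n_rec < min_records]
    if (length(short)) {
      dropped$short_children <- short
      x <- x[!x$child_id %in% short, , drop = FALSE]
    }
  }
  if (!nrow(x)) stop("no children remain after filtering")

  x$t <- stats::ave(x$exam_age, x$child_id, FUN = function(a) a - a[1L])
  x$bmi <- compute_bmi(x$weight, x$height)
  x$initial_bmi <- stats::ave(x$bmi, x$child_id, FUN = function(b) b[1L])
  rownames(x) <- NULL
  structure(x, class = c("weight_panel", "data.frame"),
            n_children = length(unique(x$child_id)),
            dropped = dropped)
}

#' @export
print.weight_panel <- function(x, ...) {
  cat(sprintf("weight_panel: %d records, %d children\n",
              nrow(x), attr(x, "n_children")))
  d <- attr(x, "dropped")
  if (length(d)) {
    if (!is.null(d$invalid_rows))
      cat("  dropped", nrow(d$invalid_rows), "invalid row(s)\n")
    if (!is.null(d$incomplete_children))
      cat("  excluded", length(d$incomplete_children),
          "child(ren) with missing waves\n")
  }
  cat(sprintf("  columns: %s\n", paste(names(x), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  invisible(x)
}

#' Load a longitudinal panel from delimited text
#'
#' Reads a CSV/TSV with one row per child per examination and builds a
#' validated [weight_panel()]. Column names are mapped through `schema`
#' (a named list or a YAML file path: names are the canonical fields
#' `child_id, sex, area, exam_age, height, weight` or
#' `exam_date, birth_date`; values are the file's column names). When exam
#' and birth dates (ISO-8601) are supplied instead of a decimal age, age is
#' computed as the day difference divided by 365.25.
#'
#' @param path Delimited text file with a header.
#' @param schema Named list or YAML path mapping canonical fields to file
#'   columns; `NULL` if the file already uses canonical names.
#' @param sep Field separator; `","` default, `"\t"` for TSV.
#' @param complete_case Passed to [weight_panel()].
#' @return A [weight_panel()].
#' @export
load_panel <- function(path, schema = NULL, sep = ",", complete_case = TRUE) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (is.character(schema) && length(schema) == 1L)
    schema <- yaml::read_yaml(schema)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw))
        stop("schema maps '", canon, "' to missing column '", src, "'")
      names(raw)[names(raw) == src] <- canon
    }
  }
  if (!"exam_age" %in% names(raw)) {
    if (!all(c("exam_date", "birth_date") %in% names(raw)))
      stop("need either 'exam_age' or both 'exam_date' and 'birth_date'")
    raw$exam_age <- as.numeric(as.Date(raw$exam_date) - as.Date(raw$birth_date)) / 365.25
  }
  weight_panel(raw, complete_case = complete_case)
}

#' Attach annualized height and weight increments
#'
#' The annual height increment (AHI, cm/year) and annual weight increment
#' (AWI, kg/year) over each examination interval are the forward
#' differences divided by the elapsed time, attached to the interval's
#' starting record; the last record of each child has no following interval
#' and gets `NA`. Annualizing by the actual interval length keeps unequal
#' spacing meaningful.
#'
#' @param ds A [weight_panel()].
#' @return `ds` with columns `ahi` and `awi` added.
#' @export
compute_increments <- function(ds) {
  stopifnot(inherits(ds, "weight_panel"))
  lead_within <- function(v, id) {
    out <- c(v[-1L], NA)
    out[id != c(id[-1L], NA)] <- NA
    out
  }
  id <- ds$child_id
  dt <- lead_within(ds$t, id) - ds$t
  ds$ahi <- (lead_within(ds$height, id) - ds$height) / dt
  ds$awi <- (lead_within(ds$weight, id) - ds$weight) / dt
  singles <- names(which(table(id) < 2L))
  if (length(singles))
    warning(length(singles), " child(ren) with a single record have no increments")
  ds
}

#' Count observed consecutive-wave state pairs
#'
#' Entry (r, s) is the number of consecutive observation pairs in state r
#' at one examination and s at the next. These are observed panel pairs,
#' not instantaneous jumps: a pair 1 -> 3 can occur even though the
#' continuous-time model forbids direct normal <-> obese jumps, because the
#' path passes through overweight between examinations.
#'
#' @param ds A [weight_panel()] with a `state` column.
#' @return 3x3 integer matrix with dimnames
#'   `c("normal", "overweight", "obese")`.
#' @export
count_transitions <- function(ds) {
  stopifnot(inherits(ds, "weight_panel"))
  if (is.null(ds$state)) stop("states not assigned; run classify_status() first")
  iv <- panel_intervals(ds)
  m <- matrix(0L, 3L, 3L,
              dimnames = rep(list(c("normal", "overweight", "obese")), 2L))
  tab <- table(factor(iv$from, 1:3), factor(iv$to, 1:3))
  m[] <- as.integer(tab)
  m
}

#' Internal: consecutive observation pairs of a panel
#'
#' One row per interval: start/end state, elapsed time, and any covariate
#' columns evaluated at the interval start (piecewise-constant convention).
#' @noRd
panel_intervals <- function(ds, covariate = NULL) {
  id <- ds$child_id
  nxt_same <- c(id[-1L] == id[-length(id)], FALSE)
  i <- which(nxt_same)
  out <- data.frame(from = ds$state[i], to = ds$state[i + 1L],
                    dt = ds$t[i + 1L] - ds$t[i])
  if (any(out$dt <= 0)) stop("non-positive interval length in panel")
  if (!is.null(covariate)) {
    if (!covariate %in% names(ds)) stop("covariate column not found: ", covariate)
    out$z <- ds[[covariate]][i]
    if (any(is.na(out$z)))
      stop("covariate '", covariate, "' has missing values at interval starts")
  }
  out
}

#' Baseline characteristics summary with two-group sex comparison
#'
#' Counts and percentages for sex, area and baseline weight status, and
#' median (IQR) for age, height, weight, BMI and (if attached) first-year
#' AHI/AWI, at each child's first examination, split by sex. Group
#' differences use the chi-squared test for categorical rows and the
#' Mann-Whitney (Wilcoxon rank-sum) test for continuous rows.
#'
#' @param ds A [weight_panel()], optionally with `state`, `ahi`, `awi`.
#' @return data.frame with columns `variable`, `all`, `girls`, `boys`, `p`.
#' @export
baseline_summary <- function(ds) {
  stopifnot(inherits(ds, "weight_panel"))
  b <- ds[ds$t == 0, , drop = FALSE]
  g <- b[b$sex == "girl", , drop = FALSE]
  y <- b[b$sex == "boy", , drop = FALSE]
  fmt_n <- function(k, n) sprintf("%d (%.1f)", k, if (n) 100 * k / n else NA)
  fmt_med <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return("--")
    sprintf("%.1f (%.1f)", stats::median(v), stats::IQR(v))
  }
  rows <- list()
  add <- function(variable, all, girls, boys, p = NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(variable = variable, all = all,
                                             girls = girls, boys = boys, p = p)
  add("n", as.character(nrow(b)),
      fmt_n(nrow(g), nrow(b)), fmt_n(nrow(y), nrow(b)))
  cat_row <- function(label, col, levels) {
    tab <- table(factor(b[[col]], levels), b$sex == "girl")
    # sparse tables trigger the usual approximation warning; a thin summary
    # reports the p-value as-is rather than switching tests
    p <- if (all(dim(tab) == c(length(levels), 2L)) && all(colSums(tab) > 0))
      tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
               error = function(e) NA_real_)
    else NA_real_
    add(label, "", "", "", p)
    for (lv in levels)
      add(paste0("  ", lv),
          fmt_n(sum(b[[col]] == lv, na.rm = TRUE), nrow(b)),
          if (nrow(g)) fmt_n(sum(g[[col]] == lv, na.rm = TRUE), nrow(g)) else "absent",
          if (nrow(y)) fmt_n(sum(y[[col]] == lv, na.rm = TRUE), nrow(y)) else "absent")
  }
  cat_row("area, n (%)", "area", c("urban", "semi-urban"))
  if (!is.null(b$state)) {
    b$status <- c("normal", "overweight", "obese")[b$state]
    cat_row("baseline weight status, n (%)", "status",
            c("normal", "overweight", "obese"))
  }
  num_row <- function(label, col) {
    if (is.null(b[[col]])) return(invisible())
    p <- if (nrow(g) && nrow(y))
      tryCatch(stats::wilcox.test(g[[col]], y[[col]], exact = FALSE)$p.value,
               error = function(e) NA_real_)
    else NA_real_
    add(label, fmt_med(b[[col]]),
        if (nrow(g)) fmt_med(g[[col]]) else "absent",
        if (nrow(y)) fmt_med(y[[col]]) else "absent", p)
  }
  num_row("age (year), median (IQR)", "exam_age")
  num_row("height (cm), median (IQR)", "height")
  num_row("weight (kg), median (IQR)", "weight")
  num_row("BMI (kg/m2), median (IQR)", "bmi")
  num_row("AHI (first interval, cm/y), median (IQR)", "ahi")
  num_row("AWI (first interval, kg/y), median (IQR)", "awi")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
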