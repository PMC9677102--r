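#' Compute body mass index
#'
#' BMI in kg/m^2 from weight in kilograms and height in centimetres.
#'
#' @param weight Numeric vector, kilograms. Must be positive.
#' @param height Numeric vector, centimetres. Must be positive.
#' @return Numeric vector of BMI values (kg/m^2).
#' @examples
#' compute_bmi(23.8, 122.4)
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight) | weight <= 0))
    stop("'weight' must be positive and finite (kg)")
  if (any(!is.finite(height) | height <= 0))
    stop("'height' must be positive and finite (cm)")
  weight / (height / 100)^2
}

#' Construct an age- and sex-specific BMI cutoff table
#'
#' A cutoff table holds, per sex and half-open age bracket `[age_lo, age_hi)`,
#' the overweight threshold `c_ow` and the obesity threshold `c_ob`
#' (both kg/m^2). A child with BMI below `c_ow` is normal weight (state 1),
#' with `c_ow <= BMI < c_ob` overweight (state 2), and with `BMI >= c_ob`
#' obese (state 3); thresholds are inclusive upward, the common convention
#' for growth references.
#'
#' Official standards (WHO BMI-for-age, the China Obesity Task Force norms)
#' are not bundled: supply them via [load_cutoffs()]. [synthetic_cutoffs()]
#' provides plausible synthetic tables for simulation and testing.
#'
#' @param x A data.frame with columns `sex` ("girl"/"boy"), `age_lo`,
#'   `age_hi` (years), `c_ow`, `c_ob` (kg/m^2).
#' @param provenance Label describing where the thresholds come from.
#' @return An object of class `cutoff_table`.
#' @export
cutoff_table <- function(x, provenance = "custom") {
  req <- c("sex", "age_lo", "age_hi", "c_ow", "c_ob")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols))
    stop("cutoff table is missing column(s): ", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x)[req]
  x$sex <- as.character(x$sex)
  bad_sex <- setdiff(unique(x$sex), c("girl", "boy"))
  if (length(bad_sex))
    stop("unknown sex level(s) in cutoff table: ", paste(bad_sex, collapse = ", "))
  if (any(x$age_hi <= x$age_lo))
    stop("every bracket must have age_lo < age_hi")
  if (any(x$c_ow >= x$c_ob))
    stop("every bracket must have c_ow < c_ob")
  # brackets must tile the covered range per sex: no overlaps, no gaps
  for (s in unique(x$sex)) {
    b <- x[x$sex == s, , drop = FALSE]
    b <- b[order(b$age_lo), , drop = FALSE]
    if (nrow(b) > 1L) {
      lo <- b$age_lo[-1L]
      hi <- b$age_hi[-nrow(b)]
      if (any(lo < hi - 1e-9))
        stop("overlapping age brackets for sex '", s, "'")
      gap <- which(lo > hi + 1e-9)
      if (length(gap))
        stop(sprintf("gap in age brackets for sex '%s': [%g,%g) uncovered",
                     s, hi[gap[1L]], lo[gap[1L]]))
    }
  }
  x <- x[order(x$sex, x$age_lo), ]
  rownames(x) <- NULL
  structure(x, class = c("cutoff_table", "data.frame"),
            provenance = provenance)
}

#' @export
print.cutoff_table <- function(x, ...) {
  cat("BMI-for-age cutoff table (", attr(x, "provenance"), ")\n", sep = "")
  for (s in unique(x$sex)) {
    b <- x[x$sex == s, ]
    cat(sprintf("  %s: %d bracket(s) covering [%g, %g) years\n",
                s, nrow(b), min(b$age_lo), max(b$age_hi)))
  }
  print.data.frame(x, ...)
  invisible(x)
}

#' Load a cutoff table from a YAML or CSV file
#'
#' CSV files need a header with columns `sex, age_lo, age_hi, c_ow, c_ob`.
#' YAML files hold a list of entries with the same keys, optionally under a
#' top-level `cutoffs:` key with a sibling `provenance:` label.
#'
#' @param path Path to a `.csv`, `.yml` or `.yaml` file.
#' @param provenance Optional provenance label overriding any in the file.
#' @return A [cutoff_table()].
#' @export
load_cutoffs <- function(path, provenance = NULL) {
  if (!file.exists(path)) stop("cutoff file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    entries <- if (!is.null(y$cutoffs)) y$cutoffs else y
    if (is.null(provenance)) provenance <- y$provenance
    df <- do.call(rbind, lapply(entries, function(e)
      data.frame(sex = e$sex, age_lo = e$age_lo, age_hi = e$age_hi,
                 c_ow = e$c_ow, c_ob = e$c_ob)))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  cutoff_table(df, provenance = if (is.null(provenance)) "custom" else provenance)
}

#' Splice two cutoff tables at a switching age
#'
#' Cohorts spanning a reference-standard boundary (e.g. one standard below
#' age 7, another from 7 up) classify with a mixed table: brackets from
#' `before` clipped to end at `switch_age` and brackets from `after`
#' starting there.
#'
#' @param before,after [cutoff_table()] objects.
#' @param switch_age Age in years at which `after` takes over.
#' @return A [cutoff_table()] covering both ranges.
#' @export
splice_cutoffs <- function(before, after, switch_age = 7) {
  b <- as.data.frame(before); a <- as.data.frame(after)
  b <- b[b$age_lo < switch_age, , drop = FALSE]
  b$age_hi <- pmin(b$age_hi, switch_age)
  a <- a[a$age_hi > switch_age, , drop = FALSE]
  a$age_lo <- pmax(a$age_lo, switch_age)
  cutoff_table(rbind(b, a),
               provenance = sprintf("%s|%s@%g", attr(before, "provenance"),
                                    attr(after, "provenance"), switch_age))
}

#' Synthetic BMI cutoff tables for simulation and tests
#'
#' Smoothly age-increasing overweight/obesity thresholds with a small sex
#' difference, shaped like (but numerically distinct from) published
#' growth-reference cutoffs. These are synthetic values: analyses of real
#' cohorts must load the applicable official standard with [load_cutoffs()].
#'
#' @param style `"school_age"`: one-year brackets covering ages 2-19.
#'   `"mixed_standard"`: the same shape but with a deliberate level shift
#'   from age 7 upward, emulating a switch between two reference standards.
#' @return A [cutoff_table()].
#' @export
synthetic_cutoffs <- function(style = c("school_age", "mixed_standard")) {
  style <- match.arg(style)
  grid <- expand.grid(sex = c("girl", "boy"), age_lo = 2:18,
                      stringsAsFactors = FALSE)
  grid$age_hi <- grid$age_lo + 1
  mid <- grid$age_lo + 0.5
  # thresholds rise with age past a shallow minimum near the preschool years
  base_ow <- 16.0 + 0.35 * pmax(mid - 5.5, 0) - 0.10 * pmax(5.5 - mid, 0)
  sex_shift <- ifelse(grid$sex == "boy", 0.25, 0)
  grid$c_ow <- round(base_ow + sex_shift, 2)
  grid$c_ob <- round(grid$c_ow + 2.0 + 0.12 * pmax(mid - 5.5, 0), 2)
  if (style == "mixed_standard") {
    shift <- grid$age_lo >= 7
    grid$c_ow[shift] <- grid$c_ow[shift] + 0.4
    grid$c_ob[shift] <- grid$c_ob[shift] + 0.4
  }
  cutoff_table(grid, provenance = paste0("synthetic-", style))
}

#' Classify weight status from BMI, age and sex
#'
#' Returns weight-status states: 1 = normal weight, 2 = overweight,
#' 3 = obese, by comparing BMI against the age/sex bracket of `table`.
#' Thresholds are inclusive upward (BMI equal to a cutoff falls in the
#' heavier class). Ages outside the table's coverage are an error - the
#' table is never extrapolated.
#'
#' @param bmi Numeric vector, kg/m^2.
#' @param age Numeric vector, years (age at examination).
#' @param sex Character vector, `"girl"` or `"boy"`.
#' @param table A [cutoff_table()].
#' @return Integer vector of states in `{1, 2, 3}`.
#' @export
classify_status <- function(bmi, age, sex, table) {
  if (!inherits(table, "cutoff_table")) table <- cutoff_table(table)
  n <- length(bmi)
  stopifnot(length(age) == n, length(sex) == n)
  sex <- as.character(sex)
  out <- integer(n)
  for (s in unique(sex)) {
    idx <- which(sex == s)
    b <- table[table$sex == s, , drop = FALSE]
    if (!nrow(b)) stop("cutoff table has no brackets for sex '", s, "'")
    pos <- findInterval(age[idx], c(b$age_lo, b$age_hi[nrow(b)]),
                        rightmost.closed = FALSE)
    uncovered <- pos < 1L | pos > nrow(b)
    if (any(uncovered))
      stop(sprintf("age(s) outside cutoff table coverage for sex '%s': %s",
                   s, paste(unique(round(age[idx][uncovered], 2)), collapse = ", ")))
    c_ow <- b$c_ow[pos]; c_ob <- b$c_ob[pos]
    out[idx] <- 1L + (bmi[idx] >= c_ow) + (bmi[idx] >= c_ob)
  }
  out
}

#' Look up the cutoff band for a state
#'
#' Internal helper for the simulator: returns, per element, the BMI interval
#' `[lo, hi)` consistent with the given state at the given age/sex.
#' Open-ended bands (below overweight, above obesity) are closed off at
#' `c_ow - normal_width` and `c_ob + obese_width`.
#' @noRd
state_band <- function(state, age, sex, table,
                       normal_width = 3.5, obese_width = 5) {
  n <- length(state)
  lo <- hi <- numeric(n)
  sex <- as.character(sex)
  for (s in unique(sex)) {
    idx <- which(sex == s)
    b <- table[table$sex == s, , drop = FALSE]
    pos <- findInterval(age[idx], c(b$age_lo, b$age_hi[nrow(b)]))
    if (any(pos < 1L | pos > nrow(b))) stop("age outside cutoff coverage")
    c_ow <- b$c_ow[pos]; c_ob <- b$c_ob[pos]
    st <- state[idx]
    lo[idx] <- ifelse(st == 1L, c_ow - normal_width, ifelse(st == 2L, c_ow, c_ob))
    hi[idx] <- ifelse(st == 1L, c_ow, ifelse(st == 2L, c_ob, c_ob + obese_width))
  }
  cbind(lo = lo, hi = hi)
}
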