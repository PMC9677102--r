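# Adiposity rebound: per-child quadratic BMI-versus-age curves and the age
# of the BMI nadir. A quadratic is the minimal curve family with an
# interior minimum, matching the "lowest BMI" definition of the rebound.

#' Fit per-child quadratic BMI curves
#'
#' Fits `bmi ~ age + age^2` with child-level deviations. The default mixed
#' model (random intercept, linear and quadratic terms per child, via
#' [lme4::lmer()]) pools information across children; per-child fitted
#' coefficients are the sum of fixed effects and the child's BLUPs. When
#' the mixed fit fails or is degenerate (for example noiseless data), the
#' function falls back to independent per-child least squares and records
#' that in the `method` column.
#'
#' Children with fewer than 3 observations cannot identify a quadratic and
#' are returned with `NA` coefficients and `flag = "too_few_points"`.
#'
#' @param ds A [weight_panel()] or data.frame with `child_id`, `bmi` and an
#'   age column (`exam_age` or `age`).
#' @param method `"auto"` (mixed with per-child fallback), `"mixed"`, or
#'   `"perchild"`.
#' @return data.frame with one row per child: `child_id`, `b0`, `b1`, `b2`
#'   (BMI = b0 + b1*age + b2*age^2), `n_obs`, `method`, `flag`. The age
#'   range of the data is kept in attribute `age_range`; for a mixed fit
#'   the population fixed effects are in attribute `fixed_effects`.
#' @export
fit_bmi_curves <- function(ds, method = c("auto", "mixed", "perchild")) {
  method <- match.arg(method)
  df <- as.data.frame(ds)
  if (!"age" %in% names(df)) {
    if (!"exam_age" %in% names(df)) stop("need an 'age' or 'exam_age' column")
    df$age <- df$exam_age
  }
  stopifnot(all(c("child_id", "bmi") %in% names(df)))
  df <- df[is.finite(df$age) & is.finite(df$bmi), ]
  df$child_id <- as.character(df$child_id)
  n_obs <- table(df$child_id)
  ids <- names(n_obs)
  fit_df <- df[df$child_id %in% ids[n_obs >= 3L], ]

  out <- data.frame(child_id = ids, b0 = NA_real_, b1 = NA_real_,
                    b2 = NA_real_, n_obs = as.integer(n_obs),
                    method = NA_character_, flag = "")
  out$flag[out$n_obs < 3L] <- "too_few_points"
  fixed <- NULL

  per_child <- function(d) {
    res <- lapply(split(d, d$child_id), function(ch) {
      co <- stats::coef(stats::lm(bmi ~ age + I(age^2), data = ch))
      unname(co)
    })
    do.call(rbind, res)
  }

  used <- method
  co <- NULL
  if (method %in% c("auto", "mixed")) {
    mm <- tryCatch(
      withCallingHandlers(
        lme4::lmer(bmi ~ age + I(age^2) + (age + I(age^2) | child_id),
                   data = fit_df, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore")),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(mm, "error")) {
      if (method == "mixed") stop("mixed-effects fit failed: ",
                                  conditionMessage(mm))
      used <- "perchild_fallback"
    } else {
      cc <- stats::coef(mm)$child_id
      co <- as.matrix(cc)
      rownames(co) <- rownames(cc)
      fixed <- lme4::fixef(mm)
      used <- "mixed"
    }
  }
  if (is.null(co)) {
    co <- per_child(fit_df)
    if (used == "auto") used <- "perchild"
  }
  idx <- match(rownames(co), out$child_id)
  if (anyNA(idx)) idx <- match(sort(unique(fit_df$child_id)), out$child_id)
  out$b0[idx] <- co[, 1L]; out$b1[idx] <- co[, 2L]; out$b2[idx] <- co[, 3L]
  out$method[idx] <- used
  structure(out,
            age_range = range(fit_df$age),
            fixed_effects = fixed)
}

#' Age at adiposity rebound from a fitted quadratic curve
#'
#' The rebound age is the BMI nadir, the vertex `-b1 / (2 * b2)` of the
#' quadratic, provided the curve is convex (`b2 > 0`) and the vertex lies
#' inside `age_range`; otherwise the rebound is absent (`NA`): a concave or
#' monotone curve has no BMI minimum to rebound from. Children whose
#' rebound age is at or after 7 years are flagged `late_ar`; an absent
#' rebound is never late. A vertex below the youngest observed age is
#' still reported but flagged `"extrapolated"`, since the nadir is then
#' inferred from curvature rather than observed.
#'
#' @param curves data.frame from [fit_bmi_curves()] (needs `b1`, `b2`).
#' @param age_range Ages (years) within which a vertex counts as a real
#'   nadir; default `c(2, 20)`.
#' @param observed_range Optional observed age support used for the
#'   extrapolation flag; defaults to `attr(curves, "age_range")`.
#' @return `curves` with columns `ar_age`, `late_ar`, `ar_flag` added.
#' @export
ar_age <- function(curves, age_range = c(2, 20), observed_range = NULL) {
  stopifnot(all(c("b1", "b2") %in% names(curves)))
  if (is.null(observed_range)) observed_range <- attr(curves, "age_range")
  vertex <- -curves$b1 / (2 * curves$b2)
  has_nadir <- !is.na(curves$b2) & curves$b2 > 0 &
    vertex >= age_range[1L] & vertex <= age_range[2L]
  curves$ar_age <- ifelse(has_nadir, vertex, NA_real_)
  curves$late_ar <- !is.na(curves$ar_age) & curves$ar_age >= 7
  curves$ar_flag <- ifelse(!is.na(curves$b2) & curves$b2 <= 0, "no_nadir",
                    ifelse(!has_nadir & !is.na(curves$b2), "vertex_out_of_range",
                           ""))
  if (!is.null(observed_range)) {
    extrap <- has_nadir & vertex < observed_range[1L]
    curves$ar_flag[extrap] <- "extrapolated"
  }
  curves
}

#' Share of children with late adiposity rebound
#'
#' @param results data.frame from [ar_age()] (needs `late_ar`).
#' @return Proportion in `[0, 1]` of children whose BMI nadir falls at or
#'   after age 7 (children without an identifiable nadir count as not
#'   late).
#' @export
late_ar_rate <- function(results) {
  stopifnot("late_ar" %in% names(results))
  mean(results$late_ar)
}
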