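#' Interaction regression of censored log C-peptide
#'
#' Ordinary least squares of log10 C-peptide (below-detection values set
#' to zero) on the standard covariate set: plasma glucose dichotomized
#' (indicator `> glucose_cut` mmol/l), square root of age at onset,
#' female sex, duration, type 1 and type 2 genotypic risk scores, BMI,
#' and the interaction of the square root of age at onset with each of
#' female sex, duration, the two scores, and BMI. All covariates are
#' mean-centred before interactions are formed, so each main effect is
#' the predicted effect at the mean of the other covariates.
#' Individuals labelled `possible_t2` are excluded (they are classified
#' first when titres are available and no `label` column exists).
#'
#' @param records Phenotype tibble (see [simulate_phenotypes()] for the
#'   layout).
#' @param scores Optional tibble with `individual_id`, `t1_score`,
#'   `t2_score` overriding score columns in `records`.
#' @param lod Detection limit passed to [transform_cpeptide()].
#' @param glucose_cut Glucose dichotomization threshold, mmol/l
#'   (default 5; 8 has also been used for random glucose).
#' @return An object of class `cpep_reg`; use [tidy()] for the
#'   coefficient table (term, estimate, SE, p), [glance()] for fit
#'   summaries, [autoplot()] for a coefficient plot.
#' @export
fit_cpeptide_regression <- function(records, scores = NULL, lod = 3,
                                    glucose_cut = 5) {
  if (!is.null(scores)) {
    records <- records |>
      dplyr::select(-dplyr::any_of(c("t1_score", "t2_score"))) |>
      dplyr::inner_join(scores, by = "individual_id")
  }
  if (!"label" %in% names(records) &&
      all(c("gad", "ia2", "znt8") %in% names(records))) {
    records <- classify_possible_t2(records)
  }
  if ("label" %in% names(records)) {
    records <- dplyr::filter(records,
                             is.na(.data$label) | .data$label != "possible_t2")
  }
  needed <- c("cpeptide", "glucose", "age_onset", "sex", "duration",
              "t1_score", "t2_score", "bmi")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop_cpep("Missing phenotype column(s): ", fmt_ids(miss))
  records <- records[complete.cases(records[needed]), , drop = FALSE]

  covars <- tibble(
    glucose_high = as.numeric(records$glucose > glucose_cut),
    sqrt_onset = sqrt(records$age_onset),
    female = as.numeric(records$sex == "female"),
    duration = records$duration,
    t1_score = records$t1_score,
    t2_score = records$t2_score,
    bmi = records$bmi
  )
  X <- cpep_model_matrix(covars)
  qrX <- qr(cbind(`(Intercept)` = 1, X))
  if (qrX$rank < ncol(X) + 1L) {
    aliased <- colnames(cbind(1, X))[qrX$pivot[-seq_len(qrX$rank)]]
    stop_cpep("Model is rank deficient; collinear term(s): ",
              fmt_ids(aliased))
  }
  y <- transform_cpeptide(records$cpeptide, lod = lod)
  fit <- lm(y ~ X)
  structure(
    list(fit = fit, n = nrow(records), terms = colnames(X),
         lod = lod, glucose_cut = glucose_cut),
    class = "cpep_reg"
  )
}

#' @export
print.cpep_reg <- function(x, ...) {
  cat("<cpep_reg> OLS of censored log10 C-peptide, n =", x$n, "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @rdname fit_cpeptide_regression
#' @param x A `cpep_reg` object.
#' @param ... Unused.
#' @export
tidy.cpep_reg <- function(x, ...) {
  ct <- summary(x$fit)$coefficients
  tibble(
    term = sub("^X", "", rownames(ct)),
    estimate = ct[, 1], std.error = ct[, 2],
    statistic = ct[, 3], p.value = ct[, 4]
  )
}

#' @rdname fit_cpeptide_regression
#' @export
glance.cpep_reg <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma, nobs = x$n, df.residual = x$fit$df.residual
  )
}

#' @rdname fit_cpeptide_regression
#' @param object A `cpep_reg` object.
#' @export
autoplot.cpep_reg <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot(d, aes(x = .data$estimate, y = .data$term)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    geom_pointrange(aes(xmin = .data$estimate - 1.96 * .data$std.error,
                        xmax = .data$estimate + 1.96 * .data$std.error)) +
    labs(x = "Effect on log10 C-peptide (per unit, covariates centred)",
         y = NULL) +
    theme_minimal()
}

#' Smoothed geometric-mean C-peptide surface
#'
#' Locally weighted polynomial (LOESS) fit of censored log10 C-peptide
#' on age at onset and diabetes duration, evaluated over a grid and
#' back-transformed to the concentration scale (`10^fit`), i.e. a
#' geometric-mean surface. Predictors are standardized internally
#' (tricube weights on standardized Euclidean distance).
#'
#' @param records Phenotype tibble with `age_onset`, `duration`,
#'   `cpeptide`.
#' @param degree Local polynomial degree (default 2).
#' @param span LOESS span (default 0.25).
#' @param grid Optional tibble/list with `age_onset` and `duration`
#'   grid values; defaults to 25 x 25 over the observed ranges.
#' @param lod Detection limit for [transform_cpeptide()].
#' @return Tibble with `age_onset`, `duration`, `log10_cpeptide`,
#'   `cpeptide` at each grid node.
#' @export
loess_surface <- function(records, degree = 2, span = 0.25, grid = NULL,
                          lod = 3) {
  dat <- tibble(
    age_onset = records$age_onset,
    duration = records$duration,
    y = transform_cpeptide(records$cpeptide, lod = lod)
  )
  fit <- tryCatch(
    loess(y ~ age_onset + duration, data = dat, degree = degree,
          span = span, family = "gaussian",
          control = loess.control(surface = "direct")),
    error = function(e) {
      stop_cpep("LOESS fit failed (span too small for the data density?): ",
                conditionMessage(e))
    }
  )
  if (is.null(grid)) {
    grid <- list(
      age_onset = seq(min(dat$age_onset), max(dat$age_onset),
                      length.out = 25),
      duration = seq(min(dat$duration), max(dat$duration),
                     length.out = 25)
    )
  }
  nodes <- tidyr::expand_grid(age_onset = grid$age_onset,
                              duration = grid$duration)
  pred <- predict(fit, newdata = as.data.frame(nodes))
  nodes |>
    dplyr::mutate(log10_cpeptide = as.numeric(pred),
                  cpeptide = 10^.data$log10_cpeptide)
}

#' Plot a C-peptide surface
#'
#' Tile plot of the smoothed geometric-mean C-peptide over age at onset
#' and duration, as produced by [loess_surface()].
#'
#' @param surface Tibble from [loess_surface()].
#' @return A ggplot object.
#' @export
plot_cpeptide_surface <- function(surface) {
  ggplot(surface, aes(x = .data$age_onset, y = .data$duration,
                      fill = .data$cpeptide)) +
    geom_tile() +
    scale_fill_viridis_c(trans = "log10",
                         name = "C-peptide\n(pmol/l)") +
    labs(x = "Age at onset (years)", y = "Duration (years)") +
    theme_minimal()
}
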