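test_that("C-peptide transform censors at the detection limit", {
  expect_equal(transform_cpeptide(100), 2)
  expect_equal(transform_cpeptide(2), 0)   # below LOD 3
  expect_equal(transform_cpeptide(1), 0)
  expect_error(transform_cpeptide(-1), "non-negative")
  # monotone non-decreasing on [lod, Inf)
  x <- sort(runif(50, 3, 5000))
  expect_true(all(diff(transform_cpeptide(x)) >= 0))
  # custom LOD
  expect_equal(transform_cpeptide(5, lod = 10), 0)
})

test_that("antibody positivity uses the reference thresholds", {
  expect_true(antibody_positive("GAD", 12))
  expect_false(antibody_positive("GAD", 11))   # strictly greater than
  expect_false(antibody_positive("IA2", 0))
  expect_true(antibody_positive("IA2", 8))
  # ZnT8 threshold switches at age 30
  expect_false(antibody_positive("ZnT8", 20, age_sampling = 25))
  expect_true(antibody_positive("ZnT8", 20, age_sampling = 35))
  expect_false(antibody_positive("ZnT8", 9.1, age_sampling = 35))
  expect_error(antibody_positive("IAA", 5), "Unknown analyte")
  expect_error(antibody_positive("ZnT8", 5), "age_sampling")
})

test_that("possible type 2 classification follows the printed rule", {
  rec <- tibble::tibble(
    cpeptide = c(700, 700, 600, 601, 700),
    gad = c(0, 100, 0, 0, NA),
    ia2 = 0, znt8 = 0, age_sampling = 40
  )
  expect_warning(out <- classify_possible_t2(rec), "unclassified")
  expect_identical(out$label,
                   c("possible_t2", "definite_t1", "definite_t1",
                     "possible_t2", NA))
  # partition: every classified record is exactly one of the two labels
  expect_true(all(out$label[!is.na(out$label)] %in%
                    c("definite_t1", "possible_t2")))
})

test_that("prevalence tables reproduce printed cells from expanded counts", {
  counts <- prevalence_counts("cpeptide")
  records <- expand_prevalence_records(counts, "cpeptide")
  tab <- prevalence_by_onset_duration(records)
  cell <- function(dur, onset) {
    dplyr::filter(tab, duration == dur, age_onset == onset)
  }
  c1 <- cell("15 or more", "0 to 15")
  expect_equal(c1$percent, 19)
  expect_equal(c1$numerator, 317)
  expect_equal(c1$denominator, 1643)
  all_col <- cell("All", "0 to 15")
  expect_equal(all_col$denominator, 17 + 128 + 237 + 1643)
  expect_equal(all_col$numerator, 469)
  expect_equal(all_col$percent, 23)
})

test_that("antibody-negative tables reproduce printed cells", {
  counts <- prevalence_counts("antibody")
  records <- expand_prevalence_records(counts, "antibody")
  tab <- abneg_by_duration_cpeptide(records)
  top <- dplyr::filter(tab, duration == "15 or more",
                       cpeptide_range == "(600, 7000]")
  expect_equal(top$percent, 80)
  expect_equal(top$numerator, 49)
  all_row <- dplyr::filter(tab, duration == "All",
                           cpeptide_range == "(600, 7000]")
  expect_equal(all_row$numerator, 203)
  expect_equal(all_row$percent, 57)

  # an all-positive cohort gives 0% everywhere
  pos <- dplyr::mutate(records, gad = 100)
  tab0 <- abneg_by_duration_cpeptide(pos)
  expect_true(all(tab0$percent[tab0$denominator > 0] == 0))
})

test_that("table margins are consistent and empty cells render as NA", {
  set.seed(12)
  rec <- tibble::tibble(
    age_onset = runif(200, 0, 60), duration = runif(200, 0, 40),
    cpeptide = 10^rnorm(200, 1, 1)
  )
  tab <- prevalence_by_onset_duration(rec)
  for (on in unique(tab$age_onset)) {
    cells <- dplyr::filter(tab, age_onset == on, duration != "All")
    marg <- dplyr::filter(tab, age_onset == on, duration == "All")
    expect_equal(sum(cells$numerator), marg$numerator)
    expect_equal(sum(cells$denominator), marg$denominator)
  }
  empty <- prevalence_by_onset_duration(rec[0, ])
  expect_true(all(is.na(empty$percent)))
  expect_true(all(empty$denominator == 0))
})

test_that("percent rendering rounds half away from zero", {
  # 77.54 % -> 78; 51.49 % -> 51; exact halves go away from zero
  expect_equal(cpepgrs:::round_half_away(c(77.54, 51.49, 0.5, 1.5, -0.5)),
               c(78, 51, 1, 2, -1))
})

test_that("the interaction regression is centred and validates inputs", {
  cfg <- synthetic_config(n_cohort = 800, h2_cpep = 0, sigma_resid = 0.2,
                          seed = 61)
  study <- simulate_cohort(cfg)
  ph <- study$phenotypes
  fit <- fit_cpeptide_regression(ph)
  td <- tidy(fit)
  expect_identical(td$term,
                   c("(Intercept)", names(default_beta_table())[-1]))

  # centering invariance: shifting a covariate leaves interactions alone
  ph2 <- dplyr::mutate(ph, bmi = bmi + 7)
  td2 <- tidy(fit_cpeptide_regression(ph2))
  inter <- grep("sqrt_onset:", td$term)
  expect_equal(td$estimate[inter], td2$estimate[inter], tolerance = 1e-10)

  expect_error(fit_cpeptide_regression(dplyr::select(ph, -bmi)), "bmi")

  # collinear scores are reported by name
  ph3 <- dplyr::mutate(ph, t2_score = t1_score)
  expect_error(fit_cpeptide_regression(ph3), "rank deficient")
})

test_that("possible type 2 individuals are excluded before fitting", {
  cfg <- synthetic_config(n_cohort = 400, seed = 62)
  ph <- simulate_cohort(cfg)$phenotypes
  ph <- classify_possible_t2(ph)
  n_t2 <- sum(ph$label == "possible_t2", na.rm = TRUE)
  fit <- fit_cpeptide_regression(ph)
  expect_equal(fit$n, nrow(ph) - n_t2)
})

test_that("zero-noise synthetic data is recovered exactly", {
  bt <- default_beta_table()
  bt["(Intercept)"] <- 2.5
  cfg <- synthetic_config(n_cohort = 600, beta_table = bt,
                          sigma_resid = 0, h2_cpep = 0, seed = 63)
  study <- simulate_cohort(cfg)
  expect_false(any(study$phenotypes$below_detection))
  # keep the full generative sample: selecting on antibody status would
  # condition on the outcome and is tested separately
  ph <- dplyr::select(study$phenotypes, -gad, -ia2, -znt8)
  # a zero-noise fit is an exact interpolation; lm warns about it
  td <- suppressWarnings(tidy(fit_cpeptide_regression(ph)))
  expect_equal(setNames(td$estimate, td$term), bt[td$term],
               tolerance = 1e-8)
})

test_that("LOESS surface is exact on polynomial data and monotone", {
  # constant surface
  rec_c <- tibble::tibble(age_onset = runif(200, 5, 40),
                          duration = runif(200, 1, 30),
                          cpeptide = 10^1.7)
  surf_c <- loess_surface(rec_c, span = 0.5)
  expect_equal(surf_c$cpeptide, rep(10^1.7, nrow(surf_c)),
               tolerance = 1e-6)

  # planar data reproduced at interior grid points
  set.seed(13)
  on <- runif(300, 5, 40); du <- runif(300, 1, 30)
  y <- 2 + 0.02 * on - 0.03 * du
  rec_p <- tibble::tibble(age_onset = on, duration = du,
                          cpeptide = 10^y)
  grid <- list(age_onset = seq(10, 35, length.out = 5),
               duration = seq(5, 25, length.out = 5))
  surf_p <- loess_surface(rec_p, span = 0.5, grid = grid)
  expect_equal(surf_p$log10_cpeptide,
               2 + 0.02 * surf_p$age_onset - 0.03 * surf_p$duration,
               tolerance = 1e-6)

  # monotone-decreasing truth stays monotone on the grid
  y_m <- 2.5 - 0.04 * du
  rec_m <- tibble::tibble(age_onset = on, duration = du,
                          cpeptide = 10^(y_m + rnorm(300, 0, 0.01)))
  surf_m <- loess_surface(rec_m, span = 0.6, grid = grid)
  by_onset <- split(surf_m, surf_m$age_onset)
  for (s in by_onset) {
    expect_true(all(diff(s$log10_cpeptide[order(s$duration)]) < 0))
  }
  expect_error(loess_surface(rec_m[1:4, ], span = 0.01), "LOESS")
})
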