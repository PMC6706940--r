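#' Log-transform C-peptide with censoring at the detection limit
#'
#' Returns `log10(cpeptide)` for detectable values (`>= lod`) and `0`
#' for values below the assay's lower limit of detection — the
#' convention used when modelling censored C-peptide on the log scale.
#'
#' @param cpeptide Numeric vector of C-peptide concentrations, pmol/l.
#' @param lod Lower limit of detection, pmol/l (default 3).
#' @return Numeric vector of log10 values with below-LOD set to 0.
#' @export
#' @examples
#' transform_cpeptide(c(100, 2, 1))
transform_cpeptide <- function(cpeptide, lod = 3) {
  if (any(cpeptide < 0, na.rm = TRUE)) {
    stop_cpep("C-peptide concentrations must be non-negative.")
  }
  ifelse(cpeptide >= lod, log10(cpeptide), 0)
}

#' Autoantibody positivity at the assay reference thresholds
#'
#' A titre is positive when it exceeds the 97.5th percentile of the
#' reference range: 11 WHO units/ml for GAD, 7.5 for IA2, and for ZnT8
#' 65 in those aged up to 30 years at sampling and 9.1 in those older
#' than 30.
#'
#' @param analyte One of `"GAD"`, `"IA2"`, `"ZnT8"` (case-insensitive).
#' @param titre Numeric vector of titres, WHO units/ml.
#' @param age_sampling Age at sampling in years; required for ZnT8.
#' @return Logical vector of positivity.
#' @export
#' @examples
#' antibody_positive("GAD", c(12, 10))
#' antibody_positive("ZnT8", 20, age_sampling = c(25, 35))
antibody_positive <- function(analyte, titre, age_sampling = NULL) {
  if (any(titre < 0, na.rm = TRUE)) stop_cpep("Titres must be non-negative.")
  key <- toupper(analyte)
  if (length(key) != 1L || !key %in% c("GAD", "IA2", "ZNT8")) {
    stop_cpep("Unknown analyte: ", analyte)
  }
  threshold <- switch(key,
    GAD = 11,
    IA2 = 7.5,
    ZNT8 = {
      if (is.null(age_sampling)) {
        stop_cpep("ZnT8 positivity needs `age_sampling`.")
      }
      ifelse(age_sampling <= 30, 65, 9.1)
    }
  )
  titre > threshold
}

# All-three-antibody-negative flag for a phenotype tibble; NA when any
# titre is missing.
all_antibody_negative <- function(records) {
  !antibody_positive("GAD", records$gad) &
    !antibody_positive("IA2", records$ia2) &
    !antibody_positive("ZnT8", records$znt8, records$age_sampling)
}

#' Classify possible misdiagnosed type 2 diabetes
#'
#' Labels an individual `possible_t2` when C-peptide exceeds `cpep_cut`
#' (strictly) and all three autoantibodies (GAD, IA2, ZnT8) are
#' negative; everyone else is `definite_t1`. Records with a missing
#' titre cannot be classified: they get an `NA` label and a warning.
#'
#' @param records Phenotype tibble with `cpeptide`, `gad`, `ia2`,
#'   `znt8`, `age_sampling`.
#' @param cpep_cut C-peptide threshold, pmol/l (default 600).
#' @return `records` with a `label` column (`"definite_t1"` /
#'   `"possible_t2"`) appended.
#' @export
#' @examples
#' rec <- tibble::tibble(cpeptide = c(700, 700, 600),
#'                       gad = c(0, 100, 0), ia2 = 0, znt8 = 0,
#'                       age_sampling = 40)
#' classify_possible_t2(rec)$label
classify_possible_t2 <- function(records, cpep_cut = 600) {
  incomplete <- is.na(records$gad) | is.na(records$ia2) |
    is.na(records$znt8) | is.na(records$cpeptide)
  if (any(incomplete)) {
    warn(paste0(sum(incomplete),
                " record(s) with missing titre or C-peptide left unclassified."))
  }
  abneg <- all_antibody_negative(records)
  label <- ifelse(records$cpeptide > cpep_cut & abneg,
                  "possible_t2", "definite_t1")
  label[incomplete] <- NA_character_
  records$label <- label
  records
}

# Shared binner: half-open [lo, hi) bins for onset/duration, right-closed
# (lo, hi] bins for C-peptide, with printed-style labels.
bin_values <- function(x, breaks, right = FALSE) {
  labels <- character(length(breaks) - 1L)
  for (i in seq_along(labels)) {
    lo <- breaks[i]; hi <- breaks[i + 1L]
    labels[i] <- if (is.infinite(hi)) {
      paste0(lo, " or more")
    } else {
      paste0(lo, " to ", hi)
    }
  }
  cut(x, breaks = breaks, labels = labels, right = right,
      include.lowest = TRUE)
}

cpep_bin_labels <- function(breaks) {
  vapply(seq_len(length(breaks) - 1L), function(i) {
    paste0(if (i == 1L) paste0("[", breaks[1]) else paste0("(", breaks[i]),
           ", ", breaks[i + 1L], "]")
  }, character(1))
}

# Build the cross-tabulation with "All" margins from a logical outcome.
prevalence_table <- function(rows, cols, outcome, row_name, col_name) {
  keep <- !is.na(rows) & !is.na(cols) & !is.na(outcome)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    inform(paste0(dropped, " record(s) with missing ", row_name, ", ",
                  col_name, " or outcome excluded from the table."))
  }
  dat <- tibble(row = rows[keep], col = cols[keep],
                out = outcome[keep])
  cells <- dat |>
    dplyr::count(.data$row, .data$col, wt = as.integer(.data$out),
                 name = "numerator") |>
    dplyr::left_join(dplyr::count(dat, .data$row, .data$col,
                                  name = "denominator"),
                     by = c("row", "col"))
  # complete missing cells with zeros
  grid <- tidyr::expand_grid(row = levels(dat$row), col = levels(dat$col))
  cells <- grid |>
    dplyr::left_join(
      cells |> dplyr::mutate(row = as.character(.data$row),
                             col = as.character(.data$col)),
      by = c("row", "col")
    ) |>
    tidyr::replace_na(list(numerator = 0L, denominator = 0L))
  col_margin <- cells |>
    dplyr::group_by(.data$col) |>
    dplyr::summarise(numerator = sum(.data$numerator),
                     denominator = sum(.data$denominator),
                     .groups = "drop") |>
    dplyr::mutate(row = "All")
  out <- dplyr::bind_rows(cells, col_margin) |>
    dplyr::mutate(percent = ifelse(
      .data$denominator > 0,
      round_half_away(100 * .data$numerator / .data$denominator),
      NA_real_
    ))
  names(out)[names(out) == "row"] <- row_name
  names(out)[names(out) == "col"] <- col_name
  structure(
    dplyr::relocate(out, dplyr::all_of(c(row_name, col_name))),
    class = c("cpep_prevtab", class(out)),
    row_name = row_name, col_name = col_name
  )
}

#' Prevalence of detectable C-peptide by age at onset and duration
#'
#' Cross-tabulates the proportion of individuals with detectable
#' C-peptide (`cpeptide >= detect_lod`) by age-at-onset and duration
#' strata, with an "All" duration margin. Onset and duration bins are
#' half-open on the right (`[0, 15)`, `[15, 25)`, ...), matching the
#' conventional rendering of overlapping printed labels.
#'
#' @param records Phenotype tibble with `age_onset`, `duration`,
#'   `cpeptide` (or a `below_detection` logical used in preference).
#' @param onset_breaks,duration_breaks Numeric break vectors (last break
#'   may be `Inf`).
#' @param detect_lod Detection limit, pmol/l.
#' @return A `cpep_prevtab` tibble with columns `duration`, `age_onset`,
#'   `numerator`, `denominator`, `percent` (percent rounded half away
#'   from zero; `NA` for empty cells).
#' @export
prevalence_by_onset_duration <- function(records,
                                         onset_breaks = c(0, 15, 25, 35, Inf),
                                         duration_breaks = c(0, 5, 10, 15, Inf),
                                         detect_lod = 3) {
  detectable <- if ("below_detection" %in% names(records)) {
    !records$below_detection
  } else {
    records$cpeptide >= detect_lod
  }
  prevalence_table(
    rows = bin_values(records$duration, duration_breaks),
    cols = bin_values(records$age_onset, onset_breaks),
    outcome = detectable,
    row_name = "duration", col_name = "age_onset"
  )
}

#' Proportion autoantibody-negative by duration and C-peptide
#'
#' Cross-tabulates the proportion negative for all three autoantibodies
#' by duration stratum and C-peptide range (right-closed bins
#' `[0, 30]`, `(30, 200]`, `(200, 600]`, `(600, 7000]` by default).
#'
#' @param records Phenotype tibble with `duration`, `cpeptide`, `gad`,
#'   `ia2`, `znt8`, `age_sampling`.
#' @param cpep_breaks,duration_breaks Numeric break vectors.
#' @return A `cpep_prevtab` tibble with columns `duration`,
#'   `cpeptide_range`, `numerator`, `denominator`, `percent`.
#' @export
abneg_by_duration_cpeptide <- function(records,
                                       cpep_breaks = c(0, 30, 200, 600, 7000),
                                       duration_breaks = c(0, 5, 10, 15, Inf)) {
  cpep_bin <- cut(records$cpeptide, breaks = cpep_breaks,
                  labels = cpep_bin_labels(cpep_breaks),
                  right = TRUE, include.lowest = TRUE)
  prevalence_table(
    rows = bin_values(records$duration, duration_breaks),
    cols = cpep_bin,
    outcome = all_antibody_negative(records),
    row_name = "duration", col_name = "cpeptide_range"
  )
}

#' @export
print.cpep_prevtab <- function(x, ...) {
  rn <- attr(x, "row_name"); cn <- attr(x, "col_name")
  wide <- x |>
    dplyr::mutate(cell = ifelse(
      is.na(.data$percent), "",
      paste0(.data$percent, "% ", .data$numerator, "/", .data$denominator)
    )) |>
    dplyr::select(dplyr::all_of(c(rn, cn)), "cell") |>
    tidyr::pivot_wider(names_from = dplyr::all_of(cn),
                       values_from = "cell")
  cat("Prevalence table (", rn, " x ", cn, ")\n", sep = "")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' Expand printed prevalence counts into individual-level records
#'
#' Reconstructs a minimal individual-level dataset from a table of
#' per-cell numerators and denominators (such as published prevalence
#' cross-tabulations), placing each synthetic individual at a
#' representative value inside its stratum. For `type = "cpeptide"` the
#' counts are detectable C-peptide by onset/duration cell; for
#' `type = "antibody"` they are all-antibody-negative counts by
#' duration/C-peptide cell (negatives get zero titres, positives a
#' clearly supra-threshold GAD titre).
#'
#' @param counts Tibble of counts. For `"cpeptide"`: columns
#'   `onset_bin`, `duration_bin`, `detectable`, `total`; for
#'   `"antibody"`: `duration_bin`, `cpep_bin`, `abneg`, `total`. Bin
#'   columns are indices into the default break vectors.
#' @param type `"cpeptide"` or `"antibody"`.
#' @return Tibble of phenotype records compatible with the tabulation
#'   and classification functions.
#' @export
expand_prevalence_records <- function(counts,
                                      type = c("cpeptide", "antibody")) {
  type <- match.arg(type)
  onset_rep <- c(7, 20, 30, 45)
  duration_rep <- c(2, 7, 12, 25)
  cpep_rep <- c(10, 100, 400, 1000)
  rows <- purrr::pmap(counts, function(...) {
    cell <- list(...)
    dur <- duration_rep[cell$duration_bin]
    if (type == "cpeptide") {
      n_yes <- cell$detectable
      tibble(
        age_onset = onset_rep[cell$onset_bin],
        duration = dur,
        cpeptide = rep(c(100, 1), c(n_yes, cell$total - n_yes))
      )
    } else {
      n_neg <- cell$abneg
      tibble(
        age_onset = 20,
        duration = dur,
        cpeptide = cpep_rep[cell$cpep_bin],
        gad = rep(c(0, 100), c(n_neg, cell$total - n_neg)),
        ia2 = 0, znt8 = 0
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  out$age_sampling <- out$age_onset + out$duration
  out$individual_id <- sprintf("fx_%05d", seq_len(nrow(out)))
  dplyr::relocate(out, "individual_id")
}

#' Bundled prevalence count fixtures
#'
#' Loads the per-cell counts shipped with the package: detectable
#' C-peptide by onset and duration (`"cpeptide"`) or
#' all-antibody-negative by duration and C-peptide range
#' (`"antibody"`), as published for a large Scottish type 1 diabetes
#' cohort.
#'
#' @param type `"cpeptide"` or `"antibody"`.
#' @return Tibble of counts suitable for
#'   [expand_prevalence_records()].
#' @export
prevalence_counts <- function(type = c("cpeptide", "antibody")) {
  type <- match.arg(type)
  file <- system.file(
    "extdata",
    if (type == "cpeptide") "cpeptide_prevalence_counts.tsv"
    else "antibody_negative_counts.tsv",
    package = "cpepgrs", mustWork = TRUE
  )
  readr::read_tsv(file, show_col_types = FALSE,
                  comment = "#")
}
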