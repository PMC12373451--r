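#' Reference education-class composition
#'
#' The published education-class counts of a 397,162-participant,
#' 38-country navigation-game cohort, used as a worked example for the
#' education-merge arithmetic: university 166,714 (42%), college 111,463
#' (28%), high-school 107,849 (27%), no formal 11,290 (3%).
#'
#' @return A tibble (`education4`, `n`) with attribute `total` holding the
#'   published cohort total (397,162; note the four class counts sum to
#'   397,316, a small bookkeeping discrepancy in the published table).
#' @examples
#' merged_education_counts(reference_education_counts())
#' @export
reference_education_counts <- function() {
  out <- tibble(
    education4 = factor(education4_levels(), levels = education4_levels()),
    n = c(166714L, 111463L, 107849L, 11290L)
  )
  attr(out, "total") <- 397162L
  out
}

#' Merge education-class counts into the two analysis classes
#'
#' Aggregates a 4-class count table into tertiary and secondary-and-lower
#' totals via [merge_education()], and reports each class's share of a
#' reference total as a percentage.
#'
#' @param counts Tibble (`education4`, `n`).
#' @param total Reference total for the percentage shares; defaults to the
#'   sum of the counts (or the table's `total` attribute when present).
#' @return A tibble (`education2`, `n`, `share_pct`).
#' @export
merged_education_counts <- function(counts, total = NULL) {
  check_columns(counts, c("education4", "n"), "`counts`")
  total <- total %||% attr(counts, "total") %||% sum(counts$n)
  counts |>
    mutate(education2 = merge_education(.data$education4)) |>
    group_by(.data$education2) |>
    summarise(n = sum(.data$n), .groups = "drop") |>
    mutate(share_pct = 100 * .data$n / total)
}
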