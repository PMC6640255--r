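# Yearly-total ranking, top-fraction cohort selection, concentration share,
# and the cohort's baseline monthly aggregates.

#' Yearly expenditure totals per beneficiary
#'
#' @param matrix a [monthly_spend_matrix()].
#' @return named double vector of integer cents, one entry per beneficiary.
#' @export
yearly_totals <- function(matrix) {
  rowSums(unclass(matrix))
}

#' Select the top-fraction high-cost cohort
#'
#' Beneficiaries are ranked by yearly total, highest first, and the first
#' `ceiling(fraction * N)` are taken. Ties at the cutoff are broken by
#' `tie_rule`: `"id"` (default) prefers the lexicographically smaller
#' beneficiary id among equal totals.
#'
#' `ceiling` is the rounding rule consistent with a 10% cut of a population
#' whose size is not a multiple of ten: 0.10 x 1,222,402 = 122,240.2 selects
#' 122,241 beneficiaries.
#'
#' @param totals named vector of yearly totals in cents (from [yearly_totals()]).
#' @param fraction proportion in (0, 1] (default 0.10, the top decile).
#' @param tie_rule `"id"` only at present; documented hook for alternatives.
#' @return a `cohort_selection` list: `cohort_ids` (in rank order),
#'   `fraction`, `cutoff_rank`, `cohort_yearly_total`,
#'   `population_yearly_total`, `n_population`.
#' @export
select_top_fraction <- function(totals, fraction = 0.10, tie_rule = c("id")) {
  tie_rule <- match.arg(tie_rule)
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction > 1) {
    stop("fraction must be a single value in (0, 1]", call. = FALSE)
  }
  if (!length(totals)) stop("totals must be non-empty", call. = FALSE)
  ids <- names(totals)
  if (is.null(ids)) stop("totals must be named by beneficiary id", call. = FALSE)
  n <- length(totals)
  k <- as.integer(ceiling(fraction * n))
  ord <- order(-totals, ids, method = "radix")
  cohort <- ids[ord[seq_len(k)]]
  structure(list(
    cohort_ids = cohort,
    fraction = fraction,
    cutoff_rank = k,
    cohort_yearly_total = sum(totals[cohort]),
    population_yearly_total = sum(totals),
    n_population = n
  ), class = "cohort_selection")
}

#' @export
print.cohort_selection <- function(x, ...) {
  cat(sprintf("<cohort_selection> top %.1f%%: n = %s of %s, $%.0fM of $%.0fM\n",
              100 * x$fraction, format(x$cutoff_rank, big.mark = ","),
              format(x$n_population, big.mark = ","),
              x$cohort_yearly_total / 1e8, x$population_yearly_total / 1e8))
  invisible(x)
}

#' Cohort share of population yearly spending
#'
#' @param selection a `cohort_selection` from [select_top_fraction()].
#' @return percentage (0..100) of population yearly spend held by the cohort.
#' @export
concentration_share <- function(selection) {
  if (selection$population_yearly_total <= 0) {
    stop("population yearly total must be positive", call. = FALSE)
  }
  100 * selection$cohort_yearly_total / selection$population_yearly_total
}

#' Baseline monthly spending series for a cohort
#'
#' Sums cohort spend per calendar month and summarizes the M monthly totals.
#' The standard-deviation convention is configurable: `"population"`
#' (divide by M, the default) or `"sample"` (divide by M-1).
#'
#' @param matrix a [monthly_spend_matrix()].
#' @param cohort_ids beneficiary ids (must all be rows of `matrix`).
#' @param sd_convention `"population"` or `"sample"`.
#' @return a `baseline_series` list: `monthly_totals` (cents, length M),
#'   `mean_monthly`, `sd_monthly`, `sd_convention`.
#' @export
baseline_monthly <- function(matrix, cohort_ids, sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  missing_ids <- setdiff(cohort_ids, rownames(matrix))
  if (length(missing_ids)) {
    stop("cohort ids not present in matrix: ", missing_ids[1], call. = FALSE)
  }
  sub <- unclass(matrix)[match(cohort_ids, rownames(matrix)), , drop = FALSE]
  totals <- colSums(sub)
  m <- length(totals)
  mu <- mean(totals)
  s <- if (m > 1) stats::sd(totals) else 0
  if (sd_convention == "population" && m > 1) s <- s * sqrt((m - 1) / m)
  structure(list(monthly_totals = unname(totals), mean_monthly = mu,
                 sd_monthly = s, sd_convention = sd_convention),
            class = "baseline_series")
}

#' @export
print.baseline_series <- function(x, ...) {
  cat(sprintf("<baseline_series> %d months, mean $%.1fM/month (SD $%.1fM, %s)\n",
              length(x$monthly_totals), x$mean_monthly / 1e8, x$sd_monthly / 1e8,
              x$sd_convention))
  invisible(x)
}

#' Concentration summary as a plain list for JSON export
#' @param selection a `cohort_selection`.
#' @param baseline a `baseline_series` for the cohort.
#' @return list ready for `jsonlite::write_json`.
#' @export
concentration_summary <- function(selection, baseline) {
  list(
    n_population = selection$n_population,
    n_cohort = selection$cutoff_rank,
    fraction = selection$fraction,
    cohort_total_cents = selection$cohort_yearly_total,
    population_total_cents = selection$population_yearly_total,
    share_pct = if (selection$population_yearly_total > 0) {
      concentration_share(selection)
    } else NA_real_,
    monthly_totals_cents = baseline$monthly_totals,
    mean_monthly_cents = baseline$mean_monthly,
    sd_monthly_cents = baseline$sd_monthly,
    sd_convention = baseline$sd_convention
  )
}

#' Reporting-precision helpers
#'
#' `round_half_up` rounds half away from zero (the convention used for all
#' printed figures); `report_millions` converts cents to nearest million
#' dollars; `report_pct` rounds a percentage to `digits` decimals.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @rdname round_half_up
#' @param cents amounts in integer cents.
#' @export
report_millions <- function(cents) round_half_up(cents / 1e8)

#' @rdname round_half_up
#' @export
report_pct <- function(x, digits = 0) round_half_up(x, digits)
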