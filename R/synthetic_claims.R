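# Seeded generator of beneficiary spending panels with the statistical
# structure the segmentation method assumes: heavy-tailed yearly totals
# (log-normal chronic levels), zero-utilization months, episodic acute
# spikes that create month-to-month migration, and decedent truncation
# (months after death are zero but the beneficiary stays in the denominator).

#' Configuration for the synthetic claims generator
#'
#' Monthly spend for beneficiary b in month m is
#' `chronic_b * noise_bm + spike_bm`, zeroed outright with probability
#' `zero_month_prob` (a zero-utilization month has no claims at all).
#' `chronic_b` is a log-normal per-beneficiary baseline (dollar scale),
#' `noise_bm` is log-normal month-to-month variation, and an independent
#' log-normal acute episode of cost `spike_bm` is added with probability
#' `spike_prob` per month. A fraction
#' `death_prob` of beneficiaries die in a uniform random month; their later
#' months are truncated to zero. Defaults were fixed once by the calibration
#' script in `scripts/calibrate_generator.R` so that the generated panels
#' reproduce the qualitative spending-concentration shape of aged Medicare
#' fee-for-service claims (top decile holding roughly 45-70% of yearly
#' spend).
#'
#' @param n_beneficiaries number of beneficiaries (>= 1).
#' @param months study period length M (default 12).
#' @param year calendar year stamped on generated claim dates.
#' @param chronic_log_mean,chronic_log_sd log-scale mean/sd of the
#'   per-beneficiary chronic monthly spend level, in dollars.
#' @param month_log_sd log-scale sd of within-beneficiary month-to-month
#'   noise (0 turns month noise off).
#' @param zero_month_prob probability a month has no routine utilization.
#' @param spike_prob per-month probability of an acute episode.
#' @param spike_log_mean,spike_log_sd log-scale parameters of episode cost,
#'   in dollars.
#' @param death_prob probability a beneficiary dies during the year.
#' @param claims_per_positive_month mean number of claim lines a positive
#'   month's total is split into (>= 1).
#' @param seed integer RNG seed; all generator output is a deterministic
#'   function of the config including the seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_beneficiaries = 1000L,
                             months = 12L,
                             year = 2012L,
                             chronic_log_mean = 5.5,
                             chronic_log_sd = 1.9,
                             month_log_sd = 1.2,
                             zero_month_prob = 0.15,
                             spike_prob = 0.08,
                             spike_log_mean = 9.0,
                             spike_log_sd = 1.0,
                             death_prob = 0.04,
                             claims_per_positive_month = 3,
                             seed = 1L) {
  cfg <- list(n_beneficiaries = as.integer(n_beneficiaries), months = as.integer(months),
              year = as.integer(year), chronic_log_mean = chronic_log_mean,
              chronic_log_sd = chronic_log_sd, month_log_sd = month_log_sd,
              zero_month_prob = zero_month_prob, spike_prob = spike_prob,
              spike_log_mean = spike_log_mean, spike_log_sd = spike_log_sd,
              death_prob = death_prob,
              claims_per_positive_month = claims_per_positive_month,
              seed = as.integer(seed))
  probs <- c(zero_month_prob = cfg$zero_month_prob, spike_prob = cfg$spike_prob,
             death_prob = cfg$death_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "), call. = FALSE)
  }
  if (cfg$n_beneficiaries < 1L) stop("n_beneficiaries must be >= 1", call. = FALSE)
  if (cfg$months < 1L) stop("months must be >= 1", call. = FALSE)
  if (any(c(cfg$chronic_log_sd, cfg$month_log_sd, cfg$spike_log_sd) < 0)) {
    stop("log-scale sd parameters must be non-negative", call. = FALSE)
  }
  if (cfg$claims_per_positive_month < 1) {
    stop("claims_per_positive_month must be >= 1", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic monthly spend matrix with eligibility records
#'
#' @param config a [generator_config()].
#' @return list with `matrix` (a [monthly_spend_matrix()]) and `eligibility`
#'   (a `data.table` with `beneficiary_id`, `age_eligible`,
#'   `continuously_enrolled`, `death_month`).
#' @export
generate_monthly_matrix <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_beneficiaries
  m <- config$months
  ids <- sprintf("B%06d", seq_len(n))

  chronic <- rlnorm(n, config$chronic_log_mean, config$chronic_log_sd)
  noise <- matrix(rlnorm(n * m, 0, config$month_log_sd), n, m)
  zeroed <- matrix(runif(n * m) < config$zero_month_prob, n, m)
  spiked <- matrix(runif(n * m) < config$spike_prob, n, m)
  spike_cost <- matrix(rlnorm(n * m, config$spike_log_mean, config$spike_log_sd), n, m)
  # a zeroed month has no utilization at all, episodes included
  dollars <- chronic * noise + spiked * spike_cost
  dollars[zeroed] <- 0

  dies <- runif(n) < config$death_prob
  death_month <- rep(NA_integer_, n)
  death_month[dies] <- sample.int(m, sum(dies), replace = TRUE)
  if (any(dies)) {
    after_death <- outer(ifelse(is.na(death_month), m + 1L, death_month),
                         seq_len(m), `<`)
    dollars[after_death] <- 0
  }

  cents <- floor(dollars * 100 + 0.5)
  rownames(cents) <- ids
  list(
    matrix = monthly_spend_matrix(cents, year = config$year),
    eligibility = data.table::data.table(
      beneficiary_id = ids, age_eligible = TRUE,
      continuously_enrolled = TRUE, death_month = death_month)
  )
}

#' Generate synthetic claim-level records
#'
#' Regenerates the monthly matrix for `config` and splits every positive
#' month's total into claim lines with through-dates inside that calendar
#' month. The split is cent-exact: claim amounts for a (beneficiary, month)
#' cell sum to the matrix cell, so rebuilding the matrix from the claims
#' reproduces it bit-exactly. The number of lines per positive month is
#' `1 + Poisson(claims_per_positive_month - 1)`; zero-cent fragments are
#' dropped, so every positive month keeps at least one claim.
#'
#' @param config a [generator_config()].
#' @return list with `claims` (a `data.table`: `beneficiary_id`,
#'   `claim_through_date`, `paid_cents`), `eligibility`, and `matrix` (the
#'   panel the claims were split from).
#' @export
generate_claims <- function(config) {
  gen <- generate_monthly_matrix(config)
  mat <- unclass(gen$matrix)
  pos <- which(mat > 0, arr.ind = TRUE)
  if (!nrow(pos)) {
    empty <- data.table::data.table(beneficiary_id = character(),
                                    claim_through_date = as.Date(character()),
                                    paid_cents = numeric())
    return(list(claims = empty, eligibility = gen$eligibility, matrix = gen$matrix))
  }
  cells <- data.table::data.table(
    row = pos[, 1], month = pos[, 2], cents = mat[pos],
    k = 1L + rpois(nrow(pos), config$claims_per_positive_month - 1)
  )
  cells[, cell := .I]
  parts <- cells[rep(cell, k), list(cell, month, cents)]
  parts[, w := runif(.N)]
  parts[, amt := {
    cum <- floor(cents[1] * cumsum(w) / sum(w) + 0.5)
    cum[length(cum)] <- cents[1]  # guard rounding at the top end
    diff(c(0, cum))
  }, by = cell]
  parts <- parts[amt > 0]
  dim_days <- days_in_month(config$year, seq_len(config$months))
  parts[, day := 1L + as.integer(floor(runif(.N) * dim_days[month]))]
  claims <- data.table::data.table(
    beneficiary_id = rownames(mat)[cells$row[parts$cell]],
    claim_through_date = as.Date(sprintf("%04d-%02d-%02d",
                                         config$year, parts$month, parts$day)),
    paid_cents = parts$amt
  )
  data.table::setorder(claims, beneficiary_id, claim_through_date)
  list(claims = claims, eligibility = gen$eligibility, matrix = gen$matrix)
}

days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  nxt <- as.Date(ifelse(month == 12L, sprintf("%04d-01-01", year + 1L),
                        sprintf("%04d-%02d-01", year, month + 1L)))
  as.integer(nxt - first)
}

#' Write claims / eligibility tables in the reader formats
#'
#' Claims are written with amounts in signed dollars with two decimals and
#' ISO-8601 dates; eligibility with `true`/`false` flags and an empty
#' `death_month` for survivors — exactly what [read_claims()] and
#' [read_eligibility()] consume.
#'
#' @param claims claims table with `paid_cents`.
#' @param eligibility eligibility table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path) {
  out <- data.table::data.table(
    beneficiary_id = claims$beneficiary_id,
    claim_through_date = format(claims$claim_through_date, "%Y-%m-%d"),
    paid_amount = sprintf("%.2f", claims$paid_cents / 100)
  )
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_claims
#' @export
write_eligibility <- function(eligibility, path) {
  out <- data.table::data.table(
    beneficiary_id = eligibility$beneficiary_id,
    age_eligible = ifelse(eligibility$age_eligible, "true", "false"),
    continuously_enrolled = ifelse(eligibility$continuously_enrolled, "true", "false"),
    death_month = ifelse(is.na(eligibility$death_month), "",
                         as.character(eligibility$death_month))
  )
  data.table::fwrite(out, path)
  invisible(path)
}
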