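#' @import data.table
#' @importFrom stats rbinom rlnorm rmultinom rpois runif sd setNames
#' @importFrom utils head
NULL

# Currency convention: all amounts are held internally as *integer cents*,
# stored in doubles (exact for |x| < 2^53; population-scale totals overflow
# 32-bit integers). Conversion to dollars happens only at reporting.

#' Assert a vector holds integer-valued cents
#' @noRd
stopifnot_cents <- function(x, what = "amount") {
  if (anyNA(x) || any(x != trunc(x))) {
    stop(sprintf("%s must be integer-valued cents without NAs", what), call. = FALSE)
  }
  invisible(x)
}

#' Parse dollar amounts to integer cents
#'
#' Accepts signed decimal dollar strings (e.g. `"-15.00"`, `"1200.5"`) or
#' numerics, and returns integer cents as a double vector. Rounding is
#' half-away-from-zero at the third decimal to absorb binary representation
#' noise in `0.01`-grain inputs.
#'
#' @param x character or numeric vector of dollar amounts.
#' @return double vector of integer cents.
#' @examples
#' dollars_to_cents(c("12.34", "-15.00"))
#' @export
dollars_to_cents <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  cents <- sign(v) * floor(abs(v) * 100 + 0.5)
  cents[v == 0] <- 0
  cents
}

#' Format integer cents as dollars
#' @param cents double vector of integer cents.
#' @return numeric dollars.
#' @export
cents_to_dollars <- function(cents) cents / 100

default_claims_dialect <- function() {
  list(beneficiary_id = "beneficiary_id",
       claim_through_date = "claim_through_date",
       paid_amount = "paid_amount")
}

default_eligibility_dialect <- function() {
  list(beneficiary_id = "beneficiary_id",
       age_eligible = "age_eligible",
       continuously_enrolled = "continuously_enrolled",
       death_month = "death_month")
}

#' Read a claim-level table
#'
#' Reads a delimited text file of paid claim lines into a claims table with
#' columns `beneficiary_id` (character), `claim_through_date` (Date) and
#' `paid_cents` (integer cents as double). The month a claim belongs to is
#' always derived from the claim-through date (the service-period end date),
#' never prorated across months.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect named list mapping the canonical column names
#'   (`beneficiary_id`, `claim_through_date`, `paid_amount`) to the column
#'   names used in the file. Unmapped names default to themselves.
#' @param sep field separator (default comma).
#' @return a `data.table` with one row per claim.
#' @export
read_claims <- function(path, dialect = list(), sep = ",") {
  if (!file.exists(path)) stop("claims file not found: ", path, call. = FALSE)
  dia <- utils::modifyList(default_claims_dialect(), dialect)
  dt <- data.table::fread(path, sep = sep, colClasses = "character",
                          header = TRUE, data.table = TRUE)
  for (col in unlist(dia)) {
    if (!col %in% names(dt)) {
      stop("claims file is missing required column: '", col, "'", call. = FALSE)
    }
  }
  out <- data.table::data.table(
    beneficiary_id = dt[[dia$beneficiary_id]],
    claim_through_date = as.Date(dt[[dia$claim_through_date]], format = "%Y-%m-%d"),
    paid_cents = dollars_to_cents(dt[[dia$paid_amount]])
  )
  bad_date <- which(is.na(out$claim_through_date))
  if (length(bad_date)) {
    stop(sprintf("unparseable claim_through_date at data row %d ('%s')",
                 bad_date[1], dt[[dia$claim_through_date]][bad_date[1]]), call. = FALSE)
  }
  bad_amt <- which(is.na(out$paid_cents))
  if (length(bad_amt)) {
    stop(sprintf("unparseable paid amount at data row %d ('%s')",
                 bad_amt[1], dt[[dia$paid_amount]][bad_amt[1]]), call. = FALSE)
  }
  if (any(!nzchar(out$beneficiary_id))) {
    stop("empty beneficiary_id in claims file", call. = FALSE)
  }
  out[]
}

#' Read an eligibility (denominator) table
#'
#' Eligibility is precomputed at the criterion level: age eligibility and
#' continuous enrollment arrive as booleans, and `death_month` (1..M, empty
#' for survivors) records the month of death for decedents, who stay in the
#' denominator all year.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect named list mapping canonical names (`beneficiary_id`,
#'   `age_eligible`, `continuously_enrolled`, `death_month`) to file columns.
#' @param months number of months M in the study period (default 12); a
#'   `death_month` outside 1..M is an error.
#' @param sep field separator.
#' @return a `data.table` with one row per beneficiary.
#' @export
read_eligibility <- function(path, dialect = list(), months = 12L, sep = ",") {
  if (!file.exists(path)) stop("eligibility file not found: ", path, call. = FALSE)
  dia <- utils::modifyList(default_eligibility_dialect(), dialect)
  dt <- data.table::fread(path, sep = sep, colClasses = "character",
                          header = TRUE, data.table = TRUE)
  for (col in unlist(dia)) {
    if (!col %in% names(dt)) {
      stop("eligibility file is missing required column: '", col, "'", call. = FALSE)
    }
  }
  parse_flag <- function(x) {
    v <- tolower(trimws(x))
    out <- rep(NA, length(v))
    out[v %in% c("true", "t", "1", "yes")] <- TRUE
    out[v %in% c("false", "f", "0", "no")] <- FALSE
    if (anyNA(out)) stop("unparseable boolean flag in eligibility file", call. = FALSE)
    out
  }
  dm_raw <- trimws(dt[[dia$death_month]])
  dm <- suppressWarnings(as.integer(dm_raw))
  dm[dm_raw == "" | toupper(dm_raw) == "NA"] <- NA_integer_
  if (any(!is.na(dm) & (dm < 1L | dm > months))) {
    stop("death_month outside 1..", months, " in eligibility file", call. = FALSE)
  }
  data.table::data.table(
    beneficiary_id = dt[[dia$beneficiary_id]],
    age_eligible = parse_flag(dt[[dia$age_eligible]]),
    continuously_enrolled = parse_flag(dt[[dia$continuously_enrolled]]),
    death_month = dm
  )[]
}

#' Select the initial study population
#'
#' Keeps beneficiaries who are age-eligible, continuously enrolled, and have
#' at least one claim in the study year; beneficiaries with no claims are
#' excluded. Decedents are retained (their enrollment flag covers the period
#' up to death). Claims whose id is absent from the eligibility table are
#' dropped with a warning.
#'
#' @param claims claims table from [read_claims()].
#' @param eligibility eligibility table from [read_eligibility()].
#' @return character vector of included beneficiary ids (sorted).
#' @export
filter_initial_population <- function(claims, eligibility) {
  unknown <- setdiff(unique(claims$beneficiary_id), eligibility$beneficiary_id)
  if (length(unknown)) {
    warning(length(unknown), " claimant id(s) absent from eligibility table; excluded (e.g. '",
            unknown[1], "')", call. = FALSE)
  }
  eligible <- eligibility[eligibility$age_eligible & eligibility$continuously_enrolled, ]
  has_claim <- unique(claims$beneficiary_id)
  sort(intersect(eligible$beneficiary_id, has_claim))
}

#' Construct a monthly spend matrix
#'
#' The central structure of the method: an `n x M` matrix of integer cents,
#' rows named by beneficiary id, one column per calendar month. Months with
#' no claims are zero-filled so every beneficiary has a defined value for
#' every month.
#'
#' @param values numeric matrix of integer cents (rows = beneficiaries,
#'   columns = months), with row names set to beneficiary ids.
#' @param year study year recorded as metadata (may be `NA`).
#' @return a `monthly_spend_matrix` object.
#' @export
monthly_spend_matrix <- function(values, year = NA_integer_) {
  ids <- rownames(values)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop("values must carry unique, non-empty beneficiary ids as rownames", call. = FALSE)
  }
  stopifnot_cents(values, "spend matrix")
  storage.mode(values) <- "double"
  colnames(values) <- paste0("m", seq_len(ncol(values)))
  structure(values, year = as.integer(year), class = c("monthly_spend_matrix", "matrix", "array"))
}

#' @export
print.monthly_spend_matrix <- function(x, ...) {
  cat(sprintf("<monthly_spend_matrix> %d beneficiaries x %d months, total $%.2f\n",
              nrow(x), ncol(x), sum(x) / 100))
  invisible(x)
}

#' Number of months in a monthly spend matrix
#' @param matrix a `monthly_spend_matrix`.
#' @return integer M.
#' @export
n_months <- function(matrix) ncol(matrix)

#' Build the monthly spend matrix from claims
#'
#' Sums `paid_cents` per (beneficiary, calendar month of claim-through date)
#' for beneficiaries in `population`; claims for ids outside the population
#' are ignored. Every population member gets a row even with no claims, and
#' months without claims are zero. A claim dated outside `year` signals a
#' wrong-year extract and is a hard error.
#'
#' @param claims claims table from [read_claims()].
#' @param population character vector of included beneficiary ids.
#' @param months number of months M (default 12).
#' @param year study year; claims must fall within it.
#' @return a [monthly_spend_matrix()].
#' @export
build_monthly_matrix <- function(claims, population, months = 12L, year = 2012L) {
  population <- sort(unique(as.character(population)))
  mat <- matrix(0, nrow = length(population), ncol = months,
                dimnames = list(population, paste0("m", seq_len(months))))
  keep <- claims[claims$beneficiary_id %in% population, ]
  if (nrow(keep)) {
    yr <- as.integer(format(keep$claim_through_date, "%Y"))
    if (any(yr != year)) {
      stop("claim dated outside study year ", year, ": ",
           keep$claim_through_date[which(yr != year)[1]], call. = FALSE)
    }
    mo <- as.integer(format(keep$claim_through_date, "%m"))
    if (any(mo > months)) {
      stop("claim month ", max(mo), " exceeds study period of ", months, " months", call. = FALSE)
    }
    agg <- keep[, list(cents = sum(paid_cents)), by = list(beneficiary_id, month = mo)]
    mat[cbind(match(agg$beneficiary_id, population), agg$month)] <- agg$cents
  }
  monthly_spend_matrix(mat, year = year)
}

#' Write / read a monthly spend matrix
#'
#' The delimited export has one row per beneficiary with columns
#' `beneficiary_id, m1..mM` in integer cents, plus a JSON sidecar
#' (`<path>.json`) recording `{year, M, n_beneficiaries, total_cents}`.
#' Re-reading the export reproduces the matrix bit-exactly.
#'
#' @param matrix a `monthly_spend_matrix`.
#' @param path output path for the delimited table.
#' @return `path`, invisibly.
#' @export
write_monthly_matrix <- function(matrix, path) {
  dt <- data.table::data.table(beneficiary_id = rownames(matrix))
  for (j in seq_len(ncol(matrix))) dt[[paste0("m", j)]] <- matrix[, j]
  data.table::fwrite(dt, path)
  meta <- list(year = attr(matrix, "year"), M = ncol(matrix),
               n_beneficiaries = nrow(matrix), total_cents = sum(matrix))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_monthly_matrix
#' @export
read_monthly_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  meta_path <- paste0(path, ".json")
  year <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)$year else NA_integer_
  vals <- as.matrix(dt[, -1])
  rownames(vals) <- as.character(dt$beneficiary_id)
  monthly_spend_matrix(vals, year = if (is.null(year)) NA_integer_ else year)
}
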