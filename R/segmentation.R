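# The core of the method: per-beneficiary spending-order index assignment
# (1 = that beneficiary's highest-spend month, unique even under ties) and
# aggregation into month x index segment grids of spend and headcount.

#' Assign spending-order indices to one beneficiary's months
#'
#' Returns a permutation of 1..M where index 1 marks the highest-spend month.
#' Ties (including runs of zero-spend months) are broken deterministically:
#' under the default `"chronological"` rule the earlier calendar month gets
#' the smaller index; `"reverse"` gives the later month the smaller index.
#'
#' @param monthly_spend numeric vector of M integer cents.
#' @param tie_rule `"chronological"` (default) or `"reverse"`.
#' @return integer vector of length M; element m is month m's index.
#' @examples
#' assign_spending_order(c(500, 0, 700))   # c(2, 3, 1)
#' assign_spending_order(c(3, 9, 9, 1))    # c(3, 1, 2, 4)
#' @export
assign_spending_order <- function(monthly_spend, tie_rule = c("chronological", "reverse")) {
  tie_rule <- match.arg(tie_rule)
  m <- length(monthly_spend)
  months <- seq_len(m)
  o <- if (tie_rule == "chronological") {
    order(-monthly_spend, months, method = "radix")
  } else {
    order(-monthly_spend, -months, method = "radix")
  }
  idx <- integer(m)
  idx[o] <- months
  idx
}

#' Assign spending orders for a whole cohort
#'
#' @param matrix a [monthly_spend_matrix()].
#' @param cohort_ids beneficiary ids to assign (default: all rows).
#' @param tie_rule see [assign_spending_order()].
#' @return an `order_assignment`: integer matrix (rows = beneficiaries,
#'   columns = months, entries = spending-order index), with the tie rule
#'   recorded as an attribute.
#' @export
assign_orders <- function(matrix, cohort_ids = rownames(matrix),
                          tie_rule = c("chronological", "reverse")) {
  tie_rule <- match.arg(tie_rule)
  missing_ids <- setdiff(cohort_ids, rownames(matrix))
  if (length(missing_ids)) {
    stop("ids not present in matrix: ", missing_ids[1], call. = FALSE)
  }
  sub <- unclass(matrix)[match(cohort_ids, rownames(matrix)), , drop = FALSE]
  orders <- t(apply(sub, 1, assign_spending_order, tie_rule = tie_rule))
  if (ncol(sub) == 1L) orders <- matrix(orders, ncol = 1L, dimnames = list(cohort_ids, NULL))
  dimnames(orders) <- list(cohort_ids, paste0("m", seq_len(ncol(sub))))
  structure(orders, tie_rule = tie_rule, class = c("order_assignment", "matrix", "array"))
}

#' @export
print.order_assignment <- function(x, ...) {
  cat(sprintf("<order_assignment> %d beneficiaries x %d months (tie rule: %s)\n",
              nrow(x), ncol(x), attr(x, "tie_rule")))
  invisible(x)
}

new_segment_grid <- function(cells, kind, tie_rule = NULL) {
  m <- ncol(cells)
  dimnames(cells) <- list(index = paste0("i", seq_len(nrow(cells))),
                          month = paste0("m", seq_len(m)))
  structure(cells, kind = kind, tie_rule = tie_rule,
            class = c("segment_grid", "matrix", "array"))
}

#' @export
print.segment_grid <- function(x, ...) {
  cat(sprintf("<segment_grid:%s> %d indices x %d months\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

check_orders_cover <- function(orders, cohort_ids) {
  missing_ids <- setdiff(cohort_ids, rownames(orders))
  if (length(missing_ids)) {
    stop("no order assignment for cohort member: ", missing_ids[1], call. = FALSE)
  }
}

#' Aggregate cohort spend into the month x index segment grid
#'
#' Cell (k, m) is the total spend, in cents, of cohort members whose month-m
#' spending-order index is k. Column sums reproduce the cohort's baseline
#' monthly totals exactly. With M = 12 this is the 144-cell spend grid.
#'
#' @param matrix a [monthly_spend_matrix()].
#' @param orders an [assign_orders()] result covering `cohort_ids`.
#' @param cohort_ids beneficiary ids to aggregate (default: all order rows).
#' @return a `segment_grid` of kind `"spend"` (rows = index, cols = month).
#' @export
segment_spend <- function(matrix, orders, cohort_ids = rownames(orders)) {
  check_orders_cover(orders, cohort_ids)
  m <- ncol(orders)
  spend <- unclass(matrix)[match(cohort_ids, rownames(matrix)), , drop = FALSE]
  ord <- unclass(orders)[match(cohort_ids, rownames(orders)), , drop = FALSE]
  cells <- matrix(0, nrow = m, ncol = m)
  for (mo in seq_len(m)) {
    if (nrow(ord)) {
      sums <- rowsum(spend[, mo], group = ord[, mo])
      cells[as.integer(rownames(sums)), mo] <- sums[, 1]
    }
  }
  new_segment_grid(cells, "spend", attr(orders, "tie_rule"))
}

#' Aggregate cohort headcounts into the month x index segment grid
#'
#' Cell (k, m) is the number of cohort members holding index k in month m.
#' Every column sums to the cohort size (each beneficiary holds exactly one
#' index per month).
#'
#' @inheritParams segment_spend
#' @return a `segment_grid` of kind `"count"`.
#' @export
segment_counts <- function(orders, cohort_ids = rownames(orders)) {
  check_orders_cover(orders, cohort_ids)
  m <- ncol(orders)
  ord <- unclass(orders)[match(cohort_ids, rownames(orders)), , drop = FALSE]
  cells <- matrix(0, nrow = m, ncol = m)
  for (mo in seq_len(m)) {
    cells[, mo] <- tabulate(ord[, mo], nbins = m)
  }
  new_segment_grid(cells, "count", attr(orders, "tie_rule"))
}

#' Per-index summary of a segment grid
#'
#' For each spending-order index, the mean and standard deviation of its
#' cell values across months, plus its percentage share of the grid's mean
#' monthly column total (for a spend grid, the share of mean baseline
#' monthly spend; for a count grid, the share of the cohort).
#'
#' @param grid a `segment_grid`.
#' @param sd_convention `"population"` (divide by M) or `"sample"`.
#' @return a `data.frame` with columns `index`, `mean`, `sd`, `share_pct`.
#' @export
segment_summary <- function(grid, sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  g <- unclass(grid)
  m <- ncol(g)
  means <- rowMeans(g)
  sds <- apply(g, 1, function(r) if (m > 1) stats::sd(r) else 0)
  if (sd_convention == "population" && m > 1) sds <- sds * sqrt((m - 1) / m)
  mean_col_total <- mean(colSums(g))
  share <- if (mean_col_total > 0) 100 * means / mean_col_total else rep(NA_real_, m)
  data.frame(index = seq_len(nrow(g)), mean = unname(means), sd = unname(sds),
             share_pct = unname(share))
}

#' Write / read a segment grid
#'
#' Delimited export with rows = index 1..M and columns = month 1..M (spend in
#' cents), plus a JSON metadata sidecar `{kind, tie_rule, M, n_cohort}`.
#'
#' @param grid a `segment_grid`.
#' @param path output path.
#' @param n_cohort cohort size recorded in the metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_segment_grid <- function(grid, path, n_cohort = NA_integer_) {
  dt <- data.table::data.table(index = seq_len(nrow(grid)))
  for (j in seq_len(ncol(grid))) dt[[paste0("m", j)]] <- unclass(grid)[, j]
  data.table::fwrite(dt, path)
  meta <- list(kind = attr(grid, "kind"),
               tie_rule = attr(grid, "tie_rule"),
               M = ncol(grid), n_cohort = n_cohort)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_segment_grid
#' @export
read_segment_grid <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list(kind = "spend")
  cells <- as.matrix(dt[, -1])
  new_segment_grid(unname(cells), meta$kind,
                   if (!is.null(meta$tie_rule)) meta$tie_rule else NULL)
}

#' Long-format export of spend and count grids
#'
#' One row per (month, index) with both spend and count — the layout plotting
#' tools expect for stacked-column figures.
#'
#' @param spend_grid a spend `segment_grid`.
#' @param count_grid a count `segment_grid` on the same cohort.
#' @return a `data.table` with columns `month`, `index`, `spend_cents`, `count`.
#' @export
grids_to_long <- function(spend_grid, count_grid) {
  m <- ncol(spend_grid)
  data.table::data.table(
    month = rep(seq_len(m), each = m),
    index = rep(seq_len(m), times = m),
    spend_cents = as.vector(unclass(spend_grid)),
    count = as.vector(unclass(count_grid))
  )
}
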