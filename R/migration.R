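# Subgroup isolation and migration tracking: the beneficiaries holding the
# highest spending-order index (1) in a chosen anchor month, decomposed into
# per-subgroup occupancy layers of the full segment grids.

#' Isolate the highest-segment subgroup for an anchor month
#'
#' Members are exactly the beneficiaries whose spending-order index in
#' `anchor_month` is 1 — i.e. the anchor month is their own highest-spend
#' month. Empty subgroups are legal in tiny or degenerate cohorts.
#'
#' @param orders an [assign_orders()] result.
#' @param anchor_month month in 1..M.
#' @return a `subgroup` list: `anchor_month`, `member_ids`.
#' @export
isolate_top_subgroup <- function(orders, anchor_month) {
  m <- ncol(orders)
  if (!is.numeric(anchor_month) || length(anchor_month) != 1L ||
      anchor_month < 1 || anchor_month > m || anchor_month != trunc(anchor_month)) {
    stop("anchor_month must be an integer in 1..", m, call. = FALSE)
  }
  members <- rownames(orders)[unclass(orders)[, anchor_month] == 1L]
  structure(list(anchor_month = as.integer(anchor_month), member_ids = members),
            class = "subgroup")
}

#' @export
print.subgroup <- function(x, ...) {
  cat(sprintf("<subgroup> anchor month %d, %d member(s)\n",
              x$anchor_month, length(x$member_ids)))
  invisible(x)
}

#' Occupancy of one subgroup throughout the segment grids
#'
#' Recomputes the count and spend grids over subgroup members only. By
#' construction the subgroup fully occupies cell (1, anchor_month), occupies
#' no other cell of the anchor month, never reappears at index 1 in any
#' other month, and its monthly headcount is constant all year.
#'
#' @param subgroup a [isolate_top_subgroup()] result.
#' @param matrix a [monthly_spend_matrix()].
#' @param orders an [assign_orders()] result covering the members.
#' @return an `occupancy_grid` list: `anchor_month`, `n_members`, `counts`
#'   (count `segment_grid`), `spend` (spend `segment_grid`).
#' @export
subgroup_occupancy <- function(subgroup, matrix, orders) {
  ids <- subgroup$member_ids
  missing_ids <- setdiff(ids, rownames(matrix))
  if (length(missing_ids)) {
    stop("subgroup member not in matrix: ", missing_ids[1], call. = FALSE)
  }
  check_orders_cover(orders, ids)
  structure(list(
    anchor_month = subgroup$anchor_month,
    n_members = length(ids),
    counts = segment_counts(orders, ids),
    spend = segment_spend(matrix, orders, ids)
  ), class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("<occupancy_grid> anchor month %d, %d member(s)\n",
              x$anchor_month, x$n_members))
  invisible(x)
}

#' Occupancy grids for every anchor month
#'
#' One subgroup per month; because every beneficiary has exactly one index-1
#' month, the M subgroups are pairwise disjoint and their union is the whole
#' cohort, and the occupancy grids sum cell-wise to the full grids.
#'
#' @inheritParams subgroup_occupancy
#' @return list of M `occupancy_grid`s, one per anchor month.
#' @export
all_subgroup_occupancy <- function(matrix, orders) {
  lapply(seq_len(ncol(orders)), function(mo) {
    subgroup_occupancy(isolate_top_subgroup(orders, mo), matrix, orders)
  })
}

#' Migration summary across anchor subgroups
#'
#' For each anchor month: the subgroup's share of the cohort (percent), its
#' share of that month's baseline spend (percent), and its total monthly
#' spend trajectory across the year. With near-uniform index-1 counts each
#' subgroup holds about 100/M percent of the cohort.
#'
#' @param spend_grid the full spend `segment_grid`.
#' @param count_grid the full count `segment_grid`.
#' @param occupancy list of `occupancy_grid`s from [all_subgroup_occupancy()].
#' @return a `migration_summary` list: `n_cohort`, a `per_anchor` data.frame
#'   (`anchor_month`, `n_members`, `share_of_cohort_pct`,
#'   `share_of_anchor_month_spend_pct`) and `trajectories`, an M x M matrix
#'   (rows = anchor subgroup, cols = month) of subgroup monthly spend totals
#'   in cents.
#' @export
migration_summary <- function(spend_grid, count_grid, occupancy) {
  m <- ncol(spend_grid)
  n_cohort <- sum(unclass(count_grid)[, 1])
  baseline <- colSums(unclass(spend_grid))
  per <- data.frame(
    anchor_month = vapply(occupancy, function(o) o$anchor_month, integer(1)),
    n_members = vapply(occupancy, function(o) o$n_members, numeric(1))
  )
  per$share_of_cohort_pct <- if (n_cohort > 0) 100 * per$n_members / n_cohort else NA_real_
  anchor_spend <- vapply(occupancy, function(o) {
    sum(unclass(o$spend)[, o$anchor_month])
  }, numeric(1))
  per$share_of_anchor_month_spend_pct <- ifelse(
    baseline[per$anchor_month] > 0,
    100 * anchor_spend / baseline[per$anchor_month], NA_real_)
  traj <- do.call(rbind, lapply(occupancy, function(o) colSums(unclass(o$spend))))
  dimnames(traj) <- list(paste0("anchor", per$anchor_month), paste0("m", seq_len(m)))
  structure(list(n_cohort = n_cohort, per_anchor = per, trajectories = traj),
            class = "migration_summary")
}

#' @export
print.migration_summary <- function(x, ...) {
  cat(sprintf("<migration_summary> cohort n = %s, %d anchor subgroups\n",
              format(x$n_cohort, big.mark = ","), nrow(x$per_anchor)))
  print(x$per_anchor)
  invisible(x)
}

#' Long-format export of all occupancy grids
#'
#' @param occupancy list of `occupancy_grid`s.
#' @return `data.table` with columns `anchor_month`, `month`, `index`,
#'   `count`, `spend_cents`.
#' @export
occupancy_to_long <- function(occupancy) {
  data.table::rbindlist(lapply(occupancy, function(o) {
    m <- ncol(o$counts)
    data.table::data.table(
      anchor_month = o$anchor_month,
      month = rep(seq_len(m), each = m),
      index = rep(seq_len(m), times = m),
      count = as.vector(unclass(o$counts)),
      spend_cents = as.vector(unclass(o$spend))
    )
  }))
}
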