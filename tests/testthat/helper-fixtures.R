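# Fixtures are built in code at test time; no binary data ships with the
# package.

# Two-beneficiary toy panel (dollars 5/0/7 and 2/3/1 over three months).
# Hand-worked reference values for this panel appear throughout the suite.
toy_matrix <- function() {
  vals <- rbind(A = c(500, 0, 700), B = c(200, 300, 100))
  monthly_spend_matrix(vals, year = 2012L)
}

write_toy_claims <- function(dir) {
  claims_path <- file.path(dir, "claims.csv")
  writeLines(c(
    "beneficiary_id,claim_through_date,paid_amount",
    "A,2012-01-03,50.00",
    "A,2012-01-29,30.00",
    "A,2012-03-01,20.00",
    "B,2012-02-10,100.00",
    "B,2012-02-20,-40.00"
  ), claims_path)
  elig_path <- file.path(dir, "eligibility.csv")
  writeLines(c(
    "beneficiary_id,age_eligible,continuously_enrolled,death_month",
    "A,true,true,",
    "B,true,true,",
    "C,true,true,6",
    "D,false,true,",
    "E,true,false,"
  ), elig_path)
  list(claims = claims_path, eligibility = elig_path)
}

# ---- Independent oracles (deliberately different algorithms from R/) ----

# Spending-order assignment by repeated argmax selection: pick the largest
# remaining value (earliest month on ties under the chronological rule,
# latest under "reverse") and hand out indices 1, 2, ... in turn.
oracle_order <- function(spend, tie_rule = "chronological") {
  m <- length(spend)
  idx <- integer(m)
  remaining <- seq_len(m)
  for (k in seq_len(m)) {
    vals <- spend[remaining]
    best <- remaining[vals == max(vals)]
    pick <- if (tie_rule == "chronological") min(best) else max(best)
    idx[pick] <- k
    remaining <- setdiff(remaining, pick)
  }
  idx
}

# Segment grids by explicit triple loops over (beneficiary, month, index).
oracle_grids <- function(spend_matrix, tie_rule = "chronological") {
  n <- nrow(spend_matrix)
  m <- ncol(spend_matrix)
  orders <- t(apply(spend_matrix, 1, oracle_order, tie_rule = tie_rule))
  if (m == 1L) orders <- matrix(orders, ncol = 1L)
  spend <- matrix(0, m, m)
  count <- matrix(0, m, m)
  for (b in seq_len(n)) {
    for (mo in seq_len(m)) {
      k <- orders[b, mo]
      spend[k, mo] <- spend[k, mo] + spend_matrix[b, mo]
      count[k, mo] <- count[k, mo] + 1
    }
  }
  list(spend = spend, count = count, orders = orders)
}

random_panel <- function(n, m, seed, max_cents = 1000L, zero_prob = 0.3) {
  set.seed(seed)
  vals <- matrix(ifelse(runif(n * m) < zero_prob, 0,
                        sample.int(max_cents, n * m, replace = TRUE)), n, m)
  rownames(vals) <- sprintf("S%03d", seq_len(n))
  monthly_spend_matrix(vals)
}
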