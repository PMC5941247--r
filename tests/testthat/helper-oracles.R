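# shared evaluation date: the packaged worked-example record sets are
# anchored here
EVAL_DATE <- as.Date("2018-06-01")

mk_assertions <- function(sig, dates, cat = "criteria_provided") {
  ct_assertions(significance = sig, last_evaluated = as.Date(dates),
                submitter_category = cat)
}

# brute-force raw-score oracle: plain loops, no shared code with the
# implementation's pooled/vectorized path
oracle_ctrs <- function(assertions, eval_date) {
  total <- 0
  for (i in seq_len(nrow(assertions))) {
    cat_i <- assertions$submitter_category[i]
    sig_i <- assertions$significance[i]
    date_i <- assertions$last_evaluated[i]
    if (!cat_i %in% c("practice_guideline", "expert_panel",
                      "criteria_provided")) next
    if (is.na(sig_i) || !sig_i %in% c("B", "LB", "US", "LP", "P")) next
    if (is.na(date_i)) next
    x <- c(B = -6, LB = -3, US = -0.3, LP = 3, P = 6)[[sig_i]]
    days <- as.numeric(eval_date - date_i)
    yrs <- floor(max(days, 0) / 365.25)
    d <- if (yrs < 2) 1 else if (yrs <= 6) (11 - yrs) / 10 else 0.5
    s <- switch(cat_i, practice_guideline = 1.25, expert_panel = 1.10,
                criteria_provided = 1.00)
    total <- total + x * d * s
  }
  total
}

# direct sorted-indexing prediction-interval oracle
oracle_pi <- function(values, alpha) {
  v <- sort(values)
  n <- length(v)
  ck <- trunc(alpha / 2 * (n + 1))
  c(v[ck], v[n - ck + 1])
}

# scale-walking reclassification oracle: step one position at a time and
# count zone-boundary transitions
oracle_ctrr <- function(cvcs, ctps) {
  ord <- c(B = 1, BLB = 2, LB = 3, US = 4, CI = 4, LP = 5, PLP = 6, P = 7)
  zone <- function(p) if (p <= 3) "benign" else if (p == 4) "uncertain" else "pathogenic"
  a <- ord[[cvcs]]; b <- ord[[ctps]]
  points <- 0
  while (a != b) {
    nxt <- a + sign(b - a)
    points <- points + 1
    if (zone(nxt) != zone(a)) points <- points + 1
    a <- nxt
  }
  min(points, 3)
}

# random assertion tables, including invalid/incomplete ones
random_assertions <- function(n) {
  sigs <- sample(c("B", "LB", "US", "LP", "P", "not provided", NA), n,
                 replace = TRUE)
  dates <- EVAL_DATE - sample(c(0:4000, NA), n, replace = TRUE)
  cats <- sample(ct_submitter_categories(), n, replace = TRUE)
  ct_assertions(significance = sigs, last_evaluated = dates,
                submitter_category = cats)
}
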