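#' Fixed lower bound of a predicted-significance range
#'
#' The bound of each class range nearer zero is not data-driven: it is fixed
#' at \code{2 * (assertion weight) * 0.7 * 1.0}, the minimum score a variant
#' can hold while meeting the two-star criterion (two concordant
#' criteria-provided assertions, neither more than five years old, so each
#' carries at least the 0.7 age factor). The uncertain class has no fixed
#' bound: its range is simply what lies between the LB and LP bounds.
#'
#' @param sig one of `"B"`, `"LB"`, `"LP"`, `"P"`.
#' @param constants a [ct_constants()] object.
#' @return The fixed bound (signed; negative for benign classes).
#' @examples
#' ct_fixed_lower_bound("LP")  # 4.2
#' ct_fixed_lower_bound("P")   # 8.4
#' @export
ct_fixed_lower_bound <- function(sig, constants = ct_constants()) {
  sig <- match.arg(sig, ct_significance_levels())
  if (sig == "US") {
    stop("the uncertain-significance class has no fixed lower bound",
         call. = FALSE)
  }
  2 * ct_assertion_weight(sig, constants) * 0.7 * 1.0
}

#' Non-parametric prediction interval from order statistics
#'
#' For a sample of size \eqn{n} the two-sided prediction interval at
#' confidence \eqn{1 - \alpha} is the pair of order statistics at ranks
#' \eqn{c = \mathrm{trunc}(\alpha/2 \times (n + 1))} and
#' \eqn{r = n - c + 1} (1-based). Appropriate for the markedly non-normal,
#' outlier-skewed score distributions the calibration works with.
#'
#' @param values numeric sample (sorted ascending; unsorted input is sorted).
#' @param alpha miscoverage probability in (0, 1).
#' @return Named numeric vector `c(low = , high = )`.
#' @examples
#' ct_prediction_interval(1:199, alpha = 0.05)  # ranks 5 and 195
#' @export
ct_prediction_interval <- function(values, alpha) {
  stopifnot(length(values) >= 2, alpha > 0, alpha < 1)
  values <- sort(values)
  n <- length(values)
  c_rank <- trunc(alpha / 2 * (n + 1))
  if (c_rank < 1) {
    stop("sample too small for a prediction interval at confidence ",
         format(1 - alpha), " (rank c < 1)", call. = FALSE)
  }
  r_rank <- n - c_rank + 1
  c(low = values[c_rank], high = values[r_rank])
}

#' Assemble per-class calibration score sets from two-star records
#'
#' Applies the three control-set filters: records must (i) carry exactly two
#' stars, (ii) have an unambiguous Mendelian overall significance (the
#' combined PLP/BLB categories cannot be placed in a single class and are
#' excluded, as are CI and non-Mendelian records), and (iii) hold at least
#' two valid clinical assertions. Raw scores of the survivors are grouped by
#' overall significance.
#'
#' @param records a `ct_records` tibble.
#' @param evaluation_date `Date` at which assertion ages are measured.
#' @param constants a [ct_constants()] object.
#' @return Named list of numeric score vectors, one per class present.
#' @export
ct_calibration_set <- function(records, evaluation_date = Sys.Date(),
                               constants = ct_constants()) {
  sc <- ct_record_scores(records, evaluation_date, constants)
  keep <- records$stars == 2L &
    records$cvcs %in% ct_significance_levels() &
    sc$cvna >= 2L
  split(sc$ctrs[keep],
        factor(records$cvcs[keep], levels = ct_significance_levels()),
        drop = TRUE)
}

#' Select the prediction-interval confidence aligned to the fixed bound
#'
#' Scans a descending grid of confidences and keeps the highest one whose
#' interval endpoint nearer zero does not cross the class's fixed lower bound
#' toward zero; that endpoint is then clamped onto the fixed bound, so the
#' shipped range boundary is exactly the two-star minimum. The uncertain
#' class, having no fixed bound, gets the highest confidence computable for
#' its sample size.
#'
#' @param values numeric vector of class scores.
#' @param sig the class label (`"B"`, `"LB"`, `"US"`, `"LP"`, `"P"`).
#' @param grid descending numeric vector of candidate confidences in (0, 1).
#' @param constants a [ct_constants()] object.
#' @return One-row tibble: `significance`, `n`, `median`, `pi_low`,
#'   `pi_high`, `confidence_pct`.
#' @export
ct_select_confidence <- function(values, sig,
                                 grid = ct_confidence_grid(),
                                 constants = ct_constants()) {
  stopifnot(length(values) > 0)
  if (length(grid) == 0) stop("empty confidence grid", call. = FALSE)
  grid <- sort(grid, decreasing = TRUE)
  sig <- match.arg(sig, ct_significance_levels())
  bound <- if (sig == "US") NA_real_ else ct_fixed_lower_bound(sig, constants)
  for (conf in grid) {
    pi <- tryCatch(ct_prediction_interval(values, alpha = 1 - conf),
                   error = function(e) NULL)
    if (is.null(pi)) next
    ok <- if (sig == "US") {
      TRUE
    } else if (sig %in% c("LP", "P")) {
      pi[["low"]] >= bound   # zero-side endpoint must not dip below the bound
    } else {
      pi[["high"]] <= bound  # benign mirror: must not rise above the bound
    }
    if (ok) {
      if (sig %in% c("LP", "P")) pi[["low"]] <- bound
      if (sig %in% c("B", "LB")) pi[["high"]] <- bound
      return(tibble(
        significance = sig, n = length(values),
        median = stats::median(values),
        pi_low = pi[["low"]], pi_high = pi[["high"]],
        confidence_pct = 100 * conf
      ))
    }
  }
  stop("no confidence in the grid aligns with the fixed lower bound for ",
       sig, call. = FALSE)
}

#' @rdname ct_select_confidence
#' @export
ct_confidence_grid <- function() {
  c(0.999, 0.998, 0.995, 0.99, 0.98, 0.96, 0.95, 0.90)
}

#' Build the seven predicted-significance score ranges
#'
#' From the four calibrated class prediction intervals (B, LB, LP, P) the
#' real line is partitioned into seven contiguous ranges. The combined
#' categories are the overlaps of adjacent intervals: BLB is the overlap of
#' the B and LB intervals, PLP that of LP and P. Scores beyond the outermost
#' interval endpoints still classify as B or P -- however far outside the
#' calibration distribution a score falls, the prediction is unchanged.
#' Boundary ownership: the overlap ranges are closed; LB and LP include
#' their fixed bound nearer zero; the uncertain range is open on both sides.
#'
#' @param stats a tibble of per-class interval rows as produced by
#'   [ct_select_confidence()] (rows for B, LB, LP, P required).
#' @return A `ct_ranges` tibble: `label`, `lower`, `upper`, `lower_closed`,
#'   `upper_closed`, ordered benign to pathogenic.
#' @examples
#' ct_default_ranges()
#' @export
ct_build_ranges <- function(stats) {
  need <- c("B", "LB", "LP", "P")
  if (!all(need %in% stats$significance)) {
    stop("calibration stats must cover classes B, LB, LP and P",
         call. = FALSE)
  }
  g <- function(sig, col) stats[[col]][match(sig, stats$significance)]
  b_hi <- g("B", "pi_high"); lb_lo <- g("LB", "pi_low")
  lb_hi <- g("LB", "pi_high"); lp_lo <- g("LP", "pi_low")
  lp_hi <- g("LP", "pi_high"); p_lo <- g("P", "pi_low")
  if (!(lb_lo <= b_hi && b_hi <= lb_hi && lb_hi < lp_lo &&
        lp_lo <= p_lo && p_lo <= lp_hi)) {
    stop("class prediction intervals do not overlap in the required order; ",
         "cannot form contiguous ranges", call. = FALSE)
  }
  out <- tibble(
    label = c("B", "BLB", "LB", "US", "LP", "PLP", "P"),
    lower = c(-Inf, lb_lo, b_hi, lb_hi, lp_lo, p_lo, lp_hi),
    upper = c(lb_lo, b_hi, lb_hi, lp_lo, p_lo, lp_hi, Inf),
    lower_closed = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    upper_closed = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  )
  class(out) <- unique(c("ct_ranges", class(out)))
  out
}

#' Calibrate predicted-significance ranges from a record set
#'
#' Convenience pipeline: [ct_calibration_set()] then [ct_select_confidence()]
#' per class. The result carries the per-class interval table; pass it to
#' [ct_build_ranges()] (or use `autoplot()`) downstream.
#'
#' @inheritParams ct_calibration_set
#' @param grid descending confidence grid (see [ct_select_confidence()]).
#' @return A `ct_calibration` tibble: one row per class with `n`, `median`,
#'   interval bounds and selected confidence.
#' @export
ct_calibrate <- function(records, evaluation_date = Sys.Date(),
                         grid = ct_confidence_grid(),
                         constants = ct_constants()) {
  sets <- ct_calibration_set(records, evaluation_date, constants)
  out <- purrr::imap(sets, function(v, sig) {
    ct_select_confidence(v, sig, grid = grid, constants = constants)
  })
  out <- dplyr::bind_rows(out)
  out <- out[order(match(out$significance, ct_significance_levels())), ]
  class(out) <- unique(c("ct_calibration", class(out)))
  out
}

#' Packaged default calibration and score ranges
#'
#' `ct_default_calibration()` returns the shipped per-class control
#' statistics (sample sizes, medians, prediction-interval bounds and
#' confidences for the five Mendelian classes, derived from two-star ClinVar
#' control distributions); `ct_default_ranges()` builds the seven score
#' ranges from them. With the defaults the ranges are: B below -26.7;
#' BLB \[-26.7, -8.4\]; LB (-8.4, -4.2\]; US (-4.2, 4.2); LP \[4.2, 8.4);
#' PLP \[8.4, 14.7\]; P above 14.7.
#'
#' @return A `ct_calibration` tibble / a `ct_ranges` tibble.
#' @examples
#' ct_default_ranges()
#' @export
ct_default_calibration <- function() {
  path <- system.file("extdata", "calibration_default.tsv",
                      package = "clinotatr", mustWork = TRUE)
  ct_read_calibration(path)
}

#' @rdname ct_default_calibration
#' @export
ct_default_ranges <- function() {
  ct_build_ranges(ct_default_calibration())
}

#' Read or write a calibration table
#'
#' Calibration constants are stored as a plain tab-separated table with
#' columns `significance`, `n`, `median`, `pi_low`, `pi_high`,
#' `confidence_pct`, so a recalibration can be saved and passed back to the
#' scoring run.
#'
#' @param path file path.
#' @return `ct_read_calibration()` returns a `ct_calibration` tibble;
#'   `ct_write_calibration()` returns `path` invisibly.
#' @export
ct_read_calibration <- function(path) {
  out <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("significance", "n", "median", "pi_low", "pi_high",
            "confidence_pct")
  if (!all(need %in% names(out))) {
    stop("calibration table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- as_tibble(out[need])
  class(out) <- unique(c("ct_calibration", class(out)))
  out
}

#' @rdname ct_read_calibration
#' @param calibration a `ct_calibration` tibble.
#' @export
ct_write_calibration <- function(calibration, path) {
  utils::write.table(calibration, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
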