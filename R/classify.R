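#' Columns of the metrics table
#'
#' The annotation output carries nine ClinVar-derived fields and the four
#' computed metrics plus `vcf_match`, in this fixed order.
#'
#' @return Character vector of the 14 column names.
#' @export
ct_metrics_columns <- function() {
  c("VID", "rsID", "CVCS", "CVSZ", "CVNA", "CVDS", "CVAL", "CVLE", "CVVT",
    "CTRS", "CTAA", "CTPS", "CTRR", "vcf_match")
}

#' Predicted significance of a raw score
#'
#' Locates each score within the calibrated ranges. A prediction is only
#' meaningful when the record holds at least two valid clinical assertions;
#' below that the result is `NA`.
#'
#' @param ctrs numeric vector of raw scores.
#' @param n_valid integer vector of valid-assertion counts (recycled).
#' @param ranges a `ct_ranges` tibble ([ct_default_ranges()]).
#' @return Character vector of range labels, `NA` where `n_valid < 2`.
#' @examples
#' ct_assign_ctps(c(24.903, 8.4, 0), c(6, 2, 1))
#' @export
ct_assign_ctps <- function(ctrs, n_valid, ranges = ct_default_ranges()) {
  n_valid <- rep_len(n_valid, length(ctrs))
  out <- vapply(ctrs, function(x) {
    if (is.na(x)) return(NA_character_)
    hit <- (ranges$lower < x | (ranges$lower_closed & ranges$lower == x)) &
           (x < ranges$upper | (ranges$upper_closed & ranges$upper == x))
    if (sum(hit) != 1L) {
      stop("score ", x, " matches ", sum(hit), " ranges; ranges must ",
           "partition the line", call. = FALSE)
    }
    ranges$label[hit]
  }, character(1))
  out[is.na(n_valid) | n_valid < 2L] <- NA_character_
  out
}

#' Significance zone of an overall label
#'
#' The seven-position scale divides into three zones: all-benign (B, BLB,
#' LB), uncertain (US and CI), and all-pathogenic (LP, PLP, P). Zone
#' crossings carry an extra reclassification point.
#'
#' @param sig character vector of overall-significance labels.
#' @return Character vector `"benign"` / `"uncertain"` / `"pathogenic"`,
#'   `NA` for unmapped labels.
#' @examples
#' ct_zone(c("BLB", "CI", "PLP"))
#' @export
ct_zone <- function(sig) {
  ord <- ct_ordinal(sig)
  dplyr::case_when(
    ord <= 3 ~ "benign",
    ord == 4 ~ "uncertain",
    ord >= 5 ~ "pathogenic"
  )
}

#' Reclassification recommendation rank
#'
#' The rank measures the disagreement between the reported overall
#' significance (CVCS) and the predicted one (CTPS) on the seven-position
#' scale: one point per position shifted, one extra point per zone boundary
#' crossed (benign | uncertain | pathogenic), capped at three. CI is scored
#' at the uncertain position. Ranks run 0 (consistent) to 3 (high priority
#' for reclassification). The rank is `NA` when the prediction is missing or
#' the reported significance is outside the scale (a warning is raised for
#' the latter).
#'
#' @param cvcs character vector of reported overall significances.
#' @param ctps character vector of predicted significances (recycled).
#' @return Integer vector of ranks 0-3, `NA` where undefined.
#' @examples
#' ct_reclassification("CI", "PLP")  # 3: two steps + one zone crossing
#' ct_reclassification("LB", "B")    # 2: two steps within the benign zone
#' ct_reclassification("US", "US")   # 0
#' @export
ct_reclassification <- function(cvcs, ctps) {
  n <- max(length(cvcs), length(ctps))
  cvcs <- rep_len(as.character(cvcs), n)
  ctps <- rep_len(as.character(ctps), n)
  a <- ct_ordinal(cvcs)
  b <- ct_ordinal(ctps)
  unmapped <- is.na(a) & !is.na(cvcs) & !is.na(ctps)
  if (any(unmapped)) {
    warning("overall significance not on the reclassification scale: ",
            paste(unique(cvcs[unmapped]), collapse = ", "), call. = FALSE)
  }
  steps <- abs(a - b)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  # zone boundaries sit between positions 3|4 and 4|5
  crossings <- (lo <= 3 & hi >= 4) + (lo <= 4 & hi >= 5)
  as.integer(pmin(3L, steps + crossings))
}

#' Annotate variation records with the full metrics table
#'
#' Computes, for every record, the valid-assertion count (CVNA), raw score
#' (CTRS), mean assertion age (CTAA), predicted significance (CTPS) and
#' reclassification rank (CTRR), alongside the ClinVar-derived fields. CTPS
#' and CTRR are `NA` whenever fewer than two valid assertions exist; CTRR is
#' additionally `NA` for records whose overall significance is not on the
#' Mendelian scale (e.g. drug-response records). `vcf_match` pairs each
#' rsID with the record's alleles and flags haplotypes.
#'
#' @param records a `ct_records` tibble.
#' @param ranges a `ct_ranges` tibble ([ct_default_ranges()]).
#' @param evaluation_date `Date` at which assertion ages are measured
#'   (defaults to the run date).
#' @param constants a [ct_constants()] object.
#' @return A `ct_metrics` tibble with the 14 columns of
#'   [ct_metrics_columns()], one row per record.
#' @examples
#' rec <- ct_record("18011", rsids = "121909551", cvcs = "CI", stars = 1,
#'                  alt_alleles = "T",
#'                  assertions = ct_assertions(
#'                    c("P", "P"), as.Date(c("2016-06-14", "2018-01-19")),
#'                    "criteria_provided"))
#' ct_annotate(rec, evaluation_date = as.Date("2018-06-01"))
#' @export
ct_annotate <- function(records, ranges = ct_default_ranges(),
                        evaluation_date = Sys.Date(),
                        constants = ct_constants()) {
  n <- nrow(records)
  sc <- ct_record_scores(records, evaluation_date, constants)
  cvna <- sc$cvna; ctrs <- sc$ctrs; ctaa <- sc$ctaa
  ctps <- ct_assign_ctps(ctrs, cvna, ranges)
  ctrr <- suppressWarnings(ct_reclassification(records$cvcs, ctps))
  join <- function(xs) {
    vapply(xs, function(x) {
      if (length(x) == 0) NA_character_ else paste(x, collapse = "|")
    }, character(1))
  }
  vcf_match <- purrr::pmap_chr(
    list(records$rsids, records$alt_alleles, records$variant_type),
    function(rs, al, vt) {
      if (length(rs) == 0) return(NA_character_)
      tag <- paste0("rs", rs, collapse = "|")
      al_tag <- if (length(al) > 0) paste(al, collapse = "|") else "."
      paste0(tag, ":", al_tag, if (identical(vt, "Haplotype")) ":Haplotype")
    })
  out <- tibble(
    VID = records$vid,
    rsID = join(records$rsids),
    CVCS = records$cvcs,
    CVSZ = records$stars,
    CVNA = cvna,
    CVDS = join(records$conditions),
    CVAL = join(records$alt_alleles),
    CVLE = records$cv_last_evaluated,
    CVVT = records$variant_type,
    CTRS = ctrs,
    CTAA = ctaa,
    CTPS = ctps,
    CTRR = ctrr,
    vcf_match = vcf_match
  )
  attr(out, "evaluation_date") <- as.Date(evaluation_date)
  class(out) <- unique(c("ct_metrics", class(out)))
  out
}

# vectorized per-record CVNA/CTRS/CTAA: assertions are pooled into one long
# table so large record sets score in a single pass
ct_record_scores <- function(records, evaluation_date = Sys.Date(),
                             constants = ct_constants()) {
  n <- nrow(records)
  n_assert <- purrr::map_int(records$assertions, nrow)
  cvna <- rep(0L, n); ctrs <- rep(0, n); ctaa <- rep(NA_real_, n)
  if (sum(n_assert) > 0) {
    terms <- ct_assertion_terms(dplyr::bind_rows(records$assertions),
                                evaluation_date, constants)
    rec <- rep(seq_len(n), n_assert)
    cvna <- as.integer(rowsum_fill(as.integer(terms$valid), rec, n))
    ctrs <- rowsum_fill(terms$contribution, rec, n)
    age_sum <- rowsum_fill(ifelse(terms$valid, terms$age_years, 0), rec, n)
    ctaa <- ifelse(cvna > 0, age_sum / cvna, NA_real_)
  }
  tibble(cvna = cvna, ctrs = ctrs, ctaa = ctaa)
}

rowsum_fill <- function(x, group, n) {
  out <- rep(0, n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
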