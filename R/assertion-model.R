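#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

#' Controlled vocabularies for clinical significance and submitter category
#'
#' The scoring model recognises the five ACMG/AMP descriptors of Mendelian
#' disorders for individual assertions, an eight-label overall-significance
#' scale for variation records (the five descriptors plus the combined
#' categories BLB and PLP and the conflicting-interpretations status CI), and
#' five submitter expertise categories mirroring ClinVar's review-status
#' tiers.
#'
#' @return Character vectors of the recognised labels, in ordinal order where
#'   an order exists (`B < LB < US < LP < P`).
#' @examples
#' ct_significance_levels()
#' ct_overall_levels()
#' @export
ct_significance_levels <- function() c("B", "LB", "US", "LP", "P")

#' @rdname ct_significance_levels
#' @export
ct_overall_levels <- function() c("B", "BLB", "LB", "US", "CI", "LP", "PLP", "P")

#' @rdname ct_significance_levels
#' @export
ct_submitter_categories <- function() {
  c("practice_guideline", "expert_panel", "criteria_provided",
    "no_criteria", "literature_only")
}

# ordinal positions on the 7-position reclassification scale; CI shares the
# uncertain position with US
.ct_ordinal <- c(B = 1, BLB = 2, LB = 3, US = 4, CI = 4, LP = 5, PLP = 6, P = 7)

#' Ordinal position of an overall significance on the reclassification scale
#'
#' The seven-position scale runs B, BLB, LB, US/CI, LP, PLP, P (positions 1
#' through 7); CI (conflicting interpretations) is scored at the uncertain
#' position 4. Labels outside the scale (e.g. "drug response") map to `NA`.
#'
#' @param sig character vector of overall-significance labels.
#' @return Integer vector of positions 1-7, `NA` for unmapped labels.
#' @examples
#' ct_ordinal(c("B", "CI", "P", "risk factor"))
#' @export
ct_ordinal <- function(sig) {
  out <- unname(.ct_ordinal[as.character(sig)])
  as.integer(out)
}

#' Build a tibble of clinical assertions
#'
#' One row per assertion: the unit the raw score sums over. Vectors are
#' recycled to a common length.
#'
#' @param significance assertion significance label (`"B"`, `"LB"`, `"US"`,
#'   `"LP"`, `"P"`), or `NA` when the submitter supplied none.
#' @param last_evaluated `Date` (or string coercible to one) the assertion was
#'   last evaluated; `NA` when blank in the source record.
#' @param submitter_category one of [ct_submitter_categories()].
#' @param submitter_name free-text submitter name.
#' @param conditions list of character vectors of associated conditions.
#' @return A tibble with one row per assertion.
#' @examples
#' ct_assertions(c("P", "US"), c("2016-09-16", NA), "criteria_provided")
#' @export
ct_assertions <- function(significance = character(),
                          last_evaluated = as.Date(character()),
                          submitter_category = character(),
                          submitter_name = NA_character_,
                          conditions = list(character())) {
  n <- max(length(significance), length(last_evaluated),
           length(submitter_category))
  if (n == 0L) {
    return(tibble(
      significance = character(), last_evaluated = as.Date(character()),
      submitter_category = character(), submitter_name = character(),
      conditions = list()
    ))
  }
  bad <- setdiff(unique(stats::na.omit(as.character(submitter_category))),
                 ct_submitter_categories())
  if (length(bad) > 0) {
    stop("unknown submitter category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble(
    significance = rep_len(as.character(significance), n),
    last_evaluated = rep_len(as.Date(last_evaluated), n),
    submitter_category = rep_len(as.character(submitter_category), n),
    submitter_name = rep_len(as.character(submitter_name), n),
    conditions = rep_len(as.list(conditions), n)
  )
}

#' Is a clinical assertion valid for scoring?
#'
#' An assertion enters the raw score only when all three conditions hold: the
#' submitter has published assertion criteria (category practice guideline,
#' expert panel or criteria provided -- literature-only submissions such as
#' OMIM reviews are evidence, not clinical assertions), the significance is
#' one of the five Mendelian descriptors, and a last-evaluated date is
#' present. Incomplete assertions are omitted because their reliability is
#' unknown.
#'
#' @param assertions a tibble as built by [ct_assertions()].
#' @return Logical vector, one element per assertion row.
#' @examples
#' a <- ct_assertions(c("P", "P", "US"),
#'                    as.Date(c("2016-09-16", "2007-01-05", NA)),
#'                    c("criteria_provided", "literature_only",
#'                      "criteria_provided"))
#' ct_is_valid_assertion(a)
#' @export
ct_is_valid_assertion <- function(assertions) {
  assertions$submitter_category %in%
    c("practice_guideline", "expert_panel", "criteria_provided") &
    assertions$significance %in% ct_significance_levels() &
    !is.na(assertions$significance) &
    !is.na(assertions$last_evaluated)
}

#' Build a table of variation records
#'
#' A variation record mirrors a ClinVar variation report: identifiers, the
#' overall (aggregate) clinical significance, the review-status star rating,
#' alleles, and the list of per-submitter clinical assertions. Records are
#' held as a tibble with one row per record; multi-valued fields (`rsids`,
#' `alt_alleles`, `conditions`, `assertions`) are list-columns.
#'
#' Non-Mendelian overall significances (e.g. `"drug response"`) are carried
#' as opaque text: such records still receive a raw score and mean assertion
#' age but no predicted significance or reclassification rank.
#'
#' @param vid ClinVar Variation ID (coerced to character).
#' @param rsids list of character vectors of dbSNP rsIDs (digits only, no
#'   `"rs"` prefix).
#' @param cvcs overall clinical significance label (see
#'   [ct_overall_levels()]), or free text for non-Mendelian records.
#' @param stars integer review-status star rating, 0-4.
#' @param variant_type `"Simple"` (single allele ID) or `"Haplotype"`
#'   (several).
#' @param alt_alleles list of character vectors of alternate alleles.
#' @param conditions list of character vectors of record-level conditions.
#' @param cv_last_evaluated `Date` the overall significance was last
#'   evaluated, or `NA`.
#' @param assertions list of assertion tibbles (see [ct_assertions()]).
#' @return A `ct_records` tibble, one row per variation record.
#' @examples
#' ct_record(
#'   vid = "10768", rsids = "199473684", cvcs = "CI", stars = 1,
#'   alt_alleles = "A",
#'   assertions = ct_assertions(c("P", "P"),
#'                              as.Date(c("2014-10-07", "2018-01-02")),
#'                              "criteria_provided")
#' )
#' @export
ct_record <- function(vid, rsids = character(), cvcs = NA_character_,
                      stars = 0L, variant_type = NULL,
                      alt_alleles = character(), conditions = character(),
                      cv_last_evaluated = as.Date(NA),
                      assertions = ct_assertions()) {
  stars <- as.integer(stars)
  if (is.na(stars) || stars < 0L || stars > 4L) {
    stop("stars must be an integer in [0, 4]", call. = FALSE)
  }
  variant_type <- variant_type %||%
    if (length(alt_alleles) > 1L) "Haplotype" else "Simple"
  out <- tibble(
    vid = as.character(vid),
    rsids = list(as.character(rsids)),
    cvcs = as.character(cvcs),
    stars = stars,
    variant_type = variant_type,
    alt_alleles = list(as.character(alt_alleles)),
    conditions = list(as.character(conditions)),
    cv_last_evaluated = as.Date(cv_last_evaluated),
    assertions = list(assertions)
  )
  new_ct_records(out)
}

new_ct_records <- function(x) {
  class(x) <- unique(c("ct_records", class(x)))
  x
}

#' @rdname ct_record
#' @param ... one-row `ct_records` tibbles (or lists of them) to combine.
#' @export
ct_records <- function(...) {
  recs <- list(...)
  recs <- unlist(lapply(recs, function(x) if (is.data.frame(x)) list(x) else x),
                 recursive = FALSE)
  new_ct_records(dplyr::bind_rows(recs))
}
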