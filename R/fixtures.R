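#' Packaged worked-example record sets
#'
#' Two small record sets ship with the package as JSON-lines fixtures:
#'
#' * `"threestar"` -- ten three-star uncertain-significance variants whose
#'   criteria-based assertions (the first from an expert panel, the rest
#'   from criteria-providing clinical laboratories) point firmly to the
#'   pathogenic family; classic candidates for reclassification
#'   prioritization.
#' * `"conflicting"` -- sixteen one-star conflicting-interpretation (CI)
#'   variants holding exactly two criteria-driven assertions each, plus the
#'   older criteria-less or literature-only submissions that caused the
#'   conflict (those are invalid for scoring).
#'
#' Assertion significances, dates and submitter tiers are the documented
#' values for these ClinVar variation IDs; alternate alleles and the
#' matching VCF are synthetic placeholders for exercising allele matching.
#' Assertion ages for these sets are anchored at the evaluation date
#' 2018-06-01.
#'
#' @param which `"threestar"` or `"conflicting"`.
#' @return A `ct_records` tibble ([ct_example_records()]); the path to a
#'   three-site VCF whose ID column carries fixture rsIDs
#'   ([ct_example_vcf()]).
#' @examples
#' recs <- ct_example_records("conflicting")
#' ct_annotate(recs, evaluation_date = as.Date("2018-06-01"))
#' @export
ct_example_records <- function(which = c("threestar", "conflicting")) {
  which <- match.arg(which)
  file <- switch(which, threestar = "threestar_records.jsonl",
                 conflicting = "conflicting_records.jsonl")
  ct_read_records(system.file("extdata", file, package = "clinotatr",
                              mustWork = TRUE))
}

#' @rdname ct_example_records
#' @export
ct_example_vcf <- function() {
  system.file("extdata", "synthetic_example.vcf", package = "clinotatr",
              mustWork = TRUE)
}
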