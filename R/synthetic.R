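#' Generate synthetic variation records
#'
#' Draws variation records with controllable statistical structure for
#' calibration experiments and property tests. Each record gets a true
#' Mendelian class; its assertions carry that class's significance (possibly
#' perturbed one step by label noise), gamma-distributed ages and sampled
#' submitter categories. Overall significance and stars are then assigned
#' the way ClinVar would: records whose assertions span more than one zone
#' become CI with one star; concordant records with at least two valid
#' assertions get two stars and either their single shared label or the
#' combined PLP/BLB label when full and "likely" calls mix within a zone.
#'
#' Defaults mirror the reported census of multiply-asserted ClinVar
#' variants: about 3.3 +/- 1.9 assertions per record (clamped to at least
#' two) and assertion ages around 1.5 +/- 0.9 years. The class mix follows
#' the relative sizes of the five two-star control groups.
#'
#' @param n_records number of records.
#' @param class_mix named proportions over the five Mendelian classes.
#' @param assertion_mean,assertion_sd mean and sd of the per-record
#'   assertion count (rounded, clamped to >= 2).
#' @param age_mean,age_sd mean and sd in years of assertion ages
#'   (gamma-distributed).
#' @param submitter_mix named proportions over submitter categories.
#' @param label_noise probability an assertion's significance deviates one
#'   step from the record's true class.
#' @param evaluation_date `Date` ages are anchored to (assertion dates are
#'   generated backwards from it).
#' @param seed integer; fully determines the output.
#' @return A `ct_records` tibble with an extra `true_class` column.
#' @examples
#' ct_generate_records(3, seed = 1)
#' @export
ct_generate_records <- function(n_records,
                                class_mix = c(B = 0.17, LB = 0.19, US = 0.50,
                                              LP = 0.02, P = 0.12),
                                assertion_mean = 3.3, assertion_sd = 1.9,
                                age_mean = 1.5, age_sd = 0.9,
                                submitter_mix = c(criteria_provided = 0.95,
                                                  expert_panel = 0.03,
                                                  no_criteria = 0.02),
                                label_noise = 0,
                                evaluation_date = Sys.Date(),
                                seed = NULL) {
  stopifnot(n_records >= 0, label_noise >= 0, label_noise <= 1,
            all(names(class_mix) %in% ct_significance_levels()),
            all(names(submitter_mix) %in% ct_submitter_categories()))
  if (n_records == 0) {
    out <- ct_records_empty()
    out$true_class <- character()
    return(out)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  lv <- ct_significance_levels()
  evaluation_date <- as.Date(evaluation_date)
  true_class <- sample(names(class_mix), n_records, replace = TRUE,
                       prob = class_mix)
  k <- pmax(2L, as.integer(round(stats::rnorm(n_records, assertion_mean,
                                              assertion_sd))))
  total <- sum(k)
  rec_of <- rep(seq_len(n_records), k)
  # one-step label noise on the five-level scale, clamped at the ends
  pos <- match(true_class, lv)[rec_of]
  bump <- stats::rbinom(total, 1, label_noise) *
    sign(stats::runif(total) - 0.5)
  pos <- pmin(pmax(pos + bump, 1L), 5L)
  shape <- (age_mean / age_sd)^2
  rate <- age_mean / age_sd^2
  ages <- stats::rgamma(total, shape = shape, rate = rate)
  dates <- evaluation_date - round(ages * 365.25)
  cats <- sample(names(submitter_mix), total, replace = TRUE,
                 prob = submitter_mix)
  bases <- c("A", "C", "G", "T")
  alts <- bases[(seq_len(n_records) - 1L) %% 4L + 1L]

  a_tbl <- tibble(
    significance = lv[pos], last_evaluated = dates,
    submitter_category = cats,
    submitter_name = paste0("synthetic_lab_", rec_of),
    conditions = rep(list(character()), total)
  )
  valid <- ct_is_valid_assertion(a_tbl)
  zone_of <- function(s) {
    ifelse(s %in% c("B", "LB"), "benign",
           ifelse(s %in% c("LP", "P"), "pathogenic", "uncertain"))
  }
  per_rec <- lapply(split(seq_len(total), rec_of), function(ix) {
    sig <- a_tbl$significance[ix][valid[ix]]
    zones <- unique(zone_of(sig))
    n_valid <- length(sig)
    if (length(zones) > 1) {
      list(cvcs = "CI", stars = 1L)
    } else if (n_valid >= 2) {
      u <- unique(sig)
      cvcs <- if (length(u) == 1) u else if (all(u %in% c("P", "LP"))) {
        "PLP"
      } else if (all(u %in% c("B", "LB"))) "BLB" else u[1]
      list(cvcs = cvcs, stars = 2L)
    } else {
      list(cvcs = if (n_valid == 1) sig else NA_character_, stars = 1L)
    }
  })
  a_split <- split(a_tbl, factor(rec_of, levels = seq_len(n_records)))
  out <- tibble(
    vid = sprintf("S%06d", seq_len(n_records)),
    rsids = as.list(as.character(900000000 + seq_len(n_records))),
    cvcs = unname(purrr::map_chr(per_rec, "cvcs")),
    stars = unname(purrr::map_int(per_rec, "stars")),
    variant_type = "Simple",
    alt_alleles = as.list(alts),
    conditions = rep(list(character()), n_records),
    cv_last_evaluated = as.Date(rep(NA_character_, n_records)),
    assertions = unname(a_split),
    true_class = true_class
  )
  new_ct_records(out)
}
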