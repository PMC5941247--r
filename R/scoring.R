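#' Scoring constants for the raw score
#'
#' The raw score (CTRS) of a variation record is the sum, over its valid
#' clinical assertions, of three multiplicative factors:
#' \deqn{CTRS = \sum_i x_i d_i s_i}
#' where \eqn{x_i} is the assertion-significance weight, \eqn{d_i} an
#' age-decay factor and \eqn{s_i} a submitter-expertise factor.
#'
#' Defaults: weights B = -6, LB = -3, US = -0.3, LP = +3, P = +6 (the full
#' categories are twice their "likely" counterparts, so an assertion aged past
#' the decay limit is effectively downgraded one tier); no age penalty for the
#' first two years, then a 10% reduction per year through year six, then a
#' static 50%; submitter factors 1.25 for practice guidelines, 1.10 for
#' expert panels, 1.00 for ordinary criteria-providing submitters, and 0
#' otherwise (which is what makes criteria-less assertions score nothing).
#'
#' @param assertion_weights named numeric vector of significance weights.
#' @param age_grace_years years with no age penalty.
#' @param age_floor_factor terminal decay factor.
#' @param submitter_factors named numeric vector of submitter-category
#'   factors; missing categories default to 0.
#' @return A list of class `ct_constants`.
#' @examples
#' ct_constants()
#' @export
ct_constants <- function(assertion_weights = c(B = -6, LB = -3, US = -0.3,
                                               LP = 3, P = 6),
                         age_grace_years = 2,
                         age_floor_factor = 0.5,
                         submitter_factors = c(practice_guideline = 1.25,
                                               expert_panel = 1.10,
                                               criteria_provided = 1.00)) {
  stopifnot(setequal(names(assertion_weights), ct_significance_levels()),
            all(submitter_factors >= 0),
            age_floor_factor >= 0, age_floor_factor <= 1)
  structure(
    list(assertion_weights = assertion_weights,
         age_grace_years = age_grace_years,
         age_floor_factor = age_floor_factor,
         submitter_factors = submitter_factors),
    class = "ct_constants"
  )
}

#' Per-assertion weight factors
#'
#' `ct_assertion_weight()` returns the significance weight \eqn{x_i};
#' `ct_age_years()` the floored whole-year age of an assertion at the
#' evaluation date (`floor(days / 365.25)`, negative spans clamped to 0 with
#' a warning); `ct_age_factor()` the decay factor \eqn{d_i} (1 below 2
#' years, \eqn{(11 - n)/10} for 2-6 years, 0.5 past 6);
#' `ct_submitter_factor()` the expertise factor \eqn{s_i}.
#'
#' @param sig character vector of the five significance labels.
#' @param constants a [ct_constants()] object.
#' @return Numeric (or integer, for `ct_age_years()`) vector.
#' @examples
#' ct_assertion_weight(c("B", "US", "P"))
#' ct_age_factor(0:8)
#' @export
ct_assertion_weight <- function(sig, constants = ct_constants()) {
  sig <- as.character(sig)
  bad <- !sig %in% names(constants$assertion_weights)
  if (any(bad)) {
    stop("invalid assertion significance: ",
         paste(unique(sig[bad]), collapse = ", "), call. = FALSE)
  }
  unname(constants$assertion_weights[sig])
}

#' @rdname ct_assertion_weight
#' @param last_evaluated `Date` vector of assertion last-evaluated dates.
#' @param evaluation_date the `Date` ages are measured at (assertion ages are
#'   computed at run time by default).
#' @export
ct_age_years <- function(last_evaluated, evaluation_date = Sys.Date()) {
  days <- as.numeric(as.Date(evaluation_date)) - as.numeric(as.Date(last_evaluated))
  if (any(days < 0, na.rm = TRUE)) {
    warning("assertion dated after the evaluation date; age clamped to 0",
            call. = FALSE)
    days <- pmax(days, 0)
  }
  as.integer(floor(days / 365.25))
}

#' @rdname ct_assertion_weight
#' @param n integer vector of assertion ages in whole years.
#' @export
ct_age_factor <- function(n, constants = ct_constants()) {
  stopifnot(all(n >= 0, na.rm = TRUE))
  dplyr::case_when(
    n < constants$age_grace_years ~ 1,
    n <= 6 ~ (11 - n) / 10,
    TRUE ~ constants$age_floor_factor
  )
}

#' @rdname ct_assertion_weight
#' @param category character vector of submitter categories.
#' @export
ct_submitter_factor <- function(category, constants = ct_constants()) {
  out <- unname(constants$submitter_factors[as.character(category)])
  out[is.na(out)] <- 0
  out
}

# per-assertion contribution table: one row per assertion with validity flag,
# age and the three factors. The workhorse behind CTRS/CTAA/CVNA.
ct_assertion_terms <- function(assertions, evaluation_date = Sys.Date(),
                               constants = ct_constants()) {
  valid <- ct_is_valid_assertion(assertions)
  age <- rep(NA_integer_, nrow(assertions))
  age[valid] <- ct_age_years(assertions$last_evaluated[valid], evaluation_date)
  weight <- rep(NA_real_, nrow(assertions))
  weight[valid] <- ct_assertion_weight(assertions$significance[valid], constants)
  dfac <- rep(NA_real_, nrow(assertions))
  dfac[valid] <- ct_age_factor(age[valid], constants)
  sfac <- ct_submitter_factor(assertions$submitter_category, constants)
  dplyr::mutate(assertions, valid = valid, age_years = age,
                weight = weight, age_factor = dfac, submitter_factor = sfac,
                contribution = ifelse(valid, weight * dfac * sfac, 0))
}

#' Raw score, mean assertion age and valid-assertion count
#'
#' `ct_score()` computes the raw score (CTRS): the sum over valid assertions
#' of significance weight x age factor x submitter factor; 0 when no
#' assertion is valid. `ct_assertion_age()` computes the mean age in whole
#' years of the valid assertions (CTAA); `NA` when none is valid.
#' `ct_count_valid()` counts the valid assertions (CVNA).
#'
#' @param assertions an assertion tibble ([ct_assertions()]).
#' @param evaluation_date `Date` at which assertion ages are measured.
#' @param constants a [ct_constants()] object.
#' @return A single numeric (`ct_score`, `ct_assertion_age`) or integer
#'   (`ct_count_valid`).
#' @examples
#' a <- ct_assertions(c("P", "P"), as.Date(c("2014-10-07", "2018-01-02")),
#'                    "criteria_provided")
#' ct_score(a, evaluation_date = as.Date("2018-06-01"))   # 10.8
#' ct_assertion_age(a, evaluation_date = as.Date("2018-06-01"))
#' @export
ct_score <- function(assertions, evaluation_date = Sys.Date(),
                     constants = ct_constants()) {
  terms <- ct_assertion_terms(assertions, evaluation_date, constants)
  sum(terms$contribution)
}

#' @rdname ct_score
#' @export
ct_assertion_age <- function(assertions, evaluation_date = Sys.Date(),
                             constants = ct_constants()) {
  terms <- ct_assertion_terms(assertions, evaluation_date, constants)
  if (!any(terms$valid)) return(NA_real_)
  mean(terms$age_years[terms$valid])
}

#' @rdname ct_score
#' @export
ct_count_valid <- function(assertions) {
  sum(ct_is_valid_assertion(assertions))
}
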