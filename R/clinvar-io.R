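#' Read a plain-text identifier list
#'
#' One identifier per line, in order; duplicates are preserved (batch
#' semantics depend on it). Blank lines are skipped with a warning, as is an
#' entirely empty file.
#'
#' @param path path to a text file.
#' @param kind `"vid"` (ClinVar Variation IDs) or `"rsid"` (dbSNP rsIDs;
#'   a leading `"rs"` prefix is tolerated and stripped).
#' @return A tibble with columns `kind` and `id`.
#' @export
ct_read_id_list <- function(path, kind = c("vid", "rsid")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("cannot read id list: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  blanks <- sum(lines == "")
  if (blanks > 0) {
    warning(blanks, " blank line(s) skipped in ", path, call. = FALSE)
  }
  ids <- lines[lines != ""]
  if (length(ids) == 0) {
    warning("empty id list: ", path, call. = FALSE)
  }
  if (kind == "rsid") ids <- sub("^rs", "", ids)
  tibble(kind = rep(kind, length(ids)), id = ids)
}

# ---- line-delimited JSON record fixtures ------------------------------------

.ct_record_fields <- c("vid", "rsids", "cvcs", "stars", "variant_type",
                       "alt_alleles", "conditions", "cv_last_evaluated",
                       "assertions")

#' Read and write variation records in the line-delimited JSON format
#'
#' The canonical on-disk form of a record set: one JSON object per line with
#' the fields of [ct_record()] (dates ISO-8601, `null` for absent values;
#' assertions as an array of objects with `significance`, `last_evaluated`,
#' `submitter_category`, `submitter_name`, `conditions`). Unknown fields are
#' ignored; missing optional fields are set absent with a warning. The
#' round trip `ct_read_records(ct_write_records(x))` is lossless for all
#' modeled fields.
#'
#' @param path file path.
#' @return `ct_read_records()` returns a `ct_records` tibble;
#'   `ct_write_records()` returns `path` invisibly.
#' @export
ct_read_records <- function(path) {
  if (!file.exists(path)) stop("cannot read records: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) return(ct_records_empty())
  missing_opt <- character()
  recs <- purrr::imap(lines, function(line, i) {
    obj <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = FALSE),
      error = function(e) {
        stop("malformed record at line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      })
    if (is.null(obj$vid)) {
      stop("malformed record at line ", i, ": missing vid", call. = FALSE)
    }
    absent <- setdiff(c("cvcs", "stars", "assertions"), names(obj))
    if (length(absent) > 0) {
      missing_opt <<- c(missing_opt,
                        paste0(obj$vid, " (", paste(absent, collapse = ","), ")"))
    }
    chrs <- function(x) as.character(unlist(x))
    a <- obj$assertions %||% list()
    assertions <- if (length(a) == 0) ct_assertions() else {
      ct_assertions(
        significance = purrr::map_chr(a, ~ .x$significance %||% NA_character_),
        last_evaluated = as.Date(
          purrr::map_chr(a, ~ .x$last_evaluated %||% NA_character_)),
        submitter_category = purrr::map_chr(
          a, ~ .x$submitter_category %||% "no_criteria"),
        submitter_name = purrr::map_chr(
          a, ~ .x$submitter_name %||% NA_character_),
        conditions = purrr::map(a, ~ chrs(.x$conditions))
      )
    }
    ct_record(
      vid = obj$vid,
      rsids = chrs(obj$rsids),
      cvcs = obj$cvcs %||% NA_character_,
      stars = obj$stars %||% 0L,
      variant_type = obj$variant_type,
      alt_alleles = chrs(obj$alt_alleles),
      conditions = chrs(obj$conditions),
      cv_last_evaluated = as.Date(obj$cv_last_evaluated %||% NA_character_),
      assertions = assertions
    )
  })
  if (length(missing_opt) > 0) {
    warning("records with missing optional fields: ",
            paste(missing_opt, collapse = "; "), call. = FALSE)
  }
  ct_records(recs)
}

ct_records_empty <- function() {
  new_ct_records(tibble(
    vid = character(), rsids = list(), cvcs = character(), stars = integer(),
    variant_type = character(), alt_alleles = list(), conditions = list(),
    cv_last_evaluated = as.Date(character()), assertions = list()
  ))
}

#' @rdname ct_read_records
#' @param records a `ct_records` tibble.
#' @export
ct_write_records <- function(records, path) {
  iso <- function(d) if (is.na(d)) NULL else format(d, "%Y-%m-%d")
  lines <- purrr::pmap_chr(records, function(vid, rsids, cvcs, stars,
                                             variant_type, alt_alleles,
                                             conditions, cv_last_evaluated,
                                             assertions) {
    a_list <- purrr::pmap(assertions, function(significance, last_evaluated,
                                               submitter_category,
                                               submitter_name, conditions) {
      list(significance = if (is.na(significance)) NULL else significance,
           last_evaluated = iso(last_evaluated),
           submitter_category = submitter_category,
           submitter_name = if (is.na(submitter_name)) NULL else submitter_name,
           conditions = as.list(conditions))
    })
    jsonlite::toJSON(list(
      vid = vid, rsids = as.list(rsids),
      cvcs = if (is.na(cvcs)) NULL else cvcs,
      stars = stars, variant_type = variant_type,
      alt_alleles = as.list(alt_alleles),
      conditions = as.list(conditions),
      cv_last_evaluated = iso(cv_last_evaluated),
      assertions = a_list
    ), auto_unbox = TRUE, null = "null")
  })
  writeLines(lines, path)
  invisible(path)
}

# ---- ClinVar variation-report XML subset ------------------------------------

#' Map ClinVar review-status text to a star rating
#'
#' The review-status tiers: practice guideline (4 stars), reviewed by expert
#' panel (3), criteria provided with multiple concordant submitters (2),
#' criteria provided by a single submitter or with conflicting
#' interpretations (1), anything else (0).
#'
#' @param status character vector of review-status strings.
#' @return Integer vector of stars 0-4.
#' @examples
#' ct_stars_from_review_status("criteria provided, multiple submitters, no conflicts")
#' @export
ct_stars_from_review_status <- function(status) {
  s <- tolower(trimws(as.character(status)))
  dplyr::case_when(
    grepl("practice guideline", s) ~ 4L,
    grepl("expert panel", s) ~ 3L,
    grepl("no assertion", s) ~ 0L,
    grepl("multiple submitters, no conflicts", s) ~ 2L,
    grepl("criteria provided", s) ~ 1L,
    TRUE ~ 0L
  )
}

ct_category_from_review_status <- function(status) {
  s <- tolower(trimws(as.character(status)))
  dplyr::case_when(
    grepl("practice guideline", s) ~ "practice_guideline",
    grepl("expert panel", s) ~ "expert_panel",
    grepl("literature|no assertion provided", s) ~ "literature_only",
    grepl("no assertion criteria", s) ~ "no_criteria",
    grepl("criteria provided", s) ~ "criteria_provided",
    TRUE ~ "no_criteria"
  )
}

ct_significance_from_text <- function(text) {
  s <- tolower(trimws(as.character(text)))
  out <- dplyr::case_when(
    s == "pathogenic/likely pathogenic" ~ "PLP",
    s == "benign/likely benign" ~ "BLB",
    s == "likely pathogenic" ~ "LP",
    s == "likely benign" ~ "LB",
    s == "uncertain significance" ~ "US",
    s == "pathogenic" ~ "P",
    s == "benign" ~ "B",
    grepl("^conflicting interpretations", s) ~ "CI",
    TRUE ~ NA_character_
  )
  # non-Mendelian significances pass through as opaque text
  ifelse(is.na(out) & !is.na(text) & text != "", as.character(text), out)
}

#' Parse a ClinVar variation-report XML subset
#'
#' Reads `VariationReport` elements (identifiers, record-level clinical
#' significance with review status and date, allele rsIDs and alternate
#' alleles, and the clinical assertion list) into the same record model as
#' the JSON-lines fixtures. Submitter categories are inferred from each
#' assertion's review-status text; review status maps to stars via
#' [ct_stars_from_review_status()]. Assertions lacking a last-evaluated date
#' are retained but invalid for scoring, with a warning naming the record.
#'
#' @param x path to an XML file, or an `xml2` document.
#' @return A `ct_records` tibble.
#' @export
ct_read_clinvar_xml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  reports <- xml2::xml_find_all(doc, ".//VariationReport")
  if (length(reports) == 0) {
    stop("no <VariationReport> elements found; if this is not ClinVar ",
         "variation-report XML, use the JSON-lines fixture format instead",
         call. = FALSE)
  }
  recs <- purrr::map(reports, ct_parse_variation_report)
  ct_records(recs)
}

ct_parse_variation_report <- function(node) {
  attr1 <- function(n, a) {
    v <- xml2::xml_attr(n, a)
    if (length(v) == 0 || is.na(v)) NA_character_ else v
  }
  text1 <- function(n, xpath) {
    hit <- xml2::xml_find_first(n, xpath)
    if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
  }
  vid <- attr1(node, "VariationID")
  alleles <- xml2::xml_find_all(node, "./Allele")
  rsids <- xml2::xml_attr(
    xml2::xml_find_all(alleles, ".//XRef[@DB='dbSNP']"), "ID")
  rsids <- unique(rsids[!is.na(rsids)])
  alts <- xml2::xml_attr(
    xml2::xml_find_all(alleles, ".//SequenceLocation[@alternateAllele]"),
    "alternateAllele")
  alts <- unique(alts[!is.na(alts)])
  overall <- xml2::xml_find_first(node, "./ClinicalSignificance")
  cvcs <- ct_significance_from_text(text1(node, "./ClinicalSignificance/Description"))
  stars <- ct_stars_from_review_status(
    text1(node, "./ClinicalSignificance/ReviewStatus"))
  cvle <- if (inherits(overall, "xml_missing")) {
    NA_character_
  } else xml2::xml_attr(overall, "DateLastEvaluated")
  a_nodes <- xml2::xml_find_all(node, ".//ClinicalAssertionList/ClinicalAssertion")
  assertions <- if (length(a_nodes) == 0) ct_assertions() else {
    dates <- purrr::map_chr(a_nodes, function(a) {
      cs <- xml2::xml_find_first(a, "./ClinicalSignificance")
      if (inherits(cs, "xml_missing")) NA_character_ else
        xml2::xml_attr(cs, "DateLastEvaluated")
    })
    if (any(is.na(dates))) {
      warning("variation ", vid, ": ", sum(is.na(dates)),
              " assertion(s) with blank date last evaluated (invalid for ",
              "scoring)", call. = FALSE)
    }
    ct_assertions(
      significance = purrr::map_chr(
        a_nodes, ~ ct_significance_from_text(
          text1(.x, "./ClinicalSignificance/Description"))),
      last_evaluated = as.Date(dates),
      submitter_category = purrr::map_chr(
        a_nodes, ~ ct_category_from_review_status(
          text1(.x, "./ClinicalSignificance/ReviewStatus"))),
      submitter_name = purrr::map_chr(a_nodes, ~ attr1(.x, "SubmitterName")),
      conditions = purrr::map(a_nodes, function(a) {
        ph <- xml2::xml_find_all(a, ".//PhenotypeList/Phenotype")
        stats::na.omit(xml2::xml_attr(ph, "Name"))
      })
    )
  }
  ct_record(
    vid = vid, rsids = rsids, cvcs = cvcs, stars = stars,
    variant_type = attr1(node, "VariationType"),
    alt_alleles = alts,
    conditions = character(),
    cv_last_evaluated = as.Date(if (is.na(cvle)) NA_character_ else cvle),
    assertions = assertions
  )
}

#' Expand an rsID to every matching variation record
#'
#' The rsID-to-VID relation is not 1:1: a multi-allelic rsID can map to one
#' VID per allele, so an rsID query returns every matching record (in input
#' order); the alternate-allele column then disambiguates.
#'
#' @param rsid a single rsID (with or without the `"rs"` prefix).
#' @param records a `ct_records` tibble.
#' @return The matching subset of `records` (possibly 0 rows, with a
#'   warning).
#' @export
ct_expand_rsid <- function(rsid, records) {
  key <- sub("^rs", "", as.character(rsid))
  hit <- purrr::map_lgl(records$rsids, ~ key %in% .x)
  if (!any(hit)) {
    warning("no variation record for rs", key, call. = FALSE)
  }
  records[hit, , drop = FALSE]
}

# ---- batched-fetch adapter contract -----------------------------------------

#' Batching policy for the optional E-utilities adapter
#'
#' Identifier lists posted to the Entrez history server are split into link
#' batches of at most 1000 ids; record fetches use batches of at most 4500
#' (the service ceiling is nominally 10,000 but smaller batches reduce HTTP
#' errors). Each batch is retried up to three times before the run gives up.
#'
#' @param elink_batch link-step batch size (max 1000).
#' @param efetch_batch fetch-step batch size (max 10000).
#' @param retries attempts per batch.
#' @return A list of class `ct_fetch_policy`.
#' @export
ct_fetch_policy <- function(elink_batch = 1000L, efetch_batch = 4500L,
                            retries = 3L) {
  stopifnot(elink_batch >= 1, elink_batch <= 1000L,
            efetch_batch >= 1, efetch_batch <= 10000L, retries >= 1)
  structure(list(elink_batch = as.integer(elink_batch),
                 efetch_batch = as.integer(efetch_batch),
                 retries = as.integer(retries)),
            class = "ct_fetch_policy")
}

#' Fetch documents for an identifier list through an injected transport
#'
#' Pure batching/retry engine for the network adapter contract: the ids are
#' partitioned into policy-sized batches, each batch is handed to
#' `transport` (a function of a character vector of ids returning one
#' document) and retried on error up to the policy's retry count. No network
#' code lives in the package; a live transport must be supplied by the
#' caller (NCBI requires a user email in that case). Results are
#' concatenated in batch order.
#'
#' @param ids character vector of identifiers.
#' @param transport `function(ids) -> document`; may throw to signal a
#'   transient failure.
#' @param policy a [ct_fetch_policy()].
#' @param batch_size batch size; defaults to the policy's fetch batch.
#' @return List of documents, one per batch.
#' @export
ct_fetch <- function(ids, transport, policy = ct_fetch_policy(),
                     batch_size = policy$efetch_batch) {
  if (length(ids) == 0) return(list())
  batches <- split(ids, ceiling(seq_along(ids) / batch_size))
  purrr::imap(unname(batches), function(batch, b) {
    for (attempt in seq_len(policy$retries)) {
      out <- tryCatch(list(ok = TRUE, doc = transport(batch)),
                      error = function(e) list(ok = FALSE, err = e))
      if (out$ok) return(out$doc)
    }
    stop("batch ", b, " failed after ", policy$retries, " attempts: ",
         conditionMessage(out$err), call. = FALSE)
  })
}
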