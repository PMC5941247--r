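.ct_info_prefix <- "CTO_"

#' INFO field definitions added to annotated VCFs
#'
#' Twelve metric fields are appended to the INFO column: every metrics-table
#' field except `vcf_match` (meaningless inside a VCF) and `rsID` (already
#' the VCF ID column). Keys carry a fixed `CTO_` prefix to avoid collisions
#' with pre-existing annotations; values are per-alternate-allele
#' (`Number=A`), comma-separated in alt order.
#'
#' @return A tibble with columns `field`, `id`, `number`, `type`,
#'   `description`.
#' @export
ct_vcf_info_keys <- function() {
  fields <- setdiff(ct_metrics_columns(), c("rsID", "vcf_match"))
  types <- c(VID = "String", CVCS = "String", CVSZ = "Integer",
             CVNA = "Integer", CVDS = "String", CVAL = "String",
             CVLE = "String", CVVT = "String", CTRS = "Float",
             CTAA = "Float", CTPS = "String", CTRR = "Integer")
  descs <- c(
    VID = "ClinVar Variation ID",
    CVCS = "ClinVar clinical significance",
    CVSZ = "ClinVar review-status stars",
    CVNA = "Number of valid clinical assertions",
    CVDS = "Associated conditions",
    CVAL = "ClinVar alternate allele",
    CVLE = "Date the overall significance was last evaluated",
    CVVT = "Variation type (Simple or Haplotype)",
    CTRS = "Clinotator raw score",
    CTAA = "Mean age in years of valid clinical assertions",
    CTPS = "Clinotator predicted significance",
    CTRR = "Clinotator reclassification recommendation (0-3)")
  tibble(field = fields, id = paste0(.ct_info_prefix, fields),
         number = "A", type = unname(types[fields]),
         description = unname(descs[fields]))
}

# VCF 4.3 reserves whitespace, semicolon, comma and equals inside INFO values
ct_sanitize_info <- function(x) {
  x <- gsub("[;,=[:space:]]+", "_", as.character(x))
  ifelse(is.na(x) | x == "", ".", x)
}

#' Match variation records to a VCF site by rsID and alternate allele
#'
#' Matching follows the documented semantics exactly: the site's ID column
#' must carry an rsID, and each alternate allele is paired with the record
#' whose rsID list contains that rsID and whose allele list contains the
#' allele. Haplotype records match by membership of the site allele in the
#' haplotype's allele list. Position is deliberately not used.
#'
#' @param id the VCF ID column value (an rsID or `"."`).
#' @param alts character vector of alternate alleles at the site.
#' @param records a `ct_records` tibble.
#' @return Integer vector of record row indices, one per alt (`NA` where
#'   unmatched).
#' @export
ct_match_annotation <- function(id, alts, records) {
  if (is.na(id) || id == "." || !grepl("^rs[0-9]+$", id)) {
    return(rep(NA_integer_, length(alts)))
  }
  key <- sub("^rs", "", id)
  has_rsid <- purrr::map_lgl(records$rsids, ~ key %in% .x)
  vapply(alts, function(alt) {
    hit <- which(has_rsid & purrr::map_lgl(records$alt_alleles,
                                           ~ alt %in% .x))
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1), USE.NAMES = FALSE)
}

#' Annotate a VCF file with the computed metrics
#'
#' Header and body are preserved byte-for-byte except for the additions: 12
#' new `##INFO` definition lines ([ct_vcf_info_keys()]) before the `#CHROM`
#' line, and, for matched sites, new `KEY=value[,value...]` entries appended
#' to the INFO column (one comma-separated value per alternate allele;
#' unmatched alleles get `.` placeholders). Sites whose alleles match no
#' record pass through untouched. Input may be plain or gzipped VCF 4.2/4.3;
#' output is plain text.
#'
#' @param in_vcf path to the input VCF.
#' @param records a `ct_records` tibble to annotate from.
#' @param out_vcf output path; defaults to `<prefix>.anno.vcf` next to the
#'   input.
#' @inheritParams ct_annotate
#' @return `out_vcf`, invisibly.
#' @export
ct_annotate_vcf <- function(in_vcf, records, out_vcf = NULL,
                            ranges = ct_default_ranges(),
                            evaluation_date = Sys.Date(),
                            constants = ct_constants()) {
  if (is.null(out_vcf)) {
    out_vcf <- paste0(sub("\\.vcf(\\.gz)?$", "", in_vcf), ".anno.vcf")
  }
  lines <- readLines(in_vcf, warn = FALSE)
  header <- grepl("^#", lines)
  chrom_at <- which(startsWith(lines, "#CHROM"))
  if (length(chrom_at) != 1) {
    stop("not a VCF: expected exactly one #CHROM header line", call. = FALSE)
  }
  defs <- ct_vcf_info_keys()
  clash <- purrr::map_lgl(defs$id, function(k) {
    any(grepl(paste0("^##INFO=<ID=", k, ","), lines))
  })
  if (any(clash)) {
    stop("INFO key(s) already defined in header: ",
         paste(defs$id[clash], collapse = ", "), call. = FALSE)
  }
  def_lines <- sprintf(
    '##INFO=<ID=%s,Number=%s,Type=%s,Description="%s">',
    defs$id, defs$number, defs$type, defs$description)

  metrics <- ct_annotate(records, ranges = ranges,
                         evaluation_date = evaluation_date,
                         constants = constants)
  fmt <- ct_format_metrics(metrics)

  body_ix <- which(!header)
  new_body <- vapply(body_ix, function(li) {
    line <- lines[li]
    cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(cols) < 8) {
      stop("malformed VCF data line ", li, ": fewer than 8 columns",
           call. = FALSE)
    }
    alts <- strsplit(cols[5], ",", fixed = TRUE)[[1]]
    hit <- ct_match_annotation(cols[3], alts, records)
    if (all(is.na(hit))) return(line)
    adds <- vapply(seq_len(nrow(defs)), function(j) {
      vals <- ifelse(is.na(hit), ".",
                     ct_sanitize_info(fmt[[defs$field[j]]][hit]))
      paste0(defs$id[j], "=", paste(vals, collapse = ","))
    }, character(1))
    add_str <- paste(adds, collapse = ";")
    cols[8] <- if (cols[8] %in% c(".", "")) add_str else {
      paste0(cols[8], ";", add_str)
    }
    paste(cols, collapse = "\t")
  }, character(1))
  lines[body_ix] <- new_body
  out <- c(lines[seq_len(chrom_at - 1)], def_lines, lines[chrom_at:length(lines)])
  writeLines(out, out_vcf)
  invisible(out_vcf)
}

#' Strip this package's annotations from a VCF
#'
#' Removes the `CTO_`-prefixed `##INFO` header definitions and INFO entries,
#' restoring the pre-annotation file (the body byte-identically).
#'
#' @param in_vcf annotated VCF path.
#' @param out_vcf output path.
#' @return `out_vcf`, invisibly.
#' @export
ct_strip_vcf_annotations <- function(in_vcf, out_vcf) {
  lines <- readLines(in_vcf, warn = FALSE)
  keep <- !grepl(paste0("^##INFO=<ID=", .ct_info_prefix), lines)
  lines <- lines[keep]
  body <- !grepl("^#", lines)
  strip1 <- function(line) {
    cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(cols) < 8) return(line)
    entries <- strsplit(cols[8], ";", fixed = TRUE)[[1]]
    entries <- entries[!startsWith(entries, .ct_info_prefix)]
    cols[8] <- if (length(entries) == 0) "." else paste(entries, collapse = ";")
    paste(cols, collapse = "\t")
  }
  lines[body] <- vapply(lines[body], strip1, character(1), USE.NAMES = FALSE)
  writeLines(lines, out_vcf)
  invisible(out_vcf)
}

#' Parse this package's INFO annotations back out of a VCF
#'
#' Convenience for round-trip checks: returns one row per (site, alt) pair
#' carrying the `CTO_` INFO values as characters.
#'
#' @param vcf annotated VCF path.
#' @return A tibble with columns `id`, `alt`, then one column per annotated
#'   field.
#' @export
ct_read_vcf_annotations <- function(vcf) {
  lines <- readLines(vcf, warn = FALSE)
  body <- lines[!grepl("^#", lines)]
  defs <- ct_vcf_info_keys()
  rows <- purrr::map(body, function(line) {
    cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
    entries <- strsplit(cols[8], ";", fixed = TRUE)[[1]]
    ours <- entries[startsWith(entries, .ct_info_prefix)]
    if (length(ours) == 0) return(NULL)
    kv <- strsplit(ours, "=", fixed = TRUE)
    vals <- stats::setNames(
      lapply(kv, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]]),
      vapply(kv, `[[`, character(1), 1))
    alts <- strsplit(cols[5], ",", fixed = TRUE)[[1]]
    out <- tibble(id = cols[3], alt = alts)
    for (j in seq_len(nrow(defs))) {
      v <- vals[[defs$id[j]]]
      out[[defs$field[j]]] <- if (is.null(v)) NA_character_ else {
        rep_len(v, length(alts))
      }
    }
    out
  })
  dplyr::bind_rows(rows)
}

# render a metrics tibble as characters, "." for missing (shared by the TSV
# writer and the VCF annotator)
ct_format_metrics <- function(metrics) {
  fmt1 <- function(x) {
    out <- if (inherits(x, "Date")) format(x, "%Y-%m-%d") else as.character(x)
    ifelse(is.na(out), ".", out)
  }
  out <- metrics
  out[] <- lapply(metrics, fmt1)
  as_tibble(out)
}
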