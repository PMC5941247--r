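test_that("id lists read one identifier per line, preserving duplicates", {
  path <- withr::local_tempfile(lines = c("10768", "12348", "10768"))
  ids <- ct_read_id_list(path, "vid")
  expect_equal(ids$id, c("10768", "12348", "10768"))

  blanky <- withr::local_tempfile(lines = c("rs123", "", "rs456"))
  expect_warning(ids2 <- ct_read_id_list(blanky, "rsid"), "blank")
  expect_equal(ids2$id, c("123", "456"))

  empty <- withr::local_tempfile(lines = character())
  expect_warning(ids3 <- ct_read_id_list(empty, "vid"), "empty")
  expect_equal(nrow(ids3), 0L)

  expect_error(ct_read_id_list(file.path(tempdir(), "nope.txt"), "vid"),
               "cannot read")
})

test_that("record fixtures round-trip losslessly through JSON lines", {
  recs <- ct_records(ct_example_records("threestar"),
                     ct_example_records("conflicting"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  ct_write_records(recs, path)
  back <- ct_read_records(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))
})

test_that("malformed or incomplete fixture lines are reported by position", {
  path <- withr::local_tempfile(lines = c('{"vid":"1","cvcs":"P","stars":1,"assertions":[]}',
                                          "{not json"))
  expect_error(ct_read_records(path), "line 2")

  sparse <- withr::local_tempfile(lines = '{"vid":"5"}')
  expect_warning(recs <- ct_read_records(sparse), "missing optional")
  expect_equal(recs$vid, "5")
  expect_equal(nrow(recs$assertions[[1]]), 0L)

  none <- withr::local_tempfile(lines = character())
  expect_equal(nrow(ct_read_records(none)), 0L)
})

test_that("an assertion missing its date parses but is invalid for scoring", {
  path <- withr::local_tempfile(
    lines = paste0('{"vid":"8","cvcs":"US","stars":1,"assertions":',
                   '[{"significance":"US","last_evaluated":null,',
                   '"submitter_category":"criteria_provided"}]}'))
  recs <- ct_read_records(path)
  expect_equal(ct_count_valid(recs$assertions[[1]]), 0L)
})

test_that("the XML subset parses to the same record as its JSON twin", {
  xml_path <- system.file("extdata", "synthetic_variation_report.xml",
                          package = "clinotatr")
  recs <- ct_read_clinvar_xml(xml_path)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$vid, "900001")
  expect_equal(recs$rsids[[1]], "900000101")
  expect_equal(recs$cvcs, "P")
  expect_equal(recs$stars, 2L)
  expect_equal(nrow(recs$assertions[[1]]), 2L)

  twin <- ct_record(
    vid = "900001", rsids = "900000101", cvcs = "P", stars = 2,
    variant_type = "Simple", alt_alleles = "G",
    cv_last_evaluated = as.Date("2018-01-19"),
    assertions = ct_assertions(
      significance = c("P", "P"),
      last_evaluated = as.Date(c("2016-06-14", "2018-01-19")),
      submitter_category = "criteria_provided",
      submitter_name = c("Synthetic Genetics Lab", "Synthetic Hospital"),
      conditions = list("Synthetic condition A", "Synthetic condition A")))
  expect_equal(as.data.frame(recs[, names(twin)]), as.data.frame(twin))
  # and the same metrics either way
  expect_equal(ct_annotate(recs, evaluation_date = EVAL_DATE)$CTRS,
               ct_annotate(twin, evaluation_date = EVAL_DATE)$CTRS)
})

test_that("XML assertions with a blank evaluation date warn and stay invalid", {
  doc <- xml2::read_xml(paste0(
    '<Set><VariationReport VariationID="77" VariationType="Simple">',
    '<ClinicalSignificance DateLastEvaluated="2017-01-01">',
    '<ReviewStatus>criteria provided, single submitter</ReviewStatus>',
    '<Description>Likely pathogenic</Description></ClinicalSignificance>',
    '<ClinicalAssertionList><ClinicalAssertion SubmitterName="x">',
    '<ClinicalSignificance><ReviewStatus>criteria provided, single submitter',
    '</ReviewStatus><Description>Likely pathogenic</Description>',
    '</ClinicalSignificance></ClinicalAssertion></ClinicalAssertionList>',
    '</VariationReport></Set>'))
  expect_warning(recs <- ct_read_clinvar_xml(doc), "blank date")
  expect_equal(ct_count_valid(recs$assertions[[1]]), 0L)
  expect_equal(recs$stars, 1L)
})

test_that("non-ClinVar XML is rejected with advice", {
  doc <- xml2::read_xml("<foo><bar/></foo>")
  expect_error(ct_read_clinvar_xml(doc), "fixture format")
})

test_that("review-status text maps onto the 0-4 star tiers", {
  expect_equal(ct_stars_from_review_status(c(
    "practice guideline",
    "reviewed by expert panel",
    "criteria provided, multiple submitters, no conflicts",
    "criteria provided, conflicting interpretations",
    "criteria provided, single submitter",
    "no assertion criteria provided",
    "no assertion provided")), c(4L, 3L, 2L, 1L, 1L, 0L, 0L))
})

test_that("rsID expansion returns every matching record, in order", {
  recs <- ct_records(
    ct_record("1", rsids = "100", alt_alleles = "A"),
    ct_record("2", rsids = c("100", "200"), alt_alleles = "C"),
    ct_record("3", rsids = "300", alt_alleles = "G"))
  expect_equal(ct_expand_rsid("rs100", recs)$vid, c("1", "2"))
  expect_equal(ct_expand_rsid("300", recs)$vid, "3")
  expect_warning(none <- ct_expand_rsid("999", recs), "no variation record")
  expect_equal(nrow(none), 0L)
})

test_that("fetch batches partition the id list and honor the retry policy", {
  ids <- as.character(seq_len(2500))
  seen <- list()
  transport <- function(batch) {
    seen[[length(seen) + 1]] <<- batch
    paste0("doc", length(seen))
  }
  docs <- ct_fetch(ids, transport, batch_size = 1000)
  expect_length(docs, 3L)
  expect_equal(lengths(seen), c(1000L, 1000L, 500L))
  expect_equal(unlist(seen), ids)  # order and multiplicity preserved

  # two transient failures then success: succeeds within three retries
  flaky_calls <- 0
  flaky <- function(batch) {
    flaky_calls <<- flaky_calls + 1
    if (flaky_calls < 3) stop("http 502")
    "ok"
  }
  expect_equal(ct_fetch("1", flaky), list("ok"))
  expect_equal(flaky_calls, 3)

  expect_error(ct_fetch("1", function(batch) stop("down")),
               "batch 1 failed after 3 attempts")
})
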