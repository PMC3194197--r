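# Syntax checker: verdicts, halt positions, classification, batch mode.

test_that("check reports validity and the matched description form", {
  r <- hgvs_check("NM_003002.2:c.274G>T")
  expect_true(r$valid)
  expect_identical(r$matched_form, "full")
  expect_true(is.na(r$halt_position))

  r <- hgvs_check("274G>T")
  expect_true(r$valid)
  expect_identical(r$matched_form, "bare")

  r <- hgvs_check("c.274G>")
  expect_false(r$valid)
  expect_identical(r$halt_position, 7L)  # a nucleotide was expected at the end

  r <- hgvs_check("")
  expect_false(r$valid)
  expect_identical(r$halt_position, 0L)
})

test_that("classification returns the most complete matching form", {
  expect_identical(hgvs_classify("NM_003002.2:c.274G>T"), "full")
  expect_identical(hgvs_classify("c.274G>T"), "coordinate_prefixed")
  expect_identical(hgvs_classify("274G>T"), "bare")
  expect_identical(hgvs_classify("hello"), "none")
  expect_identical(hgvs_classify("g.[158A>C/124C>T]"), "coordinate_prefixed")
  expect_identical(hgvs_classify("p.Ser124Arg", level = "protein"),
                   "coordinate_prefixed")
  expect_identical(hgvs_classify("Gly123del", level = "protein"), "bare")
})

test_that("a full match implies validity and a valid suffix after the reference", {
  words <- c("NM_003002.2:c.274G>T", "LRG_1t1:c.24_65inv{46G>T}",
             "AB000001.1:g.[1del;2dup]")
  for (w in words) {
    expect_identical(hgvs_classify(w), "full")
    expect_true(hgvs_check(w)$valid)
    suffix <- sub("^[^:]*:", "", w)
    expect_identical(hgvs_classify(suffix), "coordinate_prefixed")
  }
})

test_that("batch mode checks one record per line and keeps order", {
  rep <- hgvs_batch_check(c("NM_003002.2:c.274G>T", "274G>T", "notavariant"))
  expect_identical(nrow(rep), 3L)
  expect_identical(rep$valid, c(TRUE, TRUE, FALSE))
  expect_identical(rep$matched_form, c("full", "bare", "none"))
  s <- attr(rep, "summary")
  expect_identical(s[c("n", "n_valid", "n_invalid")],
                   list(n = 3L, n_valid = 2L, n_invalid = 1L))
  expect_identical(glance(rep)$n_valid, 2L)

  empty <- hgvs_batch_check(character())
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "summary")$n, 0L)

  # tab-delimited records: only the first field is checked
  rep <- hgvs_batch_check(c("274G>T\tcomment here", "  c.85C>T  "))
  expect_true(all(rep$valid))
  expect_identical(rep$input, c("274G>T", "c.85C>T"))

  # internal whitespace flags the record instead of crashing
  rep <- hgvs_batch_check("274G >T")
  expect_false(rep$valid)
  expect_match(rep$message, "whitespace")
})

test_that("batch report writes machine-parseable TSV", {
  rep <- hgvs_batch_check(c("274G>T", "nope"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  hgvs_write_batch_report(rep, tmp)
  back <- utils::read.delim(tmp)
  expect_identical(nrow(back), 2L)
  expect_identical(names(back),
                   c("input", "level", "dialect", "valid", "matched_form",
                     "halt_position", "message"))
  expect_identical(back$valid, c(TRUE, FALSE))
})

test_that("arbitrary byte strings yield well-formed results, never crashes", {
  for (s in fuzz_strings(400, seed = 4)) {
    res <- hgvs_check(s)
    expect_s3_class(res, "hgvs_syntax_result")
    if (res$valid) {
      expect_true(is.na(res$halt_position))
    } else {
      expect_true(res$halt_position >= 0L && res$halt_position <= nchar(s))
    }
    resp <- hgvs_check(s, level = "protein")
    expect_s3_class(resp, "hgvs_syntax_result")
  }
})

test_that("tidiers flatten results into tibbles", {
  td <- tidy(hgvs_check("c.274G>"))
  expect_s3_class(td, "tbl_df")
  expect_identical(td$halt_position, 7L)
  nodes <- tidy(hgvs_parse_genotype("c.274G>T"))
  expect_true(all(c("rule", "start", "end", "depth", "leaf") %in%
                    names(nodes)))
  expect_identical(nodes$rule[[1]], "Var")
  expect_true(any(nodes$leaf))
  plt <- autoplot(hgvs_batch_check(c("274G>T", "nope")))
  expect_s3_class(plt, "ggplot")
})
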