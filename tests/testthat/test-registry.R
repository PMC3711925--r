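test_that("packaged gene table loads to 107 validated records", {
  reg <- load_registry()
  expect_s3_class(reg, "kc_registry")
  expect_equal(nrow(reg), 107L)
  expect_equal(length(unique(reg$subfamily)), 21L)
  expect_false(anyDuplicated(reg$symbol) > 0)
})

test_that("empty table and malformed cells are handled per contract", {
  empty <- write_registry_file(character(0))
  expect_equal(nrow(load_registry(empty)), 0L)

  bad_expr <- write_registry_file(registry_row(hvc = "++++"))
  expect_error(load_registry(bad_expr), "\\+\\+\\+\\+")

  dup <- write_registry_file(c(registry_row("KCNA1"), registry_row("KCNA1")))
  expect_error(load_registry(dup), "duplicate symbol")

  bad_flag <- write_registry_file(
    registry_row(dnds = "0.05", flagged = "TRUE"))
  expect_error(load_registry(bad_flag), "> 0.1")
})

test_that("declarative predicates reproduce the headline counts", {
  reg <- load_registry()
  expect_equal(count_by_predicate(
    reg, kc_pred("ortholog_class", "eq", "one_to_one_human")), 100L)
  expect_equal(count_by_predicate(
    reg, kc_pred("novelty_flag", "eq", "delta")), 7L)
  expect_equal(count_by_predicate(reg, kc_pred("dnds", "gt", 0.1)), 10L)
  expect_equal(count_by_predicate(reg, kc_false()), 0L)
  expect_error(count_by_predicate(reg, kc_pred("no_such_field", "eq", 1)),
               "unknown field")
  ## composition
  expect_equal(count_by_predicate(reg, kc_and(
    kc_pred("dnds", "gt", 0.1),
    kc_pred("subfamily", "eq", "KCNK"))), 6L)
  ## "<0.01" entries satisfy numeric relations only under explicit coercion
  n_strict <- count_by_predicate(reg, kc_pred("dnds", "lt", 0.02))
  n_coerced <- count_by_predicate(reg, kc_pred("dnds", "lt", 0.02),
                                  coerce_qualifiers = TRUE)
  expect_gt(n_coerced, n_strict)
})

test_that("reconciliation identities hold on the packaged fixtures", {
  reg <- load_registry()
  missing <- load_missing_genes()
  rec <- reconcile_annotations(reg, missing)
  expect_equal(rec$finch_total, 107L)
  expect_equal(rec$one_to_one, 100L)
  expect_equal(rec$novel_non_human, 7L)
  expect_equal(rec$human_start, 123L)
  expect_equal(rec$missing_total, 23L)
  expect_equal(rec$missing_by_category, c(3L, 8L, 8L, 2L, 2L))
  expect_length(rec$violations, 0L)

  ## deleting a record breaks the arithmetic and is reported, not thrown
  reg2 <- reg[-1, ]
  class(reg2) <- class(reg)
  reg2$finch_total <- NULL
  rec2 <- reconcile_annotations(reg2, missing)
  ## 106 = 99 + 7 still holds internally; force a violation via overlap
  missing2 <- missing
  missing2$symbol[1] <- reg$symbol[1]
  rec3 <- reconcile_annotations(reg, missing2)
  expect_true(length(rec3$violations) > 0L)
})

test_that("serialization round-trips byte-identically up to column order", {
  src <- kc_fixture("table1_registry.tsv")
  reg <- load_registry(src)
  out <- tempfile(fileext = ".tsv")
  write_registry(reg, out)
  reg2 <- load_registry(out)
  for (col in c("symbol", "dnds", "hvc", "lman", "ra", "x", "clone",
                "variant_codes", "dnds_note")) {
    expect_identical(reg[[col]], reg2[[col]], label = col)
  }
  ## a second round trip is literally byte-identical
  out2 <- tempfile(fileext = ".tsv")
  write_registry(reg2, out2)
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(out2, "raw", file.size(out2)))
})

test_that("every flagged record is in the published bold set", {
  reg <- load_registry()
  bold <- c("KCNG2", "KCNMB1", "KCNK5", "KCNK10", "KCNK16", "KCNK16L",
            "KCNK17", "KCNK18", "KCTD18", "KCNRG")
  expect_setequal(reg$symbol[reg$dnds_flagged], bold)
})
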