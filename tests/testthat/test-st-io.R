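test_that("standoff records parse into exactly one record each", {
  txt <- "BMP-6 inhibits growth ."
  a1 <- "T1\tProtein 0 5\tBMP-6"
  a2 <- c("T2\tNegative_regulation 6 14\tinhibits",
          "T3\tGene_expression 15 21\tgrowth",
          "E1\tGene_expression:T3 Theme:T1",
          "E2\tNegative_regulation:T2 Theme:E1",
          "M1\tNegation E2",
          "*\tEquiv T1 T1")
  d <- read_st_document(txt, a1, a2, id = "doc1")
  expect_equal(nrow(d$entities), 3)
  e1 <- d$entities[1, ]
  expect_equal(e1$type, "Protein")
  expect_equal(c(e1$start, e1$end), c(0L, 5L))
  expect_true(e1$given)
  # nested structure: an event-valued Theme
  expect_equal(d$events$trigger, c("T3", "T2"))
  expect_equal(d$events$args[[2]]$target, "E1")
  expect_equal(d$modifiers$kind, "Negation")
  expect_equal(d$equivs[[1]], c("T1", "T1"))
})

test_that("malformed and inconsistent standoff input is rejected with context", {
  expect_error(read_st_document("abc", a1 = "T1\tProtein 0 3"),
               "needs 3 fields")
  expect_error(read_st_document("abc", a1 = "X1\twhat 0 3\tabc"),
               "unknown record kind")
  # offset/text mismatch is an integrity error
  expect_error(read_st_document("abcdef", a1 = "T1\tProtein 0 3\txyz"),
               "does not match")
})

test_that("writing renumbers deterministically and round-trips", {
  g <- gen_corpus(6, seed = 13, nesting_rate = 0.3, shared_trigger_rate = 0.3,
                  equiv_rate = 0.3, site_rate = 0.5)
  for (d in g$st_documents) {
    out <- write_st_document(d)
    d2 <- read_st_document(out$txt, out$a1, out$a2, id = d$id)
    expect_true(st_documents_equivalent(d, d2))
    # a second write of the re-read document is byte-identical
    out2 <- write_st_document(d2)
    expect_identical(out$a1, out2$a1)
    expect_identical(out$a2, out2$a2)
  }
})

test_that("an event with trigger, Theme and Site is a single E line", {
  g <- gen_corpus(20, seed = 17, site_rate = 1, optional_rate = 0)
  found <- FALSE
  for (d in g$st_documents) {
    out <- write_st_document(d)
    hit <- grep("Theme:T\\d+ Site:T\\d+", out$a2, value = TRUE)
    if (length(hit)) found <- TRUE
  }
  expect_true(found)
})

test_that("dangling references are refused at write time, naming the record", {
  d <- st_document("d", "abc def",
                   entities = tibble::tibble(id = "T1", type = "Protein",
                                             start = 0L, end = 3L,
                                             text = "abc", given = TRUE),
                   events = tibble::tibble(
                     id = "E1", type = "Phosphorylation", trigger = "T9",
                     args = list(tibble::tibble(role = "Theme",
                                                target = "T1"))))
  expect_error(write_st_document(d), "T9")
})

test_that("standoff directories round-trip document sets", {
  g <- gen_corpus(3, seed = 23)
  dir <- withr::local_tempdir()
  write_st_directory(g$st_documents, dir)
  docs <- read_st_directory(dir)
  expect_equal(length(docs), 3)
  for (i in seq_along(docs)) {
    expect_true(st_documents_equivalent(g$st_documents[[i]], docs[[i]]))
  }
})
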