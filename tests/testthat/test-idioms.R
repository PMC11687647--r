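test_that("idiom membership is exact after normalization", {
  lex <- idiom_lexicon(c("hta", "avc", "bpco"))
  expect_true(is_idiom("hta", lex))
  expect_false(is_idiom("hypertension", lex))
  expect_true(is_idiom("HTA ", lex))
  expect_true(is_idiom("Avc", lex))
  expect_false(is_idiom("hta x", lex))
  # prefix mode is opt-in
  expect_true(is_idiom("ht", lex, mode = "prefix"))
  expect_false(is_idiom("ht", lex))
})

test_that("idiom lexicon validates, deduplicates and round-trips", {
  lex <- idiom_lexicon(c("HTA", "hta ", "avc"))
  expect_length(lex, 2L)
  expect_error(idiom_lexicon(c("", "  ")), "at least one")
  p <- withr::local_tempfile(fileext = ".txt")
  write_idiom_lexicon(lex, p)
  expect_equal(unclass(read_idiom_lexicon(p)), unclass(lex))
})

test_that("labels with idiom queries are collected", {
  lex <- idiom_lexicon(c("hta", "avc"))
  log <- tibble::tibble(
    user = "u",
    query = c("hta", "hypertension", "avc", "diab", "avc", "x"),
    label_id = c(10L, 10L, 30L, 20L, 30L, 40L)
  )
  expect_equal(labels_with_idiom_queries(log, lex), c(10L, 30L))
  none <- tibble::tibble(user = "u", query = "diab", label_id = 1L)
  expect_length(labels_with_idiom_queries(none, lex), 0L)
  expect_true(all(labels_with_idiom_queries(log, lex) %in% log$label_id))
})

test_that("idiom proportions match hand computation on a 10-record fixture", {
  lex <- idiom_lexicon(c("hta", "avc"))
  log <- tibble::tibble(
    user  = c("a", "b", "c", "d", "e", "a", "b", "c", "d", "e"),
    query = c("hta", "hta", "avc", "hta", "x1", "hta", "x2", "x3", "x4", "x5"),
    label_id = rep(1:5, 2),
    seniority = rep(1:2, each = 5)
  )
  # all five labels are idiom-associated except label 5 (queries x1/x5 only)
  # level 1: hta,hta,avc,hta -> 4 idioms of 4 records on labels 1-4
  # level 2: hta,x2,x3,x4 -> 1 of 4
  prop <- idiom_proportion_by_seniority(log, lex, S_cap = 2)
  expect_equal(prop$n, c(4L, 4L))
  expect_equal(prop$n_idiom, c(4L, 1L))
  expect_equal(prop$proportion, c(1.0, 0.25))

  # all-idiomatic log: proportion 1 at every level
  log2 <- tibble::tibble(user = "u", query = "hta", label_id = 1L,
                         seniority = rep(1:3, 2))
  prop2 <- idiom_proportion_by_seniority(log2, lex, 3)
  expect_equal(prop2$proportion, c(1, 1, 1))
})

test_that("case study tables partition records into seniority zones", {
  lex <- idiom_lexicon("hta")
  trm <- fig_terminology()
  log <- tibble::tibble(
    user = "u",
    query = c(rep("hta", 4), rep("hypertension", 5), "hyperten"),
    label_id = 15L,
    seniority = c(1:4, 5:9, 10)
  )
  cs <- query_case_study(log, 15L, boundaries = c(4L, 8L), trm = trm,
                         lexicon = lex)
  expect_equal(unique(cs$zone), c("1-4", "5-8", "9+"))
  a <- cs[cs$zone == "1-4", ]
  expect_equal(a$query[1], "hta")
  expect_true(a$is_idiom[1])
  b <- cs[cs$zone == "5-8", ]
  expect_equal(b$query[which.max(b$count)], "hypertension")
  expect_equal(sum(cs$count), nrow(log))  # conservation
  expect_equal(cs$current_rank[cs$query == "hta"][1],
               rank_of_label(trm, 15L, "hta"))
  expect_error(query_case_study(log, 999L), "does not occur")
  expect_error(query_case_study(log, 15L, boundaries = c(5L, 5L)),
               "strictly increasing")
})

test_that("top idioms rank expressions and report the modal label", {
  lex <- idiom_lexicon(c("hta", "avc", "drs"))
  log <- tibble::tibble(
    user = "u",
    query = c("hta", "hta", "hta", "avc", "avc", "plain"),
    label_id = c(15L, 15L, 20L, 30L, 30L, 40L)
  )
  top <- top_idioms(log, lex)
  expect_equal(top$expression, c("hta", "avc"))
  expect_equal(top$occurrences, c(3L, 2L))
  expect_equal(top$top_label_id, c(15L, 30L))
  expect_lte(sum(top$occurrences), nrow(log))
  empty <- top_idioms(tibble::tibble(user = "u", query = "q", label_id = 1L),
                      lex)
  expect_equal(nrow(empty), 0L)
})
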