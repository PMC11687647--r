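test_that("query length counts raw characters, spaces included", {
  expect_equal(qlen("diabet"), 6L)
  expect_equal(qlen("ivrs"), 4L)
  expect_equal(qlen("drs"), 3L)
  expect_equal(qlen("a"), 1L)
  expect_equal(qlen("ac vas"), 6L)
  expect_error(qlen(""), "non-empty")
})

test_that("seniority starts at 1 and increments per user-label pair", {
  log <- data.frame(
    user = c("jd", "jd", "bl", "jd"),
    query = c("diabet", "diab", "diab", "diab"),
    label_id = 4578L,
    timestamp = 1:4
  )
  enr <- assign_seniority(log)
  expect_equal(enr$seniority[enr$user == "jd"], 1:3)
  expect_equal(enr$seniority[enr$user == "bl"], 1L)
})

test_that("an initial seniority map offsets the counter", {
  log <- data.frame(user = "J. Doe", query = c("diabet", "diab", "diab"),
                    label_id = 4578L,
                    timestamp = as.Date(c("2022-03-14", "2022-03-15",
                                          "2022-03-17")))
  enr <- assign_seniority(
    log, initial = data.frame(user = "J. Doe", label_id = 4578L, start = 7L))
  expect_equal(enr$seniority, c(7L, 8L, 9L))
})

test_that("seniority is permutation-stable given timestamps", {
  set.seed(42)
  log <- data.frame(
    user = sample(c("a", "b", "c"), 40, TRUE),
    query = "q",
    label_id = sample(1:3, 40, TRUE),
    timestamp = seq_len(40)
  )
  ref <- assign_seniority(log)
  shuf <- assign_seniority(log[sample.int(40), ])
  expect_equal(shuf, ref)
  # sort-then-count oracle
  oracle <- unlist(lapply(split(seq_len(40), paste(log$user, log$label_id)),
                          seq_along))
  expect_setequal(ref$seniority, oracle)
})

test_that("rank annotation recomputes ranks and flags infeasible records", {
  trm <- fig_terminology()
  log <- data.frame(
    user = "u", query = c("avc", "qqqq"), label_id = c(2477L, 4578L),
    timestamp = 1:2
  )
  expect_message(enr <- enrich_log(log, trm), "1 record")
  expect_equal(enr$rank[1], 1L)
  expect_true(is.na(enr$rank[2]))
  expect_false(enr$feasible[2])
  expect_equal(attr(enr, "infeasible"), 1L)
})

test_that("annotated ranks equal a linear search of the completion list", {
  trm <- generate_terminology(50, seed = 12)
  lex <- generate_idiom_lexicon(trm, seed = 12)
  log <- simulate_log(simulation_config(n_users = 10, n_labels = 50,
                                        n_events = 600, seed = 12), trm, lex)
  enr <- enrich_log(log, trm)
  idx <- seq(1, nrow(enr), by = 37)
  for (i in idx) {
    expect_identical(enr$rank[i],
                     match(enr$label_id[i],
                           as.integer(complete_query(trm, enr$query[i]))))
  }
})

test_that("level occupancy never grows with seniority", {
  trm <- generate_terminology(40, seed = 8)
  log <- simulate_log(simulation_config(n_users = 10, n_labels = 40,
                                        n_events = 1200, seed = 8), trm)
  enr <- enrich_log(log, trm)
  counts <- table(enr$seniority)
  expect_true(all(diff(as.integer(counts)) <= 0))
})

test_that("unknown labels and empty queries are rejected with positions", {
  trm <- fig_terminology()
  log <- data.frame(user = "u", query = "a", label_id = 999L, timestamp = 1)
  expect_error(enrich_log(log, trm), "absent from the terminology")
  log2 <- data.frame(user = "u", query = c("a", ""), label_id = 2477L,
                     timestamp = 1:2)
  expect_error(assign_seniority(log2), "row\\(s\\) 2")
})
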