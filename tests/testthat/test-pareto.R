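test_that("feasible points match a brute-force filter of the query space", {
  trm <- fig_terminology()
  space <- c("avc", "accident", "diab", "hyperten", "zzz", "douleur r",
             "infection", "de", "a", "hta", "vasculaire", "type 2",
             "diabete de type 2", "resp", "sup", "voies", "arterielle",
             "retro", "isch", "acci vas")
  for (t in c(2477L, 4578L, 15L)) {
    pts <- feasible_points(space, t, trm, J = 30L)
    oracle <- Filter(function(q) {
      !is.na(rank_of_label(trm, t, q, J = 30L))
    }, space)
    expect_setequal(pts$query, oracle)
    for (i in seq_len(nrow(pts))) {
      expect_equal(pts$j[i], rank_of_label(trm, t, pts$query[i], J = 30L))
      expect_equal(pts$k[i], nchar(pts$query[i]))
    }
  }
  # a query space reaching nothing
  expect_equal(nrow(feasible_points("zzz", 2477L, trm)), 0L)
  expect_error(feasible_points("avc", 1L, trm), "unknown")
})

test_that("pareto front keeps exactly the non-dominated points", {
  expect_equal(pareto_front(data.frame(k = 3, j = 1))[, c("k", "j")],
               tibble::tibble(k = 3, j = 1))
  fr <- pareto_front(data.frame(k = c(3, 5, 4, 6), j = c(5, 2, 7, 1)))
  expect_equal(fr$k, c(3, 5, 6))
  expect_equal(fr$j, c(5, 2, 1))
  # the single-optimum pattern: one point dominates everything
  fr2 <- pareto_front(data.frame(k = c(3, 4, 10), j = c(1, 1, 1)))
  expect_equal(nrow(fr2), 1L)
  expect_equal(unlist(fr2[, c("k", "j")]), c(k = 3, j = 1))
  expect_error(pareto_front(data.frame(k = numeric(0), j = numeric(0))),
               "non-empty")
})

test_that("sorted front equals the brute-force front on random point sets", {
  set.seed(123)
  for (rep in 1:300) {
    n <- sample.int(50, 1)
    pts <- data.frame(k = sample.int(100, n, TRUE),
                      j = sample.int(100, n, TRUE))
    got <- pareto_front(pts)
    want <- brute_force_front(pts$k, pts$j)
    expect_identical(
      sort(paste(got$k, got$j)),
      sort(paste(want$k, want$j))
    )
  }
})

test_that("duplicate objective pairs keep the lexicographically smallest query", {
  fr <- pareto_front(data.frame(k = c(3, 3), j = c(1, 1),
                                query = c("bb", "aa")))
  expect_equal(fr$query, "aa")
})

test_that("extreme optima are the ends of the front", {
  pts <- data.frame(k = c(3, 5, 6), j = c(5, 2, 1))
  eo <- extreme_optima(pts)
  expect_equal(unlist(eo$shortest[, c("k", "j")]), c(k = 3, j = 5))
  expect_equal(unlist(eo$best_rank[, c("k", "j")]), c(k = 6, j = 1))
  one <- extreme_optima(data.frame(k = 3, j = 1))
  expect_equal(one$shortest, one$best_rank)
  set.seed(9)
  for (rep in 1:50) {
    pts <- data.frame(k = sample.int(40, 50, TRUE),
                      j = sample.int(40, 50, TRUE))
    fr <- pareto_front(pts)
    eo <- extreme_optima(pts)
    expect_true(paste(eo$shortest$k, eo$shortest$j) %in% paste(fr$k, fr$j))
    expect_true(paste(eo$best_rank$k, eo$best_rank$j) %in% paste(fr$k, fr$j))
  }
})

test_that("distance to front is the exhaustive minimum and zero only on it", {
  front <- data.frame(k = c(3, 4), j = c(1, 2))
  expect_equal(distance_to_front(3, 1, front), 0)
  expect_equal(distance_to_front(5, 4, front), sqrt(5))
  set.seed(77)
  for (rep in 1:50) {
    fr <- brute_force_front(sample.int(30, 10, TRUE), sample.int(30, 10, TRUE))
    k <- sample.int(30, 1); j <- sample.int(30, 1)
    d <- distance_to_front(k, j, fr)
    expect_equal(d, min(sqrt((k - fr$k)^2 + (j - fr$j)^2)))
    expect_identical(d == 0, any(fr$k == k & fr$j == j))
  }
  expect_error(distance_to_front(1, 1, data.frame(k = numeric(0),
                                                  j = numeric(0))),
               "non-empty")
})

test_that("dominated points never change the front, dominating points never hurt", {
  set.seed(5)
  for (rep in 1:30) {
    pts <- data.frame(k = sample.int(50, 20, TRUE),
                      j = sample.int(50, 20, TRUE))
    fr <- pareto_front(pts)
    # add a point dominated by a front member
    dom <- data.frame(k = fr$k[1] + 3, j = fr$j[1] + 3)
    fr2 <- pareto_front(rbind(pts[, c("k", "j")], dom))
    expect_identical(sort(paste(fr2$k, fr2$j)), sort(paste(fr$k, fr$j)))
    # measuring against a superset of reference points never increases the
    # distance (re-fronting can: an advancing optimum widens gaps)
    strong <- data.frame(k = max(min(fr$k) - 1, 0), j = max(min(fr$j) - 1, 0))
    wider <- rbind(fr[, c("k", "j")], strong)
    qk <- sample.int(50, 5, TRUE); qj <- sample.int(50, 5, TRUE)
    expect_true(all(distance_to_front(qk, qj, wider) <=
                      distance_to_front(qk, qj, fr) + 1e-12))
    # the dominating point itself sits on the new front at distance zero
    fr3 <- pareto_front(rbind(pts[, c("k", "j")], strong))
    expect_equal(distance_to_front(strong$k, strong$j, fr3), 0)
  }
})

test_that("per-label fronts and distances flow through an enriched log", {
  trm <- generate_terminology(30, seed = 21)
  lex <- generate_idiom_lexicon(trm, seed = 21)
  log <- simulate_log(simulation_config(n_users = 8, n_labels = 30,
                                        n_events = 500, seed = 21), trm, lex)
  enr <- enrich_log(log, trm)
  fronts <- pareto_fronts(enr, trm)
  expect_true(all(fronts$label_id %in% enr$label_id))
  # per-label front invariants: k ascending, j strictly decreasing
  for (lid in unique(fronts$label_id)) {
    fr <- fronts[fronts$label_id == lid, ]
    expect_true(!is.unsorted(fr$k, strictly = TRUE))
    expect_true(all(diff(fr$j) < 0) || nrow(fr) == 1)
  }
  dst <- annotate_distance(enr, fronts)
  expect_true(all(dst$distance >= 0))
  # a record whose point lies on its label front has distance zero
  on_front <- merge(as.data.frame(dst), as.data.frame(fronts),
                    by.x = c("label_id", "qlen", "rank"),
                    by.y = c("label_id", "k", "j"))
  if (nrow(on_front) > 0) expect_true(all(on_front$distance == 0))
})
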