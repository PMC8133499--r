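test_that("per-hand aligner reproduces the canonical toy outcomes", {
  a <- align_hand(c(60, 62, 64), c(60, 62, 64))
  expect_equal(attr(a, "cost"), 0)
  expect_equal(a$status, rep("match", 3))

  b <- align_hand(c(60, 62, 64), c(60, 64))
  expect_equal(attr(b, "cost"), 0.6)
  expect_equal(b$status, c("match", "missed", "match"))
  expect_equal(attr(b, "cost"), oracle_align_cost(c(60, 62, 64), c(60, 64)))

  d <- align_hand(c(60, 62), c(60, 61, 62))
  expect_equal(attr(d, "cost"), 0.6)
  expect_equal(d$status[2], "extra")
  expect_equal(attr(d, "cost"), oracle_align_cost(c(60, 62), c(60, 61, 62)))

  e <- align_hand(integer(0), c(60, 62))
  expect_equal(attr(e, "cost"), 1.2)
  expect_equal(e$status, c("extra", "extra"))
})

test_that("DP cost equals the exhaustive-matching minimum on random toys", {
  set.seed(402)
  for (rep in 1:40) {
    n <- sample(1:8, 1); m <- sample(1:8, 1)
    sp <- sample(58:66, n, TRUE)
    pp <- sample(58:66, m, TRUE)
    expect_equal(attr(align_hand(sp, pp), "cost"), oracle_align_cost(sp, pp),
                 info = paste("score", paste(sp, collapse = ","),
                              "perf", paste(pp, collapse = ",")))
  }
})

test_that("alignment invariants hold: every score note once, order kept", {
  set.seed(77)
  sp <- sample(55:70, 8, TRUE)
  pp <- sample(55:70, 10, TRUE)
  a <- align_hand(sp, pp)
  sc <- a$score_ordinal[!is.na(a$score_ordinal)]
  expect_equal(sort(sc), 0:(length(sp) - 1))
  pf <- a$perf_index[!is.na(a$perf_index)]
  expect_equal(pf, sort(pf))
  matched <- a[a$status %in% c("match", "sub"), ]
  expect_true(all(diff(matched$score_ordinal) > 0))
  expect_true(all(diff(matched$perf_index) > 0))
})

test_that("joint hand assignment recovers the truth on clean input", {
  sc <- toy_unison_score(c(60, 62, 64, 65))
  p <- generate_performance(sc, noise_free_params(), performer_seed = 5)
  h <- split_hands(p, sc)
  expect_equal(h$cost, 0)
  expect_equal(h$assignment$hand, p$truth_hand)
  expect_equal(sum(h$rh$status == "match"), 4)
  expect_equal(sum(h$lh$status == "match"), 4)
})

test_that("a dropped left-hand note is reported missed, nothing else", {
  sc <- toy_unison_score(c(60, 62, 64, 65))
  p <- generate_performance(sc, noise_free_params(), performer_seed = 5)
  drop_row <- which(p$truth_hand == "LH")[2]
  p2 <- piano_performance(as.data.frame(p)[-drop_row, ],
                          excerpt_id = attr(p, "excerpt_id"))
  h <- split_hands(p2, sc)
  expect_equal(h$cost, 0.6)
  expect_equal(h$lh$status[h$lh$score_ordinal == 1], "missed")
  expect_equal(sum(h$lh$status == "missed"), 1)
  expect_equal(sum(h$rh$status != "match"), 0)
})

test_that("one inserted wrong pitch yields exactly one extra", {
  sc <- toy_unison_score(c(60, 62, 64, 65))
  p <- generate_performance(sc, noise_free_params(), performer_seed = 5)
  ins <- data.frame(pitch = 59, onset_sec = p$onset_sec[3] + 0.01,
                    offset_sec = p$onset_sec[3] + 0.1, velocity = 60,
                    source_track = 1L, truth_hand = "LH")
  p2 <- piano_performance(rbind(as.data.frame(p), ins))
  h <- split_hands(p2, sc)
  expect_equal(sum(h$assignment$status == "extra"), 1)
  expect_equal(sum(h$rh$status == "match") + sum(h$lh$status == "match"), 8)
})

test_that("alignment ignores global time shifts and velocity scaling", {
  sc <- small_excerpts()$scale
  p <- generate_performance(sc, group_params("amateur"), performer_seed = 9)
  h0 <- split_hands(p, sc)
  shifted <- as.data.frame(p)
  shifted$onset_sec <- shifted$onset_sec + 12.3
  shifted$offset_sec <- shifted$offset_sec + 12.3
  shifted$velocity <- pmin(127, pmax(1, shifted$velocity * 0.5))
  h1 <- split_hands(piano_performance(shifted), sc)
  expect_equal(h1$cost, h0$cost)
  expect_equal(as.data.frame(h1$rh), as.data.frame(h0$rh))
  expect_equal(as.data.frame(h1$lh), as.data.frame(h0$lh))
})

test_that("hand assignment stays above 99% on low-error cohorts", {
  excerpts <- small_excerpts()
  total <- 0; correct <- 0
  for (seed in 1:6) {
    for (exc in excerpts) {
      pars <- group_params(if (seed %% 2) "expert" else "amateur",
                           error_wrong = 0.02, error_miss = 0.02,
                           error_extra = 0.02)
      p <- generate_performance(exc, pars, performer_seed = 1000 + seed)
      h <- split_hands(p, exc)
      ok <- !is.na(h$assignment$hand)
      total <- total + nrow(p)
      correct <- correct + sum(h$assignment$hand[ok] == p$truth_hand[ok])
    }
  }
  expect_gte(correct / total, 0.99)
})
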