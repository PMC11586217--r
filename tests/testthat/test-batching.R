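test_that("max batch size is half the smallest change-point gap", {
  expect_equal(max_batch_size(change_point_set(c(10, 20, 35), 50)), 5L)
  expect_equal(max_batch_size(change_point_set(c(3, 4), 10)), 1L)
  # < 2 points: floor(n/4), capped
  expect_equal(max_batch_size(change_point_set(integer(0), 100)), 25L)
  expect_equal(max_batch_size(change_point_set(7L, 1000)), 50L)
})

test_that("max batch size always admits a window inside every gap", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(60:300, 1)
    pts <- sort(sample(seq_len(n), sample(2:8, 1)))
    pts <- pts[c(TRUE, diff(pts) > 0)]
    if (length(pts) < 2) next
    smax <- max_batch_size(change_point_set(pts, n))
    expect_equal(smax, max(1L, min(diff(pts)) %/% 2L))
    for (i in seq_len(length(pts) - 1)) {
      gap <- pts[i + 1] - pts[i]
      if (gap >= 2) {
        # restrict the exhaustive enumeration to the open interval
        vs <- brute_valid_starts(n, smax, pts)
        inside <- vs[vs > pts[i] & vs + smax - 1 < pts[i + 1]]
        expect_gte(length(inside), 1)
      }
    }
  }
})

test_that("window containment matches the worked batch-selection example", {
  # batch [23, 28] with the change point at 34: permissible
  expect_false(window_contains_changepoint(window_sample(23, 28),
                                           change_point_set(34, 40)))
  # batch [31, 36]: the change point lies inside, not allowed
  expect_true(window_contains_changepoint(window_sample(31, s = 6),
                                          change_point_set(34, 40)))
  expect_false(window_contains_changepoint(window_sample(1, 10),
                                           change_point_set(integer(0), 40)))
})

test_that("valid_starts enumerates exactly the change-point-free windows", {
  expect_equal(valid_starts(10, 3, integer(0)), 1:8)
  expect_equal(valid_starts(10, 3, 6L), c(1L, 2L, 3L, 7L, 8L))
  expect_length(valid_starts(6, 6, 3L), 0)
  expect_error(valid_starts(5, 6, integer(0)), "longer")
  set.seed(22)
  for (rep in 1:25) {
    n <- sample(20:80, 1)
    s <- sample(2:8, 1)
    pts <- sort(sample(seq_len(n), sample(0:5, 1)))
    pts <- unique(pts)
    expect_equal(valid_starts(n, s, pts), brute_valid_starts(n, s, pts))
  }
})

test_that("valid_starts margin also protects the forecast target", {
  # s = 3 with margin 1 must exclude windows whose target (start+3) is a cp
  vs <- valid_starts(10, 3, 6L, margin = 1)
  expect_true(all(vs + 3 != 6))
  expect_equal(vs, brute_valid_starts(10, 4, 6L))
})

test_that("sampled windows never cover a change point", {
  set.seed(23)
  cps <- change_point_set(34L, 40)
  for (i in 1:2000) {
    w <- sample_valid_window(40, 6, cps)
    expect_false(window_contains_changepoint(w, cps))
  }
  expect_error(sample_valid_window(6, 6, change_point_set(3L, 6)),
               "no valid window")
})

test_that("minibatch assembly respects the filter and the seed", {
  fx <- std_fixture()
  n <- nrow(fx$series)
  cps <- fx$change_points
  s <- 14
  set.seed(1)
  batches <- make_training_batches(n, s, cps, minibatch_size = 32)
  expect_true(all(vapply(batches, nrow, integer(1)) == 32))
  viol <- 0L
  for (b in batches) {
    for (j in seq_len(nrow(b))) {
      viol <- viol + window_contains_changepoint(
        window_sample(b$start[j], b$end[j]), cps)
    }
  }
  expect_equal(viol, 0L)
  # determinism under a fixed seed
  set.seed(99)
  b1 <- make_training_batches(n, s, cps, minibatch_size = 8)
  set.seed(99)
  b2 <- make_training_batches(n, s, cps, minibatch_size = 8)
  expect_identical(b1, b2)
  expect_error(make_training_batches(n, s, cps, minibatch_size = 0), ">= 1")
})

test_that("an unconstrained epoch covers the whole index range", {
  set.seed(31)
  n <- 60
  batches <- make_training_batches(n, 5, integer(0), batches_per_epoch = 40,
                                   minibatch_size = 16)
  covered <- sort(unique(unlist(lapply(batches, function(b)
    unlist(Map(seq.int, b$start, b$end))))))
  expect_equal(covered, 1:60)
})
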