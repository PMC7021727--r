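# Track speeds, cohort summaries, and the Mann-Whitney rank-sum comparison.

fake_track <- function(frame, x, y, assigned = 1L) {
  list(id = 1L,
       samples = data.frame(frame = frame, x = x, y = y,
                            det_x = x, det_y = y,
                            assigned = rep_len(assigned, length(frame))))
}

test_that("track speed is displacement over time with physical units", {
  tr <- fake_track(0:10, 2 * (0:10), rep(0, 11))
  # 2 px/frame * 0.5 um/px / 0.05 s = 20 um/s
  expect_equal(track_speed(tr, 0.5, 0.05), 20)
  expect_equal(track_speed(fake_track(0:5, rep(3, 6), rep(4, 6)), 0.5, 0.05), 0)
  expect_error(track_speed(fake_track(0, 1, 1), 0.5, 0.05), "undefined")
})

test_that("a coast gap enters the speed through its frame difference", {
  s <- data.frame(frame = c(0, 1, 4, 5), x = c(0, 2, 8, 10),
                  y = 0, det_x = NA, det_y = NA, assigned = 1L)
  tr <- list(samples = s)
  hand <- mean(c(2 / 1, 6 / 3, 2 / 1)) * 0.5 / 0.05  # per-pair oracle
  expect_equal(track_speed(tr, 0.5, 0.05), hand)
})

test_that("speed scales with pixel size, inversely with frame interval, and is rigid-motion invariant", {
  set.seed(4)
  xs <- cumsum(rnorm(12, 2)); ys <- cumsum(rnorm(12, 1))
  tr <- fake_track(0:11, xs, ys)
  v <- track_speed(tr, 0.5, 0.05)
  expect_equal(track_speed(tr, 1.0, 0.05), 2 * v)
  expect_equal(track_speed(tr, 0.5, 0.10), v / 2)
  th <- 0.7
  rot <- fake_track(0:11, cos(th) * xs - sin(th) * ys + 40,
                    sin(th) * xs + cos(th) * ys - 13)
  expect_equal(track_speed(rot, 0.5, 0.05), v)
})

test_that("flow summary averages speeds and unit displacement directions", {
  trs <- structure(list(fake_track(0:9, 1 * (0:9), rep(0, 10)),
                        fake_track(0:9, 3 * (0:9), rep(5, 10))),
                   class = "bead_tracks")
  fs <- summarize_flow(trs, 0.5, 0.05)  # speeds 10 and 30 um/s
  expect_equal(fs$per_track_speed, c(10, 30), ignore_attr = TRUE)
  expect_equal(fs$mean_speed, 20)
  expect_equal(fs$direction, c(1, 0))   # all moving +x
  expect_identical(fs$n_tracks, 2L)
  expect_error(summarize_flow(structure(list(), class = "bead_tracks"),
                              0.5, 0.05), "no track")
})

test_that("isotropic random walks give a near-zero resultant direction", {
  set.seed(10)
  trs <- structure(lapply(1:100, function(i) {
    fake_track(0:20, cumsum(c(0, rnorm(20))), cumsum(c(0, rnorm(20))))
  }), class = "bead_tracks")
  fs <- summarize_flow(trs, 0.5, 0.05)
  expect_lte(sqrt(sum(fs$direction^2)), 0.2)
})

test_that("rank-sum U follows the exact enumeration on small groups", {
  r <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$U, 4.5)                 # n1 n2 / 2 under perfect symmetry
  expect_equal(r$U_a + r$U_b, 9)

  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$U_a, 0)
  expect_equal(r$U_b, 4)
  expect_equal(r$p, 2 / 6)               # 2 of the 6 orderings as extreme
  expect_match(r$method, "exact")

  expect_error(rank_sum_test(numeric(0), 1), "nonempty")
})

test_that("U_a + U_b = n1 n2 and ties are handled by midranks", {
  set.seed(20)
  for (rep in 1:20) {
    a <- sample(1:8, sample(3:10, 1), replace = TRUE)  # ties likely
    b <- sample(1:8, sample(3:10, 1), replace = TRUE)
    r <- rank_sum_test(a, b)
    expect_equal(r$U_a + r$U_b, length(a) * length(b))
    # cross-check U against the established implementation
    w <- suppressWarnings(stats::wilcox.test(a, b))
    expect_equal(r$U_a, unname(w$statistic))
  }
})

test_that("exact and normal-approximation p-values agree at n = 8 per group", {
  set.seed(30)
  for (rep in 1:10) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    re <- rank_sum_test(a, b)                      # exact path
    rn <- rank_sum_test(a, b, exact_limit = 1)     # force normal path
    expect_match(re$method, "exact")
    expect_match(rn$method, "normal")
    expect_lt(abs(re$p - rn$p), 0.02)
  }
})
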