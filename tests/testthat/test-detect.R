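# Detection chain: LoG response maps, local-optima extraction, non-minima
# suppression, heatmap merging, stationary removal.

test_that("apply_log is linear and null on the zero image", {
  bank <- build_log_bank(c(3, 5))
  z <- matrix(0, 32, 32)
  maps <- apply_log(z, bank)
  expect_true(all(vapply(maps, function(m) max(abs(m)), numeric(1)) < 1e-12))

  set.seed(7)
  f1 <- matrix(runif(32 * 32), 32)
  f2 <- matrix(runif(32 * 32), 32)
  lhs <- apply_log(2 * f1 + 3 * f2, bank)
  r1 <- apply_log(f1, bank); r2 <- apply_log(f2, bank)
  for (s in seq_along(lhs)) {
    rhs <- 2 * r1[[s]] + 3 * r2[[s]]
    expect_lt(max(abs(lhs[[s]] - rhs)) / max(abs(rhs)), 1e-9)
  }
})

test_that("an impulse reproduces the kernel and small images error out", {
  bank <- build_log_bank(3)   # 11 x 11 kernel
  f <- matrix(0, 25, 25); f[13, 13] <- 1
  m <- apply_log(f, bank)[[1]]
  expect_equal(m[8:18, 8:18], bank$kernels[[1]], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(apply_log(matrix(0, 8, 8), bank), "smaller than")
})

test_that("a rendered bead produces its global response minimum at center", {
  set.seed(11)
  sc <- make_bead_frame(h = 64, w = 64, n = 1, radius = 3)
  bank <- build_log_bank(3)
  m <- apply_log(sc$frame, bank)[[1]]
  opt <- which(m == min(m), arr.ind = TRUE)  # brute-force scan
  err <- sqrt((opt[1, 2] - 1 - sc$centers[1, 1])^2 +
              (opt[1, 1] - 1 - sc$centers[1, 2])^2)
  expect_lt(err, 1)
})

test_that("local optima respect the sensitivity threshold", {
  bank <- build_log_bank(1, sensitivity = 2)  # kernel 5x5, tau = 2
  flat <- matrix(1, 32, 32)
  expect_identical(nrow(extract_local_optima(list(flat), bank, 0L)), 0L)

  m <- matrix(0, 32, 32)
  m[10, 10] <- -20      # depth 10 tau
  m[10, 30 - 1] <- -20  # 19 px away
  det <- extract_local_optima(list(m), bank, 0L, exclude_border = FALSE)
  expect_identical(nrow(det), 2L)
  expect_true(all(det$response == -20))
  expect_setequal(det$x, c(9, 28))

  m2 <- matrix(0, 32, 32)
  m2[10, 10] <- -1      # depth tau/2: below sensitivity
  expect_identical(
    nrow(extract_local_optima(list(m2), bank, 0L, exclude_border = FALSE)),
    0L)
})

test_that("a flat minimum plateau yields one detection at its smallest pixel", {
  bank <- build_log_bank(1, sensitivity = 2)
  m <- matrix(0, 20, 20)
  m[8:9, 8:9] <- -10
  det <- extract_local_optima(list(m), bank, 0L, exclude_border = FALSE)
  expect_identical(nrow(det), 1L)
  expect_identical(c(det$y, det$x), c(7, 7))
})

test_that("suppression follows dominance and matches the brute force", {
  d <- new_det(frame = c(0, 0), x = c(10, 11), y = c(10, 10),
               response = c(-5, -9))
  out <- nonminima_suppression(d, radius = 3)
  expect_identical(nrow(out), 1L)
  expect_identical(out$response, -9)

  grid <- expand.grid(x = seq(0, 90, 10), y = seq(0, 90, 10))
  d <- new_det(frame = 0, x = grid$x, y = grid$y,
               response = -runif(nrow(grid), 1, 2))
  expect_identical(nrow(nonminima_suppression(d, 3)), nrow(grid))

  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    d <- new_det(frame = sample(0:1, n, replace = TRUE),
                 x = runif(n, 0, 30), y = runif(n, 0, 30),
                 response = -round(runif(n, 0, 10), 1))
    r <- runif(1, 1, 8)
    got <- nonminima_suppression(d, r)
    want <- d[oracle_suppression(d, r), , drop = FALSE]
    expect_equal(got[, names(want)], want, ignore_attr = TRUE)
    # idempotence
    expect_equal(nonminima_suppression(got, r)[, names(want)],
                 got[, names(got) != "stage"], ignore_attr = TRUE)
  }
})

test_that("heatmap merging combines close detections and keeps isolated ones", {
  cfg <- refine_config(heatmap_sigma = 2)
  d <- new_det(frame = c(0, 0), x = c(20, 21), y = c(15, 15),
               response = c(-4, -6))
  merged <- merge_by_heatmap(d, cfg, dim = c(40, 40))
  expect_identical(nrow(merged), 1L)
  expect_true(merged$x >= 20 && merged$x <= 21)  # between the pair
  expect_identical(merged$response, -6)          # strongest member

  iso <- new_det(frame = 0, x = 10, y = 25, response = -3)
  expect_identical(nrow(merge_by_heatmap(iso, cfg, c(40, 40))), 1L)

  empty <- new_det()
  expect_identical(nrow(merge_by_heatmap(empty, cfg, c(40, 40))), 0L)
})

test_that("stationary clusters are removed wholesale, movers are kept", {
  cfg <- refine_config(cheb_link_dist = 2, max_stationary_frames = 10)
  still <- new_det(frame = 0:99, x = rep(10, 100), y = rep(10, 100),
                   response = rep(-5, 100))
  expect_identical(nrow(remove_stationary(still, cfg)), 0L)

  mover <- new_det(frame = 0:99, x = 3 * (0:99), y = rep(10, 100),
                   response = rep(-5, 100))
  expect_identical(nrow(remove_stationary(mover, cfg)), 100L)

  expect_identical(nrow(remove_stationary(new_det(), cfg)), 0L)
})

test_that("complete-linkage Chebyshev clustering matches the merge oracle", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    xy <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    h <- runif(1, 0.5, 5)
    ours <- stats::cutree(
      stats::hclust(stats::dist(xy, method = "maximum"),
                    method = "complete"), h = h)
    expect_true(same_partition(ours, oracle_complete_linkage(xy, h)))
  }
})

test_that("detect_sequence localizes well-separated beads to within a pixel", {
  set.seed(5)
  sc <- make_bead_frame(h = 96, w = 96, n = 5, radius = 4, noise = 10)
  seq <- image_sequence(list(sc$frame))
  det <- detect_sequence(seq, drop_stationary = FALSE)
  expect_identical(nrow(det), 5L)
  for (b in seq_len(5)) {
    err <- min(sqrt((det$x - sc$centers[b, 1])^2 +
                    (det$y - sc$centers[b, 2])^2))
    expect_lt(err, 1)
  }
})
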