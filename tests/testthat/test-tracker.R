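# Kalman predict/update, gated minimum-cost association, frame-by-frame
# linking. Oracles: an independently written closed-form recursion (plain
# covariance update, not the package's Joseph form) and exhaustive
# assignment enumeration.

test_that("predict follows the constant-velocity transition", {
  m0 <- kalman_model(process_noise = diag(0, 4))
  pr <- kf_predict(c(0, 0, 1, 2), diag(0, 4), m0)
  expect_equal(pr$state, c(1, 2, 1, 2))

  mq <- kalman_model(process_noise = diag(0.7, 4))
  pr <- kf_predict(c(5, 5, 0, 0), diag(0, 4), mq)
  expect_equal(pr$P, diag(0.7, 4))
})

test_that("predict and update match the closed-form recursion", {
  set.seed(1)
  model <- kalman_model()
  for (rep in 1:50) {
    P <- random_psd(4)
    st <- rnorm(4)
    z <- rnorm(2)
    want <- oracle_kf(st, P, z, model$A, model$H, model$Q, model$R)
    pr <- kf_predict(st, P, model)
    expect_equal(pr$state, want$pred_state, tolerance = 1e-12)
    expect_equal(pr$P, want$pred_P, tolerance = 1e-12)
    up <- kf_update(pr$state, pr$P, z, model)
    expect_equal(up$state, want$state, tolerance = 1e-12)
    expect_equal(up$P, want$P, tolerance = 1e-10)
  }
})

test_that("update limits: R -> 0 pins to the detection, scalar gain is P/(P+R)", {
  m_small <- kalman_model(measurement_noise = diag(1e-12, 2))
  up <- kf_update(c(3, 4, 0, 0), diag(1, 4), c(7, 9), m_small)
  expect_equal(up$state[1:2], c(7, 9), tolerance = 1e-6)

  # diagonal case: position gain is exactly p / (p + r) per coordinate
  p <- 2.5; r <- 0.8
  m <- kalman_model(measurement_noise = diag(r, 2))
  up <- kf_update(c(0, 0, 0, 0), diag(c(p, p, 1, 1)), c(1, -2), m)
  expect_equal(up$state[1:2], c(1, -2) * p / (p + r), tolerance = 1e-12)

  m_big <- kalman_model(measurement_noise = diag(1e12, 2))
  up <- kf_update(c(3, 4, 0, 0), diag(1, 4), c(7, 9), m_big)
  expect_equal(up$state[1:2], c(3, 4), tolerance = 1e-6)
})

test_that("covariances stay symmetric PSD over long random predict/update runs", {
  set.seed(2)
  model <- kalman_model()
  P <- random_psd(4)
  st <- rnorm(4)
  for (i in 1:500) {
    pr <- kf_predict(st, P, model)
    up <- kf_update(pr$state, pr$P, rnorm(2, pr$state[1:2], 1), model)
    st <- up$state; P <- up$P
    expect_identical(P, t(P))
  }
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("larger process noise pulls the correction toward the detection", {
  z <- c(10, 10)
  st <- c(0, 0, 0, 0)
  P <- diag(1, 4)
  dists <- vapply(c(0.1, 1, 10, 100), function(q) {
    m <- kalman_model(process_noise = diag(q, 4))
    pr <- kf_predict(st, P, m)
    up <- kf_update(pr$state, pr$P, z, m)
    sqrt(sum((up$state[1:2] - z)^2))
  }, numeric(1))
  expect_true(all(diff(dists) < 0))
})

test_that("association is gated, one-to-one, and globally optimal", {
  a <- associate(matrix(c(5, 5), 1), matrix(c(5.2, 30, 5.1, 30), 2), 3)
  expect_identical(a, 1L)
  expect_identical(associate(matrix(c(5, 5), 1),
                             matrix(numeric(0), 0, 2), 3),
                   rep(NA_integer_, 1))

  # crossing configuration: greedy would mispair
  pred <- rbind(c(0, 0), c(1, 0))
  obs <- rbind(c(1.1, 0), c(2, 0))
  a <- associate(pred, obs, 5)
  expect_identical(a, c(1L, 2L))

  set.seed(3)
  for (rep in 1:30) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    pred <- matrix(runif(2 * n, 0, 10), n)
    obs <- matrix(runif(2 * m, 0, 10), m)
    gate <- runif(1, 2, 12)
    a <- associate(pred, obs, gate)
    d <- sqrt(outer(pred[, 1], obs[, 1], `-`)^2 +
              outer(pred[, 2], obs[, 2], `-`)^2)
    got <- matching_cost(d, a, gate)
    expect_true(all(is.na(a) | d[cbind(seq_len(n), a)] <= gate))
    expect_identical(anyDuplicated(a[!is.na(a)]), 0L)
    # maximum-cardinality feasible matching at minimum cost: compare against
    # enumeration restricted to matchings of the same cardinality
    best <- oracle_assignment_best(d, gate)
    expect_identical(got$n, best$n)
    expect_equal(got$cost, best$cost, tolerance = 1e-9)
  }
})

test_that("noiseless constant-velocity motion is recovered to numerical precision", {
  frames <- 0:29
  det <- new_det(frame = frames, x = 5 + 2 * frames, y = 20 + 0 * frames,
                 response = -5)
  trk <- track_sequence(det, kalman_model(), track_config())
  expect_length(trk, 1L)
  s <- trk[[1]]$samples
  late <- s$frame >= 20
  expect_lt(max(abs(s$x[late] - (5 + 2 * s$frame[late]))), 1e-6)
  expect_lt(max(abs(s$y[late] - 20)), 1e-6)
  expect_identical(sum(s$assigned), 30L)
})

test_that("short-lived tracks are pruned and coasting obeys max_misses", {
  det <- new_det(frame = 0:4, x = 10 + 2 * (0:4), y = 10, response = -5)
  trk <- track_sequence(det, config = track_config(min_visible_frames = 10),
                        n_frames = 30)
  expect_length(trk, 0L)

  # a 2-frame detection gap within max_misses: track survives and bridges
  fr <- c(0:9, 12:19)
  det <- new_det(frame = fr, x = 10 + 2 * fr, y = 10, response = -5)
  trk <- track_sequence(det, config = track_config(max_misses = 3),
                        n_frames = 20)
  expect_length(trk, 1L)
  s <- trk[[1]]$samples
  expect_identical(sum(s$assigned == 0L), 2L)  # the coasted frames 10, 11
  expect_equal(max(s$frame), 19)

  # a gap beyond max_misses splits the bead into two tracks
  fr <- c(0:9, 16:25)
  det <- new_det(frame = fr, x = 10 + 2 * fr, y = 10, response = -5)
  trk <- track_sequence(det, config = track_config(max_misses = 3),
                        n_frames = 26)
  expect_length(trk, 2L)
  # terminated at the last assignment: no trailing coasts
  expect_equal(max(trk[[1]]$samples$frame), 9)
})

test_that("an empty detection set yields an empty track list", {
  expect_length(track_sequence(new_det()), 0L)
})

test_that("simulated scene is recovered as single accurate tracks", {
  cfg <- scene_config(height = 128, width = 128, n_frames = 40, n_beads = 10,
                      flow_velocity = c(2, 1), diffusion_sigma = 0.3,
                      n_stationary = 0, detect_prob = 0.95,
                      noise_sigma = 10, seed = 7)
  sim <- generate_bead_video(cfg)
  det <- detect_sequence(sim$sequence, drop_stationary = FALSE)
  trk <- track_sequence(det, n_frames = 40)
  truth <- sim$truth[!sim$truth$stationary, ]
  # every track should shadow one true bead with small RMSE
  rmses <- vapply(trk, function(tr) {
    s <- tr$samples[tr$samples$assigned == 1L, ]
    errs <- vapply(seq_len(nrow(s)), function(i) {
      tt <- truth[truth$frame == s$frame[i], ]
      min(sqrt((tt$x - s$x[i])^2 + (tt$y - s$y[i])^2))
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_gte(length(trk), 8L)
  expect_lt(mean(rmses), 1)
})
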