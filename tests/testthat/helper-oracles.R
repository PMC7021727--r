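# Independent brute-force oracles used across the suite. Each is written
# from the definition, not from the package's code path.

# Build a detections data frame the way the package lays it out
# (sorted by frame, y, x, scale).
new_det <- function(frame = integer(), x = numeric(), y = numeric(),
                    response = numeric(), scale = 3) {
  if (length(frame) == 0L) scale <- numeric()
  df <- data.frame(frame = as.integer(frame), x = as.numeric(x),
                   y = as.numeric(y), scale = as.numeric(scale),
                   response = as.numeric(response))
  df <- df[order(df$frame, df$y, df$x, df$scale), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "stage") <- "raw"
  df
}

# Elementwise LoG kernel evaluation straight from the formula
# h(i,j) = (i^2 + j^2 - 2 s^2) g(i,j) / (s^4 sum(g)), g = exp(-(i^2+j^2)/2s^2)
oracle_log_kernel <- function(r) {
  s <- r / sqrt(2)
  w <- ceiling(2 * s)
  n <- 2 * w + 1
  g <- matrix(0, n, n)
  for (i in -w:w) for (j in -w:w) {
    g[i + w + 1, j + w + 1] <- exp(-(i^2 + j^2) / (2 * s^2))
  }
  h <- matrix(0, n, n)
  for (i in -w:w) for (j in -w:w) {
    h[i + w + 1, j + w + 1] <-
      (i^2 + j^2 - 2 * s^2) * g[i + w + 1, j + w + 1] / (s^4 * sum(g))
  }
  h
}

# All-pairs dominance filter: a detection is removed iff some other
# detection of the same frame within `radius` is stronger (more negative
# response; ties by (frame, y, x, scale) lexicographic order).
oracle_suppression <- function(det, radius) {
  n <- nrow(det)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || det$frame[i] != det$frame[j]) next
      dd <- sqrt((det$x[i] - det$x[j])^2 + (det$y[i] - det$y[j])^2)
      if (dd >= radius) next
      stronger <- det$response[j] < det$response[i] ||
        (det$response[j] == det$response[i] &&
           order_lex(det, j) < order_lex(det, i))
      if (stronger) keep[i] <- FALSE
    }
  }
  keep
}

order_lex <- function(det, i) {
  # scalar rank key for (frame, y, x, scale)
  which(order(det$frame, det$y, det$x, det$scale) == i)
}

# Brute-force agglomerative complete linkage under Chebyshev distance:
# repeatedly merge the pair of clusters with the smallest maximum pairwise
# distance, stopping when that exceeds h. Returns cluster labels.
oracle_complete_linkage <- function(xy, h) {
  n <- nrow(xy)
  clusters <- as.list(seq_len(n))
  cheb <- function(a, b) max(abs(xy[a, 1] - xy[b, 1]), abs(xy[a, 2] - xy[b, 2]))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      link <- max(vapply(clusters[[i]], function(a) {
        max(vapply(clusters[[j]], function(b) cheb(a, b), numeric(1)))
      }, numeric(1)))
      if (link < best) { best <- link; bi <- i; bj <- j }
    }
    if (best > h) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  lab <- integer(n)
  for (c in seq_along(clusters)) lab[clusters[[c]]] <- c
  lab
}

# Partition equality up to label permutation.
same_partition <- function(a, b) {
  identical(canonical_labels(a), canonical_labels(b))
}
canonical_labels <- function(lab) as.integer(factor(lab, levels = unique(lab)))

# Closed-form Kalman recursion in a different algebraic form than the
# package (plain covariance update P - K S K' instead of Joseph form).
oracle_kf <- function(state, P, z, A, H, Q, R) {
  xp <- A %*% state
  Pp <- A %*% P %*% t(A) + Q
  S <- H %*% Pp %*% t(H) + R
  K <- Pp %*% t(H) %*% solve(S)
  xs <- xp + K %*% (z - H %*% xp)
  Ps <- Pp - K %*% S %*% t(K)
  list(pred_state = as.numeric(xp), pred_P = Pp,
       state = as.numeric(xs), P = Ps)
}

# Random PSD matrix via M M' + eps I.
random_psd <- function(n, eps = 1e-6) {
  M <- matrix(rnorm(n * n), n)
  M %*% t(M) + diag(eps, n)
}

# Exhaustive gated one-to-one assignment: maximize the number of matched
# pairs first, then minimize total cost. Entries above `gate` are forbidden.
oracle_assignment_best <- function(d, gate) {
  n <- nrow(d); m <- ncol(d)
  best <- list(n = -1L, cost = Inf)
  cols <- seq_len(m)
  rec <- function(i, used, acc, k) {
    if (i > n) {
      if (k > best$n || (k == best$n && acc < best$cost)) {
        best <<- list(n = k, cost = acc)
      }
      return(invisible())
    }
    rec(i + 1L, used, acc, k)  # row i unmatched
    for (j in cols[!used]) {
      if (d[i, j] <= gate) {
        used2 <- used; used2[j] <- TRUE
        rec(i + 1L, used2, acc + d[i, j], k + 1L)
      }
    }
  }
  rec(1L, rep(FALSE, m), 0, 0L)
  best
}

# Total cost and cardinality of a gated matching.
matching_cost <- function(d, assignment, gate) {
  tot <- 0; k <- 0L
  for (i in seq_along(assignment)) {
    j <- assignment[i]
    if (!is.na(j)) { tot <- tot + d[i, j]; k <- k + 1L }
  }
  list(cost = tot, n = k)
}

# Synthetic single frame with well-separated Gaussian beads; returns the
# frame and the 0-based bead centers.
make_bead_frame <- function(h = 96, w = 96, n = 6, radius = 3, peak = 100,
                            background = 10, noise = 0, margin = NULL,
                            min_sep = NULL) {
  if (is.null(margin)) margin <- 4 * radius
  if (is.null(min_sep)) min_sep <- 4 * radius + 1
  centers <- matrix(NA_real_, 0, 2)
  while (nrow(centers) < n) {
    cand <- c(runif(1, margin, w - 1 - margin),
              runif(1, margin, h - 1 - margin))
    if (nrow(centers) == 0 ||
        min(sqrt((centers[, 1] - cand[1])^2 +
                 (centers[, 2] - cand[2])^2)) >= min_sep) {
      centers <- rbind(centers, cand)
    }
  }
  fr <- matrix(background, h, w)
  s <- radius / sqrt(2)
  for (b in seq_len(n)) {
    x <- centers[b, 1]; y <- centers[b, 2]
    for (i in seq_len(h)) for (j in seq_len(w)) {
      fr[i, j] <- fr[i, j] +
        peak * exp(-(((j - 1) - x)^2 + ((i - 1) - y)^2) / (2 * s^2))
    }
  }
  if (noise > 0) fr <- pmax(fr + matrix(rnorm(h * w, 0, noise), h), 0)
  list(frame = fr, centers = centers)
}
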