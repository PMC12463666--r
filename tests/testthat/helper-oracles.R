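# Independent brute-force oracles and small fixtures, built in code.

# Voxelised solid sphere mask.
voxel_sphere <- function(dim = 32L, radius = 10, spacing = 1) {
  ctr <- (dim - 1) / 2
  idx <- seq_len(dim) - 1
  occ <- array(0L, c(dim, dim, dim))
  for (k in seq_len(dim)) {
    d2 <- outer((idx - ctr)^2, (idx - ctr)^2, "+") + (idx[k] - ctr)^2
    occ[, , k] <- (sqrt(d2) * spacing <= radius) * 1L
  }
  voxel_mask(occ, rep(spacing, 3))
}

# Voxelised solid ellipsoid mask.
voxel_ellipsoid <- function(dim = 48L, radii = c(18, 14, 20), spacing = 1) {
  ctr <- (dim - 1) / 2
  idx <- seq_len(dim) - 1
  occ <- array(0L, c(dim, dim, dim))
  for (k in seq_len(dim)) {
    q <- outer(((idx - ctr) * spacing / radii[1])^2,
               ((idx - ctr) * spacing / radii[2])^2, "+") +
      ((idx[k] - ctr) * spacing / radii[3])^2
    occ[, , k] <- (q <= 1) * 1L
  }
  voxel_mask(occ, rep(spacing, 3))
}

# Brute-force TFCE: explicit loop over thresholds and connected components.
bf_tfce <- function(stat, edges, E, H, n_steps, w = rep(1, length(stat))) {
  nv <- length(stat)
  h_max <- max(stat)
  if (h_max <= 0) return(numeric(nv))
  dh <- h_max / n_steps
  adj <- vector("list", nv)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
  }
  out <- numeric(nv)
  for (k in seq_len(n_steps)) {
    h <- dh * k
    active <- stat >= h
    lab <- rep(NA_integer_, nv)
    cur <- 0L
    for (v in which(active)) {
      if (!is.na(lab[v])) next
      cur <- cur + 1L
      queue <- v
      lab[v] <- cur
      while (length(queue)) {
        x <- queue[1]; queue <- queue[-1]
        for (nb in adj[[x]]) {
          if (active[nb] && is.na(lab[nb])) { lab[nb] <- cur; queue <- c(queue, nb) }
        }
      }
    }
    for (v in which(active)) {
      ext <- sum(w[lab == lab[v] & !is.na(lab)])
      out[v] <- out[v] + ext^E * h^H * dh
    }
  }
  out
}

# Random connected-ish graph for TFCE oracle checks.
random_graph <- function(nv, p_edge = 0.15) {
  pairs <- which(upper.tri(matrix(0, nv, nv)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  e <- pairs[keep, , drop = FALSE]
  # chain to guarantee some structure
  chain <- cbind(seq_len(nv - 1), 2:nv)
  storage.mode(e) <- "integer"
  storage.mode(chain) <- "integer"
  unique(rbind(e, chain))
}

# Dense-sampling oracle for min distance from a point to a triangle.
bf_point_triangle <- function(p, a, b, c3, n = 201) {
  s <- seq(0, 1, length.out = n)
  best <- Inf
  for (u in s) {
    vmax <- 1 - u
    vs <- seq(0, vmax, length.out = max(2, ceiling(n * vmax)))
    pts <- outer(rep(1, length(vs)), a) + u * outer(rep(1, length(vs)), b - a) +
      vs %o% (c3 - a)
    d <- sqrt(rowSums(sweep(pts, 2, p)^2))
    best <- min(best, min(d))
  }
  best
}

# Two-visit random-intercept data with known variance components.
sim_lmm_data <- function(n = 200, sigma_b = 2, sigma = 1, beta_visit = 0.8,
                         beta_age = 0.3) {
  b <- rnorm(n, 0, sigma_b)
  age <- rnorm(n)
  dat <- data.frame(subject = rep(seq_len(n), each = 2),
                    visit = rep(0:1, n), age = rep(age, each = 2))
  dat$y <- 10 + beta_visit * dat$visit + beta_age * dat$age +
    b[dat$subject] + rnorm(2 * n, 0, sigma)
  dat
}
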