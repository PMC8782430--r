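# Independent brute-force oracles for the texture descriptors. Written as
# plain double loops, deliberately sharing no code with the package, so that
# agreement is a genuine cross-check.

oracle_quantize <- function(p, nl) {
  mx <- max(p)
  out <- matrix(1L, nrow(p), ncol(p))
  if (mx > 0) {
    for (r in 1:nrow(p)) for (c in 1:ncol(p)) {
      lv <- trunc(p[r, c] * nl / mx) + 1
      out[r, c] <- as.integer(min(lv, nl))
    }
  }
  out
}

# value at (r, c) of patch with replicate padding
.pix <- function(p, r, c) {
  p[min(max(r, 1), nrow(p)), min(max(c, 1), ncol(p))]
}

oracle_sobel_mag <- function(p) {
  g <- matrix(0, nrow(p), ncol(p))
  for (r in 1:nrow(p)) for (c in 1:ncol(p)) {
    gx <- .pix(p, r + 1, c - 1) + 2 * .pix(p, r + 1, c) + .pix(p, r + 1, c + 1) -
          .pix(p, r - 1, c - 1) - 2 * .pix(p, r - 1, c) - .pix(p, r - 1, c + 1)
    gy <- .pix(p, r - 1, c + 1) + 2 * .pix(p, r, c + 1) + .pix(p, r + 1, c + 1) -
          .pix(p, r - 1, c - 1) - 2 * .pix(p, r, c - 1) - .pix(p, r + 1, c - 1)
    g[r, c] <- sqrt(gx^2 + gy^2)
  }
  g
}

oracle_ggcm <- function(p, nh, ng) {
  fl <- oracle_quantize(p, nh)
  gl <- oracle_quantize(oracle_sobel_mag(p), ng)
  H <- matrix(0L, nh, ng)
  for (r in 1:nrow(p)) for (c in 1:ncol(p)) {
    H[fl[r, c], gl[r, c]] <- H[fl[r, c], gl[r, c]] + 1L
  }
  H
}

oracle_idm <- function(p, nh, ng) {
  H <- oracle_ggcm(p, nh, ng)
  P <- H / sum(H)
  s <- 0
  for (i in 1:nh) for (j in 1:ng) s <- s + P[i, j] / (1 + (i - j)^2)
  s
}

# maximal runs of quantized patch q along direction offset (dr, dc);
# returns the run-length count matrix
oracle_rlm <- function(q, nh, dr, dc, max_run) {
  p <- matrix(0L, nh, max_run)
  for (r0 in 1:nrow(q)) for (c0 in 1:ncol(q)) {
    pr <- r0 - dr; pc <- c0 - dc
    if (pr >= 1 && pr <= nrow(q) && pc >= 1 && pc <= ncol(q)) next
    r <- r0; c <- c0
    cur <- q[r, c]; len <- 0L
    while (r >= 1 && r <= nrow(q) && c >= 1 && c <= ncol(q)) {
      if (q[r, c] == cur) len <- len + 1L
      else {
        p[cur, len] <- p[cur, len] + 1L
        cur <- q[r, c]; len <- 1L
      }
      r <- r + dr; c <- c + dc
    }
    p[cur, len] <- p[cur, len] + 1L
  }
  p
}

oracle_lrlge <- function(patch, nh) {
  q <- oracle_quantize(patch, nh)
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  vals <- sapply(dirs, function(d) {
    mr <- if (d[2] == 0) nrow(q) else if (d[1] == 0) ncol(q) else min(dim(q))
    p <- oracle_rlm(q, nh, d[1], d[2], mr)
    s <- 0
    for (i in 1:nrow(p)) for (j in 1:ncol(p)) s <- s + p[i, j] * j^2 / i^2
    s / sum(p)
  })
  mean(vals)
}

oracle_glcm_corr <- function(patch, nh) {
  q <- oracle_quantize(patch, nh)
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  vals <- sapply(dirs, function(d) {
    C <- matrix(0, nh, nh)
    for (r in 1:nrow(q)) for (c in 1:ncol(q)) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
      C[q[r, c], q[r2, c2]] <- C[q[r, c], q[r2, c2]] + 1
      C[q[r2, c2], q[r, c]] <- C[q[r2, c2], q[r, c]] + 1
    }
    if (sum(C) == 0) return(0)
    P <- C / sum(C)
    mi <- 0; mj <- 0
    for (i in 1:nh) for (j in 1:nh) { mi <- mi + i * P[i, j]; mj <- mj + j * P[i, j] }
    vi <- 0; vj <- 0; cv <- 0
    for (i in 1:nh) for (j in 1:nh) {
      vi <- vi + (i - mi)^2 * P[i, j]
      vj <- vj + (j - mj)^2 * P[i, j]
      cv <- cv + (i - mi) * (j - mj) * P[i, j]
    }
    if (sqrt(vi) * sqrt(vj) < 1e-12) 0 else cv / (sqrt(vi) * sqrt(vj))
  })
  mean(vals)
}

# small reusable fixtures -----------------------------------------------

small_model <- function(grid = 32, n_radial = 49, n_angles = 40) {
  system_model(grid, n_radial, n_angles)
}

# a reduced 6-frame study on a 64x64 phantom (composites split cleanly 2/2/2)
small_study <- function(seed = 11, realizations = 1, total = 2e6) {
  ph <- brain_phantom(64)
  sch <- frame_schedule(rep(100, 6))
  imgs <- render_dynamic_images(ph, default_tacs(), sch)
  m <- system_model(64, n_radial = 95, n_angles = 60)
  acq <- simulate_acquisition(imgs, m,
    acquisition_settings(total, 0.2, realizations, seed = seed))
  list(phantom = ph, schedule = sch, images = imgs, model = m, acq = acq)
}
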