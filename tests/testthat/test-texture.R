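test_that("gray-level quantization follows the normalization rule with clamping", {
  q <- quantize_gray(matrix(c(4, 8), 1, 2), 8)
  expect_identical(q$levels[1, 1], 5L)   # floor(4*8/8) + 1
  expect_identical(q$levels[1, 2], 8L)   # raw rule gives 9; clamped
  expect_equal(q$f_max, 8)

  const <- quantize_gray(matrix(3, 4, 4), 8)
  expect_true(all(const$levels == 8L))   # patch max maps to top level
  expect_true(all(quantize_gray(matrix(0, 3, 3), 8)$levels == 1L))
  expect_error(quantize_gray(matrix(-1, 2, 2)), "nonnegative")

  # monotone in source intensity
  set.seed(4)
  p <- matrix(runif(25), 5, 5)
  lv <- quantize_gray(p, 8)$levels
  expect_true(all(diff(lv[order(p)]) >= 0))
})

test_that("sobel gradient matches hand-computed kernels and is rotation-consistent", {
  flat <- sobel_gradient(matrix(5, 5, 5))
  expect_true(all(flat$g == 0))
  expect_true(all(flat$levels == 1L))

  # step across rows of height h: interior |gx| = 4h, gy = 0
  h <- 2.5
  p <- matrix(0, 6, 6); p[4:6, ] <- h
  sg <- sobel_gradient(p)
  expect_equal(abs(sg$gx[3, 3]), 4 * h)
  expect_equal(abs(sg$gx[4, 3]), 4 * h)
  expect_true(all(sg$gy == 0))

  # 90-degree rotation (transpose) swaps gx and gy magnitudes
  set.seed(5)
  q <- matrix(runif(25), 5, 5)
  a <- sobel_gradient(q); b <- sobel_gradient(t(q))
  expect_equal(abs(t(b$gy)), abs(a$gx))
  expect_equal(sort(a$g), sort(b$g))
})

test_that("GGCM counts and IDM match direct evaluation", {
  # constant patch: one (level, gradient) cell holds all counts
  gm <- ggcm(matrix(7, 4, 4))
  expect_equal(sum(gm$H), 16)
  expect_equal(max(gm$H), 16L)
  expect_equal(sum(gm$P), 1)
  expect_equal(gm$H[8, 1], 16L)  # level 8 (clamped max), gradient level 1

  # diagonal mass gives IDM = 1; a single off-diagonal cell gives 1/(1+d^2)
  P <- matrix(0, 8, 8); diag(P) <- 1 / 8
  expect_equal(idm(P), 1)
  P2 <- matrix(0, 8, 8); P2[8, 1] <- 1
  expect_equal(idm(P2), 1 / 50)
  expect_equal(idm(P2), 0.02)
  expect_error(idm(matrix(0.3, 2, 2)), "normalized")

  # checkerboard and random patches against the brute-force oracle
  chk <- matrix(c(1, 8, 1, 8, 8, 1, 8, 1, 1, 8, 1, 8, 8, 1, 8, 1), 4, 4)
  expect_equal(ggcm(chk)$H, oracle_ggcm(chk, 8, 8))
  set.seed(6)
  for (i in 1:20) {
    p <- matrix(runif(25, 0, 10), 5, 5)
    expect_equal(ggcm(p)$H, oracle_ggcm(p, 8, 8))
    expect_equal(idm(ggcm(p)$P), oracle_idm(p, 8, 8))
  }
})

test_that("GLRLM counts maximal runs and conserves pixel count", {
  r1 <- glrlm(matrix(c(1L, 1L, 2L), 1, 3), 8, "0")
  expect_equal(r1$p[1, 2], 1L)
  expect_equal(r1$p[2, 1], 1L)
  expect_equal(r1$n_r, 2L)

  # all-distinct at 0 degrees: every run has length 1
  d <- matrix(1:8, 2, 4)
  rd <- glrlm(d, 8, "0")
  expect_true(all(rd$p[, -1] == 0))
  expect_equal(rd$n_r, 8L)

  # constant 3x3 at 0 degrees: three rows of one 3-run each
  rc <- glrlm(matrix(5L, 3, 3), 8, "0")
  expect_equal(rc$p[5, 3], 3L)
  expect_equal(rc$n_r, 3L)

  expect_error(glrlm(matrix(1L, 2, 2), 8, "30"))
  expect_error(glrlm(matrix(9L, 2, 2), 8, "0"), "gray levels")

  # pixel-count conservation in every direction, random quantized patches
  set.seed(7)
  for (i in 1:20) {
    q <- matrix(sample(1:8, 9, replace = TRUE), 3, 3)
    for (dir in c("0", "45", "90", "135")) {
      r <- glrlm(q, 8, dir)
      expect_equal(sum(r$p * col(r$p)), 9)
    }
  }
})

test_that("LRLGE evaluates the run-length statistic and responds to run length", {
  # single run: level 1, length 3 -> 9; level 1, length 1 -> 1
  expect_equal(lrlge(glrlm(matrix(1L, 1, 3), 8, "0")), 9)
  expect_equal(lrlge(glrlm(matrix(1L, 1, 1), 8, "0")), 1)

  # four-direction mean on a constant patch vs brute force
  p <- matrix(8, 3, 3)
  dirs <- lapply(c("0", "45", "90", "135"), function(d)
    glrlm(quantize_gray(p)$levels, 8, d))
  expect_equal(lrlge(dirs), oracle_lrlge(p, 8))

  # longer runs at a fixed level never decrease LRLGE
  vals <- sapply(1:5, function(L) lrlge(glrlm(matrix(2L, 1, L), 8, "0")))
  expect_true(all(diff(vals) >= 0))
})

test_that("GLCM correlation is 1 on aligned stripes, ~0 on noise, transpose-invariant", {
  stripes <- matrix(rep(c(1, 9), each = 6), 6, 2)  # rows constant per stripe? no:
  stripes <- matrix(rep(c(1, 9), 3), 6, 6)          # alternating rows
  expect_equal(glcm_correlation(stripes, 8, directions = "0"), 1)

  set.seed(8)
  vals <- replicate(100, glcm_correlation(matrix(runif(81), 9, 9), 8))
  expect_lt(mean(abs(vals)), 0.2)
  expect_lt(abs(mean(vals)), 0.1)

  p <- matrix(runif(25), 5, 5)
  expect_equal(glcm_correlation(p), glcm_correlation(t(p)), tolerance = 1e-12)
  expect_equal(glcm_correlation(matrix(4, 3, 3)), 0)  # zero-variance marginal
})

test_that("feature maps equal the per-window composition and slide equivariantly", {
  # constant positive image: single GGCM cell at (8, 1) -> IDM 0.02 everywhere
  f <- feature_image(matrix(3, 10, 10), "idm")
  expect_equal(f, matrix(0.02, 10, 10))
  expect_identical(dim(feature_image(matrix(runif(80), 10, 8), "lrlge")),
                   c(10L, 8L))

  set.seed(9)
  img <- matrix(runif(12 * 10, 0, 5), 12, 10)
  pad <- function(m, h) m[pmin(pmax(row(matrix(0, nrow(m) + 2 * h, ncol(m) + 2 * h)) - h, 1), nrow(m)) +
                          (pmin(pmax(col(matrix(0, nrow(m) + 2 * h, ncol(m) + 2 * h)) - h, 1), ncol(m)) - 1) * nrow(m)]
  for (desc in c("idm", "lrlge", "glcm_correlation")) {
    w <- if (desc == "lrlge") 3L else 5L
    h <- w %/% 2
    fm <- feature_image(img, desc, w, normalization = "window")
    padded <- matrix(pad(img, h), nrow(img) + 2 * h, ncol(img) + 2 * h)
    ref <- matrix(0, nrow(img), ncol(img))
    for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
      patch <- padded[r:(r + w - 1), c:(c + w - 1)]
      ref[r, c] <- switch(desc,
        idm = idm(ggcm(patch)$P),
        lrlge = lrlge(lapply(c("0", "45", "90", "135"), function(d)
          glrlm(quantize_gray(patch)$levels, 8, d))),
        glcm_correlation = glcm_correlation(patch))
    }
    expect_equal(fm, ref, tolerance = 1e-12)
  }

  # global normalization: windows count levels quantized by the image max
  Fg <- quantize_gray(img)$levels
  Gg <- sobel_gradient(img)$levels
  Fp <- matrix(pad(Fg, 2), nrow(img) + 4, ncol(img) + 4)
  Gp <- matrix(pad(Gg, 2), nrow(img) + 4, ncol(img) + 4)
  fg <- feature_image(img, "idm")
  for (pt in list(c(1, 1), c(6, 4), c(12, 10))) {
    wF <- Fp[pt[1]:(pt[1] + 4), pt[2]:(pt[2] + 4)]
    wG <- Gp[pt[1]:(pt[1] + 4), pt[2]:(pt[2] + 4)]
    H <- matrix(0, 8, 8)
    for (t in seq_along(wF)) H[wF[t], wG[t]] <- H[wF[t], wG[t]] + 1
    expect_equal(fg[pt[1], pt[2]], idm(H / 25), tolerance = 1e-12)
  }
  lg <- feature_image(img, "lrlge")
  Fp1 <- matrix(pad(Fg, 1), nrow(img) + 2, ncol(img) + 2)
  w3 <- Fp1[6:8, 4:6]
  expect_equal(lg[6, 4],
               lrlge(lapply(c("0", "45", "90", "135"), function(d)
                 glrlm(w3, 8, d))), tolerance = 1e-12)
  # in a flat-activity region, global LRLGE reflects the region gray level
  two <- matrix(2, 9, 9); two[, 6:9] <- 8
  lr2 <- feature_image(two, "lrlge", 3)
  expect_gt(lr2[5, 2], lr2[5, 8])  # low-gray side emphasized

  # translation equivariance away from borders (window-local maxima)
  sh <- img[3:12, 2:10]
  f_full <- feature_image(img, "idm", normalization = "window")
  f_sh <- feature_image(sh, "idm", normalization = "window")
  expect_equal(f_sh[3:7, 3:7], f_full[5:9, 4:8], tolerance = 1e-12)

  expect_error(feature_image(matrix(1, 4, 4), "idm", window_size = 5), "larger")
  expect_error(feature_image(matrix(1, 8, 8), "idm", window_size = 4), "odd")
})
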