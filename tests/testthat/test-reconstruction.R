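test_that("MLEM with an identity system converges to the data in one iteration", {
  A <- Matrix::Diagonal(9)
  m <- custom_system_model(A, c(3, 3), c(9, 1))
  y <- matrix(c(4, 0, 2, 7, 1, 3, 5, 2, 8), 9, 1)
  out <- mlem(y, m, settings = recon_settings(iterations = 1))
  expect_equal(as.numeric(out$image), as.numeric(y), tolerance = 1e-12)
})

test_that("MLEM recovers the exact solution of a tiny noiseless system", {
  # 3 bins, 2 pixels, consistent data with known solution x* = (2, 3)
  A <- matrix(c(1, 0, 1,
                0, 1, 1), nrow = 3)
  m <- custom_system_model(A, c(2, 1), c(3, 1))
  xstar <- matrix(c(2, 3), 2, 1)
  y <- matrix(as.numeric(A %*% xstar), 3, 1)
  out <- mlem(y, m, settings = recon_settings(iterations = 500))
  expect_lt(sum((out$image - xstar)^2) / sum(xstar^2), 1e-6)
  expect_true(all(diff(out$loglik) > -1e-9 * abs(out$loglik[1])))
})

test_that("EM iterates stay nonnegative and satisfy count consistency", {
  st <- small_study(seed = 13)
  y <- st$acq$realizations[[1]]$frames[[6]]
  out <- mlem(y, st$model, settings = recon_settings(iterations = 5))
  expect_true(all(out$image >= 0))
  # with r = 0, total projected counts match the data total after iteration 1,
  # restricted to sinogram bins actually reached by rays through the FOV
  # (uniform background places counts in unreachable bins too)
  sens <- back_project(st$model, matrix(1, st$model$n_radial, st$model$n_angles))
  fov_img <- matrix(0, 64, 64); fov_img[st$model$fov] <- 1
  reached <- forward_project(st$model, fov_img) > 0
  expect_equal(sum(sens * out$image), sum(y[reached]), tolerance = 1e-8)
})

test_that("KEM with the identity kernel reproduces MLEM iterate for iterate", {
  st <- small_study(seed = 14)
  y <- st$acq$realizations[[1]]$frames[[3]]
  r <- st$acq$background$frames[[3]]
  K <- identity_kernel(c(64, 64))
  for (iters in c(1, 7)) {
    a <- mlem(y, st$model, r, recon_settings(iterations = iters))
    b <- kem(y, st$model, K, r, recon_settings(iterations = iters))
    expect_equal(b$image, a$image, tolerance = 1e-13)
    expect_equal(b$loglik, a$loglik, tolerance = 1e-13)
  }
})

test_that("KEM with a texture kernel keeps the likelihood non-decreasing and improves NMSE", {
  st <- small_study(seed = 15, total = 3e6)
  acq <- st$acq
  comp <- rebin_composite_frames(acq$realizations[[1]], 3)
  comp_bg <- rebin_composite_frames(acq$background, 3)
  priors <- make_priors(comp, st$model, comp_bg, recon_settings(iterations = 40))
  chans <- c(priors,
             lapply(priors, feature_image, descriptor = "idm"),
             lapply(priors, feature_image, descriptor = "lrlge"))
  field <- build_feature_field(chans, mask = st$model$fov)
  K <- build_kernel(field, k = 20, search_window = 7)

  y <- acq$realizations[[1]]$frames[[6]]
  r <- acq$background$frames[[6]]
  truth <- st$images$frames[[6]] * acq$scale
  km <- kem(y, st$model, K, r, recon_settings(iterations = 30))
  ml <- mlem(y, st$model, r, recon_settings(iterations = 30))
  expect_true(all(diff(km$loglik) > -1e-9 * abs(km$loglik[1])))
  expect_true(all(km$image >= 0))
  expect_lt(nmse(km$image, truth), nmse(ml$image, truth))
})

test_that("dynamic reconstruction is frame-independent and validates inputs", {
  st <- small_study(seed = 16)
  series <- st$acq$realizations[[1]]
  expect_error(reconstruct_dynamic(series, st$model, "kem"), "kernel")

  set <- recon_settings(iterations = 3)
  r12 <- reconstruct_dynamic(series, st$model, "mlem",
                             background = st$acq$background,
                             settings = set, frames = c(1, 2))
  r21 <- reconstruct_dynamic(series, st$model, "mlem",
                             background = st$acq$background,
                             settings = set, frames = c(2, 1))
  expect_equal(r12$images[["2"]], r21$images[["2"]])
  expect_length(r12$images, 2)

  K <- identity_kernel(c(64, 64))
  rk <- reconstruct_dynamic(series, st$model, "kem", K = K,
                            background = st$acq$background,
                            settings = set, frames = 2)
  expect_equal(rk$images[[1]], r12$images[["2"]], tolerance = 1e-13)
})

test_that("composite priors are consistent with their data at high counts", {
  # noiseless uniform disc: 100 MLEM iterations reproduce the disc
  m <- small_model(32, 49, 40)
  disc <- matrix(0, 32, 32); disc[m$fov] <- 2
  y <- forward_project(m, disc)
  ser <- dynamic_series(list(y, y, y), frame_schedule(rep(10, 3)), "sinogram")
  priors <- make_priors(ser, m, settings = recon_settings(iterations = 100))
  expect_lt(nmse(priors[[1]], disc), 1e-3)
  expect_true(all(priors[[2]] >= 0))
  # count totals track the data (parallel-beam: each angle sees the total)
  expect_lt(abs(sum(priors[[1]]) - sum(y) / m$n_angles) / sum(disc), 0.01)
})
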