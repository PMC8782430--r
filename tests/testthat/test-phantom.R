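test_that("phantom masks are disjoint, cover the support, and tumor geometry is exact", {
  ph <- brain_phantom(217)
  with_masks <- ph$masks$gray_matter + ph$masks$white_matter + ph$masks$tumor
  expect_true(all(with_masks[ph$masks$support] == 1))  # disjoint cover
  expect_true(all(with_masks[!ph$masks$support] == 0))
  expect_identical(dim(ph$labels), c(217L, 217L))

  # brute-force count of integer pixels with dx^2 + dy^2 <= 25
  cnt <- 0
  for (dx in -5:5) for (dy in -5:5) if (dx^2 + dy^2 <= 25) cnt <- cnt + 1
  expect_equal(sum(ph$masks$tumor), cnt)
  expect_equal(cnt, 81)

  expect_identical(sum(brain_phantom(64, tumor_radius = 0)$masks$tumor), 0L)
  expect_error(brain_phantom(64, tumor_center = c(5, 5), tumor_radius = 5),
               "tumor")
})

test_that("frame schedule invariants hold and the default has 24 frames over 60 min", {
  sch <- default_schedule()
  expect_length(sch$durations, 24)
  expect_equal(sum(sch$durations), 3600)
  expect_equal(sch$start_times[1], 0)
  expect_true(all(diff(sch$start_times) > 0))
  expect_equal(sch$start_times, cumsum(c(0, sch$durations[-24])))
  expect_error(frame_schedule(c(10, 0, 5)), "positive")
})

test_that("frame means integrate piecewise-linear TACs exactly", {
  # linear ramp (0,0)-(60,2): mean rate over [0,20] is 1/3, emissions 20/3
  tacs <- tac_set(list(gray_matter = cbind(c(0, 60), c(0, 2)),
                       white_matter = cbind(c(0, 60), c(0, 2)),
                       tumor = cbind(c(0, 60), c(0, 2))))
  sch <- frame_schedule(20)
  fm <- tac_frame_means(tacs, sch)
  expect_equal(unname(fm[1, "gray_matter"]), 1 / 3)

  ph <- brain_phantom(64)
  imgs <- render_dynamic_images(ph, tacs, sch)
  expect_equal(max(imgs$frames[[1]]), 20 / 3)

  # constant TAC: every frame is c * duration on the support
  const <- tac_set(list(gray_matter = cbind(0, 4), white_matter = cbind(0, 4),
                        tumor = cbind(0, 4)))
  imgs2 <- render_dynamic_images(ph, const, frame_schedule(c(30, 50)))
  expect_equal(imgs2$frames[[2]], 4 * 50 * (ph$masks$support + 0))

  expect_error(
    render_dynamic_images(ph, tac_set(list(gray_matter = cbind(0, 1))), sch),
    "white_matter")
})

test_that("default TACs render the 24-frame series and tumor exceeds gray matter late", {
  imgs <- render_dynamic_images(brain_phantom(64))
  expect_length(imgs$frames, 24)
  fm <- tac_frame_means(default_tacs(), default_schedule())
  expect_true(all(fm >= 0))
  expect_gt(fm[24, "tumor"], fm[24, "gray_matter"])
  expect_gt(fm[24, "gray_matter"], fm[24, "white_matter"])
})

test_that("acquisition calibration is exact and realizations are seeded", {
  st <- small_study(seed = 5, realizations = 2, total = 2e6)
  acq <- st$acq
  tot <- sum(sapply(acq$trues$frames, sum)) + sum(sapply(acq$background$frames, sum))
  expect_equal(tot, 2e6, tolerance = 1e-12)
  bg <- sum(sapply(acq$background$frames, sum))
  expect_equal(bg / tot, 0.2, tolerance = 1e-12)
  # background apportioned proportionally to frame trues, uniform per frame
  tf <- sapply(acq$trues$frames, sum)
  bf <- sapply(acq$background$frames, sum)
  expect_equal(bf / sum(bf), tf / sum(tf), tolerance = 1e-12)
  expect_equal(length(unique(as.numeric(acq$background$frames[[3]]))), 1L)

  # no background: Poisson mean equals trues exactly
  acq0 <- simulate_acquisition(st$images, st$model,
    acquisition_settings(2e6, 0, 1, seed = 5))
  expect_equal(sum(sapply(acq0$trues$frames, sum)), 2e6, tolerance = 1e-12)
  expect_equal(sum(sapply(acq0$background$frames, sum)), 0)

  # identical seed, bit-identical realizations; realizations differ
  st2 <- small_study(seed = 5, realizations = 2, total = 2e6)
  expect_identical(st$acq$realizations[[1]]$frames, st2$acq$realizations[[1]]$frames)
  expect_false(identical(st$acq$realizations[[1]]$frames,
                         st$acq$realizations[[2]]$frames))

  zero <- tac_set(list(gray_matter = cbind(0, 0), white_matter = cbind(0, 0),
                       tumor = cbind(0, 0)))
  zimgs <- render_dynamic_images(st$phantom, zero, st$schedule)
  expect_error(simulate_acquisition(zimgs, st$model), "all-zero")
})

test_that("composite rebinning partitions the default schedule at 20-min boundaries", {
  sch <- default_schedule()
  frames <- lapply(seq_len(24), function(t) matrix(t, 4, 3))
  series <- dynamic_series(frames, sch, "sinogram")
  comp <- rebin_composite_frames(series, 3)
  expect_equal(comp$schedule$durations, rep(1200, 3))
  expect_identical(attr(comp, "groups"),
                   list(1:16, 17:20, 21:24))
  # exact count conservation
  expect_equal(sum(sapply(comp$frames, sum)), sum(sapply(frames, sum)))
  expect_equal(comp$frames[[2]], Reduce(`+`, frames[17:20]))

  # n = 1 composite is the plain frame-wise sum
  one <- rebin_composite_frames(series, 1)
  expect_equal(one$frames[[1]], Reduce(`+`, frames))

  # a misaligned edge errors and names the offending boundary
  bad <- dynamic_series(frames[1:5], frame_schedule(rep(100, 5)), "sinogram")
  expect_error(rebin_composite_frames(bad, 3), "align")
})

test_that("poisson realizations have the configured mean on average", {
  # reduced-size calibration: empirical mean over 200 realizations
  ph <- brain_phantom(64)
  sch <- frame_schedule(rep(200, 3))
  imgs <- render_dynamic_images(ph, default_tacs(), sch)
  m <- system_model(64, n_radial = 49, n_angles = 30)
  acq <- simulate_acquisition(imgs, m, acquisition_settings(5e5, 0.2, 200, seed = 3))
  lam <- acq$trues$frames[[2]] + acq$background$frames[[2]]
  emp <- Reduce(`+`, lapply(acq$realizations, function(s) s$frames[[2]])) / 200
  # total within 3 standard errors
  se_tot <- sqrt(sum(lam) / 200)
  expect_lt(abs(sum(emp) - sum(lam)), 3 * se_tot)
  # per-bin 3-SE exceedances at the chance level (0.27%), not above 1%
  z <- (emp - lam) / sqrt(pmax(lam, 1e-12) / 200)
  expect_lt(mean(abs(z[lam > 0]) > 3), 0.01)
})
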