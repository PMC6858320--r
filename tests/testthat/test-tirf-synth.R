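test_that("FRAP forward model hits its closed-form landmarks", {
  crv <- make_frap_curve(D = 0.224, r = 1, n_points = 61, t_max = 6)
  # tau_half = 0.224 r^2 / D = 1 s; half the bleached depth at t = 1
  expect_equal(crv$I[crv$t == 1], 0.75, tolerance = 1e-12)
  expect_equal(crv$I[1], 0.5)
  long <- make_frap_curve(D = 1, r = 1, n_points = 10, t_max = 500)
  expect_equal(tail(long$I, 1), 1, tolerance = 1e-6)
  expect_error(make_frap_curve(D = 0, r = 1), "> 0")
  expect_error(make_frap_curve(D = 1, r = -1), "> 0")
  # seeded noise is reproducible
  a <- make_frap_curve(1, 1, noise_sd = 0.05, seed = 4)
  b <- make_frap_curve(1, 1, noise_sd = 0.05, seed = 4)
  expect_identical(a, b)
})

test_that("titration tables encode the area-per-lipid density conversion", {
  tt <- make_titration_table(c(0.001, 0.005, 0.01), A_true = 0.4)
  # 0.005 / 0.68 nm^2, both leaflets: 1.47e4 per um^2
  expect_equal(tt$slb$density_um2[2], 2 * 0.005 / 0.68 * 1e6,
               tolerance = 1e-9)
  one <- make_titration_table(0.005, A_true = 0.4, leaflets = "single")
  expect_equal(one$slb$density_um2, 0.005 / 0.68 * 1e6)
  # zero noise: intensity = density / A exactly, so calibrate_A round-trips
  expect_equal(calibrate_A(tt$slb), 0.4, tolerance = 1e-9)
  expect_warning(make_titration_table(0.2, A_true = 0.4), "5%")
})

test_that("kymograph rendering is deterministic and photon-conserving", {
  tr <- make_linear_traj(v_f = 0, v_p = 0, L0_su = 1000, duration = 100)
  img <- imaging_config(noise_model = "none")
  ky <- render_kymograph(tr, img)
  # static noiseless filament: all rows identical
  for (i in 2:nrow(ky$grid)) expect_equal(ky$grid[i, ], ky$grid[1, ])
  # photon conservation: summed signal above background = counts per
  # subunit times subunit count
  expect_equal(sum(ky$grid[1, ] - img$background),
               img$intensity_per_su * 1000, tolerance = 0.01 * 5 * 1000)
  # noisy rendering is seed-reproducible
  imgp <- imaging_config(seed = 9)
  expect_identical(render_kymograph(tr, imgp)$grid,
                   render_kymograph(tr, imgp)$grid)
})

test_that("kymograph ground truth tracks the configured kinematics", {
  # pure elongation at 1 su/s: barbed edge advances 27 nm per 10 s frame
  tr <- make_linear_traj(v_f = 0, v_p = 1, duration = 200)
  ky <- render_kymograph(tr, imaging_config(noise_model = "none"))
  expect_equal(unique(round(diff(ky$truth$barbed_nm), 9)), -27)
  expect_equal(unique(round(diff(ky$truth$pointed_nm), 9)), 0)
  # pure gliding: truth slope equals configured v_f exactly
  tr2 <- make_linear_traj(v_f = 16, v_p = 0, duration = 200)
  ky2 <- render_kymograph(tr2, imaging_config(noise_model = "none"))
  slope <- coef(lm(ky2$truth$pointed_nm ~ ky2$truth$t_s))[2]
  expect_equal(unname(slope), 16, tolerance = 1e-9)
})

test_that("movie rendering obeys background, motion and field contracts", {
  img <- imaging_config(noise_model = "none")
  empty <- render_movie(list(), img)
  expect_true(all(empty$frames[[1]] == img$background))
  # static filament: first and last frames identical
  tr <- make_linear_traj(v_f = 0, v_p = 0, L0_su = 1000, duration = 100)
  mv <- render_movie(tr, img)
  expect_identical(mv$frames[[1]], mv$frames[[length(mv$frames)]])
  # 16 nm/s at 10 s/frame and 160 nm px: centroid advances 1 px per frame
  trm <- make_linear_traj(v_f = 16, v_p = 0, L0_su = 1000, duration = 100)
  mvm <- render_movie(trm, img)
  centroid <- vapply(mvm$frames, function(f) {
    cs <- colSums(f - img$background)
    sum(cs * seq_along(cs)) / sum(cs)
  }, 0)
  expect_equal(diff(centroid), rep(1, length(centroid) - 1),
               tolerance = 1e-6)
  # leaving a fixed field is an error naming the frame
  img_small <- imaging_config(noise_model = "none", field = c(10, 20))
  expect_error(render_movie(trm, img_small), "frame")
})

test_that("movies round-trip through 16-bit TIFF with a JSON sidecar", {
  skip_if_not_installed("tiff")
  tr <- make_linear_traj(v_f = 16, L0_su = 500, duration = 50)
  mv <- render_movie(tr, imaging_config(noise_model = "none"))
  f <- file.path(tempdir(), "mov.tif")
  write_movie_tiff(mv, f)
  back <- read_movie_tiff(f)
  expect_equal(length(back$frames), length(mv$frames))
  expect_equal(back$frames[[1]], round(mv$frames[[1]]), tolerance = 1)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$pixel_size, 160)
  unlink(c(f, paste0(f, ".json")))
})
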