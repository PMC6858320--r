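test_that("band flattening reproduces the line profile of a straight
           filament and conserves intensity on a bent one", {
  img <- imaging_config(noise_model = "none", background = 10)
  ny <- 20; nx <- 60
  straight <- render_segments_frame(
    data.frame(x0 = 2000, y0 = 1600, x1 = 6000, y1 = 1600), img, nx, ny)
  path <- cbind(x = c(5, 55), y = c(10, 10))
  ky <- flatten_band(list(straight), path, imaging = img)
  expect_equal(ncol(ky$grid), 51)
  # band average matches the central line profile where the filament lies
  line <- straight[10, 10:50]
  expect_equal(ky$grid[1, 5:45], line, tolerance = 0.02 * max(line))
  # 90-degree bend: flatten along the bent path, compare total intensity
  bent <- render_segments_frame(
    data.frame(x0 = c(2000, 4000), y0 = c(1600, 1600),
               x1 = c(4000, 1600), y1 = c(1600, 3600)), img, nx, 30)
  bpath <- cbind(x = c(5, 25, 25), y = c(10, 10, 25))
  kyb <- flatten_band(list(bent), bpath, imaging = img)
  tot_straight <- sum(ky$grid[1, ] - 10) * img$pixel_size
  tot_bent <- sum(kyb$grid[1, ] - 10) * img$pixel_size
  expect_equal(tot_bent, tot_straight, tolerance = 0.02 * tot_straight)
})

test_that("edge extraction recovers truth within one pixel on noiseless
           kymographs", {
  tr <- make_linear_traj(v_f = 40, v_p = 1.5, duration = 300)
  ky <- render_kymograph(tr, imaging_config(noise_model = "none"))
  ed <- extract_edges(ky)
  expect_true(all(ed$valid))
  err_b <- abs(ed$edge_lo_nm - ky$truth$barbed_nm)
  err_p <- abs(ed$edge_hi_nm - ky$truth$pointed_nm)
  expect_lt(max(err_b, err_p), 160)
  expect_error(extract_edges(structure(list(
    grid = matrix(0, 10, 40), pixel_size = 160, frame_interval = 10,
    origin = 0, truth = NULL), class = "kymograph_image")), "valid rows")
})

test_that("edge RMS error stays below one pixel at SNR 10", {
  img0 <- imaging_config(noise_model = "none")
  errs <- numeric(0)
  for (k in 1:100) {
    tr <- make_linear_traj(v_f = 20 + (k %% 5) * 8, v_p = k %% 3,
                           duration = 200)
    ky <- render_kymograph(tr, img0)
    plateau <- max(ky$grid[1, ]) - img0$background
    set.seed(k)
    ky$grid <- ky$grid + matrix(rnorm(length(ky$grid), sd = plateau / 10),
                                nrow = nrow(ky$grid))
    ed <- extract_edges(ky)
    ok <- ed$valid
    errs <- c(errs, ed$edge_lo_nm[ok] - ky$truth$barbed_nm[ok],
              ed$edge_hi_nm[ok] - ky$truth$pointed_nm[ok])
  }
  expect_lt(sqrt(mean(errs^2)), 160)
})

test_that("filament filters enforce length and directionality rules", {
  img <- imaging_config(noise_model = "none")
  # 15 px filament (min length is 20 px): rejected
  short <- extract_edges(render_kymograph(
    make_linear_traj(v_f = 30, L0_su = 15 * 160 / 2.7, duration = 200), img))
  f1 <- filter_filaments(short)
  expect_length(f1$accepted, 0)
  expect_equal(f1$rejections$reason, "min_length")
  # monotone 25 px filament: accepted
  ok <- extract_edges(render_kymograph(
    make_linear_traj(v_f = 30, L0_su = 26 * 160 / 2.7, duration = 200), img))
  expect_length(filter_filaments(ok)$accepted, 1)
  # zig-zag reversing every frame: rejected for directionality
  zig <- ok
  amp <- 400
  zig$edge_lo_nm <- zig$edge_lo_nm + amp * (-1)^zig$frame
  zig$edge_hi_nm <- zig$edge_hi_nm + amp * (-1)^zig$frame
  f3 <- filter_filaments(zig)
  expect_length(f3$accepted, 0)
  expect_equal(f3$rejections$reason, "directionality")
})

test_that("sliding velocity and elongation recover configured rates through
           the full rendering chain", {
  img <- imaging_config(noise_model = "none")
  ed <- extract_edges(render_kymograph(
    make_linear_traj(v_f = 16, v_p = 0, duration = 300), img))
  expect_equal(sliding_velocity(ed), 16, tolerance = 0.05)
  static <- extract_edges(render_kymograph(
    make_linear_traj(v_f = 0, v_p = 0, duration = 300), img))
  expect_equal(sliding_velocity(static), 0, tolerance = 1e-6)
  fast <- extract_edges(render_kymograph(
    make_linear_traj(v_f = 56.4, v_p = 0, duration = 300), img))
  expect_equal(sliding_velocity(fast), 56.4, tolerance = 0.5)
  # elongation: constant length gives a zero trace
  tr0 <- elongation_trace(static)
  expect_true(all(abs(tr0$dL_su) < 0.2))
  # 27 nm per 10 s frame is 1 su/s
  grow <- extract_edges(render_kymograph(
    make_linear_traj(v_f = 0, v_p = 1, duration = 300), img))
  expect_equal(attr(elongation_trace(grow), "v_p"), 1, tolerance = 0.02)
  grow2 <- extract_edges(render_kymograph(
    make_linear_traj(v_f = 30, v_p = 2, duration = 300), img))
  expect_equal(attr(elongation_trace(grow2), "v_p"), 2, tolerance = 0.05)
})

test_that("estimates are invariant under kymograph mirroring", {
  tr <- make_linear_traj(v_f = 35, v_p = 1, duration = 300)
  ky <- render_kymograph(tr, imaging_config(noise_model = "none"))
  ed <- extract_edges(ky)
  mir <- ky
  mir$grid <- ky$grid[, rev(seq_len(ncol(ky$grid))), drop = FALSE]
  mir$truth <- NULL
  edm <- extract_edges(mir)
  expect_equal(sliding_velocity(edm), sliding_velocity(ed),
               tolerance = 1e-6)
  expect_equal(attr(elongation_trace(edm), "v_p"),
               attr(elongation_trace(ed), "v_p"), tolerance = 1e-6)
})

test_that("pointed-end displacement isolates pointed-end dynamics", {
  img <- imaging_config(noise_model = "none")
  # inert pointed end, fiducial co-moving with the body
  tr <- make_linear_traj(v_f = 30, v_p = 0, duration = 300)
  ed <- extract_edges(render_kymograph(tr, img))
  fid <- ed$edge_hi_nm - 1000 # body-fixed mark
  expect_equal(pointed_end_displacement(ed, fid), 0, tolerance = 0.02)
  # co-moving fiducial: result independent of gliding speed
  tr2 <- make_linear_traj(v_f = 60, v_p = 0, duration = 300)
  ed2 <- extract_edges(render_kymograph(tr2, img))
  expect_equal(pointed_end_displacement(ed2, ed2$edge_hi_nm - 1000), 0,
               tolerance = 0.02)
  # pointed-end shrinkage at 0.5 su/s reads -1.35 nm/s against a
  # body-fixed fiducial
  t <- seq(0, 300, by = 1)
  L0 <- 2000
  x_body <- 30 * t + 2.7 * L0
  x_p <- x_body - 2.7 * 0.5 * t
  x_b <- 30 * t
  samples <- data.frame(time_s = t, x_b_nm = x_b, x_p_nm = x_p,
                        length_su = (x_p - x_b) / 2.7, n_on = 0, n_off = 0,
                        n_p_off = round(0.5 * t), n_motors_driving = 0,
                        n_motors_resisting = 0, v_inst = 30)
  trs <- structure(list(samples = samples, events = NULL, absorbed = FALSE,
                        config = list(barbed = barbed_end_model())),
                   class = "filament_trajectory")
  ky <- render_kymograph(trs, img)
  eds <- extract_edges(ky)
  # body-fixed mark 1.5 um inside the filament from the initial tip
  fid_body <- (30 * eds$t_s + 2.7 * L0 - 1500) - ky$origin
  expect_equal(pointed_end_displacement(eds, fid_body), -1.35,
               tolerance = 0.05)
  expect_error(pointed_end_displacement(eds, fid_body + 1e6), "fiducial")
})
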