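#' Imaging parameters for synthetic TIRF rendering
#'
#' @param pixel_size camera pixel size at the sample (nm).
#' @param frame_interval time between frames (s).
#' @param psf_sigma Gaussian point-spread-function sigma (nm).
#' @param intensity_per_su photon counts contributed by one labeled subunit.
#' @param background background level (counts).
#' @param noise_model `"poisson"`, `"gaussian"` (additive with `noise_sd`),
#'   or `"none"` for noiseless rendering.
#' @param noise_sd standard deviation of Gaussian noise (counts).
#' @param bleach_rate photobleaching rate (1/s); intensity decays as
#'   `exp(-bleach_rate * t)`.
#' @param field optional `c(ny, nx)` field size in pixels for
#'   [render_movie()]; `NULL` sizes the field to the trajectories.
#' @param seed integer seed for the rendering noise.
#' @return An object of class `"imaging_config"`.
#' @export
imaging_config <- function(pixel_size = 160, frame_interval = 10,
                           psf_sigma = 200, intensity_per_su = 5,
                           background = 100,
                           noise_model = c("poisson", "gaussian", "none"),
                           noise_sd = 10, bleach_rate = 0, field = NULL,
                           seed = 1) {
  noise_model <- match.arg(noise_model)
  stopifnot(pixel_size > 0, frame_interval > 0, psf_sigma > 0,
            intensity_per_su > 0, background >= 0, noise_sd >= 0,
            bleach_rate >= 0)
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 psf_sigma = psf_sigma, intensity_per_su = intensity_per_su,
                 background = background, noise_model = noise_model,
                 noise_sd = noise_sd, bleach_rate = bleach_rate,
                 field = field, seed = as.integer(seed)),
            class = "imaging_config")
}

#' Deterministic straight-line trajectory
#'
#' Builds a noise-free `"filament_trajectory"` with constant sliding
#' velocity and elongation rate; the exact-kinematics input used to
#' validate the rendering and measurement chain.
#'
#' @param v_f sliding velocity of the leading (pointed) edge (nm/s).
#' @param v_p elongation rate (subunits/s).
#' @param L0_su initial length (subunits).
#' @param x0 initial barbed-end position (nm).
#' @param duration length of the trajectory (s).
#' @param sample_dt sampling interval (s).
#' @return A `"filament_trajectory"` with exact linear kinematics.
#' @export
linear_trajectory <- function(v_f = 16, v_p = 0, L0_su = 2000, x0 = 0,
                              duration = 300, sample_dt = 1) {
  stopifnot(duration > 0, sample_dt > 0, L0_su > 0)
  t <- seq(0, duration, by = sample_dt)
  L <- L0_su + v_p * t
  if (any(L <= 0)) stop("trajectory depolymerizes completely")
  x_p <- x0 + SUBUNIT_NM * L0_su + v_f * t
  x_b <- x_p - SUBUNIT_NM * L
  samples <- data.frame(
    time_s = t, x_b_nm = x_b, x_p_nm = x_p, length_su = L,
    n_on = pmax(round(v_p * t), 0), n_off = 0, n_p_off = 0,
    n_motors_driving = 0, n_motors_resisting = 0, v_inst = v_f)
  structure(list(samples = samples,
                 events = data.frame(time_s = numeric(),
                                     kind = character()),
                 absorbed = FALSE,
                 config = list(barbed = barbed_end_model(),
                               mode = "synthetic")),
            class = "filament_trajectory")
}

# interpolate trajectory edges at the frame times
.frame_edges <- function(traj, imaging) {
  s <- traj$samples
  t_end <- max(s$time_s)
  t_frames <- seq(0, t_end + 1e-9, by = imaging$frame_interval)
  t_frames <- t_frames[t_frames <= t_end + 1e-9]
  data.frame(
    frame = seq_along(t_frames), t_s = t_frames,
    x_b = approx(s$time_s, s$x_b_nm, t_frames, rule = 2)$y,
    x_p = approx(s$time_s, s$x_p_nm, t_frames, rule = 2)$y,
    length_su = approx(s$time_s, s$length_su, t_frames, rule = 2)$y)
}

.apply_noise <- function(m, imaging) {
  switch(imaging$noise_model,
         none = m,
         poisson = matrix(rpois(length(m), lambda = pmax(m, 0)),
                          nrow = nrow(m)),
         gaussian = m + matrix(rnorm(length(m), sd = imaging$noise_sd),
                               nrow = nrow(m)))
}

#' Render a trajectory directly into a kymograph
#'
#' Rasterizes the filament's one-dimensional intensity profile (a top-hat
#' of linear density `intensity_per_su / 2.7` per nm convolved with the
#' Gaussian PSF) at each frame time along the gliding axis, bypassing 2-D
#' rendering.  The exact edge positions are stored as ground truth.
#'
#' @param traj a [simulate_gliding()] result (or any object with the same
#'   `samples` layout).
#' @param imaging an [imaging_config()].
#' @param pad margin added on both sides of the swept region (nm).
#' @return An object of class `"kymograph_image"`: list with `grid` (matrix,
#'   rows = frames, columns = position along the path), `pixel_size`,
#'   `frame_interval`, `origin` (nm offset of the path start in trajectory
#'   coordinates) and `truth` (data.frame of exact `barbed_nm`,
#'   `pointed_nm` per frame, in path coordinates).
#' @export
render_kymograph <- function(traj, imaging = imaging_config(), pad = NULL) {
  stopifnot(inherits(imaging, "imaging_config"))
  fe <- .frame_edges(traj, imaging)
  px <- imaging$pixel_size
  if (is.null(pad)) pad <- 3 * imaging$psf_sigma + 2 * px
  origin <- min(fe$x_b) - pad
  n_col <- ceiling((max(fe$x_p) + pad - origin) / px)
  centers <- origin + (seq_len(n_col) - 0.5) * px
  dens <- imaging$intensity_per_su / SUBUNIT_NM * px
  grid <- matrix(0, nrow = nrow(fe), ncol = n_col)
  for (i in seq_len(nrow(fe))) {
    prof <- dens * (pnorm((fe$x_p[i] - centers) / imaging$psf_sigma) -
                    pnorm((fe$x_b[i] - centers) / imaging$psf_sigma))
    grid[i, ] <- imaging$background +
      prof * exp(-imaging$bleach_rate * fe$t_s[i])
  }
  set.seed(imaging$seed)
  grid <- .apply_noise(grid, imaging)
  structure(list(grid = grid, pixel_size = px,
                 frame_interval = imaging$frame_interval, origin = origin,
                 truth = data.frame(frame = fe$frame, t_s = fe$t_s,
                                    barbed_nm = fe$x_b - origin,
                                    pointed_nm = fe$x_p - origin)),
            class = "kymograph_image")
}

#' @export
print.kymograph_image <- function(x, ...) {
  cat(sprintf("<kymograph_image> %d frames x %d px (%g nm/px, %g s/frame)%s\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size, x$frame_interval,
              if (!is.null(x$truth)) ", with ground truth" else ""))
  invisible(x)
}

#' @export
plot.kymograph_image <- function(x, ...) {
  image(t(x$grid)[, rev(seq_len(nrow(x$grid))), drop = FALSE],
        col = gray.colors(128), axes = FALSE,
        xlab = "position along path", ylab = "time", ...)
  invisible(x)
}

#' Render trajectories into a synthetic TIRF movie
#'
#' Each frame is the sum of the filaments' line profiles convolved with an
#' isotropic Gaussian PSF, plus background, with optional exponential
#' bleaching and shot/read noise.  Filaments are laid out as horizontal
#' lines on separate y lanes.
#'
#' @param trajectories a single trajectory or a list of them.
#' @param imaging an [imaging_config()]; if `imaging$field` is given
#'   (`c(ny, nx)` pixels) a trajectory leaving the field is an error.
#' @param y_nm optional vector of lane positions (nm); defaults to evenly
#'   spaced lanes.
#' @return An object of class `"tirf_movie"`: list with `frames` (list of
#'   ny x nx matrices), `imaging`, `origin` (nm, x offset of the field) and
#'   `truth` (list of per-filament data.frames with exact edge positions in
#'   field coordinates).
#' @export
render_movie <- function(trajectories, imaging = imaging_config(),
                         y_nm = NULL) {
  if (inherits(trajectories, "filament_trajectory"))
    trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 0, inherits(imaging, "imaging_config"))
  px <- imaging$pixel_size
  pad <- 3 * imaging$psf_sigma + 2 * px
  fes <- lapply(trajectories, .frame_edges, imaging = imaging)
  if (length(fes) > 0) {
    origin <- min(vapply(fes, function(f) min(f$x_b), 0)) - pad
    x_max <- max(vapply(fes, function(f) max(f$x_p), 0)) + pad
    n_frames <- max(vapply(fes, nrow, 0L))
  } else {
    origin <- 0; x_max <- 20 * px; n_frames <- 1L
  }
  if (is.null(y_nm))
    y_nm <- pad + (seq_along(fes) - 1) * 2 * pad
  if (!is.null(imaging$field)) {
    ny <- imaging$field[1]; nx <- imaging$field[2]
  } else {
    nx <- ceiling((x_max - origin) / px)
    ny <- ceiling((max(c(y_nm, 0)) + pad) / px)
  }
  xc <- origin + (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  dens <- imaging$intensity_per_su / SUBUNIT_NM * px
  frames <- vector("list", n_frames)
  set.seed(imaging$seed)
  for (f in seq_len(n_frames)) {
    m <- matrix(imaging$background, nrow = ny, ncol = nx)
    for (k in seq_along(fes)) {
      fe <- fes[[k]]
      if (f > nrow(fe)) next
      if (fe$x_b[f] < origin || fe$x_p[f] > origin + nx * px ||
          y_nm[k] < 0 || y_nm[k] > ny * px)
        stop(sprintf("trajectory %d exits the field at frame %d", k, f))
      xprof <- pnorm((fe$x_p[f] - xc) / imaging$psf_sigma) -
               pnorm((fe$x_b[f] - xc) / imaging$psf_sigma)
      yprof <- pnorm((yc + px / 2 - y_nm[k]) / imaging$psf_sigma) -
               pnorm((yc - px / 2 - y_nm[k]) / imaging$psf_sigma)
      m <- m + dens * exp(-imaging$bleach_rate * fe$t_s[f]) *
        outer(yprof, xprof)
    }
    frames[[f]] <- .apply_noise(m, imaging)
  }
  truth <- lapply(seq_along(fes), function(k) {
    fe <- fes[[k]]
    data.frame(frame = fe$frame, t_s = fe$t_s,
               barbed_nm = fe$x_b - origin, pointed_nm = fe$x_p - origin,
               y_nm = y_nm[k])
  })
  structure(list(frames = frames, imaging = imaging, origin = origin,
                 truth = truth),
            class = "tirf_movie")
}

#' @export
print.tirf_movie <- function(x, ...) {
  cat(sprintf("<tirf_movie> %d frames of %d x %d px, %d filament(s)\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              length(x$truth)))
  invisible(x)
}

#' Write / read a movie as a multi-page 16-bit TIFF with a JSON truth sidecar
#'
#' @param movie a [render_movie()] result.
#' @param file TIFF path; the truth sidecar is written next to it as
#'   `<file>.json`.
#' @return Invisibly, `file`.
#' @export
write_movie_tiff <- function(movie, file) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF movies")
  stopifnot(inherits(movie, "tirf_movie"))
  pages <- lapply(movie$frames, function(m) pmin(pmax(m, 0), 65535) / 65535)
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  jsonlite::write_json(
    list(origin_nm = movie$origin,
         pixel_size = movie$imaging$pixel_size,
         frame_interval = movie$imaging$frame_interval,
         truth = movie$truth),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(file)
}

#' @rdname write_movie_tiff
#' @param imaging an [imaging_config()] describing the acquisition of the
#'   file being read.
#' @export
read_movie_tiff <- function(file, imaging = imaging_config()) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF movies")
  pages <- tiff::readTIFF(file, all = TRUE)
  frames <- lapply(pages, function(p) p * 65535)
  structure(list(frames = frames, imaging = imaging, origin = 0,
                 truth = NULL),
            class = "tirf_movie")
}

#' Synthetic FRAP recovery curve
#'
#' Single-exponential recovery normalized to the pre-bleach intensity,
#' `I(t) = 1 - 0.5 * exp(-t * ln 2 / tau_half)`, with the half-recovery
#' time tied to the diffusion coefficient through the Soumpasis relation
#' `tau_half = 0.224 * r^2 / D`.
#'
#' @param D diffusion coefficient (um^2/s), `> 0`.
#' @param r radius of the bleached spot (um), `> 0`.
#' @param n_points number of samples.
#' @param t_max last time point (s); defaults to `6 * tau_half`.
#' @param noise_sd additive Gaussian noise on the normalized intensity.
#' @param seed integer seed.
#' @return A data.frame with columns `t` (s) and `I` (normalized).
#' @export
make_frap_curve <- function(D, r, n_points = 100, t_max = NULL,
                            noise_sd = 0, seed = 1) {
  if (D <= 0 || r <= 0) stop("D and r must be > 0")
  tau_half <- 0.224 * r^2 / D
  if (is.null(t_max)) t_max <- 6 * tau_half
  t <- seq(0, t_max, length.out = n_points)
  I <- 1 - 0.5 * exp(-t * log(2) / tau_half)
  if (noise_sd > 0) {
    set.seed(seed)
    I <- I + rnorm(n_points, sd = noise_sd)
  }
  data.frame(t = t, I = I)
}

#' Synthetic fluorescent-lipid titration table for density calibration
#'
#' Emulates the calibration measurement in which supported bilayers doped
#' with known mole fractions of a fluorescent lipid are imaged: the lipid
#' surface density follows from the mole fraction and the area per lipid
#' (0.68 nm^2), counting one or both leaflets, and the measured intensity
#' is `density / A_true` plus relative noise.  A paired bulk dye titration
#' (`I_alexa = ratio_true * I_dope`) provides the dye-ratio correction used
#' when the protein of interest carries a different fluorophore.
#'
#' @param fractions fluorescent-lipid mole fractions; values above 0.05
#'   trigger a warning (outside the linear calibration regime).
#' @param A_true true density-per-intensity slope (1/um^2 per count).
#' @param ratio_true true bulk brightness ratio of the protein dye to the
#'   lipid dye.
#' @param noise_sd relative (fractional) Gaussian noise on intensities.
#' @param seed integer seed.
#' @param leaflets `"both"` (TIRF excites both leaflets) or `"single"`.
#' @param area_per_lipid area per lipid (nm^2).
#' @return A list with `slb` (data.frame `fraction`, `density_um2`,
#'   `intensity`) and `dye` (data.frame `conc`, `I_dope`, `I_alexa`).
#' @export
make_titration_table <- function(fractions, A_true, ratio_true = 1.5,
                                 noise_sd = 0, seed = 1,
                                 leaflets = c("both", "single"),
                                 area_per_lipid = 0.68) {
  leaflets <- match.arg(leaflets)
  stopifnot(all(fractions >= 0), A_true > 0, ratio_true > 0)
  if (any(fractions > 0.05))
    warning("mole fractions above 5% are outside the linear calibration regime")
  set.seed(seed)
  nl <- if (leaflets == "both") 2 else 1
  density <- nl * fractions / area_per_lipid * 1e6 # per um^2
  intensity <- density / A_true
  if (noise_sd > 0)
    intensity <- intensity * (1 + rnorm(length(intensity), sd = noise_sd))
  conc <- seq_along(fractions)
  I_dope <- 100 * conc
  I_alexa <- ratio_true * I_dope
  if (noise_sd > 0)
    I_alexa <- I_alexa * (1 + rnorm(length(I_alexa), sd = noise_sd))
  list(slb = data.frame(fraction = fractions, density_um2 = density,
                        intensity = intensity),
       dye = data.frame(conc = conc, I_dope = I_dope, I_alexa = I_alexa))
}

#' Rasterize filament segments into a single synthetic frame
#'
#' Draws one or more straight segments of uniform linear intensity density
#' convolved with the Gaussian PSF; used to build fixtures with curved
#' (polyline) filaments that [render_movie()], which models gliding along a
#' straight axis, does not produce.
#'
#' @param segments data.frame with columns `x0`, `y0`, `x1`, `y1` (nm).
#' @param imaging an [imaging_config()].
#' @param nx,ny frame size (pixels).
#' @param ds integration step along the segments (nm).
#' @return An ny x nx matrix of counts (background included, no noise).
#' @export
render_segments_frame <- function(segments, imaging, nx, ny, ds = 2) {
  stopifnot(all(c("x0", "y0", "x1", "y1") %in% names(segments)))
  px <- imaging$pixel_size
  sig <- imaging$psf_sigma
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  m <- matrix(0, nrow = ny, ncol = nx)
  dens <- imaging$intensity_per_su / SUBUNIT_NM # counts per nm of filament
  for (k in seq_len(nrow(segments))) {
    L <- sqrt((segments$x1[k] - segments$x0[k])^2 +
              (segments$y1[k] - segments$y0[k])^2)
    n <- max(2L, ceiling(L / ds))
    s <- seq(0, 1, length.out = n)
    xs <- segments$x0[k] + s * (segments$x1[k] - segments$x0[k])
    ys <- segments$y0[k] + s * (segments$y1[k] - segments$y0[k])
    w <- dens * L / n / (2 * pi * sig^2) * px^2
    for (i in seq_len(n)) {
      gx <- exp(-(xc - xs[i])^2 / (2 * sig^2))
      gy <- exp(-(yc - ys[i])^2 / (2 * sig^2))
      m <- m + w * outer(gy, gx)
    }
  }
  m + imaging$background
}
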