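#' Flatten a (possibly curved) filament into a kymograph band
#'
#' For each frame, samples the intensity along a polyline path and averages
#' transversely over a band (10 pixels wide by default), producing one
#' kymograph row per frame.  This reproduces the segmented-line band
#' flattening used in kymograph plugins; the path can come from
#' [trace_path()] or from a manually drawn polyline file.
#'
#' @param movie a [render_movie()] result, or a list of matrices with an
#'   `imaging` attribute.
#' @param path matrix or data.frame of polyline vertices, columns `x`, `y`,
#'   in pixel units (pixel `(i, j)` has center `(j - 0.5, i - 0.5)`).
#' @param band_width transverse averaging width (pixels).
#' @param imaging an [imaging_config()]; defaults to `movie$imaging`.
#' @return A [render_kymograph()]-style `"kymograph_image"` (no truth).
#' @export
flatten_band <- function(movie, path, band_width = 10, imaging = NULL) {
  if (inherits(movie, "tirf_movie")) {
    frames <- movie$frames
    if (is.null(imaging)) imaging <- movie$imaging
  } else {
    frames <- movie
    if (is.null(imaging)) stop("imaging configuration required")
  }
  path <- as.matrix(path)
  if (ncol(path) < 2 || nrow(path) < 2)
    stop("path must be a polyline with at least 2 vertices (columns x, y)")
  seg <- diff(path)
  seg_len <- sqrt(rowSums(seg^2))
  arc <- c(0, cumsum(seg_len))
  total <- arc[length(arc)]
  s <- seq(0, total, by = 1) # 1-pixel sampling along the path
  xs <- approx(arc, path[, 1], s)$y
  ys <- approx(arc, path[, 2], s)$y
  # unit tangents/normals per sample (from local differences)
  tx <- c(diff(xs), tail(diff(xs), 1))
  ty <- c(diff(ys), tail(diff(ys), 1))
  tl <- pmax(sqrt(tx^2 + ty^2), 1e-12)
  nxv <- -ty / tl
  nyv <- tx / tl
  offs <- seq(-(band_width - 1) / 2, (band_width - 1) / 2, by = 1)
  grid <- matrix(NA_real_, nrow = length(frames), ncol = length(s))
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    acc <- numeric(length(s))
    for (o in offs)
      acc <- acc + .bilinear(m, xs + o * nxv, ys + o * nyv)
    grid[f, ] <- acc / length(offs)
  }
  structure(list(grid = grid, pixel_size = imaging$pixel_size,
                 frame_interval = imaging$frame_interval, origin = 0,
                 truth = NULL, path = path),
            class = "kymograph_image")
}

# bilinear interpolation of matrix m at continuous pixel coords (x right,
# y down, pixel centers at half-integers); clamps to the border
.bilinear <- function(m, x, y) {
  ny <- nrow(m); nx <- ncol(m)
  cx <- pmin(pmax(x - 0.5, 0), nx - 1)
  cy <- pmin(pmax(y - 0.5, 0), ny - 1)
  j0 <- pmin(floor(cx), nx - 2); i0 <- pmin(floor(cy), ny - 2)
  fx <- cx - j0; fy <- cy - i0
  i0 <- i0 + 1; j0 <- j0 + 1 # to 1-based
  m[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    m[cbind(i0, j0 + 1)] * fx * (1 - fy) +
    m[cbind(i0 + 1, j0)] * (1 - fx) * fy +
    m[cbind(i0 + 1, j0 + 1)] * fx * fy
}

#' Automatic filament path from a temporal-maximum projection
#'
#' Default replacement for a manually drawn segmented line: projects the
#' movie by per-pixel temporal maximum, finds, for each column crossing the
#' filament, the intensity-weighted y centroid of above-threshold pixels,
#' and returns the resulting ridge as a polyline.  Works for filaments
#' gliding along the x axis, which is how [render_movie()] lays them out.
#'
#' @param movie a [render_movie()] result.
#' @param extend pixels by which the traced path is extended past both
#'   filament ends, so that the flattened band contains background for the
#'   edge detector.
#' @return A two-column matrix of path vertices in pixel units.
#' @export
trace_path <- function(movie, extend = 10) {
  stopifnot(inherits(movie, "tirf_movie"))
  proj <- Reduce(pmax, movie$frames)
  bg <- median(proj)
  thr <- bg + 0.5 * (max(proj) - bg)
  cols <- which(apply(proj, 2, max) >= thr)
  if (length(cols) < 2) stop("no filament ridge found in the projection")
  ys <- vapply(cols, function(j) {
    w <- pmax(proj[, j] - bg, 0)
    sum(w * seq_along(w)) / sum(w)
  }, 0)
  path <- cbind(x = cols - 0.5, y = ys - 0.5)
  if (extend > 0) {
    n <- nrow(path)
    t1 <- path[1, ] - path[2, ]
    t2 <- path[n, ] - path[n - 1, ]
    t1 <- t1 / max(sqrt(sum(t1^2)), 1e-12)
    t2 <- t2 / max(sqrt(sum(t2^2)), 1e-12)
    path <- rbind(path[1, ] + extend * t1, path, path[n, ] + extend * t2)
  }
  path
}

#' Extract filament edge trajectories from a kymograph
#'
#' Per row: estimates the background from the dimmest pixels, the plateau
#' from the brightest, thresholds at half of the plateau above background,
#' and takes the outermost threshold crossings with linear sub-pixel
#' interpolation.  Rows with no usable crossing are flagged invalid.
#'
#' @param kymo a `"kymograph_image"`.
#' @return An object of class `"edge_trajectories"`: data.frame with
#'   columns `frame`, `t_s`, `edge_lo_nm`, `edge_hi_nm`, `valid`, and
#'   attributes `pixel_size`, `frame_interval`, `direction` (+1 if the
#'   filament moves toward larger path positions), `leading`
#'   (`"hi"`/`"lo"`) and `truth` (copied from the kymograph if present).
#' @export
extract_edges <- function(kymo) {
  stopifnot(inherits(kymo, "kymograph_image"))
  g <- kymo$grid
  if (nrow(g) < 3) stop("kymograph must have at least 3 rows")
  px <- kymo$pixel_size
  centers <- (seq_len(ncol(g)) - 0.5) * px
  out <- data.frame(frame = seq_len(nrow(g)), t_s = (seq_len(nrow(g)) - 1) *
                      kymo$frame_interval,
                    edge_lo_nm = NA_real_, edge_hi_nm = NA_real_,
                    valid = FALSE)
  nb <- max(3, min(5, floor(ncol(g) / 4))) # border columns used for background
  for (i in seq_len(nrow(g))) {
    v <- g[i, ]
    # the outermost columns are outside the filament by construction (the
    # renderer pads the path; traced paths are extended past the ends), so
    # they estimate the background without contamination by the filament
    bg <- median(c(head(v, nb), tail(v, nb)))
    peak <- quantile(v, 0.99, names = FALSE)
    if (!(peak > bg)) next
    above0 <- v >= bg + 0.5 * (peak - bg)
    plateau <- median(v[above0])
    noise <- mad(v[!above0] - bg)
    if (plateau - bg <= max(5 * noise, .Machine$double.eps)) next
    thr <- bg + 0.5 * (plateau - bg)
    idx <- which(v >= thr)
    if (length(idx) == 0) next
    lo_i <- idx[1]; hi_i <- idx[length(idx)]
    lo <- if (lo_i == 1) centers[1] else {
      centers[lo_i - 1] + (thr - v[lo_i - 1]) / (v[lo_i] - v[lo_i - 1]) * px
    }
    hi <- if (hi_i == ncol(g)) centers[ncol(g)] else {
      centers[hi_i] + (thr - v[hi_i]) / (v[hi_i + 1] - v[hi_i]) * px
    }
    out$edge_lo_nm[i] <- lo
    out$edge_hi_nm[i] <- hi
    out$valid[i] <- TRUE
  }
  if (!any(out$valid)) stop("no valid rows: edge extraction failed everywhere")
  mid <- (out$edge_lo_nm + out$edge_hi_nm) / 2
  disp <- sum(diff(mid[out$valid]))
  direction <- if (disp >= 0) 1 else -1
  structure(out,
            pixel_size = px, frame_interval = kymo$frame_interval,
            direction = direction,
            leading = if (direction > 0) "hi" else "lo",
            truth = kymo$truth,
            class = c("edge_trajectories", "data.frame"))
}

.leading_edge <- function(edges) {
  if (attr(edges, "leading") == "hi") edges$edge_hi_nm else edges$edge_lo_nm
}
.trailing_edge <- function(edges) {
  if (attr(edges, "leading") == "hi") edges$edge_lo_nm else edges$edge_hi_nm
}

#' Select analyzable filaments
#'
#' Applies the acceptance rules of the measurement chain: a filament must
#' stay longer than `min_length_px` pixels in every frame, and, when it
#' moves, must move directionally — the fraction of frame-to-frame
#' displacements of its leading edge that oppose the net direction must not
#' exceed `max_reversal_frac`.
#'
#' @param candidates a list of `"edge_trajectories"` (a single one is
#'   wrapped).
#' @param min_length_px minimum filament length (pixels).
#' @param max_reversal_frac maximum tolerated fraction of sign-reversing
#'   frame steps.
#' @return A list with `accepted` (the passing edge trajectories, original
#'   indices in `names`) and `rejections` (data.frame `index`, `reason`
#'   with reasons `"min_length"`, `"directionality"`, `"too_few_frames"`).
#' @export
filter_filaments <- function(candidates, min_length_px = 20,
                             max_reversal_frac = 0.1) {
  if (inherits(candidates, "edge_trajectories")) candidates <- list(candidates)
  accepted <- list()
  rej_i <- integer(); rej_r <- character()
  for (k in seq_along(candidates)) {
    e <- candidates[[k]]
    px <- attr(e, "pixel_size")
    val <- e[e$valid, , drop = FALSE]
    if (nrow(val) < 3) {
      rej_i <- c(rej_i, k); rej_r <- c(rej_r, "too_few_frames"); next
    }
    len_px <- (val$edge_hi_nm - val$edge_lo_nm) / px
    if (any(len_px <= min_length_px)) {
      rej_i <- c(rej_i, k); rej_r <- c(rej_r, "min_length"); next
    }
    lead <- .leading_edge(e)[e$valid]
    d <- diff(lead)
    moving <- d[d != 0]
    if (length(moving) > 0) {
      s <- if (sum(moving) >= 0) 1 else -1
      if (mean(sign(d) == -s) > max_reversal_frac) {
        rej_i <- c(rej_i, k); rej_r <- c(rej_r, "directionality"); next
      }
    }
    accepted[[as.character(k)]] <- e
  }
  list(accepted = accepted,
       rejections = data.frame(index = rej_i, reason = rej_r))
}

#' Sliding velocity from edge trajectories
#'
#' Least-squares slope of the leading (pointed) edge position versus time.
#'
#' @param edges an [extract_edges()] result.
#' @param pixel_size,frame_interval overrides for the metadata carried by
#'   `edges` (normally not needed).
#' @return Velocity in nm/s (signed along the path; positive in the
#'   direction of motion).
#' @export
sliding_velocity <- function(edges, pixel_size = NULL,
                             frame_interval = NULL) {
  stopifnot(inherits(edges, "edge_trajectories"))
  val <- edges[edges$valid, , drop = FALSE]
  if (nrow(val) < 3) stop("need at least 3 valid rows")
  lead <- .leading_edge(edges)[edges$valid]
  slope <- unname(coef(lm(lead ~ val$t_s))[2])
  slope * attr(edges, "direction")
}

#' Barbed-end elongation trace in subunits
#'
#' `dL(t) = (length(t) - length(t0)) / 2.7` with length measured between
#' the two detected edges; the least-squares slope of `dL` versus time is
#' the barbed-end elongation rate `v_p` (subunits/s), attached as attribute
#' `v_p`.
#'
#' @param edges an [extract_edges()] result.
#' @param pixel_size override for the pixel size (normally not needed).
#' @return A data.frame `frame`, `t_s`, `dL_su` with attribute `v_p`.
#' @export
elongation_trace <- function(edges, pixel_size = NULL) {
  stopifnot(inherits(edges, "edge_trajectories"))
  val <- edges[edges$valid, , drop = FALSE]
  if (nrow(val) < 3) stop("need at least 3 valid rows")
  len <- (val$edge_hi_nm - val$edge_lo_nm)
  dL <- (len - len[1]) / SUBUNIT_NM
  out <- data.frame(frame = val$frame, t_s = val$t_s, dL_su = dL)
  attr(out, "v_p") <- unname(coef(lm(dL ~ val$t_s))[2])
  out
}

#' Pointed-end displacement relative to a fiducial mark
#'
#' Slope of (pointed edge - fiducial position) versus time; a body-fixed
#' fiducial makes this a pure measure of pointed-end subunit exchange,
#' independent of gliding.  Near zero when the pointed end is inert.
#'
#' @param edges an [extract_edges()] result.
#' @param fiducial per-frame fiducial positions (nm, same coordinates as
#'   the edges); recycled if length 1.
#' @return Displacement rate in nm/s (negative for pointed-end shrinkage).
#' @export
pointed_end_displacement <- function(edges, fiducial) {
  stopifnot(inherits(edges, "edge_trajectories"))
  val_idx <- which(edges$valid)
  if (length(val_idx) < 3) stop("need at least 3 valid rows")
  fid <- rep_len(fiducial, nrow(edges))[val_idx]
  lo <- edges$edge_lo_nm[val_idx]; hi <- edges$edge_hi_nm[val_idx]
  if (any(fid < lo - attr(edges, "pixel_size") |
          fid > hi + attr(edges, "pixel_size")))
    stop("fiducial exits the filament")
  pointed <- .leading_edge(edges)[val_idx]
  rel <- (pointed - fid) * attr(edges, "direction")
  t <- edges$t_s[val_idx]
  unname(coef(lm(rel ~ t))[2])
}
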