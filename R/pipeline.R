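#' Describe one experimental condition of a gliding scenario
#'
#' @param label unique condition label.
#' @param species a [motor_species()].
#' @param motor_density motor surface density (1/um^2).
#' @param ATP ATP concentration (mM).
#' @param mode `"immobilized"` or `"membrane"`.
#' @param xi_anchor anchor drag for membrane mode (pN s/nm); `NULL` uses
#'   the species value.
#' @param eta_b bulk viscosity (Pa s).
#' @param crowding crowding factor on the bulk drag.
#' @param stabilized logical; `TRUE` for phalloidin-like filaments with no
#'   end chemistry (the condition then ignores the scenario's C_m grid).
#' @param barbed a [barbed_end_model()] for polymerizing conditions.
#' @param dt integrator step (s); fast-cycling species need a smaller step.
#' @return A list of class `"gliding_condition"`.
#' @export
gliding_condition <- function(label, species = reference_species("myo1b"),
                              motor_density = 8000, ATP = 2,
                              mode = "immobilized", xi_anchor = NULL,
                              eta_b = 1e-2, crowding = 3,
                              stabilized = FALSE,
                              barbed = barbed_end_model(), dt = 0.008) {
  stopifnot(is.character(label), length(label) == 1L,
            inherits(species, "motor_species"))
  structure(list(label = label, species = species,
                 motor_density = motor_density, ATP = ATP, mode = mode,
                 xi_anchor = xi_anchor, eta_b = eta_b, crowding = crowding,
                 stabilized = stabilized, barbed = barbed, dt = dt),
            class = "gliding_condition")
}

#' Define a seeded end-to-end gliding-assay scenario
#'
#' A scenario is a crossed design of conditions and G-actin concentrations
#' with a fixed number of filaments per cell, a root seed from which every
#' per-filament seed derives, and the imaging parameters used to render
#' each filament before analysis.  Filament-to-filament variability is
#' emulated by a lognormal motor-bed quality factor (coefficient of
#' variation `heterogeneity_cv`) scaling the actuation velocity, and by
#' drawing initial lengths uniformly from `length_range_su`.
#'
#' @param name scenario name.
#' @param conditions list of [gliding_condition()] objects with unique
#'   labels.
#' @param n_filaments filaments per condition and concentration, `>= 1`.
#' @param cm_grid G-actin concentrations (uM) for polymerizing conditions.
#' @param root_seed integer root seed.
#' @param duration simulated/observed time per filament (s).
#' @param imaging an [imaging_config()].
#' @param heterogeneity_cv coefficient of variation of the per-filament
#'   motor-bed quality factor.
#' @param length_range_su range of initial lengths (subunits).
#' @param control label of the reference condition for k_off comparisons.
#' @return A list of class `"scenario"`.
#' @export
scenario <- function(name, conditions, n_filaments = 30,
                     cm_grid = c(0.1, 0.3, 0.6, 0.8, 1),
                     root_seed = 1, duration = 300,
                     imaging = imaging_config(),
                     heterogeneity_cv = 0.2,
                     length_range_su = c(1500, 3000),
                     control = NULL) {
  labels <- vapply(conditions, function(c) c$label, "")
  if (anyDuplicated(labels)) stop("condition labels must be unique")
  stopifnot(n_filaments >= 1, duration > 0, heterogeneity_cv >= 0)
  structure(list(name = name, conditions = conditions,
                 n_filaments = as.integer(n_filaments), cm_grid = cm_grid,
                 root_seed = as.integer(root_seed), duration = duration,
                 imaging = imaging, heterogeneity_cv = heterogeneity_cv,
                 length_range_su = length_range_su, control = control),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> '%s': %d condition(s) x %d filament(s), seed %d\n",
              x$name, length(x$conditions), x$n_filaments, x$root_seed))
  for (c in x$conditions)
    cat(sprintf("  - %s (%s, %s, %g /um^2, %g mM ATP)\n", c$label,
                c$species$label, if (c$stabilized) "stabilized" else
                  paste0("C_m grid ", paste(x$cm_grid, collapse = "/")),
                c$motor_density, c$ATP))
  invisible(x)
}

# deterministic seed chain; all intermediates stay far below 2^53 so the
# modular arithmetic is exact in doubles
.derive_seed <- function(root, ...) {
  h <- root %% 2147483647
  for (k in c(...)) h <- (h * 31 + k + 1) %% 2147483647
  as.integer(h)
}

#' Measure one simulated filament through the imaging chain
#'
#' Renders the trajectory into a kymograph, extracts the edges, applies
#' the analyzability filters and, when the filament passes, measures the
#' sliding velocity and (for polymerizing filaments) the elongation rate.
#'
#' @param traj a [simulate_gliding()] result.
#' @param imaging an [imaging_config()].
#' @param min_length_px,max_reversal_frac filter settings, see
#'   [filter_filaments()].
#' @return A list with `v_f` (nm/s), `v_p` (su/s, `NA` for stabilized
#'   filaments), `accepted`, `reason` and the `edges`.
#' @export
analyze_trajectory <- function(traj, imaging = imaging_config(),
                               min_length_px = 20,
                               max_reversal_frac = 0.1) {
  kym <- render_kymograph(traj, imaging)
  edges <- tryCatch(extract_edges(kym), error = function(e) NULL)
  if (is.null(edges))
    return(list(v_f = NA_real_, v_p = NA_real_, accepted = FALSE,
                reason = "edge_extraction", edges = NULL))
  flt <- filter_filaments(edges, min_length_px, max_reversal_frac)
  if (length(flt$accepted) == 0)
    return(list(v_f = NA_real_, v_p = NA_real_, accepted = FALSE,
                reason = flt$rejections$reason[1], edges = edges))
  v_f <- sliding_velocity(edges)
  v_p <- if (is.null(traj$config$barbed)) NA_real_
         else attr(elongation_trace(edges), "v_p")
  list(v_f = v_f, v_p = v_p, accepted = TRUE, reason = NA_character_,
       edges = edges)
}

# build the sim_config for one filament of one scenario cell
.filament_config <- function(sc, cond, cm, seed) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + sc$heterogeneity_cv^2))
  q <- if (sdlog > 0) rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
  L0 <- round(runif(1, sc$length_range_su[1], sc$length_range_su[2]))
  # bed quality scales speed, force and cycling together
  sp <- cond$species
  sp$v0_max <- sp$v0_max * q
  sp$F_stall <- sp$F_stall * q
  sp$k_det_c <- sp$k_det_c * q
  sim_config(species = sp,
             barbed = if (cond$stabilized) NULL else cond$barbed,
             motor_density = cond$motor_density,
             C_m = if (cond$stabilized) 0 else cm,
             ATP = cond$ATP, eta_b = cond$eta_b, crowding = cond$crowding,
             initial_length = L0, duration = sc$duration, dt = cond$dt,
             sample_dt = 1, seed = seed, mode = cond$mode,
             xi_anchor = cond$xi_anchor)
}

#' Run a scenario end to end
#'
#' For every condition and (for polymerizing conditions) every G-actin
#' concentration, simulates `n_filaments` filaments, renders each into a
#' kymograph, analyzes it, and aggregates: velocity summaries per cell,
#' a barbed-end kinetics fit per condition with at least three
#' concentrations, and k_off ratios against the control condition.  Fully
#' reproducible from the root seed; per-filament seeds are logged in the
#' result table.  Stage failures are recorded per filament, never dropped
#' silently.
#'
#' @param sc a [scenario()].
#' @param conditions optional subset of condition labels to run.
#' @param cm_grid optional override of the concentration grid.
#' @param n_filaments optional override of the per-cell filament count.
#' @return An object of class `"scenario_report"`: list with `table`
#'   (per-filament data.frame), `summaries` (per condition x C_m velocity
#'   summaries), `fits` (named list of [fit_vp_vs_cm()] objects),
#'   `koff_vs_control` (named list of [compare_koff()] results) and the
#'   scenario echo.
#' @export
run_scenario <- function(sc, conditions = NULL, cm_grid = NULL,
                         n_filaments = NULL) {
  stopifnot(inherits(sc, "scenario"))
  conds <- sc$conditions
  if (!is.null(conditions)) {
    labels <- vapply(conds, function(c) c$label, "")
    missing <- setdiff(conditions, labels)
    if (length(missing) > 0)
      stop("unknown condition(s): ", paste(missing, collapse = ", "))
    conds <- conds[labels %in% conditions]
  }
  if (is.null(cm_grid)) cm_grid <- sc$cm_grid
  if (is.null(n_filaments)) n_filaments <- sc$n_filaments
  rows <- list()
  for (ci in seq_along(conds)) {
    cond <- conds[[ci]]
    cms <- if (cond$stabilized) NA_real_ else cm_grid
    for (mi in seq_along(cms)) {
      for (i in seq_len(n_filaments)) {
        seed <- .derive_seed(sc$root_seed, ci, mi, i)
        img <- sc$imaging
        img$seed <- .derive_seed(seed, 7L)
        res <- tryCatch({
          cfg <- .filament_config(sc, cond, cms[mi], seed)
          traj <- simulate_gliding(cfg)
          a <- analyze_trajectory(traj, img)
          list(v_f = a$v_f, v_p = a$v_p, accepted = a$accepted,
               reason = a$reason)
        }, error = function(e)
          list(v_f = NA_real_, v_p = NA_real_, accepted = FALSE,
               reason = paste0("error: ", conditionMessage(e))))
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond$label, C_m = cms[mi], filament = i, seed = seed,
          v_f = res$v_f, v_p = res$v_p, accepted = res$accepted,
          reason = res$reason, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  summaries <- list()
  fits <- list()
  for (cond in conds) {
    sub <- tab[tab$condition == cond$label & tab$accepted, , drop = FALSE]
    cells <- split(sub, format(sub$C_m))
    summaries[[cond$label]] <- lapply(cells, function(cell) {
      s <- if (sum(is.finite(cell$v_f)) >= 2) summarize_condition(cell$v_f)
           else list(mean = NA_real_, sem = NA_real_,
                     n = sum(is.finite(cell$v_f)))
      c(s, list(C_m = cell$C_m[1]))
    })
    if (!cond$stabilized && length(unique(sub$C_m)) >= 3 &&
        sum(is.finite(sub$v_p)) >= 6) {
      pts <- sub[is.finite(sub$v_p), c("C_m", "v_p")]
      vars <- tapply(pts$v_p, pts$C_m, var)
      if (all(is.finite(vars)) && all(vars > 0))
        pts$weight <- 1 / vars[as.character(pts$C_m)]
      fits[[cond$label]] <- fit_vp_vs_cm(
        pts, seed = .derive_seed(sc$root_seed, 999L))
    }
  }
  koff <- list()
  if (!is.null(sc$control) && sc$control %in% names(fits)) {
    for (lbl in setdiff(names(fits), sc$control))
      koff[[lbl]] <- compare_koff(fits[[sc$control]], fits[[lbl]])
  }
  structure(list(name = sc$name, root_seed = sc$root_seed, table = tab,
                 summaries = summaries, fits = fits,
                 koff_vs_control = koff, schema_version = 1L),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> '%s' (root seed %d)\n", x$name, x$root_seed))
  for (lbl in names(x$summaries)) {
    for (s in x$summaries[[lbl]]) {
      cm <- if (is.na(s$C_m)) "stabilized" else sprintf("C_m %g uM", s$C_m)
      cat(sprintf("  %s [%s]: v_f = %.1f +/- %.1f nm/s (n = %d)\n",
                  lbl, cm, s$mean, s$sem, s$n))
    }
    if (lbl %in% names(x$fits)) {
      f <- x$fits[[lbl]]
      cat(sprintf("    fit: k_on %.2f, k_off %.2f, Cc+ %.3f\n",
                  f$k_on, f$k_off, f$C_c_plus))
    }
  }
  invisible(x)
}

#' Write a scenario report to disk (JSON summary + CSV table)
#'
#' @param report a [run_scenario()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the JSON path.
#' @export
write_scenario_report <- function(report, dir) {
  stopifnot(inherits(report, "scenario_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report$table, file.path(dir, "filaments.csv"), row.names = FALSE)
  js <- list(schema_version = report$schema_version, name = report$name,
             root_seed = report$root_seed,
             summaries = report$summaries,
             fits = lapply(report$fits, function(f)
               list(k_on = f$k_on, k_off = f$k_off, C_c_plus = f$C_c_plus,
                    se = as.list(f$se),
                    ci = apply(f$ci, 1, as.list, simplify = FALSE))),
             koff_vs_control = lapply(report$koff_vs_control, function(k)
               list(ratio = k$ratio, ci = k$ci, p = k$p)))
  path <- file.path(dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bundled reference scenarios
#'
#' Two ready-made designs reproducing the reference assay layouts:
#' \describe{
#'   \item{`"immobilized_reference"`}{motors on glass: a stabilized-filament
#'     myosin-1b condition at 2 mM ATP plus four polymerizing conditions
#'     crossed with the G-actin grid — no motors (control), myosin 1b at
#'     2 mM and at 0.2 mM ATP, and fast slip-bond myosin II; motor density
#'     8000 per um^2.}
#'   \item{`"bilayer_reference"`}{motors on a supported lipid bilayer at
#'     8500 per um^2 in methylcellulose buffer, with the anchor drag taken
#'     from the reference mobility calibration: stabilized and polymerizing
#'     membrane conditions plus an immobilized stabilized condition for the
#'     velocity-reduction comparison.}
#' }
#'
#' @param name scenario name.
#' @param n_filaments filaments per condition and concentration.
#' @param root_seed integer root seed.
#' @return A [scenario()].
#' @export
bundled_scenario <- function(name = c("immobilized_reference",
                                      "bilayer_reference"),
                             n_filaments = 50, root_seed = 1) {
  name <- match.arg(name)
  myo1b <- reference_species("myo1b")
  myoII <- reference_species("myoII")
  if (name == "immobilized_reference") {
    conds <- list(
      gliding_condition("stabilized_myo1b_2mM", myo1b, stabilized = TRUE),
      gliding_condition("no_motor", myo1b, motor_density = 0),
      gliding_condition("myo1b_2mM", myo1b),
      gliding_condition("myo1b_0.2mM", myo1b, ATP = 0.2),
      gliding_condition("myoII", myoII, dt = 0.004))
    scenario(name, conds, n_filaments = n_filaments,
             cm_grid = c(0.1, 0.3, 0.6, 0.8, 1), root_seed = root_seed,
             control = "no_motor")
  } else {
    xi <- anchor_drag_from_D(reference_anchor_mobility())
    conds <- list(
      gliding_condition("membrane_stabilized", myo1b, motor_density = 8500,
                        mode = "membrane", xi_anchor = xi,
                        stabilized = TRUE),
      gliding_condition("membrane_polymerizing", myo1b,
                        motor_density = 8500, mode = "membrane",
                        xi_anchor = xi),
      gliding_condition("immobilized_stabilized", myo1b,
                        stabilized = TRUE))
    scenario(name, conds, n_filaments = n_filaments,
             cm_grid = c(0.1, 0.3, 0.6, 0.8, 1), root_seed = root_seed,
             control = NULL)
  }
}

#' Reference in-plane mobility of an engaged membrane-anchored motor
#'
#' Effective diffusion coefficient (um^2/s) assigned to a bilayer-anchored
#' motor while it is engaged with a filament.  It is far below the free
#' lipid or free motor mobility: when a filament bridges many motors their
#' drags add and the measured motor mobility collapses, so the effective
#' per-anchor drag relevant to force transmission corresponds to a much
#' slower diffusive scale.  The value is part of the tuned reference
#' parameter set (see the methods vignette).
#'
#' @return Diffusion coefficient in um^2/s.
#' @export
reference_anchor_mobility <- function() 3.42e-4
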