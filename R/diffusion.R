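#' Configuration for a needle-skin-receptor diffusion simulation
#'
#' Sets up the half unit cell of one microneedle and its surrounding skin,
#' solved with an explicit forward-time centred-space (FTCS) scheme for
#' Fick's second law. The model is linear in the drug load, so the solver
#' tracks the *fraction* of the load in each compartment and rescales to
#' micrograms afterwards.
#'
#' Lengths are micrometres, times minutes, masses micrograms. The donor
#' window of the Franz cell is 1 cm^2 for the vertical device and 1.13 cm^2
#' for the horizontal one; cumulative amounts are reported per 1 cm^2.
#'
#' @param needle A [frustum_needle()] or [pyramid_needle()], dims in um.
#' @param D Diffusion coefficient in um^2/min. Values outside the typical
#'   skin range 50-1000 trigger a warning.
#' @param t_end Simulated duration in minutes.
#' @param load_per_needle Drug load per needle in ug (total load divided by
#'   the needle count).
#' @param n_needles Number of needles on the patch.
#' @param dx,dy Grid spacing in um (default 2).
#' @param dt Time step in minutes; capped at 0.9 x [stability_limit()]. If
#'   `NULL` the cap itself is used.
#' @param skin_thickness Skin depth in um (default 1000, i.e. 1 mm).
#' @param unit_cell_width Half the needle-to-needle spacing in um: the half
#'   unit cell runs from the needle symmetry axis to the midline between
#'   adjacent needles.
#' @param receptor_mode `"finite"` (well-mixed receptor of volume
#'   `receptor_volume`, bidirectional exchange, reaches equilibrium) or
#'   `"sink"` (receptor concentration pinned at zero).
#' @param receptor_volume Receptor solution volume in uL (default 5000, a
#'   typical Franz cell).
#' @param mn_type `"hydrogel"` (drug impregnated in the needle polymer) or
#'   `"plastic"` (needle only pre-treats the skin; drug solution sits in a
#'   donor layer above the skin and fills the needle-shaped cavity).
#' @param donor_layer_height Height of the donor solution layer in um
#'   (plastic mode only; default 1000).
#' @param device `"vertical"` (1 cm^2 window) or `"horizontal"` (1.13 cm^2).
#' @param output_times Times (min) at which the curve is sampled; default 25
#'   evenly spaced points over `[0, t_end]`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(needle, D, t_end, load_per_needle, n_needles,
                              dx = 2, dy = 2, dt = NULL,
                              skin_thickness = 1000, unit_cell_width = 300,
                              receptor_mode = c("finite", "sink"),
                              receptor_volume = 5000,
                              mn_type = c("hydrogel", "plastic"),
                              donor_layer_height = 1000,
                              device = c("vertical", "horizontal"),
                              output_times = NULL) {
  stopifnot(inherits(needle, "mn_needle"))
  receptor_mode <- match.arg(receptor_mode)
  mn_type <- match.arg(mn_type)
  device <- match.arg(device)
  check_nonneg(D = D, load_per_needle = load_per_needle)
  if (any(c(dx, dy, skin_thickness, unit_cell_width, t_end,
            receptor_volume, donor_layer_height) <= 0)) {
    stop("dx, dy, t_end, skin_thickness, unit_cell_width, receptor_volume ",
         "and donor_layer_height must be positive", call. = FALSE)
  }
  if (D < 50 || D > 1000) {
    warning(sprintf(
      "D = %g um^2/min is outside the typical skin range [50, 1000]", D),
      call. = FALSE)
  }
  if (needle_length(needle) > skin_thickness) {
    stop("needle length exceeds the skin thickness", call. = FALSE)
  }
  if (!is.null(dt) && dt <= 0) stop("dt must be positive", call. = FALSE)
  if (is.null(output_times)) {
    output_times <- seq(0, t_end, length.out = 25)
  }
  if (any(output_times < 0 | output_times > t_end)) {
    stop("output_times must lie within [0, t_end]", call. = FALSE)
  }
  structure(
    list(needle = needle, D = D, t_end = t_end,
         load_per_needle = load_per_needle, n_needles = as.integer(n_needles),
         dx = dx, dy = dy, dt = dt, skin_thickness = skin_thickness,
         unit_cell_width = unit_cell_width, receptor_mode = receptor_mode,
         receptor_volume = receptor_volume, mn_type = mn_type,
         donor_layer_height = donor_layer_height, device = device,
         output_times = sort(output_times)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "diffusion simulation: %s MN, D=%g um^2/min, %d needles x %g ug,\n",
    x$mn_type, x$D, x$n_needles, x$load_per_needle))
  cat(sprintf(
    "  grid %gx%g um over %g um skin, cell width %g um, receptor %s, t_end %g min\n",
    x$dx, x$dy, x$skin_thickness, x$unit_cell_width, x$receptor_mode,
    x$t_end))
  invisible(x)
}

#' Classify mesh elements by their available neighbours
#'
#' The discretized unit cell has five element types, distinguished by which
#' neighbours exist to exchange drug with: `internal` (4 neighbours),
#' `edge` (3; top-row interior and side-column interior), `bottom_edge`
#' (bottom-row interior, which additionally faces the receptor), `corner`
#' (top-row ends) and `bottom_corner` (bottom-row ends).
#'
#' @param nrows,ncols Grid dimensions, each >= 2.
#' @return Character matrix of classes; an exhaustive, exclusive partition.
#' @export
classify_elements <- function(nrows, ncols) {
  if (nrows < 2 || ncols < 2) {
    stop("the mesh must be at least 2 x 2", call. = FALSE)
  }
  cls <- matrix("internal", nrows, ncols)
  cls[1, ] <- "edge"
  cls[nrows, ] <- "bottom_edge"
  cls[2:(nrows - 1), c(1, ncols)] <- "edge"
  cls[1, c(1, ncols)] <- "corner"
  cls[nrows, c(1, ncols)] <- "bottom_corner"
  cls
}

#' Largest stable time step of the explicit scheme
#'
#' The FTCS scheme is stable for
#' `dt <= dx^2 dy^2 / (2 D (dx^2 + dy^2))`, which reduces to `dx^2/(4D)` on
#' a square grid. With D = 1000 um^2/min and dx = dy = 2 um the bound is
#' 0.001 min.
#'
#' @param D Diffusion coefficient (um^2/min) or a [simulation_config()].
#' @param dx,dy Grid spacing in um (ignored when `D` is a config).
#' @return Maximum stable `dt` in minutes (`Inf` when D = 0).
#' @export
stability_limit <- function(D, dx = 2, dy = 2) {
  if (inherits(D, "simulation_config")) {
    dx <- D$dx; dy <- D$dy; D <- D$D
  }
  stopifnot(D >= 0, dx > 0, dy > 0)
  if (D == 0) return(Inf)
  dx^2 * dy^2 / (2 * D * (dx^2 + dy^2))
}

#' Advance the concentration field by one FTCS step
#'
#' Low-level single-step update, mainly for validation: the field `conc`
#' (mass per cell) exchanges mass across every interior face with
#' coefficient `D*dt/dx^2` (horizontal) and `D*dt/dy^2` (vertical); faces
#' on the symmetry axis, outer midline and top exchange nothing. The bottom
#' row optionally exchanges with a receptor. Mass is conserved exactly up
#' to floating-point rounding.
#'
#' @param conc Numeric matrix of mass per cell (ug).
#' @param D,dx,dy,dt Diffusion coefficient and discretization.
#' @param bottom `"none"` (closed bottom), `"sink"` or `"finite"`.
#' @param receptor_mass Current receptor mass (finite mode).
#' @param receptor_area 2D receptor capacity in um^2 (finite mode).
#' @return List with the updated `conc` matrix and `receptor_mass`.
#' @export
diffusion_step <- function(conc, D, dx, dy, dt,
                           bottom = c("none", "sink", "finite"),
                           receptor_mass = 0, receptor_area = NULL) {
  bottom <- match.arg(bottom)
  mode <- match(bottom, c("none", "sink", "finite")) - 1L
  if (mode == 2L && (is.null(receptor_area) || receptor_area <= 0)) {
    stop("finite mode needs a positive receptor_area", call. = FALSE)
  }
  res <- ftcs_run(conc, D, dx, dy, dt, 1L, integer(0), mode,
                  if (is.null(receptor_area)) 1 else receptor_area,
                  receptor_mass, integer(0))
  list(conc = res$conc, receptor_mass = res$receptor_mass)
}

window_area_cm2 <- function(device) {
  switch(device, vertical = 1.0, horizontal = 1.13,
         stop("unknown device label: ", device, call. = FALSE))
}

#' Run the permeation simulation
#'
#' Builds the half unit cell, distributes the drug load uniformly over the
#' needle cells (hydrogel mode) or over the donor layer plus the
#' needle-shaped cavity (plastic mode), advances the FTCS scheme to
#' `t_end`, and converts the receptor mass fraction into a permeation
#' curve: cumulative amount is `fraction x load_per_needle x n_needles`
#' divided by the donor window area (reported per 1 cm^2), and cumulative
#' percentage is `100 x fraction` of the total load.
#'
#' @param config A [simulation_config()].
#' @param snapshot_times Optional times (min) at which to return the full
#'   concentration field (ug per cell), e.g. for heat maps.
#' @return A `permeation_curve` data frame with columns `time_min`,
#'   `time_h`, `amount_ug_per_cm2`, `percentage`; attributes carry the
#'   config, the relative mass-balance error and any snapshots.
#' @export
run_simulation <- function(config, snapshot_times = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  dx <- config$dx; dy <- config$dy
  nrow_skin <- max(2L, as.integer(round(config$skin_thickness / dy)))
  ncols <- max(2L, as.integer(round(config$unit_cell_width / dx)))
  w0 <- needle_half_width(config$needle, 0)
  if (!is.na(w0) && w0 > config$unit_cell_width + 1e-9) {
    stop("needle is wider than the unit cell", call. = FALSE)
  }
  mask <- rasterize_half_needle(config$needle, dx, dy,
                                config$skin_thickness, ncols = ncols)

  if (config$mn_type == "hydrogel") {
    n_donor <- 0L
    init <- matrix(0, nrow_skin, ncols)
    if (any(mask)) init[mask] <- 1 / sum(mask)
  } else {
    n_donor <- max(1L, as.integer(round(config$donor_layer_height / dy)))
    init <- matrix(0, n_donor + nrow_skin, ncols)
    loaded <- matrix(FALSE, n_donor + nrow_skin, ncols)
    loaded[seq_len(n_donor), ] <- TRUE
    cavity <- which(mask, arr.ind = TRUE)
    if (nrow(cavity)) {
      cavity[, 1] <- cavity[, 1] + n_donor
      loaded[cavity] <- TRUE
    }
    init[loaded] <- 1 / sum(loaded)
  }
  total0 <- sum(init)

  out_t <- config$output_times
  if (total0 == 0 || config$D == 0) {
    frac <- rep(0, length(out_t))
    mass_err <- 0
    snaps <- NULL
  } else {
    dt_cap <- 0.9 * stability_limit(config$D, dx, dy)
    dt <- if (is.null(config$dt)) dt_cap else min(config$dt, dt_cap)
    nsteps <- as.integer(ceiling(config$t_end / dt))
    steps_frac <- out_t / dt
    lo <- pmin(floor(steps_frac), nsteps)
    hi <- pmin(lo + 1, nsteps)
    rec_steps <- sort(unique(as.integer(c(lo, hi))))
    snap_steps <- if (is.null(snapshot_times)) integer(0) else
      sort(unique(as.integer(round(snapshot_times / dt))))
    mode <- switch(config$receptor_mode, sink = 1L, finite = 2L)
    recv_area <- receptor_area_um2(config, ncols)
    res <- ftcs_run(init, config$D, dx, dy, dt, nsteps, rec_steps, mode,
                    recv_area, 0.0, snap_steps)
    rec <- stats::setNames(res$receptor, as.character(rec_steps))
    f_lo <- rec[as.character(as.integer(lo))]
    f_hi <- rec[as.character(as.integer(hi))]
    w <- ifelse(hi > lo, steps_frac - lo, 0)
    frac <- as.numeric(f_lo + w * (f_hi - f_lo))
    mass_err <- abs(sum(res$conc) + res$receptor_mass - total0) / total0
    snaps <- if (length(snap_steps)) {
      lapply(res$snapshots, function(m) m * config$load_per_needle)
    } else NULL
  }

  m_total <- config$load_per_needle * config$n_needles
  curve <- data.frame(
    time_min = out_t,
    time_h = out_t / 60,
    amount_ug_per_cm2 = frac * m_total / window_area_cm2(config$device),
    percentage = 100 * frac
  )
  structure(curve,
            class = c("permeation_curve", "data.frame"),
            config = config, mass_balance_error = mass_err,
            snapshots = snaps)
}

# 2D receptor capacity: the real receptor volume spread under the donor
# window gives a liquid height; the unit cell sees that height times its own
# width.
receptor_area_um2 <- function(config, ncols) {
  window_um2 <- window_area_cm2(config$device) * 1e8
  height_um <- config$receptor_volume * 1e9 / window_um2 # uL -> um^3
  height_um * ncols * config$dx
}

#' @export
print.permeation_curve <- function(x, ...) {
  cat(sprintf("permeation curve: %d time points, %.3g--%.3g h\n",
              nrow(x), min(x$time_h), max(x$time_h)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Cumulative permeation percentage
#'
#' `100 * m_t / m_total`: the cumulative permeated mass as a percentage of
#' the total drug load.
#'
#' @param m_t Cumulative permeated mass (ug), >= 0.
#' @param m_total Total loaded mass (ug), > 0.
#' @return Percentage (vectorized over `m_t`).
#' @export
cumulative_percentage <- function(m_t, m_total) {
  if (any(m_total <= 0)) stop("m_total must be positive", call. = FALSE)
  if (any(m_t < 0)) stop("m_t must be non-negative", call. = FALSE)
  100 * m_t / m_total
}

#' Analytic fractional release of a uniformly loaded slab
#'
#' Closed-form series for a slab of thickness `L`, uniformly loaded, with a
#' no-flux face at the top and a perfect sink at the bottom:
#' `1 - sum_n 8/((2n+1)^2 pi^2) exp(-D (2n+1)^2 pi^2 t / (4 L^2))`.
#' Used as an independent oracle for the finite-difference solver in its
#' slab limit (needle spanning the full cell width and depth, sink mode).
#'
#' @param D Diffusion coefficient (um^2/min).
#' @param thickness Slab thickness L (um).
#' @param t Time(s) in minutes.
#' @return Fraction released in `[0, 1]`, vectorized over `t`.
#' @export
slab_release_oracle <- function(D, thickness, t) {
  stopifnot(D >= 0, thickness >= 0, all(t >= 0))
  if (thickness == 0) return(ifelse(t > 0, 1, 0))
  vapply(t, function(tt) {
    if (tt == 0 || D == 0) return(0)
    tau <- D * pi^2 * tt / (4 * thickness^2)
    s <- 0
    for (n in 0:1000000) {
      k <- 2 * n + 1
      term <- 8 / (k^2 * pi^2) * exp(-k^2 * tau)
      s <- s + term
      if (term < 1e-12) break
    }
    1 - s
  }, numeric(1))
}
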