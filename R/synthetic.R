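#' Map molecular weight to a skin diffusion coefficient
#'
#' Monotone decreasing size-scaling map `D = c * MW^(-1/3)` (a
#' Stokes-Einstein-like dependence on molecular radius), clipped to the
#' 50-1000 um^2/min range typical of drugs in skin. The constant `c` is
#' anchored so that a mid-range small molecule (MW 194, caffeine) gets
#' D = 600 um^2/min: `c = 600 * 194^(1/3)`.
#'
#' @param mw Molecular weight(s) in Da, > 0.
#' @return Diffusion coefficient(s) in um^2/min, within `[50, 1000]`.
#' @export
mw_to_diffusion <- function(mw) {
  if (any(mw <= 0)) stop("molecular weight must be positive", call. = FALSE)
  c0 <- 600 * 194^(1 / 3)
  pmin(1000, pmax(50, c0 * mw^(-1 / 3)))
}

#' Default study drugs for the synthetic generator
#'
#' The six permeants with their molecular weight, the needle and skin
#' types they were tested with, how many records each contributes (191 in
#' total, lidocaine 73 = 38%), and a per-drug loading window. Each source
#' study used its own formulation, so loadings cluster by drug (the union
#' of the windows spans the full 50-70,940 ug range); this clustering is
#' what makes leave-one-drug-out extrapolation hard.
#'
#' @return Data frame with columns `drug`, `mw`, `mn_type`, `skins`,
#'   `count`, `loading_min`, `loading_max`.
#' @export
default_drug_table <- function() {
  data.frame(
    drug = c("lidocaine", "BSA", "GHK", "copper", "rhodamine", "caffeine"),
    mw = c(234, 66430, 340, 64, 479, 194),
    mn_type = c("both", "hydrogel", "plastic", "plastic", "hydrogel",
                "hydrogel"),
    skins = c("H,R", "R", "H,R", "R,H", "R", "H"),
    count = c(73L, 33L, 24L, 23L, 19L, 19L),
    loading_min = c(20000, 2000, 200, 100, 50, 5000),
    loading_max = c(70940, 10000, 2000, 1000, 500, 20000),
    stringsAsFactors = FALSE
  )
}

#' Default patch geometry pool for the synthetic generator
#'
#' Four hydrogel frustum patches (64 needles each, lengths 700-999 um,
#' radii chosen so patch areas land in the published 27-37 mm^2 range)
#' and the fully specified 351-needle square-pyramid plastic patch
#' (base edge 75 um, height 700 um).
#'
#' @return List with elements `hydrogel` and `plastic`, each a list of
#'   [patch_layout()] objects.
#' @export
default_geometry_pool <- function() {
  list(
    hydrogel = list(
      patch_layout(frustum_needle(80, 120, length = 700), 64, "hydrogel"),
      patch_layout(frustum_needle(75, 115, length = 820), 64, "hydrogel"),
      patch_layout(frustum_needle(70, 110, length = 889), 64, "hydrogel"),
      patch_layout(frustum_needle(60, 100, length = 999), 64, "hydrogel")
    ),
    plastic = list(
      patch_layout(pyramid_needle(75, 700), 351, "plastic")
    )
  )
}

#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the compiled Franz-cell database: for each drug
#' it builds experimental conditions (patch geometry, skin type, drug
#' loading), runs the diffusion simulator over the sampling time grid, and
#' perturbs the amounts with multiplicative lognormal noise. Defaults
#' reproduce the study conditions: 191 records over six drugs (lidocaine
#' 73), MW 64-66,430 Da, per-drug loading windows whose union spans 50-70,940 ug,
#' a typical Franz sampling grid within 0.0833-48 h, and a 15% relative
#' noise level.
#'
#' @param seed Integer seed (mandatory; the generator is fully
#'   deterministic given the config).
#' @param drugs Data frame like `default_drug_table()`: columns `drug`,
#'   `mw`, `mn_type` (`"hydrogel"`, `"plastic"` or `"both"`), `skins`
#'   (comma-separated subset of R,H), `count`, and optionally
#'   `loading_min`/`loading_max` per-drug overrides.
#' @param loading_range Global loading range in ug (default the published
#'   50-70,940).
#' @param time_grid_h Sampling times in hours (default
#'   0.25, 0.5, 1, 2, 4, 6, 8, 24, 48).
#' @param noise_sd Standard deviation of the lognormal log-noise on
#'   amounts (default 0.15); the noise factor is winsorized to
#'   `[1 - 3*sd, 1 + 3*sd]` so records stay physical.
#' @param geometry_pool Patch layouts per needle type (see
#'   `default_geometry_pool()`).
#' @param dx,dy Simulator grid spacing in um (default 10: the generator
#'   trades grid resolution for throughput across many curves).
#' @param receptor_volume,receptor_mode,device,skin_thickness,unit_cell_width
#'   Passed to [simulation_config()].
#' @return A `generator_config`.
#' @export
generator_config <- function(seed,
                             drugs = default_drug_table(),
                             loading_range = c(50, 70940),
                             time_grid_h = c(0.25, 0.5, 1, 2, 4, 6, 8, 24, 48),
                             noise_sd = 0.15,
                             geometry_pool = default_geometry_pool(),
                             dx = 10, dy = 10,
                             receptor_volume = 5000,
                             receptor_mode = "finite",
                             device = "vertical",
                             skin_thickness = 1000,
                             unit_cell_width = 300) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(is.data.frame(drugs),
            all(c("drug", "mw", "mn_type", "skins", "count") %in%
                  names(drugs)),
            length(loading_range) == 2, loading_range[1] > 0,
            diff(loading_range) >= 0, noise_sd >= 0,
            all(time_grid_h > 0), all(time_grid_h <= 48))
  structure(
    list(seed = as.integer(seed), drugs = drugs,
         loading_range = loading_range, time_grid_h = sort(time_grid_h),
         noise_sd = noise_sd, geometry_pool = geometry_pool,
         dx = dx, dy = dy, receptor_volume = receptor_volume,
         receptor_mode = receptor_mode, device = device,
         skin_thickness = skin_thickness,
         unit_cell_width = unit_cell_width),
    class = "generator_config"
  )
}

#' Generate a synthetic permeation dataset from the simulator
#'
#' For each drug a small set of experimental protocols is laid out, one
#' per combination of the drug's needle types and skin types: a protocol
#' fixes a patch geometry (cycled from the pool), a skin type and a
#' log-uniform drug loading drawn once from the drug's loading window.
#' The diffusion simulator (with D derived from MW via
#' [mw_to_diffusion()]) produces the protocol's noiseless curve over the
#' time grid; the drug's record count is then filled with replicate
#' curves of the protocols in rotation, mirroring replicate Franz cells
#' run at the same sampling times. Amounts receive multiplicative
#' lognormal noise per row, and the percentage is recomputed from the
#' noisy amount so each row stays internally consistent. A noiseless
#' ground-truth table accompanies the records.
#'
#' @param config A [generator_config()].
#' @return List with `records` (a `permeation_data` frame) and `truth`
#'   (same rows, noiseless responses, plus the diffusion coefficient used).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  local_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  tg <- config$time_grid_h
  rows <- list()
  for (d in seq_len(nrow(config$drugs))) {
    spec <- config$drugs[d, ]
    skins <- trimws(strsplit(spec$skins, ",")[[1]])
    types <- if (spec$mn_type == "both") c("hydrogel", "plastic")
    else spec$mn_type
    lo <- if (!is.null(spec$loading_min) && !is.na(spec$loading_min))
      spec$loading_min else config$loading_range[1]
    hi <- if (!is.null(spec$loading_max) && !is.na(spec$loading_max))
      spec$loading_max else config$loading_range[2]
    n_cond <- ceiling(spec$count / length(tg))
    # at least ~3 replicate curves per protocol, as in replicate Franz runs
    n_proto <- max(1L, min(length(types) * length(skins),
                           as.integer(round(n_cond / 3))))
    protos <- vector("list", n_proto)
    for (p in seq_len(n_proto)) {
      ti <- (p - 1) %% length(types)
      type_p <- types[ti + 1]
      pool <- config$geometry_pool[[type_p]]
      layout <- pool[[(p - 1) %/% length(types) %% length(pool) + 1]]
      skin_p <- skins[((p - 1) + (p - 1) %/% length(types)) %%
                        length(skins) + 1]
      loading <- exp(stats::runif(1, log(lo), log(hi)))
      D <- mw_to_diffusion(spec$mw)
      cfg <- simulation_config(
        needle = layout$needle, D = D, t_end = max(tg) * 60,
        load_per_needle = loading / layout$n_needles,
        n_needles = layout$n_needles,
        dx = config$dx, dy = config$dy,
        skin_thickness = config$skin_thickness,
        unit_cell_width = config$unit_cell_width,
        receptor_mode = config$receptor_mode,
        receptor_volume = config$receptor_volume,
        mn_type = type_p, device = config$device,
        output_times = tg * 60)
      curve <- run_simulation(cfg)
      protos[[p]] <- data.frame(
        drug = spec$drug, skin_type = skin_p, mn_type = type_p,
        mn_length = needle_length(layout$needle),
        mn_surface_area = patch_surface_area(scale_layout_mm(layout)),
        drug_loading = loading,
        permeation_time = tg, mw = spec$mw,
        permeation_amount = curve$amount_ug_per_cm2,
        permeation_percentage = curve$percentage,
        D = D, stringsAsFactors = FALSE)
    }
    drug_rows <- lapply(seq_len(n_cond), function(k) {
      protos[[(k - 1) %% n_proto + 1]]
    })
    dr <- do.call(rbind, drug_rows)
    rows[[d]] <- dr[seq_len(spec$count), , drop = FALSE]
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL

  n <- nrow(truth)
  noisy <- truth
  if (config$noise_sd > 0) {
    fac <- exp(stats::rnorm(n, 0, config$noise_sd))
    fac <- pmin(pmax(fac, max(0, 1 - 3 * config$noise_sd)),
                1 + 3 * config$noise_sd)
    noisy$permeation_amount <- truth$permeation_amount * fac
  }
  win <- window_area_cm2(config$device)
  noisy$permeation_percentage <- ifelse(
    noisy$drug_loading > 0,
    100 * noisy$permeation_amount * win / noisy$drug_loading, 0)
  noisy$D <- NULL
  list(records = suppressWarnings(as_permeation_data(noisy)), truth = truth)
}

# convert a layout's needle dims from um to mm so areas come out in mm^2
scale_layout_mm <- function(layout) {
  nd <- layout$needle
  nd2 <- if (inherits(nd, "pyramid_needle")) {
    pyramid_needle(nd$base_edge / 1000, nd$height / 1000)
  } else {
    frustum_needle(nd$r_top / 1000, nd$r_base / 1000, nd$length / 1000)
  }
  patch_layout(nd2, layout$n_needles, layout$needle_type_label)
}
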