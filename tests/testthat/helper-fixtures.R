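# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# the default synthetic study dataset (191 records, six drugs), cached
# because generation runs ~8 diffusion simulations
default_synth <- function() {
  if (is.null(.fixtures$synth)) {
    .fixtures$synth <- generate_dataset(generator_config(seed = 42))
  }
  .fixtures$synth
}

# a small handcrafted record table with valid schema
make_records <- function(n = 10,
                         drug = "drugA",
                         skin_type = "R",
                         mn_type = "hydrogel",
                         mn_length = 700,
                         mn_surface_area = 30,
                         drug_loading = 1000,
                         permeation_time = seq(0.25, 48, length.out = n),
                         mw = 234,
                         permeation_amount = NULL,
                         permeation_percentage = NULL) {
  if (is.null(permeation_amount)) {
    permeation_amount <- 10 * permeation_time
  }
  df <- data.frame(drug = drug, skin_type = skin_type, mn_type = mn_type,
                   mn_length = mn_length, mn_surface_area = mn_surface_area,
                   drug_loading = drug_loading,
                   permeation_time = permeation_time, mw = mw,
                   permeation_amount = permeation_amount,
                   stringsAsFactors = FALSE)
  if (is.null(permeation_percentage)) {
    df$permeation_percentage <-
      100 * df$permeation_amount / df$drug_loading
  } else {
    df$permeation_percentage <- permeation_percentage
  }
  df
}

# quick simulation config on a coarse grid for property tests
quick_config <- function(D = 500, len = 700, load = 1000, n = 64,
                         mode = "finite", dx = 10, t_end = 48 * 60,
                         needle = frustum_needle(80, 120, length = len),
                         output_times = c(0.25, 1, 4, 8, 24, 48) * 60, ...) {
  suppressWarnings(simulation_config(
    needle = needle, D = D, t_end = t_end, load_per_needle = load / n,
    n_needles = n, dx = dx, dy = dx, unit_cell_width = 300,
    receptor_mode = mode, output_times = output_times, ...))
}

# decimal round-half-up (guards against floats sitting a hair below an
# exact decimal .5 boundary)
round_half_up <- function(x, digits) {
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}
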