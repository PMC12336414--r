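# Small fixture builders shared across the suite; everything is generated
# in code under fixed seeds.

tiny_config <- function(...) {
  colony_config(n_plots = 2, nests_per_plot_range = c(5, 8), seed = 101L, ...)
}

# uniform-response nest table for playback closed-form checks
flat_nests <- function(n, p, occupied = TRUE) {
  data.frame(
    nest_id = sprintf("n%05d", seq_len(n)),
    plot_id = "P01",
    position_m = 0,
    occupied = occupied,
    response_prob = ifelse(occupied, p, 0),
    male_present = occupied,
    stringsAsFactors = FALSE
  )
}

# a colony whose occupied nests all hatched on a fixed date, for
# age-controlled calling checks
hatched_colony <- function(n = 30, hatch = as.Date("2023-07-20"),
                           seed = 77L) {
  cfg <- colony_config(n_plots = 1, nests_per_plot_range = c(n, n),
                       prop_empty = 0, seed = seed)
  col <- generate_colony(cfg)
  col$nests$outcome <- "success"
  col$nests$hatch_date <- hatch
  col$nests$failure_day <- NA_real_
  col
}

# labelled single-call clip at a given distance for detector checks
render_one_call <- function(type, distance_m, seed,
                            specs = call_type_specs()) {
  sp <- specs[[type]]
  set.seed(seed)
  dur <- runif(1, sp$dur_lo, sp$dur_hi)
  ev <- data.frame(call_type = type, start_s = 1.5, duration_s = dur,
                   position_m = distance_m)
  render_plot_night(ev, duration_s = 5, seed = seed)
}
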