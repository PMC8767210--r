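# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# a small full cohort at desk scale (movement/dives shortened, behaviour
# per hour unchanged)
small_cohort <- function() {
  cached("small_cohort",
         simulate_cohort(sim_config(seed = 101, n_males = 3, n_females = 5,
                                    trip_scale = 0.03)))
}

# straight noise-free hourly track fixture
straight_fixes <- function(n = 30, lc = "3") {
  t0 <- as.POSIXct("2010-03-01", tz = "UTC")
  data.frame(time = t0 + (0:(n - 1)) * 3600,
             lon = -122.33 - (0:(n - 1)) * 0.02,
             lat = 37.11 + (0:(n - 1)) * 0.015,
             lc = lc)
}

# hand-built two-slope V-dive depth series at 8 s (steady limbs, brief
# terminal spike), matching the transit archetype's construction
v_dive_series <- function(depth = 100, n_desc = 20, t0 = as.POSIXct("2010-03-01", tz = "UTC")) {
  s <- c(seq(0, 1, length.out = n_desc), seq(1, 0, length.out = n_desc)[-1])
  d <- depth * ifelse(s < 0.94, 0.65 * s / 0.94, 0.65 + 0.35 * (s - 0.94) / 0.06)
  d <- c(numeric(5), d, numeric(5))
  data.frame(time = t0 + (seq_along(d) - 1) * 8, depth_m = d)
}
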