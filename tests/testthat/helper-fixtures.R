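# shared fixture cache: rendering is the slow step, so scenes used by more
# than one test are built once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# compact render settings for module-level tests (full-size scenes are
# exercised in the acceptance suite)
small_params <- function(image_px = 512, ...) {
  render_params(image_px = image_px, ...)
}

# independent rotation helper for oracles (plain rotation matrix arithmetic,
# no package internals)
rotate_xy <- function(xy, phi_deg) {
  phi <- phi_deg * pi / 180
  cbind(cos(phi) * xy[, 1] - sin(phi) * xy[, 2],
        sin(phi) * xy[, 1] + cos(phi) * xy[, 2])
}
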