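# Reduced synthetic-study settings shared across tests: small segments keep
# the suite fast while preserving the pause/nonpause design.

small_spec <- function(..., segments = c(s1 = 50000L, s2 = 50000L),
                       n_pause = 4L, plants = list()) {
  study_spec(segments = segments, n_pause = n_pause, plants = plants, ...)
}

# a fixture bundle on disk, built once per test run
local_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "fragilescan-fixture")
      paths <- suppressMessages(make_study_fixture(
        dir, seed = 11,
        spec = small_spec(plants = default_plants()[1:2])))
      cache <<- paths
    }
    cache
  }
})
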