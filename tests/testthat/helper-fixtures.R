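# Shared fixtures: short sessions keep the suite fast; scientific checks that
# need longer recordings set their own durations.

test_config <- function(...) {
  args <- utils::modifyList(list(session_duration = 60, seed = 1), list(...))
  do.call(synth_config, args)
}

# A raw_photometry object built directly from closed-form channels.
make_raw <- function(duration = 2, pr = 500, fr = 30,
                     f470 = function(t) rep(2, length(t)),
                     f405 = function(t) rep(1, length(t))) {
  t <- seq(0, duration - 1 / pr, by = 1 / pr)
  frames <- seq(0, duration - 1 / fr, by = 1 / fr)
  raw_photometry(t, f470(t), f405(t), frames)
}

# Minimal aligned-session data.frame for module-level tests.
make_aligned <- function(n = 300, fr = 30, animal_id = "m01",
                         session_id = "m01_s001", lighting = "light",
                         zdff = rnorm(n), speed = runif(n, 0, 20),
                         state = "exploratory_walking") {
  lg <- log2(pmax(speed, 0.25))
  out <- data.frame(animal_id = animal_id, session_id = session_id,
                    lighting = lighting, frame = seq_len(n) - 1L,
                    time_s = (seq_len(n) - 1L) / fr, dff = zdff, zdff = zdff,
                    speed = speed, logspeed = lg, stationary = speed < 3,
                    state = state,
                    community = unname(cholspeed:::STATE_COMMUNITY[
                      cholspeed:::STATE_SHORT[state]]))
  class(out) <- c("aligned_session", "data.frame")
  out
}

expect_same_file <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
}
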