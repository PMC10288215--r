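# Shared synthetic fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# a medium noisy session, reused by kinematics/coordination/pipeline tests
noisy_session <- function() {
  fixture("noisy", function() {
    simulate_session(session_config("tied_slow", n_cycles = 120, seed = 42))
  })
}

# a noiseless tied-belt session (all jitter off, coupling concentrations Inf)
noiseless_session <- function() {
  fixture("noiseless", function() {
    simulate_session(session_config("tied_slow", n_cycles = 60, seed = 7,
                                    noiseless = TRUE))
  })
}

# minimal hand-built event table for one limb
simple_limb_events <- function(limb = "LH", contacts = c(0, 1, 2),
                               liftoffs = c(0.6, 1.6),
                               contact_x = rep(0.1, length(contacts)),
                               liftoff_x = rep(-0.14, length(liftoffs))) {
  tibble::tibble(
    limb = limb,
    event = c(rep("contact", length(contacts)), rep("liftoff", length(liftoffs))),
    time_s = c(contacts, liftoffs),
    x_m = c(contact_x, liftoff_x)
  ) |> dplyr::arrange(time_s)
}

# two-limb event table with prescribed contact offsets for coupling tests
paired_limb_events <- function(ref = "LF", other = "RF", n = 10, dur = 1,
                               offset = 0.5, v = 0.4, stance = 0.6) {
  build <- function(limb, t0) {
    ct <- t0 + dur * (0:n)
    lo <- ct[-length(ct)] + stance * dur
    ct_x <- rep(0.15, length(ct))
    lo_x <- ct_x[-length(ct)] - v * stance * dur
    tibble::tibble(
      limb = limb,
      event = c(rep("contact", length(ct)), rep("liftoff", length(lo))),
      time_s = c(ct, lo),
      x_m = c(ct_x, lo_x)
    )
  }
  dplyr::arrange(dplyr::bind_rows(build(ref, 0), build(other, offset)),
                 limb, time_s)
}
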