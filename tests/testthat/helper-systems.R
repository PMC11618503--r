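# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; nothing is read from disk.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

default_params <- function() fixture("params", water_params)

# minimized dimer cluster (open boundaries)
fix_dimer <- function() fixture("dimer", function() build_cluster(2))

# minimized 8-molecule periodic box at 1.0 g/cm^3: short 300 K MD then
# classical minimization, so it is a liquid-like inherent structure
fix_box_is <- function() {
  fixture("box_is", function() {
    cfg <- build_box(8, 1.0, seed = 42)
    st <- beads_state(cfg, 1, 300, seed = 43)
    tr <- pimd_run(st, 800, temperature = 300, save_every = 800, seed = 44)
    minimize_classical(centroid_config(tr$state), default_params())
  })
}

# mass-weighted Hessian eigen-frequencies straight from a record
freqs_of <- function(rec) classical_modes(rec)$frequency_cm1

# standard error with crude blocking (for correlated MD series)
blocked_sem <- function(x, n_blocks = 10) {
  m <- length(x) %/% n_blocks
  if (m < 1) return(sd(x) / sqrt(length(x)))
  bm <- vapply(seq_len(n_blocks), function(b) mean(x[((b - 1) * m + 1):(b * m)]),
               numeric(1))
  sd(bm) / sqrt(n_blocks)
}
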