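# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture_atlas <- function() {
  if (is.null(.fixtures$atlas))
    .fixtures$atlas <- make_toy_atlas(c(32L, 32L, 32L), seed = 1)
  .fixtures$atlas
}

# small default-condition cohort for fast unit tests
fixture_cohort <- function(n = 60L, seed = 42L, ...) {
  key <- paste0("cohort_", n, "_", seed, "_", length(list(...)))
  if (is.null(.fixtures[[key]])) {
    atl <- fixture_atlas()
    cfg <- default_study_config(atl, n_patients = n, seed = seed, ...)
    .fixtures[[key]] <- simulate_cohort(cfg, atl)
  }
  .fixtures[[key]]
}

# tiny hand-built lattice helpers
blank_mask <- function(d = c(8L, 8L, 8L)) array(0L, dim = d)

# evaluate code under a temporary seed without disturbing the global stream
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
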