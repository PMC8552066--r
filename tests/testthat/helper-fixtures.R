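# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

small_mesh <- function() fixture("small_mesh", function()
  build_synthetic_atria(256, rng_seed = 11))

small_torso <- function() fixture("small_torso", function()
  build_torso(small_mesh()))

small_tm <- function() fixture("small_tm", function()
  build_transfer_matrix(small_mesh(), small_torso()))

# corpus-resolution mesh for rotor / phase-detector tests (rotor dynamics
# on the 256-node mesh are too coarse to be representative)
medium_mesh <- function() fixture("medium_mesh", function()
  build_synthetic_atria(720, rng_seed = 13))

# one rotor episode at corpus resolution (region 3)
rotor_episode <- function() fixture("rotor_episode", function()
  simulate_propagation(medium_mesh(),
                       protocol = stimulus_protocol("cross_field_rotor",
                                                    target_region = 3,
                                                    rng_seed = 5),
                       duration_s = 1.2, fs = 500))

# deterministic pseudo-64-channel frame for tensorizer tests
frame64 <- function(seed = 1) {
  set.seed(seed)
  stats::rnorm(64)
}
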