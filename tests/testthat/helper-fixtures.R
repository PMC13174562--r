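# Shared fixtures, built once per test run.

# small default-condition 3-D phantom (sparse filaments, coincidence 0.5)
fixture_phantom_3d <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_filament_stack_3d(phantom_spec_3d(
        shape = c(96, 96, 12), n_mt_filaments = 8, n_sep_filaments = 6,
        coincidence_fraction = 0.5, seed = 42))
    cache
  }
})

# a straight solid tube along x in a 3-D volume (isotropic voxels)
make_tube <- function(len = 60, radius = 2.5, nx = len + 10, ny = 13,
                      nz = 13) {
  tb <- array(FALSE, c(nx, ny, nz))
  cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  for (y in 1:ny) for (z in 1:nz)
    if ((y - cy)^2 + (z - cz)^2 <= radius^2)
      tb[6:(5 + len), y, z] <- TRUE
  tb
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
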