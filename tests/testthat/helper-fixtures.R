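# Shared small-scale fixtures for the test suite. Everything is generated in
# code; the "smoke" scale keeps grids and iteration counts small enough for a
# routine test run while exercising every stage end to end.

smoke_geometry <- function(n = 32L) {
  scan_geometry(n_pixels = n, n_radial = n, n_angles = 48L,
                voxel_size_mm = 2.602 * 128 / n)
}

# A deterministic little annular phantom example with kinetics, used by
# scanner/mtcm/evaluation tests.
smoke_example <- function(seed = 11L, n = 32L) {
  ph <- generate_phantom(seed, n_pixels = n)
  kin <- sample_kinetics(ph, seed = seed + 1L)
  list(phantom = ph, kinetics = kin)
}

table1_means <- function() {
  list(FDG       = compartment_params(0.6, 1.2, 0.1, 0, 0.38),
       Rb82      = compartment_params(1.4822, 0.3159, 0.004, 0, 0.38),
       sestamibi = compartment_params(0.4, 0.094, 0.02, 0.007, 0.38))
}
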