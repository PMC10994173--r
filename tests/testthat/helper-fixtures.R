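# Shared small fixtures, built once per test run.  Everything is generated
# in code; nothing is read from disk.

# small clean blob series (fast, noise-free) reused by several suites
small_clean_series <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      tr <- ground_truth(21, tilt_axis_deg = 0)
      val <<- simulate_tilt_series(seed = 101, size = 128,
                                   angles_deg = seq(-30, 30, by = 3),
                                   truth = tr, n_blobs = 500,
                                   slab_thickness_px = 30,
                                   dose_e_per_A2 = NA)
    }
    val
  }
})

# moderately sized full-truth case with noise, shared by alignment tests
medium_case <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_tilt_series(seed = 11, size = 512)
    val
  }
})

expect_close <- function(x, y, tol) {
  expect_true(all(abs(x - y) <= tol),
              label = sprintf("max|diff| = %g (tol %g)", max(abs(x - y)),
                              tol))
}
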