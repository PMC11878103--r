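# Shared fixtures, memoised so the expensive simulations (calibration and
# the whole-phantom runs) are computed once per test session regardless of
# file order.

fx <- new.env()

fx_calibration <- function() {
  if (is.null(fx$cal)) fx$cal <- calibrate_excitability(0.713)
  fx$cal
}

fx_phantom <- function() {
  if (is.null(fx$phantom)) fx$phantom <- make_heart_phantom(phantom_spec())
  fx$phantom
}

fx_sinus <- function() {
  if (is.null(fx$sinus)) {
    fx_calibration()
    fx$sinus <- run_sinus(fx_phantom(), config = sim_config(duration = 400))
  }
  fx$sinus
}

fx_ectopic <- function() {
  if (is.null(fx$ectopic)) {
    fx_calibration()
    fx$ectopic <- run_ectopic(fx_phantom(), config = sim_config(duration = 400))
  }
  fx$ectopic
}

# planar CV in the standard 30 x 3 x 3 mm calibration slab at the
# calibrated upstroke scale
fx_slab_cv <- function(D = 0.3, dx = 0.292, dt = 0.01) {
  key <- paste0("cv_", D, "_", dx, "_", dt)
  if (is.null(fx[[key]]))
    fx[[key]] <- slab_cv(fx_calibration(), D = D, dx = dx, dt = dt)
  fx[[key]]
}

# small uniform cable volume for solver property tests
make_cable <- function(len_mm = 10, width_mm = 1.5, vs = 0.5, code = 4L) {
  make_slab(c(len_mm, width_mm, width_mm), vs, code)
}

median_by_code <- function(run) {
  stats::setNames(run$summary$median, run$summary$code)
}
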