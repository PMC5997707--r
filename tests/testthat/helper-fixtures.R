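# Shared fixtures: a small reference basis on the canonical grid and the
# packaged photophysics profile. Built once per test run.

test_profile <- hybret::read_photophysics()
test_basis <- hybret::default_basis(test_profile)

# Flat-field single-frame stack helper
flat_stack <- function(cyan_level, yellow_level, H = 20, W = 20, T = 1) {
  hybret::ratio_stack(array(cyan_level, c(H, W, T)),
                      array(yellow_level, c(H, W, T)))
}
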