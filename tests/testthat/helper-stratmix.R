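# Shared scaled-down mixing profiles, computed once per test run. The
# reduced ensembles keep per-bin Monte-Carlo noise small enough for the
# qualitative and tolerance checks below while keeping the suite fast.
test_kernel_ws25 <- mixing_params(ws = 2.5, n_particles = 1500, n_runs = 8,
                                  seed = 42)
test_profile_ws25 <- median_mixing_profile(test_kernel_ws25)

test_kernel_ws05 <- mixing_params(ws = 0.5, n_particles = 1500, n_runs = 10,
                                  seed = 42)
test_profile_ws05 <- median_mixing_profile(test_kernel_ws05)
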