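# Shared fixtures, computed lazily and cached so expensive fits run at
# most once per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

truth_params <- function() default_truth()

# noiseless dataset at the default sampling design
noiseless_dataset <- function() {
  fixture("ds0", {
    tr <- truth_params()
    generate_dataset(tr$growth, tr$qs, design_spec(cv = c(X = 0, A = 0, L = 0)))
  })
}

# noisy dataset (default CV 5%) used by the profile and bootstrap tests
noisy_dataset <- function() {
  fixture("ds_noisy", {
    tr <- truth_params()
    generate_dataset(tr$growth, tr$qs, design_spec(seed = 42))
  })
}

# growth fit on the noiseless dataset (fast, closed form)
growth_fit_noiseless <- function() {
  fixture("gfit0", fit_growth(noiseless_dataset(),
                              control = de_control(max_gen = 400, seed = 7)))
}

# converged kinetic baseline on the noisy dataset (shared by the
# identifiability and uncertainty acceptance checks)
kinetic_fit_noisy <- function() {
  fixture("kfit_noisy", {
    g <- fit_growth(noisy_dataset(), control = de_control(max_gen = 400, seed = 7))
    fit_qs(noisy_dataset(), g$par,
           control = de_control(pop_size = 60, max_gen = 500,
                                tol = 1e-12, seed = 1))
  })
}
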