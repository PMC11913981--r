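# Shared fixtures, all generated in code.

# a small phantom study with one water-rich and one fat-rich lesion
make_test_study <- function(seed, noise_sd = 0.02,
                            shape = c(32L, 96L, 96L)) {
  les <- list(lesion_spec("modic1", round(shape * c(0.5, 0.2, 0.4)), 3),
              lesion_spec("modic2", round(shape * c(0.5, 0.6, 0.4)), 3))
  phantom_subject(phantom_spec(shape = shape, seed = seed, lesions = les,
                               noise_sd = noise_sd))
}

# finite-difference gradient of f at selected indices of x
num_grad_at <- function(f, x, idx, eps = 1e-3) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-6, max(abs(a)), max(abs(b)))
}

# published per-rater misclassification rates shipped with the package
reader_rates_path <- function() {
  system.file("extdata", "turing_misclassification_rates.csv",
              package = "spinesynth")
}
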