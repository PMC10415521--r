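# Shared fixtures, built once per test run. Phantoms are cached in an
# environment so several test files can reuse the same generated case.
.fixture_env <- new.env(parent = emptyenv())

cached_phantom <- function(name, ...) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, generate_phantom(phantom_config(...)), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# default study conditions, noise-free / with noise
phantom_clean <- function() cached_phantom("clean", noise_sigma = 0)
phantom_noisy <- function() cached_phantom("noisy", noise_sigma = 0.02)
phantom_flat <- function() {
  cached_phantom("flat", noise_sigma = 0, bias_amplitude = 0)
}

cached_masks <- function(name, phantom) {
  key <- paste0("masks_", name)
  if (!exists(key, envir = .fixture_env)) {
    assign(key, mask_breast(phantom$t2w), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

dice <- function(a, b) {
  a <- if (is.list(a)) a$values else a
  b <- if (is.list(b)) b$values else b
  2 * sum(a & b) / (sum(a) + sum(b))
}

truth_breast_values <- function(phantom) {
  phantom$truth$breast_mask_left$values |
    phantom$truth$breast_mask_right$values
}

# Per-breast summary of the generated voxel enhancement ground truth.
truth_enhancement <- function(phantom, laterality) {
  side <- phantom$truth[[paste0("breast_mask_", laterality)]]$values
  e <- phantom$truth$true_voxel_enhancement_pct[
    side & phantom$truth$fgt_mask$values]
  e[is.finite(e)]
}

moment_kurtosis <- function(v) {
  m2 <- mean((v - mean(v))^2)
  mean((v - mean(v))^4) / m2^2
}
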