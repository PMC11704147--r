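# shared fixtures: small phantoms are rebuilt per test from specs; anything
# expensive is cached in this environment for reuse across test blocks
.fix <- new.env(parent = emptyenv())

# a small, fast phantom domain for unit tests
tiny_spec <- function(..., seed = 1) {
  phantom_spec(domain_um = c(200, 200, 120), n_large = 0, n_medium = 0,
               n_small = 4, tilt_deg = 0, speckle_cv = 0.15,
               tail_strength = 0.2, seed = seed, ...)
}

# one straight noiseless tube of known diameter (um)
single_tube_spec <- function(d, speckle_cv = 0, tilt_deg = 0,
                             tail_strength = 0, seed = 5) {
  phantom_spec(domain_um = c(300, 300, 200), n_large = 0, n_medium = 0,
               n_small = 1, small_diam_mean_um = d, small_diam_sd_um = 1e-6,
               speckle_cv = speckle_cv, tail_strength = tail_strength,
               tilt_deg = tilt_deg, seed = seed)
}

# cache helper
fixture <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

# noiseless Gaussian profile on a 1-um grid
gauss_profile <- function(sigma_um, amp = 1, offset = 0, center = NULL,
                          span = NULL) {
  span <- span %||% max(40, ceiling(8 * sigma_um))
  x <- seq(0, span, by = 1)
  center <- center %||% (span / 2)
  list(x = x, y = offset + amp * exp(-(x - center)^2 / (2 * sigma_um^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
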