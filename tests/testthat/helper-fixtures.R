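# Shared fixtures, built programmatically and cached for the test session.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# Analytic shapes -------------------------------------------------------------

regular_ngon <- function(n = 256, r = 1, cx = 0, cy = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  as_outline(cbind(cx + r * cos(th), cy + r * sin(th)))
}

ellipse_outline <- function(a = 1, b = 0.5, n = 512, angle = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  p <- cbind(a * cos(th), b * sin(th))
  if (angle != 0) p <- cladescan:::rotate_points(p, angle)
  as_outline(p)
}

# exact ellipse perimeter by numerical quadrature of the arc-length integral
ellipse_perimeter_exact <- function(a, b) {
  4 * a * integrate(function(t) sqrt(1 - (1 - (b / a)^2) * sin(t)^2),
                    0, pi / 2, rel.tol = 1e-12)$value
}

# Small generated datasets (written under tempdir, reused across tests) -------

small_dataset <- function(preset = "keyhole_like", n = 12, image_size = 64,
                          seed = 11) {
  key <- sprintf("ds_%s_%d_%d_%d", preset, n, image_size, seed)
  cached(key, {
    dir <- file.path(tempdir(), key)
    generate_dataset(generator_config(preset, n_per_clade = n,
                                      image_size = image_size, seed = seed),
                     dir)
  })
}

# Independent Mann-Whitney oracle: exact two-sided p by full enumeration of
# rank assignments (tie-free samples only).
mwu_enum <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, function(ix) sum(ix) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  list(u = u_obs, p = min(1, p))
}
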