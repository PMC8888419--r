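# shared fixtures and independent oracles

mk_spec <- function(nr = 4L, nc = 4L, cell = 10, x0 = 0, y0 = nr * cell,
                    crs = "EPSG:32610") {
  grid_spec(nr, nc, x0, y0, cell, crs = crs)
}

mk_grid <- function(values, nr = NULL, nc = NULL, cell = 10, ...) {
  if (is.matrix(values)) { nr <- nrow(values); nc <- ncol(values) }
  grid_new(mk_spec(nr, nc, cell = cell, ...), values)
}

# Independent ordinary-kriging oracle: builds the augmented system with
# explicit loops and its own spherical semivariance, then solves with
# qr.solve. Shares no code with krige_point beyond base linear algebra.
oracle_spherical_gamma <- function(h, nugget, psill, range_m) {
  if (h == 0) return(0)
  r <- min(h / range_m, 1)
  nugget + psill * (1.5 * r - 0.5 * r^3)
}

oracle_krige <- function(x, y, z, nugget, psill, range_m, x0, y0) {
  n <- length(x)
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    h <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    A[i, j] <- oracle_spherical_gamma(h, nugget, psill, range_m)
  }
  A[n + 1, seq_len(n)] <- 1
  A[seq_len(n), n + 1] <- 1
  b <- numeric(n + 1)
  for (i in seq_len(n))
    b[i] <- oracle_spherical_gamma(sqrt((x[i] - x0)^2 + (y[i] - y0)^2),
                                   nugget, psill, range_m)
  b[n + 1] <- 1
  sol <- qr.solve(A, b)
  w <- sol[seq_len(n)]
  list(prediction = sum(w * z), variance = sum(w * b[seq_len(n)]) + sol[n + 1],
       weights = w)
}

# brute-force per-pixel depth-weighted average (oracle for soil_sand)
oracle_depth_avg <- function(layers) {
  sp <- layers[[1]]$grid$spec
  out <- matrix(NA_real_, sp$n_rows, sp$n_cols)
  for (i in seq_len(sp$n_rows)) for (j in seq_len(sp$n_cols)) {
    num <- 0; den <- 0
    for (l in layers) {
      v <- l$grid$values[i, j]
      if (!is.na(v)) {
        w <- l$bottom_cm - l$top_cm
        num <- num + w * v; den <- den + w
      }
    }
    if (den > 0) out[i, j] <- num / den
  }
  out
}

# the published per-site single-factor labels of the 23 confirmed sites
site_fixture <- function() confirmed_site_labels()
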