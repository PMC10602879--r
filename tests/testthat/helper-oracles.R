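# Shared helpers for the test suite: an independently coded MSD oracle and
# small synthetic-table builders.

# Brute-force cumulative radial-increment MSD, written as plain loops so it
# shares no code path with msd_paper().
oracle_msd_paper <- function(x, y) {
  n <- length(x)
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- sqrt((x[i] - x[1])^2 + (y[i] - y[1])^2)
  }
  out <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    s <- 0
    for (i in seq_len(k)) s <- s + (d[i + 1] - d[i])^2
    out[k] <- s
  }
  out
}

# Random nuclei table (spheres) for colocalization tests.
make_nuclei_table <- function(n, r_um = 2.5, seed = 1) {
  withr::with_seed(seed, data.frame(
    nucleus_id = seq_len(n),
    x_um = runif(n, 5, 50), y_um = runif(n, 5, 50),
    z_um = runif(n, 3, 6), r_um = r_um))
}

# n uniform points inside one nucleus row.
points_in_nucleus <- function(nuc, n) {
  u <- runif(n)
  rho <- nuc$r_um * u^(1 / 3)
  ct <- runif(n, -1, 1)
  ph <- runif(n, 0, 2 * pi)
  st <- sqrt(1 - ct^2)
  data.frame(x_um = nuc$x_um + rho * st * cos(ph),
             y_um = nuc$y_um + rho * st * sin(ph),
             z_um = nuc$z_um + rho * ct)
}

# Foci table with per_nuc uniform foci in every nucleus of a nuclei table.
make_random_foci <- function(nuclei, per_nuc, volume_um3 = 0.065) {
  rows <- lapply(seq_len(nrow(nuclei)), function(i) {
    cbind(nucleus_id = nuclei$nucleus_id[i],
          points_in_nucleus(nuclei[i, ], per_nuc),
          volume_um3 = volume_um3)
  })
  df <- do.call(rbind, rows)
  df$focus_id <- seq_len(nrow(df))
  df
}

msd_curve_from <- function(lag_s, value) {
  structure(list(variant = "standard", lag_s = lag_s, value = value,
                 frame_interval = lag_s[1]), class = "MSDCurve")
}
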