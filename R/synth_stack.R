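# Synthetic 3-D microscopy: spherical nuclei with diffraction-limited foci.
# Defaults emulate fixed germline RNA FISH acquisitions: nuclei of 2-3 um
# radius imaged at a 0.2 um z-step with 0.1 um pixels, an RNA focus channel
# carrying 0-6 foci per nucleus and an optional telomere-marker channel with
# ~12 foci per nucleus.

#' Zone radial boundaries for the three-zone nuclear zonation
#'
#' Returns the two normalized-radius boundaries `(b1, b2)` separating the
#' interior zone 3 (`rho <= b1`), the middle zone 2 (`b1 < rho <= b2`) and
#' the peripheral zone 1 (`rho > b2`).
#'
#' @param convention `"equal_area"` (boundaries `sqrt(1/3)`, `sqrt(2/3)`;
#'   default, the Meister-style convention) or `"equal_volume"`
#'   (`(1/3)^(1/3)`, `(2/3)^(1/3)`).
#' @return numeric length-2
#' @export
zone_bounds <- function(convention = c("equal_area", "equal_volume")) {
  convention <- match.arg(convention)
  if (convention == "equal_area") c(sqrt(1 / 3), sqrt(2 / 3))
  else c((1 / 3)^(1 / 3), (2 / 3)^(1 / 3))
}

#' Sample focus positions inside a spherical nucleus
#'
#' Positions are uniform over the sphere volume by default. With
#' `zone_probs`, the zone is first drawn from the given probabilities and the
#' radial coordinate is then uniform-in-volume within that zone's shell, so
#' empirical zone fractions converge to `zone_probs`.
#'
#' @param center nucleus centre `(x, y, z)` in micrometres
#' @param radius nucleus radius in micrometres
#' @param n number of positions
#' @param zone_probs optional length-3 probabilities for zones (1, 2, 3)
#' @param convention zonation convention, see [zone_bounds()]
#' @param rho_max cap on the normalized radius (default 1)
#' @param seed optional RNG seed
#' @return data.frame with columns `x`, `y`, `z` (um), `rho`, `zone`
#' @export
sample_focus_positions <- function(center, radius, n, zone_probs = NULL,
                                   convention = "equal_area", rho_max = 1,
                                   seed = NULL) {
  with_seed(seed, {
    b <- zone_bounds(convention)
    shells <- rbind(c(b[2], rho_max), c(b[1], b[2]), c(0, b[1]))
    if (is.null(zone_probs)) {
      rho <- pmin(runif(n)^(1 / 3), rho_max)
      zone <- assign_zone(rho, convention)
    } else {
      stopifnot(length(zone_probs) == 3, all(zone_probs >= 0))
      zone <- sample.int(3L, n, replace = TRUE, prob = zone_probs)
      lo <- shells[zone, 1]; hi <- shells[zone, 2]
      rho <- (runif(n) * (hi^3 - lo^3) + lo^3)^(1 / 3)
    }
    # isotropic direction
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- rho * radius
    data.frame(x = center[1] + u[, 1] * r,
               y = center[2] + u[, 2] * r,
               z = center[3] + u[, 3] * r,
               rho = rho, zone = zone)
  })
}

#' Specification of one synthetic focus channel
#'
#' @param n_range integer range (min, max) of foci per nucleus, drawn
#'   uniformly
#' @param sigma_um isotropic Gaussian sigma of a rendered focus (um)
#' @param amplitude_range peak-amplitude range, drawn uniformly
#' @param compartment `"nuclear"` or `"cytoplasmic"`
#' @param zone_probs optional zone placement bias, see
#'   [sample_focus_positions()]
#' @param min_sep_um minimum centre separation between same-channel foci in a
#'   nucleus (default 0.6 um, discrete objects)
#' @param coloc_with optional name of an earlier channel; `coloc_frac` of
#'   this channel's foci are placed exactly at positions of that channel's
#'   foci in the same nucleus (ground-truth colocalized pairs)
#' @param coloc_frac fraction of foci colocalized with `coloc_with`
#' @return a list of class `focus_channel_spec`
#' @export
focus_channel_spec <- function(n_range = c(0L, 6L), sigma_um = 0.15,
                               amplitude_range = c(80, 200),
                               compartment = c("nuclear", "cytoplasmic"),
                               zone_probs = NULL, min_sep_um = 0.6,
                               coloc_with = NULL, coloc_frac = 0) {
  compartment <- match.arg(compartment)
  stopifnot(sigma_um > 0, all(amplitude_range > 0),
            coloc_frac >= 0, coloc_frac <= 1, min_sep_um >= 0)
  structure(list(n_range = as.integer(n_range), sigma_um = sigma_um,
                 amplitude_range = amplitude_range, compartment = compartment,
                 zone_probs = zone_probs, min_sep_um = min_sep_um,
                 coloc_with = coloc_with, coloc_frac = coloc_frac),
            class = "focus_channel_spec")
}

#' Simulate a multichannel nuclei + foci stack with ground truth
#'
#' Renders a DNA channel of soft-edged filled spheres and one rendered focus
#' channel per entry of `focus_channels` (sums of isotropic 3-D Gaussians),
#' adds Gaussian read noise (optionally Poisson shot noise) on a constant
#' background, and returns the truth tables used to validate segmentation,
#' measurement, zonation and colocalization.
#'
#' @param n_nuclei number of nuclei; placement rejects overlaps and fails
#'   after `max_tries` draws per nucleus
#' @param radius_range nucleus radius range in um (default 2-3 um)
#' @param shape stack dimensions `(nz, ny, nx)`
#' @param voxel_size `(dz, dy, dx)` um (default `c(0.2, 0.1, 0.1)`)
#' @param focus_channels named list of [focus_channel_spec()]s
#' @param dna_amplitude peak intensity of the DNA channel spheres
#' @param background constant offset added to every channel
#' @param noise_sd Gaussian read-noise standard deviation
#' @param shot_noise if TRUE, add Poisson shot noise on the rendered signal
#' @param max_tries placement retry budget per nucleus
#' @param seed RNG seed
#' @return list with elements `stack` (an [image_stack()]; channel 1 is
#'   `"dna"`), `nuclei` (truth data.frame: `nucleus_id, x_um, y_um, z_um,
#'   r_um`) and `foci` (truth data.frame: `focus_id, channel, nucleus_id,
#'   x_um, y_um, z_um, sigma_um, amplitude, rho, zone, compartment,
#'   partner_id, rendered_mass`)
#' @export
simulate_nuclei_stack <- function(n_nuclei = 3,
                                  radius_range = c(2, 3),
                                  shape = c(36L, 256L, 256L),
                                  voxel_size = c(0.2, 0.1, 0.1),
                                  focus_channels = list(
                                    terra = focus_channel_spec()
                                  ),
                                  dna_amplitude = 500,
                                  background = 100,
                                  noise_sd = 10,
                                  shot_noise = FALSE,
                                  max_tries = 200L,
                                  seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 4), all(radius_range > 0))
  extent <- shape * voxel_size            # (z, y, x) um
  with_seed(seed, {
    # --- place nuclei (rejection sampling, no overlap, inside the stack)
    centers <- matrix(NA_real_, n_nuclei, 3)  # x, y, z
    radii <- numeric(n_nuclei)
    margin <- 0.1
    for (i in seq_len(n_nuclei)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r <- runif(1, radius_range[1], radius_range[2])
        if (any(2 * (r + margin) > rev(extent))) {
          stop("nucleus of radius ", round(r, 2), " um does not fit the stack")
        }
        p <- c(runif(1, r + margin, extent[3] - r - margin),
               runif(1, r + margin, extent[2] - r - margin),
               runif(1, r + margin, extent[1] - r - margin))
        ok <- TRUE
        if (i > 1) {
          dd <- sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - p)^2))
          ok <- all(dd > radii[seq_len(i - 1)] + r + margin)
        }
        if (ok) { centers[i, ] <- p; radii[i] <- r; placed <- TRUE; break }
      }
      if (!placed) stop("cannot place ", n_nuclei, " non-overlapping nuclei ",
                        "within ", max_tries, " tries; enlarge the stack")
    }
    nuclei <- data.frame(nucleus_id = seq_len(n_nuclei),
                         x_um = centers[, 1], y_um = centers[, 2],
                         z_um = centers[, 3], r_um = radii)

    # --- draw ground-truth foci per channel
    foci <- list()
    fid <- 0L
    for (ch_name in names(focus_channels)) {
      spec <- focus_channels[[ch_name]]
      for (i in seq_len(n_nuclei)) {
        n_f <- if (spec$n_range[1] == spec$n_range[2]) spec$n_range[1] else
          sample(seq(spec$n_range[1], spec$n_range[2]), 1L)
        if (n_f == 0L) next
        if (spec$compartment == "nuclear") {
          pos <- NULL
          for (try in seq_len(max_tries)) {
            cand <- sample_focus_positions(
              c(centers[i, 1], centers[i, 2], centers[i, 3]), radii[i], n_f,
              zone_probs = spec$zone_probs)
            dmin <- if (n_f > 1) min(stats::dist(cand[, c("x", "y", "z")])) else Inf
            if (dmin >= spec$min_sep_um) { pos <- cand; break }
          }
          if (is.null(pos)) stop("cannot place ", n_f, " foci at min ",
                                 "separation ", spec$min_sep_um, " um")
        } else {
          # cytoplasmic: uniform in the stack, outside every nucleus
          pos <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                            rho = numeric(0), zone = integer(0))
          while (nrow(pos) < n_f) {
            p <- c(runif(1, 0.3, extent[3] - 0.3),
                   runif(1, 0.3, extent[2] - 0.3),
                   runif(1, 0.3, extent[1] - 0.3))
            dd <- sqrt(colSums((t(centers) - p)^2))
            if (all(dd > radii + 0.3)) {
              pos <- rbind(pos, data.frame(x = p[1], y = p[2], z = p[3],
                                           rho = NA_real_, zone = NA_integer_))
            }
          }
        }
        amp <- runif(n_f, spec$amplitude_range[1], spec$amplitude_range[2])
        partner <- rep(NA_integer_, n_f)
        if (!is.null(spec$coloc_with) && spec$coloc_frac > 0) {
          donors <- Filter(function(f) f$channel == spec$coloc_with &&
                             identical(f$nucleus_id, i), foci)
          n_co <- min(round(spec$coloc_frac * n_f), length(donors))
          if (n_co > 0) {
            pick <- sample(seq_along(donors), n_co)
            for (j in seq_len(n_co)) {
              d <- donors[[pick[j]]]
              pos[j, c("x", "y", "z")] <- c(d$x, d$y, d$z)
              pos$rho[j] <- d$rho; pos$zone[j] <- d$zone
              partner[j] <- d$focus_id
            }
          }
        }
        for (j in seq_len(n_f)) {
          fid <- fid + 1L
          foci[[fid]] <- list(
            focus_id = fid, channel = ch_name,
            nucleus_id = if (spec$compartment == "nuclear") i else NA_integer_,
            x = pos$x[j], y = pos$y[j], z = pos$z[j],
            sigma_um = spec$sigma_um, amplitude = amp[j],
            rho = pos$rho[j], zone = pos$zone[j],
            compartment = spec$compartment, partner_id = partner[j])
        }
      }
    }

    # --- render
    nc <- 1L + length(focus_channels)
    ch_names <- c("dna", names(focus_channels))
    vox <- array(0, dim = c(nc, shape))
    zc <- (seq_len(shape[1]) - 0.5) * voxel_size[1]
    yc <- (seq_len(shape[2]) - 0.5) * voxel_size[2]
    xc <- (seq_len(shape[3]) - 0.5) * voxel_size[3]

    box_idx <- function(c_um, half_um) {
      # (x, y, z) um centre -> index ranges (iz, iy, ix)
      list(
        iz = which(abs(zc - c_um[3]) <= half_um),
        iy = which(abs(yc - c_um[2]) <= half_um),
        ix = which(abs(xc - c_um[1]) <= half_um)
      )
    }

    edge <- 0.2  # soft-edge width of the DNA sphere, um
    for (i in seq_len(n_nuclei)) {
      b <- box_idx(centers[i, ], radii[i] + 2 * edge)
      dz2 <- (zc[b$iz] - centers[i, 3])^2
      dy2 <- (yc[b$iy] - centers[i, 2])^2
      dx2 <- (xc[b$ix] - centers[i, 1])^2
      dd <- sqrt(outer(outer(dz2, dy2, `+`), dx2, `+`))
      prof <- pmin(pmax((radii[i] - dd) / edge + 0.5, 0), 1)
      vox[1, b$iz, b$iy, b$ix] <- vox[1, b$iz, b$iy, b$ix] + dna_amplitude * prof
    }

    rendered_mass <- numeric(length(foci))
    for (k in seq_along(foci)) {
      f <- foci[[k]]
      ch <- match(f$channel, ch_names)
      b <- box_idx(c(f$x, f$y, f$z), 4 * f$sigma_um)
      if (!length(b$iz) || !length(b$iy) || !length(b$ix)) next
      gz <- exp(-(zc[b$iz] - f$z)^2 / (2 * f$sigma_um^2))
      gy <- exp(-(yc[b$iy] - f$y)^2 / (2 * f$sigma_um^2))
      gx <- exp(-(xc[b$ix] - f$x)^2 / (2 * f$sigma_um^2))
      g <- f$amplitude * outer(outer(gz, gy), gx)
      vox[ch, b$iz, b$iy, b$ix] <- vox[ch, b$iz, b$iy, b$ix] + g
      rendered_mass[k] <- sum(g)
    }

    if (shot_noise) {
      vox[] <- stats::rpois(length(vox), lambda = pmax(vox, 0))
    }
    vox[] <- pmax(vox + background + rnorm(length(vox), sd = noise_sd), 0)

    foci_df <- if (length(foci)) {
      data.frame(
        focus_id = vapply(foci, `[[`, integer(1), "focus_id"),
        channel = vapply(foci, `[[`, character(1), "channel"),
        nucleus_id = vapply(foci, `[[`, integer(1), "nucleus_id"),
        x_um = vapply(foci, `[[`, numeric(1), "x"),
        y_um = vapply(foci, `[[`, numeric(1), "y"),
        z_um = vapply(foci, `[[`, numeric(1), "z"),
        sigma_um = vapply(foci, `[[`, numeric(1), "sigma_um"),
        amplitude = vapply(foci, `[[`, numeric(1), "amplitude"),
        rho = vapply(foci, `[[`, numeric(1), "rho"),
        zone = vapply(foci, function(f) as.integer(f$zone), integer(1)),
        compartment = vapply(foci, `[[`, character(1), "compartment"),
        partner_id = vapply(foci, `[[`, integer(1), "partner_id"),
        rendered_mass = rendered_mass
      )
    } else {
      data.frame(focus_id = integer(), channel = character(),
                 nucleus_id = integer(), x_um = numeric(), y_um = numeric(),
                 z_um = numeric(), sigma_um = numeric(), amplitude = numeric(),
                 rho = numeric(), zone = integer(), compartment = character(),
                 partner_id = integer(), rendered_mass = numeric())
    }

    list(stack = image_stack(vox, voxel_size, ch_names),
         nuclei = nuclei, foci = foci_df)
  })
}
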