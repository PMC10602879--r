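# 3D segmentation and measurement of nuclei and fluorescent foci.

#' Fit the equal-volume sphere of a nucleus mask
#'
#' The nucleus is approximated by a sphere: the centroid is the unweighted
#' voxel centroid and the radius is the equal-volume radius
#' `r = (3 V / 4 pi)^(1/3)` with `V` = voxel count x voxel volume.
#'
#' @param mask logical 3-D array `(z, y, x)`
#' @param voxel_size `(dz, dy, dx)` um
#' @return list with `centroid` (named x, y, z in um), `r_um`, `volume_um3`
#'   and `n_voxels`
#' @export
fit_nucleus_sphere <- function(mask, voxel_size) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  cen <- voxel_centers_um(idx[, 1], idx[, 2], idx[, 3], voxel_size)
  v <- nrow(idx) * prod(voxel_size)
  list(centroid = colMeans(cen), r_um = (3 * v / (4 * pi))^(1 / 3),
       volume_um3 = v, n_voxels = nrow(idx))
}

# split label regions whose interior distance map carries several deep cores
# (marker-based watershed-style split of touching nuclei)
split_touching_nuclei <- function(labels, voxel_size, min_radius_um,
                                  merge_um) {
  out <- labels
  next_label <- max(labels) + 1L
  for (lab in setdiff(sort(unique(as.integer(labels))), 0L)) {
    region <- labels == lab
    dist <- mask_distance(region, voxel_size)
    sm <- gauss_blur3(dist, c(1, 1, 1))
    sm[!region] <- -Inf
    peaks <- local_maxima3(sm, min_radius_um)
    if (nrow(peaks) < 2L) next
    pk_um <- voxel_centers_um(peaks[, 1], peaks[, 2], peaks[, 3], voxel_size)
    ord <- order(-sm[peaks])
    keep <- integer(0)
    for (i in ord) {
      if (!length(keep) ||
          all(sqrt(rowSums((pk_um[keep, , drop = FALSE] -
                            matrix(pk_um[i, ], length(keep), 3,
                                   byrow = TRUE))^2)) > merge_um)) {
        keep <- c(keep, i)
      }
    }
    if (length(keep) < 2L) next
    markers <- pk_um[keep, , drop = FALSE]
    idx <- which(region, arr.ind = TRUE)
    vox_um <- voxel_centers_um(idx[, 1], idx[, 2], idx[, 3], voxel_size)
    d2 <- sapply(seq_len(nrow(markers)), function(m) {
      rowSums((vox_um - matrix(markers[m, ], nrow(vox_um), 3, byrow = TRUE))^2)
    })
    assign <- max.col(-d2, ties.method = "first")
    new_labs <- c(lab, next_label + seq_len(length(keep) - 1L) - 1L)
    next_label <- next_label + length(keep) - 1L
    out[region] <- new_labs[assign]
  }
  out
}

#' Segment nuclei in the DNA channel
#'
#' Global Otsu threshold, 26-connected 3-D components, volume filter, and an
#' optional marker-based split of touching nuclei (cores of the interior
#' distance map become markers; voxels are assigned to the nearest marker).
#' Each retained region is approximated by its equal-volume sphere.
#'
#' @param stack an [image_stack()]
#' @param dna_channel channel name or index of the DNA stain (default
#'   `"dna"`)
#' @param config a [run_config()]; uses the `detection` block
#'   (`min_volume_um3`, `max_volume_um3`, `watershed`, `split_min_radius_um`,
#'   `marker_merge_um`)
#' @return An object of class `NucleusSet`: list with `labels` (integer 3-D
#'   array, 0 = background), `table` (data.frame `nucleus_id, x_um, y_um,
#'   z_um, r_um, volume_um3, n_voxels`) and `voxel_size`. A constant or
#'   signal-free stack yields zero nuclei with a warning.
#' @export
segment_nuclei <- function(stack, dna_channel = "dna",
                           config = run_config()) {
  p <- config$detection
  vol <- stack_channel(stack, dna_channel)
  thr <- otsu_threshold(vol)
  empty <- function(msg) {
    warning(msg)
    structure(list(labels = array(0L, dim(vol)),
                   table = data.frame(nucleus_id = integer(), x_um = numeric(),
                                      y_um = numeric(), z_um = numeric(),
                                      r_um = numeric(), volume_um3 = numeric(),
                                      n_voxels = integer()),
                   voxel_size = stack$voxel_size),
              class = "NucleusSet")
  }
  if (is.na(thr)) return(empty("constant image: no nuclei segmented"))
  mask <- vol > thr
  if (!any(mask) || all(mask)) return(empty("degenerate threshold: no nuclei"))
  labels <- label_components(mask)
  voxvol <- prod(stack$voxel_size)
  counts <- tabulate(labels[labels > 0L])
  ok <- which(counts * voxvol >= p$min_volume_um3 &
              counts * voxvol <= p$max_volume_um3)
  if (!length(ok)) return(empty("no regions within the nucleus volume range"))
  labels[!(labels %in% ok)] <- 0L
  if (isTRUE(p$watershed)) {
    labels <- split_touching_nuclei(labels, stack$voxel_size,
                                    p$split_min_radius_um, p$marker_merge_um)
  }
  # relabel 1..n in order of first voxel occurrence (deterministic)
  old <- unique(as.integer(labels[labels > 0L]))
  relab <- labels
  tab <- vector("list", length(old))
  for (i in seq_along(old)) {
    region <- labels == old[i]
    relab[region] <- i
    fit <- fit_nucleus_sphere(region, stack$voxel_size)
    tab[[i]] <- data.frame(nucleus_id = i, x_um = fit$centroid[["x"]],
                           y_um = fit$centroid[["y"]], z_um = fit$centroid[["z"]],
                           r_um = fit$r_um, volume_um3 = fit$volume_um3,
                           n_voxels = fit$n_voxels)
  }
  structure(list(labels = relab, table = do.call(rbind, tab),
                 voxel_size = stack$voxel_size),
            class = "NucleusSet")
}

#' @export
print.NucleusSet <- function(x, ...) {
  cat(sprintf("NucleusSet: %d nuclei, mean r = %.2f um\n",
              nrow(x$table),
              if (nrow(x$table)) mean(x$table$r_um) else NA_real_))
  invisible(x)
}

#' Detect and measure 3-D foci in one channel
#'
#' Band-pass detection (scale-normalized Laplacian of Gaussian at the
#' expected focus scale), local maxima above `k_mad` MADs of the filtered
#' image whose raw peak also clears `k_mad` MADs above the raw background,
#' region growing on the Gaussian-smoothed image down to `rel_cutoff`
#' of the peak above local background, and per-focus measurements on the raw
#' intensities: the region's voxel count gives the volume; the integrated
#' density is, by default, the local-background-subtracted raw sum over a
#' spherical aperture of radius `aperture_factor * sigma_um` around the
#' centroid (mode `"aperture"`; it estimates the focus's total signal mass),
#' or the plain raw sum over the grown region (mode `"region"`); the average
#' intensity is the integrated density divided by the measured voxel count.
#'
#' @param stack an [image_stack()]
#' @param focus_channel channel name or index
#' @param nuclei optional [segment_nuclei()] result for nucleus assignment
#'   and compartment classification
#' @param restrict_to_nuclei if TRUE, drop foci whose centroid lies outside
#'   every nucleus
#' @param config a [run_config()]; uses the `detection` and `zonation` blocks
#' @return data.frame with one row per focus: `focus_id, channel, x_um, y_um,
#'   z_um, n_voxels, volume_um3, integrated_density, average_intensity,
#'   peak_intensity, nucleus_id, compartment`, plus `d_center_um, d_edge_um,
#'   rho, rho_clamped, zone` when `nuclei` is supplied
#' @export
detect_foci <- function(stack, focus_channel, nuclei = NULL,
                        restrict_to_nuclei = FALSE, config = run_config()) {
  p <- config$detection
  if (p$sigma_um <= 0) stop("detection sigma must be positive")
  ch_name <- if (is.numeric(focus_channel))
    stack$channel_names[channel_index(stack, focus_channel)] else focus_channel
  vol <- stack_channel(stack, focus_channel)
  d3 <- dim(vol)
  sigma_vox <- p$sigma_um / stack$voxel_size  # (z, y, x)
  resp <- log_response(vol, sigma_vox)
  thr <- median(resp) + p$k_mad * mad(resp)
  peaks <- local_maxima3(resp, thr)
  # the same noise-scaled rule in the raw domain: a candidate's raw peak must
  # also clear k_mad MADs above the raw background (rejects smooth-field
  # noise maxima that survive the band-pass threshold)
  if (nrow(peaks) > 0L) {
    thr_raw <- median(vol) + p$k_mad * mad(vol)
    peaks <- peaks[vol[peaks] >= thr_raw, , drop = FALSE]
  }
  empty_foci <- data.frame(
    focus_id = integer(), channel = character(), x_um = numeric(),
    y_um = numeric(), z_um = numeric(), n_voxels = integer(),
    volume_um3 = numeric(), integrated_density = numeric(),
    average_intensity = numeric(), peak_intensity = numeric(),
    nucleus_id = integer(), compartment = character())
  if (nrow(peaks) == 0L) {
    return(annotate_foci(empty_foci, nuclei, config, restrict_to_nuclei))
  }
  # order by response, then deduplicate peaks closer than 2 sigma
  ord <- order(-resp[peaks])
  peaks <- peaks[ord, , drop = FALSE]
  pk_um <- voxel_centers_um(peaks[, 1], peaks[, 2], peaks[, 3],
                            stack$voxel_size)
  keep <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    if (!length(keep) ||
        min(sqrt(rowSums((pk_um[keep, , drop = FALSE] -
                          matrix(pk_um[i, ], length(keep), 3,
                                 byrow = TRUE))^2))) > 2 * p$sigma_um) {
      keep <- c(keep, i)
    }
  }
  peaks <- peaks[keep, , drop = FALSE]

  sm <- gauss_blur3(vol, sigma_vox)
  half_vox <- pmax(ceiling(p$aperture_factor * sigma_vox) + 2L, 3L)
  voxvol <- prod(stack$voxel_size)
  rows <- vector("list", nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    pz <- peaks[k, 1]; py <- peaks[k, 2]; px <- peaks[k, 3]
    iz <- max(1L, pz - half_vox[1]):min(d3[1], pz + half_vox[1])
    iy <- max(1L, py - half_vox[2]):min(d3[2], py + half_vox[2])
    ix <- max(1L, px - half_vox[3]):min(d3[3], px + half_vox[3])
    raw_box <- vol[iz, iy, ix, drop = FALSE]
    sm_box <- sm[iz, iy, ix, drop = FALSE]
    dim(raw_box) <- c(length(iz), length(iy), length(ix))
    dim(sm_box) <- dim(raw_box)
    border <- array(TRUE, dim(raw_box))
    border[-c(1, dim(border)[1]), -c(1, dim(border)[2]),
           -c(1, dim(border)[3])] <- FALSE
    bg_raw <- median(raw_box[border])
    bg_sm <- median(sm_box[border])
    pk_pos <- c(match(pz, iz), match(py, iy), match(px, ix))
    peak_sm <- sm_box[pk_pos[1], pk_pos[2], pk_pos[3]]
    cutoff <- bg_sm + p$rel_cutoff * (peak_sm - bg_sm)
    region_mask <- sm_box >= cutoff
    lab <- label_components(region_mask)
    region <- lab == lab[pk_pos[1], pk_pos[2], pk_pos[3]]
    n_vox <- sum(region)
    ridx <- which(region, arr.ind = TRUE)
    rcen <- voxel_centers_um(iz[ridx[, 1]], iy[ridx[, 2]], ix[ridx[, 3]],
                             stack$voxel_size)
    w <- pmax(raw_box[region] - bg_raw, 0)
    centroid <- if (sum(w) > 0) colSums(rcen * w) / sum(w) else colMeans(rcen)
    if (p$measure == "aperture") {
      bidx <- which(array(TRUE, dim(raw_box)), arr.ind = TRUE)
      bcen <- voxel_centers_um(iz[bidx[, 1]], iy[bidx[, 2]], ix[bidx[, 3]],
                               stack$voxel_size)
      in_ap <- sqrt((bcen[, 1] - centroid[["x"]])^2 +
                    (bcen[, 2] - centroid[["y"]])^2 +
                    (bcen[, 3] - centroid[["z"]])^2) <=
        p$aperture_factor * p$sigma_um
      integ <- sum(raw_box[bidx[in_ap, , drop = FALSE]] - bg_raw)
      n_meas <- sum(in_ap)
    } else {
      integ <- sum(raw_box[region])
      n_meas <- n_vox
    }
    rows[[k]] <- data.frame(
      focus_id = NA_integer_, channel = ch_name,
      x_um = centroid[["x"]], y_um = centroid[["y"]], z_um = centroid[["z"]],
      n_voxels = n_vox, volume_um3 = n_vox * voxvol,
      integrated_density = integ,
      average_intensity = integ / max(n_meas, 1L),
      peak_intensity = vol[pz, py, px],
      nucleus_id = NA_integer_, compartment = NA_character_)
  }
  foci <- do.call(rbind, rows)
  foci$focus_id <- seq_len(nrow(foci))
  annotate_foci(foci, nuclei, config, restrict_to_nuclei)
}

# nucleus assignment, compartment, radial position and zone
annotate_foci <- function(foci, nuclei, config, restrict_to_nuclei) {
  if (is.null(nuclei)) return(foci)
  foci <- classify_compartment(foci, nuclei)
  if (restrict_to_nuclei && nrow(foci)) {
    foci <- foci[foci$compartment == "nuclear", , drop = FALSE]
    if (nrow(foci)) foci$focus_id <- seq_len(nrow(foci))
  }
  foci <- radial_position(foci, nuclei)
  conv <- config$zonation$convention
  foci$zone <- ifelse(is.na(foci$rho), NA_integer_,
                      assign_zone(pmin(pmax(foci$rho, 0), 1), conv))
  foci
}

#' Classify foci as nuclear or cytoplasmic
#'
#' A focus is nuclear iff the voxel containing its centroid belongs to any
#' nucleus mask (boundary voxels inclusive); otherwise cytoplasmic. Nuclear
#' foci receive the id of the containing nucleus.
#'
#' @param foci a [detect_foci()] table (needs `x_um, y_um, z_um`)
#' @param nuclei a [segment_nuclei()] result
#' @return `foci` with `nucleus_id` and `compartment` filled
#' @export
classify_compartment <- function(foci, nuclei) {
  if (!inherits(nuclei, "NucleusSet")) stop("nuclei must be a NucleusSet")
  if (nrow(foci) == 0L) return(foci)
  idx <- um_to_voxel(foci$x_um, foci$y_um, foci$z_um, nuclei$voxel_size,
                     dim(nuclei$labels))
  lab <- nuclei$labels[idx]
  foci$nucleus_id <- ifelse(lab > 0L, lab, NA_integer_)
  foci$compartment <- ifelse(lab > 0L, "nuclear", "cytoplasmic")
  foci
}

#' Radial position of nuclear foci in the spherical nucleus model
#'
#' For each focus assigned to a nucleus: `d_center` is the distance from the
#' focus centroid to the nucleus centroid, `d_edge = r - d_center` (negative
#' if the focus lies outside the fitted sphere, which can happen for
#' non-spherical nuclei), and `rho = d_center / r` clamped to `[0, 1]` with a
#' flag recording whether clamping occurred. Unassigned foci get `NA`s.
#'
#' @param foci a foci table with `nucleus_id` set for nuclear foci
#' @param nuclei a [segment_nuclei()] result (or its `table`)
#' @return `foci` with `d_center_um`, `d_edge_um`, `rho`, `rho_clamped`
#' @export
radial_position <- function(foci, nuclei) {
  ntab <- if (inherits(nuclei, "NucleusSet")) nuclei$table else nuclei
  if (any(ntab$r_um <= 0)) stop("nucleus radius must be positive")
  n <- nrow(foci)
  foci$d_center_um <- NA_real_
  foci$d_edge_um <- NA_real_
  foci$rho <- NA_real_
  foci$rho_clamped <- FALSE
  if (n == 0L) return(foci)
  m <- match(foci$nucleus_id, ntab$nucleus_id)
  has <- !is.na(m)
  if (any(has)) {
    dc <- sqrt((foci$x_um[has] - ntab$x_um[m[has]])^2 +
               (foci$y_um[has] - ntab$y_um[m[has]])^2 +
               (foci$z_um[has] - ntab$z_um[m[has]])^2)
    r <- ntab$r_um[m[has]]
    foci$d_center_um[has] <- dc
    foci$d_edge_um[has] <- r - dc
    foci$rho[has] <- pmin(dc / r, 1)
    foci$rho_clamped[has] <- dc / r > 1
  }
  foci
}

#' Assign the three-zone radial label
#'
#' Zones follow the equal-area concentric-zone convention: zone 1 (the
#' nuclear periphery) for `rho > sqrt(2/3)`, zone 2 for
#' `sqrt(1/3) < rho <= sqrt(2/3)`, zone 3 (the interior) for
#' `rho <= sqrt(1/3)`. The `"equal_volume"` convention uses boundaries
#' `(1/3)^(1/3)` and `(2/3)^(1/3)` instead.
#'
#' @param rho normalized radial position in `[0, 1]` (vectorized)
#' @param convention see [zone_bounds()]
#' @return integer vector of zones in `{1, 2, 3}`
#' @export
assign_zone <- function(rho, convention = "equal_area") {
  if (any(rho < 0 | rho > 1, na.rm = TRUE)) stop("rho must lie in [0, 1]")
  b <- zone_bounds(convention)
  ifelse(rho > b[2], 1L, ifelse(rho > b[1], 2L, 3L))
}

#' Per-zone percentages of nuclear foci
#'
#' @param foci a foci table with a `zone` column (non-nuclear foci, whose
#'   zone is `NA`, are excluded)
#' @return named numeric: percentage of foci in zones 1, 2, 3 (sums to 100)
#' @export
zone_fractions <- function(foci) {
  z <- foci$zone[!is.na(foci$zone)]
  if (length(z) == 0L) stop("no zoned foci")
  counts <- tabulate(z, nbins = 3L)
  setNames(100 * counts / sum(counts), paste0("zone", 1:3))
}

#' Per-group summaries of nuclei and foci
#'
#' A nucleus is focus-positive iff at least one nuclear focus of
#' `focus_channel` is assigned to it. The group key is any metadata column of
#' the nucleus table (e.g. a gonad zone label `z1`-`z7`, or a strain).
#'
#' @param nuclei_table nucleus data.frame with `nucleus_id` and the group
#'   column
#' @param foci a foci table with `nucleus_id` and `channel`
#' @param group name of the grouping column in `nuclei_table`
#' @param focus_channel channel counted for positivity (default: all)
#' @return data.frame: `group, n_nuclei, pct_positive, mean_foci_per_nucleus,
#'   sd_foci_per_nucleus, mean_volume_um3, mean_integrated_density`
#' @export
summarize_by_group <- function(nuclei_table, foci, group,
                               focus_channel = NULL) {
  if (!group %in% names(nuclei_table)) stop("unknown group key: ", group)
  f <- foci[!is.na(foci$nucleus_id), , drop = FALSE]
  if (!is.null(focus_channel)) f <- f[f$channel == focus_channel, , drop = FALSE]
  groups <- unique(nuclei_table[[group]])
  out <- lapply(groups, function(g) {
    nuc <- nuclei_table[nuclei_table[[group]] == g, , drop = FALSE]
    ff <- f[f$nucleus_id %in% nuc$nucleus_id, , drop = FALSE]
    per_nuc <- vapply(nuc$nucleus_id,
                      function(id) sum(ff$nucleus_id == id), numeric(1))
    data.frame(
      group = g,
      n_nuclei = nrow(nuc),
      pct_positive = 100 * mean(per_nuc >= 1),
      mean_foci_per_nucleus = mean(per_nuc),
      sd_foci_per_nucleus = if (length(per_nuc) > 1) sd(per_nuc) else NA_real_,
      mean_volume_um3 = if (nrow(ff)) mean(ff$volume_um3) else NA_real_,
      mean_integrated_density = if (nrow(ff)) mean(ff$integrated_density)
                                else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the full stack quantification
#'
#' Segments nuclei in the DNA channel, detects and measures foci in every
#' other channel, assigns compartments and zones, and builds a run summary.
#'
#' @param stack an [image_stack()]
#' @param dna_channel DNA-stain channel (default `"dna"`)
#' @param focus_channels channels to quantify (default: all others)
#' @param config a [run_config()]
#' @return list with `nuclei` (a `NucleusSet`), `foci` (combined table) and
#'   `summary` (named list)
#' @export
quantify_stack <- function(stack, dna_channel = "dna", focus_channels = NULL,
                           config = run_config()) {
  nuclei <- segment_nuclei(stack, dna_channel, config)
  if (is.null(focus_channels)) {
    focus_channels <- setdiff(stack$channel_names,
                              stack$channel_names[channel_index(stack, dna_channel)])
  }
  foci <- do.call(rbind, lapply(focus_channels, function(ch) {
    detect_foci(stack, ch, nuclei = nuclei, config = config)
  }))
  if (!is.null(foci) && nrow(foci)) foci$focus_id <- seq_len(nrow(foci))
  nuclear <- if (!is.null(foci)) sum(foci$compartment == "nuclear") else 0L
  summary <- list(
    n_nuclei = nrow(nuclei$table),
    n_foci = if (is.null(foci)) 0L else nrow(foci),
    n_nuclear_foci = nuclear,
    pct_nuclear = if (!is.null(foci) && nrow(foci))
      100 * nuclear / nrow(foci) else NA,
    zone_fractions = if (!is.null(foci) && any(!is.na(foci$zone)))
      as.list(zone_fractions(foci)) else NULL
  )
  list(nuclei = nuclei, foci = foci, summary = summary)
}
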