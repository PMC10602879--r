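# Object-based colocalization between two focus channels, with an empirical
# shuffle-null significance test: channel-A objects are re-placed uniformly
# at random inside their nucleus and the observed nearest-neighbour distance
# is compared against the resulting null distribution.

equal_volume_radius <- function(volume_um3) (3 * volume_um3 / (4 * pi))^(1 / 3)

#' Match focus objects between two channels
#'
#' Within each nucleus, channel-A foci are paired one-to-one with channel-B
#' foci by greedy nearest centre distance (ties broken by the smaller
#' `focus_b` id, then the smaller `focus_a` id). A pair is colocalized iff
#' its centre distance does not exceed the sum of the two equal-volume object
#' radii plus `tolerance_um` (touching or overlapping spheres).
#'
#' @param foci_a,foci_b measured foci tables (need `focus_id, nucleus_id,
#'   x_um, y_um, z_um, volume_um3`); foci without a nucleus are ignored
#' @param tolerance_um slack added to the distance criterion (default 0)
#' @return data.frame of class `ColocPairs`: `nucleus_id, focus_a, focus_b,
#'   center_distance_um, d_max_um, colocalized, p_shuffle, significant`
#'   (`focus_b` is `NA` and `colocalized` FALSE for A-foci with no B focus in
#'   their nucleus; `p_shuffle`/`significant` are filled by [shuffle_null()])
#' @export
match_objects <- function(foci_a, foci_b, tolerance_um = 0) {
  need <- c("focus_id", "nucleus_id", "x_um", "y_um", "z_um", "volume_um3")
  for (nm in need) {
    if (!nm %in% names(foci_a) || !nm %in% names(foci_b)) {
      stop("foci tables must carry measured column: ", nm)
    }
  }
  if (any(is.na(foci_a$volume_um3)) || any(is.na(foci_b$volume_um3))) {
    stop("unmeasured foci: missing volume")
  }
  a <- foci_a[!is.na(foci_a$nucleus_id), , drop = FALSE]
  b <- foci_b[!is.na(foci_b$nucleus_id), , drop = FALSE]
  out <- list()
  for (nuc in sort(unique(a$nucleus_id))) {
    ai <- a[a$nucleus_id == nuc, , drop = FALSE]
    bi <- b[b$nucleus_id == nuc, , drop = FALSE]
    if (nrow(bi) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        nucleus_id = nuc, focus_a = ai$focus_id, focus_b = NA_integer_,
        center_distance_um = NA_real_, d_max_um = NA_real_,
        colocalized = FALSE)
      next
    }
    dmat <- outer(seq_len(nrow(ai)), seq_len(nrow(bi)), function(i, j) {
      sqrt((ai$x_um[i] - bi$x_um[j])^2 + (ai$y_um[i] - bi$y_um[j])^2 +
           (ai$z_um[i] - bi$z_um[j])^2)
    })
    cand <- data.frame(
      i = rep(seq_len(nrow(ai)), nrow(bi)),
      j = rep(seq_len(nrow(bi)), each = nrow(ai)),
      d = as.vector(dmat))
    cand <- cand[order(cand$d, bi$focus_id[cand$j], ai$focus_id[cand$i]), ]
    used_a <- logical(nrow(ai)); used_b <- logical(nrow(bi))
    pairs <- list()
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      dmax <- equal_volume_radius(ai$volume_um3[i]) +
        equal_volume_radius(bi$volume_um3[j]) + tolerance_um
      pairs[[length(pairs) + 1L]] <- data.frame(
        nucleus_id = nuc, focus_a = ai$focus_id[i], focus_b = bi$focus_id[j],
        center_distance_um = cand$d[k], d_max_um = dmax,
        colocalized = cand$d[k] <= dmax)
      if (all(used_a) || all(used_b)) break
    }
    if (any(!used_a)) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        nucleus_id = nuc, focus_a = ai$focus_id[!used_a],
        focus_b = NA_integer_, center_distance_um = NA_real_,
        d_max_um = NA_real_, colocalized = FALSE)
    }
    out[[length(out) + 1L]] <- do.call(rbind, pairs)
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    nucleus_id = integer(), focus_a = integer(), focus_b = integer(),
    center_distance_um = numeric(), d_max_um = numeric(),
    colocalized = logical())
  res$p_shuffle <- NA_real_
  res$significant <- NA
  rownames(res) <- NULL
  class(res) <- c("ColocPairs", "data.frame")
  res
}

# uniform positions inside a nucleus: from the mask voxels when a label
# array is available (uniform jitter within the voxel), otherwise uniform in
# the fitted sphere
sample_in_nucleus <- function(n, nucleus_row, nuclei = NULL) {
  if (!is.null(nuclei) && inherits(nuclei, "NucleusSet") &&
      !is.null(nuclei$labels)) {
    idx <- which(nuclei$labels == nucleus_row$nucleus_id, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("nucleus mask missing for nucleus ",
                              nucleus_row$nucleus_id)
    pick <- idx[sample.int(nrow(idx), n, replace = TRUE), , drop = FALSE]
    vs <- nuclei$voxel_size
    cbind(
      x = (pick[, 3] - 1 + runif(n)) * vs[3],
      y = (pick[, 2] - 1 + runif(n)) * vs[2],
      z = (pick[, 1] - 1 + runif(n)) * vs[1])
  } else {
    rho <- runif(n)^(1 / 3) * nucleus_row$r_um
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    cbind(x = nucleus_row$x_um + u[, 1] * rho,
          y = nucleus_row$y_um + u[, 2] * rho,
          z = nucleus_row$z_um + u[, 3] * rho)
  }
}

#' Shuffle-null significance of colocalization events
#'
#' For each of `n_shuffles` rounds, every channel-A focus is re-placed
#' uniformly at random inside its nucleus (object sizes and channel-B
#' positions are kept fixed) and its nearest-B centre distance recorded. The
#' per-focus p-value uses the add-one estimator
#' `p = (1 + #\{shuffles with nearest-B distance <= observed\}) /
#' (n_shuffles + 1)`, so `p >= 1/(n_shuffles + 1)` and `p = 0` is impossible.
#' A pair is significant iff it is colocalized and `p <= alpha`.
#'
#' @param pairs result of [match_objects()]
#' @param foci_a channel-A foci table
#' @param foci_b channel-B foci table
#' @param nuclei a [segment_nuclei()] result (mask-based placement) or a
#'   nucleus truth table with `nucleus_id, x_um, y_um, z_um, r_um` (spherical
#'   placement)
#' @param n_shuffles number of shuffles (>= 19 for alpha = 0.05; default 100)
#' @param alpha significance level (default 0.05)
#' @param seed RNG seed
#' @return `pairs` with `p_shuffle` and `significant` filled
#' @export
shuffle_null <- function(pairs, foci_a, foci_b, nuclei, n_shuffles = 100L,
                         alpha = 0.05, seed = 1L) {
  if (n_shuffles < 19L) stop("n_shuffles must be at least 19")
  ntab <- if (inherits(nuclei, "NucleusSet")) nuclei$table else nuclei
  a <- foci_a[!is.na(foci_a$nucleus_id), , drop = FALSE]
  b <- foci_b[!is.na(foci_b$nucleus_id), , drop = FALSE]
  p_obs <- setNames(rep(NA_real_, nrow(pairs)), NULL)
  with_seed(seed, {
    for (nuc in sort(unique(a$nucleus_id))) {
      ai <- a[a$nucleus_id == nuc, , drop = FALSE]
      bi <- b[b$nucleus_id == nuc, , drop = FALSE]
      nrow_a <- nrow(ai)
      nuc_row <- ntab[ntab$nucleus_id == nuc, , drop = FALSE]
      if (nrow(nuc_row) == 0L) stop("nucleus ", nuc, " missing from nuclei")
      nearest_b <- function(px, py, pz) {
        if (nrow(bi) == 0L) return(rep(Inf, length(px)))
        vapply(seq_along(px), function(i) {
          min(sqrt((bi$x_um - px[i])^2 + (bi$y_um - py[i])^2 +
                   (bi$z_um - pz[i])^2))
        }, numeric(1))
      }
      d_obs <- nearest_b(ai$x_um, ai$y_um, ai$z_um)
      hits <- numeric(nrow_a)
      for (s in seq_len(n_shuffles)) {
        pos <- sample_in_nucleus(nrow_a, nuc_row, nuclei)
        d_s <- nearest_b(pos[, "x"], pos[, "y"], pos[, "z"])
        hits <- hits + (d_s <= d_obs)
      }
      p_nuc <- (1 + hits) / (n_shuffles + 1)
      rows <- which(pairs$nucleus_id == nuc)
      m <- match(pairs$focus_a[rows], ai$focus_id)
      p_obs[rows] <- p_nuc[m]
    }
  })
  pairs$p_shuffle <- p_obs
  pairs$significant <- !is.na(pairs$colocalized) & pairs$colocalized &
    !is.na(p_obs) & p_obs <= alpha
  pairs
}

#' Classify foci as telomeric or extratelomeric
#'
#' A focus is telomeric iff its colocalization with the telomere-marker
#' channel is significant under the shuffle null.
#'
#' @param foci_a the RNA-focus table used as channel A in [match_objects()]
#' @param pairs a [shuffle_null()] result
#' @return list with `labels` (data.frame `focus_id, label`) and `summary`
#'   (named percentages `telomeric`, `extratelomeric` over all A foci)
#' @export
classify_telomeric <- function(foci_a, pairs) {
  sig <- pairs$focus_a[!is.na(pairs$significant) & pairs$significant]
  lab <- ifelse(foci_a$focus_id %in% sig, "telomeric", "extratelomeric")
  n <- nrow(foci_a)
  list(
    labels = data.frame(focus_id = foci_a$focus_id, label = lab,
                        stringsAsFactors = FALSE),
    summary = c(telomeric = if (n) 100 * mean(lab == "telomeric") else NA,
                extratelomeric = if (n) 100 * mean(lab == "extratelomeric")
                                 else NA))
}

#' Rank correlation between paired focus measurements
#'
#' Spearman rank correlation between a channel-A metric and a channel-B
#' metric over the significant colocalized pairs. No p-value is reported;
#' with a zero-variance metric the coefficient is undefined and flagged.
#'
#' @param pairs a [shuffle_null()] result
#' @param foci_a,foci_b the foci tables
#' @param metric_a,metric_b column names among `volume_um3`,
#'   `integrated_density`, `average_intensity`
#' @return list `estimate` (Spearman rho or NA), `n` (pair count),
#'   `undefined` (TRUE when a metric has zero variance)
#' @export
signal_correlation <- function(pairs, foci_a, foci_b,
                               metric_a = "integrated_density",
                               metric_b = "integrated_density") {
  ok <- !is.na(pairs$significant) & pairs$significant
  sig <- pairs[ok, , drop = FALSE]
  if (nrow(sig) < 3L) stop("fewer than 3 significant pairs")
  va <- foci_a[[metric_a]][match(sig$focus_a, foci_a$focus_id)]
  vb <- foci_b[[metric_b]][match(sig$focus_b, foci_b$focus_id)]
  if (var(va) == 0 || var(vb) == 0) {
    return(list(estimate = NA_real_, n = nrow(sig), undefined = TRUE))
  }
  list(estimate = cor(va, vb, method = "spearman"), n = nrow(sig),
       undefined = FALSE)
}
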