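# qPCR delta-Ct relative quantification and primer-efficiency standard
# curves.
#
# Two conventions from the published workflow are kept verbatim where they
# are unambiguous, and normalized where the printed text cannot be computed
# as written:
# * the delta-Ct error is described as "the square root of the quadratic sum
#   of the respective CT means"; summing squared means is dimensionally not
#   an error, so the replicate standard deviations are used:
#   e = sqrt(sd_target^2 + sd_housekeeping^2);
# * the relative-expression error i = e * 2^-dCt / dCt is implemented
#   verbatim ("paper" mode, singular at dCt = 0) next to the first-order
#   propagation i = ln(2) * e * 2^-dCt ("corrected" mode, the default);
# * the printed efficiency expression "(10 - (1/slope) - 1) x 100" is read
#   as the standard E% = (10^(-1/slope) - 1) x 100.

#' Primer efficiency from a dilution-series standard curve
#'
#' Fits `Ct ~ log10(dilution)` by least squares and converts the slope to a
#' percent efficiency `E = (10^(-1/slope) - 1) * 100`; a slope of
#' `-1/log10(2) = -3.3219` is perfect doubling (100%).
#'
#' @param log10_dilution numeric vector (>= 3 points)
#' @param ct threshold-cycle values, same length
#' @return list `slope`, `intercept`, `r_squared`, `e_percent`
#' @export
primer_efficiency <- function(log10_dilution, ct) {
  if (length(log10_dilution) < 3L || length(ct) != length(log10_dilution)) {
    stop("need at least 3 (dilution, Ct) points of equal length")
  }
  fit <- lm(ct ~ log10_dilution)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope == 0) stop("zero or undefined slope")
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  list(slope = slope, intercept = unname(coef(fit)[1]), r_squared = r2,
       e_percent = (10^(-1 / slope) - 1) * 100)
}

#' Delta-Ct between target and housekeeping replicates
#'
#' `dCt = mean(target Ct) - mean(housekeeping Ct)`, with error
#' `e = sqrt(sd_target^2 + sd_hk^2)` from the replicate standard deviations.
#' With several housekeeping genes (given as a list of replicate vectors),
#' the mean of the per-gene Ct means is used and the housekeeping variance
#' term is `sum(sd_g^2) / G^2`, the variance of that average.
#'
#' @param target_ct numeric vector of target replicate Cts (>= 2)
#' @param housekeeping_ct numeric vector, or list of numeric vectors (one per
#'   housekeeping gene), each with >= 2 replicates
#' @return list `delta_ct`, `e`
#' @export
delta_ct <- function(target_ct, housekeeping_ct) {
  if (!is.list(housekeeping_ct)) housekeeping_ct <- list(housekeeping_ct)
  if (length(target_ct) < 2L ||
      any(vapply(housekeeping_ct, length, integer(1)) < 2L)) {
    stop("need at least 2 replicates per primer")
  }
  hk_means <- vapply(housekeeping_ct, mean, numeric(1))
  hk_vars <- vapply(housekeeping_ct, var, numeric(1))
  g <- length(housekeeping_ct)
  list(delta_ct = mean(target_ct) - mean(hk_means),
       e = sqrt(var(target_ct) + sum(hk_vars) / g^2))
}

#' Relative expression 2^-dCt with propagated error
#'
#' `rel_expr = 2^-dCt`. The error is `i = ln(2) * e * rel_expr` in
#' `"corrected"` mode (first-order propagation; default) or the verbatim
#' published `i = e * rel_expr / dCt` in `"paper"` mode, which is singular at
#' `dCt = 0` and raises an error there.
#'
#' @param delta_ct delta-Ct value(s)
#' @param e delta-Ct error(s)
#' @param error_mode `"corrected"` or `"paper"`
#' @return data.frame `rel_expr`, `i`, `error_mode`
#' @export
rel_expression <- function(delta_ct, e, error_mode = c("corrected", "paper")) {
  error_mode <- match.arg(error_mode)
  rel <- 2^(-delta_ct)
  i <- if (error_mode == "paper") {
    if (any(delta_ct == 0)) {
      stop("undefined error (printed formula singular at delta_ct = 0); ",
           "use error_mode = \"corrected\"")
    }
    e * rel / delta_ct
  } else {
    log(2) * e * rel
  }
  data.frame(rel_expr = rel, i = i, error_mode = error_mode,
             stringsAsFactors = FALSE)
}

#' Fold change of relative expression over a reference sample
#'
#' `fold = rel_expr(sample) / rel_expr(reference)` per primer; the reference
#' fold is exactly 1.
#'
#' @param results data.frame with columns `sample, primer, rel_expr`
#' @param reference reference sample name
#' @return `results` with a `fold_change` column
#' @export
fold_change <- function(results, reference) {
  if (!reference %in% results$sample) stop("missing reference: ", reference)
  ref <- results[results$sample == reference, c("primer", "rel_expr")]
  m <- match(results$primer, ref$primer)
  if (any(is.na(m))) stop("reference sample lacks primer(s): ",
                          paste(unique(results$primer[is.na(m)]), collapse = ", "))
  if (any(ref$rel_expr[m] <= 0)) stop("zero reference expression")
  results$fold_change <- results$rel_expr / ref$rel_expr[m]
  results
}

#' Full delta-Ct analysis of a Ct replicate table
#'
#' Computes, per sample and target primer, the delta-Ct against the
#' housekeeping primer(s), its error, the relative expression `2^-dCt` with
#' its propagated error, and the fold change over a reference sample.
#'
#' @param ct_table data.frame with columns `sample, primer, role, replicate,
#'   ct` (role `"target"` or `"housekeeping"`), e.g. from
#'   [simulate_ct_table()]
#' @param reference reference sample for fold changes (optional)
#' @param error_mode `"corrected"` (default) or `"paper"`, see
#'   [rel_expression()]
#' @return data.frame: `sample, primer, delta_ct, e, rel_expr, i,
#'   error_mode` and, with a reference, `fold_change`
#' @export
qpcr_analysis <- function(ct_table, reference = NULL,
                          error_mode = c("corrected", "paper")) {
  error_mode <- match.arg(error_mode)
  need <- c("sample", "primer", "role", "ct")
  if (!all(need %in% names(ct_table))) {
    stop("ct_table needs columns ", paste(need, collapse = ", "))
  }
  rows <- list()
  for (smp in unique(ct_table$sample)) {
    sub <- ct_table[ct_table$sample == smp, , drop = FALSE]
    hk <- sub[sub$role == "housekeeping", , drop = FALSE]
    if (nrow(hk) == 0L) stop("no housekeeping rows for sample ", smp)
    hk_list <- lapply(split(hk$ct, hk$primer), as.numeric)
    for (prm in unique(sub$primer[sub$role == "target"])) {
      tct <- sub$ct[sub$primer == prm & sub$role == "target"]
      dc <- delta_ct(tct, hk_list)
      re <- rel_expression(dc$delta_ct, dc$e, error_mode)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, primer = prm, delta_ct = dc$delta_ct, e = dc$e,
        rel_expr = re$rel_expr, i = re$i, error_mode = error_mode,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(reference)) out <- fold_change(out, reference)
  out
}
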