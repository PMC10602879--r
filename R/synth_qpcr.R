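#' Simulate a qPCR Ct replicate table with known relative expression
#'
#' Generates threshold-cycle values from the exponential-amplification model
#' `Ct = baseline - log(expression) / log(1 + E) + noise`, where `expression`
#' is the target abundance relative to the housekeeping gene (whose
#' expression is 1 by construction) and `E` is the per-cycle primer
#' efficiency as a fraction (1 = 100%, perfect doubling). With zero noise and
#' `E = 1`, the downstream delta-Ct analysis recovers the true expression
#' ratios exactly.
#'
#' @param expression named list: one element per sample, each a named numeric
#'   vector of target-primer expressions relative to housekeeping, e.g.
#'   `list(WT = c(tel1R = 1), mut = c(tel1R = 4))`
#' @param efficiency primer efficiency as a fraction; a scalar applied to all
#'   primers or a named vector per primer (default 1)
#' @param housekeeping name of the housekeeping primer (default `"hk"`)
#' @param n_replicates technical replicates per sample x primer (>= 2;
#'   duplicates and triplicates are the common designs)
#' @param noise_sd Gaussian Ct replicate noise, cycles (default 0.2)
#' @param baseline_ct housekeeping mean Ct (default 15)
#' @param seed optional RNG seed
#' @return data.frame of class `CtTable` with columns `sample, primer, role,
#'   replicate, ct`
#' @export
simulate_ct_table <- function(expression,
                              efficiency = 1,
                              housekeeping = "hk",
                              n_replicates = 3L,
                              noise_sd = 0.2,
                              baseline_ct = 15,
                              seed = NULL) {
  stopifnot(is.list(expression), length(expression) > 0, n_replicates >= 2)
  eff_of <- function(primer) {
    e <- if (length(efficiency) == 1L && is.null(names(efficiency)))
      efficiency else efficiency[[primer]]
    if (is.null(e) || is.na(e) || e <= 0) stop("invalid efficiency for ", primer)
    e
  }
  with_seed(seed, {
    rows <- list()
    for (smp in names(expression)) {
      ex <- expression[[smp]]
      if (any(ex <= 0)) stop("expression values must be positive")
      primers <- c(names(ex), housekeeping)
      roles <- c(rep("target", length(ex)), "housekeeping")
      levels <- c(ex, 1)
      for (j in seq_along(primers)) {
        mu <- unname(baseline_ct - log(levels[j]) / log(1 + eff_of(primers[j])))
        ct <- rep(mu, n_replicates) +
          if (noise_sd > 0) rnorm(n_replicates, sd = noise_sd) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          sample = smp, primer = primers[j], role = roles[j],
          replicate = seq_len(n_replicates), ct = ct,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("CtTable", "data.frame")
    out
  })
}
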