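#' Pairwise genotype r-squared within a breed
#'
#' Squared Pearson correlation of genotype dosages over jointly-called
#' samples, for intra-chromosomal SNP pairs separated by at most
#' `max_dist_mb`. Pairs where either SNP has zero variance among the jointly
#' called samples are skipped.
#'
#' @param gm A [genotypes] object.
#' @param breed Breed code; a warning is issued below 10 samples.
#' @param max_dist_mb Maximum pair distance in Mb (default 10).
#' @return A tibble: `chrom`, `bp_i`, `bp_j`, `dist_bp`, `r2`.
#' @export
pairwise_r2 <- function(gm, breed, max_dist_mb = 10) {
  ids <- gm$samples$sample_id[gm$samples$breed == breed]
  if (!length(ids)) stop("breed not in cohort: ", breed, call. = FALSE)
  if (length(ids) < 10) {
    warning("breed ", breed, " has only ", length(ids),
            " samples; r2 estimates will be noisy", call. = FALSE)
  }
  calls <- subset_calls(gm, ids)
  max_bp <- max_dist_mb * 1e6
  out <- list()
  for (cc in unique(gm$snps$chrom)) {
    on_c <- which(gm$snps$chrom == cc)
    bp <- gm$snps$bp[on_c]
    m <- length(on_c)
    if (m < 2) next
    for (i in seq_len(m - 1)) {
      js <- which(bp > bp[i] & bp - bp[i] <= max_bp)
      js <- js[js > i]
      if (!length(js)) next
      r <- suppressWarnings(
        stats::cor(calls[, on_c[i]], calls[, on_c[js], drop = FALSE],
                   use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      keep <- !is.na(r2)
      if (any(keep)) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = as.character(cc), bp_i = bp[i], bp_j = bp[js[keep]],
          dist_bp = bp[js[keep]] - bp[i], r2 = r2[keep])
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), bp_i = integer(),
                          bp_j = integer(), dist_bp = integer(),
                          r2 = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Recombination-distance bins for a target list of generations
#'
#' The Sved relation ties the generation looked back to the recombination
#' distance via t = 1/(2c), so each requested generation t maps to a bin
#' centered at c = 1/(2t) Morgan with a +/-10% multiplicative window.
#'
#' @param generations Positive generation values (e.g. `c(13, 50, 983)`).
#' @return A tibble: `generations_ago`, `c_mid`, `c_lo`, `c_hi` (Morgan).
#' @export
ne_bins_from_generations <- function(generations) {
  stopifnot(all(generations > 0))
  c_mid <- 1 / (2 * generations)
  tibble::tibble(generations_ago = generations, c_mid = c_mid,
                 c_lo = 0.9 * c_mid, c_hi = 1.1 * c_mid)
}

#' Effective population size trend from binned LD
#'
#' Implements the Sved relation E\[r2\] = 1/(alpha + 4 Ne c) + 1/(2n):
#' within each recombination-distance bin the sample-size-corrected LD is
#' r2_adj = mean(r2) - 1/(2 n_samples) and
#' Ne = (1/(4 c_mid)) (1/r2_adj - alpha), reported at t = 1/(2 c_mid)
#' generations ago. Bins with no pairs or with r2_adj <= 0 yield `NA` and
#' are flagged.
#'
#' @param pairs Tibble from [pairwise_r2()] (columns `dist_bp`, `r2`).
#' @param bins Tibble from [ne_bins_from_generations()] (columns `c_mid`,
#'   `c_lo`, `c_hi`).
#' @param n_samples Number of animals behind the r2 values.
#' @param alpha Mutation adjustment in the Sved relation; 1 by default
#'   (2 and 2.2 are common alternatives).
#' @param cm_per_mb Map scaling, centimorgan per megabase (default 1).
#' @return A tibble of class `ne_trend`: `generations_ago`, `c_morgans`,
#'   `n_pairs`, `mean_r2`, `r2_adj`, `ne`, `flagged`.
#' @export
ne_trend <- function(pairs, bins, n_samples, alpha = 1, cm_per_mb = 1) {
  stopifnot(nrow(bins) >= 1, n_samples >= 1)
  if (any(bins$c_lo <= 0)) {
    stop("bin bounds must be positive", call. = FALSE)
  }
  c_pair <- pairs$dist_bp / 1e6 * cm_per_mb / 100
  rows <- lapply(seq_len(nrow(bins)), function(k) {
    inb <- c_pair >= bins$c_lo[k] & c_pair <= bins$c_hi[k]
    mean_r2 <- if (any(inb)) mean(pairs$r2[inb]) else NA_real_
    r2_adj <- mean_r2 - 1 / (2 * n_samples)
    ne <- if (!is.na(r2_adj) && r2_adj > 0) {
      (1 / (4 * bins$c_mid[k])) * (1 / r2_adj - alpha)
    } else NA_real_
    tibble::tibble(
      generations_ago = 1 / (2 * bins$c_mid[k]),
      c_morgans = bins$c_mid[k], n_pairs = sum(inb),
      mean_r2 = mean_r2, r2_adj = r2_adj, ne = ne,
      flagged = is.na(ne))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ne_trend", class(out))
  out
}
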