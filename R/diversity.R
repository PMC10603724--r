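#' Per-breed heterozygosity and Wright's FIS
#'
#' For every SNP within a breed: expected heterozygosity He = 2p(1-p) from
#' the breed allele frequency, observed heterozygosity Ho = fraction of
#' heterozygotes among non-missing genotypes. Breed-level He and Ho are the
#' means over SNPs with at least one callable genotype, and
#' FIS = (He - Ho)/He (0 by convention when He = 0); positive FIS marks a
#' heterozygote deficit. An optional small-sample correction multiplies
#' per-SNP He by 2n/(2n-1).
#'
#' @param gm A [genotypes] object.
#' @param breeds Breed codes to summarize; default all breeds present.
#' @param unbiased Apply the 2n/(2n-1) small-sample correction to He
#'   (default `FALSE`).
#' @return A tibble with one row per breed: `breed`, `n`, `he`, `ho`, `fis`.
#' @export
breed_diversity <- function(gm, breeds = NULL, unbiased = FALSE) {
  if (is.null(breeds)) breeds <- sort(unique(gm$samples$breed))
  absent <- setdiff(breeds, gm$samples$breed)
  if (length(absent)) {
    stop("breed(s) not in cohort: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(breeds, function(b) {
    ids <- gm$samples$sample_id[gm$samples$breed == b]
    if (length(ids) < 2) {
      stop("breed ", b, " has fewer than 2 samples", call. = FALSE)
    }
    calls <- subset_calls(gm, ids)
    n_called <- colSums(!is.na(calls))
    ok <- n_called > 0
    p <- colSums(calls[, ok, drop = FALSE], na.rm = TRUE) /
      (2 * n_called[ok])
    he_l <- 2 * p * (1 - p)
    if (unbiased) he_l <- he_l * (2 * n_called[ok]) / (2 * n_called[ok] - 1)
    ho_l <- colMeans(calls[, ok, drop = FALSE] == 1, na.rm = TRUE)
    he <- mean(he_l)
    ho <- mean(ho_l)
    fis <- if (he == 0) 0 else (he - ho) / he
    tibble::tibble(breed = b, n = length(ids), he = he, ho = ho, fis = fis)
  })
  dplyr::bind_rows(rows)
}
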