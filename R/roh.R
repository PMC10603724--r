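#' Parameters for sliding-window ROH detection
#'
#' The default values are the standard set used for medium-density goat
#' chip data: windows of 20 SNPs stepped by 5, no heterozygotes and at most
#' 2 missing calls per qualifying window, a SNP is a run candidate when at
#' least 99% of its covering windows qualify, and accepted runs need at
#' least 10 SNPs, 1000 kb, a mean density of at most 500 kb per SNP and no
#' internal gap above 500 kb.
#'
#' @param roh_quartile Minimum fraction of covering windows that must
#'   qualify for a SNP to be a run candidate.
#' @param min_nsnp Minimum SNPs per accepted segment.
#' @param max_nsnp Accepted for completeness; the window-scoring semantics
#'   used here place no upper bound on run size, so it is inert.
#' @param windef Window size in SNPs.
#' @param interval Window step in SNPs (must be <= `windef`).
#' @param het_allowed Maximum heterozygous calls in a qualifying window.
#' @param min_kb_length Minimum segment length in kb.
#' @param density_kb_per_snp Maximum mean kb per SNP within a segment.
#' @param max_internal_gap_kb Maximum adjacent-SNP gap inside a segment, kb;
#'   runs are split at larger gaps before the acceptance tests.
#' @param max_miss Maximum missing calls in a qualifying window.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(roh_quartile = 0.99, min_nsnp = 10, max_nsnp = 30,
                       windef = 20, interval = 5, het_allowed = 0,
                       min_kb_length = 1000, density_kb_per_snp = 500,
                       max_internal_gap_kb = 500, max_miss = 2) {
  stopifnot(interval <= windef, interval >= 1, min_nsnp >= 1,
            min_kb_length > 0, density_kb_per_snp > 0,
            max_internal_gap_kb > 0,
            roh_quartile >= 0, roh_quartile <= 1)
  structure(list(roh_quartile = roh_quartile, min_nsnp = min_nsnp,
                 max_nsnp = max_nsnp, windef = windef, interval = interval,
                 het_allowed = het_allowed, min_kb_length = min_kb_length,
                 density_kb_per_snp = density_kb_per_snp,
                 max_internal_gap_kb = max_internal_gap_kb,
                 max_miss = max_miss),
            class = "roh_params")
}

#' Detect runs of homozygosity by sliding windows
#'
#' Per individual and chromosome: (1) windows of `windef` consecutive SNPs
#' are stepped by `interval` (a single whole-chromosome window when the
#' chromosome has fewer than `windef` SNPs); a window qualifies when its
#' heterozygote count is at most `het_allowed` and its missing count at most
#' `max_miss`. (2) A SNP is a run candidate when the fraction of covering
#' windows that qualify is at least `roh_quartile` (SNPs covered by no
#' window are never candidates). (3) Maximal runs of consecutive candidate
#' SNPs, split wherever an adjacent-SNP gap exceeds `max_internal_gap_kb`,
#' become segments bounded by their first and last SNP. (4) A segment is
#' accepted when it has at least `min_nsnp` SNPs, spans at least
#' `min_kb_length` kb and averages at most `density_kb_per_snp` kb per SNP.
#'
#' @param gm A [genotypes] object (SNPs sorted by chromosome and position).
#' @param params A [roh_params()] list.
#' @return A tibble of accepted segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_kb` (1-based inclusive coordinates;
#'   `length_kb` = (end - start + 1)/1000).
#' @export
detect_roh <- function(gm, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  chroms <- unique(gm$snps$chrom)
  out <- list()
  for (cc in chroms) {
    on_c <- which(gm$snps$chrom == cc)
    bp <- gm$snps$bp[on_c]
    if (is.unsorted(bp, strictly = TRUE)) {
      stop("SNP map not sorted on chromosome ", cc, call. = FALSE)
    }
    for (i in seq_len(nrow(gm$calls))) {
      g <- gm$calls[i, on_c]
      cand <- candidate_snps(g, params)
      segs <- candidate_runs_to_segments(cand, bp, params)
      if (nrow(segs)) {
        segs$sample_id <- gm$samples$sample_id[i]
        segs$chrom <- as.character(cc)
        out[[length(out) + 1]] <- segs
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start_bp = integer(), end_bp = integer(),
                          n_snps = integer(), length_kb = numeric()))
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$sample_id, chrom_key(res$chrom), res$start_bp), ]
  tibble::as_tibble(res[, c("sample_id", "chrom", "start_bp", "end_bp",
                            "n_snps", "length_kb")])
}

# window scoring for one individual on one chromosome -> logical candidates
candidate_snps <- function(g, params) {
  m <- length(g)
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  if (m < params$windef) {
    qual <- sum(het) <= params$het_allowed && sum(mis) <= params$max_miss
    return(rep(qual, m))
  }
  starts <- seq(1L, m - params$windef + 1L, by = params$interval)
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  ends <- starts + params$windef - 1L
  qual <- (ch[ends + 1L] - ch[starts]) <= params$het_allowed &
    (cm[ends + 1L] - cm[starts]) <= params$max_miss
  cover <- numeric(m + 1L)
  qcov <- numeric(m + 1L)
  cover[starts] <- cover[starts] + 1
  cover[ends + 1L] <- cover[ends + 1L] - 1
  qs <- starts[qual]
  if (length(qs)) {
    qe <- qs + params$windef - 1L
    for (k in seq_along(qs)) {
      qcov[qs[k]] <- qcov[qs[k]] + 1
      qcov[qe[k] + 1L] <- qcov[qe[k] + 1L] - 1
    }
  }
  cover <- cumsum(cover[seq_len(m)])
  qcov <- cumsum(qcov[seq_len(m)])
  cover > 0 & qcov >= params$roh_quartile * cover - 1e-9
}

# maximal candidate runs -> gap-split, predicate-tested segments
candidate_runs_to_segments <- function(cand, bp, params) {
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  segs <- list()
  for (k in keep) {
    idx <- starts[k]:ends[k]
    pieces <- split_at_gaps(idx, bp, params$max_internal_gap_kb * 1000)
    for (p in pieces) {
      n <- length(p)
      len_kb <- (bp[p[n]] - bp[p[1]] + 1) / 1000
      if (n >= params$min_nsnp && len_kb >= params$min_kb_length &&
          len_kb / n <= params$density_kb_per_snp) {
        segs[[length(segs) + 1]] <- data.frame(
          start_bp = bp[p[1]], end_bp = bp[p[n]],
          n_snps = n, length_kb = len_kb)
      }
    }
  }
  if (!length(segs)) {
    return(data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_kb = numeric()))
  }
  do.call(rbind, segs)
}

split_at_gaps <- function(idx, bp, max_gap_bp) {
  if (length(idx) == 1) return(list(idx))
  gaps <- diff(bp[idx])
  cuts <- which(gaps > max_gap_bp)
  if (!length(cuts)) return(list(idx))
  bounds <- c(0L, cuts, length(idx))
  lapply(seq_len(length(bounds) - 1L),
         function(i) idx[(bounds[i] + 1L):bounds[i + 1L]])
}

#' ROH-based inbreeding coefficient by length class
#'
#' F_ROH for an individual is the summed length of its accepted ROH divided
#' by the SNP-covered autosome length (sum over chromosomes of last SNP bp
#' minus first SNP bp plus 1). The total is also partitioned into the five
#' conventional length classes 1-2, 2-4, 4-8, 8-16 and >16 Mb (the lowest
#' class absorbs any shorter segment produced by non-default detection
#' thresholds), which sum exactly to the total.
#'
#' @param segments Segment tibble from [detect_roh()] on the same cohort.
#' @param gm The [genotypes] object the segments were detected on.
#' @return A tibble with one row per sample: `sample_id`, `breed`,
#'   `n_segments`, `froh_1_2`, `froh_2_4`, `froh_4_8`, `froh_8_16`,
#'   `froh_gt16`, `froh_total` and `covered_autosome_bp`.
#' @export
compute_froh <- function(segments, gm) {
  unknown <- setdiff(segments$chrom, as.character(gm$snps$chrom))
  if (length(unknown)) {
    stop("segment references unknown chromosome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  covered <- sum(vapply(split(gm$snps$bp, gm$snps$chrom),
                        function(b) diff(range(b)) + 1, numeric(1)))
  classes <- c("froh_1_2", "froh_2_4", "froh_4_8", "froh_8_16", "froh_gt16")
  base <- tibble::tibble(sample_id = gm$samples$sample_id,
                         breed = gm$samples$breed)
  acc <- matrix(0, nrow = nrow(base), ncol = length(classes),
                dimnames = list(base$sample_id, classes))
  n_seg <- stats::setNames(integer(nrow(base)), base$sample_id)
  if (nrow(segments)) {
    cls <- cut(segments$length_kb / 1000, c(0, 2, 4, 8, 16, Inf),
               labels = classes, right = FALSE)
    for (k in seq_len(nrow(segments))) {
      sid <- segments$sample_id[k]
      acc[sid, as.character(cls[k])] <-
        acc[sid, as.character(cls[k])] + segments$length_kb[k] * 1000
      n_seg[sid] <- n_seg[sid] + 1L
    }
  }
  froh <- acc / covered
  out <- base
  out$n_segments <- unname(n_seg)
  for (j in classes) out[[j]] <- unname(froh[, j])
  out$froh_total <- unname(rowSums(froh))
  out$covered_autosome_bp <- covered
  out
}

#' Per-SNP ROH incidence in a sample subset
#'
#' For each SNP, the fraction of the subset's individuals carrying at least
#' one accepted ROH segment whose interval covers the SNP position. This is
#' the per-group ingredient of the delta H-score ([delta_h()]).
#'
#' @param segments Segment tibble from [detect_roh()].
#' @param gm The [genotypes] object the segments were detected on.
#' @param sample_subset Character vector of sample ids (non-empty).
#' @return A tibble with one row per SNP: `id`, `chrom`, `bp`, `incidence`.
#' @export
roh_incidence <- function(segments, gm, sample_subset) {
  if (length(sample_subset) == 0) {
    stop("sample subset must be non-empty", call. = FALSE)
  }
  count <- numeric(nrow(gm$snps))
  segs <- segments[segments$sample_id %in% sample_subset, , drop = FALSE]
  for (id in unique(segs$sample_id)) {
    covered <- rep(FALSE, nrow(gm$snps))
    si <- segs[segs$sample_id == id, , drop = FALSE]
    for (k in seq_len(nrow(si))) {
      covered <- covered |
        (gm$snps$chrom == si$chrom[k] &
           gm$snps$bp >= si$start_bp[k] & gm$snps$bp <= si$end_bp[k])
    }
    count <- count + covered
  }
  tibble::tibble(id = gm$snps$id, chrom = gm$snps$chrom, bp = gm$snps$bp,
                 incidence = count / length(sample_subset))
}
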