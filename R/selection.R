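#' Per-SNP Wright's FST between two groups
#'
#' Two-population fixation index with unweighted group means: with group
#' allele frequencies p_a and p_b, pbar = (p_a + p_b)/2,
#' H_T = 2 pbar (1 - pbar), H_S = \[2 p_a (1 - p_a) + 2 p_b (1 - p_b)\]/2 and
#' FST = (H_T - H_S)/H_T, defined 0 when H_T = 0 and clamped to \[0, 1\].
#' SNPs where either group has fewer than two callable genotypes are `NA`.
#'
#' @param gm A [genotypes] object.
#' @param group_a,group_b Non-empty character vectors of sample ids.
#' @return A tibble: `id`, `chrom`, `bp`, `fst`.
#' @export
snp_fst <- function(gm, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  fa <- allele_freq(gm, group_a)
  fb <- allele_freq(gm, group_b)
  pa <- fa$freq; pb <- fb$freq
  ok <- fa$n_called >= 2 & fb$n_called >= 2
  pbar <- (pa + pb) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * pa * (1 - pa) + 2 * pb * (1 - pb)) / 2
  fst <- ifelse(ht == 0, 0, (ht - hs) / ht)
  fst <- pmin(1, pmax(0, fst))
  fst[!ok] <- NA_real_
  tibble::tibble(id = gm$snps$id, chrom = gm$snps$chrom, bp = gm$snps$bp,
                 fst = fst)
}

#' Delta H-score between two groups' ROH incidences
#'
#' The per-SNP absolute difference between the two groups in the proportion
#' of animals whose ROH cover the SNP.
#'
#' @param incidence_a,incidence_b Tibbles from [roh_incidence()] on the
#'   same SNP panel.
#' @return A tibble: `id`, `chrom`, `bp`, `delta_h`.
#' @export
delta_h <- function(incidence_a, incidence_b) {
  if (nrow(incidence_a) != nrow(incidence_b) ||
      !all(incidence_a$id == incidence_b$id)) {
    stop("incidence tables are not on the same SNP panel", call. = FALSE)
  }
  tibble::tibble(id = incidence_a$id, chrom = incidence_a$chrom,
                 bp = incidence_a$bp,
                 delta_h = abs(incidence_a$incidence -
                                 incidence_b$incidence))
}

#' Retain the top fraction of a per-SNP statistic
#'
#' Flags the floor(fraction x M) highest of the M SNPs with a defined
#' statistic value. Ordering is by value descending with a stable
#' positional tie-break on (chrom, bp), so the flagged set is invariant to
#' input order; the threshold is the smallest flagged value.
#'
#' @param values Tibble with columns `id`, `chrom`, `bp` and the statistic
#'   in `statistic` (or the column named by `statistic`).
#' @param fraction Retained fraction in (0, 1); 0.01 retains the top 1%.
#' @param statistic Name of the statistic column (default: the last
#'   non-coordinate column).
#' @return A tibble of class `scan_result` with `rank` and `selected`
#'   added; attributes `statistic_name`, `threshold_value`, `n_selected`.
#' @export
select_top <- function(values, fraction = 0.01, statistic = NULL) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  values <- tibble::as_tibble(values)
  if (is.null(statistic)) {
    statistic <- setdiff(names(values), c("id", "chrom", "bp"))[1]
  }
  v <- values[[statistic]]
  if (all(is.na(v))) stop("all statistic values are undefined", call. = FALSE)
  n_defined <- sum(!is.na(v))
  n_keep <- floor(fraction * n_defined)
  ord <- order(-v, chrom_key(values$chrom), values$bp, na.last = TRUE)
  out <- values[ord, ]
  out$rank <- seq_len(nrow(out))
  out$selected <- !is.na(out[[statistic]]) & out$rank <= n_keep
  threshold <- if (n_keep > 0) min(out[[statistic]][out$selected]) else NA_real_
  structure(out, class = c("scan_result", class(out)),
            statistic_name = statistic, threshold_value = threshold,
            n_selected = n_keep)
}

#' @importFrom generics tidy
#' @export
tidy.scan_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "scan_result")
  attr(out, "statistic_name") <- NULL
  attr(out, "threshold_value") <- NULL
  attr(out, "n_selected") <- NULL
  out
}

#' @importFrom generics glance
#' @export
glance.scan_result <- function(x, ...) {
  tibble::tibble(statistic = attr(x, "statistic_name"),
                 n_snps = nrow(x),
                 n_selected = attr(x, "n_selected"),
                 threshold = attr(x, "threshold_value"))
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open on disk; intervals are converted to 1-based
#' inclusive coordinates (`start_bp = start + 1`, `end_bp = end`).
#'
#' @param path Path to a BED file (chrom, start, end, name).
#' @return A tibble: `chrom`, `start_bp`, `end_bp`, `name`.
#' @export
read_bed_genes <- function(path) {
  bed <- utils::read.table(path, colClasses = c("character", "integer",
                                                "integer", "character"))
  tibble::tibble(chrom = bed[[1]], start_bp = bed[[2]] + 1L,
                 end_bp = bed[[3]], name = bed[[4]])
}

#' Map flagged SNPs onto gene intervals
#'
#' Every flagged SNP is paired with each gene whose (optionally flanked)
#' interval contains its position; flagged SNPs overlapping no gene are
#' reported with `gene = NA`.
#'
#' @param scan A `scan_result` from [select_top()].
#' @param genes Tibble of 1-based inclusive intervals (`chrom`, `start_bp`,
#'   `end_bp`, `name`), e.g. from [read_bed_genes()].
#' @param flank_bp Symmetric flank added to every gene interval.
#' @return A tibble: `id`, `chrom`, `bp`, `gene`.
#' @export
map_to_genes <- function(scan, genes, flank_bp = 0) {
  genes <- tibble::as_tibble(genes)
  if (!nrow(genes)) stop("gene annotation is empty", call. = FALSE)
  hits <- scan[scan$selected, c("id", "chrom", "bp")]
  if (!nrow(hits)) {
    return(tibble::tibble(id = character(), chrom = character(),
                          bp = integer(), gene = character()))
  }
  snp_gr <- GenomicRanges::GRanges(
    hits$chrom, IRanges::IRanges(hits$bp, hits$bp))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$start_bp - flank_bp),
                     genes$end_bp + flank_bp))
  ov <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  mapped <- tibble::tibble(
    id = hits$id[S4Vectors::queryHits(ov)],
    chrom = hits$chrom[S4Vectors::queryHits(ov)],
    bp = hits$bp[S4Vectors::queryHits(ov)],
    gene = genes$name[S4Vectors::subjectHits(ov)])
  unmapped <- hits[!hits$id %in% mapped$id, ]
  if (nrow(unmapped)) {
    mapped <- dplyr::bind_rows(
      mapped, tibble::tibble(id = unmapped$id, chrom = unmapped$chrom,
                             bp = unmapped$bp, gene = NA_character_))
  }
  dplyr::arrange(mapped, chrom_key(chrom), bp)
}

#' Genes found by both selection scans
#'
#' Intersection of the gene names hit by the flagged SNPs of two scans
#' (e.g. the FST scan and the delta H-score scan), the standard consensus
#' criterion for candidate regions.
#'
#' @param scan_fst,scan_dh `scan_result` objects from [select_top()].
#' @param genes Gene interval tibble as in [map_to_genes()].
#' @param flank_bp Flank passed to [map_to_genes()].
#' @return Character vector of consensus gene names (possibly empty).
#' @export
consensus_hits <- function(scan_fst, scan_dh, genes, flank_bp = 0) {
  g1 <- stats::na.omit(map_to_genes(scan_fst, genes, flank_bp)$gene)
  g2 <- stats::na.omit(map_to_genes(scan_dh, genes, flank_bp)$gene)
  sort(intersect(unique(g1), unique(g2)))
}
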