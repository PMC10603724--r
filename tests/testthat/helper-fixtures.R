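# Small in-code fixtures and independent oracles shared across test files.

# genotype object from a bare calls matrix, one chromosome unless given
make_gm <- function(calls, bp = NULL, chrom = NULL, breed = "A") {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(bp)) bp <- seq(1e5, by = 1e5, length.out = m)
  if (is.null(chrom)) chrom <- rep("1", m)
  breed <- rep_len(breed, n)
  genotypes(
    calls,
    tibble::tibble(chrom = as.character(chrom),
                   id = sprintf("s%03d", seq_len(m)), cm = 0,
                   bp = as.integer(bp)),
    tibble::tibble(sample_id = sprintf("%s_%02d", breed, seq_len(n)),
                   breed = breed)
  )
}

# brute-force ROH enumerator: naive loops, independent of detect_roh()
oracle_roh_one <- function(g, bp, params) {
  m <- length(g)
  if (m < params$windef) {
    starts <- 1L
    ends <- m
  } else {
    starts <- seq(1L, m - params$windef + 1L, by = params$interval)
    ends <- starts + params$windef - 1L
  }
  qual <- logical(length(starts))
  for (w in seq_along(starts)) {
    win <- g[starts[w]:ends[w]]
    qual[w] <- sum(win == 1, na.rm = TRUE) <= params$het_allowed &&
      sum(is.na(win)) <= params$max_miss
  }
  cand <- logical(m)
  for (i in seq_len(m)) {
    cov <- which(starts <= i & ends >= i)
    if (length(cov) &&
        sum(qual[cov]) / length(cov) >= params$roh_quartile - 1e-9) {
      cand[i] <- TRUE
    }
  }
  segs <- list()
  i <- 1L
  while (i <= m) {
    if (!cand[i]) { i <- i + 1L; next }
    j <- i
    while (j < m && cand[j + 1L]) j <- j + 1L
    piece <- i
    for (k in if (j > i) (i + 1L):j else integer()) {
      if (bp[k] - bp[k - 1L] > params$max_internal_gap_kb * 1000) {
        segs <- c(segs, list(piece))
        piece <- integer()
      }
      piece <- c(piece, k)
    }
    segs <- c(segs, list(piece))
    i <- j + 1L
  }
  out <- list()
  for (p in segs) {
    n <- length(p)
    len_kb <- (bp[p[n]] - bp[p[1]] + 1) / 1000
    if (n >= params$min_nsnp && len_kb >= params$min_kb_length &&
        len_kb / n <= params$density_kb_per_snp) {
      out[[length(out) + 1]] <- data.frame(
        start_bp = bp[p[1]], end_bp = bp[p[n]], n_snps = n,
        length_kb = len_kb)
    }
  }
  if (!length(out)) {
    return(data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_kb = numeric()))
  }
  do.call(rbind, out)
}

# random single-chromosome ROH fixture: mostly homozygous with occasional
# hets/missing and mixed inter-SNP gaps so every acceptance rule is hit
random_roh_fixture <- function(m, p_het = 0.08, p_miss = 0.04,
                               gap_kb_choices = c(20, 50, 120, 600)) {
  g <- sample(c(0L, 2L), m, replace = TRUE)
  g[runif(m) < p_het] <- 1L
  g[runif(m) < p_miss] <- NA_integer_
  gaps <- sample(gap_kb_choices, m - 1, replace = TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1)) * 1000
  bp <- cumsum(c(1e5, gaps))
  list(g = g, bp = as.integer(bp))
}

# fraction of a truth interval covered by detected segments of one animal
overlap_fraction <- function(segs, truth_start, truth_end) {
  if (!nrow(segs)) return(0)
  ov <- pmax(0, pmin(segs$end_bp, truth_end) -
               pmax(segs$start_bp, truth_start) + 1)
  sum(ov) / (truth_end - truth_start + 1)
}

# param sets exercising different corners of the acceptance predicate
roh_param_grid <- function() {
  list(
    roh_params(),
    roh_params(windef = 8, interval = 3, min_nsnp = 5, min_kb_length = 100,
               density_kb_per_snp = 100, max_internal_gap_kb = 100,
               het_allowed = 1, max_miss = 1),
    roh_params(windef = 5, interval = 5, min_nsnp = 3, min_kb_length = 50,
               density_kb_per_snp = 60, max_internal_gap_kb = 60,
               het_allowed = 0, max_miss = 0),
    roh_params(roh_quartile = 0.5, windef = 10, interval = 2, min_nsnp = 4,
               min_kb_length = 200, density_kb_per_snp = 150,
               max_internal_gap_kb = 150, het_allowed = 1, max_miss = 2)
  )
}
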