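#' Identity-by-state distance between individuals
#'
#' For each pair, over SNPs where both genotypes are called, the per-SNP
#' similarity is (2 - |g_i - g_j|)/2 (the shared-allele fraction) and the
#' distance is one minus its mean, so identical genotypes give 0 and
#' opposite homozygotes give 1.
#'
#' @param gm A [genotypes] object with at least two samples.
#' @return A symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
ibs_distance <- function(gm) {
  n <- nrow(gm$calls)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  g <- gm$calls
  M <- !is.na(g)
  A <- lapply(0:2, function(v) (M & g == v) * 1)
  callable <- M %*% t(M)
  diff1 <- A[[1]] %*% t(A[[2]]) + A[[2]] %*% t(A[[1]]) +
    A[[2]] %*% t(A[[3]]) + A[[3]] %*% t(A[[2]])
  diff2 <- A[[1]] %*% t(A[[3]]) + A[[3]] %*% t(A[[1]])
  off <- callable == 0 & upper.tri(callable)
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1, ]
    stop("samples ", gm$samples$sample_id[bad[1]], " and ",
         gm$samples$sample_id[bad[2]], " share no called SNPs",
         call. = FALSE)
  }
  d <- (diff1 + 2 * diff2) / (2 * callable)
  diag(d) <- 0
  dimnames(d) <- list(gm$samples$sample_id, gm$samples$sample_id)
  d
}

#' Reynolds coancestry distance between two breeds
#'
#' Multi-locus Reynolds estimator as a ratio of sums: with breed allele
#' frequencies p and q at locus l, numerator 2(p - q)^2 and denominator
#' 2\[1 - (pq + (1-p)(1-q))\]; theta is the summed numerator over the summed
#' denominator across loci with positive denominator, and the distance is
#' D = -ln(1 - theta), with theta capped at 1 - 1e-12 before the log.
#'
#' @param gm A [genotypes] object.
#' @param breed_a,breed_b Breed codes.
#' @return A one-row tibble: `breed_a`, `breed_b`, `theta`, `d`, `n_loci`.
#' @export
reynolds_distance <- function(gm, breed_a, breed_b) {
  fa <- breed_freqs(gm, breed_a)
  fb <- breed_freqs(gm, breed_b)
  reynolds_from_freqs(fa, fb, breed_a, breed_b)
}

breed_freqs <- function(gm, breed) {
  ids <- gm$samples$sample_id[gm$samples$breed == breed]
  if (!length(ids)) stop("breed not in cohort: ", breed, call. = FALSE)
  allele_freq(gm, ids)$freq
}

reynolds_from_freqs <- function(p, q, breed_a = "a", breed_b = "b") {
  ok <- !is.na(p) & !is.na(q)
  p <- p[ok]; q <- q[ok]
  num <- 2 * (p - q)^2
  den <- 2 * (1 - (p * q + (1 - p) * (1 - q)))
  use <- den > 0
  if (!any(use)) {
    stop("no locus with positive Reynolds denominator between ", breed_a,
         " and ", breed_b, call. = FALSE)
  }
  theta <- sum(num[use]) / sum(den[use])
  tibble::tibble(breed_a = breed_a, breed_b = breed_b, theta = theta,
                 d = -log(1 - min(theta, 1 - 1e-12)), n_loci = sum(use))
}

#' Reynolds distance matrix over all breeds
#'
#' @param gm A [genotypes] object with at least two breeds.
#' @return A symmetric matrix of Reynolds D with breed codes as dimnames.
#' @export
reynolds_matrix <- function(gm) {
  breeds <- sort(unique(gm$samples$breed))
  freqs <- vapply(breeds, function(b) breed_freqs(gm, b),
                  numeric(nrow(gm$snps)))
  d <- matrix(0, length(breeds), length(breeds),
              dimnames = list(breeds, breeds))
  for (i in seq_along(breeds)[-length(breeds)]) {
    for (j in (i + 1):length(breeds)) {
      d[i, j] <- d[j, i] <-
        reynolds_from_freqs(freqs[, i], freqs[, j], breeds[i], breeds[j])$d
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}), with any negative
#' branch length clamped to zero and its deficit moved onto the sibling
#' edge so path lengths are preserved as far as possible.
#'
#' @param dm Symmetric distance matrix with at least 3 labels.
#' @return An \pkg{ape} `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need at least 3 labels", call. = FALSE)
  tree <- ape::nj(stats::as.dist(dm))
  clamp_negative_edges(tree)
}

clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < -1e-12)
    if (!length(neg)) break
    e <- neg[1]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sibs)) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] +
        tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrapped neighbor-joining breed tree from Reynolds distances
#'
#' Builds the full-data NJ tree on the Reynolds D matrix, then resamples
#' SNP columns with replacement `B` times, recomputing the distance matrix
#' and tree each time; the support of each internal edge of the full tree
#' is the fraction of replicates containing the same bipartition, stored in
#' the tree's node labels.
#'
#' @param gm A [genotypes] object with at least three breeds.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Integer seed for the column resampling.
#' @return An \pkg{ape} `phylo` tree with bootstrap supports (fractions in
#'   \[0, 1\]) as `node.label`.
#' @export
bootstrap_breed_tree <- function(gm, B = 100, seed = 1) {
  breeds <- sort(unique(gm$samples$breed))
  if (length(breeds) < 3) stop("need at least 3 breeds", call. = FALSE)
  stopifnot(B >= 1)
  freqs <- vapply(breeds, function(b) breed_freqs(gm, b),
                  numeric(nrow(gm$snps)))
  nj_from_freqs <- function(fr) {
    d <- matrix(0, length(breeds), length(breeds),
                dimnames = list(breeds, breeds))
    for (i in seq_along(breeds)[-length(breeds)]) {
      for (j in (i + 1):length(breeds)) {
        d[i, j] <- d[j, i] <-
          reynolds_from_freqs(fr[, i], fr[, j], breeds[i], breeds[j])$d
      }
    }
    neighbor_joining(d)
  }
  main <- nj_from_freqs(freqs)
  boot <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      idx <- sample.int(nrow(freqs), replace = TRUE)
      nj_from_freqs(freqs[idx, , drop = FALSE])
    })
  })
  counts <- ape::prop.clades(main, boot, rooted = FALSE)
  counts[is.na(counts)] <- B
  main$node.label <- format(counts / B, trim = TRUE)
  attr(main, "bootstrap") <- counts / B
  attr(main, "B") <- B
  main
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Principal-coordinates analysis: the squared-distance matrix is double
#' centered and eigendecomposed; coordinates are the top-k eigenvectors
#' scaled by the square roots of the (nonnegative) eigenvalues. When fewer
#' than k positive eigenvalues exist, the missing dimensions are zero
#' columns and a warning is issued.
#'
#' @param dm Symmetric distance matrix.
#' @param k Number of dimensions to return.
#' @return A list of class `mds_result`: `coordinates` (tibble with `label`
#'   and `C1`..`Ck`) and `eigenvalues` (all eigenvalues, non-increasing).
#' @export
classical_mds <- function(dm, k = 3) {
  dm <- as.matrix(dm)
  stopifnot(k >= 1)
  n <- nrow(dm)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm), k = min(k, n - 1), eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  # eigenvalues at numerical-noise scale are zero dimensions, not coordinates
  n_pos <- sum(fit$eig > max(fit$eig, 0) * 1e-8)
  if (ncol(pts) > n_pos) pts <- pts[, seq_len(n_pos), drop = FALSE]
  if (ncol(pts) < k) {
    warning("only ", ncol(pts), " positive dimension(s); remaining ",
            "coordinates filled with zeros", call. = FALSE)
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  coords <- tibble::as_tibble(pts, .name_repair = ~ paste0("C", seq_len(k)))
  coords <- dplyr::bind_cols(
    tibble::tibble(label = rownames(dm) %||% as.character(seq_len(n))),
    coords)
  structure(list(coordinates = coords,
                 eigenvalues = sort(fit$eig, decreasing = TRUE)),
            class = "mds_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mds_result <- function(x, ...) {
  cat("<mds_result> ", nrow(x$coordinates), " points, ",
      ncol(x$coordinates) - 1, " dimensions\n", sep = "")
  print(utils::head(x$coordinates))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.mds_result <- function(x, ...) x$coordinates
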