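#' Genotype container for SNP-array cohorts
#'
#' `genotypes()` bundles a samples-by-SNPs matrix of diploid genotype codes
#' with its SNP map and sample metadata. Codes count copies of the designated
#' alternate allele: 0, 1, 2 or `NA` (missing). This is the object every
#' analysis stage of the package consumes.
#'
#' @param calls Integer matrix, samples in rows and SNPs in columns, values in
#'   \{0, 1, 2, NA\}.
#' @param snps Data frame with columns `chrom` (autosome label), `id`
#'   (unique SNP id), `cm` (genetic position, may be 0) and `bp` (1-based
#'   physical position). Optional columns `allele_ref` / `allele_alt` carry
#'   the allele symbols used when writing PED files.
#' @param samples Data frame with columns `sample_id` (unique), `breed`
#'   (non-empty), and optionally `farm`, `sex` and binary trait columns such
#'   as `horns`, `wattles`, `ears` coded "present"/"absent"/"unknown".
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(calls, snps, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  snps <- tibble::as_tibble(snps)
  samples <- tibble::as_tibble(samples)
  stopifnot(
    all(c("chrom", "id", "bp") %in% names(snps)),
    all(c("sample_id", "breed") %in% names(samples))
  )
  if (!"cm" %in% names(snps)) snps$cm <- 0
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(snps)) {
    stop("calls dimensions (", nrow(calls), " x ", ncol(calls),
         ") do not match samples (", nrow(samples), ") x snps (",
         nrow(snps), ")", call. = FALSE)
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (anyDuplicated(snps$id)) stop("SNP ids must be unique", call. = FALSE)
  if (anyDuplicated(samples$sample_id)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  if (any(!nzchar(samples$breed)) || any(is.na(samples$breed))) {
    stop("breed must be non-empty for every sample", call. = FALSE)
  }
  if (any(snps$bp < 1)) stop("bp positions must be >= 1", call. = FALSE)
  ord <- order(chrom_key(snps$chrom), snps$bp)
  if (is.unsorted(ord, strictly = TRUE) || any(ord != seq_along(ord))) {
    snps <- snps[ord, ]
    calls <- calls[, ord, drop = FALSE]
  }
  dup <- duplicated(snps[, c("chrom", "bp")])
  if (any(dup)) {
    stop("SNP positions must be strictly increasing within chromosome; ",
         "duplicated position at ", snps$id[which(dup)[1]], call. = FALSE)
  }
  rownames(calls) <- samples$sample_id
  colnames(calls) <- snps$id
  structure(list(calls = calls, snps = snps, samples = samples),
            class = "genotypes")
}

# numeric-aware chromosome ordering key ("2" < "10", non-numeric after)
chrom_key <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(u))
  key <- ifelse(is.na(num), Inf, num)
  match(as.character(chrom), u[order(key, u)])
}

#' @export
print.genotypes <- function(x, ...) {
  cat("<genotypes> ", nrow(x$calls), " samples x ", ncol(x$calls),
      " SNPs, ", length(unique(x$samples$breed)), " breed(s), ",
      length(unique(x$snps$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$calls)

#' One-row summary of a genotype cohort
#'
#' @param x A `genotypes` object.
#' @param ... Unused.
#' @return A one-row tibble: sample, SNP, breed and chromosome counts,
#'   overall call rate and mean minor allele frequency.
#' @importFrom generics glance
#' @export
glance.genotypes <- function(x, ...) {
  p <- allele_freq(x)$freq
  maf <- pmin(p, 1 - p)
  tibble::tibble(
    n_samples = nrow(x$calls),
    n_snps = ncol(x$calls),
    n_breeds = length(unique(x$samples$breed)),
    n_chroms = length(unique(x$snps$chrom)),
    call_rate = mean(!is.na(x$calls)),
    mean_maf = mean(maf, na.rm = TRUE)
  )
}

#' Read PLINK text genotypes (PED/MAP)
#'
#' Parses the whitespace-delimited PLINK text dialect: each MAP row is
#' `chrom id cm bp`; each PED row holds six leading columns
#' (family, individual, father, mother, sex, phenotype) followed by two
#' allele symbols per SNP, with `0 0` denoting a missing genotype. The
#' alternate allele at each SNP is the minor allele observed in the file
#' (ties broken by taking the lexicographically smaller symbol); genotype
#' codes count its copies. At monomorphic SNPs all calls are coded 0.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A [genotypes] object, SNPs sorted by (chrom, bp). PED sex codes
#'   1/2 map to male/female; the family id is stored as `farm`.
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, colClasses = "character")
  if (ncol(map) != 4) {
    stop("MAP file must have 4 columns, found ", ncol(map), call. = FALSE)
  }
  names(map) <- c("chrom", "id", "cm", "bp")
  map$cm <- as.numeric(map$cm)
  map$bp <- as.integer(map$bp)
  n_snps <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  expected <- 6L + 2L * n_snps
  calls <- matrix(NA_integer_, nrow = length(fields), ncol = n_snps)
  meta <- vector("list", length(fields))
  a_all <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != expected) {
      stop("PED row ", i, " has ", length(f), " fields; expected ", expected,
           " for ", n_snps, " SNPs", call. = FALSE)
    }
    meta[[i]] <- f[1:6]
    a_all[[i]] <- f[-(1:6)]
  }
  a1 <- do.call(rbind, lapply(a_all, function(a) a[c(TRUE, FALSE)]))
  a2 <- do.call(rbind, lapply(a_all, function(a) a[c(FALSE, TRUE)]))
  a1 <- matrix(a1, nrow = length(fields))
  a2 <- matrix(a2, nrow = length(fields))
  half_missing <- xor(a1 == "0", a2 == "0")
  a1[half_missing] <- "0"
  a2[half_missing] <- "0"

  ref <- alt <- character(n_snps)
  for (j in seq_len(n_snps)) {
    obs <- c(a1[, j], a2[, j])
    obs <- obs[obs != "0"]
    syms <- sort(unique(obs))
    if (length(syms) > 2) {
      stop("SNP ", map$id[j], " has more than two allele symbols: ",
           paste(syms, collapse = ", "), call. = FALSE)
    }
    if (length(syms) == 0) {
      ref[j] <- "0"; alt[j] <- "0"
    } else if (length(syms) == 1) {
      ref[j] <- syms; alt[j] <- "0"           # monomorphic: all calls 0
    } else {
      counts <- table(factor(obs, levels = syms))
      if (counts[1] == counts[2]) {
        alt[j] <- syms[1]; ref[j] <- syms[2]  # lexicographic tie-break
      } else {
        alt[j] <- syms[which.min(counts)]
        ref[j] <- syms[which.max(counts)]
      }
    }
    missing <- a1[, j] == "0"
    g <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
    g[missing] <- NA_integer_
    calls[, j] <- g
  }

  meta <- do.call(rbind, meta)
  sex <- c("1" = "male", "2" = "female")[meta[, 5]]
  sex[is.na(sex)] <- "unknown"
  samples <- tibble::tibble(
    sample_id = meta[, 2],
    breed = ifelse(nzchar(meta[, 1]) & meta[, 1] != "0", meta[, 1], "UNK"),
    farm = "",
    sex = unname(sex)
  )
  map$allele_ref <- ref
  map$allele_alt <- alt
  genotypes(calls, map, samples)
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' Inverse of [read_ped_map()]: emits whitespace-delimited PED/MAP files
#' that reproduce the genotype codes exactly when read back. Allele symbols
#' come from the `allele_ref`/`allele_alt` columns of the SNP map when
#' present (as set by [read_ped_map()]), otherwise "A" (reference) and "B"
#' (alternate) are used.
#'
#' @param gm A [genotypes] object.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `gm`.
#' @export
write_ped_map <- function(gm, ped_path, map_path) {
  snps <- gm$snps
  ref <- if ("allele_ref" %in% names(snps)) snps$allele_ref else
    rep("A", nrow(snps))
  alt <- if ("allele_alt" %in% names(snps)) snps$allele_alt else
    rep("B", nrow(snps))
  ref[ref == "0" | is.na(ref)] <- "A"
  alt[alt == "0" | is.na(alt)] <- "B"
  utils::write.table(
    data.frame(snps$chrom, snps$id, snps$cm, snps$bp),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  n <- nrow(gm$calls)
  con <- file(ped_path, "w")
  on.exit(close(con))
  sex_code <- c(male = "1", female = "2", unknown = "0")
  smp <- gm$samples
  fam <- if ("breed" %in% names(smp)) smp$breed else rep("0", n)
  sex <- if ("sex" %in% names(smp)) {
    unname(ifelse(smp$sex %in% names(sex_code), sex_code[smp$sex], "0"))
  } else rep("0", n)
  for (i in seq_len(n)) {
    g <- gm$calls[i, ]
    x1 <- ifelse(is.na(g), "0", ifelse(g >= 1, alt, ref))
    x2 <- ifelse(is.na(g), "0", ifelse(g == 2, alt, ref))
    writeLines(paste(c(fam[i], smp$sample_id[i], "0", "0", sex[i], "-9",
                       as.vector(rbind(x1, x2))), collapse = " "), con)
  }
  invisible(gm)
}

#' Per-SNP alternate-allele frequency
#'
#' @param gm A [genotypes] object.
#' @param sample_subset Optional character vector of sample ids; defaults to
#'   all samples.
#' @return A tibble with one row per SNP: `id`, `chrom`, `bp`, `freq`
#'   (alternate-allele frequency, `NA` where every genotype in the subset is
#'   missing) and `n_called`.
#' @export
allele_freq <- function(gm, sample_subset = NULL) {
  calls <- subset_calls(gm, sample_subset)
  n_called <- colSums(!is.na(calls))
  p <- colSums(calls, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0] <- NA_real_
  tibble::tibble(id = gm$snps$id, chrom = gm$snps$chrom, bp = gm$snps$bp,
                 freq = unname(p), n_called = unname(n_called))
}

subset_calls <- function(gm, sample_subset) {
  if (is.null(sample_subset)) return(gm$calls)
  if (length(sample_subset) == 0) {
    stop("sample subset must be non-empty", call. = FALSE)
  }
  missing_ids <- setdiff(sample_subset, gm$samples$sample_id)
  if (length(missing_ids)) {
    stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  gm$calls[match(sample_subset, gm$samples$sample_id), , drop = FALSE]
}

#' Keep a subset of samples or SNPs
#'
#' @param gm A [genotypes] object.
#' @param sample_ids,snp_ids Ids to retain (either may be `NULL` = all).
#' @return A [genotypes] object.
#' @export
subset_genotypes <- function(gm, sample_ids = NULL, snp_ids = NULL) {
  si <- if (is.null(sample_ids)) seq_len(nrow(gm$calls)) else
    match(sample_ids, gm$samples$sample_id)
  vi <- if (is.null(snp_ids)) seq_len(ncol(gm$calls)) else
    match(snp_ids, gm$snps$id)
  if (anyNA(si)) stop("unknown sample id(s)", call. = FALSE)
  if (anyNA(vi)) stop("unknown SNP id(s)", call. = FALSE)
  genotypes(gm$calls[si, vi, drop = FALSE], gm$snps[vi, ], gm$samples[si, ])
}

#' Quality-control a genotype cohort
#'
#' Applies the standard SNP-chip screening in a fixed order: (1) restrict to
#' the configured autosomes; (2) drop samples whose call rate is below
#' `min_sample_call_rate`; (3) drop SNPs whose call rate (over retained
#' samples) is below `min_snp_call_rate`; (4) drop SNPs whose minor allele
#' frequency is below `min_maf`. Defaults follow common 50K goat chip
#' practice: 95% call rates and MAF 0.1%.
#'
#' @param gm A [genotypes] object.
#' @param min_sample_call_rate,min_snp_call_rate Fractions in \[0, 1\].
#' @param min_maf Minimum minor allele frequency (default 0.001).
#' @param autosomes Chromosome labels to keep (default "1".."29", the goat
#'   autosomes).
#' @return A list with `genotypes` (the filtered cohort) and `report`, a
#'   tibble of per-step removal counts.
#' @export
apply_qc <- function(gm, min_sample_call_rate = 0.95,
                     min_snp_call_rate = 0.95, min_maf = 0.001,
                     autosomes = as.character(1:29)) {
  stopifnot(min_sample_call_rate >= 0, min_sample_call_rate <= 1,
            min_snp_call_rate >= 0, min_snp_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  report <- list()
  # 1. autosomes
  keep_snp <- as.character(gm$snps$chrom) %in% as.character(autosomes)
  report$non_autosomal_snps <- sum(!keep_snp)
  gm <- subset_genotypes(gm, snp_ids = gm$snps$id[keep_snp])

  # 2. sample call rate
  cr <- rowMeans(!is.na(gm$calls))
  keep_s <- cr >= min_sample_call_rate
  report$low_call_rate_samples <- sum(!keep_s)
  if (!any(keep_s)) {
    stop("QC removed every sample: empty cohort", call. = FALSE)
  }
  gm <- subset_genotypes(gm, sample_ids = gm$samples$sample_id[keep_s])

  # 3. SNP call rate
  snp_cr <- colMeans(!is.na(gm$calls))
  keep_v <- snp_cr >= min_snp_call_rate
  report$low_call_rate_snps <- sum(!keep_v)
  gm <- subset_genotypes(gm, snp_ids = gm$snps$id[keep_v])

  # 4. MAF
  p <- allele_freq(gm)$freq
  maf <- pmin(p, 1 - p)
  keep_m <- !is.na(maf) & maf >= min_maf
  report$low_maf_snps <- sum(!keep_m)
  gm <- subset_genotypes(gm, snp_ids = gm$snps$id[keep_m])

  list(
    genotypes = gm,
    report = tibble::tibble(
      step = c("autosome_restriction", "sample_call_rate", "snp_call_rate",
               "snp_maf"),
      unit = c("snps", "samples", "snps", "snps"),
      n_removed = c(report$non_autosomal_snps, report$low_call_rate_samples,
                    report$low_call_rate_snps, report$low_maf_snps)
    )
  )
}

# IBS similarity s = (IBS2 + 0.5 * IBS1) / callable for one pair of rows
pair_ibs_similarity <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok)) return(NA_real_)
  mean((2 - abs(gi[ok] - gj[ok])) / 2)
}

#' Exclude directly related samples
#'
#' Flags pairs of directly related animals from genotype data and removes a
#' minimal-effort cover of them. Pairwise identity-by-state similarity
#' s = (IBS2 + 0.5 IBS1) / callable SNPs is rescaled against the cohort
#' baseline (the median s over all pairs, which unrelated pairs dominate)
#' into a kinship-style proxy k = (s - s0) / (1 - s0); k is near 1 for
#' duplicates, near 0.5 for first-degree relatives and near 0 for unrelated
#' animals. Pairs with k >= `threshold` are flagged and samples are removed
#' greedily: the sample in the most flagged pairs goes first (ties broken by
#' larger missingness, then lexicographic id) until no flagged pair remains.
#'
#' @param gm A [genotypes] object with at least two samples.
#' @param threshold Kinship-proxy threshold in (0, 1\]; the default 0.25
#'   targets first-degree relationships.
#' @return A list with `genotypes` (related animals removed) and `removed`,
#'   a character vector of removed sample ids.
#' @export
exclude_related <- function(gm, threshold = 0.25) {
  if (nrow(gm$calls) < 2) stop("need at least 2 samples", call. = FALSE)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(gm$calls)
  s <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s[i, j] <- s[j, i] <- pair_ibs_similarity(gm$calls[i, ], gm$calls[j, ])
    }
  }
  s0 <- stats::median(s[upper.tri(s)], na.rm = TRUE)
  k <- (s - s0) / (1 - s0)
  flagged <- !is.na(k) & k >= threshold
  diag(flagged) <- FALSE

  ids <- gm$samples$sample_id
  missingness <- rowMeans(is.na(gm$calls))
  removed <- character()
  while (any(flagged)) {
    deg <- rowSums(flagged)
    worst <- which(deg == max(deg))
    if (length(worst) > 1) {
      worst <- worst[order(-missingness[worst], ids[worst])][1]
    }
    removed <- c(removed, ids[worst])
    flagged[worst, ] <- FALSE
    flagged[, worst] <- FALSE
  }
  keep <- setdiff(ids, removed)
  list(genotypes = subset_genotypes(gm, sample_ids = keep), removed = removed)
}

#' Cap the number of animals per breed
#'
#' Breeds larger than `max_per_breed` are subsampled uniformly at random
#' (reproducibly, via `seed`); smaller breeds are kept whole. Mirrors the
#' common practice of balancing breed sizes (e.g., to 35) before
#' population-structure analyses.
#'
#' @param gm A [genotypes] object.
#' @param max_per_breed Maximum animals retained per breed (default 35).
#' @param seed Integer seed controlling the subsampling.
#' @return A [genotypes] object.
#' @export
cap_breed_size <- function(gm, max_per_breed = 35, seed = 1) {
  stopifnot(max_per_breed >= 1)
  keep <- with_seed(seed, {
    unlist(lapply(split(gm$samples$sample_id, gm$samples$breed),
                  function(ids) {
      if (length(ids) <= max_per_breed) ids else sample(ids, max_per_breed)
    }), use.names = FALSE)
  })
  keep <- gm$samples$sample_id[gm$samples$sample_id %in% keep]
  subset_genotypes(gm, sample_ids = keep)
}

# evaluate an expression under a temporary, seeded RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}
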