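#' Configuration for a synthetic multi-breed SNP-chip cohort
#'
#' Builds the parameter set for [simulate_cohort()]. The defaults emulate a
#' medium-density (~50K) goat chip survey of 15 Italian breeds: the breed
#' codes and sizes of [goat_survey_counts()], ~48,000 autosomal biallelic
#' SNPs on 29 autosomes, Balding-Nichols differentiation of F = 0.04 per
#' breed (pairwise Wright's FST around 0.04-0.08, the range typical of
#' Italian goat breeds), and 1% missing genotypes.
#'
#' @param breeds Character vector of breed codes.
#' @param breed_sizes Integer vector, one size per breed.
#' @param n_snps Total SNP count.
#' @param n_chroms Number of autosomes (goat: 29).
#' @param chrom_length Chromosome length in bp (uniform across autosomes).
#' @param fst_per_breed Balding-Nichols F per breed, recycled if scalar.
#' @param missing_rate Genotype missingness rate.
#' @param n_related_pairs Number of parent-offspring pairs to plant (the
#'   offspring replaces an unrelated animal of the same breed).
#' @param planted_roh Data frame of homozygous segments to plant; columns
#'   `breed`, `frac_individuals`, `length_mb`, `n_per_individual`.
#' @param trait_loci Data frame of trait-associated windows; columns
#'   `chrom`, `center_bp`, `window_bp`, `delta` (group frequency shift).
#' @param trait_name Metadata column receiving the simulated binary trait.
#' @param seed Integer seed; every random draw in the simulator descends
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(breeds = goat_survey_counts()$breed,
                       breed_sizes = goat_survey_counts()$initial_n,
                       n_snps = 48000,
                       n_chroms = 29,
                       chrom_length = 85e6,
                       fst_per_breed = 0.04,
                       missing_rate = 0.01,
                       n_related_pairs = 0,
                       planted_roh = NULL,
                       trait_loci = NULL,
                       trait_name = "horns",
                       seed = 1) {
  if (length(fst_per_breed) == 1) {
    fst_per_breed <- rep(fst_per_breed, length(breeds))
  }
  stopifnot(
    length(breed_sizes) == length(breeds),
    length(fst_per_breed) == length(breeds),
    all(fst_per_breed >= 0), all(fst_per_breed < 1),
    missing_rate >= 0, missing_rate <= 1,
    n_snps >= 1, n_chroms >= 1, chrom_length > 0
  )
  if (!is.null(planted_roh)) {
    planted_roh <- tibble::as_tibble(planted_roh)
    stopifnot(all(c("breed", "frac_individuals", "length_mb",
                    "n_per_individual") %in% names(planted_roh)))
    if (any(planted_roh$length_mb * 1e6 > chrom_length)) {
      stop("planted ROH longer than a chromosome", call. = FALSE)
    }
  }
  if (!is.null(trait_loci)) {
    trait_loci <- tibble::as_tibble(trait_loci)
    stopifnot(all(c("chrom", "center_bp", "window_bp", "delta") %in%
                    names(trait_loci)))
  }
  structure(
    list(breeds = breeds, breed_sizes = breed_sizes, n_snps = n_snps,
         n_chroms = n_chroms, chrom_length = chrom_length,
         fst_per_breed = fst_per_breed, missing_rate = missing_rate,
         n_related_pairs = n_related_pairs, planted_roh = planted_roh,
         trait_loci = trait_loci, trait_name = trait_name, seed = seed),
    class = "sim_config"
  )
}

#' Simulate a structured multi-breed genotype cohort
#'
#' Generates genotypes under the Balding-Nichols model: each SNP has an
#' ancestral allele frequency drawn uniformly on \[0.05, 0.95\]; breed-level
#' frequencies are Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral p
#' (equal to p when F = 0); genotypes are Binomial(2, breed frequency).
#' SNPs are placed uniformly on the autosomes and sorted. Optional layers
#' add parent-offspring pairs, planted homozygous segments
#' ([plant_roh()]), trait-associated allele-frequency shifts
#' ([assign_trait_groups()]) and missing genotypes, in that order. SNPs are
#' otherwise unlinked, so downstream linkage-based statistics on simulated
#' data reflect sampling noise only.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genotypes` (a [genotypes] object) and `truth`, a
#'   list recording ancestral and per-breed allele frequencies, planted
#'   segments, related pairs and trait-locus assignments: everything needed
#'   to recompute any latent quantity.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_snps <- cfg$n_snps
    per_chrom <- table(factor(sort(sample.int(cfg$n_chroms, n_snps,
                                              replace = TRUE)),
                              levels = seq_len(cfg$n_chroms)))
    chrom <- rep(seq_len(cfg$n_chroms), per_chrom)
    bp <- unlist(lapply(per_chrom, function(m) {
      sort(sample.int(cfg$chrom_length, m))
    }), use.names = FALSE)
    snps <- tibble::tibble(
      id = sprintf("snp_%d_%d", chrom, bp),
      chrom = as.character(chrom),
      cm = 0, bp = as.integer(bp)
    )

    p_anc <- stats::runif(n_snps, 0.05, 0.95)
    n_total <- sum(cfg$breed_sizes)
    calls <- matrix(NA_integer_, nrow = n_total, ncol = n_snps)
    breed_freq <- matrix(NA_real_, nrow = length(cfg$breeds), ncol = n_snps,
                         dimnames = list(cfg$breeds, NULL))
    row0 <- 0L
    for (b in seq_along(cfg$breeds)) {
      Fb <- cfg$fst_per_breed[b]
      pb <- if (Fb > 0) {
        stats::rbeta(n_snps, p_anc * (1 - Fb) / Fb,
                     (1 - p_anc) * (1 - Fb) / Fb)
      } else p_anc
      breed_freq[b, ] <- pb
      nb <- cfg$breed_sizes[b]
      calls[row0 + seq_len(nb), ] <-
        matrix(stats::rbinom(nb * n_snps, 2, rep(pb, each = nb)), nrow = nb)
      row0 <- row0 + nb
    }

    breed <- rep(cfg$breeds, cfg$breed_sizes)
    samples <- tibble::tibble(
      sample_id = sprintf("%s_%03d", breed,
                          unlist(lapply(cfg$breed_sizes, seq_len))),
      breed = breed,
      farm = rep_len(c("FarmA", "FarmB"), n_total),
      sex = sample(c("female", "male"), n_total, replace = TRUE,
                   prob = c(0.85, 0.15))
    )

    # parent-offspring pairs: offspring gets one gamete copied from the
    # parent, the other drawn from its breed's allele frequencies
    related <- tibble::tibble(parent = character(), offspring = character())
    if (cfg$n_related_pairs > 0) {
      big <- which(cfg$breed_sizes >= 2 * cfg$n_related_pairs + 1)[1]
      if (is.na(big)) stop("no breed large enough for related pairs",
                           call. = FALSE)
      off0 <- sum(cfg$breed_sizes[seq_len(big - 1)])
      for (r in seq_len(cfg$n_related_pairs)) {
        i_par <- off0 + r
        i_off <- off0 + cfg$breed_sizes[big] - r + 1
        g_par <- calls[i_par, ]
        gam <- ifelse(g_par == 2, 1L,
                      ifelse(g_par == 0, 0L,
                             stats::rbinom(n_snps, 1, 0.5)))
        other <- stats::rbinom(n_snps, 1, breed_freq[big, ])
        calls[i_off, ] <- as.integer(gam + other)
        related <- rbind(related, tibble::tibble(
          parent = samples$sample_id[i_par],
          offspring = samples$sample_id[i_off]))
      }
    }

    gm <- genotypes(calls, snps, samples)
    truth <- list(ancestral_freq = p_anc, breed_freq = breed_freq,
                  related_pairs = related,
                  planted_segments = NULL, trait = NULL)

    if (!is.null(cfg$planted_roh)) {
      planted <- plant_roh(gm, cfg$planted_roh,
                           seed = sub_seed(cfg$seed, 1))
      gm <- planted$genotypes
      truth$planted_segments <- planted$segments
    }
    if (!is.null(cfg$trait_loci)) {
      tr <- assign_trait_groups(gm, cfg$trait_loci,
                                seed = sub_seed(cfg$seed, 2),
                                trait_name = cfg$trait_name)
      gm <- tr$genotypes
      truth$trait <- tr$truth
    }
    if (cfg$missing_rate > 0) {
      idx <- which(stats::runif(length(gm$calls)) < cfg$missing_rate)
      gm$calls[idx] <- NA_integer_
    }
    list(genotypes = gm, truth = truth)
  })
}

# derive a distinct 32-bit sub-seed from a master seed
sub_seed <- function(seed, k) (as.integer(seed) * 7919L + k * 104729L) %% 2147483647L

#' Plant homozygous segments into a genotype cohort
#'
#' For each specification row, a fraction of the individuals of a breed
#' receive `n_per_individual` homozygous segments of the requested length at
#' random positions: every SNP inside a planted interval is set to 0 or 2,
#' matching a haplotype sampled from the breed's allele frequencies. Used to
#' create ground truth for ROH detection.
#'
#' @param gm A [genotypes] object.
#' @param spec Data frame with columns `breed`, `frac_individuals`,
#'   `length_mb`, `n_per_individual`.
#' @param seed Integer seed.
#' @return A list with `genotypes` (segments planted) and `segments`, a
#'   tibble of the exact planted intervals (`sample_id`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`).
#' @export
plant_roh <- function(gm, spec, seed = 1) {
  spec <- tibble::as_tibble(spec)
  with_seed(seed, {
    segs <- list()
    for (r in seq_len(nrow(spec))) {
      brd <- spec$breed[r]
      members <- gm$samples$sample_id[gm$samples$breed == brd]
      if (!length(members)) stop("breed not found: ", brd, call. = FALSE)
      n_pick <- max(1L, ceiling(spec$frac_individuals[r] * length(members)))
      picked <- sample(members, n_pick)
      p_breed <- allele_freq(gm, members)$freq
      len_bp <- round(spec$length_mb[r] * 1e6)
      chroms <- unique(gm$snps$chrom)
      for (id in picked) {
        i <- match(id, gm$samples$sample_id)
        for (s in seq_len(spec$n_per_individual[r])) {
          placed <- FALSE
          for (try in 1:50) {
            cc <- sample(chroms, 1)
            on_c <- which(gm$snps$chrom == cc)
            span <- range(gm$snps$bp[on_c])
            if (span[2] - span[1] + 1 < len_bp) next
            start <- span[1] + sample.int(span[2] - span[1] - len_bp + 2, 1) - 1L
            end <- start + len_bp - 1L
            inside <- on_c[gm$snps$bp[on_c] >= start & gm$snps$bp[on_c] <= end]
            if (length(inside) == 0) next
            hap <- stats::rbinom(length(inside), 1, p_breed[inside])
            gm$calls[i, inside] <- as.integer(2L * hap)
            segs[[length(segs) + 1]] <- tibble::tibble(
              sample_id = id, chrom = as.character(cc),
              start_bp = as.integer(start), end_bp = as.integer(end),
              n_snps = length(inside))
            placed <- TRUE
            break
          }
          if (!placed) {
            stop("could not place a ", spec$length_mb[r],
                 " Mb segment containing SNPs", call. = FALSE)
          }
        }
      }
    }
    list(genotypes = gm, segments = dplyr::bind_rows(segs))
  })
}

#' Assign binary trait groups with localized allele-frequency divergence
#'
#' Splits the cohort into trait-present and trait-absent groups and, inside
#' each specified genomic window, shifts the two groups' allele frequencies
#' by +delta/2 and -delta/2 (clamped to \[0, 1\]) before re-drawing the
#' genotypes in the window. SNPs outside the windows are untouched, so a
#' two-group differentiation scan has a known localized signal on a null
#' background.
#'
#' @param gm A [genotypes] object.
#' @param loci Data frame with columns `chrom`, `center_bp`, `window_bp`,
#'   `delta`.
#' @param seed Integer seed.
#' @param trait_name Metadata column to write ("present"/"absent").
#' @param n_present Group size; default half the cohort.
#' @return A list with `genotypes` (trait column set, windows re-drawn) and
#'   `truth` (group membership and the affected SNP ids per locus).
#' @export
assign_trait_groups <- function(gm, loci, seed = 1, trait_name = "horns",
                                n_present = NULL) {
  loci <- tibble::as_tibble(loci)
  with_seed(seed, {
    n <- nrow(gm$calls)
    if (is.null(n_present)) n_present <- floor(n / 2)
    present <- sort(sample.int(n, n_present))
    status <- rep("absent", n)
    status[present] <- "present"
    gm$samples[[trait_name]] <- status

    locus_truth <- list()
    for (r in seq_len(nrow(loci))) {
      w <- which(gm$snps$chrom == as.character(loci$chrom[r]) &
                   abs(gm$snps$bp - loci$center_bp[r]) <= loci$window_bp[r] / 2)
      if (!length(w)) {
        stop("trait window on chromosome ", loci$chrom[r],
             " contains no SNPs", call. = FALSE)
      }
      p0 <- allele_freq(gm)$freq[w]
      d <- loci$delta[r]
      p_pres <- pmin(1, pmax(0, p0 + d / 2))
      p_abs <- pmin(1, pmax(0, p0 - d / 2))
      for (grp in list(list(rows = which(status == "present"), p = p_pres),
                       list(rows = which(status == "absent"), p = p_abs))) {
        m <- length(grp$rows)
        gm$calls[grp$rows, w] <-
          matrix(stats::rbinom(m * length(w), 2, rep(grp$p, each = m)),
                 nrow = m)
      }
      locus_truth[[r]] <- tibble::tibble(
        locus = r, chrom = as.character(loci$chrom[r]),
        center_bp = loci$center_bp[r], window_bp = loci$window_bp[r],
        delta = d, snp_ids = list(gm$snps$id[w]))
    }
    list(genotypes = gm,
         truth = list(trait = trait_name,
                      present = gm$samples$sample_id[status == "present"],
                      absent = gm$samples$sample_id[status == "absent"],
                      loci = dplyr::bind_rows(locus_truth)))
  })
}
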