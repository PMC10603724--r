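test_that("single-run examples follow the whole-chromosome window rule", {
  # 12 homozygous SNPs spaced 100 kb on an otherwise empty chromosome
  bp <- seq(1e5, by = 1e5, length.out = 12)
  gm <- make_gm(matrix(0L, 1, 12), bp = bp)
  segs <- detect_roh(gm)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 12L)
  expect_equal(segs$start_bp, as.integer(bp[1]))
  expect_equal(segs$end_bp, as.integer(bp[12]))
  expect_equal(segs$length_kb, (bp[12] - bp[1] + 1) / 1000)

  # one heterozygote disqualifies the whole-chromosome window
  g2 <- rep(0L, 12); g2[6] <- 1L
  gm2 <- make_gm(matrix(g2, 1), bp = bp)
  expect_equal(nrow(detect_roh(gm2)), 0)

  # an unsorted map is rejected
  gm3 <- make_gm(matrix(0L, 1, 12), bp = bp)
  gm3$snps$bp[1:2] <- gm3$snps$bp[2:1]
  expect_error(detect_roh(gm3), "not sorted")
})

test_that("runs are split at large gaps and filtered by every predicate", {
  # 30 homozygous SNPs (so the stepped windows cover every SNP) with a
  # 600 kb gap in the middle: two 15-SNP pieces
  bp <- c(seq(1e5, by = 1e5, length.out = 15),
          seq(2.1e6, by = 1e5, length.out = 15))
  gm <- make_gm(matrix(0L, 1, 30), bp = bp)
  segs <- detect_roh(gm)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_snps, c(15L, 15L))

  # windows step by `interval` from the chromosome start, so trailing SNPs
  # that no window reaches are never candidates: with 24 SNPs only one
  # 20-SNP window exists and the 600 kb gap leaves an 8-SNP tail piece
  # below minNsnp
  bp24 <- c(seq(1e5, by = 1e5, length.out = 12),
            seq(1.8e6, by = 1e5, length.out = 12))
  gm24 <- make_gm(matrix(0L, 1, 24), bp = bp24)
  segs24 <- detect_roh(gm24)
  expect_equal(nrow(segs24), 1)
  expect_equal(segs24$n_snps, 12L)

  # low density: 12 SNPs spanning 6.6 Mb at 600 kb spacing are split into
  # single-SNP fragments by the gap rule and rejected
  gm4 <- make_gm(matrix(0L, 1, 12), bp = seq(1e5, by = 6e5, length.out = 12))
  expect_equal(nrow(detect_roh(gm4)), 0)
})

test_that("detector equals the exhaustive enumerator on random fixtures", {
  set.seed(51)
  grid <- roh_param_grid()
  n_checked <- 0
  for (rep in 1:60) {
    params <- grid[[1 + (rep %% length(grid))]]
    m <- sample(c(30, 80, 200, 500), 1)
    for (ind in 1:3) {
      fx <- random_roh_fixture(m)
      gm <- make_gm(matrix(fx$g, 1), bp = fx$bp)
      got <- detect_roh(gm, params)
      want <- oracle_roh_one(fx$g, fx$bp, params)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        expect_equal(got$start_bp, want$start_bp)
        expect_equal(got$end_bp, want$end_bp)
        expect_equal(got$n_snps, want$n_snps)
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 180)
})

test_that("accepted segments satisfy every acceptance predicate and never overlap", {
  set.seed(52)
  params <- roh_params(windef = 8, interval = 3, min_nsnp = 5,
                       min_kb_length = 100, density_kb_per_snp = 100,
                       max_internal_gap_kb = 100, het_allowed = 1,
                       max_miss = 1)
  for (rep in 1:10) {
    fx <- random_roh_fixture(300)
    gm <- make_gm(matrix(fx$g, 1), bp = fx$bp)
    segs <- detect_roh(gm, params)
    if (!nrow(segs)) next
    expect_true(all(segs$n_snps >= params$min_nsnp))
    expect_true(all(segs$length_kb >= params$min_kb_length))
    expect_true(all(segs$length_kb / segs$n_snps <=
                      params$density_kb_per_snp))
    if (nrow(segs) > 1) {
      expect_true(all(segs$start_bp[-1] > segs$end_bp[-nrow(segs)]))
    }
  }
})

test_that("FROH arithmetic, class partition and incidence bookkeeping are exact", {
  # one 24.66 Mb segment over a 2466 Mb covered genome: FROH = 0.01
  gm <- genotypes(
    matrix(0L, 2, 4),
    tibble::tibble(chrom = c("1", "1", "2", "2"),
                   id = paste0("s", 1:4), cm = 0,
                   bp = c(1, 24660000, 1, 2441340000)),
    tibble::tibble(sample_id = c("A_01", "A_02"), breed = "A"))
  segs <- tibble::tibble(sample_id = "A_01", chrom = "1", start_bp = 1,
                         end_bp = 24660000, n_snps = 2L,
                         length_kb = 24660)
  fr <- compute_froh(segs, gm)
  expect_equal(fr$froh_total[fr$sample_id == "A_01"], 0.01)
  expect_equal(fr$froh_gt16[fr$sample_id == "A_01"], 0.01)
  expect_equal(fr$froh_total[fr$sample_id == "A_02"], 0)

  # class masses are proportional to segment lengths and sum exactly
  segs3 <- tibble::tibble(
    sample_id = "A_01", chrom = "1",
    start_bp = c(1L, 3000001L, 8000001L),
    end_bp = c(1500000L, 6000000L, 28000000L),
    n_snps = c(10L, 10L, 10L),
    length_kb = c(1500, 3000, 20000))
  fr3 <- compute_froh(segs3, gm)
  r <- fr3[fr3$sample_id == "A_01", ]
  expect_equal(r$froh_1_2 + r$froh_2_4 + r$froh_4_8 + r$froh_8_16 +
                 r$froh_gt16, r$froh_total, tolerance = 1e-12)
  expect_equal(r$froh_1_2 / r$froh_gt16, 1500 / 20000, tolerance = 1e-12)

  expect_error(compute_froh(dplyr::mutate(segs, chrom = "99"), gm),
               "unknown chromosome")

  # incidence: brute-force per-animal interval membership
  set.seed(53)
  gm2 <- make_gm(matrix(0L, 6, 50))
  segs2 <- tibble::tibble(
    sample_id = sample(gm2$samples$sample_id, 8, replace = TRUE),
    chrom = "1",
    start_bp = as.integer(sample(seq(1e5, 40e5, by = 1e5), 8)),
    n_snps = 5L)
  segs2$end_bp <- as.integer(segs2$start_bp + sample(5:15, 8, TRUE) * 1e5)
  segs2$length_kb <- (segs2$end_bp - segs2$start_bp + 1) / 1000
  inc <- roh_incidence(segs2, gm2, gm2$samples$sample_id)
  want <- vapply(seq_len(nrow(gm2$snps)), function(j) {
    covered <- vapply(gm2$samples$sample_id, function(id) {
      s <- segs2[segs2$sample_id == id, ]
      any(s$start_bp <= gm2$snps$bp[j] & s$end_bp >= gm2$snps$bp[j])
    }, logical(1))
    mean(covered)
  }, numeric(1))
  expect_equal(inc$incidence, want)
  expect_equal(nrow(roh_incidence(segs2[0, ], gm2,
                                  gm2$samples$sample_id[1])), 50)
  expect_error(roh_incidence(segs2, gm2, character()), "non-empty")
})

test_that("planted segments of 3 Mb are recovered with at least 90% overlap", {
  cfg <- sim_config(breeds = "X", breed_sizes = 10, n_snps = 2000,
                    n_chroms = 1, chrom_length = 10e6, fst_per_breed = 0,
                    missing_rate = 0,
                    planted_roh = data.frame(breed = "X",
                                             frac_individuals = 0.3,
                                             length_mb = 3,
                                             n_per_individual = 1),
                    seed = 54)
  sim <- simulate_cohort(cfg)
  segs <- detect_roh(sim$genotypes)
  tr <- sim$truth$planted_segments
  for (k in seq_len(nrow(tr))) {
    ss <- segs[segs$sample_id == tr$sample_id[k] &
                 segs$chrom == tr$chrom[k], ]
    expect_gte(overlap_fraction(ss, tr$start_bp[k], tr$end_bp[k]), 0.9)
  }

  # negative control: unplanted F = 0 cohort yields no comparable segments
  cfg0 <- sim_config(breeds = "X", breed_sizes = 10, n_snps = 2000,
                     n_chroms = 1, chrom_length = 10e6, fst_per_breed = 0,
                     missing_rate = 0, seed = 55)
  segs0 <- detect_roh(simulate_cohort(cfg0)$genotypes)
  expect_lte(nrow(segs0), 1)
})
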