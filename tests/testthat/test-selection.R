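test_that("two-group FST follows the Wright two-population form", {
  # equal frequencies -> 0; fixed opposite -> 1
  gm <- make_gm(rbind(c(1L, 2L, 0L), c(1L, 2L, 0L),
                      c(1L, 0L, 2L), c(1L, 0L, 2L)))
  a <- gm$samples$sample_id[1:2]; b <- gm$samples$sample_id[3:4]
  fst <- snp_fst(gm, a, b)
  expect_equal(fst$fst, c(0, 1, 1))

  # p_a = 0.8, p_b = 0.2 -> (0.5 - 0.32)/0.5 = 0.36
  calls <- matrix(c(2L, 2L, 2L, 1L, 1L, 0L, 0L, 0L, 1L, 1L), ncol = 1)
  gm2 <- make_gm(calls)
  fst2 <- snp_fst(gm2, gm2$samples$sample_id[1:5], gm2$samples$sample_id[6:10])
  expect_equal(fst2$fst, 0.36)

  # under 2 callable genotypes in a group -> undefined at that SNP
  gm3 <- make_gm(rbind(c(0L, NA), c(2L, NA), c(0L, 0L), c(2L, 2L)))
  fst3 <- snp_fst(gm3, gm3$samples$sample_id[1:2], gm3$samples$sample_id[3:4])
  expect_true(is.na(fst3$fst[2]))
  expect_error(snp_fst(gm3, character(), gm3$samples$sample_id[3:4]),
               "non-empty")
  expect_true(all(fst$fst >= 0 & fst$fst <= 1))
})

test_that("delta H-score is the absolute incidence difference on a shared panel", {
  inc_a <- tibble::tibble(id = c("s1", "s2", "s3"), chrom = "1",
                          bp = c(1, 2, 3) * 1e5,
                          incidence = c(1, 0.5, 0.75))
  inc_b <- dplyr::mutate(inc_a, incidence = c(0, 0.5, 0.25))
  dh <- delta_h(inc_a, inc_b)
  expect_equal(dh$delta_h, c(1, 0, 0.5))
  expect_error(delta_h(inc_a, inc_b[1:2, ]), "panel")
})

test_that("top-quantile retention uses floor counts and positional tie-breaks", {
  set.seed(71)
  vals <- tibble::tibble(id = sprintf("s%05d", 1:48039),
                         chrom = as.character(rep(1:29, length.out = 48039)),
                         bp = rep(seq_len(2000), length.out = 48039) * 1e4,
                         fst = runif(48039))
  sc <- select_top(vals, 0.01)
  expect_equal(attr(sc, "n_selected"), 480L)
  expect_equal(sum(sc$selected), 480L)
  expect_equal(attr(sc, "threshold_value"), min(sc$fst[sc$selected]))
  expect_true(all(sort(sc$fst[sc$selected]) >=
                    max(sc$fst[!sc$selected & !is.na(sc$fst)])))

  # 100 distinct values at 1%: only the maximum
  v100 <- tibble::tibble(id = sprintf("s%03d", 1:100), chrom = "1",
                         bp = (1:100) * 1e5, fst = (1:100) / 100)
  s100 <- select_top(v100, 0.01)
  expect_equal(sc_sel <- s100$id[s100$selected], "s100")

  # 10 equal values at 20%: exactly two flagged, earliest positions first
  v10 <- tibble::tibble(id = sprintf("s%02d", 1:10), chrom = "1",
                        bp = (10:1) * 1e5, fst = rep(0.5, 10))
  s10 <- select_top(v10, 0.2)
  expect_equal(sum(s10$selected), 2L)
  expect_setequal(s10$id[s10$selected], c("s10", "s09"))  # smallest bp

  # permutation invariance of the flagged set
  sh <- v10[sample(10), ]
  expect_setequal(select_top(sh, 0.2)$id[select_top(sh, 0.2)$selected],
                  s10$id[s10$selected])
  expect_error(select_top(dplyr::mutate(v10, fst = NA_real_), 0.2),
               "undefined")
  expect_error(select_top(v10, 0), "fraction")
})

test_that("gene mapping equals a brute-force interval scan", {
  set.seed(72)
  genes <- tibble::tibble(
    chrom = as.character(sample(1:3, 30, TRUE)),
    start_bp = sample(seq(1e5, 9e6, by = 1e5), 30),
    name = sprintf("GENE%02d", 1:30))
  genes$end_bp <- genes$start_bp + sample(seq(5e4, 5e5, by = 5e4), 30, TRUE)
  snps <- tibble::tibble(id = sprintf("s%03d", 1:200),
                         chrom = as.character(sample(1:3, 200, TRUE)),
                         bp = sample(seq(1e5, 95e5, by = 1e4), 200),
                         fst = runif(200))
  scan <- select_top(snps, 0.25)
  mapped <- map_to_genes(scan, genes, flank_bp = 1e4)
  flagged <- scan[scan$selected, ]
  for (k in seq_len(nrow(flagged))) {
    want <- genes$name[genes$chrom == flagged$chrom[k] &
                         genes$start_bp - 1e4 <= flagged$bp[k] &
                         genes$end_bp + 1e4 >= flagged$bp[k]]
    got <- mapped$gene[mapped$id == flagged$id[k]]
    if (length(want)) {
      expect_setequal(got, want)
    } else {
      expect_true(all(is.na(got)))
    }
  }

  # single-SNP sanity: inside -> one pair, outside with no flank -> unannotated
  one <- select_top(tibble::tibble(id = c("x", "y"), chrom = "1",
                                   bp = c(2e5, 9e6), fst = c(1, 0.9)), 0.99)
  one$selected <- TRUE  # both flagged for the sanity check
  g1 <- tibble::tibble(chrom = "1", start_bp = 1e5, end_bp = 3e5,
                       name = "G")
  m1 <- map_to_genes(one, g1, flank_bp = 0)
  expect_equal(m1$gene[m1$id == "x"], "G")
  expect_true(is.na(m1$gene[m1$id == "y"]))
})

test_that("BED input converts to 1-based inclusive coordinates", {
  dir <- withr::local_tempdir()
  writeLines(c("1\t999\t2000\tGENE1", "2\t0\t100\tGENE2"),
             file.path(dir, "g.bed"))
  genes <- read_bed_genes(file.path(dir, "g.bed"))
  expect_equal(genes$start_bp, c(1000L, 1L))
  expect_equal(genes$end_bp, c(2000L, 100L))
})

test_that("consensus genes are the intersection of both scans' gene hits", {
  genes <- tibble::tibble(chrom = c("1", "1", "2"),
                          start_bp = c(1e5, 5e6, 1e5),
                          end_bp = c(1e6, 6e6, 1e6),
                          name = c("G1", "G2", "G3"))
  snps <- tibble::tibble(id = sprintf("s%02d", 1:40),
                         chrom = rep(c("1", "2"), each = 20),
                         bp = rep(seq(1e5, 96e5, by = 5e5), 2))
  on_g1 <- function(s) ifelse(s$chrom == "1" & s$bp < 1e6, 1, 0)
  on_g3 <- function(s) ifelse(s$chrom == "2" & s$bp < 1e6, 1, 0)
  fst_scan <- select_top(dplyr::mutate(snps, stat = on_g1(snps)),
                         0.05, statistic = "stat")
  dh_same <- select_top(dplyr::mutate(snps, stat = on_g1(snps)),
                        0.05, statistic = "stat")
  dh_disjoint <- select_top(dplyr::mutate(snps, stat = on_g3(snps)),
                            0.05, statistic = "stat")
  expect_equal(consensus_hits(fst_scan, dh_same, genes), "G1")
  expect_length(consensus_hits(fst_scan, dh_disjoint, genes), 0)
})

test_that("a strong trait locus is found by both scans when it also differs in ROH", {
  # power experiment: an allele-frequency shift (FST signal) plus
  # group-specific planted homozygosity (delta H signal) at the same gene
  set.seed(73)
  found <- 0
  n_trials <- 20
  for (tr in 1:n_trials) {
    cfg <- sim_config(breeds = "A", breed_sizes = 40, n_snps = 1500,
                      n_chroms = 2, chrom_length = 20e6, fst_per_breed = 0,
                      missing_rate = 0,
                      trait_loci = data.frame(chrom = 1, center_bp = 10e6,
                                              window_bp = 2e6, delta = 0.6),
                      seed = 7300 + tr)
    sim <- simulate_cohort(cfg)
    gm <- sim$genotypes
    pres <- sim$truth$trait$present
    abs_ <- sim$truth$trait$absent
    # plant a shared 3 Mb homozygous tract over the locus in the present group
    on_target <- which(gm$snps$chrom == "1" &
                         abs(gm$snps$bp - 10e6) <= 1.5e6)
    for (id in pres) {
      gm$calls[match(id, gm$samples$sample_id), on_target] <- 2L
    }
    segs <- detect_roh(gm)
    fst_scan <- select_top(snp_fst(gm, pres, abs_), 0.02)
    dh <- delta_h(roh_incidence(segs, gm, pres),
                  roh_incidence(segs, gm, abs_))
    dh_scan <- select_top(dh, 0.02)
    genes <- tibble::tibble(chrom = "1", start_bp = 9.5e6, end_bp = 10.5e6,
                            name = "TARGET")
    if ("TARGET" %in% consensus_hits(fst_scan, dh_scan, genes)) {
      found <- found + 1
    }
  }
  expect_gte(found, round(0.9 * n_trials))
})
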