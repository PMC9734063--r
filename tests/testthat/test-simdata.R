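test_that("bulk simulator is deterministic and validates its config", {
  cfg <- bulk_sim_config(n_regions = 3, n_genes = 100, n_replicates = 2,
                         seed = 5)
  s1 <- simulate_bulk(cfg)
  s2 <- simulate_bulk(cfg)
  expect_identical(s1, s2)
  # empty modules -> truth all null
  expect_true(all(s1$truth$trueStatus == "null"))
  expect_true(all(s1$truth$trueLog2FC == 0))
  # counts are non-negative integers with complete metadata
  expect_true(all(s1$sham$counts >= 0))
  expect_true(all(s1$sham$counts == round(s1$sham$counts)))
  expect_equal(nrow(s1$treated$meta), 3 * 2)
  expect_error(bulk_sim_config(n_regions = 0, n_genes = 10), "dimensions")
  expect_error(bulk_sim_config(n_replicates = 1), "replicates")
  expect_error(
    bulk_sim_config(n_genes = 50, modules = list(
      planted_module(c("g00001", "g00002"), c(R01 = 1)),
      planted_module(c("g00002"), c(R01 = 1)))),
    "disjoint")
})

test_that("planted bulk effects are recovered by direct moments", {
  # module of 100 genes, effect +1, mean 200, dispersion 0.05, n = 4:
  # per-gene empirical log2(mean treated / mean sham) averages to 1
  lfc_means <- vapply(1:50, function(s) {
    mod <- planted_module(bulk_gene_ids(150)[1:100], c(R01 = 1), "m")
    cfg <- bulk_sim_config(n_regions = 1, n_genes = 150, n_replicates = 4,
                           baseline_meanlog = log(200), baseline_sdlog = 0,
                           dispersion_fixed = 0.05, modules = list(mod),
                           regions = "R01", seed = s)
    sim <- simulate_bulk(cfg)
    mt <- rowMeans(sim$treated$counts[1:100, ])
    ms <- rowMeans(sim$sham$counts[1:100, ])
    mean(log2(mt / ms))
  }, numeric(1))
  expect_lt(abs(mean(lfc_means) - 1), 0.15)
})

test_that("moment estimates of planted effects tighten as replicates grow", {
  err <- vapply(c(4, 16, 64), function(n) {
    mod <- planted_module(bulk_gene_ids(100)[1:50], c(R01 = 1), "m")
    cfg <- bulk_sim_config(n_regions = 1, n_genes = 100,
                           n_replicates = n,
                           baseline_meanlog = log(200),
                           baseline_sdlog = 0, dispersion_fixed = 0.1,
                           sizefactor_sdlog = 0, modules = list(mod),
                           regions = "R01", seed = 9)
    sim <- simulate_bulk(cfg)
    lfc <- log2(rowMeans(sim$treated$counts[1:50, ]) /
                  rowMeans(sim$sham$counts[1:50, ]))
    mean(abs(lfc - 1))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("chip simulator geometry and effect coupling are correct", {
  bt <- data.frame(featureId = bulk_gene_ids(150), region = "R01",
                   trueLog2FC = c(rep(c(1, -1), 25), rep(0, 100)),
                   stringsAsFactors = FALSE)
  ch <- simulate_chip(bt, rho = 1, seed = 2)
  # rho = 1: promoter-peak effect equals the gene effect for every gene
  prom <- ch$truth[!is.na(ch$truth$promoterOf), ]
  expect_equal(prom$trueLog2FC,
               bt$trueLog2FC[match(prom$promoterOf, bt$featureId)])
  # BED intervals pairwise non-overlapping and inside [0, genomeSize)
  o <- order(ch$peaks$start)
  expect_true(all(ch$peaks$start[o][-1] >=
                    ch$peaks$end[o][-nrow(ch$peaks)]))
  expect_true(all(ch$peaks$start >= 0 & ch$peaks$end <= ch$genome_size))
  # promoter peaks inside +/- (1 kb + half width) of their TSS
  mid <- floor((ch$peaks$start + ch$peaks$end) / 2)
  pidx <- seq_len(nrow(ch$tss))
  expect_true(all(abs(mid[pidx] - ch$tss$pos) <= 1000))
  # decoys at least 10 kb from every TSS
  dec_mid <- mid[-pidx]
  min_d <- vapply(dec_mid, function(x) min(abs(ch$tss$pos - x)),
                  numeric(1))
  expect_true(all(min_d >= 10000))
  expect_error(simulate_chip(bt, rho = 1.2), "rho")
})

test_that("rho = 0 decouples peak effects from gene effects", {
  inside <- vapply(1:50, function(s) {
    bt <- data.frame(featureId = bulk_gene_ids(500), region = "R01",
                     trueLog2FC = with_seed_helper(s, stats::rnorm(500)),
                     stringsAsFactors = FALSE)
    ch <- simulate_chip(bt, rho = 0, n_decoys = 1, seed = s)
    prom <- ch$truth[!is.na(ch$truth$promoterOf), ]
    r <- cor(prom$trueLog2FC,
             bt$trueLog2FC[match(prom$promoterOf, bt$featureId)])
    abs(r) < 0.1
  }, logical(1))
  # analytic CI for the correlation of independent normals at n = 500:
  # sd ~ 1/sqrt(499) ~ 0.045, so |r| < 0.1 ~ 97% of the time
  expect_gte(sum(inside), 45)
})

test_that("scrna simulator is deterministic with exact cell counts", {
  cfg <- scrna_sim_config(n_types = 4, n_genes = 600,
                          cells_per_replicate = 50, n_replicates = 2,
                          regions = "dorDG", seed = 21)
  s1 <- simulate_scrna(cfg)
  s2 <- simulate_scrna(cfg)
  expect_identical(s1, s2)
  expect_equal(unname(table(s1$sham$meta$replicate)),
               rep(50, 2), ignore_attr = TRUE)
  expect_equal(ncol(s1$treated$counts), 50 * 2)
  expect_true(all(s1$sham$counts@x >= 0))
  # no planted shifts -> empty truth
  expect_equal(nrow(s1$truth), 0)
  expect_error(scrna_sim_config(n_replicates = 1), "replicates")
})

test_that("a planted proportion doubling is realized within 20%", {
  ratios <- vapply(1:20, function(s) {
    cfg <- scrna_sim_config(
      n_types = 6, n_genes = 600, cells_per_replicate = 100,
      n_replicates = 5, regions = "dorDG",
      proportion_shift = list(type = "type02", region = "dorDG",
                              factor = 2), seed = s)
    sc <- simulate_scrna(cfg)
    p_s <- mean(sc$sham$meta$trueType == "type02")
    p_t <- mean(sc$treated$meta$trueType == "type02")
    p_t / p_s
  }, numeric(1))
  # renormalization makes the expected realized ratio 2/(1+p); with mean
  # base proportions ~1/6 that is ~1.7-1.9, inside the 20% band around 2
  expect_lt(abs(mean(ratios) - 2), 0.4)
})

test_that("null scrna proportions show only sampling noise", {
  pvals <- vapply(1:20, function(s) {
    cfg <- scrna_sim_config(n_types = 4, n_genes = 400,
                            cells_per_replicate = 80, n_replicates = 5,
                            regions = "dorDG", seed = s + 400)
    sc <- simulate_scrna(cfg)
    comb <- combine_cells(sc$sham, sc$treated)
    pr <- test_proportions(comb$meta$trueType, comb$meta)
    pr$pValue
  }, numeric(4))
  # p-values approximately uniform: no mass collapse at the bottom
  expect_gt(mean(pvals > 0.05), 0.80)
  expect_gt(mean(pvals > 0.5), 0.30)
})
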