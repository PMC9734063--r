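# one small typed simulation shared across several blocks
sc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scrna_sim_config(
        n_types = 6, n_genes = 800, cells_per_replicate = 150,
        n_replicates = 5, regions = "dorDG",
        module_shift = list(type = "type01", region = "dorDG",
                            log2fc = 1),
        seed = 5)
      sc <- simulate_scrna(cfg)
      norm <- qc_and_normalize(combine_cells(sc$sham, sc$treated),
                               min_genes = 200)
      cache <<- list(sc = sc, norm = norm,
                     labels = norm$meta$trueType)
    }
    cache
  }
})

test_that("QC removes poor cells, rare genes, and is idempotent", {
  fx <- sc_fixture()
  raw <- combine_cells(fx$sc$sham, fx$sc$treated)
  # a cell with few detected genes is removed
  crip <- raw
  crip$counts[, 1] <- 0
  crip$counts[1:50, 1] <- 1
  norm <- qc_and_normalize(crip, min_genes = 200)
  expect_false(raw$meta$cell[1] %in% norm$meta$cell)
  # depth invariance: proportional cells get identical normalized vectors
  two <- raw$counts[, 2, drop = FALSE]
  m <- cbind(two, two * 3)
  colnames(m) <- c("c1", "c2")
  cm <- cell_matrix(m, data.frame(cell = c("c1", "c2"), replicate = "r",
                                  condition = "sham", region = "x"))
  n2 <- qc_and_normalize(cm, min_genes = 1, min_cells_per_gene = 1)
  expect_equal(as.numeric(n2$logcounts[, 1]),
               as.numeric(n2$logcounts[, 2]), tolerance = 1e-12)
  # idempotence on its own output
  again <- qc_and_normalize(fx$norm, min_genes = 200)
  expect_equal(as.matrix(again$logcounts), as.matrix(fx$norm$logcounts))
  expect_equal(again$meta$cell, fx$norm$meta$cell)
  # all cells failing -> error
  expect_error(qc_and_normalize(raw, min_genes = 1e5), "all cells")
})

test_that("mitochondrial fraction drives cell removal", {
  fx <- sc_fixture()
  raw <- combine_cells(fx$sc$sham, fx$sc$treated)
  mito <- startsWith(rownames(raw$counts), "mt-")
  hot <- raw
  hot$counts[mito, 3] <- hot$counts[mito, 3] + 2000
  norm <- qc_and_normalize(hot, min_genes = 200, max_mito = 0.2)
  expect_false(raw$meta$cell[3] %in% norm$meta$cell)
})

test_that("two-step typing recovers planted labels", {
  cfg <- scrna_sim_config(n_types = 6, n_genes = 800,
                          cells_per_replicate = 100, n_replicates = 5,
                          regions = "dorDG", seed = 11)
  sc <- simulate_scrna(cfg)
  norm <- qc_and_normalize(combine_cells(sc$sham, sc$treated),
                           min_genes = 200)
  ty <- assign_cell_types(norm, sc$reference, seed = 2)
  unamb <- ty$type != "ambiguous"
  acc <- mean(ty$type[unamb] == norm$meta$trueType[unamb])
  expect_gte(acc, 0.9)
  # a cell equal to a centroid gets that label, unflagged
  shared <- rownames(sc$reference)
  pure <- norm
  pure$logcounts[shared, 5] <- sc$reference[, "type03"]
  ty2 <- assign_cell_types(pure, sc$reference, seed = 2)
  expect_equal(ty2$type[5], "type03")
  # a flat profile is ambiguous
  flat <- norm
  flat$logcounts[shared, 7] <- 0
  ty3 <- assign_cell_types(flat, sc$reference, seed = 2)
  expect_equal(ty3$type[7], "ambiguous")
  expect_error(assign_cell_types(
    subset_cells(norm, genes = setdiff(rownames(norm$logcounts),
                                       shared)),
    sc$reference), "marker")
})

test_that("exact rank-sum matches enumeration and handles ties", {
  # fully separated 5 vs 5 -> p = 2/252
  x <- c(0.20, 0.22, 0.21, 0.19, 0.23)
  y <- c(0.10, 0.12, 0.11, 0.13, 0.09)
  expect_equal(rank_sum_test(x, y)$pValue, 2 / choose(10, 5))
  # identical groups -> p = 1
  expect_equal(rank_sum_test(rep(0.1, 4), rep(0.1, 4))$pValue, 1)
  # tie-free instances agree with the standard exact implementation
  set.seed(31)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- rnorm(n1); b <- rnorm(n2)
    mine <- rank_sum_test(a, b)$pValue
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
  # tied instances agree with the independent recursive oracle
  for (i in 1:8) {
    a <- sample(1:4, 5, replace = TRUE)
    b <- sample(1:4, 5, replace = TRUE)
    expect_equal(rank_sum_test(a, b)$pValue, oracle_rank_sum_p(a, b),
                 tolerance = 1e-10)
  }
  # large-sample path is close to the exact path near the boundary
  a <- rnorm(8); b <- rnorm(8) + 1.2
  p_apx <- rank_sum_test(a, b)$pValue
  p_ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_apx, p_ref, tolerance = 1e-10)
})

test_that("proportion tests flag only the shifted type", {
  cfg <- scrna_sim_config(
    n_types = 6, n_genes = 800, cells_per_replicate = 100,
    n_replicates = 5, regions = "dorDG",
    proportion_shift = list(type = "type03", region = "dorDG",
                            factor = 2), seed = 11)
  sc <- simulate_scrna(cfg)
  comb <- combine_cells(sc$sham, sc$treated)
  pr <- test_proportions(comb$meta$trueType, comb$meta)
  expect_lte(pr$pValue[pr$cellType == "type03"], 0.05)
  expect_equal(pr$direction[pr$cellType == "type03"], "up")
  # replicate proportions sum to one across types
  prop <- attr(pr, "proportions")
  expect_equal(unname(rowSums(prop)), rep(1, nrow(prop)))
  expect_error(test_proportions(
    comb$meta$trueType[comb$meta$replicate %in%
                         unique(comb$meta$replicate)[1:2]],
    comb$meta[comb$meta$replicate %in%
                unique(comb$meta$replicate)[1:2], ]),
    "replicates")
})

test_that("pseudo-bulk DE recovers a planted two-fold module shift", {
  fx <- sc_fixture()
  de <- pseudobulk_de(fx$norm, fx$labels)
  d1 <- de[["type01"]]
  mg <- intersect(fx$sc$module_genes, d1$featureId)
  up <- d1$featureId[!is.na(d1$qValue) & d1$qValue < 0.2 & d1$log2FC > 0]
  expect_gte(mean(mg %in% up), 0.7)
  expect_lte(mean(!(up %in% mg)), 0.2)
  # a gene with identical unit means in both conditions is ns at lfc 0
  flat <- fx$norm
  flat$logcounts[1, ] <- 0.7
  dflat <- pseudobulk_de(flat, fx$labels)[["type02"]]
  expect_equal(dflat$log2FC[1], 0)
  expect_equal(dflat$status[1], "ns")
  # types without 2 qualifying units per condition are excluded
  lab2 <- fx$labels
  lab2[lab2 == "type05" & fx$norm$meta$condition == "treated"] <- "type06"
  de2 <- pseudobulk_de(fx$norm, lab2)
  expect_true("type05" %in% attr(de2, "excluded"))
})

test_that("module scores isolate the shifted cell type", {
  fx <- sc_fixture()
  ms <- score_gene_module(fx$norm, fx$sc$module_genes, fx$labels,
                          seed = 4)
  bt <- ms$by_type
  expect_equal(bt$cellType[which.min(bt$qValue)], "type01")
  expect_gt(bt$delta[bt$cellType == "type01"], 0)
  expect_true(all(bt$qValue >= bt$pValue))
  # constructed shift: adding c to set genes in treated cells of a type
  # moves that type's delta by ~c and makes it minimal-q
  set.seed(8)
  null_set <- sample(setdiff(rownames(fx$norm$logcounts),
                             fx$sc$module_genes), 30)
  shifted <- fx$norm
  sel <- fx$labels == "type04" & fx$norm$meta$condition == "treated"
  shifted$logcounts[null_set, sel] <-
    shifted$logcounts[null_set, sel] + 0.5
  ms2 <- score_gene_module(shifted, null_set, fx$labels, seed = 4)
  bt2 <- ms2$by_type
  expect_equal(bt2$cellType[which.min(bt2$qValue)], "type04")
  expect_equal(bt2$delta[bt2$cellType == "type04"], 0.5,
               tolerance = 0.1)
  expect_error(score_gene_module(fx$norm, c("zz1", "zz2"), fx$labels),
               "fewer than 5")
})

test_that("module scores are null when no shift is planted", {
  cfg <- scrna_sim_config(n_types = 4, n_genes = 600,
                          cells_per_replicate = 80, n_replicates = 5,
                          regions = "dorDG", seed = 77)
  sc <- simulate_scrna(cfg)
  norm <- qc_and_normalize(combine_cells(sc$sham, sc$treated),
                           min_genes = 150)
  labels <- norm$meta$trueType
  genes <- rownames(norm$logcounts)
  ok <- vapply(1:50, function(s) {
    set.seed(s + 900)
    set <- sample(genes, 20)
    bt <- score_gene_module(norm, set, labels, seed = s)$by_type
    min(bt$qValue) > 0.05
  }, logical(1))
  expect_gte(sum(ok), 45)
})

test_that("regulon activity is a normalized recovery-curve area", {
  fx <- sc_fixture()
  norm <- fx$norm
  G <- nrow(norm$logcounts)
  regs <- list(top = list(tf = rownames(norm$logcounts)[1],
                          targets = rownames(norm$logcounts)[2:10]))
  # construct one cell whose regulon genes occupy exactly the top ranks
  hot <- norm
  hot$logcounts[, 1] <- 0
  hot$logcounts[1:10, 1] <- 10 - (1:10) / 100
  ra <- regulon_activity_and_diff(hot, regs, fx$labels)
  expect_equal(unname(ra$activity["top", 1]), 1)
  # and one with regulon genes at zero expression -> activity 0
  cold <- norm
  cold$logcounts[1:10, 2] <- 0
  cold$logcounts[11:G, 2] <- pmax(as.numeric(cold$logcounts[11:G, 2]),
                                  0.01)
  ra2 <- regulon_activity_and_diff(cold, regs, fx$labels)
  expect_equal(unname(ra2$activity["top", 2]), 0)
  # activity bounded in [0, 1] everywhere
  expect_true(all(ra$activity >= 0 & ra$activity <= 1))
  expect_error(
    regulon_activity_and_diff(norm, list(tiny = list(tf = "zz",
                                                     targets = "zz2")),
                              fx$labels), "fewer than 5")
})

test_that("random regulons score at the uniform-ranking expectation", {
  fx <- sc_fixture()
  norm <- fx$norm
  genes <- rownames(norm$logcounts)
  G <- length(genes)
  m <- ceiling(0.05 * G)
  R <- 20
  # permutation oracle: mean activity of a random 20-gene regulon over
  # random rankings of one cell
  set.seed(55)
  perm_act <- vapply(1:2000, function(i) {
    pos <- sort(sample(G, R))
    pos <- pos[pos <= m]
    max_area <- R * m - R * (R - 1) / 2
    if (length(pos) == 0) 0 else sum(m - pos + 1) / max_area
  }, numeric(1))
  regs <- lapply(1:20, function(i)
    list(tf = sample(genes, 1), targets = sample(genes, R - 1)))
  names(regs) <- sprintf("rnd%02d", 1:20)
  ra <- regulon_activity_and_diff(norm, regs, fx$labels)
  obs <- mean(ra$activity)
  expect_lt(abs(obs - mean(perm_act)),
            3 * stats::sd(perm_act) / sqrt(20))
})

test_that("ligand-receptor specificities and deltas behave", {
  fx <- sc_fixture()
  norm <- fx$norm
  labels <- fx$labels
  genes <- rownames(norm$logcounts)
  # a ligand expressed in exactly one type has specificity 1 there
  lig <- genes[50]; rec <- genes[60]
  mono <- norm
  mono$logcounts[lig, ] <- 0
  mono$logcounts[lig, labels == "type02"] <- 1
  mono$counts[lig, ] <- 0
  mono$counts[lig, labels == "type02"] <- 1
  cat1 <- data.frame(ligand = lig, receptor = rec,
                     stringsAsFactors = FALSE)
  lr <- lr_edges_and_diff(mono, labels, cat1, min_detect = 0)
  w <- lr[lr$sender == "type02", ]
  other <- lr[lr$sender != "type02", ]
  expect_true(all(other$weightSham == 0 & other$weightTreated == 0))
  expect_true(nrow(w) > 0)
  # specificities sum to 1 over types: the edge weights over all
  # sender x receiver combinations of one expressed pair sum to
  # (sum lig spec) x (sum rec spec) = 1
  lig2 <- genes[70]; rec2 <- genes[80]
  cat2 <- data.frame(ligand = lig2, receptor = rec2,
                     stringsAsFactors = FALSE)
  lr2 <- lr_edges_and_diff(norm, labels, cat2, min_detect = 0)
  expect_equal(sum(lr2$weightSham), 1, tolerance = 1e-8)
  expect_equal(sum(lr2$weightTreated), 1, tolerance = 1e-8)
  expect_error(lr_edges_and_diff(norm, labels,
                                 data.frame(ligand = "zz",
                                            receptor = "zz2")),
               "empty ligand-receptor catalogue")
})

test_that("the planted LR edge carries the largest delta", {
  cfg <- scrna_sim_config(
    n_types = 6, n_genes = 800, cells_per_replicate = 100,
    n_replicates = 5, regions = "dorDG",
    lr_shift = list(sender = "type04", region = "dorDG",
                    log2fc = 1.5, pair = 1L), seed = 9)
  sc <- simulate_scrna(cfg)
  norm <- qc_and_normalize(combine_cells(sc$sham, sc$treated),
                           min_genes = 200)
  lr <- lr_edges_and_diff(norm, norm$meta$trueType, sc$lr_pairs)
  expect_equal(lr$ligand[1], sc$lr_pairs$ligand[1])
  expect_equal(lr$sender[1], "type04")
})
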