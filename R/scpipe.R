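#' Combine two cell matrices column-wise
#' @param a,b [cell_matrix()] objects over identical genes.
#' @return A `cell_matrix` with the cells of both inputs.
#' @export
combine_cells <- function(a, b) {
  stopifnot(inherits(a, "cell_matrix"), inherits(b, "cell_matrix"))
  if (!identical(rownames(a$counts), rownames(b$counts)))
    stop("gene universes differ")
  lc <- if (!is.null(a$logcounts) && !is.null(b$logcounts))
    cbind(a$logcounts, b$logcounts) else NULL
  cell_matrix(cbind(a$counts, b$counts), rbind(a$meta, b$meta),
              logcounts = lc)
}

#' Subset a cell matrix by genes and/or cells
#' @param x A [cell_matrix()].
#' @param genes,cells Index vectors; `NULL` keeps everything.
#' @return A `cell_matrix`.
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  cts <- x$counts
  lc <- x$logcounts
  if (!is.null(genes)) {
    cts <- cts[genes, , drop = FALSE]
    if (!is.null(lc)) lc <- lc[genes, , drop = FALSE]
  }
  if (!is.null(cells)) {
    cts <- cts[, cells, drop = FALSE]
    if (!is.null(lc)) lc <- lc[, cells, drop = FALSE]
  }
  meta <- x$meta[match(colnames(cts), x$meta$cell), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = cts, meta = meta, logcounts = lc),
            class = "cell_matrix")
}

#' QC filtering and depth normalization of single-cell counts
#'
#' Removes cells with fewer than `min_genes` detected genes or a
#' mitochondrial fraction above `max_mito`, then removes genes detected in
#' fewer than `min_cells_per_gene` of the retained cells, and adds a
#' log-normalized layer `log(1 + 1e4 * count / totalCounts)`. Per-cell QC
#' statistics (`totalCounts`, `nGenesDetected`, `mitoFraction`) are
#' computed at entry and stored in the metadata; if already present (e.g.
#' when re-running on QC output) they are reused, which makes the
#' operation idempotent.
#'
#' @param x A [cell_matrix()].
#' @param min_genes Minimum detected genes per cell (default 500).
#' @param max_mito Maximum mitochondrial count fraction (default 0.20).
#' @param min_cells_per_gene Minimum cells a gene must be detected in
#'   (default 3).
#' @param mito_prefix Gene-id prefix marking mitochondrial genes.
#' @return A `cell_matrix` with filtered counts, augmented metadata and a
#'   `logcounts` layer.
#' @export
qc_and_normalize <- function(x, min_genes = 500, max_mito = 0.20,
                             min_cells_per_gene = 3, mito_prefix = "mt-") {
  stopifnot(inherits(x, "cell_matrix"))
  cts <- x$counts
  meta <- x$meta
  if (!all(c("totalCounts", "nGenesDetected", "mitoFraction") %in%
           names(meta))) {
    meta$totalCounts <- Matrix::colSums(cts)
    meta$nGenesDetected <- Matrix::colSums(cts > 0)
    mito <- startsWith(rownames(cts), mito_prefix)
    meta$mitoFraction <- if (any(mito))
      Matrix::colSums(cts[mito, , drop = FALSE]) / pmax(meta$totalCounts, 1)
    else 0
  }
  keep_cell <- meta$nGenesDetected >= min_genes &
    meta$mitoFraction <= max_mito
  if (!any(keep_cell)) stop("all cells removed by QC")
  cts <- cts[, keep_cell, drop = FALSE]
  meta <- meta[keep_cell, , drop = FALSE]
  keep_gene <- Matrix::rowSums(cts > 0) >= min_cells_per_gene
  cts <- cts[keep_gene, , drop = FALSE]
  lc <- cts
  lc@x <- log1p(1e4 * cts@x / rep.int(meta$totalCounts,
                                      diff(cts@p)))
  rownames(meta) <- NULL
  structure(list(counts = cts, meta = meta, logcounts = lc),
            class = "cell_matrix")
}

#' Two-step cell typing against reference centroids
#'
#' Step 1 (supervised): each cell's marker-gene profile is correlated
#' (Spearman) with every reference centroid; the cell takes the argmax
#' label if the best correlation reaches `min_corr`, otherwise
#' `"ambiguous"`. Step 2 (unsupervised): k-means (k = number of reference
#' types) on the top `n_pcs` principal components of the normalized
#' matrix; cells whose supervised label disagrees with the majority
#' supervised label of their unsupervised cluster are flagged
#' `lowConfidence`.
#'
#' @param x A QC-normalized [cell_matrix()] (needs `logcounts`).
#' @param reference Matrix of centroids: marker genes x types, in
#'   log-normalized units (e.g. the `reference` element of
#'   [simulate_scrna()] output).
#' @param min_corr Minimum correlation for a supervised call (default
#'   0.2).
#' @param n_pcs Principal components for the unsupervised step.
#' @param seed Seed for the k-means restarts.
#' @return Data frame `cell`, `type`, `bestCorr`, `cluster`,
#'   `lowConfidence`.
#' @export
assign_cell_types <- function(x, reference, min_corr = 0.2, n_pcs = 20,
                              seed = 1L) {
  stopifnot(inherits(x, "cell_matrix"))
  if (is.null(x$logcounts)) stop("run qc_and_normalize first")
  shared <- intersect(rownames(reference), rownames(x$logcounts))
  if (length(shared) == 0) stop("no marker genes shared with the matrix")
  prof <- as.matrix(x$logcounts[shared, , drop = FALSE])
  cors <- suppressWarnings(
    stats::cor(prof, reference[shared, , drop = FALSE],
               method = "spearman"))
  cors[is.na(cors)] <- -1
  best <- max.col(cors, ties.method = "first")
  best_corr <- cors[cbind(seq_len(nrow(cors)), best)]
  type <- colnames(reference)[best]
  type[best_corr < min_corr] <- "ambiguous"

  dense <- as.matrix(x$logcounts)
  pcs <- tryCatch({
    pr <- stats::prcomp(t(dense), center = TRUE, scale. = FALSE,
                        rank. = n_pcs)
    pr$x
  }, error = function(e) t(dense))
  k <- ncol(reference)
  cl <- with_local_seed(seed,
    stats::kmeans(pcs, centers = min(k, nrow(pcs) - 1), nstart = 10,
                  iter.max = 50)$cluster)
  low <- logical(length(type))
  for (c_id in unique(cl)) {
    mem <- which(cl == c_id)
    lbl <- type[mem]
    lbl <- lbl[lbl != "ambiguous"]
    if (length(lbl) == 0) next
    maj <- names(sort(table(lbl), decreasing = TRUE))[1]
    low[mem] <- type[mem] != "ambiguous" & type[mem] != maj
  }
  data.frame(cell = colnames(x$logcounts), type = type,
             bestCorr = best_corr, cluster = cl,
             lowConfidence = low, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Exact/approximate two-sided Wilcoxon rank-sum p-value
#'
#' Uses the exact conditional distribution (enumeration of all group
#' assignments of the pooled average ranks, so ties are handled exactly)
#' when the pooled size is at most 12, and the normal approximation with
#' tie correction otherwise. Two-sided via the distance of the rank sum
#' from its conditional mean.
#'
#' @param x,y Numeric vectors (the two groups).
#' @return List `statistic` (rank sum of `x`), `pValue`.
#' @export
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n <= 12) {
    combs <- utils::combn(n, n1)
    ws <- colSums(matrix(r[combs], nrow = n1))
    mu <- mean(ws)
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(statistic = w, pValue = 1))
    z <- (abs(w - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  list(statistic = w, pValue = p)
}

#' Per-type proportion shifts between conditions
#'
#' For every cell type, computes per-replicate proportions within each
#' condition and compares conditions with a two-sided exact Wilcoxon
#' rank-sum test across replicates. Types absent from a replicate enter
#' with proportion zero; types with zero cells everywhere are skipped
#' (reported in the `skipped` attribute).
#'
#' @param labels Character vector of cell-type labels, one per cell.
#' @param meta Cell metadata (`cell`, `replicate`, `condition`).
#' @return Data frame `cellType`, `meanSham`, `meanTreated`, `direction`,
#'   `pValue`, plus attribute `proportions` (replicate x type matrix).
#' @export
test_proportions <- function(labels, meta) {
  stopifnot(length(labels) == nrow(meta))
  reps <- unique(meta[, c("replicate", "condition")])
  tab <- table(factor(reps$condition, levels = c("sham", "treated")))
  if (any(tab < 2))
    stop("at least 2 replicates per condition are required")
  types <- sort(unique(labels))
  prop <- t(vapply(reps$replicate, function(rp) {
    lab <- labels[meta$replicate == rp]
    as.numeric(table(factor(lab, levels = types)) / length(lab))
  }, numeric(length(types))))
  dimnames(prop) <- list(reps$replicate, types)
  skipped <- types[colSums(prop) == 0]
  res <- lapply(setdiff(types, skipped), function(tp) {
    ps <- prop[reps$condition == "sham", tp]
    pt <- prop[reps$condition == "treated", tp]
    tst <- rank_sum_test(pt, ps)
    data.frame(cellType = tp, meanSham = mean(ps), meanTreated = mean(pt),
               direction = ifelse(mean(pt) >= mean(ps), "up", "down"),
               pValue = tst$pValue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "proportions") <- prop
  attr(out, "skipped") <- skipped
  out
}

#' Pseudo-bulk differential expression per cell type
#'
#' Cells of one type are aggregated by replicate into an averaged
#' pseudo-bulk profile (mean of the log-normalized layer); replicates
#' with fewer than `min_cells` cells of the type are dropped, and a type
#' is tested only when both conditions keep at least 2 units. Per gene, a
#' Welch t-test compares treated and sham units; the log2 fold-change is
#' computed from the unit means with a pseudocount of 0.1; BH correction
#' is applied per type.
#'
#' @param x A QC-normalized [cell_matrix()].
#' @param labels Cell-type labels, one per cell.
#' @param min_cells Minimum cells per (type, replicate) unit (default 10).
#' @param fc_threshold,q_threshold Status thresholds (defaults
#'   `log2(1.25)` and 0.2).
#' @return Named list (type -> differential data frame `featureId`,
#'   `baseMean`, `log2FC`, `pValue`, `qValue`, `status`); excluded types
#'   are reported in the `excluded` attribute.
#' @export
pseudobulk_de <- function(x, labels, min_cells = 10,
                          fc_threshold = log2(1.25), q_threshold = 0.2) {
  stopifnot(inherits(x, "cell_matrix"), length(labels) == ncol(x$counts))
  if (is.null(x$logcounts)) stop("run qc_and_normalize first")
  meta <- x$meta
  types <- sort(unique(labels))
  excluded <- character()
  out <- list()
  for (tp in types) {
    sel <- labels == tp
    units <- list(); unit_cond <- character()
    for (rp in unique(meta$replicate)) {
      cells <- which(sel & meta$replicate == rp)
      if (length(cells) < min_cells) next
      units[[length(units) + 1L]] <-
        Matrix::rowMeans(x$logcounts[, cells, drop = FALSE])
      unit_cond <- c(unit_cond, meta$condition[cells[1]])
    }
    if (sum(unit_cond == "sham") < 2 || sum(unit_cond == "treated") < 2) {
      excluded <- c(excluded, tp)
      next
    }
    um <- do.call(cbind, units)
    is_t <- unit_cond == "treated"
    m1 <- rowMeans(um[, is_t, drop = FALSE])
    m0 <- rowMeans(um[, !is_t, drop = FALSE])
    v1 <- apply(um[, is_t, drop = FALSE], 1, stats::var)
    v0 <- apply(um[, !is_t, drop = FALSE], 1, stats::var)
    n1 <- sum(is_t); n0 <- sum(!is_t)
    se2 <- v1 / n1 + v0 / n0
    tstat <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / (pmax((v1 / n1)^2 / (n1 - 1) +
                                 (v0 / n0)^2 / (n0 - 1), 1e-300)),
                 n1 + n0 - 2)
    p <- 2 * stats::pt(-abs(tstat), df = df)
    p[se2 == 0 & m1 != m0] <- 0
    p[se2 == 0 & m1 == m0] <- 1
    q <- bh_adjust(p)
    lfc <- log2((m1 + 0.1) / (m0 + 0.1))
    status <- rep("ns", length(p))
    status[lfc >= fc_threshold & q <= q_threshold] <- "up"
    status[lfc <= -fc_threshold & q <= q_threshold] <- "down"
    out[[tp]] <- data.frame(featureId = rownames(um),
                            baseMean = (m1 + m0) / 2,
                            log2FC = lfc, pValue = p, qValue = q,
                            status = status, stringsAsFactors = FALSE,
                            row.names = NULL)
  }
  attr(out, "excluded") <- excluded
  out
}

#' Control-matched gene-module scores per cell
#'
#' For every cell, the module score is the mean log-normalized expression
#' of the set genes minus the mean over control genes drawn (seeded) from
#' the same average-expression bins, `n_control` controls per set gene.
#' Per cell type, treated and sham scores are compared with the rank-sum
#' test and BH-corrected across types.
#'
#' @param x A QC-normalized [cell_matrix()].
#' @param set Character vector of gene ids (at least 5 must be present).
#' @param labels Cell-type labels.
#' @param n_bins Expression bins (default 25).
#' @param n_control Controls sampled per set gene (default 100).
#' @param seed Seed for control sampling.
#' @return List: `cell_scores` (named per-cell score vector), `by_type`
#'   (data frame `cellType`, `meanSham`, `meanTreated`, `delta`,
#'   `pValue`, `qValue`).
#' @export
score_gene_module <- function(x, set, labels, n_bins = 25,
                              n_control = 100, seed = 1L) {
  stopifnot(inherits(x, "cell_matrix"))
  if (is.null(x$logcounts)) stop("run qc_and_normalize first")
  genes <- rownames(x$logcounts)
  set <- intersect(set, genes)
  if (length(set) < 5)
    stop("fewer than 5 set genes present in the matrix")
  avg <- Matrix::rowMeans(x$logcounts)
  bin <- cut(rank(avg, ties.method = "first"),
             breaks = n_bins, labels = FALSE)
  names(bin) <- genes
  ctrl <- with_local_seed(seed, {
    unlist(lapply(set, function(g) {
      pool <- genes[bin == bin[[g]]]
      sample(pool, min(n_control, length(pool)), replace = FALSE)
    }))
  })
  set_score <- Matrix::colMeans(x$logcounts[set, , drop = FALSE])
  ctrl_score <- Matrix::colMeans(x$logcounts[ctrl, , drop = FALSE])
  score <- set_score - ctrl_score
  meta <- x$meta
  types <- sort(unique(labels))
  rows <- lapply(types, function(tp) {
    s_sham <- score[labels == tp & meta$condition == "sham"]
    s_trt <- score[labels == tp & meta$condition == "treated"]
    if (length(s_sham) < 2 || length(s_trt) < 2) return(NULL)
    tst <- rank_sum_test(s_trt, s_sham)
    data.frame(cellType = tp, meanSham = mean(s_sham),
               meanTreated = mean(s_trt),
               delta = mean(s_trt) - mean(s_sham),
               pValue = tst$pValue, stringsAsFactors = FALSE)
  })
  by_type <- do.call(rbind, rows)
  by_type$qValue <- bh_adjust(by_type$pValue)
  rownames(by_type) <- NULL
  list(cell_scores = score, by_type = by_type)
}

# area under the recovery curve of regulon genes within the top-ranked
# genes of one cell, normalized by the maximal achievable area
aucell_one <- function(positions, m, R) {
  pos <- positions[positions <= m]
  if (length(pos) == 0) return(0)
  max_area <- R * m - R * (R - 1) / 2
  if (R > m) max_area <- m * (m + 1) / 2
  sum(m - pos + 1) / max_area
}

#' Regulon activity per cell and differential activity per type
#'
#' Activity of a regulon (TF plus targets) in a cell is the area under
#' the recovery curve of regulon genes within the top
#' `ceiling(top_fraction * G)` expression-ranked genes of that cell,
#' normalized to `[0, 1]` by the maximal achievable area (expression ties
#' broken deterministically by gene id). Per cell type, treated and sham
#' activities are compared with the rank-sum test, BH-corrected across
#' regulons within the type.
#'
#' @param x A QC-normalized [cell_matrix()].
#' @param regulons Named list of `list(tf = , targets = )`.
#' @param labels Cell-type labels.
#' @param top_fraction Fraction of the ranking considered (default 0.05).
#' @param q_threshold Significance threshold on the BH q-value (default
#'   0.1).
#' @return List: `activity` (regulon x cell matrix), `by_type` (data
#'   frame `cellType`, `regulon`, `meanSham`, `meanTreated`, `log2FC`,
#'   `pValue`, `qValue`, `significant`).
#' @export
regulon_activity_and_diff <- function(x, regulons, labels,
                                      top_fraction = 0.05,
                                      q_threshold = 0.1) {
  stopifnot(inherits(x, "cell_matrix"))
  if (is.null(x$logcounts)) stop("run qc_and_normalize first")
  genes <- rownames(x$logcounts)
  G <- length(genes)
  m <- ceiling(top_fraction * G)
  reg_genes <- lapply(regulons, function(r)
    intersect(unique(c(r$tf, r$targets)), genes))
  small <- lengths(reg_genes) < 5
  if (all(small)) stop("every regulon has fewer than 5 genes in the matrix")
  reg_genes <- reg_genes[!small]
  reg_idx <- lapply(reg_genes, function(g) match(g, genes))
  dense <- as.matrix(x$logcounts)
  n_cells <- ncol(dense)
  act <- matrix(0, length(reg_idx), n_cells,
                dimnames = list(names(reg_idx), colnames(dense)))
  for (ci in seq_len(n_cells)) {
    r_of_gene <- integer(G)
    r_of_gene[order(-dense[, ci], seq_len(G))] <- seq_len(G)
    for (ri in seq_along(reg_idx)) {
      pos <- r_of_gene[reg_idx[[ri]]]
      act[ri, ci] <- aucell_one(pos, m, length(reg_idx[[ri]]))
    }
  }
  meta <- x$meta
  types <- sort(unique(labels))
  rows <- list()
  for (tp in types) {
    sel_s <- labels == tp & meta$condition == "sham"
    sel_t <- labels == tp & meta$condition == "treated"
    if (sum(sel_s) < 2 || sum(sel_t) < 2) next
    block <- lapply(rownames(act), function(rg) {
      a_s <- act[rg, sel_s]; a_t <- act[rg, sel_t]
      tst <- rank_sum_test(a_t, a_s)
      data.frame(cellType = tp, regulon = rg,
                 meanSham = mean(a_s), meanTreated = mean(a_t),
                 log2FC = log2((mean(a_t) + 0.01) / (mean(a_s) + 0.01)),
                 pValue = tst$pValue, stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, block)
    block$qValue <- bh_adjust(block$pValue)
    rows[[tp]] <- block
  }
  by_type <- do.call(rbind, rows)
  by_type$significant <- by_type$qValue < q_threshold
  rownames(by_type) <- NULL
  list(activity = act, by_type = by_type)
}

#' Differential ligand-receptor edges between conditions
#'
#' For each condition, the specificity of a ligand for a sender type is
#' its mean log-normalized expression in that type divided by the sum of
#' mean expressions over all types (0/0 treated as 0); receptor
#' specificity is analogous. The weight of an edge (ligand, receptor,
#' sender, receiver) is the product of the two specificities, and the
#' differential signal is `delta = weight_treated - weight_sham`. An edge
#' is retained only when the ligand is detected in at least
#' `min_detect` of sender cells and the receptor in at least `min_detect`
#' of receiver cells in at least one condition.
#'
#' @param x A QC-normalized [cell_matrix()] with both conditions.
#' @param labels Cell-type labels.
#' @param catalogue Data frame with columns `ligand`, `receptor`.
#' @param min_detect Minimum detection fraction (default 0.10).
#' @return Data frame sorted by decreasing `|delta|`: `ligand`,
#'   `receptor`, `sender`, `receiver`, `weightSham`, `weightTreated`,
#'   `delta`; attribute `skipped_pairs` counts catalogue pairs absent
#'   from the matrix.
#' @export
lr_edges_and_diff <- function(x, labels, catalogue, min_detect = 0.10) {
  stopifnot(inherits(x, "cell_matrix"))
  if (is.null(x$logcounts)) stop("run qc_and_normalize first")
  genes <- rownames(x$logcounts)
  present <- catalogue$ligand %in% genes & catalogue$receptor %in% genes
  skipped <- sum(!present)
  cat2 <- catalogue[present, , drop = FALSE]
  if (nrow(cat2) == 0) stop("empty ligand-receptor catalogue after intersection")
  meta <- x$meta
  types <- sort(unique(labels))
  conds <- c("sham", "treated")
  gene_univ <- unique(c(cat2$ligand, cat2$receptor))
  mean_expr <- list(); det_frac <- list()
  for (cd in conds) {
    me <- sapply(types, function(tp) {
      cells <- labels == tp & meta$condition == cd
      if (!any(cells)) return(rep(0, length(gene_univ)))
      Matrix::rowMeans(x$logcounts[gene_univ, cells, drop = FALSE])
    })
    de <- sapply(types, function(tp) {
      cells <- labels == tp & meta$condition == cd
      if (!any(cells)) return(rep(0, length(gene_univ)))
      Matrix::rowMeans(x$counts[gene_univ, cells, drop = FALSE] > 0)
    })
    rownames(me) <- gene_univ; rownames(de) <- gene_univ
    mean_expr[[cd]] <- me; det_frac[[cd]] <- de
  }
  spec <- lapply(conds, function(cd) {
    me <- mean_expr[[cd]]
    tot <- rowSums(me)
    sw <- sweep(me, 1, ifelse(tot > 0, tot, 1), "/")
    sw[tot == 0, ] <- 0
    sw
  })
  names(spec) <- conds
  combos <- expand.grid(pair = seq_len(nrow(cat2)),
                        sender = types, receiver = types,
                        stringsAsFactors = FALSE)
  lig <- cat2$ligand[combos$pair]; rec <- cat2$receptor[combos$pair]
  w <- lapply(conds, function(cd)
    spec[[cd]][cbind(lig, combos$sender)] *
      spec[[cd]][cbind(rec, combos$receiver)])
  names(w) <- conds
  detected <- (det_frac$sham[cbind(lig, combos$sender)] >= min_detect &
                 det_frac$sham[cbind(rec, combos$receiver)] >= min_detect) |
    (det_frac$treated[cbind(lig, combos$sender)] >= min_detect &
       det_frac$treated[cbind(rec, combos$receiver)] >= min_detect)
  out <- data.frame(ligand = lig, receptor = rec,
                    sender = combos$sender, receiver = combos$receiver,
                    weightSham = w$sham, weightTreated = w$treated,
                    delta = w$treated - w$sham,
                    stringsAsFactors = FALSE)[detected, , drop = FALSE]
  out <- out[order(-abs(out$delta), out$ligand, out$sender,
                   out$receiver), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_pairs") <- skipped
  out
}
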