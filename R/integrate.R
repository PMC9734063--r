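#' Assign peaks to gene promoters by TSS proximity
#'
#' A peak is assigned to the gene whose TSS is nearest to the peak
#' midpoint among TSS within `window` bp; distance ties are broken by
#' lexicographic gene id; peaks with no TSS in range stay unassigned.
#' Assignment is strand-ignored: H3K27ac promoter signal flanks the TSS on
#' both sides.
#'
#' @param peaks BED data frame (`chrom`, `start`, `end`, `name`; 0-based
#'   half-open).
#' @param tss Data frame `chrom`, `pos`, `strand`, `geneId` (unique per
#'   gene).
#' @param window Half-width of the promoter window in bp (default 2000).
#' @return Data frame `peakId`, `geneId` (`NA` when unassigned),
#'   `distance`.
#' @export
assign_peaks_to_promoters <- function(peaks, tss, window = 2000) {
  if (any(peaks$end <= peaks$start)) stop("malformed interval: end <= start")
  if (anyDuplicated(tss$geneId)) stop("TSS must be unique per gene")
  mid <- floor((peaks$start + peaks$end) / 2)
  gene <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == ch)
    tc <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(tc) == 0) next
    tc <- tc[order(tc$pos, tc$geneId), , drop = FALSE]
    for (i in pk) {
      d <- abs(tc$pos - mid[i])
      inw <- which(d <= window)
      if (length(inw) == 0) next
      best <- inw[order(d[inw], tc$geneId[inw])][1]
      gene[i] <- tc$geneId[best]
      dist[i] <- d[best]
    }
  }
  data.frame(peakId = peaks$name, geneId = gene, distance = dist,
             stringsAsFactors = FALSE)
}

#' Concordance between DEG and promoter DA-peak fold-changes
#'
#' Restricts to genes that are differential (status not `ns`) in the
#' expression table and have an assigned promoter peak that is
#' differential in the acetylation table, then computes the Spearman
#' correlation of the paired log2 fold-changes (average ranks). The
#' p-value uses the exact permutation distribution when 10 or fewer pairs
#' are available (and ranks are untied), otherwise the t-approximation.
#'
#' @param deg Differential table for genes ([test_differential()]).
#' @param da Differential table for peaks.
#' @param assignment Data frame from [assign_peaks_to_promoters()].
#' @param require_da Restrict pairs to differential peaks as well as
#'   differential genes (default TRUE).
#' @return List: `nPairs`, `rho`, `pValue`, `pairs` (data frame
#'   `geneId`, `peakId`, `geneLog2FC`, `peakLog2FC`).
#' @export
promoter_concordance <- function(deg, da, assignment, require_da = TRUE) {
  asg <- assignment[!is.na(assignment$geneId), , drop = FALSE]
  deg_keep <- deg[deg$status != "ns", , drop = FALSE]
  da_keep <- if (require_da) da[da$status != "ns", , drop = FALSE] else da
  pairs <- merge(asg, deg_keep[, c("featureId", "log2FC")],
                 by.x = "geneId", by.y = "featureId")
  names(pairs)[names(pairs) == "log2FC"] <- "geneLog2FC"
  pairs <- merge(pairs, da_keep[, c("featureId", "log2FC")],
                 by.x = "peakId", by.y = "featureId")
  names(pairs)[names(pairs) == "log2FC"] <- "peakLog2FC"
  if (nrow(pairs) < 3)
    stop("fewer than 3 DEG / promoter-DA pairs; no correlation computed")
  pairs <- pairs[order(pairs$geneId), , drop = FALSE]
  n <- nrow(pairs)
  ties <- anyDuplicated(pairs$geneLog2FC) || anyDuplicated(pairs$peakLog2FC)
  ct <- suppressWarnings(stats::cor.test(
    pairs$geneLog2FC, pairs$peakLog2FC, method = "spearman",
    exact = (n <= 10 && !ties)))
  list(nPairs = n, rho = unname(ct$estimate), pValue = ct$p.value,
       pairs = pairs[, c("geneId", "peakId", "geneLog2FC", "peakLog2FC")])
}

#' Composite region ranking from DEG and DA-peak counts
#'
#' Regions are ranked (descending, average ties) separately by their DEG
#' and DA-peak counts; the composite score is the sum of the natural logs
#' of the two ranks, so the smallest score marks the strongest multimodal
#' response. The score depends on the counts only through their ranks.
#'
#' @param n_deg,n_da Named numeric vectors (region -> count) over the same
#'   regions.
#' @return Data frame ordered by ascending composite score: `region`,
#'   `nDEG`, `nDA`, `rankRNA`, `rankChIP`, `compositeScore`.
#' @export
composite_region_ranking <- function(n_deg, n_da) {
  if (!setequal(names(n_deg), names(n_da)) || is.null(names(n_deg)))
    stop("region keys must match between the two count maps")
  regions <- names(n_deg)
  n_da <- n_da[regions]
  rank_rna <- rank(-as.numeric(n_deg), ties.method = "average")
  rank_chip <- rank(-as.numeric(n_da), ties.method = "average")
  score <- log(rank_rna) + log(rank_chip)
  out <- data.frame(region = regions,
                    nDEG = as.numeric(n_deg), nDA = as.numeric(n_da),
                    rankRNA = rank_rna, rankChIP = rank_chip,
                    compositeScore = score, stringsAsFactors = FALSE)
  out <- out[order(out$compositeScore, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank-rank hypergeometric overlap map of two ranked lists
#'
#' Both lists are sorted by their signed ranking score, most up-regulated
#' first (the conventional score is `-log10(p) * sign(log2FC)`). At every
#' pair of rank thresholds `(i*s, j*s)` the overlap of the two top lists
#' is tested with a hypergeometric tail: the upper tail when the overlap
#' exceeds its expectation (enrichment, sign +1), the lower tail when it
#' falls below (depletion, sign -1). Values are `-log10(p)`; no
#' multiple-testing correction is applied (display statistic).
#'
#' @param scores1,scores2 Named numeric vectors over an identical feature
#'   universe.
#' @param step Rank step `s`; default `max(1, floor(N/100))` caps the grid
#'   at 100 x 100.
#' @return List: `logp` (matrix of `-log10(p)`), `sign` (+1 enrichment /
#'   -1 depletion), `overlap` (counts), `step`, `thresholds`.
#' @export
rrho_map <- function(scores1, scores2, step = NULL) {
  if (!setequal(names(scores1), names(scores2)))
    stop("feature universes differ")
  N <- length(scores1)
  if (is.null(step)) step <- max(1, floor(N / 100))
  if (step < 1) stop("step must be at least 1")
  ord1 <- names(scores1)[order(-scores1, names(scores1))]
  ord2 <- names(scores2)[order(-scores2, names(scores2))]
  pos_in_1 <- match(ord2, ord1)
  thr <- seq(step, N, by = step)
  if (thr[length(thr)] < N) thr <- c(thr, N)
  m <- length(thr)
  overlap <- matrix(0L, m, m)
  # overlap[i, j] = |top_i(list1) & top_j(list2)|; row = list1 threshold
  for (j in seq_len(m)) {
    in_top2 <- pos_in_1[seq_len(thr[j])]
    cnt <- tabulate(in_top2, nbins = N)
    overlap[, j] <- cumsum(cnt)[thr]
  }
  exp_ov <- outer(thr, thr) / N
  upper <- stats::phyper(overlap - 1, matrix(thr, m, m), N - matrix(thr, m, m),
                         matrix(thr, m, m, byrow = TRUE), lower.tail = FALSE)
  lower <- stats::phyper(overlap, matrix(thr, m, m), N - matrix(thr, m, m),
                         matrix(thr, m, m, byrow = TRUE), lower.tail = TRUE)
  enr <- overlap >= exp_ov
  p <- ifelse(enr, upper, lower)
  p <- pmax(p, 1e-320)
  list(logp = -log10(p), sign = ifelse(enr, 1L, -1L),
       overlap = overlap, step = step, thresholds = thr)
}

#' Signed ranking scores for RRHO from a differential table
#'
#' `-log10(p) * sign(log2FC)`, falling back to the signed log2FC when the
#' p-value is absent.
#'
#' @param d Differential table from [test_differential()].
#' @return Named numeric vector over the table's features.
#' @export
rrho_scores <- function(d) {
  p <- pmax(d$pValue, 1e-300)
  s <- ifelse(is.na(p), d$log2FC, -log10(p) * sign(d$log2FC))
  stats::setNames(s, d$featureId)
}
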