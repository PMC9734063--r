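#' Over-representation analysis against a gene-set collection
#'
#' Exact hypergeometric upper-tail test of the overlap between a query set
#' (e.g. a region's DEGs) and each set of a collection, with
#' fold-enrichment `(k/n)/(K/N)` and BH correction across the collection.
#' The universe should be the features actually tested for differential
#' status (guards against detection bias); query and set ids outside the
#' universe are dropped, with the dropped query count reported.
#'
#' @param query Character vector of feature ids.
#' @param collection Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of all testable ids.
#' @return Data frame: `setName`, `k` (overlap), `n` (query size), `K`
#'   (set size), `N` (universe size), `foldEnrichment`, `pValue`,
#'   `qValue`; attribute `dropped_query` counts ids outside the universe.
#' @export
ora <- function(query, collection, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  dropped <- sum(!unique(query) %in% universe)
  if (dropped > 0)
    warning(sprintf("%d query id(s) outside the universe were dropped",
                    dropped))
  query <- intersect(unique(query), universe)
  if (length(query) == 0) stop("empty query after intersection with universe")
  sets <- lapply(collection, function(s) intersect(unique(s), universe))
  keep <- lengths(sets) > 0
  sets <- sets[keep]
  N <- length(universe); n <- length(query)
  res <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    k <- length(intersect(query, sets[[nm]]))
    fe <- if (k == 0) 0 else (k / n) / (K / N)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(setName = nm, k = k, n = n, K = K, N = N,
               foldEnrichment = fe, pValue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$qValue <- bh_adjust(out$pValue)
  rownames(out) <- NULL
  attr(out, "dropped_query") <- dropped
  out
}

# weighted KS running sum over a descending-sorted score profile;
# returns the ES (maximal absolute deviation, ties toward the positive
# deviation) and the running-sum vector
gsea_es <- function(in_set, scores, weight) {
  N <- length(in_set); K <- sum(in_set)
  hitw <- abs(scores)^weight * in_set
  denom <- sum(hitw)
  if (denom == 0) hitw[in_set] <- 1 / K else hitw <- hitw / denom
  step <- ifelse(in_set, hitw, -1 / (N - K))
  if (K == N) step <- hitw
  rs <- cumsum(step)
  mx <- max(rs); mn <- min(rs)
  es <- if (mx >= abs(mn)) mx else mn
  list(es = es, running = rs)
}

#' GSEA running-sum enrichment with gene-permutation NES
#'
#' Weighted Kolmogorov-Smirnov statistic over a ranked feature list: hits
#' increment the running sum proportionally to `|score|^weight`
#' (normalized to 1 over the set), misses decrement `1/(N-K)`. The
#' enrichment score (ES) is the running-sum value of maximal absolute
#' deviation from zero, ties broken toward the positive deviation. The
#' null is built by gene permutation (set positions resampled); NES is the
#' ES divided by the mean |ES| of same-sign permutation values, and the
#' permutation p-value is one-sided by the sign of the ES. Gene
#' permutation (rather than phenotype permutation) is used because typical
#' replicate counts in this design are too small to permute labels.
#'
#' @param scores Named numeric vector of ranking scores (names are feature
#'   ids); sorted descending internally. No duplicate ids.
#' @param set Character vector of feature ids.
#' @param weight Score-weighting exponent (default 1).
#' @param n_perm Number of gene permutations (default 1000).
#' @param seed Integer seed for the permutation null.
#' @return List: `ES`, `NES`, `pValue`, `leadingEdge` (feature ids),
#'   `setSize` (after intersection), `running` (running-sum vector).
#' @export
gsea <- function(scores, set, weight = 1, n_perm = 1000, seed = 1L) {
  if (anyDuplicated(names(scores))) stop("duplicate feature ids in ranking")
  if (n_perm < 10) stop("n_perm must be at least 10")
  ord <- order(-scores)
  scores <- scores[ord]
  ids <- names(scores)
  in_set <- ids %in% set
  K <- sum(in_set)
  if (K == 0) stop("set does not intersect the ranked list")
  obs <- gsea_es(in_set, scores, weight)
  es <- obs$es
  # leading edge: set members at or before the ES extremum (positive ES),
  # or at/after it (negative ES)
  pos <- if (es >= 0) which.max(obs$running) else which.min(obs$running)
  leading <- if (es >= 0) ids[seq_len(pos)][in_set[seq_len(pos)]]
  else ids[pos:length(ids)][in_set[pos:length(ids)]]

  null_es <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- logical(length(ids))
      perm[sample.int(length(ids), K)] <- TRUE
      gsea_es(perm, scores, weight)$es
    }, numeric(1))
  })
  same <- null_es[sign(null_es) == sign(es) | es == 0]
  nes <- if (length(same) > 0 && mean(abs(same)) > 0)
    es / mean(abs(same)) else NA_real_
  p <- if (length(same) == 0) 1
  else (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(ES = es, NES = nes, pValue = p, leadingEdge = leading,
       setSize = K, running = obs$running)
}

#' Build regulatory domains for GREAT-style peak enrichment
#'
#' Each gene receives a basal domain (TSS +/- `basal` bp) extended in both
#' directions up to `extension` bp or to the nearest neighbouring basal
#' domain, whichever is closer — a fully specified simplification of
#' GREAT's basal-plus-extension association rule.
#'
#' @param tss Data frame `chrom`, `pos`, `strand`, `geneId`.
#' @param genome_size Genome length in bp (per chromosome lengths assumed
#'   equal to `genome_size` when a single value is given).
#' @param basal Basal half-width in bp (default 5000).
#' @param extension Maximal extension in bp (default 100000).
#' @return Data frame `chrom`, `start`, `end`, `geneId` (0-based
#'   half-open), one domain per gene.
#' @export
regulatory_domains <- function(tss, genome_size, basal = 5000,
                               extension = 100000) {
  if (anyDuplicated(tss$geneId)) stop("TSS must be unique per gene")
  out <- lapply(split(tss, tss$chrom), function(tc) {
    tc <- tc[order(tc$pos), , drop = FALSE]
    b_start <- pmax(tc$pos - basal, 0)
    b_end <- pmin(tc$pos + basal, genome_size)
    n <- nrow(tc)
    prev_end <- c(0, b_end[-n])
    next_start <- c(b_start[-1], genome_size)
    ext_start <- pmax(pmax(tc$pos - extension, prev_end), 0)
    ext_end <- pmin(pmin(tc$pos + extension, next_start), genome_size)
    # the extension never shrinks a domain below its basal part
    data.frame(chrom = tc$chrom,
               start = pmin(b_start, ext_start),
               end = pmax(b_end, ext_end),
               geneId = tc$geneId, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' GREAT-style binomial enrichment of a peak set in regulatory domains
#'
#' Counts the peaks whose midpoint falls in the union of the regulatory
#' domains of a gene set, and tests the count against a binomial null with
#' success probability equal to the union's fraction of the genome.
#'
#' @param peaks BED data frame (`chrom`, `start`, `end`, `name`).
#' @param domains Regulatory domains from [regulatory_domains()].
#' @param set Character vector of gene ids.
#' @param genome_size Genome length in bp.
#' @return One-row data frame: `setName` ("set"), `k`, `n` (total peaks),
#'   `coverage` (p0), `foldEnrichment` (`(k/n)/p0`), `pValue`.
#' @export
region_enrichment_binomial <- function(peaks, domains, set, genome_size) {
  dom <- domains[domains$geneId %in% set, , drop = FALSE]
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    dom$chrom, IRanges::IRanges(dom$start + 1, dom$end)))
  p0 <- sum(GenomicRanges::width(gr)) / genome_size
  mid <- floor((peaks$start + peaks$end) / 2)
  mid_gr <- GenomicRanges::GRanges(peaks$chrom,
                                   IRanges::IRanges(mid + 1, mid + 1))
  k <- sum(IRanges::overlapsAny(mid_gr, gr))
  n <- nrow(peaks)
  if (p0 == 0 && k > 0)
    stop("inconsistent inputs: zero coverage but overlapping peaks")
  p <- if (p0 == 0) 1 else stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  data.frame(setName = "set", k = k, n = n, coverage = p0,
             foldEnrichment = if (k == 0) 0 else (k / n) / p0,
             pValue = p, stringsAsFactors = FALSE)
}
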