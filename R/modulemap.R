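#' Fold-change matrix over the union of region-wise differential features
#'
#' Rows are the features called `up` or `down` in at least one region,
#' columns are regions, entries are the estimated log2 fold-changes.
#' Entries for regions where a feature was not tested (all-zero counts)
#' are set to 0 and flagged in the companion `tested` mask.
#'
#' @param per_region Named list (region -> differential table from
#'   [test_differential()]).
#' @return List with `fc` (numeric matrix), `tested` (logical matrix of
#'   the same shape) and `regions`.
#' @export
build_foldchange_matrix <- function(per_region) {
  if (length(per_region) < 1) stop("at least one region required")
  regions <- names(per_region)
  if (is.null(regions)) stop("per_region must be a named list")
  union_feats <- unique(unlist(lapply(per_region, function(d)
    d$featureId[d$status != "ns"])))
  if (length(union_feats) == 0) stop("empty union set of differential features")
  union_feats <- sort(union_feats)
  fc <- matrix(0, length(union_feats), length(regions),
               dimnames = list(union_feats, regions))
  tested <- matrix(FALSE, length(union_feats), length(regions),
                   dimnames = list(union_feats, regions))
  for (r in regions) {
    d <- per_region[[r]]
    i <- match(d$featureId, union_feats)
    keep <- !is.na(i)
    ok <- keep & !is.na(d$pValue)
    fc[i[ok], r] <- d$log2FC[ok]
    tested[i[ok], r] <- TRUE
  }
  list(fc = fc, tested = tested, regions = regions)
}

# k-means++ seeding: spread initial centres with probability proportional
# to squared distance from the nearest centre already chosen
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) i <- sample.int(n, 1)
      else i <- sample.int(n, 1, prob = d2)
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Cluster differential features into co-regulated modules
#'
#' k-means (Lloyd) on the raw, unscaled log2 fold-change profiles with
#' k-means++ initialization, best of `n_restarts` restarts by total
#' within-cluster sum of squares. Clustering on raw fold-changes keeps
#' sign and magnitude across regions as the signal, so globally
#' up-regulated modules are separable from region-specific ones. Module
#' ids are relabelled by decreasing module size (ties by first row) so the
#' output is stable under row permutation up to identical data.
#'
#' @param fcm Result of [build_foldchange_matrix()].
#' @param k Number of modules (default 8, the module count displayed for
#'   both gene and peak fold-change maps).
#' @param n_restarts Restarts (default 25).
#' @param seed Integer seed; same input and seed give identical partitions.
#' @param scale_rows Optionally z-score rows before clustering (off by
#'   default).
#' @return List with `assignment` (named integer vector, feature ->
#'   module), `centers` (k x regions), `k`, `inertia`, `size`,
#'   `masked_per_module` (count of untested entries by module).
#' @export
cluster_modules <- function(fcm, k = 8, n_restarts = 25, seed = 1L,
                            scale_rows = FALSE) {
  x <- fcm$fc
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(x)) stop("k exceeds the number of features")
  if (scale_rows) {
    sd_r <- apply(x, 1, stats::sd)
    x <- (x - rowMeans(x)) / ifelse(sd_r > 0, sd_r, 1)
  }
  with_local_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- kmeanspp_centers(x, k)
      fit <- suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = 100,
                      algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss)
        best <- fit
    }
    # stable relabelling: modules ordered by decreasing size, ties by the
    # smallest member feature id
    first_feat <- vapply(seq_len(k), function(m) {
      mem <- rownames(x)[best$cluster == m]
      if (length(mem)) min(mem) else ""
    }, character(1))
    ord <- order(-tabulate(best$cluster, k), first_feat)
    relabel <- integer(k); relabel[ord] <- seq_len(k)
    assignment <- relabel[best$cluster]
    names(assignment) <- rownames(x)
    centers <- best$centers[ord, , drop = FALSE]
    rownames(centers) <- seq_len(k)
    masked <- vapply(seq_len(k), function(m)
      sum(!fcm$tested[assignment == m, , drop = FALSE]), numeric(1))
    list(assignment = assignment, centers = centers, k = k,
         inertia = best$tot.withinss,
         size = as.integer(table(factor(assignment, levels = seq_len(k)))),
         masked_per_module = masked, seed = as.integer(seed))
  })
}

#' Cross-region sharing of differential features
#'
#' For every feature in the union differential set, counts the regions in
#' which it is up and down, and summarizes the distribution of sharing
#' degree: the fraction of union features specific to a single region and
#' the fraction altered in three or more.
#'
#' @param per_region Named list (region -> differential table).
#' @return List with `per_feature` (data frame `featureId`, `nUp`,
#'   `nDown`, `degree`), `histogram` (named counts by degree),
#'   `fraction_single`, `fraction_three_plus`, `n_regions`.
#' @export
sharing_summary <- function(per_region) {
  regions <- names(per_region)
  if (is.null(regions) || length(regions) < 1)
    stop("per_region must be a named, non-empty list")
  union_feats <- sort(unique(unlist(lapply(per_region, function(d)
    d$featureId[d$status != "ns"]))))
  if (length(union_feats) == 0) stop("no differential features in any region")
  smat <- sapply(per_region, function(d)
    d$status[match(union_feats, d$featureId)])
  smat <- matrix(smat, nrow = length(union_feats))
  n_up <- rowSums(smat == "up", na.rm = TRUE)
  n_down <- rowSums(smat == "down", na.rm = TRUE)
  per_feature <- data.frame(featureId = union_feats,
                            nUp = as.integer(n_up),
                            nDown = as.integer(n_down),
                            degree = as.integer(n_up + n_down),
                            stringsAsFactors = FALSE, row.names = NULL)
  hist <- table(factor(per_feature$degree,
                       levels = seq_len(length(regions))))
  list(per_feature = per_feature,
       histogram = hist,
       fraction_single = mean(per_feature$degree == 1),
       fraction_three_plus = mean(per_feature$degree >= 3),
       n_regions = length(regions))
}
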