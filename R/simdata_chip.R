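#' Simulate an H3K27ac consensus-peak data set coupled to a bulk truth
#'
#' Places one promoter peak per gene inside the promoter window (centre
#' within +/- 1 kb of the gene's TSS) plus distal decoy peaks at least
#' 10 kb from any TSS, on a single synthetic chromosome. Planted promoter
#' log2 effects are drawn with correlation `rho` to the gene's expression
#' effect in the same region; decoy peaks are null. Counts are then drawn
#' with the same NB machinery as the bulk simulator, with 2 replicates per
#' condition per region (the consensus-peak ChIP design).
#'
#' For `rho = 1` the peak effect equals the gene effect exactly; for
#' `rho = 0` peak effects are independent draws with the same per-region
#' spread as the gene effects (regions where no gene effect was planted
#' stay null).
#'
#' @param bulk_truth Truth table from [simulate_bulk()] (columns
#'   `featureId`, `region`, `trueLog2FC`).
#' @param rho Target correlation between promoter-peak and gene effects,
#'   in `[-1, 1]`.
#' @param n_decoys Number of distal decoy peaks (default: one per gene).
#' @param gene_spacing Distance between consecutive TSS in bp.
#' @param peak_width Width of every peak in bp.
#' @param genome_size Total genome size in bp (default sized to fit).
#' @param n_replicates ChIP replicates per condition per region (default 2).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of peak
#'   baseline means. The default mean of ~3,000 reads reflects counts
#'   aggregated over wide consensus peak intervals.
#' @param dispersion_shape,dispersion_mean Gamma parameters of per-peak NB
#'   dispersion; replicate concordance of consensus-peak H3K27ac signal
#'   is high, and a 2-replicate design only resolves differential
#'   acetylation when it is, hence a default mean dispersion of 0.005.
#' @param sizefactor_sdlog Log-sd of per-sample size factors.
#' @param seed Integer seed.
#' @return List with `sham` and `treated` [count_matrix()] objects over
#'   peaks, `peaks` (BED data frame: `chrom`, `start`, `end`, `name`),
#'   `tss` (data frame `chrom`, `pos`, `strand`, `geneId`), `truth`
#'   (per peak x region `trueLog2FC`, `trueStatus`, `promoterOf`), and
#'   `genome_size`.
#' @export
simulate_chip <- function(bulk_truth, rho = 0.8,
                          n_decoys = NULL,
                          gene_spacing = 50000L,
                          peak_width = 500L,
                          genome_size = NULL,
                          n_replicates = 2,
                          baseline_meanlog = log(3000),
                          baseline_sdlog = 0.8,
                          dispersion_shape = 2,
                          dispersion_mean = 0.005,
                          sizefactor_sdlog = 0.2,
                          seed = 1L) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  genes <- unique(bulk_truth$featureId)
  regions <- unique(bulk_truth$region)
  n_genes <- length(genes)
  if (is.null(n_decoys)) n_decoys <- n_genes
  if (gene_spacing < 25000)
    stop("gene_spacing too small to keep decoys 10 kb from every TSS")
  if (is.null(genome_size))
    genome_size <- (n_genes + 1L) * as.integer(gene_spacing)

  with_local_seed(seed, {
    # TSS laid out regularly on one synthetic chromosome
    tss_pos <- as.integer(seq_len(n_genes) * gene_spacing -
                            gene_spacing / 2)
    if (max(tss_pos) + 2000 + peak_width > genome_size)
      stop("peaks exceed genome bounds; increase genome_size")
    tss <- data.frame(chrom = "chr1", pos = tss_pos,
                      strand = rep(c("+", "-"), length.out = n_genes),
                      geneId = genes, stringsAsFactors = FALSE)

    # promoter peaks: centre uniform within +/-1 kb of the TSS
    half <- as.integer(peak_width / 2)
    centre <- tss_pos + as.integer(round(stats::runif(n_genes, -1000, 1000)))
    prom <- data.frame(chrom = "chr1",
                       start = centre - half, end = centre + half,
                       name = sprintf("prompk_%s", genes),
                       stringsAsFactors = FALSE)

    # decoys midway between TSS (>= 10 kb from any TSS by construction)
    gap_centres <- as.integer(seq_len(n_genes) * gene_spacing)
    jit_max <- max(0, gene_spacing / 2 - 10000 - 2000 - half)
    idx <- rep(seq_len(n_genes), length.out = n_decoys)
    lap <- (seq_len(n_decoys) - 1L) %/% n_genes  # extra decoys per gap
    # one jitter per gap, shared by the decoys it hosts, so decoys within a
    # gap stay exactly 3 widths apart and never overlap
    gap_jit <- as.integer(round(stats::runif(n_genes, -1, 1) *
                                  min(jit_max, 5000)))
    dec_centre <- gap_centres[idx] + gap_jit[idx] + lap * (3L * peak_width)
    decoys <- data.frame(chrom = "chr1",
                         start = dec_centre - half,
                         end = dec_centre + half,
                         name = sprintf("decoy_%05d", seq_len(n_decoys)),
                         stringsAsFactors = FALSE)
    peaks <- rbind(prom, decoys)
    if (any(peaks$start < 0) || any(peaks$end > genome_size))
      stop("peaks exceed genome bounds")
    o <- order(peaks$start)
    if (any(peaks$start[o][-1] < peaks$end[o][-nrow(peaks)]))
      stop("peak geometry produced overlapping peaks")

    # planted peak effects correlated with the gene effects per region
    gene_eff <- matrix(bulk_truth$trueLog2FC[
      match(paste(rep(genes, length(regions)),
                  rep(regions, each = n_genes)),
            paste(bulk_truth$featureId, bulk_truth$region))],
      n_genes, length(regions), dimnames = list(genes, regions))
    peak_eff <- matrix(0, nrow(peaks), length(regions),
                       dimnames = list(peaks$name, regions))
    for (r in regions) {
      ge <- gene_eff[, r]
      sdr <- stats::sd(ge)
      noise <- if (sdr > 0 && abs(rho) < 1)
        stats::rnorm(n_genes, 0, sdr) else numeric(n_genes)
      peak_eff[seq_len(n_genes), r] <- rho * ge + sqrt(1 - rho^2) * noise
    }

    # NB counts over peaks, 2 replicates per condition per region
    base <- stats::rlnorm(nrow(peaks), baseline_meanlog, baseline_sdlog)
    disp <- pmax(stats::rgamma(nrow(peaks), shape = dispersion_shape,
                               rate = dispersion_shape / dispersion_mean),
                 1e-4)
    build_half <- function(condition) {
      grid <- expand.grid(replicate = seq_len(n_replicates),
                          region = regions, stringsAsFactors = FALSE)
      sf <- stats::rlnorm(nrow(grid), 0, sizefactor_sdlog)
      cols <- lapply(seq_len(nrow(grid)), function(j) {
        mu <- sf[j] * base *
          (if (condition == "treated") 2^peak_eff[, grid$region[j]] else 1)
        stats::rnbinom(nrow(peaks), mu = mu, size = 1 / disp)
      })
      cts <- do.call(cbind, cols)
      ids <- sprintf("%s_%s_chip%d", grid$region, condition,
                     grid$replicate)
      dimnames(cts) <- list(peaks$name, ids)
      meta <- data.frame(sample = ids, region = grid$region,
                         condition = condition,
                         replicate = grid$replicate,
                         stringsAsFactors = FALSE)
      count_matrix(cts, meta)
    }
    sham <- build_half("sham")
    treated <- build_half("treated")

    truth <- data.frame(
      featureId = rep(peaks$name, times = length(regions)),
      region = rep(regions, each = nrow(peaks)),
      trueLog2FC = as.vector(peak_eff),
      promoterOf = rep(c(genes, rep(NA_character_, n_decoys)),
                       times = length(regions)),
      stringsAsFactors = FALSE)
    truth$trueStatus <- ifelse(truth$trueLog2FC > 0, "up",
                               ifelse(truth$trueLog2FC < 0, "down", "null"))
    list(sham = sham, treated = treated, peaks = peaks, tss = tss,
         truth = truth, genome_size = genome_size)
  })
}
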