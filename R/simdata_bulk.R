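#' Planted co-regulated module for bulk simulations
#'
#' A set of genes that respond with a specified log2 effect in specified
#' regions, emulating a co-regulated gene module.
#'
#' @param gene_ids Character vector of member genes.
#' @param region_effects Named numeric vector, region -> log2 effect (0
#'   means no effect in that region).
#' @param label Free-text module label.
#' @return A `planted_module` list.
#' @export
planted_module <- function(gene_ids, region_effects, label = "module") {
  if (!all(is.finite(region_effects))) stop("effects must be finite")
  structure(list(gene_ids = unique(as.character(gene_ids)),
                 region_effects = region_effects,
                 label = label),
            class = "planted_module")
}

#' Configuration for the bulk RNA-seq simulator
#'
#' Defaults emulate the multi-region bulk design of the study the package
#' models: 27 brain regions, 2 conditions (sham / treated), 4 replicates
#' per condition per region. Gene baseline means are log-normal, per-gene
#' NB dispersions are Gamma(shape 2, mean 0.1) so variance = mu + alpha
#' mu^2 matches typical bulk RNA overdispersion, and per-sample size
#' factors are log-normal(0, 0.2) so normalization is non-trivial.
#'
#' @param n_regions Number of regions (default 27).
#' @param n_genes Number of genes (default 2000).
#' @param n_replicates Replicates per condition per region (default 4).
#' @param baseline_meanlog,baseline_sdlog Log-normal location/scale of gene
#'   baseline means.
#' @param dispersion_shape,dispersion_mean Gamma shape and mean for per-gene
#'   NB dispersion.
#' @param dispersion_fixed Optional single dispersion applied to every
#'   gene (overrides the Gamma draw); useful for calibration designs at a
#'   stated dispersion.
#' @param sizefactor_sdlog Log-sd of per-sample size factors.
#' @param modules List of [planted_module()] objects (disjoint gene sets).
#' @param regions Optional explicit region names.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A `bulk_sim_config` list.
#' @export
bulk_sim_config <- function(n_regions = 27, n_genes = 2000,
                            n_replicates = 4,
                            baseline_meanlog = log(100),
                            baseline_sdlog = 1,
                            dispersion_shape = 2,
                            dispersion_mean = 0.1,
                            dispersion_fixed = NULL,
                            sizefactor_sdlog = 0.2,
                            modules = list(),
                            regions = NULL,
                            seed = 1L) {
  if (n_regions < 1 || n_genes < 1) stop("non-positive dimensions")
  if (n_replicates < 2) stop("at least 2 replicates per condition")
  if (dispersion_mean <= 0 || dispersion_shape <= 0)
    stop("dispersion parameters must be positive")
  if (is.null(regions)) regions <- sprintf("R%02d", seq_len(n_regions))
  if (length(regions) != n_regions) stop("regions length != n_regions")
  all_mod_genes <- unlist(lapply(modules, `[[`, "gene_ids"))
  if (anyDuplicated(all_mod_genes))
    stop("module gene sets must be disjoint")
  if (!is.null(dispersion_fixed) && dispersion_fixed <= 0)
    stop("dispersion_fixed must be positive")
  structure(list(n_regions = n_regions, n_genes = n_genes,
                 n_replicates = n_replicates,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion_shape = dispersion_shape,
                 dispersion_mean = dispersion_mean,
                 dispersion_fixed = dispersion_fixed,
                 sizefactor_sdlog = sizefactor_sdlog,
                 modules = modules, regions = regions,
                 seed = as.integer(seed)),
            class = "bulk_sim_config")
}

#' Gene identifiers used by the bulk simulator
#'
#' The simulators name genes `g00001`, `g00002`, ... ; this helper
#' returns the first `n` of them, e.g. for building planted modules.
#'
#' @param n Number of gene ids.
#' @return Character vector of length `n`.
#' @export
bulk_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

# effect matrix genes x regions from the planted modules
planted_effect_matrix <- function(config) {
  genes <- bulk_gene_ids(config$n_genes)
  eff <- matrix(0, config$n_genes, config$n_regions,
                dimnames = list(genes, config$regions))
  for (m in config$modules) {
    gid <- m$gene_ids
    if (!all(gid %in% genes)) stop("module gene id outside gene universe")
    re <- m$region_effects
    bad <- setdiff(names(re), config$regions)
    if (length(bad)) stop("unknown region in module effects: ",
                          paste(bad, collapse = ", "))
    for (r in names(re)) eff[gid, r] <- eff[gid, r] + re[[r]]
  }
  eff
}

#' Simulate a multi-region bulk count data set with planted truth
#'
#' Draws counts NB(mean = sizeFactor * baseMean * 2^effect, dispersion)
#' where the effect applies only to treated samples of the module's
#' regions. Returns the sham and treated halves as [count_matrix()]
#' objects plus a truth table recording every planted per-gene, per-region
#' log2 fold-change.
#'
#' @param config A [bulk_sim_config()].
#' @return List with elements `sham`, `treated` (count matrices), `truth`
#'   (data frame `featureId`, `region`, `trueLog2FC`, `trueStatus`) and
#'   `params` (per-gene base means and dispersions, per-sample size
#'   factors).
#' @export
simulate_bulk <- function(config) {
  stopifnot(inherits(config, "bulk_sim_config"))
  with_local_seed(config$seed, {
    genes <- bulk_gene_ids(config$n_genes)
    base <- stats::rlnorm(config$n_genes, config$baseline_meanlog,
                          config$baseline_sdlog)
    disp <- if (!is.null(config$dispersion_fixed))
      rep(config$dispersion_fixed, config$n_genes)
    else stats::rgamma(config$n_genes, shape = config$dispersion_shape,
                       rate = config$dispersion_shape /
                         config$dispersion_mean)
    disp <- pmax(disp, 1e-4)
    eff <- planted_effect_matrix(config)

    build_half <- function(condition) {
      grid <- expand.grid(replicate = seq_len(config$n_replicates),
                          region = config$regions,
                          stringsAsFactors = FALSE)
      sf <- stats::rlnorm(nrow(grid), 0, config$sizefactor_sdlog)
      cols <- lapply(seq_len(nrow(grid)), function(j) {
        r <- grid$region[j]
        mu <- sf[j] * base *
          (if (condition == "treated") 2^eff[, r] else 1)
        stats::rnbinom(config$n_genes, mu = mu, size = 1 / disp)
      })
      cts <- do.call(cbind, cols)
      ids <- sprintf("%s_%s_rep%d", grid$region, condition, grid$replicate)
      dimnames(cts) <- list(genes, ids)
      meta <- data.frame(sample = ids, region = grid$region,
                         condition = condition,
                         replicate = grid$replicate,
                         stringsAsFactors = FALSE)
      list(cm = count_matrix(cts, meta), sf = stats::setNames(sf, ids))
    }
    sham <- build_half("sham")
    treated <- build_half("treated")

    truth <- data.frame(
      featureId = rep(genes, times = config$n_regions),
      region = rep(config$regions, each = config$n_genes),
      trueLog2FC = as.vector(eff),
      stringsAsFactors = FALSE)
    truth$trueStatus <- ifelse(truth$trueLog2FC > 0, "up",
                               ifelse(truth$trueLog2FC < 0, "down", "null"))
    list(sham = sham$cm, treated = treated$cm, truth = truth,
         params = list(base_mean = stats::setNames(base, genes),
                       dispersion = stats::setNames(disp, genes),
                       size_factors = c(sham$sf, treated$sf),
                       effects = eff))
  })
}
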