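#' Configuration for the scRNA-seq simulator
#'
#' Defaults emulate the single-cell arm of the study the package models:
#' two hippocampal regions (dorsal and ventral dentate gyrus), 2 conditions,
#' 5 replicates per condition, and 12 cell types distinguished by disjoint
#' marker blocks. Per-cell depth is Poisson-log-normal around ~2,000 counts
#' (droplet-like sparsity at desk scale); cell counts per gene are
#' multinomial given the cell's type profile.
#'
#' Planted effects, each recorded in the returned truth table:
#' `proportion_shift` multiplies one type's expected proportion under
#' treatment; `module_shift` raises a gene set in treated cells of one
#' type; `regulon_shift` raises one regulon's targets in treated cells of
#' one type; `lr_shift` raises one catalogue ligand in treated cells of the
#' sender type. Each is a list with fields `type` (or `sender`), `region`,
#' and `factor` (proportion) or `log2fc` (expression), e.g.
#' `list(type = "type03", region = "dorDG", factor = 2)`.
#'
#' @param n_types Number of cell types (default 12).
#' @param n_genes Number of genes including markers and mito genes.
#' @param n_markers_per_type Marker genes per type (disjoint blocks).
#' @param marker_fold Fold elevation of a type's markers in that type.
#' @param n_mito_genes Mitochondrial genes (ids prefixed `mt-`).
#' @param mito_fraction Expected mitochondrial fraction of a cell's counts.
#' @param cells_per_replicate Cells per replicate (exact, by construction).
#' @param n_replicates Replicates per condition per region.
#' @param regions Region names.
#' @param depth_meanlog,depth_sdlog Poisson-log-normal depth parameters.
#' @param replicate_concentration Dirichlet concentration of per-replicate
#'   type proportions around the base proportions (larger = less noise).
#' @param n_regulons,regulon_size Regulon catalogue emitted with the data.
#' @param n_lr_pairs Ligand-receptor catalogue size.
#' @param proportion_shift,module_shift,regulon_shift,lr_shift Planted
#'   effects (see Details); `NULL` plants nothing.
#' @param module_size Genes in the planted expression module.
#' @param seed Integer seed.
#' @return An `scrna_sim_config` list.
#' @export
scrna_sim_config <- function(n_types = 12, n_genes = 1500,
                             n_markers_per_type = 10, marker_fold = 8,
                             n_mito_genes = 10, mito_fraction = 0.05,
                             cells_per_replicate = 150, n_replicates = 5,
                             regions = c("dorDG", "venDG"),
                             depth_meanlog = log(2000), depth_sdlog = 0.3,
                             replicate_concentration = 400,
                             n_regulons = 10, regulon_size = 20,
                             n_lr_pairs = 30,
                             proportion_shift = NULL,
                             module_shift = NULL,
                             regulon_shift = NULL,
                             lr_shift = NULL,
                             module_size = 100,
                             seed = 1L) {
  if (n_replicates < 2) stop("at least 2 replicates per condition")
  if (n_types < 2) stop("at least 2 cell types")
  if (n_genes < n_types * n_markers_per_type + n_mito_genes + 200)
    stop("n_genes too small for the marker/mito layout")
  structure(as.list(environment()), class = "scrna_sim_config")
}

#' Simulate a droplet-style scRNA-seq data set with planted truth
#'
#' @param config An [scrna_sim_config()].
#' @return List with `sham` and `treated` [cell_matrix()] objects (cell
#'   metadata includes the true type label `trueType`), `truth` (data frame
#'   of planted effects: `kind`, `region`, `type`, `target`, `magnitude`),
#'   `markers` (list type -> marker genes), `reference` (marker-space
#'   centroid matrix for supervised typing), `regulons` (named list of
#'   `list(tf, targets)`), `lr_pairs` (data frame `ligand`, `receptor`),
#'   `module_genes` (genes of the planted expression module, if any) and
#'   `base_proportions`.
#' @export
simulate_scrna <- function(config) {
  stopifnot(inherits(config, "scrna_sim_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    n_mk <- cfg$n_types * cfg$n_markers_per_type
    genes <- c(sprintf("sg%05d", seq_len(cfg$n_genes - cfg$n_mito_genes)),
               sprintf("mt-sg%03d", seq_len(cfg$n_mito_genes)))
    types <- sprintf("type%02d", seq_len(cfg$n_types))
    markers <- split(genes[seq_len(n_mk)],
                     rep(types, each = cfg$n_markers_per_type))
    markers <- markers[types]
    is_mito <- startsWith(genes, "mt-")

    w <- stats::rlnorm(length(genes), 0, 1)
    # scale mito weights to the target expected mito fraction
    w[is_mito] <- w[is_mito] / sum(w[is_mito]) *
      cfg$mito_fraction / (1 - cfg$mito_fraction) * sum(w[!is_mito])

    profiles <- sapply(types, function(t) {
      p <- w
      p[genes %in% markers[[t]]] <- p[genes %in% markers[[t]]] * cfg$marker_fold
      p / sum(p)
    })
    rownames(profiles) <- genes

    nonmarker <- genes[!(genes %in% unlist(markers)) & !is_mito]
    by_expr <- nonmarker[order(-w[match(nonmarker, genes)])]
    upper <- by_expr[seq_len(floor(length(by_expr) / 2))]

    # catalogues emitted alongside the data; the gene pools behind the
    # planted effects are disjoint so each planted signal has one owner
    lr_genes <- sample(upper, 2 * cfg$n_lr_pairs)
    reg_pool <- setdiff(upper, lr_genes)
    if (length(reg_pool) < cfg$regulon_size + 1)
      stop("n_genes too small for the regulon catalogue")
    # regulons may share targets with one another (as real TF programs
    # do) but never with the LR catalogue or the planted module
    regulons <- lapply(seq_len(cfg$n_regulons), function(i) {
      picks <- sample(reg_pool, cfg$regulon_size + 1)
      list(tf = picks[1], targets = sort(picks[-1]))
    })
    names(regulons) <- sprintf("regulon%02d", seq_len(cfg$n_regulons))
    mod_pool <- setdiff(nonmarker,
                        c(lr_genes, unlist(lapply(regulons, function(r)
                          c(r$tf, r$targets)))))
    if (length(mod_pool) < cfg$module_size)
      mod_pool <- setdiff(nonmarker, lr_genes)
    module_genes <- sort(sample(mod_pool, cfg$module_size))
    lr_pairs <- data.frame(
      ligand = lr_genes[seq_len(cfg$n_lr_pairs)],
      receptor = lr_genes[cfg$n_lr_pairs + seq_len(cfg$n_lr_pairs)],
      stringsAsFactors = FALSE)

    base_prop <- stats::rgamma(cfg$n_types, shape = 10, rate = 1)
    base_prop <- stats::setNames(base_prop / sum(base_prop), types)

    truth <- data.frame(kind = character(), region = character(),
                        type = character(), target = character(),
                        magnitude = numeric(), stringsAsFactors = FALSE)
    add_truth <- function(kind, region, type, target, magnitude) {
      rbind(truth, data.frame(kind = kind, region = region, type = type,
                              target = target, magnitude = magnitude,
                              stringsAsFactors = FALSE))
    }
    if (!is.null(cfg$proportion_shift))
      truth <- add_truth("proportion", cfg$proportion_shift$region,
                         cfg$proportion_shift$type,
                         cfg$proportion_shift$type,
                         cfg$proportion_shift$factor)
    if (!is.null(cfg$module_shift))
      truth <- add_truth("expression", cfg$module_shift$region,
                         cfg$module_shift$type, "module",
                         cfg$module_shift$log2fc)
    if (!is.null(cfg$regulon_shift))
      truth <- add_truth("regulon", cfg$regulon_shift$region,
                         cfg$regulon_shift$type,
                         cfg$regulon_shift$regulon %||% "regulon01",
                         cfg$regulon_shift$log2fc)
    if (!is.null(cfg$lr_shift)) {
      pr <- cfg$lr_shift$pair %||% 1L
      truth <- add_truth("lr-edge", cfg$lr_shift$region,
                         cfg$lr_shift$sender,
                         paste0(lr_pairs$ligand[pr], "->",
                                lr_pairs$receptor[pr]),
                         cfg$lr_shift$log2fc)
    }

    # condition/region/type-specific expression multipliers
    shift_genes <- function(region, type, condition, p) {
      if (condition != "treated") return(p)
      bump <- function(ids, lfc) {
        p[match(ids, genes)] <<- p[match(ids, genes)] * 2^lfc
      }
      ms <- cfg$module_shift
      if (!is.null(ms) && ms$region == region && ms$type == type)
        bump(module_genes, ms$log2fc)
      rs <- cfg$regulon_shift
      if (!is.null(rs) && rs$region == region && rs$type == type)
        bump(regulons[[rs$regulon %||% "regulon01"]]$targets, rs$log2fc)
      ls <- cfg$lr_shift
      if (!is.null(ls) && ls$region == region && ls$sender == type)
        bump(lr_pairs$ligand[ls$pair %||% 1L], ls$log2fc)
      p / sum(p)
    }

    sim_half <- function(condition) {
      cols <- list(); metas <- list()
      for (region in cfg$regions) {
        prop <- base_prop
        ps <- cfg$proportion_shift
        if (condition == "treated" && !is.null(ps) &&
            ps$region == region) {
          prop[ps$type] <- prop[ps$type] * ps$factor
          prop <- prop / sum(prop)
        }
        eff_profiles <- sapply(types, function(t)
          shift_genes(region, t, condition, profiles[, t]))
        for (r in seq_len(cfg$n_replicates)) {
          rp <- stats::rgamma(cfg$n_types,
                              shape = prop * cfg$replicate_concentration)
          rp <- rp / sum(rp)
          ctype <- sample(types, cfg$cells_per_replicate,
                          replace = TRUE, prob = rp)
          depth <- stats::rpois(cfg$cells_per_replicate,
                                stats::rlnorm(cfg$cells_per_replicate,
                                              cfg$depth_meanlog,
                                              cfg$depth_sdlog))
          depth <- pmax(depth, 1L)
          m <- matrix(0L, length(genes), cfg$cells_per_replicate)
          for (ci in seq_len(cfg$cells_per_replicate))
            m[, ci] <- stats::rmultinom(1, depth[ci],
                                        eff_profiles[, ctype[ci]])
          ids <- sprintf("%s_%s_r%d_c%03d", region, condition, r,
                         seq_len(cfg$cells_per_replicate))
          colnames(m) <- ids; rownames(m) <- genes
          cols[[length(cols) + 1L]] <- Matrix::Matrix(m, sparse = TRUE)
          metas[[length(metas) + 1L]] <- data.frame(
            cell = ids,
            replicate = sprintf("%s_%s_r%d", region, condition, r),
            condition = condition, region = region,
            trueType = ctype, stringsAsFactors = FALSE)
        }
      }
      cell_matrix(do.call(cbind, cols), do.call(rbind, metas))
    }
    sham <- sim_half("sham")
    treated <- sim_half("treated")

    marker_union <- unlist(markers, use.names = FALSE)
    reference <- sapply(types, function(t)
      log1p(1e4 * profiles[marker_union, t]))
    rownames(reference) <- marker_union

    list(sham = sham, treated = treated, truth = truth,
         markers = markers, reference = reference,
         regulons = regulons, lr_pairs = lr_pairs,
         module_genes = module_genes, base_proportions = base_prop,
         config = cfg)
  })
}
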