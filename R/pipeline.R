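#' Planted module layout for the demo study design
#'
#' Builds a set of planted co-regulated modules over a multi-region
#' design: one module up-regulated everywhere, one down-regulated
#' everywhere, and the remaining modules alternating in sign over
#' deterministic blocks of regions. Every module also covers the target
#' region, giving it the largest effect budget — the "raphe-like" region
#' expected to top the composite ranking.
#'
#' @param n_genes Gene universe size.
#' @param regions Region names.
#' @param n_modules Number of modules (default 8).
#' @param module_size Genes per module (default 25).
#' @param effect Absolute log2 effect size (default 1).
#' @param target_region Region covered by every module (default the
#'   first).
#' @return List of [planted_module()] objects.
#' @export
demo_planted_modules <- function(n_genes, regions, n_modules = 8,
                                 module_size = 25, effect = 1,
                                 target_region = regions[1]) {
  if (n_modules * module_size > n_genes)
    stop("not enough genes for the requested modules")
  genes <- bulk_gene_ids(n_genes)
  others <- setdiff(regions, target_region)
  mods <- list()
  patt <- vector("list", n_modules)
  patt[[1]] <- stats::setNames(rep(effect, length(regions)), regions)
  if (n_modules >= 2)
    patt[[2]] <- stats::setNames(rep(-effect, length(regions)), regions)
  if (n_modules >= 3) {
    nb <- n_modules - 2
    member <- vector("list", nb)
    slot <- 0L
    for (i in seq_along(others)) {
      for (rep_i in 1:2) {
        m <- (slot %% nb) + 1L
        member[[m]] <- c(member[[m]], others[i])
        slot <- slot + 1L
      }
    }
    for (m in seq_len(nb)) {
      sgn <- if (m %% 2 == 1) effect else -effect
      regs <- c(target_region, member[[m]])
      patt[[m + 2]] <- stats::setNames(rep(sgn, length(regs)), regs)
    }
  }
  for (m in seq_len(n_modules)) {
    ids <- genes[((m - 1) * module_size + 1):(m * module_size)]
    mods[[m]] <- planted_module(ids, patt[[m]],
                                label = sprintf("planted%02d", m))
  }
  mods
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    bulk = list(n_regions = 27L, n_genes = 2000L, n_replicates = 4L,
                n_modules = 8L, module_size = 25L, effect = 1.0),
    chip = list(rho = 0.8, n_replicates = 2L),
    scrna = list(n_types = 8L, n_genes = 1200L, n_markers_per_type = 10L,
                 cells_per_replicate = 120L, n_replicates = 5L,
                 proportion_shift = list(type = "type03", region = "dorDG",
                                         factor = 2),
                 module_shift = list(type = "type01", region = "dorDG",
                                     log2fc = 1),
                 regulon_shift = list(type = "type02", region = "dorDG",
                                      log2fc = 1, regulon = "regulon01"),
                 lr_shift = list(sender = "type04", region = "dorDG",
                                 log2fc = 1.5, pair = 1L)),
    thresholds = list(fc = log2(1.25), q_bulk = 0.1, q_pseudobulk = 0.2,
                      q_regulon = 0.1, alpha_proportion = 0.05),
    modules = list(k = 8L, n_restarts = 25L))
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Structural and range checks; no side effects. Unknown keys are
#' reported as errors, missing keys fall back to package defaults (a
#' missing seed is defaulted with a warning).
#'
#' @param config Path to a YAML file or a nested list.
#' @return List `config` (merged with defaults), `errors`, `warnings`.
#'   The configuration is usable iff `errors` is empty.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  errors <- character(); warnings <- character()
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errors <- c(errors, paste0("unknown config key: ", unknown))
  if (is.null(config$seed)) {
    warnings <- c(warnings, "seed missing; defaulting to 1")
  }
  merged <- merge_config(defaults, config[setdiff(names(config), unknown)])
  th <- merged$thresholds
  for (k in c("q_bulk", "q_pseudobulk", "q_regulon", "alpha_proportion")) {
    v <- th[[k]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1)
      errors <- c(errors, sprintf("thresholds.%s must lie in (0, 1)", k))
  }
  if (!is.numeric(th$fc) || th$fc < 0)
    errors <- c(errors, "thresholds.fc must be non-negative")
  if (!is.numeric(merged$chip$rho) || abs(merged$chip$rho) > 1)
    errors <- c(errors, "chip.rho must lie in [-1, 1]")
  for (k in c("n_regions", "n_genes", "n_replicates")) {
    if (merged$bulk[[k]] < 1)
      errors <- c(errors, sprintf("bulk.%s must be positive", k))
  }
  if (merged$bulk$n_replicates < 2)
    errors <- c(errors, "bulk.n_replicates must be at least 2")
  if (merged$modules$k < 1)
    errors <- c(errors, "modules.k must be at least 1")
  list(config = merged, errors = errors, warnings = warnings)
}

write_stage <- function(df, outdir, name) {
  write_tsv(df, file.path(outdir, name))
  name
}

#' Run the full synthetic study pipeline
#'
#' Orchestrates simulate -> bulk differential expression (per region) ->
#' ChIP differential acetylation (per region) -> sharing and module
#' discovery -> enrichment -> integration (promoter concordance,
#' composite region ranking, RRHO) -> single-cell stage, writing every
#' stage's tables as TSV under `outdir` and returning a run manifest.
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param config Path to a YAML configuration or a nested list (see
#'   [validate_config()]); `NULL` runs the packaged demo configuration.
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages to run, subset of
#'   `c("simulate", "bulk-de", "chip-da", "modules", "enrich",
#'   "integrate", "sc")`, or `"all"`. Later stages need the in-memory
#'   results of earlier ones, so a subset must be a prefix.
#' @param seed Optional override of the config seed.
#' @return Invisibly, the run manifest (also written as
#'   `manifest.json`): config hash, seed, stage status, file inventory
#'   with MD5 checksums, package version.
#' @export
run_pipeline <- function(config = NULL, outdir, stages = "all",
                         seed = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "demo_config.yaml",
                          package = "regionomics")
  val <- validate_config(config)
  if (length(val$errors))
    stop("configuration invalid:\n  ",
         paste(val$errors, collapse = "\n  "))
  for (w in val$warnings) message("config: ", w)
  cfg <- val$config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  all_stages <- c("simulate", "bulk-de", "chip-da", "modules", "enrich",
                  "integrate", "sc")
  if (identical(stages, "all")) stages <- all_stages
  if (!all(stages %in% all_stages))
    stop("unknown stage(s): ",
         paste(setdiff(stages, all_stages), collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  files <- character()
  status <- stats::setNames(rep("skipped", length(all_stages)), all_stages)
  log_msg <- function(...) message(sprintf("[regionomics] %s", sprintf(...)))

  th <- cfg$thresholds
  sim <- NULL; chip <- NULL; rna_de <- NULL; chip_da <- NULL
  ranking <- NULL

  run_one <- function(st, fun) {
    tic <- Sys.time()
    fun()
    status[st] <<- "ok"
    log_msg("stage %s done in %.1fs", st,
            as.numeric(difftime(Sys.time(), tic, units = "secs")))
  }

  # stage results are cached in memory and reloaded from a previous run's
  # outputs when a later stage is re-run on its own
  get_sim <- function() {
    if (!is.null(sim)) return(sim)
    sim <<- list(sham = read_counts_tsv(file.path(outdir, "rna_sham")),
                 treated = read_counts_tsv(file.path(outdir,
                                                     "rna_treated")),
                 truth = read_tsv(file.path(outdir, "rna_truth.tsv")))
    sim
  }
  get_chip <- function() {
    if (!is.null(chip)) return(chip)
    info <- jsonlite::read_json(file.path(outdir, "sim_info.json"))
    chip <<- list(sham = read_counts_tsv(file.path(outdir, "chip_sham")),
                  treated = read_counts_tsv(file.path(outdir,
                                                      "chip_treated")),
                  peaks = read_bed(file.path(outdir, "peaks.bed")),
                  tss = read_tsv(file.path(outdir, "tss.tsv")),
                  truth = read_tsv(file.path(outdir, "chip_truth.tsv")),
                  genome_size = info$genome_size)
    chip
  }
  load_de_tables <- function(prefix) {
    fs <- sort(list.files(outdir, sprintf("^%s_[^_]+\\.tsv$", prefix)))
    if (length(fs) == 0)
      stop("no ", prefix, " tables found in ", outdir,
           "; run the earlier stages first")
    res <- lapply(fs, function(f) read_tsv(file.path(outdir, f)))
    names(res) <- sub(sprintf("^%s_(.+)\\.tsv$", prefix), "\\1", fs)
    res
  }
  get_rna_de <- function() {
    if (is.null(rna_de)) rna_de <<- load_de_tables("rna_de")
    rna_de
  }
  get_chip_da <- function() {
    if (is.null(chip_da)) chip_da <<- load_de_tables("chip_da")
    chip_da
  }

  if ("simulate" %in% stages) run_one("simulate", function() {
    bcfg <- cfg$bulk
    mods <- demo_planted_modules(bcfg$n_genes,
                                 sprintf("R%02d", seq_len(bcfg$n_regions)),
                                 bcfg$n_modules, bcfg$module_size,
                                 bcfg$effect)
    bc <- bulk_sim_config(n_regions = bcfg$n_regions,
                          n_genes = bcfg$n_genes,
                          n_replicates = bcfg$n_replicates,
                          modules = mods, seed = derive_seed(cfg$seed, 1))
    sim <<- simulate_bulk(bc)
    chip <<- simulate_chip(sim$truth, rho = cfg$chip$rho,
                           n_replicates = cfg$chip$n_replicates,
                           seed = derive_seed(cfg$seed, 2))
    write_counts_tsv(sim$sham, file.path(outdir, "rna_sham"))
    write_counts_tsv(sim$treated, file.path(outdir, "rna_treated"))
    write_counts_tsv(chip$sham, file.path(outdir, "chip_sham"))
    write_counts_tsv(chip$treated, file.path(outdir, "chip_treated"))
    write_bed(chip$peaks, file.path(outdir, "peaks.bed"))
    write_tsv(chip$tss, file.path(outdir, "tss.tsv"))
    jsonlite::write_json(list(genome_size = chip$genome_size),
                         file.path(outdir, "sim_info.json"),
                         auto_unbox = TRUE)
    files <<- c(files, write_stage(sim$truth, outdir, "rna_truth.tsv"),
                write_stage(chip$truth, outdir, "chip_truth.tsv"),
                "rna_sham.counts.tsv", "rna_sham.samples.tsv",
                "rna_treated.counts.tsv", "rna_treated.samples.tsv",
                "chip_sham.counts.tsv", "chip_sham.samples.tsv",
                "chip_treated.counts.tsv", "chip_treated.samples.tsv",
                "peaks.bed", "tss.tsv", "sim_info.json")
  })

  if ("bulk-de" %in% stages) run_one("bulk-de", function() {
    sim <- get_sim()
    cm <- combine_counts(sim$sham, sim$treated)
    rna_de <<- test_differential_by_region(cm, fc_threshold = th$fc,
                                           q_threshold = th$q_bulk)
    for (r in names(rna_de))
      files <<- c(files, write_stage(rna_de[[r]], outdir,
                                     sprintf("rna_de_%s.tsv", r)))
  })

  if ("chip-da" %in% stages) run_one("chip-da", function() {
    chip <- get_chip()
    cm <- combine_counts(chip$sham, chip$treated)
    chip_da <<- test_differential_by_region(cm, fc_threshold = th$fc,
                                            q_threshold = th$q_bulk)
    for (r in names(chip_da))
      files <<- c(files, write_stage(chip_da[[r]], outdir,
                                     sprintf("chip_da_%s.tsv", r)))
  })

  if ("modules" %in% stages) run_one("modules", function() {
    for (mod in list(list(de = get_rna_de(), tag = "gene"),
                     list(de = get_chip_da(), tag = "peak"))) {
      fcm <- build_foldchange_matrix(mod$de)
      part <- cluster_modules(fcm, k = cfg$modules$k,
                              n_restarts = cfg$modules$n_restarts,
                              seed = derive_seed(cfg$seed, 3))
      asg <- data.frame(featureId = names(part$assignment),
                        module = unname(part$assignment),
                        stringsAsFactors = FALSE)
      cent <- data.frame(module = rownames(part$centers), part$centers,
                         check.names = FALSE)
      files <<- c(files,
                  write_stage(asg, outdir,
                              sprintf("%s_modules.tsv", mod$tag)),
                  write_stage(cent, outdir,
                              sprintf("%s_module_centroids.tsv", mod$tag)))
      sh <- sharing_summary(mod$de)
      files <<- c(files,
                  write_stage(sh$per_feature, outdir,
                              sprintf("%s_sharing.tsv", mod$tag)))
    }
  })

  if ("enrich" %in% stages) run_one("enrich", function() {
    sim <- get_sim(); chip <- get_chip()
    rna_de <- get_rna_de(); chip_da <- get_chip_da()
    # gene-set collection: the planted modules plus seeded random decoys
    genes <- rownames(sim$sham$counts)
    planted_sets <- lapply(planted_module_sets(sim$truth), unique)
    decoys <- with_local_seed(derive_seed(cfg$seed, 4), {
      lapply(1:5, function(i) sample(genes, 50))
    })
    names(decoys) <- sprintf("random%02d", 1:5)
    collection <- c(planted_sets, decoys)
    write_gmt(collection, file.path(outdir, "genesets.gmt"))
    files <<- c(files, "genesets.gmt")
    target <- names(rna_de)[1]
    d <- rna_de[[target]]
    tested <- d$featureId[!is.na(d$pValue)]
    degs <- d$featureId[d$status != "ns"]
    res <- ora(degs, collection, tested)
    files <<- c(files, write_stage(res, outdir,
                                   sprintf("ora_%s.tsv", target)))
    scores <- rrho_scores(d)
    g1 <- gsea(scores, collection[[1]], n_perm = 200,
               seed = derive_seed(cfg$seed, 5))
    gdf <- data.frame(setName = names(collection)[1], ES = g1$ES,
                      NES = g1$NES, pValue = g1$pValue,
                      setSize = g1$setSize,
                      leadingEdgeSize = length(g1$leadingEdge),
                      stringsAsFactors = FALSE)
    files <<- c(files, write_stage(gdf, outdir, "gsea_summary.tsv"))
    doms <- regulatory_domains(chip$tss, chip$genome_size)
    da_peaks <- chip_da[[target]]
    da_ids <- da_peaks$featureId[da_peaks$status != "ns"]
    pk <- chip$peaks[chip$peaks$name %in% da_ids, , drop = FALSE]
    if (nrow(pk) > 0) {
      gre <- region_enrichment_binomial(pk, doms, collection[[1]],
                                        chip$genome_size)
      gre$setName <- names(collection)[1]
      files <<- c(files, write_stage(gre, outdir,
                                     sprintf("great_%s.tsv", target)))
    }
  })

  if ("integrate" %in% stages) run_one("integrate", function() {
    chip <- get_chip()
    rna_de <- get_rna_de(); chip_da <- get_chip_da()
    asg <- assign_peaks_to_promoters(chip$peaks, chip$tss)
    files <<- c(files, write_stage(asg, outdir, "promoter_assignment.tsv"))
    conc <- lapply(names(rna_de), function(r) {
      res <- try(promoter_concordance(rna_de[[r]], chip_da[[r]], asg),
                 silent = TRUE)
      if (inherits(res, "try-error"))
        return(data.frame(region = r, nPairs = 0, rho = NA_real_,
                          pValue = NA_real_, stringsAsFactors = FALSE))
      data.frame(region = r, nPairs = res$nPairs, rho = res$rho,
                 pValue = res$pValue, stringsAsFactors = FALSE)
    })
    files <<- c(files, write_stage(do.call(rbind, conc), outdir,
                                   "promoter_concordance.tsv"))
    n_deg <- vapply(rna_de, function(d) sum(d$status != "ns"), numeric(1))
    n_da <- vapply(chip_da, function(d) sum(d$status != "ns"), numeric(1))
    ranking <<- composite_region_ranking(n_deg, n_da)
    files <<- c(files, write_stage(ranking, outdir, "region_ranking.tsv"))
    r1 <- names(rna_de)[1]; r2 <- names(rna_de)[min(2, length(rna_de))]
    rr <- rrho_map(rrho_scores(rna_de[[r1]]), rrho_scores(rna_de[[r2]]))
    grid <- data.frame(threshold1 = rep(rr$thresholds,
                                        times = length(rr$thresholds)),
                       threshold2 = rep(rr$thresholds,
                                        each = length(rr$thresholds)),
                       signedLogP = as.vector(rr$logp * rr$sign),
                       overlap = as.vector(rr$overlap))
    files <<- c(files, write_stage(grid, outdir,
                                   sprintf("rrho_%s_vs_%s.tsv", r1, r2)))
  })

  if ("sc" %in% stages) run_one("sc", function() {
    sc_args <- cfg$scrna
    sc_args$seed <- derive_seed(cfg$seed, 6)
    scfg <- do.call(scrna_sim_config, sc_args)
    sc <- simulate_scrna(scfg)
    write_cells_mtx(sc$sham, file.path(outdir, "sc_sham"))
    write_cells_mtx(sc$treated, file.path(outdir, "sc_treated"))
    files <<- c(files, "sc_sham.mtx", "sc_sham.features.tsv",
                "sc_sham.barcodes.tsv", "sc_sham.cells.tsv",
                "sc_treated.mtx", "sc_treated.features.tsv",
                "sc_treated.barcodes.tsv", "sc_treated.cells.tsv",
                write_stage(sc$truth, outdir, "sc_truth.tsv"))
    comb <- combine_cells(sc$sham, sc$treated)
    for (rg in unique(comb$meta$region)) {
      sub <- subset_cells(comb, cells = comb$meta$region == rg)
      norm <- qc_and_normalize(sub, min_genes = 200)
      typing <- assign_cell_types(norm, sc$reference,
                                  seed = derive_seed(cfg$seed, 7))
      files <<- c(files, write_stage(typing, outdir,
                                     sprintf("sc_%s_typing.tsv", rg)))
      labels <- typing$type
      props <- test_proportions(labels, norm$meta)
      files <<- c(files, write_stage(props, outdir,
                                     sprintf("sc_%s_proportions.tsv", rg)))
      de <- pseudobulk_de(norm, labels,
                          fc_threshold = th$fc,
                          q_threshold = th$q_pseudobulk)
      de_all <- do.call(rbind, lapply(names(de), function(tp)
        cbind(cellType = tp, de[[tp]])))
      if (!is.null(de_all))
        files <<- c(files, write_stage(de_all, outdir,
                                       sprintf("sc_%s_pseudobulk_de.tsv",
                                               rg)))
      ms <- score_gene_module(norm, sc$module_genes, labels,
                              seed = derive_seed(cfg$seed, 8))
      files <<- c(files, write_stage(ms$by_type, outdir,
                                     sprintf("sc_%s_module_scores.tsv",
                                             rg)))
      ra <- regulon_activity_and_diff(norm, sc$regulons, labels,
                                      q_threshold = th$q_regulon)
      files <<- c(files, write_stage(ra$by_type, outdir,
                                     sprintf("sc_%s_regulons.tsv", rg)))
      lr <- lr_edges_and_diff(norm, labels, sc$lr_pairs)
      files <<- c(files, write_stage(lr, outdir,
                                     sprintf("sc_%s_lr_edges.tsv", rg)))
    }
  })

  # config hash over the canonical YAML rendering
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  inventory <- sort(unique(files))
  md5 <- unname(tools::md5sum(file.path(outdir, inventory)))
  manifest <- list(config_hash = cfg_hash, seed = cfg$seed,
                   stages = as.list(status),
                   files = stats::setNames(as.list(md5), inventory),
                   version = as.character(utils::packageVersion("regionomics")),
                   elapsed_sec = round(as.numeric(
                     difftime(Sys.time(), t0, units = "secs")), 1))
  tmp <- file.path(outdir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, file.path(outdir, "manifest.json"))
  log_msg("pipeline complete: %d files in %s", length(inventory), outdir)
  invisible(manifest)
}

# planted module gene sets reconstructed from a bulk truth table: genes
# sharing an identical nonzero effect profile across regions form one set
planted_module_sets <- function(truth) {
  regions <- unique(truth$region)
  genes <- unique(truth$featureId)
  eff <- matrix(truth$trueLog2FC[
    match(paste(rep(genes, length(regions)),
                rep(regions, each = length(genes))),
          paste(truth$featureId, truth$region))],
    length(genes), length(regions), dimnames = list(genes, regions))
  nz <- which(rowSums(eff != 0) > 0)
  if (length(nz) == 0) return(list())
  prof <- apply(eff[nz, , drop = FALSE], 1, paste, collapse = ",")
  sets <- split(names(prof), prof)
  names(sets) <- sprintf("planted%02d", seq_along(sets))
  sets
}
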