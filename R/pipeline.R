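#' Default pipeline configuration
#'
#' A nested list driving [run_pipeline()]: a `synthetic` block (a
#' [synthetic_config()]) plus per-stage parameter blocks.  Any YAML file with
#' the same structure can be loaded with [read_run_config()].
#'
#' @param seed Master seed stored in the synthetic block.
#' @return A nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(synthetic = synthetic_config(seed = seed),
       peaks = list(window_bp = 500L, step_bp = 125L, alpha = 0.05,
                    min_support = 3L),
       telomere_window_bp = 15000L,
       features = list(n_features = 100L, n_overlapping = 30L,
                       feature_width_bp = 500L),
       overlap = list(n_iter = 1000L),
       composition = list(n_iter = 1000L),
       hic = list(bin_size = 10000L, read_len = 75L, tol = 1e-8,
                  max_iter = 1000L),
       proximity = list(n_iter = 200L, k_tel = 1L, all_telomeres = FALSE))
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing blocks fall back to
#' [default_run_config()] values.
#'
#' @param path Path to a YAML file.
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  merge_block <- function(b, u, where) {
    bad <- setdiff(names(u), names(b))
    if (length(bad))
      stop("unknown config key(s) in ", where, ": ", paste(bad, collapse = ", "))
    b[names(u)] <- u
    b
  }
  if (!is.null(user$synthetic)) {
    args <- merge_block(unclass(default_run_config()$synthetic),
                        user$synthetic, "synthetic")
    base$synthetic <- do.call(synthetic_config, args[names(formals(synthetic_config))])
    user$synthetic <- NULL
  }
  bad <- setdiff(names(user), names(base))
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in names(user)) {
    base[[blk]] <- if (is.list(base[[blk]]))
      merge_block(base[[blk]], user[[blk]], blk) else user[[blk]]
  }
  base
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulate -> callpeaks -> composition -> overlap -> hic ->
#' proximity -> healing -> report from one configuration.  Every stage
#' writes its artifacts under `outdir`, and a manifest records parameters,
#' derived seeds, artifact checksums and the package version, so re-running
#' with an unchanged config is byte-identical.
#'
#' @param config A configuration list ([default_run_config()]) or a path to
#'   a YAML file.
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages to run (default all, in order).
#' @return The report list, invisibly; artifacts and `manifest.json` +
#'   `report.json` under `outdir`.
#' @export
run_pipeline <- function(config = default_run_config(), outdir,
                         stages = c("simulate", "callpeaks", "composition",
                                    "overlap", "hic", "proximity", "healing",
                                    "report")) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config$synthetic
  pth <- function(...) file.path(outdir, ...)
  manifest <- list(package_version = as.character(utils::packageVersion("ntbsmap")),
                   seed = cfg$seed, stages = list())
  note <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      parameters = params,
      artifacts = as.list(tools::md5sum(files)))
    message("[", stage, "] done: ", paste(basename(files), collapse = ", "))
  }

  sim <- NULL
  load_sim <- function() {
    if (is.null(sim)) {
      assembly <- read_genome_fasta(pth("genome.fa"))
      sim <<- list(assembly = assembly,
                   ntbs = read_bed(pth("planted_ntbs.bed"), assembly),
                   features = read_bed(pth("features.bed"), assembly))
      names(sim$ntbs) <<- S4Vectors::mcols(sim$ntbs)$name
    }
    sim
  }

  if ("simulate" %in% stages) {
    g <- make_genome(cfg)
    write_genome_fasta(g$assembly, pth("genome.fa"))
    write_chrom_sizes(chrom_lengths(g$assembly), pth("genome.chrom.sizes"))
    write_bed(g$ntbs, pth("planted_ntbs.bed"))
    tracks <- make_chip_replicates(g$assembly, g$ntbs, cfg)
    write_probe_tracks(tracks, pth("probe_tracks.tsv"))
    feats <- make_feature_track(g$ntbs, g$assembly,
                                config$features$n_features,
                                config$features$n_overlapping,
                                config$features$feature_width_bp,
                                seed = derive_seed(cfg$seed, 4L))
    write_bed(feats, pth("features.bed"))
    hic <- make_hic_pairs(g$assembly, g$ntbs, cfg)
    write_pairs(hic$pairs, pth("hic_pairs.tsv"))
    write_bed(g$ntbs[hic$planted], pth("planted_telomere_proximal.bed"))
    healing <- make_healing_counts(
      c(TG80 = 1, N80 = 0, NTBS_1 = cfg$healing_freq,
        NTBS_2 = cfg$healing_freq, NTBS_3 = cfg$healing_freq,
        NTBS_4 = cfg$healing_freq),
      cfg$n_colonies, seed = derive_seed(cfg$seed, 5L))
    utils::write.table(healing, pth("healing_counts.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
    note("simulate", unclass(cfg),
         pth(c("genome.fa", "planted_ntbs.bed", "probe_tracks.tsv",
               "features.bed", "hic_pairs.tsv", "healing_counts.csv")))
  }

  if ("callpeaks" %in% stages) {
    s <- load_sim()
    tracks <- read_probe_tracks(pth("probe_tracks.tsv"))
    pk <- config$peaks
    peaksets <- lapply(tracks, call_peaks, window_bp = pk$window_bp,
                       step_bp = pk$step_bp, alpha = pk$alpha,
                       assembly = s$assembly)
    consensus <- replicate_consensus(peaksets, min_support = pk$min_support)
    tel <- telomere_windows(s$assembly, config$telomere_window_bp)
    called <- subtract_telomeric(consensus, tel)
    S4Vectors::mcols(called)$name <- sprintf("site_%03d", seq_along(called))
    S4Vectors::mcols(called)$score <- S4Vectors::mcols(called)$window_p
    write_bed(called, pth("called_ntbs.bed"))
    summary_df <- data.frame(
      replicate = c(seq_along(peaksets), NA),
      n_peaks = c(vapply(peaksets, length, integer(1)), length(called)),
      set = c(rep("replicate", length(peaksets)), "consensus_non_telomeric"))
    utils::write.table(summary_df, pth("peak_summary.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
    note("callpeaks", pk, pth(c("called_ntbs.bed", "peak_summary.csv")))
  }

  report <- list()
  called <- function() {
    s <- load_sim()
    read_bed(pth("called_ntbs.bed"), s$assembly)
  }

  if ("composition" %in% stages) {
    s <- load_sim()
    sites <- called()
    gt <- gc_permutation_test(sites, s$assembly,
                              n_iter = config$composition$n_iter,
                              seed = derive_seed(cfg$seed, 6L))
    report$composition <- list(gc_sites = gt$observed,
                               gc_genome = gc_content(NULL, s$assembly),
                               null_mean = mean(gt$null), p_value = gt$p_value)
  }

  if ("overlap" %in% stages) {
    s <- load_sim()
    ot <- overlap_permutation_test(s$features, called(), s$assembly,
                                   n_iter = config$overlap$n_iter,
                                   seed = derive_seed(cfg$seed, 7L))
    report$overlap <- list(observed = ot$observed, n_features = length(s$features),
                           null_mean = mean(ot$null), p_value = ot$p_value)
  }

  if ("hic" %in% stages) {
    s <- load_sim()
    pairs <- read_pairs(pth("hic_pairs.tsv"))
    rmap <- digest_genome(s$assembly)
    cl <- classify_pairs(pairs, rmap)
    valid <- cl$pairs[cl$pairs$class == "valid", ]
    cm <- bin_pairs(valid, s$assembly, bin_size = config$hic$bin_size,
                    read_len = config$hic$read_len)
    bal <- balance_matrix(cm, tol = config$hic$tol,
                          max_iter = config$hic$max_iter)
    write_contact_matrix(bal, pth("contact_matrix.tsv"))
    report$hic <- list(census = as.list(cl$census),
                       balance_residual = bal$balance$residual,
                       balance_iterations = bal$balance$iterations,
                       masked_bins = sum(bal$mask))
    note("hic", config$hic, pth("contact_matrix.tsv"))
  }

  if ("proximity" %in% stages) {
    s <- load_sim()
    cm <- read_contact_matrix(pth("contact_matrix.tsv"))
    sites <- called()
    names(sites) <- S4Vectors::mcols(sites)$name
    prox <- classify_sites(cm, sites, k_tel = config$proximity$k_tel,
                           all_telomeres = config$proximity$all_telomeres)
    utils::write.table(prox$sites, pth("proximity_sites.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
    ## control regions obey the site-placement constraints (telomere window
    ## plus one bin), so the randomization is matched
    tel <- telomere_windows(s$assembly,
                            config$telomere_window_bp + config$hic$bin_size)
    rt <- proximity_randomization_test(cm, sites, s$assembly,
                                       n_iter = config$proximity$n_iter,
                                       seed = derive_seed(cfg$seed, 8L),
                                       exclude = tel)
    report$proximity <- c(prox$summary,
                          list(wilcoxon_W = rt$W, wilcoxon_p = rt$p_value))
    note("proximity", config$proximity, pth("proximity_sites.csv"))
  }

  if ("healing" %in% stages) {
    healing <- utils::read.csv(pth("healing_counts.csv"))
    hf <- healing_frequency(healing)
    report$healing <- stats::setNames(as.list(hf$frequency), hf$construct)
  }

  if ("report" %in% stages) {
    jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(report)
}
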