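#' @noRd
default_pipeline_config <- function() {
  list(
    outdir = "seneschic_out",
    seed = 1L,
    bin_size = 40000L,
    synthetic = list(),                 # overrides for synthetic_config()
    ice = list(n_iter = 30L, low_coverage_quantile = 0.02),
    pca = list(sahf_threshold = -20, min_compartment_bins = 5L),
    tads = list(window_bins = 13L, z_min = 1.0),
    lvs = list(distance_cutoff = 2e6, flag_threshold = 0.5),
    gsea = list(n_perm = 1000L, weight = 1),
    windows = list(width = 2e5, max_distance = 2e6)
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills in defaults for every
#' unset key, and rejects unknown keys at any level.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The effective configuration list, with class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- default_pipeline_config()
  merge_level <- function(user, def, path) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown) && path != "synthetic") {
      stop("unknown config key", if (length(unknown) > 1) "s", ": ",
           paste0(path, if (nzchar(path)) ".", unknown, collapse = ", "),
           call. = FALSE)
    }
    for (k in names(user)) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
        def[[k]] <- merge_level(user[[k]], def[[k]], k)
      } else {
        if (!is.list(user[[k]]) && !is.null(def[[k]]) &&
            is.numeric(def[[k]]) && !is.numeric(user[[k]])) {
          stop("config key ", paste0(path, if (nzchar(path)) ".", k),
               " must be numeric", call. = FALSE)
        }
        def[[k]] <- user[[k]]
      }
    }
    def
  }
  # synthetic block is validated by synthetic_config() itself
  syn <- config$synthetic
  config$synthetic <- NULL
  eff <- merge_level(config, defaults, "")
  if (!is.null(syn)) {
    bad <- setdiff(names(syn), names(formals(synthetic_config)))
    if (length(bad)) {
      stop("unknown config keys: ",
           paste0("synthetic.", bad, collapse = ", "), call. = FALSE)
    }
    eff$synthetic <- syn
  }
  eff$seed <- as.integer(eff$seed)
  class(eff) <- c("pipeline_config", "list")
  eff
}

#' @noRd
stage_seed <- function(config, stage) {
  offs <- c(simulate = 11L, normalize = 23L, pca = 37L, compartments = 53L,
            sahf = 71L, tads = 89L, enrich = 107L)
  (config$seed * 1009L + offs[[stage]]) %% .Machine$integer.max
}

#' Run the senescence Hi-C analysis pipeline end-to-end
#'
#' Executes the requested stages in dependency order on a synthetic dataset:
#' `simulate` (generate truth, contact matrices, tracks and genes),
#' `normalize` (ICE), `pca` (compartment scores), `compartments`
#' (A/B calls, transitions, BAB flags), `sahf` (SAHF regions and LVS),
#' `tads` (border strength and borders), `enrich` (GSEA on switch-region
#' genes, SAHF distance-window sweep, replicate-style overlaps). Every
#' output file is listed in a JSON report with its checksum, the per-stage
#' seeds and the effective parameters; a rerun with the same configuration
#' is byte-identical.
#'
#' @param config A [validate_config()] result, a config list, or a YAML
#'   path.
#' @param stages Character subset of
#'   `c("simulate","normalize","pca","compartments","sahf","tads","enrich")`
#'   or `"all"`.
#' @return The report list, invisibly; also written to
#'   `<outdir>/report.json`.
#' @export
run_pipeline <- function(config = list(), stages = "all") {
  all_stages <- c("simulate", "normalize", "pca", "compartments", "sahf",
                  "tads", "enrich")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  stages <- all_stages[all_stages %in% stages]
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package = "seneschic",
                 version = as.character(utils::packageVersion("seneschic")),
                 seed = config$seed, stages = stages,
                 parameters = unclass(config), outputs = list())
  log_msg <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }
  add_output <- function(stage, path) {
    report$outputs[[length(report$outputs) + 1L]] <<-
      list(stage = stage, path = path,
           md5 = unname(tools::md5sum(path)))
  }
  need <- function(path, produced_by) {
    if (!file.exists(path)) {
      stop("missing upstream output ", path,
           "; run stage '", produced_by, "' first", call. = FALSE)
    }
    path
  }

  syn_args <- config$synthetic
  syn_args$seed <- stage_seed(config, "simulate")
  syn_args$bin_size <- config$bin_size
  cfg_syn <- do.call(synthetic_config, syn_args)
  conditions <- c("growing", "senescent", "kd")

  chrom_file <- file.path(outdir, "chromosomes.tsv")
  mat_file <- function(cond, chrom, kind) {
    file.path(outdir, sprintf("contacts_%s_%s_%s.txt", cond, chrom, kind))
  }
  load_grid <- function() {
    ch <- utils::read.table(need(chrom_file, "simulate"), header = TRUE,
                            sep = "\t", comment.char = "#")
    lapply(stats::setNames(seq_len(nrow(ch)), ch$chrom), function(i) {
      genome_bins(ch$chrom[i], ch$length[i], ch$bin_size[i])
    })
  }

  if ("simulate" %in% stages) {
    log_msg("simulate", "planting architecture and simulating data")
    truth <- plant_architecture(cfg_syn)
    write_truth(truth, file.path(outdir, "truth"))
    add_output("simulate", file.path(outdir, "truth", "truth_bins.tsv"))
    add_output("simulate", file.path(outdir, "truth", "truth_config.json"))
    write_tsv_prov(
      dplyr::mutate(cfg_syn$chromosomes, bin_size = cfg_syn$bin_size),
      chrom_file)
    add_output("simulate", chrom_file)
    for (cond in conditions) {
      for (chrom in names(truth$bins)) {
        m <- simulate_contacts(truth, chrom, cond)
        write_contacts(m, mat_file(cond, chrom, "raw"))
        add_output("simulate", mat_file(cond, chrom, "raw"))
      }
    }
    et <- simulate_expression_and_tracks(truth)
    write_tsv_prov(et$genes, file.path(outdir, "genes.tsv"))
    write_tsv_prov(et$tracks, file.path(outdir, "tracks.tsv"))
    add_output("simulate", file.path(outdir, "genes.tsv"))
    add_output("simulate", file.path(outdir, "tracks.tsv"))
  }

  if ("normalize" %in% stages) {
    grids <- load_grid()
    for (cond in conditions) {
      for (chrom in names(grids)) {
        m <- read_contacts(need(mat_file(cond, chrom, "raw"), "simulate"),
                           grids[[chrom]])
        log_msg("normalize", sprintf("ICE %s %s", cond, chrom))
        mi <- ice_normalize(m, n_iter = config$ice$n_iter,
                            low_coverage_quantile = config$ice$low_coverage_quantile)
        write_contacts(mi, mat_file(cond, chrom, "iced"))
        add_output("normalize", mat_file(cond, chrom, "iced"))
      }
    }
  }

  read_iced <- function(cond, chrom, grids) {
    m <- read_contacts(need(mat_file(cond, chrom, "iced"), "normalize"),
                       grids[[chrom]])
    m$normalized <- TRUE
    m$mask <- setdiff(seq_len(n_bins(m)), which(rowSums(m$counts) > 0)) - 1L
    m
  }
  tracks_path <- file.path(outdir, "tracks.tsv")
  pca_file <- function(cond, chrom) {
    file.path(outdir, sprintf("pca_%s_%s.bedgraph", cond, chrom))
  }
  load_pca <- function(cond, chrom, grids) {
    tr <- read_bedgraph(need(pca_file(cond, chrom), "pca"), "score")
    g <- grids[[chrom]]
    out <- g
    out$score <- tr$score[match(g$start, tr$start)]
    attr(out, "bin_size") <- bins_bin_size(g)
    out
  }

  if ("pca" %in% stages) {
    grids <- load_grid()
    tracks <- tibble::as_tibble(
      utils::read.table(need(tracks_path, "simulate"), header = TRUE,
                        sep = "\t", comment.char = "#"))
    for (cond in conditions) {
      for (chrom in names(grids)) {
        m <- read_iced(cond, chrom, grids)
        gd <- tracks$gene_density[tracks$chrom == chrom]
        log_msg("pca", sprintf("compartment scores %s %s", cond, chrom))
        pt <- pca_scores(m, gd)
        write_bedgraph(pt, pca_file(cond, chrom), "score")
        add_output("pca", pca_file(cond, chrom))
      }
    }
  }

  if ("compartments" %in% stages) {
    grids <- load_grid()
    comp_rows <- list()
    trans_rows <- list()
    for (chrom in names(grids)) {
      tg <- load_pca("growing", chrom, grids)
      ts <- load_pca("senescent", chrom, grids)
      tk <- load_pca("kd", chrom, grids)
      for (cond in conditions) {
        tt <- switch(cond, growing = tg, senescent = ts, kd = tk)
        cc <- call_compartments(tt, config$pca$min_compartment_bins)
        comp_rows[[paste(cond, chrom)]] <- dplyr::mutate(cc, condition = cond)
      }
      tm_ois <- classify_transitions(tg, ts)
      tm_kd <- classify_transitions(ts, tk)
      tm_ois$bab <- classify_bab(tm_ois, tm_kd)
      tm_ois$category_kd <- tm_kd$category
      trans_rows[[chrom]] <- tm_ois
    }
    comp <- dplyr::bind_rows(comp_rows)
    comp$name <- paste0(comp$label, "_", comp$condition)
    write_bed(comp, file.path(outdir, "compartments.bed"))
    add_output("compartments", file.path(outdir, "compartments.bed"))
    trans <- dplyr::bind_rows(trans_rows)
    write_tsv_prov(trans, file.path(outdir, "transitions.tsv"))
    add_output("compartments", file.path(outdir, "transitions.tsv"))
  }

  if ("sahf" %in% stages) {
    grids <- load_grid()
    sahf_rows <- list()
    lvs_rows <- list()
    for (chrom in names(grids)) {
      ts <- load_pca("senescent", chrom, grids)
      sr <- detect_sahf(ts, config$pca$sahf_threshold)
      sahf_rows[[chrom]] <- sr
      m <- read_iced("senescent", chrom, grids)
      lv <- lvs_scores(m, config$lvs$distance_cutoff)
      lvs_rows[[chrom]] <- lv
    }
    sahf <- dplyr::bind_rows(sahf_rows)
    sahf$name <- "SAHF"
    write_bed(sahf, file.path(outdir, "sahf.bed"))
    add_output("sahf", file.path(outdir, "sahf.bed"))
    lvs <- dplyr::bind_rows(lvs_rows)
    write_bedgraph(lvs, file.path(outdir, "lvs_senescent.bedgraph"), "lvs")
    add_output("sahf", file.path(outdir, "lvs_senescent.bedgraph"))
  }

  if ("tads" %in% stages) {
    grids <- load_grid()
    for (cond in conditions) {
      bs_tracks <- lapply(names(grids), function(chrom) {
        m <- read_iced(cond, chrom, grids)
        border_strength(m, config$tads$window_bins)
      })
      bs_tracks <- pool_border_z(bs_tracks)
      borders <- dplyr::bind_rows(lapply(bs_tracks, call_tad_borders,
                                         z_min = config$tads$z_min))
      bs_all <- dplyr::bind_rows(bs_tracks)
      write_bedgraph(bs_all, file.path(outdir, sprintf("border_z_%s.bedgraph", cond)), "z")
      borders$name <- "TAD_border"
      write_bed(borders, file.path(outdir, sprintf("tad_borders_%s.bed", cond)))
      add_output("tads", file.path(outdir, sprintf("border_z_%s.bedgraph", cond)))
      add_output("tads", file.path(outdir, sprintf("tad_borders_%s.bed", cond)))
    }
  }

  if ("enrich" %in% stages) {
    genes <- tibble::as_tibble(
      utils::read.table(need(file.path(outdir, "genes.tsv"), "simulate"),
                        header = TRUE, sep = "\t", comment.char = "#"))
    trans <- tibble::as_tibble(
      utils::read.table(need(file.path(outdir, "transitions.tsv"), "compartments"),
                        header = TRUE, sep = "\t", comment.char = "#"))
    sahf <- tibble::as_tibble(
      utils::read.table(need(file.path(outdir, "sahf.bed"), "sahf"),
                        header = FALSE, sep = "\t", comment.char = "#",
                        col.names = c("chrom", "start", "end", "name")))
    ranked <- tibble::tibble(gene_id = genes$gene_id, score = genes$log2_fc)
    ba_bins <- trans[!is.na(trans$category) & trans$category == "BA", ]
    ab_bins <- trans[!is.na(trans$category) & trans$category == "AB", ]
    gseed <- stage_seed(config, "enrich")
    res <- list()
    for (ct in c("BA", "AB")) {
      tb <- if (ct == "BA") ba_bins else ab_bins
      ids <- genes_in_intervals(genes, tb)
      if (length(ids) >= 5 && length(ids) < nrow(genes)) {
        g <- preranked_gsea(ranked, ids, n_perm = config$gsea$n_perm,
                            seed = gseed, weight = config$gsea$weight)
        res[[ct]] <- dplyr::mutate(g, gene_set = paste0(ct, "_region_genes"))
      }
    }
    gsea_tab <- dplyr::bind_rows(res)
    write_tsv_prov(gsea_tab, file.path(outdir, "gsea.tsv"))
    add_output("enrich", file.path(outdir, "gsea.tsv"))
    sweep <- sahf_window_sweep(genes, sahf, width = config$windows$width,
                               max_distance = config$windows$max_distance)
    write_tsv_prov(sweep, file.path(outdir, "sahf_window_sweep.tsv"))
    add_output("enrich", file.path(outdir, "sahf_window_sweep.tsv"))
  }

  report$stage_seeds <- lapply(stats::setNames(nm = stages),
                               function(s) stage_seed(config, s))
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
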