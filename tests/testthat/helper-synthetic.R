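# Shared synthetic fixtures, built once per test run at the generator's
# canonical seed (the synthetic_config default) and cached.

.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (!exists("sim", envir = .fixture_env)) {
    cfg <- synthetic_config()
    truth <- plant_architecture(cfg)
    b <- truth$bins[["chrS1"]]
    m_grow <- simulate_contacts(truth, "chrS1", "growing")
    m_sen <- simulate_contacts(truth, "chrS1", "senescent")
    ice_grow <- ice_normalize(m_grow)
    ice_sen <- ice_normalize(m_sen)
    expr <- simulate_expression_and_tracks(truth)
    gd <- expr$tracks$gene_density[expr$tracks$chrom == "chrS1"]
    pca_grow <- suppressWarnings(pca_scores(ice_grow, gd))
    pca_sen <- suppressWarnings(pca_scores(ice_sen, gd))
    assign("sim", list(cfg = cfg, truth = truth, bins = b,
                       m_grow = m_grow, m_sen = m_sen,
                       ice_grow = ice_grow, ice_sen = ice_sen,
                       expr = expr, gene_density = gd,
                       pca_grow = pca_grow, pca_sen = pca_sen),
           envir = .fixture_env)
  }
  get("sim", envir = .fixture_env)
}

# small symmetric random contact matrix on a toy grid
random_matrix <- function(n, seed, bin_size = 40000L) {
  withr::with_seed(seed, {
    x <- matrix(rpois(n * n, 20), n, n)
    x <- x + t(x)
    contact_matrix(x, genome_bins("toy", n * bin_size, bin_size),
                   normalized = TRUE)
  })
}

# truth-label score tracks (+1 for A, -1 for B) for transition logic tests
label_track <- function(bins, labels) {
  out <- genome_bins(bins$chrom[1], max(bins$end), attr(bins, "bin_size") %||% 40000L)
  out$score <- ifelse(labels == "A", 1, -1)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
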