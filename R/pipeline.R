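#' Run the full promoter-profiling pipeline from one configuration
#'
#' Orchestrates the stages end to end — simulate (or load) fragments,
#' optional GC correction, control pooling, RPKM promoter matrix,
#' differential testing, and downstream PCA / clustering / enrichment —
#' writing every stage's table plus a JSON run manifest to `out_dir`.
#' One global seed fans out to per-stage seeds by fixed offsets so each
#' stage is independently reproducible; identical config and seed give
#' identical manifest counts and call sets.
#'
#' The configuration is a nested list (or a YAML file with the same shape):
#'
#' * `simulate`: arguments for [synthetic_spec()] plus `n_case`, `n_control`
#'   and optional `control_depth` (defaults 0.25, vs `mean_depth` for cases);
#'   **or** `inputs`: paths `sample_sheet`, `tss`, and optional `reference`.
#' * `params`: any of `window_halfwidth`, `pool_size`, `fc_threshold`,
#'   `alpha`, `fdr_threshold`, `pseudocount`, `gc_bins`, `top_n`,
#'   `gc_correct` (logical), `fdr_scope`.
#' * `gene_sets`: optional path to a gene-set file for the
#'   over-representation stage.
#'
#' @param config A list or a path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer global seed; overrides `config$seed`.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  seed <- seed %||% config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  par <- utils::modifyList(
    list(
      window_halfwidth = 1000, pool_size = 4, fc_threshold = 1.5,
      alpha = 0.05, fdr_threshold = 0.2, pseudocount = 0.5, gc_bins = 100,
      top_n = 500, gc_correct = FALSE, fdr_scope = "tested",
      control_label = "control"
    ),
    config$params %||% list()
  )
  manifest <- list(
    tool = paste0("cftss ", as.character(utils::packageVersion("cftss"))),
    seed = seed,
    config = config,
    stages = list()
  )
  add_stage <- function(name, counts, paths = list()) {
    manifest$stages[[name]] <<- list(counts = counts, paths = paths)
  }

  ## stage 1: inputs --------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    n_case <- sim_args$n_case %||% 20
    n_control <- sim_args$n_control %||% 20
    control_depth <- sim_args$control_depth %||% 0.25
    sim_args[c("n_case", "n_control", "control_depth")] <- NULL
    spec_case <- do.call(synthetic_spec, sim_args)
    spec_control <- spec_case
    spec_control$mean_depth <- control_depth
    sim <- simulate_cohorts(spec_case, spec_control,
      n_case = n_case, n_control = n_control,
      seed = derive_seed(seed, 1)
    )
    samples <- sim$samples
    tss <- sim$tss
    reference <- sim$reference
    truth_path <- file.path(out_dir, "truth.tsv")
    write_table(sim$truth, truth_path)
    add_stage("simulate",
      counts = list(
        n_genes = nrow(tss), n_case = n_case, n_control = n_control,
        n_differential_planted = sum(sim$truth$is_differential)
      ),
      paths = list(truth = truth_path)
    )
  } else if (!is.null(config$inputs)) {
    sheet <- read_sample_sheet(config$inputs$sample_sheet)
    tss <- read_tss_table(config$inputs$tss)
    reference <- if (!is.null(config$inputs$reference)) {
      read_reference(config$inputs$reference)
    }
    frags <- purrr::map(sheet$fragment_path, read_fragments)
    samples <- dplyr::mutate(
      dplyr::select(sheet, -"fragment_path"),
      fragments = frags
    )
    if (!"total_mapped_fragments" %in% names(samples)) {
      samples$total_mapped_fragments <- purrr::map_int(frags, nrow)
    }
    add_stage("load", counts = list(
      n_samples = nrow(samples),
      n_fragments = sum(purrr::map_int(frags, nrow))
    ))
  } else {
    abort("Config must contain either a `simulate` block or an `inputs` block.")
  }

  ## stage 2: GC correction -------------------------------------------------
  if (isTRUE(par$gc_correct)) {
    if (is.null(reference)) {
      abort("GC correction requires a reference genome.")
    }
    gc_seed <- derive_seed(seed, 2)
    samples$fragments <- purrr::map(samples$fragments, function(fr) {
      fr <- annotate_gc(fr, reference)
      model <- estimate_gc_bias(fr, reference,
        gc_bins = par$gc_bins, seed = gc_seed
      )
      apply_gc_correction(fr, model)
    })
    add_stage("gc_correct", counts = list(gc_bins = par$gc_bins))
  }

  ## stage 3: pool controls -------------------------------------------------
  is_control <- samples$cohort == par$control_label
  if (sum(is_control) >= par$pool_size && par$pool_size > 1) {
    pools <- pool_controls(samples[is_control, , drop = FALSE],
      pool_size = par$pool_size, seed = derive_seed(seed, 3)
    )
    analysis_samples <- dplyr::bind_rows(samples[!is_control, , drop = FALSE], pools)
    add_stage("pool", counts = list(
      n_controls_in = sum(is_control),
      pool_size = par$pool_size,
      n_pools = nrow(pools)
    ))
  } else {
    analysis_samples <- samples
    pools <- NULL
  }

  ## stage 4: RPKM promoter matrix -----------------------------------------
  rpkm <- rpkm_matrix(analysis_samples, tss,
    window_halfwidth = par$window_halfwidth
  )
  rpkm_path <- file.path(out_dir, "rpkm.tsv")
  write_table(tibble::as_tibble(rpkm), rpkm_path)
  sheet_path <- file.path(out_dir, "analysis_samples.tsv")
  write_table(
    dplyr::select(analysis_samples, -dplyr::any_of(c("fragments", "members"))),
    sheet_path
  )
  add_stage("profile",
    counts = list(
      n_samples = nrow(analysis_samples),
      n_tss = dplyr::n_distinct(rpkm$gene_id),
      window_halfwidth = par$window_halfwidth
    ),
    paths = list(rpkm = rpkm_path, sample_sheet = sheet_path)
  )

  ## stage 5: differential testing -----------------------------------------
  diff <- differential_tss(rpkm, analysis_samples,
    fc_threshold = par$fc_threshold, alpha = par$alpha,
    fdr_threshold = par$fdr_threshold, pseudocount = par$pseudocount,
    fdr_scope = par$fdr_scope, control_label = par$control_label
  )
  diff_path <- file.path(out_dir, "differential.tsv")
  write_table(tidy(diff), diff_path)
  volcano_path <- file.path(out_dir, "volcano.tsv")
  write_table(volcano_table(diff), volcano_path)
  add_stage("difftest",
    counts = as.list(glance(diff)[c("n_tss", "n_tested", "n_up", "n_down")]),
    paths = list(differential = diff_path, volcano = volcano_path)
  )

  ## stage 6: downstream ----------------------------------------------------
  pca <- pca_samples(rpkm)
  pca_path <- file.path(out_dir, "pca_scores.tsv")
  write_table(tidy(pca), pca_path)
  down_counts <- list(pca_components = length(pca$explained))
  down_paths <- list(pca = pca_path)

  if (any(diff$call != "ns")) {
    clust <- cluster_samples(rpkm, records = diff)
    tree_path <- file.path(out_dir, "sample_tree.nwk")
    write_newick(clust, tree_path)
    heat_path <- file.path(out_dir, "heatmap_matrix.tsv")
    hm <- heatmap_matrix(rpkm, diff)
    write_table(
      dplyr::bind_cols(
        tibble::tibble(sample_id = rownames(hm)),
        tibble::as_tibble(hm)
      ),
      heat_path
    )
    down_counts$n_clustered_tss <- ncol(hm)
    down_paths$tree <- tree_path
    down_paths$heatmap <- heat_path
  }
  if (!is.null(config$gene_sets)) {
    sets <- read_gene_sets(config$gene_sets)
    enr <- hypergeom_enrich(
      selected = diff$gene_id[diff$call != "ns"],
      gene_sets = sets,
      population = unique(diff$gene_id)
    )
    enr_path <- file.path(out_dir, "enrichment.tsv")
    write_table(dplyr::select(enr, -"overlap_genes"), enr_path)
    down_counts$n_gene_sets_tested <- nrow(enr)
    down_paths$enrichment <- enr_path
  }
  add_stage("downstream", counts = down_counts, paths = down_paths)

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  invisible(manifest)
}
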