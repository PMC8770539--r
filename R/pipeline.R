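#' Pipeline configuration with validated defaults
#'
#' Builds the nested configuration consumed by [run_pipeline()]. Any field
#' can be overridden; unknown fields are rejected. `seed` drives every
#' stochastic stage.
#'
#' @param ... Named overrides of the defaults, possibly nested lists
#'   (e.g. `sim = list(n_probes = 300)`).
#' @param seed Integer seed (mandatory for the stochastic stages).
#' @param out Output directory of the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(..., seed = 1, out = tempfile("methorigin_run_")) {
  defaults <- list(
    seed = as.integer(seed),
    out = out,
    inputs = NULL,              # named paths for read_bundle(); NULL = simulate
    sim = list(),               # overrides passed to sim_config()
    stages = list(simulate = TRUE, qc = TRUE, diff_meth = TRUE,
                  diff_expr = TRUE, assoc = TRUE, epidriver = TRUE,
                  markers = TRUE, classifier = TRUE, report = TRUE),
    qc = list(k = 10),
    coexpr = list(tau = 0.6, min_size = 10, cut_height = 0.3),
    score = list(key_fraction = 0.10),
    assoc = list(n_perm = 0, q_cut = 0.05),
    markers = list(eps = 0.005, m = 2, max_k = 25),
    classifier = list(ratio = 0.7, n_boot = 1000,
                      grid = list(n_trees = seq(10, 100, by = 10),
                                  criterion = c("gini", "entropy")))
  )
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg <- modifyList(defaults, override)
  stopifnot(cfg$qc$k >= 1,
            cfg$coexpr$tau > 0, cfg$coexpr$tau <= 1,
            cfg$score$key_fraction > 0, cfg$score$key_fraction <= 1,
            cfg$markers$eps > 0, cfg$markers$m >= 1,
            cfg$classifier$ratio > 0, cfg$classifier$ratio < 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline end to end
#'
#' Executes the stages in dependency order (simulate or load, quality
#' control, differential methylation, differential expression,
#' methylation-expression association, epi-driver calling, marker
#' selection, classifier training/evaluation, report), writing each
#' stage's outputs under `cfg$out` and content-hashing every written file
#' into `manifest.json`. A rerun with an identical configuration is
#' bit-identical. A stage whose dependency was disabled aborts with the
#' stage name.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest tibble.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifest <- list()
  emit <- function(stage, files) {
    manifest[[stage]] <<- tibble::tibble(
      stage = stage, file = basename(files),
      md5 = unname(tools::md5sum(files))
    )
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  need <- function(dep, what) {
    if (is.null(res[[dep]])) {
      stop(sprintf("missing dependency '%s' (%s)", dep, what), call. = FALSE)
    }
  }
  p <- function(f) file.path(cfg$out, f)

  if (isTRUE(cfg$stages$simulate)) {
    run_stage("simulate", function() {
      sc <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
      res$bundle <<- simulate_bundle(sc)
      emit("simulate", write_bundle(res$bundle, file.path(cfg$out, "bundle")))
    })
  } else if (!is.null(cfg$inputs)) {
    run_stage("simulate", function() res$bundle <<- read_bundle(cfg$inputs))
  }

  if (isTRUE(cfg$stages$qc)) {
    run_stage("qc", function() {
      need("bundle", "qc needs input data")
      fr <- filter_probes(res$bundle$beta, res$bundle$manifest)
      res$beta_qc <<- knn_impute(fr$beta, k = cfg$qc$k)
      res$filter_report <<- fr$report
      write_table(fr$report, p("filter_report.json"), "json")
      readr::write_tsv(tibble::as_tibble(res$beta_qc, rownames = "probe_id"),
                       p("beta_qc.tsv"))
      emit("qc", c(p("filter_report.json"), p("beta_qc.tsv")))
    })
  }

  if (isTRUE(cfg$stages$diff_meth)) {
    run_stage("diff_meth", function() {
      need("beta_qc", "differential methylation needs QCed beta")
      res$dm <<- diff_methylation(res$beta_qc, res$bundle$samples)
      write_table(res$dm, p("diff_meth.tsv"), "tsv")
      emit("diff_meth", p("diff_meth.tsv"))
    })
  }

  if (isTRUE(cfg$stages$diff_expr)) {
    run_stage("diff_expr", function() {
      need("bundle", "differential expression needs counts")
      res$de <<- diff_expression(res$bundle$counts, res$bundle$samples)
      write_table(res$de, p("diff_expr.tsv"), "tsv")
      emit("diff_expr", p("diff_expr.tsv"))
    })
  }

  if (isTRUE(cfg$stages$assoc)) {
    run_stage("assoc", function() {
      need("beta_qc", "association needs QCed beta")
      res$assignments <<- annotate_regions(res$bundle$manifest, res$bundle$genes)
      res$assoc <<- fit_association(res$beta_qc, res$bundle$counts,
                                    res$bundle$samples, res$assignments,
                                    model = "type_corrected",
                                    q_cut = cfg$assoc$q_cut)
      write_table(res$assoc$assoc, p("assoc_cpg.tsv"), "tsv")
      write_table(res$assoc$genes, p("assoc_gene.tsv"), "tsv")
      files <- c(p("assoc_cpg.tsv"), p("assoc_gene.tsv"))
      if (cfg$assoc$n_perm > 0) {
        res$perm <<- permutation_null(res$beta_qc, res$bundle$counts,
                                      res$bundle$samples, res$assignments,
                                      n_perm = cfg$assoc$n_perm, seed = cfg$seed)
        write_table(res$perm, p("permutation.json"), "json")
        files <- c(files, p("permutation.json"))
      }
      emit("assoc", files)
    })
  }

  if (isTRUE(cfg$stages$epidriver)) {
    run_stage("epidriver", function() {
      need("de", "epi-driver calling needs differential expression")
      need("assoc", "epi-driver calling needs the methylation association stage")
      res$modules <<- build_coexpression_modules(
        res$bundle$counts, res$bundle$samples,
        tau = cfg$coexpr$tau, min_size = cfg$coexpr$min_size,
        cut_height = cfg$coexpr$cut_height)
      net_met <- build_directed_net(res$bundle$reactions, "metabolic")
      net_ppi <- build_directed_net(res$bundle$ppi, "ppi")
      res$scores_met <<- score_importance(net_met, res$modules,
                                          res$bundle$counts, res$bundle$samples,
                                          key_fraction = cfg$score$key_fraction)
      res$scores_ppi <<- score_importance(net_ppi, res$modules,
                                          res$bundle$counts, res$bundle$samples,
                                          key_fraction = cfg$score$key_fraction)
      assoc_genes <- res$assoc$genes$gene_id[res$assoc$genes$associated]
      res$epidrivers <<- call_epidrivers(res$de, res$scores_met, res$scores_ppi,
                                         assoc_genes)
      write_table(res$scores_met, p("gene_scores_metabolic.tsv"), "tsv")
      write_table(res$scores_ppi, p("gene_scores_ppi.tsv"), "tsv")
      write_table(res$epidrivers, p("epidrivers.tsv"), "tsv")
      emit("epidriver", c(p("gene_scores_metabolic.tsv"),
                          p("gene_scores_ppi.tsv"), p("epidrivers.tsv")))
    })
  }

  if (isTRUE(cfg$stages$markers)) {
    run_stage("markers", function() {
      need("epidrivers", "marker selection needs epi-driver calls")
      driver_genes <- res$epidrivers$gene_id[res$epidrivers$epi_driver]
      cand <- res$assignments$probe_id[res$assignments$gene_id %in% driver_genes]
      cand <- intersect(cand, rownames(res$beta_qc))
      if (!length(cand)) stop("no candidate probes in epi-driver genes")
      res$panel <<- select_markers(res$beta_qc, res$bundle$samples,
                                   candidates = cand,
                                   eps = cfg$markers$eps, m = cfg$markers$m,
                                   max_k = cfg$markers$max_k, seed = cfg$seed)
      write_table(res$panel$candidates, p("marker_candidates.tsv"), "tsv")
      write_table(res$panel$ranking, p("marker_ranking.tsv"), "tsv")
      write_table(tibble::tibble(probe_id = res$panel$panel), p("panel.tsv"), "tsv")
      emit("markers", c(p("marker_candidates.tsv"), p("marker_ranking.tsv"),
                        p("panel.tsv")))
    })
  }

  if (isTRUE(cfg$stages$classifier)) {
    run_stage("classifier", function() {
      need("panel", "classifier needs the marker panel")
      res$samples_split <<- split_cohort(res$bundle$samples,
                                         ratio = cfg$classifier$ratio,
                                         seed = cfg$seed)
      res$model <<- train_ovr_forest(res$beta_qc, res$samples_split,
                                     panel = res$panel$panel,
                                     grid = cfg$classifier$grid, seed = cfg$seed)
      res$report <<- evaluate_origin(res$model, res$beta_qc, res$samples_split,
                                     n_boot = cfg$classifier$n_boot,
                                     seed = cfg$seed)
      write_table(res$report$per_class, p("metrics_per_class.tsv"), "tsv")
      write_table(res$report$overall, p("metrics_overall.json"), "json")
      write_table(res$report$predictions, p("predictions.tsv"), "tsv")
      emit("classifier", c(p("metrics_per_class.tsv"), p("metrics_overall.json"),
                           p("predictions.tsv")))
    })
  }

  if (isTRUE(cfg$stages$report)) {
    run_stage("report", function() {
      need("panel", "report needs the marker panel")
      tum <- tumor_samples(res$bundle$samples)
      probes <- res$panel$panel
      if (length(probes) < 2 && !is.null(res$dm)) {
        # tiny panels cannot be clustered; fall back to the strongest
        # differentially methylated probes
        dm_sig <- dplyr::arrange(res$dm, .data$q)
        probes <- unique(c(probes, head(dm_sig$probe_id, 20)))
      }
      hm <- cluster_heatmap(res$beta_qc[probes, tum$sample_id, drop = FALSE])
      readr::write_tsv(tibble::as_tibble(hm$values, rownames = "probe_id"),
                       p("heatmap_matrix.tsv"))
      res$heatmap <<- hm
      emit("report", p("heatmap_matrix.tsv"))
    })
  }

  manifest_tbl <- dplyr::bind_rows(manifest)
  jsonlite::write_json(
    list(seed = cfg$seed, n_stages = length(manifest),
         stages = split(manifest_tbl[, c("file", "md5")], manifest_tbl$stage)),
    p("manifest.json"), dataframe = "rows", auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest_tbl
  invisible(res)
}

#' Row/column clustered, z-scored heatmap matrix
#'
#' Rows are z-scored (constant rows become zeros, with a warning), then
#' rows and columns are ordered by complete-linkage agglomerative
#' clustering on Euclidean distances. Leaf order is deterministic for a
#' given input (ties resolved by identifier order of the input).
#'
#' @param mat Numeric matrix (e.g. marker probes x tumor samples) with at
#'   least 2 rows and 2 columns.
#' @return A `cluster_heatmap` object: list with `values` (ordered
#'   z-scored matrix), `row_order`, `col_order`, `row_hclust`,
#'   `col_hclust`.
#' @export
cluster_heatmap <- function(mat) {
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2)
  sds <- apply(mat, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant row(s); z-score set to zero")
  }
  z <- (mat - rowMeans(mat)) / ifelse(sds == 0, 1, sds)
  rhc <- hclust(dist(z), method = "complete")
  chc <- hclust(dist(t(z)), method = "complete")
  structure(
    list(values = z[rhc$order, chc$order, drop = FALSE],
         row_order = rownames(mat)[rhc$order],
         col_order = colnames(mat)[chc$order],
         row_hclust = rhc, col_hclust = chc),
    class = "cluster_heatmap"
  )
}
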