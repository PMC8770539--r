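#' Detect co-expression modules and flag tumor-specific ones
#'
#' Builds the cancer co-expression network on tumor samples from
#' `log2(CPM + 1)` expression: the adjacency places an edge between two
#' genes when `|Pearson r| >= tau`. Modules come from average-linkage
#' hierarchical clustering of the distance `1 - |r|`, cut at `cut_height`,
#' discarding modules smaller than `min_size`. A module is tumor-specific
#' when the per-sample mean of its members' z-scored expression (z-scored
#' across all samples) differs between tumor and normal samples by rank-sum
#' test at BH `q < 0.05`.
#'
#' @param counts Genes x samples count matrix (tumor and normal).
#' @param samples Sample sheet covering the columns of `counts`.
#' @param tau Absolute-correlation threshold for network edges (default 0.6).
#' @param min_size Minimum module size (default 10).
#' @param cut_height Tree cut height on the `1 - |r|` scale (default 0.3).
#' @return A `coexpr_modules` object: list with `membership` (tibble
#'   `gene_id`, `module_id`; 0 = unassigned), `modules` (named list of
#'   member vectors), `tumor_specific` (module ids), `network_genes`
#'   (genes with at least one edge), `cor_abs` (absolute correlation
#'   matrix over tumor samples), `tau`, `min_size`, `n_constant` (genes
#'   excluded as constant).
#' @export
build_coexpression_modules <- function(counts, samples, tau = 0.6,
                                       min_size = 10, cut_height = 0.3) {
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  tum <- samples$condition == "tumor"
  if (sum(tum) < 3 || sum(!tum) < 3) {
    stop("need at least 3 tumor and 3 normal samples", call. = FALSE)
  }
  expr <- log2_cpm(counts)
  et <- expr[, tum, drop = FALSE]
  sds <- apply(et, 1, sd)
  constant <- sds == 0
  if (any(constant)) {
    warning(sum(constant), " constant-expression gene(s) excluded from correlation")
  }
  et <- et[!constant, , drop = FALSE]
  cor_abs <- abs(cor(t(et)))
  adj <- cor_abs >= tau
  diag(adj) <- FALSE
  network_genes <- rownames(adj)[rowSums(adj) > 0]

  d <- as.dist(1 - cor_abs)
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, h = cut_height)
  tab <- table(cl)
  big <- as.integer(names(tab)[tab >= min_size])
  membership <- tibble::tibble(gene_id = rownames(et), module_id = 0L)
  modules <- list()
  for (i in seq_along(big)) {
    members <- rownames(et)[cl == big[i]]
    membership$module_id[membership$gene_id %in% members] <- i
    modules[[as.character(i)]] <- members
  }
  membership <- dplyr::bind_rows(
    membership,
    tibble::tibble(gene_id = rownames(expr)[constant], module_id = 0L)
  )

  # tumor-specificity of each module
  tumor_specific <- integer()
  if (length(modules)) {
    zs <- t(scale(t(expr)))
    zs[is.na(zs)] <- 0
    pvals <- vapply(modules, function(members) {
      score <- colMeans(zs[members, , drop = FALSE])
      rank_sum_test(score[tum], score[!tum])$p
    }, numeric(1))
    qvals <- bh_adjust(pvals)
    tumor_specific <- which(qvals < 0.05)
  }

  structure(
    list(membership = membership, modules = modules,
         tumor_specific = as.integer(tumor_specific),
         network_genes = network_genes, cor_abs = cor_abs,
         tau = tau, min_size = min_size, cut_height = cut_height,
         n_constant = sum(constant)),
    class = "coexpr_modules"
  )
}

#' @export
print.coexpr_modules <- function(x, ...) {
  cat(sprintf("<coexpr_modules> %d module(s), %d tumor-specific; %d network genes (tau=%.2f)\n",
              length(x$modules), length(x$tumor_specific),
              length(x$network_genes), x$tau))
  invisible(x)
}

#' Derive a directed gene network from reactions or a PPI edge list
#'
#' In metabolic mode, gene A points to gene B when some product metabolite
#' of a reaction catalysed by A is a substrate of a reaction catalysed by
#' B (A != B). In PPI mode, each undirected edge with weight >= 0.4 is
#' expanded into both directions so out-neighborhoods are defined
#' uniformly.
#'
#' @param x A reaction tibble ([read_reaction_table()]) or an undirected
#'   edge tibble ([read_edge_list()]).
#' @param mode `"metabolic"` or `"ppi"`.
#' @param ppi_cutoff Minimum interaction weight retained in PPI mode
#'   (default 0.4).
#' @return A `directed_net` object: list with `edges` (tibble `from`,
#'   `to`), `nodes`, `source`.
#' @export
build_directed_net <- function(x, mode = c("metabolic", "ppi"), ppi_cutoff = 0.4) {
  mode <- match.arg(mode)
  if (mode == "metabolic") {
    prod_long <- tidyr::unnest(
      dplyr::select(x, gene = "enzyme_gene", met = "products"), "met")
    sub_long <- tidyr::unnest(
      dplyr::select(x, gene = "enzyme_gene", met = "substrates"), "met")
    edges <- dplyr::inner_join(prod_long, sub_long, by = "met",
                               relationship = "many-to-many") |>
      dplyr::transmute(from = .data$gene.x, to = .data$gene.y) |>
      dplyr::filter(.data$from != .data$to) |>
      dplyr::distinct()
    nodes <- unique(x$enzyme_gene)
  } else {
    kept <- dplyr::filter(x, .data$weight >= ppi_cutoff)
    edges <- dplyr::bind_rows(
      dplyr::transmute(kept, from = .data$gene_a, to = .data$gene_b),
      dplyr::transmute(kept, from = .data$gene_b, to = .data$gene_a)
    ) |> dplyr::distinct()
    nodes <- unique(c(x$gene_a, x$gene_b))
  }
  structure(list(edges = edges, nodes = nodes, source = mode),
            class = "directed_net")
}

#' @export
print.directed_net <- function(x, ...) {
  cat(sprintf("<directed_net:%s> %d nodes, %d directed edges\n",
              x$source, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Score upstream genes by module enrichment of their out-neighborhoods
#'
#' Computes, for every gene A with out-neighbors in the directed network,
#' the importance score
#' `score_a = |auc - 0.5| * log2((c_in/c_all) / (n_in/n_all))`, where
#' `c_all` is A's out-degree, `c_in` the number of out-neighbors falling in
#' any tumor-specific co-expression module, `n_all` the number of genes in
#' the co-expression network and `n_in` the number of genes in
#' tumor-specific modules. `auc` is the probability that a uniformly random
#' out-neighbor of A has a higher `|Pearson r|` with A (over tumor
#' samples) than a uniformly random non-neighbor, ties counted 1/2 — a
#' rank-statistic reading of "co-expressed with its downstream genes".
#' Genes with `c_in = 0` (or when `n_in = 0`) receive a `-Inf` sentinel
#' and can never be key genes; key genes are the top `key_fraction` of
#' finite scores (ties broken by gene id).
#'
#' @param net A `directed_net`.
#' @param modules A `coexpr_modules`.
#' @param counts,samples Count matrix and sample sheet (tumor correlations
#'   are taken from the module object when available).
#' @param key_fraction Fraction of finite scores called key genes
#'   (default 0.10).
#' @return Tibble with columns `gene_id`, `auc`, `c_in`, `c_all`, `n_in`,
#'   `n_all`, `score_a`, `key_gene`, plus an attribute `skipped` counting
#'   genes absent from the expression matrix.
#' @export
score_importance <- function(net, modules, counts, samples, key_fraction = 0.10) {
  if (!nrow(net$edges)) stop("directed network has no edges", call. = FALSE)
  ts_genes <- unique(unlist(modules$modules[modules$tumor_specific], use.names = FALSE))
  n_all <- length(modules$network_genes)
  n_in <- length(intersect(ts_genes, modules$network_genes))
  cor_abs <- modules$cor_abs

  from_genes <- unique(net$edges$from)
  skipped <- sum(!from_genes %in% rownames(cor_abs))
  out_by_gene <- split(net$edges$to, net$edges$from)

  rows <- lapply(from_genes, function(a) {
    if (!a %in% rownames(cor_abs)) return(NULL)
    nb <- unique(out_by_gene[[a]])
    c_all <- length(nb)
    c_in <- length(intersect(nb, ts_genes))
    nb_expr <- intersect(nb, rownames(cor_abs))
    non_nb <- setdiff(modules$network_genes, c(nb, a))
    auc <- auc_rank(cor_abs[a, nb_expr], cor_abs[a, non_nb])
    score <- if (c_in == 0 || n_in == 0 || c_all == 0) {
      -Inf
    } else {
      abs(auc - 0.5) * log2((c_in / c_all) / (n_in / n_all))
    }
    tibble::tibble(gene_id = a, auc = auc, c_in = c_in, c_all = c_all,
                   n_in = n_in, n_all = n_all, score_a = score)
  })
  res <- dplyr::bind_rows(rows)
  res <- dplyr::arrange(res, dplyr::desc(.data$score_a), .data$gene_id)
  n_finite <- sum(is.finite(res$score_a))
  n_key <- if (n_finite > 0) ceiling(key_fraction * n_finite) else 0L
  res$key_gene <- is.finite(res$score_a) &
    seq_len(nrow(res)) <= n_key
  attr(res, "skipped") <- skipped
  res
}

#' Call epi-driver genes by multi-omics intersection
#'
#' A gene is an epi-driver when it is differentially expressed, is a key
#' gene in at least one of the two directed networks (union by default),
#' and carries at least one significantly methylation-associated CpG. A
#' gene missing from any input simply gets that flag `FALSE`.
#'
#' @param de Differential-expression tibble ([diff_expression()]).
#' @param scores_met,scores_ppi Score tibbles from [score_importance()]
#'   for the metabolic and PPI networks (either may be `NULL`).
#' @param assoc_genes Character vector of genes with a significant CpG
#'   association (gene-level flag from [fit_association()]).
#' @param combine `"union"` (default) or `"intersection"` of the two
#'   networks' key-gene calls.
#' @return Tibble with per-gene boolean provenance columns `is_de`,
#'   `is_key_metabolic`, `is_key_ppi`, `has_meth_assoc`, `epi_driver`.
#' @export
call_epidrivers <- function(de, scores_met = NULL, scores_ppi = NULL,
                            assoc_genes = character(),
                            combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  key_of <- function(s) if (is.null(s)) character() else s$gene_id[s$key_gene]
  km <- key_of(scores_met)
  kp <- key_of(scores_ppi)
  universe <- unique(c(de$gene_id, km, kp, assoc_genes))
  de_genes <- de$gene_id[de$significant]
  out <- tibble::tibble(
    gene_id = sort(universe),
  ) |>
    dplyr::mutate(
      is_de = .data$gene_id %in% de_genes,
      is_key_metabolic = .data$gene_id %in% km,
      is_key_ppi = .data$gene_id %in% kp,
      has_meth_assoc = .data$gene_id %in% assoc_genes,
      key_any = if (combine == "union") .data$is_key_metabolic | .data$is_key_ppi
                else .data$is_key_metabolic & .data$is_key_ppi,
      epi_driver = .data$is_de & .data$key_any & .data$has_meth_assoc
    ) |>
    dplyr::select(-"key_any")
  out
}

#' One-sided Fisher (hypergeometric) overlap test
#'
#' Enrichment-tail probability of observing at least the given overlap
#' between two sets drawn from a common universe.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible elements.
#' @return Tibble with `overlap`, `n_a`, `n_b`, `n_universe`, `p`.
#' @export
overlap_significance <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("universe must be non-empty", call. = FALSE)
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  ov <- length(intersect(set_a, set_b))
  p <- phyper(ov - 1, length(set_a), length(universe) - length(set_a),
              length(set_b), lower.tail = FALSE)
  tibble::tibble(overlap = ov, n_a = length(set_a), n_b = length(set_b),
                 n_universe = length(universe), p = p)
}

#' Pairwise overlap tests across classes with BH adjustment
#'
#' Applies [overlap_significance()] to every unordered pair of named sets
#' and adjusts the p-values across pairs.
#'
#' @param sets Named list of character vectors.
#' @param universe Character vector of all eligible elements.
#' @return Tibble with one row per pair (`class_a`, `class_b`, `overlap`,
#'   `p`, `q`).
#' @export
pairwise_overlap <- function(sets, universe) {
  nm <- names(sets)
  if (length(nm) < 2) stop("need at least two sets", call. = FALSE)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    dplyr::mutate(overlap_significance(sets[[pr[1]]], sets[[pr[2]]], universe),
                  class_a = pr[1], class_b = pr[2], .before = 1)
  })
  dplyr::mutate(res, q = bh_adjust(.data$p))
}
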