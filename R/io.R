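#' Read and validate a methylation beta matrix
#'
#' The file is a TSV whose first column (`probe_id`) holds probe identifiers
#' and whose remaining columns are samples. Values must be decimals in
#' \[0, 1\] or the literal token `NA` (missing). Malformed or out-of-range
#' cells are reported with their file, row and column.
#'
#' @param path Path to a `beta.tsv`-style file.
#' @return A numeric matrix (probes x samples) with `NA` for missing entries.
#' @export
read_beta_matrix <- function(path) {
  mat <- read_id_matrix(path, id_col = "probe_id", delim = "\t")
  check_beta_values(mat, path)
  mat
}

#' Read and validate an RNA-seq count matrix
#'
#' TSV with first column `gene_id`, remaining columns samples; all values
#' must be non-negative integers.
#'
#' @param path Path to a `counts.tsv`-style file.
#' @return An integer-valued numeric matrix (genes x samples).
#' @export
read_count_matrix <- function(path) {
  mat <- read_id_matrix(path, id_col = "gene_id", delim = "\t")
  bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "%s: count at row '%s', column '%s' is not a non-negative integer",
      path, rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]
    ), call. = FALSE)
  }
  mat
}

island_vocabulary <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")

#' Read a probe manifest
#'
#' CSV with columns `probe_id, chrom, pos, island_relation, snp_flag,
#' multimap_flag`. `island_relation` must belong to the closed vocabulary
#' Island / N_Shore / S_Shore / N_Shelf / S_Shelf / OpenSea; `pos` is a
#' 1-based coordinate.
#'
#' @param path Path to `manifest.csv`.
#' @return A tibble, one row per probe.
#' @export
read_probe_manifest <- function(path) {
  df <- read_delim_ci(path, ",", c("probe_id", "chrom", "pos", "island_relation",
                                   "snp_flag", "multimap_flag"))
  df$pos <- parse_number_col(df$pos, path, "pos")
  df$snp_flag <- parse_logical_col(df$snp_flag, path, "snp_flag")
  df$multimap_flag <- parse_logical_col(df$multimap_flag, path, "multimap_flag")
  bad <- setdiff(unique(df$island_relation), island_vocabulary)
  if (length(bad)) {
    stop(sprintf("%s: unknown island_relation value(s): %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(df$pos < 1)) stop(sprintf("%s: pos must be >= 1", path), call. = FALSE)
  if (anyDuplicated(df$probe_id)) {
    stop(sprintf("%s: duplicated probe_id", path), call. = FALSE)
  }
  df
}

#' Read a gene model table
#'
#' TSV with columns `gene_id, chrom, strand, tss, tes`; coordinates are
#' 1-based and strand-consistent (`tss < tes` on `+`, `tss > tes` on `-`).
#'
#' @param path Path to `genes.tsv`.
#' @return A tibble, one row per gene.
#' @export
read_gene_model <- function(path) {
  df <- read_delim_ci(path, "\t", c("gene_id", "chrom", "strand", "tss", "tes"))
  df$tss <- parse_number_col(df$tss, path, "tss")
  df$tes <- parse_number_col(df$tes, path, "tes")
  if (!all(df$strand %in% c("+", "-"))) {
    stop(sprintf("%s: strand must be '+' or '-'", path), call. = FALSE)
  }
  ok <- ifelse(df$strand == "+", df$tss < df$tes, df$tss > df$tes)
  if (!all(ok)) {
    stop(sprintf("%s: tss/tes not consistent with strand for gene '%s'",
                 path, df$gene_id[which(!ok)[1]]), call. = FALSE)
  }
  if (anyDuplicated(df$gene_id)) stop(sprintf("%s: duplicated gene_id", path), call. = FALSE)
  df
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id, class_label, condition, pair_id, cohort`.
#' The sheet is the single source of truth for class and condition; matrices
#' read through [read_bundle()] are subset to it.
#'
#' @param path Path to `samples.tsv`.
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- read_delim_ci(path, "\t", c("sample_id", "class_label", "condition",
                                    "pair_id", "cohort"))
  if (!all(df$condition %in% c("tumor", "normal"))) {
    stop(sprintf("%s: condition must be 'tumor' or 'normal'", path), call. = FALSE)
  }
  known <- c("train", "test", "external")
  if (!all(is.na(df$cohort) | df$cohort %in% known)) {
    stop(sprintf("%s: cohort must be train/test/external or NA", path), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop(sprintf("%s: duplicated sample_id", path), call. = FALSE)
  dup <- df |>
    dplyr::filter(!is.na(.data$pair_id)) |>
    dplyr::count(.data$pair_id, .data$condition) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop(sprintf("%s: pair_id '%s' occurs more than once per condition",
                 path, dup$pair_id[1]), call. = FALSE)
  }
  df
}

#' Read a metabolic reaction table
#'
#' TSV with columns `reaction_id, enzyme_gene, substrates, products`;
#' metabolite sets are `;`-joined and must be non-empty.
#'
#' @param path Path to `reactions.tsv`.
#' @return A tibble with list-columns `substrates` and `products`.
#' @export
read_reaction_table <- function(path) {
  df <- read_delim_ci(path, "\t", c("reaction_id", "enzyme_gene", "substrates", "products"))
  split_sets <- function(x) strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  df$substrates <- split_sets(df$substrates)
  df$products <- split_sets(df$products)
  empty <- lengths(df$substrates) == 0 | lengths(df$products) == 0
  if (any(empty)) {
    stop(sprintf("%s: reaction '%s' has an empty substrate or product set",
                 path, df$reaction_id[which(empty)[1]]), call. = FALSE)
  }
  df
}

#' Read a protein-protein interaction edge list
#'
#' TSV with columns `gene_a, gene_b, weight`; weights in \[0, 1\], no
#' self-loops.
#'
#' @param path Path to `ppi.tsv`.
#' @return A tibble of undirected weighted edges.
#' @export
read_edge_list <- function(path) {
  df <- read_delim_ci(path, "\t", c("gene_a", "gene_b", "weight"))
  df$weight <- parse_number_col(df$weight, path, "weight")
  if (any(df$weight < 0 | df$weight > 1)) {
    stop(sprintf("%s: edge weights must lie in [0, 1]", path), call. = FALSE)
  }
  if (any(df$gene_a == df$gene_b)) {
    stop(sprintf("%s: self-loops are not allowed", path), call. = FALSE)
  }
  df
}

#' Read a complete input bundle with cross-reference validation
#'
#' Reads every input table, validates each against its schema, then enforces
#' the cross-references: matrix samples must appear in the sample sheet and
#' beta probes in the manifest. Offending columns/rows are dropped, never
#' silently: every dropped or unknown identifier is itemised in the
#' `report` tibble attached to the bundle.
#'
#' @param paths Named list (or vector) of file paths with elements
#'   `beta`, `counts`, `manifest`, `genes`, `samples`, `reactions`, `ppi`.
#'   `reactions` and `ppi` may be omitted.
#' @return An object of class `omics_bundle`: a list with elements `beta`,
#'   `counts`, `manifest`, `genes`, `samples`, `reactions`, `ppi` and
#'   `report` (tibble with columns `file`, `issue`, `id`).
#' @export
read_bundle <- function(paths) {
  need <- c("beta", "counts", "manifest", "genes", "samples")
  missing_paths <- setdiff(need, names(paths))
  if (length(missing_paths)) {
    stop("read_bundle: missing paths for ", paste(missing_paths, collapse = ", "),
         call. = FALSE)
  }
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  beta <- read_beta_matrix(paths$beta)
  counts <- read_count_matrix(paths$counts)
  manifest <- read_probe_manifest(paths$manifest)
  genes <- read_gene_model(paths$genes)
  samples <- read_sample_sheet(paths$samples)
  reactions <- if (!is.null(paths$reactions)) read_reaction_table(paths$reactions) else NULL
  ppi <- if (!is.null(paths$ppi)) read_edge_list(paths$ppi) else NULL

  report <- tibble::tibble(file = character(), issue = character(), id = character())
  note <- function(file, issue, ids) {
    if (length(ids)) {
      report <<- dplyr::bind_rows(report, tibble::tibble(file = file, issue = issue,
                                                         id = as.character(ids)))
    }
  }

  drop_b <- setdiff(colnames(beta), samples$sample_id)
  note("beta", "sample absent from sample sheet; dropped", drop_b)
  beta <- beta[, setdiff(colnames(beta), drop_b), drop = FALSE]

  drop_c <- setdiff(colnames(counts), samples$sample_id)
  note("counts", "sample absent from sample sheet; dropped", drop_c)
  counts <- counts[, setdiff(colnames(counts), drop_c), drop = FALSE]

  drop_p <- setdiff(rownames(beta), manifest$probe_id)
  note("beta", "probe absent from manifest; dropped", drop_p)
  beta <- beta[setdiff(rownames(beta), drop_p), , drop = FALSE]

  note("counts", "gene absent from gene model", setdiff(rownames(counts), genes$gene_id))
  if (!is.null(reactions)) {
    note("reactions", "enzyme gene external to gene model",
         setdiff(unique(reactions$enzyme_gene), genes$gene_id))
  }

  structure(
    list(beta = beta, counts = counts, manifest = manifest, genes = genes,
         samples = samples, reactions = reactions, ppi = ppi, report = report),
    class = "omics_bundle"
  )
}

#' @export
print.omics_bundle <- function(x, ...) {
  cat(sprintf("<omics_bundle> %d probes x %d samples (beta); %d genes x %d samples (counts)\n",
              nrow(x$beta), ncol(x$beta), nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  manifest: %d probes; genes: %d; samples: %d; report: %d issue(s)\n",
              nrow(x$manifest), nrow(x$genes), nrow(x$samples), nrow(x$report)))
  invisible(x)
}

#' Write a result table to disk
#'
#' @param records A data frame of results (any of the package's result
#'   tibbles). List-columns are `;`-joined for the delimited formats.
#' @param path Output file path.
#' @param format One of `"tsv"`, `"csv"`, `"json"`.
#' @return `path`, invisibly. A read-back via [read_result_table()]
#'   reproduces `records` (numbers at 12+ significant digits).
#' @export
write_table <- function(records, path, format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  df <- dplyr::mutate(records, dplyr::across(
    dplyr::where(is.list), ~ vapply(.x, paste, "", collapse = ";")
  ))
  switch(format,
    tsv = readr::write_tsv(df, path, na = "NA"),
    csv = readr::write_csv(df, path, na = "NA"),
    json = jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                                na = "null", auto_unbox = FALSE)
  )
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path File path.
#' @param format One of `"tsv"`, `"csv"`, `"json"`.
#' @return A tibble.
#' @export
read_result_table <- function(path, format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  switch(format,
    tsv = readr::read_tsv(path, show_col_types = FALSE),
    csv = readr::read_csv(path, show_col_types = FALSE),
    json = tibble::as_tibble(jsonlite::fromJSON(path))
  )
}

# ---- internal readers -------------------------------------------------------

# Read a delimited file whose header must match `cols` case-insensitively.
read_delim_ci <- function(path, delim, cols) {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()),
                          na = "NA", progress = FALSE)
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tibble::as_tibble(df[cols])
}

# id-keyed numeric matrix (first column ids, rest samples); malformed cells
# are reported with row and column names.
read_id_matrix <- function(path, id_col, delim) {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()),
                          na = character(), progress = FALSE)
  names(df)[1] <- tolower(names(df)[1])
  if (names(df)[1] != id_col) {
    stop(sprintf("%s: first column must be '%s'", path, id_col), call. = FALSE)
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop(sprintf("%s: duplicated %s", path, id_col), call. = FALSE)
  vals <- as.matrix(df[-1])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals), dimnames = dimnames(vals))
  bad <- which(is.na(num) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("%s: malformed numeric cell '%s' at row '%s', column '%s'",
                 path, vals[bad[1, , drop = FALSE]], ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]), call. = FALSE)
  }
  rownames(num) <- ids
  num
}

check_beta_values <- function(mat, path) {
  bad <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("%s: beta value %s at row '%s', column '%s' outside [0, 1]",
                 path, format(mat[bad[1, , drop = FALSE]]),
                 rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]), call. = FALSE)
  }
  invisible(mat)
}

parse_number_col <- function(x, path, col) {
  num <- suppressWarnings(as.numeric(x))
  if (any(is.na(num) & !is.na(x))) {
    stop(sprintf("%s: malformed numeric value '%s' in column '%s'",
                 path, x[which(is.na(num) & !is.na(x))[1]], col), call. = FALSE)
  }
  num
}

parse_logical_col <- function(x, path, col) {
  low <- tolower(as.character(x))
  out <- dplyr::case_when(
    low %in% c("true", "t", "1") ~ TRUE,
    low %in% c("false", "f", "0") ~ FALSE,
    TRUE ~ NA
  )
  if (anyNA(out)) {
    stop(sprintf("%s: malformed logical value in column '%s'", path, col), call. = FALSE)
  }
  out
}
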