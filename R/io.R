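#' Load an expression matrix from TSV/CSV or MatrixMarket triplets
#'
#' TSV/CSV files are genes-as-rows with a header of sample identifiers
#' and gene identifiers in the first column.  MTX input needs sidecar
#' gene and sample name files (one identifier per line), by default
#' `<stem>.genes.txt` and `<stem>.samples.txt`.  Duplicate gene
#' identifiers are suffixed deterministically (`make.unique`); duplicate
#' sample identifiers, ragged rows and missing values are errors.
#'
#' @param path input file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; default guessed from the
#'   file extension.
#' @param genes_file,samples_file sidecar name files for MTX input.
#' @return numeric genes x samples matrix with dimnames.
#' @export
load_expression <- function(path, format = NULL, genes_file = NULL,
                            samples_file = NULL) {
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("cannot guess format from extension of ", path))
  format <- match.arg(format, c("tsv", "csv", "mtx"))
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    genes_file <- genes_file %||% paste0(stem, ".genes.txt")
    samples_file <- samples_file %||% paste0(stem, ".samples.txt")
    m <- as.matrix(Matrix::readMM(path))
    g <- readLines(genes_file); s <- readLines(samples_file)
    if (length(g) != nrow(m) || length(s) != ncol(m))
      stop("sidecar name files do not match the matrix dimensions")
    dimnames(m) <- list(g, s)
  } else {
    tb <- if (format == "csv")
      utils::read.csv(path, row.names = NULL, check.names = FALSE)
    else utils::read.delim(path, row.names = NULL, check.names = FALSE)
    g <- as.character(tb[[1L]])
    m <- as.matrix(tb[-1L])
    # [.data.frame deduplicates names; restore the originals for validation
    dimnames(m) <- list(g, names(tb)[-1L])
    storage.mode(m) <- "double"
  }
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (anyDuplicated(rownames(m))) {
    message("suffixing ", sum(duplicated(rownames(m))),
            " duplicate gene identifier(s)")
    rownames(m) <- make.unique(rownames(m), sep = "_")
  }
  m
}

#' Write an expression matrix as TSV (genes x samples)
#'
#' @param expr genes x samples matrix.
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep genes expressed above a threshold in enough samples
#'
#' Mirrors the usual "expressed gene" filter (e.g. expression > 1 in at
#' least 2 samples).
#'
#' @param expr genes x samples matrix.
#' @param threshold expression threshold (default 1).
#' @param min_samples minimum number of samples above threshold
#'   (default 2).
#' @return filtered matrix; the number of dropped genes is messaged.
#' @export
filter_expressed <- function(expr, threshold = 1, min_samples = 2L) {
  expr <- as_expression_matrix(expr)
  keep <- rowSums(expr > threshold) >= min_samples
  if (any(!keep))
    message("dropping ", sum(!keep), " gene(s) below the expression filter")
  expr[keep, , drop = FALSE]
}

#' Normalise an expression matrix
#'
#' A small standard set: `log10(x + 1)`, per-gene z-score, quantile
#' normalisation across samples (via limma), or none.
#'
#' @param expr genes x samples matrix.
#' @param method one of `"log10"`, `"zscore"`, `"quantile"`, `"none"`.
#' @return normalised matrix of the same shape.
#' @export
normalize_expression <- function(expr,
                                 method = c("log10", "zscore", "quantile",
                                            "none")) {
  method <- match.arg(method)
  expr <- as_expression_matrix(expr)
  switch(method,
         log10 = log10(expr + 1),
         zscore = {
           z <- t(scale(t(expr)))
           z[is.nan(z)] <- 0
           dimnames(z) <- dimnames(expr)
           z
         },
         quantile = {
           q <- limma::normalizeQuantiles(expr)
           dimnames(q) <- dimnames(expr)
           q
         },
         none = expr)
}

#' Write an embedding as TSV
#'
#' Columns: `sample_id`, one column per embedding axis (`x`, `y`, `z`),
#' `radius`, `rank`, `strength`.
#'
#' @param embedding a `dce_embedding`.
#' @param path output file.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "dce_embedding"))
  ax <- c("x", "y", "z")[seq_len(ncol(embedding$cartesian))]
  df <- data.frame(sample_id = embedding$sample_ids,
                   stats::setNames(as.data.frame(embedding$cartesian), ax),
                   radius = embedding$radius, rank = embedding$rank,
                   strength = embedding$strength)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the ground truth of a synthetic tissue as TSV
#'
#' @param tissue a `dce_tissue`.
#' @param path output file.
#' @export
write_tissue_truth <- function(tissue, path) {
  df <- data.frame(sample_id = colnames(tissue$expr),
                   tissue$true_coords,
                   layer = tissue$layers, domain = tissue$domains,
                   lineage = tissue$lineages)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# small stable polynomial hash of a deparsed object, for config provenance
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full reconstruction pipeline and write artifacts
#'
#' Sequences the stages: expression loading and normalisation, network
#' construction, coalescent embedding, EOC scan and marker nomination,
#' optional template fitting, and optional evaluation against labels.
#' Every run writes `coordinates.tsv`, `eoc.tsv`, `config.json` (the
#' resolved configuration, its hash, beta and the top singular values)
#' and, when enabled, `markers.json`, `assignment.tsv`, `metrics.json`.
#'
#' @param expr genes x samples matrix, or path to one
#'   (see [load_expression()]).
#' @param output_dir directory for artifacts (created if needed).
#' @param normalization one of `"none"`, `"log10"`, `"zscore"`,
#'   `"quantile"` (default `"none"`: synthetic and pre-logged data come
#'   in ready to use).
#' @param metric,csi_delta,apply_sqrt,shortest_path,bridge_components
#'   network options, see [build_network()].
#' @param dims embedding dimensionality.
#' @param run_markers run the EOC scan and nominate markers.
#' @param template optional `dce_template` or template TSV path; enables
#'   template fitting.
#' @param use_markers weight the template fit by the nominated markers
#'   (requires the template to carry marker expression).
#' @param scmap,lambda,epsilon,knn_k template-fitting options, see
#'   [fit_template()].
#' @param labels optional data.frame (or TSV path) with `sample_id` and
#'   any of `layer`, `domain`, `group`; enables evaluation.
#' @param template_dim template dimensionality for marker selection.
#' @param seed seed for the seeded sub-steps (k-means, jitter).
#' @return invisibly, a list with the embedding, eoc scan, marker set,
#'   assignment and metric report (NULL where not run).
#' @export
run_pipeline <- function(expr, output_dir, normalization = "none",
                         metric = "auto", csi_delta = 0.05,
                         apply_sqrt = NULL, shortest_path = TRUE,
                         bridge_components = FALSE, dims = 3L,
                         run_markers = TRUE, template = NULL,
                         use_markers = FALSE, scmap = FALSE, lambda = 0.5,
                         epsilon = NULL, knn_k = NULL, labels = NULL,
                         template_dim = 2L, seed = 1L) {
  cfg <- list(normalization = normalization, metric = metric,
              csi_delta = csi_delta, apply_sqrt = apply_sqrt,
              shortest_path = shortest_path,
              bridge_components = bridge_components, dims = dims,
              run_markers = run_markers, use_markers = use_markers,
              scmap = scmap, lambda = lambda, epsilon = epsilon,
              knn_k = knn_k, template_dim = template_dim, seed = seed)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr_) tryCatch(expr_, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         "\nconfig: ", jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null"),
         call. = FALSE))

  if (is.character(expr)) expr <- stage("load", load_expression(expr))
  expr <- stage("normalize", normalize_expression(expr, normalization))
  net <- stage("network",
               build_network(expr, metric = metric, csi_delta = csi_delta,
                             apply_sqrt = apply_sqrt,
                             shortest_path = shortest_path,
                             bridge_components = bridge_components))
  emb <- stage("embed", dce_embed(net, dims = dims, jitter_seed = seed))
  write_embedding(emb, file.path(output_dir, "coordinates.tsv"))

  scan <- mset <- NULL
  if (run_markers) {
    scan <- stage("eoc", eoc_scan(expr, emb$cartesian))
    utils::write.table(scan$table, file.path(output_dir, "eoc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mset <- stage("markers",
                  select_markers(scan, template_dim = template_dim,
                                 k_seed = seed))
    jsonlite::write_json(mset[c("markers", "eoc_values", "cluster_sizes")],
                         file.path(output_dir, "markers.json"),
                         auto_unbox = FALSE, digits = NA)
  }

  asn <- NULL
  if (!is.null(template)) {
    if (is.character(template)) template <- read_template(template)
    mk <- if (use_markers && !is.null(mset))
      intersect(mset$markers, colnames(template$marker_expression)) else NULL
    asn <- stage("fit_template",
                 fit_template(emb, template, markers = mk, expr = expr,
                              lambda = lambda, epsilon = epsilon, k = knn_k,
                              scmap = scmap))
    adf <- data.frame(sample_id = asn$sample_ids,
                      position_id = asn$position_ids,
                      asn$fitted_coords, row.names = NULL)
    utils::write.table(adf, file.path(output_dir, "assignment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  rep <- NULL
  if (!is.null(labels)) {
    if (is.character(labels)) labels <- utils::read.delim(labels)
    lb <- labels[match(emb$sample_ids, labels$sample_id), ]
    rep <- stage("evaluate",
                 evaluate_embedding(emb$cartesian,
                                    layers = lb[["layer"]],
                                    domains = lb[["domain"]],
                                    groups = lb[["group"]]))
    jsonlite::write_json(list(oi = rep$oi, oi_per_domain = rep$oi_per_domain,
                              asi = rep$asi, psimcc = rep$psimcc),
                         file.path(output_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  log <- c(cfg,
           list(config_hash = config_hash(cfg),
                n_samples = length(emb$sample_ids),
                resolved_metric = emb$metric, beta = emb$beta,
                singular_values = emb$singular_values))
  jsonlite::write_json(log, file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(embedding = emb, eoc = scan, markers = mset,
                 assignment = asn, report = rep, config = log))
}
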