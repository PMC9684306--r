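#' Read an expression matrix from delimited text
#'
#' First row holds gene identifiers, one sample per row. The delimiter is
#' auto-detected between tab and comma. Duplicate gene ids, ragged rows,
#' missing or non-numeric cells are rejected with descriptive errors.
#'
#' @param path file path.
#' @return numeric n x p matrix with gene ids as column names.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "numeric",
                          comment.char = "")
  ids <- colnames(df)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  x <- as.matrix(df)
  if (anyNA(x)) stop("missing or non-numeric cells in ", path)
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  x
}

#' Write an expression matrix as TSV
#'
#' @param x numeric matrix with gene ids as column names.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary adjacency matrix or edge list
#'
#' Accepts either a square 0/1 CSV with a header row and first column of
#' gene ids, or a 2-column TSV edge list of gene ids (`gene_ids` then
#' fixes the node set).
#'
#' @param path file path.
#' @param gene_ids node labels, required for edge-list input.
#' @return binary adjacency matrix.
#' @export
read_adjacency <- function(path, gene_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  if (grepl(",", first)) {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    adj <- as.matrix(df)
    storage.mode(adj) <- "integer"
    check_adjacency(adj)
    return(adj)
  }
  el <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(el) < 2) stop("edge list needs at least 2 columns")
  if (is.null(gene_ids))
    gene_ids <- sort(unique(c(as.character(el[[1]]), as.character(el[[2]]))))
  p <- length(gene_ids)
  adj <- matrix(0L, p, p, dimnames = list(gene_ids, gene_ids))
  i <- match(as.character(el[[1]]), gene_ids)
  j <- match(as.character(el[[2]]), gene_ids)
  if (anyNA(i) || anyNA(j)) stop("edge list mentions unknown gene ids")
  adj[cbind(i, j)] <- 1L
  adj[cbind(j, i)] <- 1L
  adj
}

#' Write an adjacency matrix as square CSV
#' @param adj binary adjacency matrix.
#' @param path output path.
#' @export
write_adjacency <- function(adj, path) {
  utils::write.csv(as.data.frame(adj), path, quote = FALSE)
  invisible(path)
}

#' Write an edge list (upper-triangle pairs) as TSV
#' @param adj binary adjacency matrix with gene dimnames.
#' @param path output path.
#' @export
write_edge_list <- function(adj, path) {
  check_adjacency(adj)
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  ids <- colnames(adj)
  if (is.null(ids)) ids <- paste0("g", seq_len(ncol(adj)))
  utils::write.table(
    data.frame(gene_i = ids[idx[, 1]], gene_j = ids[idx[, 2]]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the posterior edge table
#'
#' Writes the edge summaries as TSV sorted by decreasing existence
#' probability (ties by lexicographic gene pair).
#'
#' @param edges edge summary data.frame or a `"bmrf"` fit.
#' @param path output path.
#' @export
write_edge_table <- function(edges, path) {
  if (inherits(edges, "bmrf")) edges <- edges$edges
  edges <- edges[order(-edges$existence_probability,
                       edges$gene_i, edges$gene_j), , drop = FALSE]
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' Flat `key = value` text; blank lines and `#` comments allowed.
#' Unrecognized keys are errors, so a typo cannot silently change a run.
#'
#' @param path config file path.
#' @return list of class `"bmrf_config"` with defaults filled in.
#' @export
read_run_config <- function(path) {
  known <- c("expression", "truth", "g_star", "m_star", "out_dir", "method",
             "tau1", "tau0", "n_iter", "burn_in", "thin", "threshold",
             "top_fraction", "informative_mean", "concentration", "seed")
  numeric_keys <- setdiff(known, c("expression", "truth", "g_star", "m_star",
                                   "out_dir", "method"))
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unrecognized config key(s): ",
                            paste(unknown, collapse = ", "))
  if (anyDuplicated(keys)) stop("duplicate config key: ",
                                keys[duplicated(keys)][1])
  cfg <- list(method = "BMRF.O", tau1 = 2, tau0 = 20, n_iter = 10000,
              burn_in = 5000, thin = 1, threshold = 0.5, top_fraction = 0.10,
              informative_mean = 0.8, concentration = 10, seed = 1,
              out_dir = ".")
  for (i in seq_along(keys)) {
    cfg[[keys[i]]] <- if (keys[i] %in% numeric_keys)
      as.numeric(vals[i]) else vals[i]
  }
  if (is.null(cfg$expression)) stop("config must set 'expression'")
  for (f in c("expression", "truth", "g_star", "m_star")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config file '", f, "' does not exist: ", cfg[[f]])
  }
  if (!cfg$method %in% c("BMRF.O", "BMRF.P"))
    stop("method must be BMRF.O or BMRF.P")
  class(cfg) <- "bmrf_config"
  cfg
}

#' Run the full screen / fit / evaluate pipeline from a configuration
#'
#' Reads the expression matrix, elicits priors (for `BMRF.P`: `G*` from
#' correlation screening and `M*` from the neighborhood screen unless
#' files override them), fits the model, writes the sorted edge table and
#' the selected network, evaluates against a truth network when provided,
#' and records a JSON manifest with every setting and seed so the run can
#' be reproduced bit-for-bit.
#'
#' @param config a `"bmrf_config"` (or path to one).
#' @return list with the fit, output paths, and the evaluation report (if
#'   a truth was given), invisibly.
#' @export
end_to_end <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  x <- standardize_expression(read_expression(config$expression))
  pri <- if (config$method == "BMRF.P") {
    g_star <- if (!is.null(config$g_star))
      read_adjacency(config$g_star, colnames(x)) else
      screen_correlation(x, config$top_fraction)
    m_star <- if (!is.null(config$m_star))
      read_adjacency(config$m_star, colnames(x)) else
      screen_neighborhood(x)
    edge_priors(g_star, m_star, config$informative_mean, config$concentration)
  } else {
    edge_priors(p = ncol(x))
  }
  fit <- bmrf(x, priors = pri, ssl = ssl_prior(config$tau1, config$tau0),
              n_iter = config$n_iter, burn_in = config$burn_in,
              thin = config$thin, threshold = config$threshold,
              seed = as.integer(config$seed), keep_draws = FALSE)
  paths <- list(edge_table = file.path(config$out_dir, "edges.tsv"),
                network = file.path(config$out_dir, "network.csv"),
                manifest = file.path(config$out_dir, "manifest.json"))
  write_edge_table(fit, paths$edge_table)
  write_adjacency(select_network(fit), paths$network)
  report <- NULL
  if (!is.null(config$truth)) {
    truth <- read_adjacency(config$truth, colnames(x))
    report <- confusion_metrics(select_network(fit), truth)
    report$brier <- brier_score(fit$edges, truth)
    paths$report <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(unclass(report), paths$report,
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- c(unclass(config),
                list(package_version = as.character(
                       utils::packageVersion("bmrfnet")),
                     n_informative_pairs =
                       sum(pri$informative_mask[upper.tri(pri$informative_mask)]),
                     n_candidate_pairs = nrow(fit$pairs)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(fit = fit, paths = paths, report = report, priors = pri))
}
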