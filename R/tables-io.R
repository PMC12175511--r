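#' Read an OTU count table from TSV
#'
#' Expects taxa as rows (first column = taxon id) and samples as columns,
#' tab-separated with a header row of sample ids.
#'
#' @param path path to the TSV file.
#' @return integer matrix with taxon rownames and sample colnames.
#' @export
readOtuTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated taxon ids: ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  dups <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dups))
    stop("duplicated sample ids: ", paste(dups, collapse = ", "))
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write an OtuExperiment (or count matrix) to TSV
#'
#' @param x OtuExperiment or matrix.
#' @param path output path.
#' @param id_column name of the taxon id column.
#' @return path, invisibly.
#' @export
writeOtuTable <- function(x, path, id_column = "taxon_id") {
  m <- if (is(x, "OtuExperiment")) otuCounts(x) else x
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample_id, location, plot, subsample) from TSV
#' @param path path to the TSV file.
#' @return data.frame keyed by sample_id.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "location", "plot", "subsample")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata")
  key <- paste(df$location, df$plot, df$subsample)
  if (anyDuplicated(key))
    stop("(location, plot, subsample) combinations must be unique")
  rownames(df) <- df$sample_id
  df
}

#' Read a taxonomy table (taxon_id, domain[, lineage...]) from TSV
#' @param path path to the TSV file.
#' @return data.frame keyed by taxon_id, with a domain column.
#' @export
readTaxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "domain") %in% colnames(df)))
    stop("taxonomy must have columns taxon_id and domain")
  if (anyDuplicated(df$taxon_id))
    stop("duplicated taxon_id in taxonomy")
  rownames(df) <- df$taxon_id
  df
}

#' Load an OTU data set from its three TSV components
#'
#' Assembles counts, sample metadata and taxonomy into a consistent
#' \linkS4class{OtuExperiment}. Taxa whose domain is neither
#' \code{"bacteria"} nor \code{"fungi"} (e.g. sporadic archaea) are
#' dropped with a message; taxa absent from the taxonomy are an error.
#'
#' @param table_path OTU count TSV (taxa x samples).
#' @param metadata_path sample metadata TSV.
#' @param taxonomy_path taxonomy TSV mapping taxon_id to domain.
#' @return OtuExperiment.
#' @export
loadDataset <- function(table_path, metadata_path, taxonomy_path) {
  counts <- readOtuTable(table_path)
  meta <- readSampleMetadata(metadata_path)
  tax <- readTaxonomy(taxonomy_path)
  missing_meta <- setdiff(colnames(counts), rownames(meta))
  if (length(missing_meta))
    stop("samples without metadata: ",
         paste(missing_meta, collapse = ", "))
  unlabeled <- setdiff(rownames(counts), rownames(tax))
  if (length(unlabeled))
    stop("taxa without a domain label: ",
         paste(utils::head(unlabeled, 10), collapse = ", "))
  dom <- tax[rownames(counts), "domain"]
  keep <- dom %in% .DOMAINS
  if (any(!keep))
    message(sum(!keep), " taxa outside bacteria/fungi excluded at load")
  counts <- counts[keep, , drop = FALSE]
  OtuExperiment(counts, domain = dom[keep],
                sample_data = meta[colnames(counts), , drop = FALSE],
                taxonomy = tax[rownames(counts),
                               setdiff(colnames(tax),
                                       c("taxon_id", "domain")),
                               drop = FALSE])
}

#' Remove samples with low sequencing depth
#'
#' Drops every sample whose total read count is strictly below
#' \code{min_reads} (a sample at exactly the threshold is kept). The ids
#' of dropped samples are recorded in
#' \code{metadata(x)$dropped_samples}.
#'
#' @param x OtuExperiment.
#' @param min_reads positive depth threshold (default 5000 reads).
#' @return filtered OtuExperiment.
#' @export
filterLowDepth <- function(x, min_reads = 5000) {
  stopifnot(min_reads > 0)
  depth <- colSums(otuCounts(x))
  drop <- colnames(x)[depth < min_reads]
  if (length(drop) == ncol(x))
    stop("all samples fall below ", min_reads, " reads")
  out <- x[, depth >= min_reads]
  metadata(out)$dropped_samples <- drop
  out
}

#' Per-sample relative abundances
#'
#' @param x OtuExperiment or count matrix.
#' @return numeric matrix of proportions; every column sums to 1.
#' @export
relativeAbundance <- function(x) {
  m <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("zero-sum sample(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  sweep(m, 2, tot, "/")
}

#' Read an undirected association network from an edge-list TSV
#'
#' Two columns (source, target) with an optional third weight column.
#' Edges are undirected and deduplicated; self-edges are an error, as is
#' any endpoint missing from \code{domain_map}.
#'
#' @param path edge-list TSV.
#' @param domain_map named character vector taxon_id -> domain.
#' @return igraph object with a \code{domain} vertex attribute.
#' @export
readNetwork <- function(path, domain_map) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list needs at least two columns")
  a <- as.character(df[[1]]); b <- as.character(df[[2]])
  if (any(a == b))
    stop("self-edge(s) found: ", paste(unique(a[a == b]), collapse = ", "))
  w <- if (ncol(df) >= 3) as.numeric(df[[3]]) else NULL
  makeNetwork(a, b, domain_map, weight = w)
}

#' Build an association network from endpoint vectors
#'
#' @param a,b character vectors of edge endpoints.
#' @param domain_map named character vector taxon_id -> domain.
#' @param weight optional numeric edge weights (kept as attribute,
#'   ignored by all statistics).
#' @param extra_nodes additional isolated nodes to include.
#' @return igraph object.
#' @export
makeNetwork <- function(a, b, domain_map, weight = NULL,
                        extra_nodes = character()) {
  nodes <- unique(c(a, b, extra_nodes))
  missing <- setdiff(nodes, names(domain_map))
  if (length(missing))
    stop("endpoints without domain label: ",
         paste(utils::head(missing, 10), collapse = ", "))
  el <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
  if (!is.null(weight)) el$weight <- weight
  g <- igraph::graph_from_data_frame(
    el, directed = FALSE,
    vertices = data.frame(name = nodes,
                          domain = unname(domain_map[nodes])))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "first")
}

#' Write an association network as an edge-list TSV
#' @param g igraph network.
#' @param path output path.
#' @return path, invisibly.
#' @export
writeNetwork <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  colnames(el)[1:2] <- c("source", "target")
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
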