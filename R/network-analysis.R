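#' @importFrom igraph V E vcount ecount gorder gsize degree
NULL

.nodeDomains <- function(g) {
  d <- igraph::vertex_attr(g, "domain")
  if (is.null(d) || anyNA(d))
    stop("all nodes must carry a domain label")
  stats::setNames(d, igraph::V(g)$name)
}

#' Extract bacterial-fungal (cross-domain) edges
#'
#' Removes every bacteria-bacteria and fungi-fungi association, keeping
#' only edges joining one bacterial and one fungal node. All nodes are
#' retained; nodes left without edges get a logical \code{isolated}
#' vertex attribute.
#'
#' @param g igraph network with a \code{domain} vertex attribute.
#' @return bipartite igraph network.
#' @export
extractBfEdges <- function(g) {
  dom <- .nodeDomains(g)
  ends <- igraph::as_edgelist(g)
  keep <- dom[ends[, 1]] != dom[ends[, 2]]
  out <- igraph::subgraph_from_edges(g, which(keep), delete.vertices = FALSE)
  igraph::V(out)$isolated <- igraph::degree(out) == 0
  out
}

#' Summary statistics of an association network
#'
#' Linkage density (complexity) is the average number of edges per node,
#' 2E/N; edge density is the realized percentage of possible undirected
#' node pairs, 100 E / (N(N-1)/2). Module count comes from
#' [detectModules()]. Weights, if present, are ignored: associations
#' are counted, not summed.
#'
#' @param g igraph network with domain labels.
#' @param core_set optional core taxon ids, adding core/non-core degree
#'   medians per domain.
#' @param modules logical; compute the module count (default TRUE).
#' @return list of statistics.
#' @export
networkStats <- function(g, core_set = NULL, modules = TRUE) {
  if (igraph::vcount(g) == 0) stop("empty network")
  dom <- .nodeDomains(g)
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  deg <- igraph::degree(g)
  out <- list(
    n_nodes = n,
    n_bacteria = sum(dom == "bacteria"),
    n_fungi = sum(dom == "fungi"),
    n_edges = e,
    linkage_density = 2 * e / n,
    max_degree = max(deg),
    edge_density = if (n > 1) 100 * e / (n * (n - 1) / 2) else NA_real_,
    degree_by_domain = do.call(rbind, lapply(.DOMAINS, function(d) {
      v <- deg[dom == d]
      data.frame(domain = d, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    })))
  if (modules) {
    mod <- detectModules(g)
    out$n_modules <- mod$n_modules
    out$modularity <- mod$modularity
  }
  if (!is.null(core_set)) {
    is_core <- igraph::V(g)$name %in% core_set
    out$degree_core <- do.call(rbind, lapply(.DOMAINS, function(d) {
      data.frame(domain = d,
                 median_core = stats::median(deg[dom == d & is_core]),
                 median_noncore = stats::median(deg[dom == d & !is_core]))
    }))
  }
  out
}

#' Detect network modules by modularity maximization
#'
#' Multilevel (Louvain) modularity maximization, made deterministic by a
#' fixed seed.
#'
#' @param g igraph network.
#' @param seed RNG seed.
#' @return list with \code{membership} (named integer vector),
#'   \code{n_modules} and \code{modularity}.
#' @export
detectModules <- function(g, seed = 1) {
  set.seed(seed)
  gu <- g
  # strip weights so modularity counts associations, not weights
  if ("weight" %in% igraph::edge_attr_names(gu))
    gu <- igraph::delete_edge_attr(gu, "weight")
  cl <- igraph::cluster_louvain(gu)
  memb <- stats::setNames(igraph::membership(cl), igraph::V(g)$name)
  list(membership = memb, n_modules = length(unique(memb)),
       modularity = igraph::modularity(cl))
}

#' Compare two module partitions by best-match Jaccard similarity
#'
#' The comparison is restricted to nodes present in both partitions.
#' Every pair of modules gets a Jaccard similarity; modules are then
#' greedily matched by descending similarity and the mean matched
#' similarity is the summary score.
#'
#' @param partition_a,partition_b named membership vectors.
#' @return list with \code{jaccard} matrix, \code{score}, \code{n_shared}
#'   and a \code{disjoint} flag (score 0 when no shared nodes).
#' @export
compareModules <- function(partition_a, partition_b) {
  shared <- intersect(names(partition_a), names(partition_b))
  if (!length(shared)) {
    warning("partitions share no nodes")
    return(list(jaccard = matrix(numeric(0), 0, 0), score = 0,
                n_shared = 0L, disjoint = TRUE))
  }
  a <- split(shared, partition_a[shared])
  b <- split(shared, partition_b[shared])
  jac <- outer(seq_along(a), seq_along(b), Vectorize(function(i, j) {
    u <- length(union(a[[i]], b[[j]]))
    if (u == 0) 0 else length(intersect(a[[i]], b[[j]])) / u
  }))
  dimnames(jac) <- list(names(a), names(b))
  # greedy matching on descending similarity
  j <- jac; matched <- numeric(0)
  while (nrow(j) > 0 && ncol(j) > 0 && max(j) > -Inf) {
    idx <- which(j == max(j), arr.ind = TRUE)[1, ]
    matched <- c(matched, j[idx[1], idx[2]])
    j <- j[-idx[1], -idx[2], drop = FALSE]
  }
  list(jaccard = jac, score = mean(matched), n_shared = length(shared),
       disjoint = FALSE)
}

#' Generate randomized null networks
#'
#' \code{"rewire"} performs degree-preserving double-edge swaps (every
#' node keeps its exact degree; edge count conserved; no self-edges or
#' multi-edges), with 10 x E swap attempts per replicate.
#' \code{"er"} draws a uniform random graph on the same node set with
#' the same edge count.
#'
#' @param g igraph network.
#' @param n number of replicates.
#' @param null_model "rewire" or "er".
#' @param seed RNG seed.
#' @return list of igraph networks (domain labels preserved).
#' @export
randomNetworks <- function(g, n, null_model = c("rewire", "er"),
                           seed = 1) {
  null_model <- match.arg(null_model)
  set.seed(seed)
  if (null_model == "rewire" && igraph::ecount(g) < 2)
    stop("degree-preserving rewiring needs at least 2 edges")
  lapply(seq_len(n), function(i) .randomizeOne(g, null_model))
}

.randomizeOne <- function(g, null_model) {
  if (null_model == "rewire") {
    igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
  } else {
    r <- igraph::sample_gnm(igraph::vcount(g), igraph::ecount(g))
    igraph::V(r)$name <- igraph::V(g)$name
    igraph::V(r)$domain <- igraph::V(g)$domain
    r
  }
}

.edgeKeys <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(character())
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
}

#' Associations shared by every network of a subset
#'
#' Edge identity is the unordered taxon-id pair, so OTU ids must form a
#' shared namespace across networks.
#'
#' @param networks named list of igraph networks (one per location).
#' @param subset location names to intersect (default: all).
#' @return data.frame with columns taxon_a, taxon_b.
#' @export
sharedAssociations <- function(networks, subset = names(networks)) {
  stopifnot(length(subset) >= 2, all(subset %in% names(networks)))
  keys <- Reduce(intersect, lapply(networks[subset], .edgeKeys))
  if (!length(keys))
    return(data.frame(taxon_a = character(), taxon_b = character()))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  data.frame(taxon_a = parts[, 1], taxon_b = parts[, 2])
}

.empiricalP <- function(observed, null_counts, two_sided = FALSE) {
  R <- length(null_counts)
  p_up <- (1 + sum(null_counts >= observed)) / (R + 1)
  if (!two_sided) return(p_up)
  p_dn <- (1 + sum(null_counts <= observed)) / (R + 1)
  min(1, 2 * min(p_up, p_dn))
}

#' Permutation test for the number of cross-network shared associations
#'
#' Jointly randomizes every network of the subset \code{n} times and
#' counts how many shared edges arise by chance; the empirical p-value
#' is (1 + #\{null >= observed\}) / (n + 1) (one-sided "greater" by
#' default; the two-sided option doubles the smaller tail).
#'
#' @param networks named list of igraph networks.
#' @param subset location names to test (default: all).
#' @param n number of joint randomizations (default 999).
#' @param null_model "rewire" (degree-preserving) or "er".
#' @param seed RNG seed.
#' @param two_sided report the doubled-min-tail p instead.
#' @return list: observed_shared, null_counts, p_value, null_model,
#'   subset.
#' @export
sharedEdgeTest <- function(networks, subset = names(networks), n = 999,
                           null_model = c("rewire", "er"), seed = 1,
                           two_sided = FALSE) {
  null_model <- match.arg(null_model)
  stopifnot(length(subset) >= 2, all(subset %in% names(networks)))
  set.seed(seed)
  nets <- networks[subset]
  obs <- nrow(sharedAssociations(nets))
  null_counts <- vapply(seq_len(n), function(i) {
    keys <- lapply(nets, function(g) .edgeKeys(.randomizeOne(g, null_model)))
    length(Reduce(intersect, keys))
  }, integer(1))
  list(observed_shared = obs, null_counts = null_counts,
       p_value = .empiricalP(obs, null_counts, two_sided),
       null_model = null_model, subset = subset, n = n)
}

#' Attach neutral-model classes to network nodes
#'
#' Maps each node to its NCM class (\code{neutral}, \code{above},
#' \code{below}; \code{unassigned} when absent from the fit), summarizes
#' class percentages per domain, and cross-tabulates the class pair of
#' every edge (unordered; for bacterial-fungal edges rows index the
#' bacterial endpoint and columns the fungal one).
#'
#' @param g igraph network with domain labels.
#' @param fit an NcmFit covering (most of) the nodes.
#' @return list: node_classes (named vector), domain_percent
#'   (data.frame), pair_counts (matrix over classes incl. unassigned
#'   when present; total equals the edge count).
#' @export
attachNcmClasses <- function(g, fit) {
  dom <- .nodeDomains(g)
  o <- as.data.frame(fit@otu)
  cls <- stats::setNames(o$class, o$taxon_id)
  node_cls <- cls[igraph::V(g)$name]
  node_cls[is.na(node_cls)] <- "unassigned"
  names(node_cls) <- igraph::V(g)$name
  levs <- c(.NCM_CLASSES, if (any(node_cls == "unassigned")) "unassigned")
  domain_percent <- do.call(rbind, lapply(split(node_cls, dom), function(v) {
    tab <- table(factor(v, levels = levs))
    data.frame(class = names(tab), n = as.integer(tab),
               percent = 100 * as.integer(tab) / length(v))
  }))
  domain_percent$domain <- rep(names(split(node_cls, dom)),
                               each = length(levs))
  rownames(domain_percent) <- NULL
  el <- igraph::as_edgelist(g)
  pair_counts <- matrix(0L, length(levs), length(levs),
                        dimnames = list(levs, levs))
  if (nrow(el)) {
    c1 <- node_cls[el[, 1]]; c2 <- node_cls[el[, 2]]
    d1 <- dom[el[, 1]]; d2 <- dom[el[, 2]]
    # orient bacteria -> rows for cross-domain edges, else sort classes
    swap <- ifelse(d1 != d2, d1 != "bacteria", c1 > c2)
    r <- ifelse(swap, c2, c1); cc <- ifelse(swap, c1, c2)
    for (i in seq_along(r))
      pair_counts[r[i], cc[i]] <- pair_counts[r[i], cc[i]] + 1L
  }
  list(node_classes = node_cls,
       domain_percent = domain_percent[, c("domain", "class", "n",
                                           "percent")],
       pair_counts = pair_counts)
}

#' Naive demonstration network inference (sparse correlation)
#'
#' A plumbing-grade stand-in for proper conditional-independence network
#' inference: counts get a pseudocount, a centered-log-ratio transform
#' per sample, and taxon pairs with |Pearson r| at or above the
#' threshold become edges. Not equivalent to graphical-model inference;
#' intended only to exercise downstream network analyses.
#'
#' @param x OtuExperiment (>= 20 samples).
#' @param threshold absolute correlation cutoff in (0, 1).
#' @param pseudocount added before the log transform.
#' @return igraph network over the table's taxa.
#' @export
naiveNetworkInference <- function(x, threshold = 0.6, pseudocount = 1) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (ncol(x) < 20) stop("need at least 20 samples")
  lm_ <- log(otuCounts(x) + pseudocount)
  clr <- sweep(lm_, 2, colMeans(lm_))
  keep <- apply(clr, 1, stats::sd) > 0
  r <- stats::cor(t(clr[keep, , drop = FALSE]))
  r[!upper.tri(r)] <- 0
  hits <- which(abs(r) >= threshold, arr.ind = TRUE)
  dom <- taxonDomain(x)
  makeNetwork(rownames(r)[hits[, 1]], colnames(r)[hits[, 2]], dom,
              weight = r[hits], extra_nodes = character())
}
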