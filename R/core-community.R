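#' Per-OTU occupancy within sample groups
#'
#' Occupancy of an OTU in a location is the fraction of that location's
#' samples in which it is detected (count > 0). Detection uses presence,
#' so occupancy is invariant to rescaling any sample's counts.
#'
#' @param x OtuExperiment with a \code{location} column in colData (or
#'   pass \code{grouping}).
#' @param grouping optional factor/character of length \code{ncol(x)}
#'   assigning samples to locations.
#' @return list with \code{fraction} (taxa x locations matrix),
#'   \code{count} (detection counts) and \code{n_samples} per location.
#' @export
occupancy <- function(x, grouping = NULL) {
  if (is.null(grouping)) {
    if (!"location" %in% colnames(colData(x)))
      stop("no location column in colData and no grouping given")
    grouping <- as.character(colData(x)$location)
  }
  stopifnot(length(grouping) == ncol(x))
  if (anyNA(grouping)) stop("grouping contains missing values")
  grouping <- as.factor(grouping)
  if (nlevels(grouping) == 0 || any(table(grouping) == 0))
    stop("empty location group")
  pres <- otuCounts(x) > 0
  cnt <- vapply(levels(grouping),
                function(l) rowSums(pres[, grouping == l, drop = FALSE]),
                numeric(nrow(x)))
  if (is.null(dim(cnt)))      # single-taxon table: keep matrix shape
    cnt <- matrix(cnt, nrow = nrow(x),
                  dimnames = list(rownames(x), levels(grouping)))
  n <- as.integer(table(grouping)[colnames(cnt)])
  list(fraction = sweep(cnt, 2, n, "/"), count = cnt,
       n_samples = stats::setNames(n, colnames(cnt)))
}

#' Core-microbiome Venn partition at per-domain occupancy thresholds
#'
#' An OTU is retained in a location when it occurs in at least
#' \code{thresholds[domain]} of that location's samples. The core set is
#' the OTUs retained in every location; the Venn partition assigns every
#' retained OTU to its exact membership pattern.
#'
#' @param x OtuExperiment.
#' @param thresholds named integer vector of minimum sample counts per
#'   domain, e.g. \code{c(bacteria = 10, fungi = 5)}.
#' @param grouping optional location assignment (see [occupancy()]).
#' @return list with \code{retained} (per-location taxon id lists),
#'   \code{venn} (region name -> taxon ids), \code{venn_counts},
#'   \code{core} (taxon ids) and \code{core_by_domain}.
#' @export
corePartition <- function(x, thresholds = c(bacteria = 10, fungi = 5),
                          grouping = NULL) {
  dom <- taxonDomain(x)
  unknown <- setdiff(unique(dom), names(thresholds))
  if (length(unknown))
    stop("no threshold for domain(s): ", paste(unknown, collapse = ", "))
  occ <- occupancy(x, grouping)
  min_n <- unname(thresholds[dom])
  retained <- lapply(colnames(occ$count), function(l) {
    rownames(x)[occ$count[, l] >= min_n & occ$count[, l] > 0]
  })
  names(retained) <- colnames(occ$count)
  # exact membership pattern of every OTU in the union
  universe <- unique(unlist(retained))
  memb <- vapply(retained, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1)
  pattern <- apply(memb, 1, function(z)
    paste(names(retained)[z], collapse = "&"))
  venn <- split(universe, pattern)
  core_name <- paste(names(retained), collapse = "&")
  core <- if (core_name %in% names(venn)) venn[[core_name]] else character()
  list(retained = retained,
       venn = venn,
       venn_counts = vapply(venn, length, integer(1)),
       core = core,
       core_by_domain = split(core, dom[core]),
       thresholds = thresholds)
}

#' Fraction of reads belonging to core OTUs, per domain
#'
#' Denominators are domain-specific: the bacterial core fraction of a
#' sample is core-bacterial reads over all bacterial reads in that
#' sample, and likewise for fungi.
#'
#' @param x OtuExperiment.
#' @param core_set character vector of core taxon ids.
#' @return list with \code{per_sample} (samples x domains matrix of
#'   fractions) and \code{mean} per domain.
#' @export
coreAbundanceFraction <- function(x, core_set) {
  stopifnot(all(core_set %in% rownames(x)))
  if (!length(core_set))
    warning("empty core set; fractions are 0")
  dom <- taxonDomain(x)
  m <- otuCounts(x)
  doms <- intersect(.DOMAINS, unique(dom))
  per <- vapply(doms, function(d) {
    rows <- names(dom)[dom == d]
    tot <- colSums(m[rows, , drop = FALSE])
    core_rows <- intersect(core_set, rows)
    num <- if (length(core_rows))
      colSums(m[core_rows, , drop = FALSE]) else rep(0, ncol(m))
    ifelse(tot > 0, num / tot, 0)
  }, numeric(ncol(m)))
  per <- matrix(per, ncol = length(doms),
                dimnames = list(colnames(m), doms))
  list(per_sample = per, mean = colMeans(per))
}

#' Abundance-occupancy relationship within a location
#'
#' For the OTUs detected in a location, relates mean relative abundance
#' (averaged over the location's samples) to occupancy, and tests the
#' association with Spearman's rank correlation (midranks for ties,
#' two-sided). The occupancy/abundance ratio is also reported per OTU.
#'
#' @param x OtuExperiment.
#' @param location location code to analyse.
#' @param domain optional domain restriction ("bacteria" or "fungi").
#' @return list with \code{table} (per-OTU occupancy, mean_abundance,
#'   ratio, domain), \code{rho}, \code{p_value}, and a \code{degenerate}
#'   flag when the correlation is undefined.
#' @export
abundanceOccupancy <- function(x, location, domain = NULL) {
  loc <- as.character(colData(x)$location)
  if (!location %in% loc) stop("unknown location: ", location)
  sub <- x[, loc == location]
  if (!is.null(domain)) sub <- sub[taxonDomain(sub) == domain, ]
  ra <- relativeAbundance(sub)
  occ <- rowMeans(otuCounts(sub) > 0)
  detected <- occ > 0
  if (sum(detected) < 3)
    stop("need at least 3 detected OTUs in ", location)
  occ <- occ[detected]
  ma <- rowMeans(ra)[detected]
  tab <- data.frame(taxon_id = names(occ), occupancy = occ,
                    mean_abundance = ma, ratio = occ / ma,
                    domain = taxonDomain(sub)[names(occ)],
                    row.names = NULL)
  degenerate <- stats::sd(occ) == 0 || stats::sd(ma) == 0
  if (degenerate) {
    rho <- NA_real_; p <- NA_real_
    warning("constant occupancy or abundance; rho undefined")
  } else {
    ct <- suppressWarnings(
      stats::cor.test(ma, occ, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  list(table = tab, rho = rho, p_value = p, degenerate = degenerate,
       location = location, n_otus = nrow(tab))
}

#' Per-sample alpha diversity
#'
#' Richness, Shannon (natural log), Simpson (1 - sum p^2), Pielou
#' evenness (Shannon / ln richness; NA for single-taxon samples) and,
#' given a tree covering the taxa, Faith's phylogenetic diversity (total
#' branch length of the rooted subtree spanning the detected tips).
#'
#' @param x OtuExperiment.
#' @param tree optional \code{phylo} whose tips cover \code{rownames(x)}.
#' @return data.frame of per-sample indices.
#' @export
alphaDiversity <- function(x, tree = NULL) {
  m <- t(otuCounts(x))
  rich <- rowSums(m > 0)
  shannon <- vegan::diversity(m, index = "shannon")
  simpson <- vegan::diversity(m, index = "simpson")
  even <- ifelse(rich > 1, shannon / log(rich), NA_real_)
  out <- data.frame(sample_id = colnames(x), richness = rich,
                    shannon = shannon, simpson = simpson,
                    evenness = even, row.names = NULL)
  if (!is.null(tree)) {
    miss <- setdiff(rownames(x), tree$tip.label)
    if (length(miss))
      stop("tree missing tips for ", length(miss), " taxa")
    tr <- ape::keep.tip(tree, rownames(x))
    # basal polytomies (e.g. star trees) count ape as unrooted; the
    # spanning subtree then already reaches the basal node
    pd <- picante::pd(m > 0, tr, include.root = ape::is.rooted(tr))
    out$faith_pd <- pd$PD
  }
  out
}
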