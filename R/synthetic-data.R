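#' Synthetic-data configuration
#'
#' Bundles the parameters of the synthetic amplicon study design: four
#' locations of 10 plots x 5 subsamples by default, bacterial and
#' fungal metacommunities with log-normal species-abundance
#' distributions, Moran-type neutral local assembly with immigration,
#' multinomial read sampling, and a minority of occupancy-perturbed
#' ("selected-for" / "selected-against") taxa.
#'
#' \code{sad_sdlog} may be a length-2 vector (bacteria, fungi): fungal
#' communities are given a more uneven abundance distribution, which
#' reproduces the field observation that fungal per-sample richness is
#' far below the bacterial one at comparable depth.
#'
#' @param seed integer RNG seed.
#' @param n_locations,plots_per_location,subsamples_per_plot design.
#' @param s_meta total metacommunity richness over both domains.
#' @param domain_split fraction of taxa that are bacterial.
#' @param sad_meanlog,sad_sdlog log-normal SAD parameters (sdlog may be
#'   per-domain: bacteria, fungi).
#' @param j_local local community size (individuals).
#' @param m migration probability per replacement, in (0, 1].
#' @param generations Moran generations (each = j_local replacements).
#' @param depth reads per sample and domain (>= 5000 so the depth
#'   filter passes by default).
#' @param frac_selected_for,frac_selected_against fractions of taxa with
#'   perturbed occupancy.
#' @param selection_strength multiplier on per-sample inclusion odds for
#'   selected-for taxa (divisor for selected-against).
#' @return list of class \code{synthetic_config}.
#' @export
syntheticConfig <- function(seed = 1,
                            n_locations = 4,
                            plots_per_location = 10,
                            subsamples_per_plot = 5,
                            s_meta = 4200,
                            domain_split = 0.8,
                            sad_meanlog = 0,
                            sad_sdlog = c(bacteria = 1.0, fungi = 3.2),
                            j_local = 10000,
                            m = 0.1,
                            generations = 50,
                            depth = 10000,
                            frac_selected_for = 0.03,
                            frac_selected_against = 0.02,
                            selection_strength = 5,
                            seed_offset = 0) {
  cfg <- list(seed = seed, n_locations = n_locations,
              plots_per_location = plots_per_location,
              subsamples_per_plot = subsamples_per_plot,
              s_meta = s_meta, domain_split = domain_split,
              sad_meanlog = sad_meanlog,
              sad_sdlog = rep(sad_sdlog, length.out = 2),
              j_local = j_local, m = m, generations = generations,
              depth = depth,
              frac_selected_for = frac_selected_for,
              frac_selected_against = frac_selected_against,
              selection_strength = selection_strength,
              seed_offset = seed_offset)
  stopifnot(cfg$m > 0, cfg$m <= 1, cfg$j_local >= 10,
            cfg$frac_selected_for >= 0, cfg$frac_selected_against >= 0,
            cfg$frac_selected_for + cfg$frac_selected_against <= 1,
            cfg$domain_split > 0, cfg$domain_split < 1)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Simulate a metacommunity relative-abundance vector
#'
#' Log-normal species abundance distribution, normalized to sum to 1.
#'
#' @param s_meta number of taxa (>= 2).
#' @param sad_params list with \code{meanlog} and \code{sdlog}.
#' @param seed optional RNG seed.
#' @return strictly positive numeric vector summing to 1.
#' @export
simulateMetacommunity <- function(s_meta,
                                  sad_params = list(meanlog = 0, sdlog = 1),
                                  seed = NULL) {
  stopifnot(s_meta >= 2)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rlnorm(s_meta, sad_params$meanlog, sad_params$sdlog)
  x / sum(x)
}

#' Simulate a neutral local community (Moran model with immigration)
#'
#' Starting from a multinomial draw of \code{j_local} individuals from
#' the metacommunity, each update kills one random individual and
#' replaces it with an immigrant sampled by metacommunity abundance
#' (probability \code{m}) or the offspring of a random local individual
#' (probability 1 - m). Community size is conserved at every step.
#'
#' @param metacommunity relative-abundance vector (sums to 1).
#' @param j_local community size in individuals (>= 10).
#' @param m migration probability in (0, 1].
#' @param generations number of generations (j_local updates each).
#' @param seed optional RNG seed.
#' @return integer vector of per-taxon individual counts (sums to
#'   j_local).
#' @export
simulateNeutralLocal <- function(metacommunity, j_local, m,
                                 generations = 50, seed = NULL) {
  stopifnot(j_local >= 10, m > 0, m <= 1)
  if (!is.null(seed)) set.seed(seed)
  init <- as.integer(stats::rmultinom(1, j_local, metacommunity))
  moran_local_cpp(metacommunity, init, m, generations)
}

# Occupancy perturbation: multiply (or divide) each selected taxon's
# per-sample inclusion odds by `strength`. Reads are moved within the
# taxon's own domain, so per-domain sample depth stays exact.
.perturbOccupancy <- function(counts, sel_for, sel_against, strength,
                              domain) {
  adjust <- function(taxon, multiply) {
    kin <- setdiff(rownames(counts)[domain == domain[taxon]], taxon)
    pres <- counts[taxon, ] > 0
    f <- mean(pres)
    if (f == 0 || f == 1) return()
    odds <- f / (1 - f)
    odds2 <- if (multiply) odds * strength else odds / strength
    f2 <- odds2 / (1 + odds2)
    if (multiply) {
      # promote some absent samples to presence (1 read from the top taxon)
      alpha <- (f2 - f) / (1 - f)
      for (j in which(!pres)) {
        if (stats::runif(1) < alpha) {
          top <- kin[which.max(counts[kin, j])]
          if (counts[top, j] > 1) {
            counts[top, j] <<- counts[top, j] - 1L
            counts[taxon, j] <<- 1L
          }
        }
      }
    } else {
      # demote some present samples (reads moved to the top taxon)
      beta <- (f - f2) / f
      for (j in which(pres)) {
        if (stats::runif(1) < beta) {
          top <- kin[which.max(counts[kin, j])]
          counts[top, j] <<- counts[top, j] + counts[taxon, j]
          counts[taxon, j] <<- 0L
        }
      }
    }
  }
  for (t in sel_for) adjust(t, TRUE)
  for (t in sel_against) adjust(t, FALSE)
  counts
}

#' Simulate a full synthetic OTU data set
#'
#' Emulates the nested field design (locations x plots x subsamples):
#' per domain a metacommunity is drawn once, every sample is an
#' independent Moran neutral local community read-sampled at
#' \code{depth}, and designated selected-for / selected-against taxa
#' have their per-sample inclusion odds multiplied / divided by
#' \code{selection_strength} within each location (perturbing occupancy
#' while conserving depth). The returned truth record carries each
#' taxon's class and the generating parameters.
#'
#' @param config a [syntheticConfig()].
#' @return list: \code{table} (OtuExperiment), \code{truth} (per-taxon
#'   data.frame), \code{metacommunity} (named vector), \code{config}.
#' @export
simulateDataset <- function(config = syntheticConfig()) {
  cfg <- config
  set.seed(cfg$seed + cfg$seed_offset)
  s_b <- round(cfg$s_meta * cfg$domain_split)
  s_f <- cfg$s_meta - s_b
  ids <- c(sprintf("B%05d", seq_len(s_b)), sprintf("F%05d", seq_len(s_f)))
  dom <- stats::setNames(rep(c("bacteria", "fungi"), c(s_b, s_f)), ids)
  meta_b <- simulateMetacommunity(s_b, list(meanlog = cfg$sad_meanlog,
                                            sdlog = cfg$sad_sdlog[1]))
  meta_f <- simulateMetacommunity(s_f, list(meanlog = cfg$sad_meanlog,
                                            sdlog = cfg$sad_sdlog[2]))
  meta <- stats::setNames(c(meta_b, meta_f), ids)

  n_sel_for <- round(cfg$frac_selected_for * length(ids))
  n_sel_against <- round(cfg$frac_selected_against * length(ids))
  sel <- sample(ids, n_sel_for + n_sel_against)
  sel_for <- sel[seq_len(n_sel_for)]
  sel_against <- setdiff(sel, sel_for)

  locs <- c("D", "G", "M", "T", paste0("L", 5:26))[seq_len(cfg$n_locations)]
  subs <- LETTERS[seq_len(cfg$subsamples_per_plot)]
  md <- expand.grid(subsample = subs,
                    plot = seq_len(cfg$plots_per_location),
                    location = locs, stringsAsFactors = FALSE)
  md$sample_id <- paste0(md$location, md$plot, md$subsample)
  md <- md[, c("sample_id", "location", "plot", "subsample")]

  sampleCounts <- function(meta_p) {
    local <- moran_local_cpp(meta_p,
                             as.integer(stats::rmultinom(1, cfg$j_local,
                                                         meta_p)),
                             cfg$m, cfg$generations)
    as.integer(stats::rmultinom(1, cfg$depth, local / cfg$j_local))
  }
  counts <- matrix(0L, length(ids), nrow(md),
                   dimnames = list(ids, md$sample_id))
  for (j in seq_len(nrow(md))) {
    counts[seq_len(s_b), j] <- sampleCounts(meta_b)
    counts[s_b + seq_len(s_f), j] <- sampleCounts(meta_f)
  }
  if (cfg$selection_strength != 1 && length(c(sel_for, sel_against))) {
    for (l in locs) {
      cols <- md$sample_id[md$location == l]
      counts[, cols] <- .perturbOccupancy(counts[, cols, drop = FALSE],
                                          sel_for, sel_against,
                                          cfg$selection_strength, dom)
    }
  }
  truth <- data.frame(
    taxon_id = ids, domain = unname(dom),
    class = ifelse(ids %in% sel_for, "selected_for",
                   ifelse(ids %in% sel_against, "selected_against",
                          "neutral")),
    p_meta = unname(meta))
  list(table = OtuExperiment(counts, domain = dom, sample_data = md),
       truth = truth, metacommunity = meta, config = cfg)
}

#' Simulate a Yule (pure-birth) phylogeny
#'
#' @param s number of tips (>= 3).
#' @param seed optional RNG seed.
#' @param tip_labels optional tip labels (defaults t1..ts).
#' @return a rooted \code{phylo} with positive branch lengths.
#' @export
simulateTree <- function(s, seed = NULL, tip_labels = NULL) {
  stopifnot(s >= 3)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(s, birth = 1, death = 0)
  tr$tip.label <- if (is.null(tip_labels)) paste0("t", seq_len(s)) else
    tip_labels
  tr
}

#' Draw a (possibly clade-restricted) community from a tree
#'
#' \code{clade_bias = 0} draws tips uniformly; \code{clade_bias = 1}
#' draws the whole community from one random clade containing at least
#' \code{size} tips; intermediate values mix the two.
#'
#' @param tree a \code{phylo}.
#' @param size community size.
#' @param clade_bias in [0, 1].
#' @param seed optional RNG seed.
#' @return character vector of tip labels.
#' @export
simulateClusteredCommunity <- function(tree, size, clade_bias = 1,
                                       seed = NULL) {
  stopifnot(clade_bias >= 0, clade_bias <= 1,
            size >= 2, size <= length(tree$tip.label))
  if (!is.null(seed)) set.seed(seed)
  n_clade <- round(clade_bias * size)
  picked <- character()
  if (n_clade > 0) {
    internal <- length(tree$tip.label) + seq_len(tree$Nnode)
    clades <- lapply(internal, function(nd)
      ape::extract.clade(tree, nd)$tip.label)
    sizes <- vapply(clades, length, integer(1))
    # prefer tight clades (community fills most of the clade) so the
    # drawn community is genuinely phylogenetically restricted
    ok <- which(sizes >= n_clade & sizes <= 2 * n_clade &
                  sizes < length(tree$tip.label))
    if (!length(ok))
      ok <- which(sizes >= n_clade & sizes < length(tree$tip.label) &
                    sizes == min(sizes[sizes >= n_clade &
                                         sizes < length(tree$tip.label)]))
    if (!length(ok)) stop("no proper clade large enough")
    clade <- clades[[if (length(ok) == 1) ok else sample(ok, 1)]]
    picked <- sample(clade, n_clade)
  }
  rest <- setdiff(tree$tip.label, picked)
  c(picked, sample(rest, size - n_clade))
}

#' Simulate per-location bipartite bacterial-fungal networks
#'
#' Each location receives a random bipartite network over an overlapping
#' subset of a global node pool; \code{n_planted_shared} bacterial-
#' fungal edges are inserted into every network (the planted truth).
#'
#' @param locations character vector of location names.
#' @param nodes_per_location nodes sampled per location from the pool.
#' @param edges_per_location total edges per network (incl. planted).
#' @param n_planted_shared edges planted into every network.
#' @param seed RNG seed.
#' @param pool_scale global pool size as a multiple of
#'   \code{nodes_per_location} (controls node-set overlap).
#' @param bf_split fraction of nodes that are bacterial.
#' @return list: \code{networks} (named list of igraph), \code{planted}
#'   (data.frame of planted pairs), \code{domain_map}.
#' @export
simulateNetworks <- function(locations = c("D", "G", "M", "T"),
                             nodes_per_location = 120,
                             edges_per_location = 300,
                             n_planted_shared = 0, seed = 1,
                             pool_scale = 1.3, bf_split = 2 / 3) {
  stopifnot(n_planted_shared <= edges_per_location)
  set.seed(seed)
  pool_n <- ceiling(nodes_per_location * pool_scale)
  n_b <- round(pool_n * bf_split)
  pool <- c(sprintf("b%04d", seq_len(n_b)),
            sprintf("f%04d", seq_len(pool_n - n_b)))
  dom <- stats::setNames(rep(c("bacteria", "fungi"),
                             c(n_b, pool_n - n_b)), pool)
  node_sets <- lapply(locations, function(l) {
    nb <- round(nodes_per_location * bf_split)
    c(sample(pool[seq_len(n_b)], nb),
      sample(pool[n_b + seq_len(pool_n - n_b)], nodes_per_location - nb))
  })
  names(node_sets) <- locations
  common <- Reduce(intersect, node_sets)
  common_b <- common[dom[common] == "bacteria"]
  common_f <- common[dom[common] == "fungi"]
  planted <- NULL
  if (n_planted_shared > 0) {
    if (length(common_b) < 1 || length(common_f) < 1 ||
        length(common_b) * length(common_f) < n_planted_shared)
      stop("planted pair endpoints missing from a location's node set")
    all_pairs <- expand.grid(taxon_a = common_b, taxon_f = common_f,
                             stringsAsFactors = FALSE)
    planted <- all_pairs[sample(nrow(all_pairs), n_planted_shared), ]
    colnames(planted) <- c("taxon_a", "taxon_b")
  }
  networks <- lapply(locations, function(l) {
    nodes <- node_sets[[l]]
    b <- nodes[dom[nodes] == "bacteria"]
    f <- nodes[dom[nodes] == "fungi"]
    n_random <- edges_per_location - n_planted_shared
    ea <- sample(b, 3 * n_random, replace = TRUE)
    eb <- sample(f, 3 * n_random, replace = TRUE)
    key <- paste(ea, eb)
    keep <- !duplicated(key)
    if (!is.null(planted))
      keep <- keep & !(key %in% paste(planted$taxon_a, planted$taxon_b))
    ea <- ea[keep][seq_len(n_random)]
    eb <- eb[keep][seq_len(n_random)]
    makeNetwork(c(ea, planted$taxon_a), c(eb, planted$taxon_b), dom,
                extra_nodes = nodes)
  })
  names(networks) <- locations
  list(networks = networks, planted = planted, domain_map = dom)
}
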