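#' Tip-to-tip patristic distance matrix
#'
#' @param tree a \code{phylo} with branch lengths.
#' @return symmetric numeric matrix (zero diagonal) of path lengths.
#' @export
patristicDistances <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  ape::cophenetic.phylo(tree)
}

#' Mean nearest taxon distance of a community
#'
#' For each community member, the distance to its nearest other member;
#' averaged (optionally abundance-weighted) over members.
#'
#' @param community_taxa character vector of member taxon ids (>= 2).
#' @param dist_matrix labelled patristic distance matrix covering them.
#' @param weights optional named abundance weights for the members.
#' @return numeric MNTD.
#' @export
mntd <- function(community_taxa, dist_matrix, weights = NULL) {
  community_taxa <- unique(community_taxa)
  if (length(community_taxa) < 2)
    stop("community must contain at least 2 taxa")
  miss <- setdiff(community_taxa, rownames(dist_matrix))
  if (length(miss))
    stop("taxa missing from distance matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  d <- dist_matrix[community_taxa, community_taxa]
  diag(d) <- Inf
  mins <- apply(d, 1, min)
  if (is.null(weights)) return(mean(mins))
  w <- weights[community_taxa]
  stopifnot(all(w >= 0), sum(w) > 0)
  sum(w * mins) / sum(w)
}

# Pool context reused across many NTI calls: distances + neighbour order.
.ntiPool <- function(dist_matrix) {
  ord <- t(apply(dist_matrix, 1, order))
  # drop self (distance 0 sorts first; ties with true-zero distances are
  # harmless since the distances are equal)
  ord <- t(vapply(seq_len(nrow(ord)),
                  function(i) ord[i, ord[i, ] != i],
                  integer(ncol(ord) - 1)))
  list(D = dist_matrix, ord = ord, labels = rownames(dist_matrix))
}

#' Nearest taxon index of a community against a taxa-shuffle null
#'
#' The null shuffles tip labels across the taxon pool, i.e. draws
#' communities of the observed size uniformly from the pool, and
#' recomputes MNTD \code{n_null} times. NTI is the sign-flipped z-score
#' \eqn{-(MNTD_{obs} - \mu_{null}) / \sigma_{null}}; positive values
#' indicate phylogenetic clustering (homogeneous selection). When the
#' community equals the whole pool the null is degenerate (MNTD is
#' invariant under label shuffles) and NTI is flagged undefined.
#'
#' @param community character vector of member taxon ids.
#' @param tree \code{phylo}, or pass \code{dist_matrix} directly.
#' @param pool taxon pool for the null (default: all tips/labels).
#' @param n_null number of randomizations (>= 99).
#' @param seed RNG seed for reproducibility.
#' @param weights optional abundance weights for weighted MNTD (the
#'   null then reuses the observed weights on shuffled identities).
#' @param dist_matrix optional precomputed patristic distances.
#' @return one-row data.frame: mntd_obs, null_mean, null_sd, nti,
#'   n_null, undefined flag.
#' @export
nti <- function(community, tree = NULL, pool = NULL, n_null = 999,
                seed = NULL, weights = NULL, dist_matrix = NULL) {
  stopifnot(n_null >= 99)
  if (is.null(dist_matrix)) dist_matrix <- patristicDistances(tree)
  if (is.null(pool)) pool <- rownames(dist_matrix)
  stopifnot(all(community %in% pool), all(pool %in% rownames(dist_matrix)))
  if (!is.null(seed)) set.seed(seed)
  D <- dist_matrix[pool, pool]
  obs <- mntd(community, D, weights)
  k <- length(unique(community))
  if (k >= length(pool)) {
    return(data.frame(mntd_obs = obs, null_mean = obs, null_sd = 0,
                      nti = NA_real_, n_null = n_null, undefined = TRUE))
  }
  if (is.null(weights)) {
    ctx <- .ntiPool(D)
    nulls <- mntd_null_cpp(ctx$D, ctx$ord, k, n_null)
  } else {
    w <- unname(weights[unique(community)])
    nulls <- vapply(seq_len(n_null), function(i) {
      pick <- sample(pool, k)
      mntd(pick, D, stats::setNames(w, pick))
    }, numeric(1))
  }
  mu <- mean(nulls); sdev <- stats::sd(nulls)
  undef <- sdev == 0
  data.frame(mntd_obs = obs, null_mean = mu, null_sd = sdev,
             nti = if (undef) NA_real_ else -(obs - mu) / sdev,
             n_null = n_null, undefined = undef)
}

#' Per-sample NTI across an OTU table
#'
#' Computes the NTI of each sample's community (taxa with count > 0)
#' against the pool of taxa detected in that sample's location. Samples
#' whose community has fewer than 2 tree-covered taxa are skipped.
#'
#' @param x OtuExperiment with location/plot metadata.
#' @param tree \code{phylo} covering the taxa (extra tips allowed).
#' @param n_null randomizations per sample.
#' @param seed RNG seed.
#' @param weighted use abundance-weighted MNTD.
#' @return data.frame: sample_id, location, plot, mntd_obs, null_mean,
#'   null_sd, nti, undefined.
#' @export
sampleNti <- function(x, tree, n_null = 999, seed = 1, weighted = FALSE) {
  set.seed(seed)
  loc <- as.character(colData(x)$location)
  plt <- if ("plot" %in% colnames(colData(x)))
    colData(x)$plot else rep(NA, ncol(x))
  taxa <- intersect(rownames(x), tree$tip.label)
  if (length(taxa) < 2) stop("tree covers fewer than 2 table taxa")
  m <- otuCounts(x)[taxa, , drop = FALSE]
  out <- vector("list", ncol(x))
  for (l in unique(loc)) {
    cols <- which(loc == l)
    pool <- taxa[rowSums(m[, cols, drop = FALSE] > 0) > 0]
    if (length(pool) < 3) next
    D <- patristicDistances(ape::keep.tip(tree, pool))[pool, pool]
    ctx <- .ntiPool(D)
    for (j in cols) {
      comm <- pool[m[pool, j] > 0]
      if (length(comm) < 2) next
      if (weighted) {
        r <- nti(comm, pool = pool, n_null = n_null,
                 weights = m[pool, j], dist_matrix = D)
      } else {
        obs <- mntd_obs_cpp(ctx$D, ctx$ord, match(comm, pool))
        if (length(comm) >= length(pool)) {
          r <- data.frame(mntd_obs = obs, null_mean = obs, null_sd = 0,
                          nti = NA_real_, n_null = n_null,
                          undefined = TRUE)
        } else {
          nulls <- mntd_null_cpp(ctx$D, ctx$ord, length(comm), n_null)
          mu <- mean(nulls); sdev <- stats::sd(nulls)
          r <- data.frame(mntd_obs = obs, null_mean = mu, null_sd = sdev,
                          nti = if (sdev == 0) NA_real_ else
                            -(obs - mu) / sdev,
                          n_null = n_null, undefined = sdev == 0)
        }
      }
      out[[j]] <- cbind(data.frame(sample_id = colnames(m)[j],
                                   location = l, plot = plt[j]), r)
    }
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Per-plot one-sample t-tests of NTI against zero
#'
#' Under neutral assembly the expected NTI is zero; each plot's NTI
#' values (its subsample communities) are tested with a two-sided
#' one-sample t-test. Plots with fewer than 2 values or zero variance
#' are flagged without a p-value.
#'
#' @param nti_df output of [sampleNti()] (needs location, plot, nti).
#' @param alpha significance level for the \code{significant} flag.
#' @return list with \code{plots} (per-plot t, df, p, significance) and
#'   \code{locations} (mean NTI per location).
#' @export
ntiPlotTest <- function(nti_df, alpha = 0.05) {
  nti_df <- nti_df[!is.na(nti_df$nti), , drop = FALSE]
  key <- interaction(nti_df$location, nti_df$plot, drop = TRUE)
  rows <- lapply(split(nti_df, key), function(d) {
    v <- d$nti
    base <- data.frame(location = d$location[1], plot = d$plot[1],
                       n = length(v), mean_nti = mean(v))
    if (length(v) < 2 || stats::sd(v) == 0) {
      cbind(base, data.frame(t_statistic = NA_real_, df = NA_real_,
                             p_two_sided = NA_real_, significant = NA,
                             degenerate = TRUE))
    } else {
      tt <- stats::t.test(v, mu = 0)
      cbind(base, data.frame(t_statistic = unname(tt$statistic),
                             df = unname(tt$parameter),
                             p_two_sided = tt$p.value,
                             significant = tt$p.value < alpha,
                             degenerate = FALSE))
    }
  })
  plots <- do.call(rbind, rows)
  rownames(plots) <- NULL
  locations <- stats::aggregate(nti ~ location, nti_df, mean)
  colnames(locations)[2] <- "mean_nti"
  list(plots = plots, locations = locations)
}
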