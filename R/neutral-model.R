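#' Predicted occurrence frequency under the Sloan neutral model
#'
#' Under neutral drift with immigration, the long-run local relative
#' abundance of a taxon with metacommunity mean relative abundance p
#' follows Beta(Nm p, Nm (1 - p)). The probability of detecting it in a
#' local community, at detection limit d, is therefore
#' \deqn{\hat f(p) = 1 - I_d(Nm\,p,\; Nm\,(1-p)),}
#' the upper tail of that beta distribution; \eqn{\hat f} is strictly
#' increasing in p for fixed Nm and d.
#'
#' @param p mean relative abundance(s), each in (0, 1).
#' @param Nm immigration parameter (> 0).
#' @param d detection limit in (0, 1).
#' @return predicted occurrence frequency in [0, 1].
#' @export
ncmPredict <- function(p, Nm, d) {
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  stopifnot(Nm > 0, d > 0, d < 1)
  stats::pbeta(d, Nm * p, Nm * (1 - p), lower.tail = FALSE)
}

# Wilson score interval for a proportion f at sample size n.
wilsonInterval <- function(f, n, ci = 0.95) {
  z <- stats::qnorm(1 - (1 - ci) / 2)
  den <- 1 + z^2 / n
  centre <- (f + z^2 / (2 * n)) / den
  half <- z * sqrt(f * (1 - f) / n + z^2 / (4 * n^2)) / den
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Fit the Sloan neutral community model
#'
#' Estimates Nm by least squares on the observed occurrence frequencies
#' against the beta-tail prediction, then classifies every OTU by a
#' Wilson score band of level \code{ci} around its predicted frequency:
#' \code{"above"} (selected-for) when f_obs exceeds the upper bound,
#' \code{"below"} (selected-against) when it falls short of the lower
#' bound, \code{"neutral"} otherwise (equality with a bound is neutral).
#'
#' The optimisation runs over log(Nm) on [1e-2, 1e9], seeded by a coarse
#' multi-start grid, because the objective is badly scaled in raw Nm.
#'
#' @param x either an OtuExperiment or a data.frame with columns
#'   \code{p} and \code{f_obs} (one row per OTU).
#' @param d detection limit; default 1/N with N = mean reads per sample
#'   for table input (must be given for pair input).
#' @param n_samples number of local communities (needed for pair input;
#'   derived from the table otherwise).
#' @param ci confidence level of the classification band.
#' @param samples optional logical/character selector of the samples
#'   (local communities) entering the fit, e.g. one location.
#' @return an \linkS4class{NcmFit}.
#' @export
ncmFit <- function(x, d = NULL, n_samples = NULL, ci = 0.95,
                   samples = NULL) {
  domain <- NULL
  if (is(x, "OtuExperiment")) {
    if (!is.null(samples)) x <- x[, samples]
    m <- otuCounts(x)
    N <- mean(colSums(m))
    if (is.null(d)) d <- 1 / N
    ra <- relativeAbundance(m)
    p <- rowMeans(ra)
    f_obs <- rowMeans(m > 0)
    keep <- p > 0 & p < 1
    df <- data.frame(taxon_id = rownames(m)[keep], p = p[keep],
                     f_obs = f_obs[keep])
    domain <- taxonDomain(x)[keep]
    n_samples <- ncol(m)
  } else {
    df <- as.data.frame(x)
    stopifnot(all(c("p", "f_obs") %in% colnames(df)))
    if (is.null(d)) stop("d must be given for (p, f_obs) input")
    if (is.null(n_samples)) stop("n_samples must be given for pair input")
    if (is.null(df$taxon_id)) df$taxon_id <- sprintf("otu%04d", seq_len(nrow(df)))
    if (!is.null(df$domain)) { domain <- df$domain; df$domain <- NULL }
    N <- NA_real_
  }
  if (any(df$p <= 0 | df$p >= 1)) stop("p must lie in (0, 1)")
  if (any(df$f_obs < 0 | df$f_obs > 1)) stop("f_obs must lie in [0, 1]")
  if (nrow(df) < 10) stop("need at least 10 OTUs to fit the model")

  sse <- function(logNm)
    sum((df$f_obs - ncmPredict(df$p, exp(logNm), d))^2)
  grid <- log(10^seq(-1, 7, by = 0.25))
  g <- vapply(grid, sse, numeric(1))
  i <- which.min(g)
  lo <- if (i > 1) grid[i - 1] else log(1e-2)
  hi <- if (i < length(grid)) grid[i + 1] else log(1e9)
  opt <- stats::optimize(sse, lower = lo, upper = hi, tol = 1e-10)
  Nm <- exp(opt$minimum)

  f_pred <- ncmPredict(df$p, Nm, d)
  ssr <- sum((df$f_obs - f_pred)^2)
  sst <- sum((df$f_obs - mean(df$f_obs))^2)
  r2 <- if (sst == 0) {
    warning("all observed frequencies identical; R-squared undefined")
    NA_real_
  } else 1 - ssr / sst
  band <- wilsonInterval(f_pred, n_samples, ci)
  cls <- ifelse(df$f_obs > band[, "upper"], "above",
                ifelse(df$f_obs < band[, "lower"], "below", "neutral"))
  otu <- DataFrame(taxon_id = df$taxon_id, p = df$p, f_obs = df$f_obs,
                   f_pred = f_pred, ci_lower = band[, "lower"],
                   ci_upper = band[, "upper"], class = cls)
  if (!is.null(domain)) otu$domain <- unname(domain)
  new("NcmFit", Nm = Nm, m = if (is.na(N)) NA_real_ else Nm / N, N = N,
      d = d, rSquared = r2, nSamples = as.integer(n_samples), ci = ci,
      otu = otu)
}

#' Percentages of OTUs per neutral-model class
#'
#' @param fit an NcmFit.
#' @param by_domain split percentages by taxon domain when labels exist.
#' @return data.frame with columns domain (optional), class, n and
#'   percent; percentages sum to 100 within each domain.
#' @export
ncmClassSummary <- function(fit, by_domain = TRUE) {
  o <- as.data.frame(fit@otu)
  grp <- if (by_domain && !is.null(o$domain)) o$domain else
    rep("all", nrow(o))
  out <- do.call(rbind, lapply(split(o$class, grp), function(cl) {
    tab <- table(factor(cl, levels = .NCM_CLASSES))
    data.frame(class = names(tab), n = as.integer(tab),
               percent = 100 * as.integer(tab) / length(cl))
  }))
  out$domain <- rep(names(split(o$class, grp)),
                    each = length(.NCM_CLASSES))
  rownames(out) <- NULL
  out[, c("domain", "class", "n", "percent")]
}
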