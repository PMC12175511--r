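#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom SummarizedExperiment rowData<- colData<-
NULL

.DOMAINS <- c("bacteria", "fungi")
.NCM_CLASSES <- c("neutral", "above", "below")

#' OtuExperiment: an OTU count table with taxon domains and sample design
#'
#' Extends \linkS4class{SummarizedExperiment}. The single assay
#' \code{"counts"} holds non-negative integer read counts (taxa as rows,
#' samples as columns). \code{rowData} carries a mandatory \code{domain}
#' column (\code{"bacteria"} or \code{"fungi"}) and optional taxonomy;
#' \code{colData} carries the nested sampling design
#' (\code{location}, \code{plot}, \code{subsample}).
#'
#' @export
setClass("OtuExperiment", contains = "SummarizedExperiment")

setValidity("OtuExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(m)) || any(m < 0))
      msg <- c(msg, "counts must be non-negative and non-missing")
    if (any(m != round(m)))
      msg <- c(msg, "counts must be integers")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "taxon ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (!"domain" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain a 'domain' column")
  else if (!all(rowData(object)$domain %in% .DOMAINS))
    msg <- c(msg, sprintf("domain labels must be one of: %s",
                          paste(.DOMAINS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an OtuExperiment
#'
#' @param counts integer matrix, taxa x samples, with dimnames.
#' @param domain character vector of per-taxon domain labels
#'   (\code{"bacteria"}/\code{"fungi"}), recycled against rows of
#'   \code{counts} by name when named.
#' @param sample_data optional data.frame of per-sample metadata with
#'   columns \code{location}, \code{plot}, \code{subsample}; rownames or a
#'   \code{sample_id} column must match \code{colnames(counts)}.
#' @param taxonomy optional data.frame of extra per-taxon annotation.
#' @return An \linkS4class{OtuExperiment}.
#' @export
OtuExperiment <- function(counts, domain, sample_data = NULL,
                          taxonomy = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (!is.null(names(domain)))
    domain <- domain[rownames(counts)]
  rd <- DataFrame(domain = unname(domain), row.names = rownames(counts))
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[match(rownames(counts), rownames(taxonomy)), ,
                         drop = FALSE]
    for (nm in colnames(taxonomy)) rd[[nm]] <- taxonomy[[nm]]
  }
  if (is.null(sample_data)) {
    cd <- DataFrame(row.names = colnames(counts))
  } else {
    sample_data <- as.data.frame(sample_data)
    if ("sample_id" %in% colnames(sample_data))
      rownames(sample_data) <- sample_data$sample_id
    miss <- setdiff(colnames(counts), rownames(sample_data))
    if (length(miss))
      stop("samples without metadata: ", paste(miss, collapse = ", "))
    cd <- DataFrame(sample_data[colnames(counts), , drop = FALSE])
  }
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowData = rd, colData = cd)
  new("OtuExperiment", se)
}

#' @describeIn OtuExperiment Count matrix accessor.
#' @param x an OtuExperiment.
#' @export
otuCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn OtuExperiment Per-taxon domain labels (named character).
#' @export
taxonDomain <- function(x) {
  stats::setNames(as.character(rowData(x)$domain), rownames(x))
}

#' @describeIn OtuExperiment Sample metadata as a data.frame.
#' @export
sampleData <- function(x) as.data.frame(colData(x))

#' @export
setMethod("show", "OtuExperiment", function(object) {
  dom <- table(rowData(object)$domain)
  cat(sprintf("OtuExperiment: %d taxa (%s) x %d samples\n",
              nrow(object),
              paste(sprintf("%d %s", as.integer(dom), names(dom)),
                    collapse = ", "),
              ncol(object)))
  if ("location" %in% colnames(colData(object))) {
    loc <- table(colData(object)$location)
    cat("locations:",
        paste(sprintf("%s (n=%d)", names(loc), as.integer(loc)),
              collapse = ", "), "\n")
  }
  dp <- colSums(otuCounts(object))
  cat(sprintf("read depth: median %s [%s, %s]\n",
              format(stats::median(dp)), format(min(dp)), format(max(dp))))
})

#' Fitted Sloan neutral community model
#'
#' Holds the fitted immigration parameter and per-OTU occurrence
#' classification of a Sloan neutral-community-model fit. The model
#' predicts an OTU's occurrence frequency across local communities from
#' its mean relative abundance p in the metacommunity:
#' \deqn{\hat f(p) = 1 - I_d(Nm\,p,\; Nm\,(1-p))}
#' where \eqn{I} is the regularized incomplete beta function, \eqn{d}
#' the detection limit, and \eqn{Nm} the product of community size and
#' migration rate.
#'
#' @slot Nm numeric; fitted immigration parameter (dimensionless).
#' @slot m numeric; migration probability Nm/N (NA when N unknown).
#' @slot N numeric; community-size proxy, mean reads per sample.
#' @slot d numeric; detection limit in relative-abundance units.
#' @slot rSquared numeric; generalized R-squared (can be negative).
#' @slot nSamples integer; number of local communities entering the fit.
#' @slot ci numeric; confidence level of the classification band.
#' @slot otu DataFrame with per-OTU columns p, f_obs, f_pred, ci_lower,
#'   ci_upper, class (and domain when available).
#' @export
setClass("NcmFit",
         representation(Nm = "numeric", m = "numeric", N = "numeric",
                        d = "numeric", rSquared = "numeric",
                        nSamples = "integer", ci = "numeric",
                        otu = "DataFrame"))

setValidity("NcmFit", function(object) {
  o <- object@otu
  msg <- character()
  need <- c("p", "f_obs", "f_pred", "ci_lower", "ci_upper", "class")
  if (!all(need %in% colnames(o)))
    msg <- c(msg, paste("otu table must contain:",
                        paste(need, collapse = ", ")))
  else {
    if (any(o$f_pred < -1e-12 | o$f_pred > 1 + 1e-12))
      msg <- c(msg, "f_pred must lie in [0, 1]")
    if (any(o$ci_lower > o$f_pred + 1e-12 | o$ci_upper < o$f_pred - 1e-12))
      msg <- c(msg, "confidence band must bracket f_pred")
    if (!all(o$class %in% .NCM_CLASSES))
      msg <- c(msg, "classes must be neutral/above/below")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn NcmFit Fitted immigration parameter Nm.
#' @param fit an NcmFit.
#' @export
ncmNm <- function(fit) fit@Nm

#' @describeIn NcmFit Generalized R-squared of the fit.
#' @export
ncmRsquared <- function(fit) fit@rSquared

#' @describeIn NcmFit Per-OTU table (p, f_obs, f_pred, CI bounds, class).
#' @export
ncmOtuTable <- function(fit) as.data.frame(fit@otu)

#' @export
setMethod("show", "NcmFit", function(object) {
  cat(sprintf("Sloan neutral community model fit (%d OTUs, %d samples)\n",
              nrow(object@otu), object@nSamples))
  cat(sprintf("  Nm = %.4g (m = %.4g, N = %.4g), d = %.3g, R2 = %.4f\n",
              object@Nm, object@m, object@N, object@d, object@rSquared))
  tab <- table(factor(object@otu$class, levels = .NCM_CLASSES))
  pct <- 100 * tab / sum(tab)
  cat(sprintf("  %s\n", paste(sprintf("%s %.1f%%", names(tab), pct),
                              collapse = ", ")))
})
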