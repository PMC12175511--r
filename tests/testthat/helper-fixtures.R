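# Small in-code fixtures shared across the suite.

# A tiny labelled count table: 4 taxa (3 bacteria, 1 fungus) x 4 samples
# over 2 locations.
tinyTable <- function() {
  counts <- matrix(c(10, 5, 0, 2,
                     0, 8, 3, 0,
                     1, 0, 0, 7,
                     4, 4, 4, 4),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(c("b1", "b2", "b3", "f1"),
                                   c("s1", "s2", "s3", "s4")))
  md <- data.frame(sample_id = colnames(counts),
                   location = c("D", "D", "G", "G"),
                   plot = c(1, 1, 1, 1),
                   subsample = c("A", "B", "A", "B"))
  OtuExperiment(counts,
                domain = c(b1 = "bacteria", b2 = "bacteria",
                           b3 = "bacteria", f1 = "fungi"),
                sample_data = md)
}

# Random OtuExperiment with reproducible structure.
randomTable <- function(n_taxa = 30, n_samples = 12, n_loc = 2,
                        seed = 1, depth = 2000) {
  set.seed(seed)
  p <- simulateMetacommunity(n_taxa, list(meanlog = 0, sdlog = 1.5))
  counts <- sapply(seq_len(n_samples), function(i)
    as.integer(rmultinom(1, depth, p)))
  rownames(counts) <- sprintf("t%03d", seq_len(n_taxa))
  colnames(counts) <- sprintf("s%03d", seq_len(n_samples))
  dom <- rep(c("bacteria", "fungi"), length.out = n_taxa)
  names(dom) <- rownames(counts)
  loc <- rep(paste0("L", seq_len(n_loc)), length.out = n_samples)
  md <- data.frame(sample_id = colnames(counts), location = loc,
                   plot = rep(seq_len(ceiling(n_samples / 2)),
                              length.out = n_samples),
                   subsample = rep(c("A", "B"),
                                   length.out = n_samples))
  OtuExperiment(counts, domain = dom, sample_data = md)
}

# Exhaustive MNTD oracle: explicit double loop over community members.
bruteMntd <- function(taxa, D, weights = NULL) {
  mins <- vapply(taxa, function(i) {
    min(vapply(setdiff(taxa, i), function(j) D[i, j], numeric(1)))
  }, numeric(1))
  if (is.null(weights)) mean(mins) else
    sum(weights[taxa] * mins) / sum(weights[taxa])
}

# Brute-force set algebra for the Venn partition.
bruteVennCounts <- function(sets) {
  universe <- unique(unlist(sets))
  memb <- sapply(sets, function(s) universe %in% s)
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1)
  table(apply(memb, 1, function(z)
    paste(names(sets)[z], collapse = "&")))
}

# Tiny bipartite graph builder.
tinyGraph <- function(edges, domains) {
  makeNetwork(edges[, 1], edges[, 2], domains)
}

writeTinyDataset <- function(dir = NULL, extra_domain = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("ds")
    dir.create(dir)
  }
  x <- tinyTable()
  tp <- file.path(dir, "counts.tsv")
  mp <- file.path(dir, "meta.tsv")
  xp <- file.path(dir, "tax.tsv")
  writeOtuTable(x, tp)
  write.table(sampleData(x), mp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tax <- data.frame(taxon_id = rownames(x),
                    domain = unname(taxonDomain(x)),
                    lineage = "k__x")
  if (!is.null(extra_domain)) tax <- rbind(tax, extra_domain)
  write.table(tax, xp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(table = tp, metadata = mp, taxonomy = xp, x = x)
}
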