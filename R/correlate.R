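#' Construct a gene-family abundance table
#'
#' Per-sample relative abundances of KEGG-Orthology-style gene families
#' from metagenomic profiling. The table is consumed as given; functional
#' reconstruction is upstream of this package.
#'
#' @param g Numeric matrix, gene families in rows (row names = KO
#'   identifiers, e.g. `"K01761"`), samples in columns.
#' @param meta `data.frame` with `sample_id`, `subject_id`, `body_site`
#'   for the metagenomic samples.
#' @return Object of class `gene_table`.
#' @export
gene_table <- function(g, meta) {
  g <- as.matrix(g)
  if (any(g < 0)) stop("gene-family abundances must be non-negative")
  req <- c("sample_id", "subject_id", "body_site")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("gene metadata missing columns: ",
                         paste(miss, collapse = ", "))
  absent <- setdiff(colnames(g), meta$sample_id)
  if (length(absent)) stop("gene samples without metadata: ",
                           paste(utils::head(absent, 5), collapse = ", "))
  structure(list(g = g,
                 meta = meta[match(colnames(g), meta$sample_id), , drop = FALSE]),
            class = "gene_table")
}

#' @export
print.gene_table <- function(x, ...) {
  cat(sprintf("<gene_table> %d gene families x %d samples\n",
              nrow(x$g), ncol(x$g)))
  invisible(x)
}

#' Pair 16S and metagenomic samples by subject and body site
#'
#' Inner join per body site on the (subject, site) key. Sites with fewer
#' than `min_pairs` matched pairs are flagged (`enough` column) but still
#' returned.
#'
#' @param ab A [clade_abundance()] table.
#' @param genes A [gene_table()].
#' @param min_pairs Minimum pairs per site before the site is considered
#'   analysable (default 10).
#' @return `data.frame` with `body_site`, `subject_id`, `sample_16s`,
#'   `sample_gene`, `enough`; zero rows (with a warning) when the tables
#'   share no subject-site keys.
#' @export
pair_samples <- function(ab, genes, min_pairs = 10) {
  stopifnot(inherits(ab, "clade_abundance"), inherits(genes, "gene_table"))
  a <- ab$meta[, c("sample_id", "subject_id", "body_site")]
  names(a)[1] <- "sample_16s"
  b <- genes$meta[, c("sample_id", "subject_id", "body_site")]
  names(b)[1] <- "sample_gene"
  m <- merge(a, b, by = c("subject_id", "body_site"))
  if (!nrow(m)) {
    warning("no overlapping (subject, body_site) keys between tables")
    return(data.frame(body_site = character(), subject_id = character(),
                      sample_16s = character(), sample_gene = character(),
                      enough = logical(), stringsAsFactors = FALSE))
  }
  n_site <- table(m$body_site)
  m$enough <- as.vector(n_site[m$body_site]) >= min_pairs
  m <- m[order(m$body_site, m$subject_id), c("body_site", "subject_id",
                                             "sample_16s", "sample_gene",
                                             "enough")]
  rownames(m) <- NULL
  m
}

#' Spearman clade-gene-family correlation with BH FDR control
#'
#' For every (clade, gene family) pair within each body site with enough
#' paired samples, computes the midrank Spearman correlation and its
#' two-sided p-value, then applies Benjamini-Hochberg adjustment within
#' each body site's family of tests. Pairs where either vector is constant
#' across the site's samples are skipped (correlation undefined) and
#' counted in the `skipped` attribute.
#'
#' @param ab A [clade_abundance()] table.
#' @param genes A [gene_table()].
#' @param clades Lineage strings to test (default: all genus-level rows).
#' @param gene_families KO identifiers to test (default: all).
#' @param q_threshold Significance threshold on the adjusted q-value
#'   (default 0.05).
#' @param min_pairs Minimum paired samples per site (default 5).
#' @return `data.frame` with `body_site`, `clade`, `gene_family`, `n`,
#'   `rho`, `p`, `q`, `significant`, sorted by `q` then `|rho|`
#'   descending.
#' @export
spearman_correlate <- function(ab, genes, clades = NULL, gene_families = NULL,
                               q_threshold = 0.05, min_pairs = 5) {
  pairs <- pair_samples(ab, genes, min_pairs = min_pairs)
  if (!nrow(pairs)) return(pairs)
  if (is.null(clades))
    clades <- ab$taxonomy$lineage[ab$taxonomy$rank == "genus"]
  if (is.null(gene_families)) gene_families <- rownames(genes$g)
  res <- list()
  skipped <- 0L
  for (site in unique(pairs$body_site)) {
    ps <- pairs[pairs$body_site == site, , drop = FALSE]
    if (nrow(ps) < min_pairs) next
    A <- ab$ab[clades, ps$sample_16s, drop = FALSE]
    G <- genes$g[gene_families, ps$sample_gene, drop = FALSE]
    rows <- list()
    for (cl in clades) {
      x <- A[cl, ]
      if (length(unique(x)) == 1L) { skipped <- skipped + length(gene_families); next }
      for (k in gene_families) {
        y <- G[k, ]
        if (length(unique(y)) == 1L) { skipped <- skipped + 1L; next }
        ct <- suppressWarnings(
          stats::cor.test(x, y, method = "spearman", exact = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          body_site = site, clade = cl, gene_family = k,
          n = length(x), rho = unname(ct$estimate), p = ct$p.value,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) next
    block <- do.call(rbind, rows)
    block$q <- stats::p.adjust(block$p, method = "BH")
    res[[site]] <- block
  }
  if (!length(res)) {
    out <- data.frame(body_site = character(), clade = character(),
                      gene_family = character(), n = integer(),
                      rho = numeric(), p = numeric(), q = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, res)
  out$significant <- out$q < q_threshold
  out <- out[order(out$q, -abs(out$rho), out$clade, out$gene_family), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
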