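#' Two-cluster consensus clustering of samples by repeated NMF
#'
#' Runs `n_runs` rank-`n_clusters` NMF fits (distinct seeded initializations)
#' on a non-negative matrix restricted to the multitask-selected genes,
#' labels samples per run by the factor with the highest relative activity
#' (argmax of the row-standardized H; standardization removes the arbitrary
#' per-factor scale of the factorization), accumulates the fraction of runs
#' in which every sample pair is co-assigned, and cuts the average-linkage
#' dendrogram of `1 - consensus` at `n_clusters` for the final labels.
#'
#' @param m Non-negative gene-by-sample matrix (typically the normalized
#'   matrix restricted to the multitask gene list).
#' @param n_clusters Number of clusters (default 2).
#' @param n_runs Number of seeded NMF runs (default 20, >= 2).
#' @param seed Base seed; run r uses `seed + r - 1`.
#' @param max_iter,tol Passed to [nmf_fit()].
#' @return List with `consensus` (samples x samples, symmetric, unit
#'   diagonal), `labels` (named integer vector in `1..n_clusters`), `n_runs`.
#' @export
consensus_cluster <- function(m, n_clusters = 2L, n_runs = 20L, seed = 1L,
                              max_iter = 500L, tol = 1e-5) {
  m <- as.matrix(m)
  if (ncol(m) < 4L) stop("consensus clustering needs >= 4 samples")
  if (n_runs < 2L) stop("n_runs must be >= 2")
  if (any(m < 0)) stop("consensus clustering input must be non-negative")
  if (all(apply(m, 1L, stats::sd) == 0))
    stop("degenerate input: all samples identical")
  cons <- consensus_matrix(m, n_clusters, n_runs = n_runs, seed = seed,
                           max_iter = max_iter, tol = tol)
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  labels <- stats::cutree(hc, k = n_clusters)
  if (length(unique(labels)) < n_clusters)
    stop("degenerate clustering: fewer than ", n_clusters, " clusters found")
  list(consensus = cons, labels = labels, n_runs = n_runs)
}

#' Choose the consensus cluster that anchors the logFC sign
#'
#' The cluster whose samples have the higher mean immune eigenvalue becomes
#' the reference, so immune-associated genes come out with positive logFC in
#' the downstream differential expression.
#'
#' @param cons Result of [consensus_cluster()].
#' @param immune_eigen Named per-sample numeric vector (the immune factor's
#'   H row).
#' @return Integer: the reference cluster label.
#' @export
orient_reference <- function(cons, immune_eigen) {
  labels <- cons$labels
  if (!all(names(labels) %in% names(immune_eigen)))
    stop("labels and immune eigenvalue cover different samples")
  e <- immune_eigen[names(labels)]
  means <- tapply(e, labels, mean)
  if (length(unique(means)) < length(means))
    stop("tied cluster means: cannot orient the reference automatically")
  as.integer(names(means)[which.max(means)])
}

#' Two-group differential expression with moderated t statistics
#'
#' Per-gene two-group comparison of the reference cluster against the rest.
#' `logFC` is the difference of group means on the input (normalized) scale,
#' reference minus other. By default variances are moderated by limma's
#' empirical-Bayes shrinkage; `moderated = FALSE` gives a plain Welch t test.
#' P values are two-sided and BH-adjusted over all genes.
#'
#' @param m Numeric gene-by-sample matrix.
#' @param labels Named cluster labels covering the columns of `m`.
#' @param reference The label treated as the reference group.
#' @param moderated Use limma's moderated t (default) or Welch's t.
#' @return `data.frame` with rownames = genes and columns `logFC`, `t`, `p`,
#'   `p_adj`.
#' @export
dge <- function(m, labels, reference, moderated = TRUE) {
  m <- as.matrix(m)
  labels <- labels[colnames(m)]
  if (anyNA(labels)) stop("labels must cover every sample in m")
  grp <- factor(ifelse(labels == reference, "ref", "other"),
                levels = c("other", "ref"))
  if (min(table(grp)) < 2L) stop("each group needs >= 2 samples")
  if (moderated) {
    design <- stats::model.matrix(~grp)
    fit <- limma::eBayes(limma::lmFit(m, design))
    tt <- limma::topTable(fit, coef = "grpref", number = Inf, sort.by = "none")
    out <- data.frame(logFC = tt$logFC, t = tt$t, p = tt$P.Value,
                      p_adj = tt$adj.P.Val, row.names = rownames(m))
  } else {
    a <- m[, grp == "ref", drop = FALSE]
    b <- m[, grp == "other", drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- rowSums((a - ma)^2) / (na - 1)
    vb <- rowSums((b - mb)^2) / (nb - 1)
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    # zero within-group variance: no evidence (p = 1) unless the means differ
    # exactly, which is then infinitely strong evidence (p = 0)
    degen <- se2 == 0
    if (any(degen)) {
      tstat[degen] <- ifelse(ma[degen] == mb[degen], 0,
                             sign(ma[degen] - mb[degen]) * Inf)
      p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
    }
    out <- data.frame(logFC = ma - mb, t = tstat, p = p,
                      p_adj = bh_adjust(p), row.names = rownames(m))
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment: the i-th smallest P becomes
#' `min_{j >= i} m p_(j) / j`, capped at 1, returned in input order.
#'
#' @param p Numeric vector of raw P values in [0, 1].
#' @return Adjusted P values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Split a differential-expression result into immune and stromal signatures
#'
#' Among the multitask-selected genes, those significant at `p_thresh` with
#' positive logFC (higher in the immune-high reference cluster) form the
#' immune signature; those with negative logFC form the stromal signature.
#' Genes with logFC exactly 0 are excluded.
#'
#' @param dge_result Output of [dge()].
#' @param mtl_genes Character vector: the multitask-selected gene list.
#' @param p_thresh Significance threshold (default 0.05).
#' @param use_adjusted Threshold the BH-adjusted P (default) or the raw P.
#' @return List of class `"tme_signature"` with character vectors `immune`
#'   and `stromal` and a `provenance` data.frame (gene, logFC, p, p_adj).
#' @export
extract_signatures <- function(dge_result, mtl_genes, p_thresh = 0.05,
                               use_adjusted = TRUE) {
  missing_genes <- setdiff(mtl_genes, rownames(dge_result))
  if (length(missing_genes))
    stop("dge result does not cover gene(s): ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  d <- dge_result[mtl_genes, , drop = FALSE]
  pv <- if (use_adjusted) d$p_adj else d$p
  immune <- mtl_genes[pv < p_thresh & d$logFC > 0]
  stromal <- mtl_genes[pv < p_thresh & d$logFC < 0]
  if (length(immune) == 0L || length(stromal) == 0L)
    stop("signature extraction failed: ", length(immune), " immune and ",
         length(stromal), " stromal genes passed the threshold")
  message("signatures: ", length(immune), " immune, ", length(stromal),
          " stromal genes")
  prov <- data.frame(gene = mtl_genes, logFC = d$logFC, p = d$p,
                     p_adj = d$p_adj, stringsAsFactors = FALSE)
  structure(list(immune = immune, stromal = stromal, provenance = prov),
            class = "tme_signature")
}

#' @export
print.tme_signature <- function(x, ...) {
  cat("TME signature pair:", length(x$immune), "immune genes,",
      length(x$stromal), "stromal genes\n")
  invisible(x)
}

#' Convert a signature pair to a two-set GMT collection
#'
#' @param sig A `"tme_signature"` object.
#' @param names Set names for the GMT (immune, stromal).
#' @return Named list suitable for [write_gmt()].
#' @export
signature_to_gmt <- function(sig, names = c("TME_IMMUNE", "TME_STROMAL")) {
  stopifnot(inherits(sig, "tme_signature"), length(names) == 2L)
  imm <- sig$immune; attr(imm, "description") <- "immune-related signature"
  str <- sig$stromal; attr(str, "description") <- "stromal-related signature"
  stats::setNames(list(imm, str), names)
}
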