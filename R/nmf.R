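#' Non-negative matrix factorization by multiplicative KL updates
#'
#' Factorizes a non-negative gene-by-sample matrix V (i x j) as V ~ W H with
#' non-negative basis W (i x k) and coefficient matrix H (k x j), minimizing
#' the generalized Kullback-Leibler divergence D(V || WH) with the classical
#' multiplicative update rules. Each row of H is the per-sample activity of
#' one latent factor (the "eigenvalue" of that factor); each column of W
#' carries the gene loadings.
#'
#' Factors are initialized from seeded non-negative uniform draws scaled so
#' that the initial reconstruction matches mean(V); entries are clipped at
#' 1e-12 to avoid zero-locking in the multiplicative updates. The fit is
#' deterministic given `seed`.
#'
#' @param V Non-negative numeric matrix (genes x samples), typically the
#'   output of [normalize_expression()].
#' @param k Factorization rank, `1 <= k < min(dim(V))`.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum number of update sweeps.
#' @param tol Relative change of the KL objective below which iteration stops.
#' @return Object of class `"tme_nmf"`: list with `W`, `H`, `k`,
#'   `objective_trace` (KL divergence after every sweep, non-increasing),
#'   `seed`, `n_iter`, `converged`.
#' @export
nmf_fit <- function(V, k, seed = 1L, max_iter = 2000L, tol = 1e-6) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("NMF input must be non-negative")
  n <- nrow(V); m <- ncol(V)
  if (k < 1L || k >= min(n, m)) stop("rank k must satisfy 1 <= k < min(dim(V))")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  eps <- 1e-12
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  scale0 <- 2 * sqrt(max(mean(V), eps) / k)
  W <- matrix(stats::runif(n * k), n, k) * scale0
  H <- matrix(stats::runif(k * m), k, m) * scale0
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  vlogv <- sum(ifelse(V > 0, V * log(V), 0))
  kl <- function(WH) vlogv - sum(V * log(WH)) - sum(V) + sum(WH)

  trace <- numeric(max_iter)
  obj_prev <- Inf
  n_iter <- max_iter
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WH <- pmax(W %*% H, eps)
    # H update: H <- H * (W' (V/WH)) / colSums(W)
    H <- H * (crossprod(W, V / WH) / pmax(colSums(W), eps))
    H[H < eps] <- eps
    WH <- pmax(W %*% H, eps)
    # W update: W <- W * ((V/WH) H') / rowSums(H)
    W <- W * (tcrossprod(V / WH, H) / rep(pmax(rowSums(H), eps), each = n))
    W[W < eps] <- eps
    WH <- pmax(W %*% H, eps)
    obj <- kl(WH)
    trace[it] <- obj
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) < tol * max(abs(obj_prev), eps)) {
      n_iter <- it
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  rownames(W) <- rownames(V); colnames(H) <- colnames(V)
  colnames(W) <- rownames(H) <- paste0("factor", seq_len(k))
  structure(list(W = W, H = H, k = k,
                 objective_trace = trace[seq_len(n_iter)],
                 seed = seed, n_iter = n_iter, converged = converged),
            class = "tme_nmf")
}

#' @export
print.tme_nmf <- function(x, ...) {
  cat("NMF model: rank", x$k, "-", nrow(x$W), "genes x", ncol(x$H), "samples\n")
  cat("  KL divergence:", format(utils::tail(x$objective_trace, 1L)),
      "after", x$n_iter, "iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' Assign samples and genes to NMF clusters
#'
#' Each sample is assigned to the factor with the largest coefficient in its
#' H column; each gene to the factor with the largest loading in its W row.
#' Ties are broken toward the lowest factor index and reported.
#'
#' @param model A fitted `"tme_nmf"` object.
#' @return List with integer vectors `sample_cluster` (named by sample) and
#'   `gene_cluster` (named by gene), values in `1..k`.
#' @export
assign_clusters <- function(model) {
  stopifnot(inherits(model, "tme_nmf"))
  zero_col <- colSums(model$H) == 0
  if (any(zero_col))
    stop("all-zero H column: sample(s) ",
         paste(colnames(model$H)[zero_col], collapse = ", "), " unassignable")
  argmax_ties <- function(M, margin) {
    idx <- apply(M, margin, which.max) # which.max takes the first (lowest) index
    n_tied <- apply(M, margin, function(v) sum(v == max(v)))
    if (any(n_tied > 1L))
      warning(sum(n_tied > 1L), " argmax tie(s) broken toward the lowest cluster index")
    idx
  }
  list(sample_cluster = argmax_ties(model$H, 2L),
       gene_cluster = argmax_ties(model$W, 1L))
}

#' Top-weight genes of one NMF factor
#'
#' Genes with the largest basis weights in a factor's W column, in
#' descending weight order; ties broken by gene identifier.
#'
#' @param model A fitted `"tme_nmf"` object.
#' @param cluster Factor index in `1..k`.
#' @param n Number of genes to return (default 100).
#' @return Character vector of gene identifiers.
#' @export
top_weight_genes <- function(model, cluster, n = 100L) {
  stopifnot(inherits(model, "tme_nmf"))
  if (cluster < 1L || cluster > model$k) stop("cluster index out of range")
  w <- model$W[, cluster]
  if (n > length(w)) {
    warning("n exceeds the number of genes; truncated to ", length(w))
    n <- length(w)
  }
  ord <- order(-w, names(w))
  names(w)[ord][seq_len(n)]
}

#' Per-sample eigenvalue (H row) of one NMF factor
#'
#' @param model A fitted `"tme_nmf"` object.
#' @param cluster Factor index in `1..k`.
#' @return Named numeric vector over samples: row `cluster` of H.
#' @export
nmf_eigenvalue <- function(model, cluster) {
  stopifnot(inherits(model, "tme_nmf"))
  if (cluster < 1L || cluster > model$k) stop("cluster index out of range")
  model$H[cluster, ]
}

#' Survey candidate NMF ranks by consensus stability
#'
#' Fits NMF at each candidate rank with `n_restarts` seeded restarts, builds
#' the sample co-assignment consensus matrix per candidate, and scores each
#' candidate by the cophenetic correlation between the consensus distance
#' (1 - consensus) and its average-linkage dendrogram. Higher cophenetic
#' correlation means more stable clustering; the maximizing candidate is
#' returned (ties toward the smaller rank). A perfectly reproducible
#' consensus (all entries 0/1) scores 1.
#'
#' @param V Non-negative gene-by-sample matrix.
#' @param candidates Integer vector of candidate ranks.
#' @param seed Integer seed; restart r of candidate k uses `seed + r - 1`.
#' @param n_restarts Restarts per candidate (default 10).
#' @param max_iter,tol Passed to [nmf_fit()].
#' @return List with `k` (selected rank) and `survey` (data.frame of
#'   candidate, cophenetic).
#' @export
select_k <- function(V, candidates, seed = 1L, n_restarts = 10L,
                     max_iter = 500L, tol = 1e-5) {
  if (length(candidates) == 0L) stop("no candidate ranks supplied")
  if (length(candidates) == 1L)
    return(list(k = candidates, survey = data.frame(candidate = candidates,
                                                    cophenetic = NA_real_)))
  coph <- vapply(candidates, function(k) {
    cons <- consensus_matrix(V, k, n_runs = n_restarts, seed = seed,
                             max_iter = max_iter, tol = tol)
    d <- stats::as.dist(1 - cons)
    if (stats::sd(d) == 0) {
      # all runs fully agree (or fully disagree); perfectly stable iff binary 0/1
      return(if (all(cons %in% c(0, 1))) 1 else 0)
    }
    dc <- stats::cophenetic(stats::hclust(d, method = "average"))
    stats::cor(d, dc)
  }, numeric(1L))
  survey <- data.frame(candidate = candidates, cophenetic = coph)
  list(k = candidates[which.max(coph)], survey = survey)
}

# per-run sample labels: argmax over factors of the row-standardized H.
# NMF factor scales are arbitrary (WH is invariant under diagonal rescaling),
# so raw argmax over H rows is scale-dependent and tends to isolate only the
# extreme tail of a skewed factor; standardizing each row first assigns every
# sample to the factor with the highest *relative* activity.
nmf_sample_labels <- function(fit) {
  H <- fit$H
  sds <- apply(H, 1L, stats::sd)
  sds[sds == 0] <- 1
  apply((H - rowMeans(H)) / sds, 2L, which.max)
}

# consensus co-assignment matrix over n_runs seeded NMF fits at rank k
consensus_matrix <- function(V, k, n_runs, seed, max_iter = 500L, tol = 1e-5) {
  m <- ncol(V)
  cons <- matrix(0, m, m)
  for (r in seq_len(n_runs)) {
    fit <- nmf_fit(V, k, seed = seed + r - 1L, max_iter = max_iter, tol = tol)
    lab <- nmf_sample_labels(fit)
    cons <- cons + outer(lab, lab, `==`)
  }
  cons <- cons / n_runs
  dimnames(cons) <- list(colnames(V), colnames(V))
  cons
}
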