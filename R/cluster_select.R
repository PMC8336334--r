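#' Hypergeometric over-representation of a gene list
#'
#' Tests a query gene list against each set of a reference collection with
#' the one-sided (upper tail) hypergeometric test, i.e. the probability of
#' observing at least the given overlap when drawing `length(query)` genes
#' from the universe. Reference sets are intersected with the universe before
#' testing; P values are BH-adjusted across sets.
#'
#' @param query Character vector of gene identifiers (subset of `universe`).
#' @param refs Named list of reference gene sets (see [read_gmt()]).
#' @param universe Character vector: all genes eligible for selection.
#' @return `data.frame` with columns `set`, `set_size`, `overlap`, `p`,
#'   `p_adj`, ordered as in `refs`.
#' @export
hypergeom_enrich <- function(query, refs, universe) {
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query")
  if (length(refs) == 0L) stop("empty reference collection")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(refs), function(nm) {
    K <- length(intersect(refs[[nm]], universe))
    k <- length(intersect(refs[[nm]], query))
    p <- if (K == 0L) 1 else stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Univariate Cox proportional-hazards screen
#'
#' Fits a single-covariate Cox model (Breslow ties) of overall survival on a
#' per-sample score, as used to screen NMF factor eigenvalues for prognostic
#' relevance.
#'
#' @param x Named numeric vector of per-sample values; names must match
#'   `clinical$sample_id`.
#' @param clinical Clinical `data.frame` with `sample_id`, `os_time`,
#'   `os_event`.
#' @return List with `hr`, `p` (two-sided Wald), `beta`, `se`, `n`, `n_event`.
#' @export
cox_univariate <- function(x, clinical) {
  idx <- match(clinical$sample_id, names(x))
  if (anyNA(idx)) stop("clinical samples missing from x")
  xv <- as.numeric(x[idx])
  if (stats::sd(xv) == 0) stop("covariate is constant: Cox model not identifiable")
  if (sum(clinical$os_event) < 2) stop("fewer than 2 events: Cox model not identifiable")
  fit <- survival::coxph(
    survival::Surv(clinical$os_time, clinical$os_event) ~ xv,
    ties = "breslow")
  s <- summary(fit)
  list(hr = unname(s$coefficients[1L, "exp(coef)"]),
       p = unname(s$coefficients[1L, "Pr(>|z|)"]),
       beta = unname(s$coefficients[1L, "coef"]),
       se = unname(s$coefficients[1L, "se(coef)"]),
       n = s$n, n_event = s$nevent)
}

#' Identify the immune and stromal NMF clusters
#'
#' Annotates every NMF factor with (i) the best hypergeometric enrichment of
#' its top-weight genes against the immune and the stromal reference sets and
#' (ii) the univariate Cox fit of its per-sample eigenvalue. The immune
#' cluster is the factor with a significantly *protective* eigenvalue
#' (Wald p < alpha, HR < 1) and the smallest adjusted immune-set enrichment
#' P; the stromal cluster the factor with a significantly *adverse*
#' eigenvalue (HR > 1) and the smallest stromal-set enrichment P. Ties are
#' broken by smaller enrichment P, then lower factor index.
#'
#' @param model A fitted `"tme_nmf"` object.
#' @param immune_refs,stromal_refs Named lists of reference gene sets.
#' @param clinical Clinical table aligned to the model's samples.
#' @param alpha Cox screening threshold on the Wald P (default 0.05).
#' @param n_top Number of top-weight genes tested per factor (default 100).
#' @return List with elements `immune` and `stromal`, each a list
#'   `(cluster, enrich_p, enrich_p_adj, best_set, cox_hr, cox_p)`, plus
#'   `annotation`: the full per-factor survey table.
#' @export
identify_tme_clusters <- function(model, immune_refs, stromal_refs, clinical,
                                  alpha = 0.05, n_top = 100L) {
  stopifnot(inherits(model, "tme_nmf"))
  if (length(immune_refs) == 0L) stop("immune reference collection is empty")
  if (length(stromal_refs) == 0L) stop("stromal reference collection is empty")
  universe <- rownames(model$W)
  ann <- lapply(seq_len(model$k), function(kk) {
    top <- top_weight_genes(model, kk, n = n_top)
    ei <- hypergeom_enrich(top, immune_refs, universe)
    es <- hypergeom_enrich(top, stromal_refs, universe)
    cx <- cox_univariate(nmf_eigenvalue(model, kk), clinical)
    bi <- which.min(ei$p_adj); bs <- which.min(es$p_adj)
    data.frame(cluster = kk,
               immune_p = ei$p[bi], immune_p_adj = ei$p_adj[bi],
               immune_set = ei$set[bi],
               stromal_p = es$p[bs], stromal_p_adj = es$p_adj[bs],
               stromal_set = es$set[bs],
               cox_hr = cx$hr, cox_p = cx$p,
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, ann)

  pick <- function(role) {
    if (role == "immune") {
      ok <- ann$cox_p < alpha & ann$cox_hr < 1
      padj <- ann$immune_p_adj; praw <- ann$immune_p
    } else {
      ok <- ann$cox_p < alpha & ann$cox_hr > 1
      padj <- ann$stromal_p_adj; praw <- ann$stromal_p
    }
    if (!any(ok)) {
      near <- ann[order(padj), c("cluster", "cox_hr", "cox_p")]
      stop("no cluster qualifies as the ", role, " cluster (need Cox p < ",
           alpha, " and HR ", if (role == "immune") "< 1" else "> 1",
           "); nearest candidates (by enrichment): ",
           paste(utils::capture.output(print(utils::head(near, 3L))),
                 collapse = "\n"))
    }
    cand <- which(ok)
    cand[order(padj[cand], praw[cand], cand)][1L]
  }
  ii <- pick("immune")
  si <- pick("stromal")
  mk <- function(i, role) {
    if (role == "immune")
      list(cluster = ann$cluster[i], enrich_p = ann$immune_p[i],
           enrich_p_adj = ann$immune_p_adj[i], best_set = ann$immune_set[i],
           cox_hr = ann$cox_hr[i], cox_p = ann$cox_p[i])
    else
      list(cluster = ann$cluster[i], enrich_p = ann$stromal_p[i],
           enrich_p_adj = ann$stromal_p_adj[i], best_set = ann$stromal_set[i],
           cox_hr = ann$cox_hr[i], cox_p = ann$cox_p[i])
  }
  list(immune = mk(ii, "immune"), stromal = mk(si, "stromal"),
       annotation = ann)
}
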