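#' Train immune and stromal TME signatures
#'
#' Runs the full training pipeline on a raw expression matrix and matched
#' survival data:
#' \enumerate{
#'   \item normalize (gene-wise z-score then min-max) and align to the
#'     clinical table;
#'   \item factorize with rank-`k` NMF and identify the immune cluster
#'     (protective eigenvalue, immune-set enrichment) and the stromal cluster
#'     (adverse eigenvalue, stromal-set enrichment);
#'   \item regress the two cluster eigenvalues jointly on all genes with the
#'     L2,1-penalized multitask model and keep genes with nonzero rows;
#'   \item consensus-cluster samples (rank 2) on the selected genes, orient
#'     the immune-high cluster as reference, run moderated differential
#'     expression, and split significant genes by logFC sign into the immune
#'     (positive) and stromal (negative) signatures.
#' }
#'
#' @param expression Raw gene-by-sample numeric matrix.
#' @param clinical Clinical table (`sample_id`, `os_time`, `os_event`).
#' @param immune_refs,stromal_refs Reference gene-set collections used to
#'   recognize the immune/stromal NMF clusters.
#' @param k NMF rank (default 11).
#' @param seed Integer seed driving every random stage.
#' @param rho1 L2,1 penalty; `NULL` (default) uses `rho1_frac * rho1_max`.
#' @param rho1_frac Fraction of [rho1_max()] used when `rho1` is `NULL`.
#' @param rhoL2 Squared-Frobenius penalty of the multitask fit.
#' @param n_top Top-weight genes per factor for the enrichment screen.
#' @param cox_alpha Wald-P threshold of the eigenvalue Cox screen.
#' @param consensus_runs NMF runs for the consensus step.
#' @param p_thresh,use_adjusted Differential-expression significance rule for
#'   the final signature split.
#' @param nmf_max_iter,nmf_tol NMF stopping rule.
#' @param verbose Emit progress messages.
#' @return List with `signatures` (a `"tme_signature"`), `nmf` (the fitted
#'   model), `clusters` (immune/stromal cluster annotation), `mtl` (the
#'   multitask fit), `mtl_genes`, `consensus`, `dge`, and `config` (all
#'   resolved parameters).
#' @export
run_train <- function(expression, clinical, immune_refs, stromal_refs,
                      k = 11L, seed = 1L, rho1 = NULL, rho1_frac = 0.2,
                      rhoL2 = 10, n_top = 100L, cox_alpha = 0.05,
                      consensus_runs = 20L, p_thresh = 0.05,
                      use_adjusted = TRUE, nmf_max_iter = 2000L,
                      nmf_tol = 1e-6, verbose = TRUE) {
  say <- if (verbose) message else function(...) invisible(NULL)
  withCallingHandlers({
    say("[1/4] normalizing and aligning")
    V <- normalize_expression(expression)
    al <- align_to_clinical(V, clinical)
    V <- al$expression
    clin <- al$clinical

    say("[2/4] NMF (k = ", k, ") and cluster identification")
    model <- nmf_fit(V, k, seed = seed, max_iter = nmf_max_iter, tol = nmf_tol)
    clusters <- identify_tme_clusters(model, immune_refs, stromal_refs, clin,
                                      alpha = cox_alpha, n_top = n_top)
    Y <- rbind(immune = nmf_eigenvalue(model, clusters$immune$cluster),
               stromal = nmf_eigenvalue(model, clusters$stromal$cluster))

    say("[3/4] L2,1 multitask gene selection")
    if (is.null(rho1)) rho1 <- rho1_frac * rho1_max(V, Y)
    mtl <- fit_mtl(V, Y, rho1 = rho1, rhoL2 = rhoL2)
    mtl_genes <- selected_genes(mtl)
    say("  ", length(mtl_genes), " genes with nonzero coefficient rows")
    if (length(mtl_genes) < 4L)
      stop("multitask selection kept fewer than 4 genes; lower rho1")

    say("[4/4] consensus clustering and differential expression")
    cons <- consensus_cluster(V[mtl_genes, , drop = FALSE], n_clusters = 2L,
                              n_runs = consensus_runs, seed = seed)
    ref <- orient_reference(cons, Y["immune", ])
    d <- dge(V, cons$labels, reference = ref)
    sig <- extract_signatures(d, mtl_genes, p_thresh = p_thresh,
                              use_adjusted = use_adjusted)
    config <- list(k = k, seed = seed, rho1 = rho1, rhoL2 = rhoL2,
                   n_top = n_top, cox_alpha = cox_alpha,
                   consensus_runs = consensus_runs, p_thresh = p_thresh,
                   use_adjusted = use_adjusted, nmf_max_iter = nmf_max_iter,
                   nmf_tol = nmf_tol)
    list(signatures = sig, nmf = model, clusters = clusters, mtl = mtl,
         mtl_genes = mtl_genes, consensus = cons, dge = d, config = config)
  }, message = function(m) {
    if (!verbose) invokeRestart("muffleMessage")
  })
}

#' Score a cohort against trained signatures
#'
#' Applies the scoring half of the pipeline: per-sample immune and stromal
#' ssGSEA scores, cohort min-max normalization, and four-class TME subtype
#' assignment. Works on any cohort — no clinical data or training required —
#' so a published signature pair supplied as a GMT can be used directly.
#'
#' @param expression Gene-by-sample numeric matrix (any monotone-equivalent
#'   scale; ssGSEA is rank-based).
#' @param signatures A `"tme_signature"` object, or a named list with
#'   `immune` and `stromal` gene vectors (e.g. a two-set GMT collection after
#'   `list(immune = gmt[[1]], stromal = gmt[[2]])`).
#' @param alpha ssGSEA rank-weight exponent.
#' @param min_genes Per-signature coverage floor.
#' @return List with `scores` (see [tme_scores()]) and `subtypes` (see
#'   [assign_subtypes()]).
#' @export
run_score <- function(expression, signatures, alpha = 0.25, min_genes = 10L) {
  scores <- tme_scores(expression, signatures, alpha = alpha,
                       min_genes = min_genes)
  subtypes <- assign_subtypes(scores)
  list(scores = scores, subtypes = subtypes)
}
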