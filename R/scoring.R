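#' Single-sample gene set enrichment (ssGSEA) scores
#'
#' For every sample, genes are ranked by decreasing expression (ties get the
#' average rank) and the enrichment score of the gene set is the integrated
#' difference between the weighted cumulative distribution of set genes
#' ("hits", weighted by the rank statistic raised to `alpha` and normalized
#' over hits) and the uniform cumulative distribution of non-set genes. The
#' rank statistic of a gene is `n_genes - rank + 1`, so the most expressed
#' gene carries the largest weight. Because the score depends on ranks only,
#' it is insensitive to monotone transformations of a sample's expression,
#' hence robust to platform differences.
#'
#' Set genes absent from the matrix are dropped with a message.
#'
#' @param m Numeric gene-by-sample matrix on any scale.
#' @param set Character vector of gene identifiers (>= 1 present in `m`).
#' @param alpha Non-negative rank-weight exponent (default 0.25).
#' @return Named numeric vector of per-sample enrichment scores.
#' @export
ssgsea_score <- function(m, set, alpha = 0.25) {
  m <- as.matrix(m)
  if (alpha < 0) stop("alpha must be non-negative")
  set <- unique(set)
  present <- intersect(set, rownames(m))
  if (length(present) == 0L) stop("no gene of the set is present in the matrix")
  if (length(present) < length(set))
    message(length(set) - length(present), " set gene(s) absent from the matrix dropped")
  n <- nrow(m)
  if (length(present) == n) stop("gene set covers the whole matrix: no miss genes")
  hit <- rownames(m) %in% present
  vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    pos <- rank(-x, ties.method = "average")   # 1 = most expressed
    stat <- (n - pos + 1)^alpha
    ord <- order(pos, rownames(m))             # deterministic walk down the list
    h <- hit[ord]
    w <- stat[ord]
    cum_hit <- cumsum(ifelse(h, w, 0)) / sum(w[h])
    cum_miss <- cumsum(!h) / (n - length(present))
    sum(cum_hit - cum_miss)
  }, numeric(1L), USE.NAMES = FALSE) -> es
  stats::setNames(es, colnames(m))
}

#' Min-max normalize a score vector across a cohort
#'
#' @param raw Numeric vector of raw enrichment scores (>= 2 values,
#'   non-constant).
#' @return Vector rescaled linearly onto [0, 1], names preserved.
#' @export
normalize_scores <- function(raw) {
  if (length(raw) < 2L) stop("need >= 2 samples to normalize scores")
  rng <- range(raw)
  if (rng[1L] == rng[2L]) stop("constant raw scores cannot be normalized")
  (raw - rng[1L]) / (rng[2L] - rng[1L])
}

#' Per-sample immune and stromal TME scores
#'
#' Scores every sample of an expression matrix against an immune/stromal
#' signature pair by [ssgsea_score()] and min-max normalizes each score
#' across the cohort. Errors if fewer than `min_genes` genes of either
#' signature are present; warns below 50% coverage.
#'
#' @param m Numeric gene-by-sample matrix (any monotone-equivalent scale).
#' @param sig A `"tme_signature"` object, or a named list with character
#'   vectors `immune` and `stromal` (e.g. from [read_gmt()] after renaming).
#' @param alpha ssGSEA rank-weight exponent (default 0.25).
#' @param min_genes Minimum signature genes that must be present (default 10).
#' @return `data.frame` with columns `sample_id`, `immune_raw`, `stromal_raw`,
#'   `immune_norm`, `stromal_norm`; attribute `genes_used` records per-
#'   signature coverage.
#' @export
tme_scores <- function(m, sig, alpha = 0.25, min_genes = 10L) {
  m <- as.matrix(m)
  if (is.null(sig$immune) || is.null(sig$stromal))
    stop("sig must provide 'immune' and 'stromal' gene lists")
  used <- lapply(sig[c("immune", "stromal")], function(g) {
    pres <- intersect(unique(g), rownames(m))
    if (length(pres) < min_genes)
      stop("signature coverage below floor (", length(pres), " < ", min_genes,
           "); missing: ", paste(utils::head(setdiff(g, pres), 10L), collapse = ", "))
    if (length(pres) < 0.5 * length(unique(g)))
      warning("less than 50% of the signature genes are present in the matrix")
    pres
  })
  immune_raw <- ssgsea_score(m, used$immune, alpha = alpha)
  stromal_raw <- ssgsea_score(m, used$stromal, alpha = alpha)
  out <- data.frame(sample_id = colnames(m),
                    immune_raw = unname(immune_raw),
                    stromal_raw = unname(stromal_raw),
                    immune_norm = unname(normalize_scores(immune_raw)),
                    stromal_norm = unname(normalize_scores(stromal_raw)),
                    stringsAsFactors = FALSE)
  attr(out, "genes_used") <- vapply(used, length, integer(1L))
  out
}

#' Classify samples into the four TME subtypes
#'
#' Splits the cohort at the median of the normalized immune and stromal
#' scores. A sample is immune-high when its immune score is strictly above
#' the cohort median (values equal to the median count as low), and likewise
#' for stromal. Labels combine the two axes: first letter immune, second
#' stromal — HH, HL, LH, LL.
#'
#' @param scores Output of [tme_scores()] (>= 4 samples).
#' @return `data.frame` with `sample_id`, `subtype`; attributes
#'   `immune_median` and `stromal_median` record the thresholds used.
#' @export
assign_subtypes <- function(scores) {
  if (nrow(scores) < 4L) stop("subtype assignment needs >= 4 samples")
  im <- stats::median(scores$immune_norm)
  sm <- stats::median(scores$stromal_norm)
  lab <- paste0(ifelse(scores$immune_norm > im, "H", "L"),
                ifelse(scores$stromal_norm > sm, "H", "L"))
  out <- data.frame(sample_id = scores$sample_id, subtype = lab,
                    stringsAsFactors = FALSE)
  attr(out, "immune_median") <- im
  attr(out, "stromal_median") <- sm
  out
}

#' Per-sample marker expression ratio
#'
#' Ratio of the summed expression of a numerator gene panel over a
#' denominator panel, per sample, on a linear non-negative expression scale.
#' Samples whose denominator sum is 0 get `NA` with a warning.
#'
#' Presets: `marker_panels$exhaustion` is the T-cell
#' co-inhibitory/co-stimulatory ratio (PD-1 + CTLA4 + LAG3 + TIM-3) /
#' (CD28 + CD40LG) with PD-1 mapped to PDCD1 and TIM-3 to HAVCR2;
#' `marker_panels$angiopoietin` is ANGPT1 / ANGPT2.
#'
#' @param m Numeric gene-by-sample matrix on a linear non-negative scale.
#' @param numerator,denominator Character vectors of gene identifiers; all
#'   must be present in `m`.
#' @return Named numeric vector of per-sample ratios.
#' @export
marker_ratio <- function(m, numerator, denominator) {
  m <- as.matrix(m)
  missing_genes <- setdiff(c(numerator, denominator), rownames(m))
  if (length(missing_genes))
    stop("marker gene(s) missing from the matrix: ",
         paste(missing_genes, collapse = ", "))
  num <- colSums(m[numerator, , drop = FALSE])
  den <- colSums(m[denominator, , drop = FALSE])
  undef <- den == 0
  if (any(undef)) {
    warning(sum(undef), " sample(s) with zero denominator flagged as NA")
    den[undef] <- NA_real_
  }
  num / den
}

#' Bundled marker panels for [marker_ratio()]
#'
#' T-cell exhaustion ratio panels (checkpoint receptors over co-stimulatory
#' molecules; PD-1 = PDCD1, TIM-3 = HAVCR2) and the angiopoietin ratio.
#'
#' @format Named list of lists with `numerator` and `denominator` character
#'   vectors.
#' @export
marker_panels <- list(
  exhaustion = list(numerator = c("PDCD1", "CTLA4", "LAG3", "HAVCR2"),
                    denominator = c("CD28", "CD40LG")),
  angiopoietin = list(numerator = "ANGPT1", denominator = "ANGPT2")
)
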