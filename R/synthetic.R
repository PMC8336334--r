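#' Default synthetic-cohort parameters
#'
#' The generator plants a latent-factor expression structure mirroring what
#' the training pipeline assumes: disjoint immune and stromal gene modules
#' driven by per-sample latent activities, extra noise factors standing in
#' for other transcriptional programs, Gaussian measurement noise, and
#' exponential survival whose log-hazard decreases with the immune activity
#' (protective) and increases with the stromal activity (adverse).
#'
#' @param n_genes,n_samples Matrix dimensions (2000 x 200).
#' @param n_immune_genes,n_stromal_genes Planted module sizes (60, 40).
#' @param n_noise_factors Additional latent factors (4), each loading on its
#'   own `noise_module_size`-gene module.
#' @param noise_module_size Genes per noise factor (50).
#' @param loading_strength Module loading on its activity (1.0).
#' @param noise_sd Gaussian measurement noise SD (0.5).
#' @param activity_cor Correlation of the immune and stromal latent
#'   log-activities (-0.7). Bulk cohorts show a polarized immune-inflamed
#'   versus stromal/fibrotic axis, and the sign-split refinement step relies
#'   on the two programs moving in opposite directions across the two-cluster
#'   consensus split, so the generator plants that anti-correlation by
#'   default; with weakly opposed programs the smaller module is
#'   under-recovered by design of the method.
#' @param beta_immune Log-hazard per SD of immune activity (-0.8, protective).
#' @param beta_stromal Log-hazard per SD of stromal activity (+0.8, adverse).
#' @param censor_rate Expected fraction of censored samples (0.3).
#' @param base_hazard Baseline exponential hazard (log(2)/10: median 10 time
#'   units at covariates 0).
#' @param seed Integer seed.
#' @return Named list of parameters for [simulate_tme()].
#' @export
sim_params <- function(n_genes = 2000L, n_samples = 200L,
                       n_immune_genes = 60L, n_stromal_genes = 40L,
                       n_noise_factors = 4L, noise_module_size = 50L,
                       loading_strength = 1.0, noise_sd = 0.5,
                       activity_cor = -0.7,
                       beta_immune = -0.8, beta_stromal = 0.8,
                       censor_rate = 0.3, base_hazard = log(2) / 10,
                       seed = 1L) {
  p <- list(n_genes = n_genes, n_samples = n_samples,
            n_immune_genes = n_immune_genes, n_stromal_genes = n_stromal_genes,
            n_noise_factors = n_noise_factors,
            noise_module_size = noise_module_size,
            loading_strength = loading_strength, noise_sd = noise_sd,
            activity_cor = activity_cor,
            beta_immune = beta_immune, beta_stromal = beta_stromal,
            censor_rate = censor_rate, base_hazard = base_hazard, seed = seed)
  n_structured <- n_immune_genes + n_stromal_genes +
    n_noise_factors * noise_module_size
  if (n_structured >= n_genes)
    stop("module genes must number fewer than n_genes")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (loading_strength <= 0 || noise_sd <= 0)
    stop("loading_strength and noise_sd must be positive")
  if (abs(activity_cor) >= 1) stop("activity_cor must be in (-1, 1)")
  if (beta_immune > 0) stop("beta_immune must be <= 0 (protective)")
  if (beta_stromal < 0) stop("beta_stromal must be >= 0 (adverse)")
  p
}

#' Simulate a synthetic cohort with planted TME structure
#'
#' Latent activities are drawn log-normal(0, 1) per factor and sample.
#' Expression is the sum over factors of
#' `loading_strength * activity * membership` plus Gaussian noise, globally
#' shifted to be non-negative (a shift, not truncation, so module-activity
#' correlations are preserved exactly). Survival times are exponential with
#' hazard `base_hazard * exp(beta_immune * z(immune) + beta_stromal *
#' z(stromal))`; censored samples (Bernoulli `censor_rate`) get an
#' independent uniform time on (0, T). Fully reproducible per seed.
#'
#' @param params List from [sim_params()].
#' @return List with `expression` (gene x sample matrix, raw scale),
#'   `clinical` (`sample_id`, `os_time`, `os_event`) and `truth` (module gene
#'   lists, latent activities, log-hazard betas).
#' @export
simulate_tme <- function(params = sim_params()) {
  p <- params
  set.seed(p$seed)
  genes <- sprintf("g%04d", seq_len(p$n_genes))
  samples <- sprintf("s%03d", seq_len(p$n_samples))
  n_fac <- 2L + p$n_noise_factors

  # disjoint gene modules: immune first, stromal next, then noise modules
  immune_genes <- genes[seq_len(p$n_immune_genes)]
  stromal_genes <- genes[p$n_immune_genes + seq_len(p$n_stromal_genes)]
  offset <- p$n_immune_genes + p$n_stromal_genes
  membership <- matrix(0, p$n_genes, n_fac,
                       dimnames = list(genes, NULL))
  membership[immune_genes, 1L] <- 1
  membership[stromal_genes, 2L] <- 1
  for (f in seq_len(p$n_noise_factors)) {
    idx <- offset + (f - 1L) * p$noise_module_size + seq_len(p$noise_module_size)
    membership[idx, 2L + f] <- 1
  }

  # log-normal(0,1) activities; immune and stromal log-activities correlated
  # at activity_cor (Gaussian copula), noise factors independent
  z <- matrix(stats::rnorm(n_fac * p$n_samples), n_fac, p$n_samples)
  z[2L, ] <- p$activity_cor * z[1L, ] +
    sqrt(1 - p$activity_cor^2) * z[2L, ]
  activity <- exp(z)
  colnames(activity) <- samples
  expr <- p$loading_strength * (membership %*% activity) +
    matrix(stats::rnorm(p$n_genes * p$n_samples, 0, p$noise_sd),
           p$n_genes, p$n_samples)
  expr <- expr - min(expr)
  dimnames(expr) <- list(genes, samples)

  zs <- function(v) (v - mean(v)) / stats::sd(v)
  lp <- p$beta_immune * zs(activity[1L, ]) + p$beta_stromal * zs(activity[2L, ])
  hazard <- p$base_hazard * exp(lp)
  t_event <- stats::rexp(p$n_samples, rate = hazard)
  censored <- stats::runif(p$n_samples) < p$censor_rate
  os_time <- ifelse(censored, stats::runif(p$n_samples) * t_event, t_event)
  clinical <- data.frame(sample_id = samples,
                         os_time = os_time,
                         os_event = as.integer(!censored),
                         stringsAsFactors = FALSE)
  truth <- list(immune_genes = immune_genes, stromal_genes = stromal_genes,
                immune_activity = stats::setNames(activity[1L, ], samples),
                stromal_activity = stats::setNames(activity[2L, ], samples),
                beta_immune = p$beta_immune, beta_stromal = p$beta_stromal)
  attr(expr, "value_scale") <- "raw"
  list(expression = expr, clinical = clinical, truth = truth)
}

#' Reference gene sets derived from the planted modules
#'
#' Builds immune and stromal reference sets from the simulation ground truth,
#' optionally replacing a fraction of module genes with random non-module
#' genes to emulate imperfect marker lists. The two sets stay disjoint.
#'
#' @param truth `truth` element of [simulate_tme()] output.
#' @param all_genes Character vector of all gene identifiers in the matrix.
#' @param contamination Fraction of each set replaced by random non-module
#'   genes (in [0, 0.5)).
#' @param seed Seed for the contamination draw.
#' @return Named list with gene sets `IMMUNE_REF` and `STROMAL_REF`.
#' @export
make_reference_sets <- function(truth, all_genes, contamination = 0,
                                seed = 1L) {
  if (contamination < 0 || contamination >= 0.5)
    stop("contamination must be in [0, 0.5)")
  pool <- setdiff(all_genes, c(truth$immune_genes, truth$stromal_genes))
  set.seed(seed)
  contaminate <- function(genes) {
    n_swap <- floor(contamination * length(genes))
    if (n_swap == 0L) return(genes)
    swapped <- sample(pool, n_swap)
    pool <<- setdiff(pool, swapped)
    c(sample(genes, length(genes) - n_swap), swapped)
  }
  imm <- contaminate(truth$immune_genes)
  str <- contaminate(truth$stromal_genes)
  attr(imm, "description") <- "synthetic immune reference set"
  attr(str, "description") <- "synthetic stromal reference set"
  list(IMMUNE_REF = imm, STROMAL_REF = str)
}
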