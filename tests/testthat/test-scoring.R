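test_that("ssGSEA reproduces hand-computed toy scores at alpha = 0", {
  # 4 genes, one sample, expression strictly decreasing g1 > g2 > g3 > g4
  m <- matrix(c(4, 3, 2, 1), 4, 1,
              dimnames = list(paste0("g", 1:4), "s1"))
  # set = top gene: running sum 1 + 2/3 + 1/3 + 0 = 2
  expect_equal(unname(ssgsea_score(m, "g1", alpha = 0)), 2)
  # set = bottom gene: -1/3 - 2/3 - 1 + 0 = -2
  expect_equal(unname(ssgsea_score(m, "g4", alpha = 0)), -2)
})

test_that("ssGSEA is invariant to strictly increasing transforms", {
  m <- rand_expr(50, 6, seed = 31)
  set <- rownames(m)[c(3, 10, 25, 40)]
  s1 <- ssgsea_score(m, set)
  m2 <- m
  m2[, 2] <- exp(m2[, 2])         # monotone transform of one sample
  m2[, 5] <- m2[, 5]^3 + 10
  s2 <- ssgsea_score(m2, set)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("ssGSEA matches a brute-force position-walk oracle", {
  brute <- function(m, set, alpha) {
    n <- nrow(m)
    sapply(seq_len(ncol(m)), function(j) {
      pos <- rank(-m[, j], ties.method = "average")
      ord <- order(pos, rownames(m))
      genes <- rownames(m)[ord]
      stat <- (n - pos[ord] + 1)^alpha
      nh <- sum(genes %in% set)
      denom_hit <- sum(stat[genes %in% set])
      cum_h <- 0; cum_m <- 0; es <- 0
      for (i in seq_len(n)) {
        if (genes[i] %in% set) cum_h <- cum_h + stat[i] / denom_hit
        else cum_m <- cum_m + 1 / (n - nh)
        es <- es + (cum_h - cum_m)
      }
      unname(es)
    })
  }
  set.seed(32)
  for (i in 1:15) {
    n <- sample(10:60, 1)
    m <- rand_expr(n, sample(2:5, 1), seed = 100 + i)
    if (i %% 3 == 0) m[sample(length(m), 5)] <- m[1, 1] # inject ties
    set <- sample(rownames(m), sample(2:min(8, n - 2), 1))
    alpha <- sample(c(0, 0.25, 1), 1)
    expect_equal(unname(ssgsea_score(m, set, alpha)), brute(m, set, alpha),
                 tolerance = 1e-10)
  }
})

test_that("ssGSEA scores are invariant to row and column reordering", {
  m <- rand_expr(30, 5, seed = 33)
  set <- rownames(m)[c(2, 7, 19)]
  s <- ssgsea_score(m, set)
  set.seed(34)
  m2 <- m[sample(nrow(m)), sample(ncol(m))]
  s2 <- ssgsea_score(m2, set)
  expect_equal(s2[names(s)], s, tolerance = 1e-12)
})

test_that("ssGSEA input contracts", {
  m <- rand_expr(10, 3, seed = 35)
  expect_error(ssgsea_score(m, c("nope1", "nope2")), "no gene")
  expect_error(ssgsea_score(m, rownames(m)[1], alpha = -1), "alpha")
  expect_message(ssgsea_score(m, c(rownames(m)[1], "absent")), "absent")
})

test_that("score normalization is an exact min-max", {
  expect_equal(normalize_scores(c(2, 4, 6)), c(0, 0.5, 1))
  r <- rnorm(20)
  n <- normalize_scores(r)
  expect_equal(min(n), 0)
  expect_equal(max(n), 1)
  expect_equal(cor(r, n, method = "spearman"), 1)
  expect_error(normalize_scores(rep(1, 5)), "constant")
  expect_error(normalize_scores(3), ">= 2")
})

test_that("cohort scoring is deterministic and tracks planted activities", {
  sim <- small_sim(seed = 3)
  sig <- list(immune = sim$truth$immune_genes, stromal = sim$truth$stromal_genes)
  sc1 <- tme_scores(sim$expression, sig)
  sc2 <- tme_scores(sim$expression, sig)
  expect_identical(sc1, sc2)
  expect_true(all(sc1$immune_norm >= 0 & sc1$immune_norm <= 1))
  expect_gte(cor(sc1$immune_norm, sim$truth$immune_activity,
                 method = "spearman"), 0.8)
  expect_gte(cor(sc1$stromal_norm, sim$truth$stromal_activity,
                 method = "spearman"), 0.8)
  expect_equal(unname(attr(sc1, "genes_used")),
               c(length(sig$immune), length(sig$stromal)))
})

test_that("scores are robust to losing 10% of the signature genes", {
  sim <- small_sim(seed = 4)
  sig <- list(immune = sim$truth$immune_genes, stromal = sim$truth$stromal_genes)
  sc_full <- tme_scores(sim$expression, sig)
  set.seed(41)
  drop <- c(sample(sig$immune, 3), sample(sig$stromal, 2))
  m2 <- sim$expression[setdiff(rownames(sim$expression), drop), ]
  sc_part <- suppressWarnings(tme_scores(m2, sig))
  expect_lt(max(abs(sc_full$immune_norm - sc_part$immune_norm)), 0.1)
  expect_lt(max(abs(sc_full$stromal_norm - sc_part$stromal_norm)), 0.1)
})

test_that("coverage floor is enforced", {
  m <- rand_expr(30, 5, seed = 36)
  expect_error(tme_scores(m, list(immune = rownames(m)[1:3],
                                  stromal = rownames(m)[4:20])),
               "coverage below floor")
})

test_that("subtype assignment follows the median-split rule", {
  sc <- data.frame(sample_id = paste0("s", 1:4),
                   immune_raw = 1:4, stromal_raw = 4:1,
                   immune_norm = c(1, 2, 3, 4), stromal_norm = c(4, 3, 2, 1))
  st <- assign_subtypes(sc)
  expect_identical(st$subtype, c("LH", "LH", "HL", "HL"))
  expect_equal(attr(st, "immune_median"), 2.5)

  # a value exactly at the median goes to the low side
  sc2 <- data.frame(sample_id = paste0("s", 1:5),
                    immune_raw = 1:5, stromal_raw = 1:5,
                    immune_norm = c(1, 2, 3, 4, 5), stromal_norm = c(5, 4, 3, 2, 1))
  st2 <- assign_subtypes(sc2)
  expect_identical(st2$subtype[3], "LL") # both scores equal their median

  expect_error(assign_subtypes(sc[1:3, ]), ">= 4")
})

test_that("all four subtypes appear for independent score permutations", {
  sc <- data.frame(sample_id = paste0("s", 1:4),
                   immune_raw = 0, stromal_raw = 0,
                   immune_norm = c(1, 2, 3, 4), stromal_norm = c(3, 1, 4, 2))
  st <- assign_subtypes(sc)
  expect_setequal(st$subtype, c("LH", "LL", "HH", "HL"))
})

test_that("subtype marginals are balanced for distinct scores and even n", {
  set.seed(42)
  n <- 30
  sc <- data.frame(sample_id = paste0("s", 1:n),
                   immune_raw = 0, stromal_raw = 0,
                   immune_norm = sample(seq_len(n)) / n,
                   stromal_norm = sample(seq_len(n)) / n)
  st <- assign_subtypes(sc)
  expect_equal(sum(substr(st$subtype, 1, 1) == "H"), n / 2)
  expect_equal(sum(substr(st$subtype, 2, 2) == "H"), n / 2)
})

test_that("marker ratios follow the panel arithmetic", {
  genes <- c(marker_panels$exhaustion$numerator,
             marker_panels$exhaustion$denominator, "OTHER")
  m <- matrix(1, length(genes), 3, dimnames = list(genes, paste0("s", 1:3)))
  r <- marker_ratio(m, marker_panels$exhaustion$numerator,
                    marker_panels$exhaustion$denominator)
  expect_equal(unname(r), rep(2, 3)) # 4 genes over 2 genes, all at 1

  # scale invariance
  r2 <- marker_ratio(2 * m, marker_panels$exhaustion$numerator,
                     marker_panels$exhaustion$denominator)
  expect_equal(r, r2)

  # zero denominator flagged as NA
  m2 <- m
  m2[marker_panels$exhaustion$denominator, 2] <- 0
  expect_warning(r3 <- marker_ratio(m2, marker_panels$exhaustion$numerator,
                                    marker_panels$exhaustion$denominator),
                 "zero denominator")
  expect_true(is.na(r3[2]) && !is.na(r3[1]))

  expect_error(marker_ratio(m[-1, ], marker_panels$exhaustion$numerator,
                            marker_panels$exhaustion$denominator), "missing")
})
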