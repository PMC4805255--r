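as_epi <- function(m, groups, types = rep("m", ncol(m)), scheme = "MIXED2") {
  colnames(m) <- colnames(m) %||% sprintf("E%03d", seq_len(ncol(m)))
  meta <- data.frame(epilocus = colnames(m), locus = colnames(m), type = types,
                     stringsAsFactors = FALSE)
  epimark:::new_epilocus_matrix(m, meta, scheme, groups)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("polymorphism is both-alleles-present within a group", {
  m <- cbind(rep(1L, 6),                # monomorphic presence
             c(1L, 1L, 1L, 0L, 0L, 0L), # polymorphic
             rep(0L, 6),                # monomorphic absence
             c(1L, NA, NA, NA, NA, 1L)) # non-missing all 1 -> monomorphic
  e <- as_epi(m, rep("A", 6))
  s <- polymorphism_summary(e)
  expect_identical(s$n_polymorphic, 1L)
  expect_equal(s$pct_polymorphic, 25)
  # 150 markers, 109 polymorphic -> 72.7% at report precision
  m2 <- cbind(matrix(rep(c(0L, 1L), each = 3), 6, 109),
              matrix(1L, 6, 41))
  s2 <- polymorphism_summary(as_epi(m2, rep("A", 6)))
  expect_identical(s2$n_markers, 150L)
  expect_equal(round(s2$pct_polymorphic, 1), 72.7)
})

test_that("private markers require presence in exactly one group", {
  g <- rep(c("A", "B", "C"), each = 2)
  m <- cbind(c(1L, 1L, 1L, 1L, 1L, 1L),   # everywhere
             c(1L, 0L, 0L, 0L, 0L, 0L),   # private to A (one carrier)
             c(1L, 1L, 0L, 0L, 1L, 0L),   # A and C
             c(0L, 0L, 1L, 1L, 0L, 0L))   # private to B (two carriers)
  p <- private_markers(as_epi(m, g), per = "group")
  expect_identical(p$n_private[p$group == "A"], 1L)
  expect_identical(p$n_private[p$group == "B"], 1L)
  expect_identical(p$n_private[p$group == "C"], 0L)
  expect_equal(p$pct_private[p$group == "A"], 25)
  # per-individual reading: only single-carrier markers count
  pi <- private_markers(as_epi(m, g), per = "individual")
  expect_identical(pi$n_private[pi$group == "A"], 1L)
  expect_identical(pi$n_private[pi$group == "B"], 0L)
  expect_error(private_markers(as_epi(m, rep("A", 6))), "2 groups")
})

test_that("Shannon index has its closed-form values and peaks at p = 0.5", {
  m <- cbind(rep(1L, 4), rep(0L, 4), c(1L, 1L, 0L, 0L))
  s <- shannon_mean(as_epi(m, rep("A", 4)))
  expect_equal(s$shannon, mean(c(0, 0, -2 * 0.5 * log(0.5))))
  # all markers at p = 0.5 -> mean is the maximum log(2)
  m2 <- matrix(rep(c(1L, 0L), each = 2), 4, 10)
  expect_equal(shannon_mean(as_epi(m2, rep("A", 4)))$shannon, log(2),
               tolerance = 1e-12)
  # entropy over a grid of presence frequencies is maximised at 0.5
  p_grid <- seq(0.1, 0.9, by = 0.1)
  vals <- vapply(p_grid, function(p) {
    mm <- matrix(c(rep(1L, round(20 * p)), rep(0L, 20 - round(20 * p))), 20, 1)
    shannon_mean(as_epi(mm, rep("A", 20)))$shannon
  }, numeric(1))
  expect_identical(p_grid[which.max(vals)], 0.5)
})

test_that("squared-distance matrix scales missing pairs pairwise-complete", {
  m <- rbind(c(1, 0, NA, 1), c(0, 0, 1, NA))
  d <- marker_sqdist(m)
  # complete markers {1,2}: raw distance 1, rescaled by 4/2
  expect_equal(d[1, 2], 2)
  full <- rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  expect_equal(marker_sqdist(full)[1, 2], 2)
  expect_equal(diag(marker_sqdist(full)), setNames(rep(0, 3), NULL),
               ignore_attr = TRUE)
})

test_that("AMOVA Phi matches the brute-force estimator and enumeration p", {
  set.seed(55)
  x <- matrix(rbinom(24, 1, 0.5), 6, 4)
  g <- rep(c("A", "B"), each = 3)
  res <- amova_phi(as_epi(x, g), n_permutations = 10000, seed = 99)
  expect_equal(res$phi, brute_phi(x, g), tolerance = 1e-12)
  enum <- brute_phi_enumeration(x, g)
  p_exact <- mean(enum >= res$phi - 1e-12)  # ties count as exceedances
  expect_lt(abs(res$p_value - p_exact), 0.02)
  expect_gte(res$p_value, 1 / (res$n_permutations + 1))
  expect_lte(res$p_value, 1)
})

test_that("fixed between-group difference with no within variance gives Phi = 1", {
  x <- rbind(matrix(0L, 4, 6), matrix(1L, 4, 6))
  res <- amova_phi(as_epi(x, rep(c("A", "B"), each = 4)),
                   n_permutations = 200, seed = 1)
  expect_equal(res$phi, 1)
  expect_equal(unname(res$ss[["within"]]), 0)
})

test_that("null data can give negative Phi estimates, never clipped", {
  set.seed(4)
  phis <- replicate(30, {
    x <- matrix(rbinom(80, 1, 0.5), 8, 10)
    amova_phi(as_epi(x, rep(c("A", "B"), each = 4)),
              n_permutations = 2, seed = 1)$phi
  })
  expect_true(any(phis < 0))
  expect_lt(abs(mean(phis)), 0.15)  # centred near zero under the null
})

test_that("Phi is invariant to marker order and within-group row order", {
  set.seed(31)
  x <- matrix(rbinom(60, 1, c(0.2, 0.7)), 10, 6)
  g <- rep(c("A", "B"), each = 5)
  base <- amova_phi(as_epi(x, g), n_permutations = 10, seed = 2)$phi
  perm_cols <- x[, sample(ncol(x))]
  expect_equal(amova_phi(as_epi(perm_cols, g), n_permutations = 10,
                         seed = 2)$phi, base)
  perm_rows <- x[c(sample(1:5), sample(6:10)), ]
  expect_equal(amova_phi(as_epi(perm_rows, g), n_permutations = 10,
                         seed = 2)$phi, base)
})

test_that("degenerate AMOVA inputs are rejected", {
  x <- matrix(rbinom(30, 1, 0.5), 6, 5)
  expect_error(amova_phi(as_epi(x, c("A", rep("B", 5)))), "at least 2")
  expect_error(amova_phi(as_epi(matrix(1L, 6, 5), rep(c("A", "B"), 3))),
               "zero total variance")
  expect_error(amova_phi(as_epi(x, rep("A", 6))), "2 groups")
})

test_that("pairwise differentiation covers all pairs and renders Table-style", {
  sim <- simulate_msap(c(A = 5, B = 5, C = 5, D = 5), 30,
                       c(0.3, 0.4, 0.1, 0.2), 0, seed = 23)
  st <- combine_digests(sim$mspI, sim$hpaII)
  m <- mixed_scoring2(st)
  pw <- pairwise_differentiation(m, n_permutations = 50, seed = 5)
  expect_identical(nrow(pw), 6L)
  tab <- render_pairwise_table(pw)
  expect_identical(dim(tab), c(4L, 4L))
  expect_equal(diag(tab), rep("", 4), ignore_attr = TRUE)
  # statistic below the diagonal, p-value above
  expect_identical(tab[2, 1],
                   formatC(pw$phi[pw$group1 == "A" & pw$group2 == "B"],
                           digits = 3, format = "f"))
  expect_identical(tab[1, 2],
                   formatC(pw$p_value[pw$group1 == "A" & pw$group2 == "B"],
                           digits = 3, format = "f"))
})
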