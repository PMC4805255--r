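test_that("dinucleotide o/e follows the length-corrected formula", {
  expect_equal(dinucleotide_oe("GGCC", "CpG"), 0)
  expect_equal(dinucleotide_oe("ACGCGT", "CpG"), 2 / 4 * 36 / 5)  # 3.6
  expect_equal(dinucleotide_oe("ACGCGT", "GpC"), 1 / 4 * 36 / 5)  # 1.8
  expect_true(is.na(dinucleotide_oe("AATT", "CpG")))  # no C: undefined
  expect_error(contig_oe("A"), "at least 2")
  # simple correction uses the plain factor l
  expect_equal(dinucleotide_oe("ACGCGT", "CpG", length_correction = "simple"),
               2 / 4 * 6)
})

test_that("counts match a brute-force scan on random sequences (with N)", {
  seqs <- random_dna(100, 60, seed = 17, letters = c("A", "C", "G", "T", "N"))
  st <- contig_oe(seqs)
  for (i in seq_len(20)) {
    expect_equal(unname(st$n_CpG[i]), brute_dinuc_count(seqs[i], "CG"),
                 ignore_attr = TRUE)
    expect_equal(unname(st$n_GpC[i]), brute_dinuc_count(seqs[i], "GC"),
                 ignore_attr = TRUE)
    expect_equal(unname(st$n_TpG[i]), brute_dinuc_count(seqs[i], "TG"),
                 ignore_attr = TRUE)
    expect_equal(unname(st$n_C[i]), brute_base_count(seqs[i], "C"),
                 ignore_attr = TRUE)
    # effective length excludes ambiguous bases
    expect_identical(st$l[i], 60L - brute_base_count(seqs[i], "N"))
  }
  # o/e recomputed from brute counts
  i <- 1L
  l <- st$l[i]
  expect_equal(st$cpg_oe[i],
               brute_dinuc_count(seqs[i], "CG") /
                 (brute_base_count(seqs[i], "C") * brute_base_count(seqs[i], "G")) *
                 l^2 / (l - 1))
})

test_that("long iid sequences give o/e ratios near 1", {
  seqs <- random_dna(100, 1000, seed = 29)
  st <- contig_oe(seqs)
  expect_lt(abs(mean(st$cpg_oe) - 1), 0.05)
  expect_lt(abs(mean(st$gpc_oe) - 1), 0.05)
  expect_lt(abs(mean(st$tpg_oe) - 1), 0.05)
})

demo_annotation <- function() {
  data.frame(
    id = sprintf("c%02d", 1:10),
    has_orf = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE),
    fpkm_benthic = c(12, 3, 9.9, 50, 40, 0, 11, 10, 22, 15),
    fpkm_planktonic = c(3, 2, 9.9, 1, 33, 2, 0, 0, 11, 8),
    fpkm_nonrepro = c(0, 1, 9.9, 0, 21, 3, 5, 2, 7, 4),
    go_bp = c("GO:0007155", "GO:0007049", "GO:0008219", "",
              "GO:0019538", "GO:0006412", "GO:0016070;GO:0006950",
              "GO:9999999", "GO:0007155", "GO:0007155;GO:0022610"),
    stringsAsFactors = FALSE)
}

test_that("contig filtering applies ORF, GO and FPKM criteria", {
  ann <- demo_annotation()
  kept <- filter_contigs(ann)
  # hand enumeration: needs ORF, non-empty go_bp, max fpkm >= 10
  expect_identical(kept$id, c("c01", "c07", "c08", "c10"))
  rem <- attr(kept, "removed")
  expect_identical(unname(rem["no_orf"]), 2L)   # c05, c09
  expect_identical(unname(rem["no_bp_go"]), 1L) # c04
  expect_identical(unname(rem["low_fpkm"]), 3L) # c02, c03, c06
  # single condition at threshold retains; all below drops
  expect_true("c08" %in% kept$id)    # max fpkm exactly 10
  expect_false("c03" %in% kept$id)   # 9.9 everywhere
  expect_identical(filter_contigs(ann, require_orf = FALSE,
                                  require_bp_go = FALSE)$id,
                   ann$id[do.call(pmax, ann[3:5]) >= 10])
})

test_that("GO Slim assignment deduplicates per bin and keeps multi-bin contigs", {
  slim <- read_slim_map(system.file("extdata", "demo_goslim_map.tsv",
                                    package = "epimark"))
  ann <- data.frame(
    id = c("a", "b", "c", "d"),
    go_bp = c("GO:0007155;GO:0022610",      # both -> cell adhesion, once
              "GO:0008219;GO:0006950",      # death + stress response
              "",                           # unbinned
              "GO:9999999"),                # unmapped term -> unbinned
    stringsAsFactors = FALSE)
  asg <- assign_goslim(ann, slim)
  expect_identical(asg$bin[asg$id == "a"], "cell adhesion")
  expect_setequal(asg$bin[asg$id == "b"], c("death", "stress response"))
  expect_setequal(attr(asg, "unbinned"), c("c", "d"))
  expect_identical(attr(asg, "unmapped_terms"), "GO:9999999")
  # idempotent and order-independent
  asg2 <- assign_goslim(ann[c(3, 1, 4, 2), ], slim[sample(nrow(slim)), ])
  o <- function(x) x[order(x$id, x$bin), ]
  expect_equal(o(asg2), o(asg), ignore_attr = TRUE)
})

test_that("category statistics: SEM, ANOVA, and pooled-SD pairwise t-tests", {
  set.seed(61)
  vals <- data.frame(
    bin = rep(c("b1", "b2", "b3"), times = c(12, 12, 1)),
    cpg_oe = c(rnorm(12, 0.6, 0.05), rnorm(12, 0.8, 0.05), 0.7))
  cs <- category_stats(vals)
  b1 <- vals$cpg_oe[vals$bin == "b1"]
  expect_equal(cs$summary$mean[cs$summary$bin == "b1"], mean(b1))
  expect_equal(cs$summary$sem[cs$summary$bin == "b1"], sd(b1) / sqrt(12))
  expect_true(is.na(cs$summary$sem[cs$summary$bin == "b3"]))  # n = 1: no SEM
  # pairwise t with pooled SD matches the textbook statistic
  b2 <- vals$cpg_oe[vals$bin == "b2"]
  sp <- sqrt(((12 - 1) * var(b1) + (12 - 1) * var(b2)) / (12 + 12 - 2))
  t_hand <- (mean(b1) - mean(b2)) / (sp * sqrt(1 / 12 + 1 / 12))
  p_hand <- 2 * pt(-abs(t_hand), 22)
  expect_equal(unname(cs$pairwise["b2", "b1"]), p_hand, tolerance = 1e-9)
})

test_that("two-bin ANOVA F equals the squared pooled t statistic", {
  set.seed(62)
  vals <- data.frame(bin = rep(c("x", "y"), each = 15),
                     cpg_oe = c(rnorm(15, 0.6, 0.1), rnorm(15, 0.7, 0.1)))
  cs <- category_stats(vals)
  tt <- t.test(cpg_oe ~ bin, data = vals, var.equal = TRUE)
  expect_equal(unname(cs$anova["F"]), unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(unname(cs$anova["p"]), tt$p.value, tolerance = 1e-9)
})

test_that("between-group contrasts report direction and skip one-sided bins", {
  set.seed(63)
  vals <- data.frame(
    bin = c(rep("shift", 40), rep("same", 40), rep("lonely", 10)),
    group = c(rep(c("benthic", "planktonic"), each = 20),
              rep(c("benthic", "planktonic"), each = 20), rep("benthic", 10)),
    cpg_oe = c(rnorm(20, 0.6, 0.05), rnorm(20, 0.75, 0.05),
               rep(c(0.6, 0.7), 20), rnorm(10, 0.5, 0.05)))
  gc <- group_contrasts(vals)
  expect_identical(attr(gc, "skipped"), "lonely")
  expect_identical(gc$higher[gc$bin == "shift"], "planktonic")
  expect_lt(gc$p_value[gc$bin == "shift"], 0.001)
  # identical group values: t = 0, p = 1
  same <- data.frame(bin = "b", group = rep(c("g1", "g2"), each = 4),
                     cpg_oe = rep(c(0.5, 0.6, 0.7, 0.8), 2))
  gc2 <- group_contrasts(same)
  expect_equal(gc2$t, 0)
  expect_equal(gc2$p_value, 1)
})

test_that("depletion correlation detects anti-correlation and degenerate input", {
  st <- data.frame(cpg_oe = c(0.2, 0.5, 0.8, 1.0),
                   gpc_oe = c(1, 1, 1, 1),
                   tpg_oe = c(1.8, 1.5, 1.2, 1.0))
  dc <- depletion_correlation(st)
  expect_equal(dc$r, -1)
  expect_identical(dc$n, 4L)
  expect_equal(unname(dc$means["tpg_oe"]), 1.375)
  const <- data.frame(cpg_oe = c(0.2, 0.5, 0.8), gpc_oe = c(1, 1, 1),
                      tpg_oe = c(1, 1, 1))
  expect_true(is.na(depletion_correlation(const)$r))
  expect_error(depletion_correlation(st[1:2, ]), "at least 3")
})

test_that("depleted simulated contigs show the negative TpG-CpG association", {
  seqs <- c(simulate_cpg_depletion(60, 800, methylation_level = 0.1,
                                   deamination_rounds = 3,
                                   deamination_rate = 0.5, seed = 71),
            simulate_cpg_depletion(60, 800, methylation_level = 0.9,
                                   deamination_rounds = 3,
                                   deamination_rate = 0.5, seed = 72))
  dc <- depletion_correlation(contig_oe(seqs))
  expect_lt(dc$r, -0.3)
  expect_lt(dc$p_value, 0.001)
})
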