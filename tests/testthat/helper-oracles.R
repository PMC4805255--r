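# Independent brute-force oracles and deterministic fixtures. These stay
# separate from the package code paths they check: counting is done by
# position-wise scans, AMOVA by explicit sums with exhaustive label
# enumeration.

# Position-by-position dinucleotide scan (counts overlapping pairs; any
# window touching a non-ACGT base is skipped, matching "N excluded").
brute_dinuc_count <- function(seq, di) {
  s <- strsplit(toupper(seq), "")[[1]]
  d <- strsplit(di, "")[[1]]
  n <- 0L
  for (i in seq_len(length(s) - 1L)) {
    if (s[i] == d[1] && s[i + 1L] == d[2]) n <- n + 1L
  }
  n
}

brute_base_count <- function(seq, base) {
  sum(strsplit(toupper(seq), "")[[1]] == base)
}

# Enumerate observed (locus, condition) combinations of the Mixed Scoring 2
# transformation directly from the state matrix.
brute_mixed2_total <- function(states) {
  cond <- c("1/1", "1/0", "0/1")
  total <- 0L
  for (j in seq_len(ncol(states))) {
    for (cc in cond) total <- total + as.integer(any(states[, j] == cc))
  }
  total
}

# Independent AMOVA: explicit pairwise squared distances and the
# sums-of-squares decomposition written out longhand.
brute_phi <- function(x, grp) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum((x[i, ] - x[j, ])^2)
  }
  grp <- as.integer(factor(grp))
  k <- max(grp)
  ssw <- 0
  for (g in seq_len(k)) {
    idx <- which(grp == g)
    ssw <- ssw + sum(d[idx, idx]) / (2 * length(idx))
  }
  sst <- sum(d) / (2 * n)
  ssa <- sst - ssw
  msw <- ssw / (n - k)
  msa <- ssa / (k - 1)
  sizes <- tabulate(grp, k)
  n0 <- (n - sum(sizes^2) / n) / (k - 1)
  s2a <- (msa - msw) / n0
  s2a / (s2a + msw)
}

# Exhaustive permutation distribution of Phi for two groups: every way of
# choosing which individuals form group 1.
brute_phi_enumeration <- function(x, grp) {
  n <- nrow(x)
  n1 <- sum(grp == unique(grp)[1])
  picks <- combn(n, n1)
  apply(picks, 2, function(idx) {
    lab <- rep(2L, n)
    lab[idx] <- 1L
    brute_phi(x, lab)
  })
}

# Deterministic MS-AFLP fixture: 165 loci over 20 individuals built so that
# the scoring pipeline finds 105 methylation-susceptible loci of which 101
# are polymorphic (4 are methylated in every individual).
acceptance_band_fixture <- function() {
  n <- 20L
  states <- matrix("1/1", n, 165,
                   dimnames = list(sprintf("ind_%02d", 1:n), sprintf("L%03d", 1:165)))
  for (j in 1:101) states[((j - 1L) %% 17L) + 1:3, j] <- "1/0"  # 3/20 methylated
  for (j in 102:105) states[, j] <- "1/0"                       # fixed methylated
  # loci 106..165: all unmethylated -> NML
  groups <- rep(c("A", "B"), each = n / 2L)
  st <- epimark:::new_methylation_states(states, groups)
  split_digests(st)
}

# Deterministic 367 bp amplicon with exactly 66 cytosines, 8 of them in CpG
# context; returns the sequence and the 1-based positions of the CpG
# cytosines (the methylation mask of the worked example).
bisulfite_amplicon_fixture <- function() {
  s <- rep("A", 367)
  cpg_pos <- seq(10, by = 40, length.out = 8)        # 10, 50, ..., 290
  for (p in cpg_pos) { s[p] <- "C"; s[p + 1] <- "G" }
  other_c <- seq(301, by = 1, length.out = 58)       # 301..358, followed by A
  s[other_c] <- "C"
  s[359:367] <- "T"                                  # keep the tail C-free
  list(reference = paste(s, collapse = ""), mask = cpg_pos)
}

random_states <- function(n, n_loci, seed,
                          probs = c(0.3, 0.3, 0.2, 0.2)) {
  set.seed(seed)
  m <- matrix(sample(c("1/1", "1/0", "0/1", "0/0"), n * n_loci, TRUE, probs),
              n, n_loci,
              dimnames = list(sprintf("i%02d", 1:n), sprintf("L%03d", 1:n_loci)))
  epimark:::new_methylation_states(m, rep("g1", n))
}

random_dna <- function(n, len, seed, letters = c("A", "C", "G", "T")) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(letters, len, TRUE), collapse = "")
  }, character(1))
}
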