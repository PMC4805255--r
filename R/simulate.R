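# Methylation state codes shared across the scoring functions.
# Band order is MspI/HpaII; 0/1 ("unspecific") is NOT interpreted as
# hemimethylation, but it still counts as a methylated pattern for
# methylation-susceptible locus classification.
STATES <- c("1/1", "1/0", "0/1", "0/0")
STATE_LABELS <- c(
  "1/1" = "Unmethylated (1/1)",
  "1/0" = "Methylated (internal cytosine) (1/0)",
  "0/1" = "Unspecific (hemimethylated) (0/1)",
  "0/0" = "Uninformative (0/0)"
)
METHYLATED_STATES <- c("1/0", "0/1")

#' Default MS-AFLP simulation design
#'
#' Four groups sized 18/12/12/12 scored at 165 anonymous loci, with
#' per-group state probabilities (over the four band patterns 1/1, 1/0,
#' 0/1, 0/0) set to values typical of an invertebrate MS-AFLP survey where
#' roughly a quarter of informative cells carry internal-cytosine
#' methylation and about half of all cells are uninformative.
#'
#' @return a named list of arguments accepted by [simulate_msap()].
#' @export
msap_sim_defaults <- function() {
  probs <- rbind(
    Herslev_B  = c(0.181, 0.265, 0.025, 0.529),
    Herslev_nr = c(0.178, 0.212, 0.022, 0.588),
    Romo_P     = c(0.241, 0.269, 0.055, 0.435),
    Romo_nr    = c(0.253, 0.243, 0.053, 0.451)
  )
  colnames(probs) <- STATES
  list(group_sizes = c(Herslev_B = 18, Herslev_nr = 12, Romo_P = 12, Romo_nr = 12),
       n_loci = 165,
       state_probs = probs,
       scoring_error_rate = 0.05)
}

check_state_probs <- function(state_probs, n_groups, n_loci) {
  if (is.vector(state_probs) && length(state_probs) == 4L) {
    state_probs <- matrix(state_probs, n_groups, 4L, byrow = TRUE)
  }
  if (is.matrix(state_probs)) {
    if (nrow(state_probs) != n_groups || ncol(state_probs) != 4L) {
      stop("'state_probs' matrix must be n_groups x 4")
    }
    arr <- array(NA_real_, c(n_groups, n_loci, 4L))
    for (s in 1:4) arr[, , s] <- state_probs[, s]
    state_probs <- arr
  }
  if (!is.array(state_probs) || length(dim(state_probs)) != 3L ||
      !all(dim(state_probs) == c(n_groups, n_loci, 4L))) {
    stop("'state_probs' must be a 4-vector, an n_groups x 4 matrix, ",
         "or an n_groups x n_loci x 4 array")
  }
  if (any(state_probs < 0 | state_probs > 1)) {
    stop("state probabilities must lie in [0, 1]")
  }
  sums <- apply(state_probs, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-12)) {
    stop("each state probability 4-vector must sum to 1 (within 1e-12)")
  }
  state_probs
}

#' Simulate group-structured MS-AFLP band profiles
#'
#' Draws, for every individual x locus cell, one of the four band patterns
#' (1/1, 1/0, 0/1, 0/0) from its group's probability vector, decomposes the
#' pattern into the MspI and HpaII presence calls, and then flips each band
#' call independently with probability `scoring_error_rate` (the two digests
#' are separate reactions, so scoring errors are independent per enzyme).
#' The drawn ("true") states are returned for recovery tests.
#'
#' @param group_sizes positive integer vector of individuals per group;
#'   names become group labels.
#' @param n_loci number of scored fragments.
#' @param state_probs probabilities over the four states `1/1, 1/0, 0/1,
#'   0/0`: a 4-vector (shared), an `n_groups x 4` matrix (per group), or an
#'   `n_groups x n_loci x 4` array (per group and locus). Each 4-vector must
#'   sum to 1.
#' @param scoring_error_rate probability that a single band call is flipped.
#' @param seed integer seed; identical `(arguments, seed)` give identical
#'   output.
#' @return list with components `mspI` and `hpaII` ([band_matrix()] pair)
#'   and `true_states` (a [methylation_states] matrix of the drawn
#'   patterns, before scoring error).
#' @examples
#' sim <- simulate_msap(c(A = 5, B = 5), n_loci = 10,
#'                      state_probs = c(0.4, 0.3, 0.1, 0.2),
#'                      scoring_error_rate = 0, seed = 1)
#' sim$mspI
#' @export
simulate_msap <- function(group_sizes, n_loci, state_probs,
                          scoring_error_rate = 0.05, seed = NULL) {
  if (any(group_sizes < 1) || any(group_sizes != round(group_sizes))) {
    stop("'group_sizes' must be positive integers")
  }
  if (scoring_error_rate < 0 || scoring_error_rate > 1) {
    stop("'scoring_error_rate' must lie in [0, 1]")
  }
  n_groups <- length(group_sizes)
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- paste0("group", seq_len(n_groups))
  }
  state_probs <- check_state_probs(state_probs, n_groups, n_loci)
  n <- sum(group_sizes)
  grp <- rep(seq_len(n_groups), group_sizes)
  groups <- rep(names(group_sizes), group_sizes)
  ind_ids <- unlist(lapply(seq_len(n_groups), function(g) {
    sprintf("%s_%02d", names(group_sizes)[g], seq_len(group_sizes[g]))
  }), use.names = FALSE)
  locus_ids <- sprintf("L%03d", seq_len(n_loci))

  with_seed(seed, {
    states <- matrix(NA_character_, n, n_loci, dimnames = list(ind_ids, locus_ids))
    for (j in seq_len(n_loci)) {
      for (g in seq_len(n_groups)) {
        rows <- which(grp == g)
        states[rows, j] <- sample(STATES, length(rows), replace = TRUE,
                                  prob = state_probs[g, j, ])
      }
    }
    msp <- (states == "1/1" | states == "1/0") + 0L
    hpa <- (states == "1/1" | states == "0/1") + 0L
    if (scoring_error_rate > 0) {
      flip_m <- matrix(runif(n * n_loci) < scoring_error_rate, n, n_loci)
      flip_h <- matrix(runif(n * n_loci) < scoring_error_rate, n, n_loci)
      msp[flip_m] <- 1L - msp[flip_m]
      hpa[flip_h] <- 1L - hpa[flip_h]
    }
    list(
      mspI = band_matrix(msp, groups = groups, enzyme = "MspI"),
      hpaII = band_matrix(hpa, groups = groups, enzyme = "HpaII"),
      true_states = new_methylation_states(states, groups)
    )
  })
}

#' Simulate CpG depletion of coding sequence by methylation-deamination
#'
#' Generates iid random nucleotide sequences at a given GC content, flags
#' each CpG site as germline-methylated once (Bernoulli at
#' `methylation_level` -- stable germline methylation, the regime the
#' CpG o/e statistic assumes), then runs `deamination_rounds` rounds in
#' which every still-intact methylated CpG mutates to TpG (C->T
#' substitution) with probability `deamination_rate`. Sequence length is
#' conserved; high methylation therefore depletes CpG and inflates TpG.
#'
#' @param n_contigs number of sequences.
#' @param contig_length length of each sequence (>= 2).
#' @param gc_content fraction of G+C in the initial iid draw.
#' @param methylation_level fraction of CpG sites methylated in germline.
#' @param deamination_rounds number of mutation rounds.
#' @param deamination_rate per-round probability that a methylated CpG
#'   mutates to TpG.
#' @param seed integer seed.
#' @return a named character vector of uppercase A/C/G/T sequences.
#' @examples
#' seqs <- simulate_cpg_depletion(5, 200, methylation_level = 1,
#'                                deamination_rounds = 1,
#'                                deamination_rate = 1, seed = 1)
#' @export
simulate_cpg_depletion <- function(n_contigs, contig_length, gc_content = 0.5,
                                   methylation_level = 0.5,
                                   deamination_rounds = 3,
                                   deamination_rate = 0.5, seed = NULL) {
  stopifnot(contig_length >= 2, n_contigs >= 1)
  for (f in c(gc_content, methylation_level, deamination_rate)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  base_probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
                  G = gc_content / 2, T = (1 - gc_content) / 2)
  with_seed(seed, {
    out <- character(n_contigs)
    for (i in seq_len(n_contigs)) {
      s <- sample(names(base_probs), contig_length, replace = TRUE,
                  prob = base_probs)
      cpg <- which(s[-contig_length] == "C" & s[-1L] == "G")
      if (length(cpg)) {
        methylated <- cpg[runif(length(cpg)) < methylation_level]
        alive <- methylated
        for (r in seq_len(deamination_rounds)) {
          if (!length(alive)) break
          hit <- runif(length(alive)) < deamination_rate
          s[alive[hit]] <- "T"
          alive <- alive[!hit]
        }
      }
      out[i] <- paste(s, collapse = "")
    }
    names(out) <- sprintf("contig_%04d", seq_len(n_contigs))
    out
  })
}

#' Simulate bisulfite conversion of a reference sequence
#'
#' Bisulfite treatment converts unmethylated cytosines to uracil (read as
#' thymine after PCR and sequencing) while methylated cytosines remain
#' unchanged. Cytosines at positions in `methylation_mask` are retained;
#' every other C becomes T with probability `conversion_efficiency`. All
#' non-C bases are untouched and length is conserved.
#'
#' @param reference a single nucleotide sequence (character scalar,
#'   A/C/G/T/N).
#' @param methylation_mask integer vector of 1-based positions flagged
#'   methylated; each must hold a C in `reference`.
#' @param conversion_efficiency probability that an unmethylated C is
#'   converted.
#' @param seed integer seed (only matters when efficiency < 1).
#' @return the converted sequence (uppercase character scalar).
#' @examples
#' simulate_bisulfite("ACGA", methylation_mask = 2L)  # "ACGA"
#' simulate_bisulfite("ACGA", methylation_mask = integer(0))  # "ATGA"
#' @export
simulate_bisulfite <- function(reference, methylation_mask = integer(0),
                               conversion_efficiency = 1, seed = NULL) {
  if (conversion_efficiency < 0 || conversion_efficiency > 1) {
    stop("'conversion_efficiency' must lie in [0, 1]")
  }
  s <- strsplit(toupper(as.character(reference)), "")[[1]]
  if (!length(s)) stop("'reference' must be non-empty")
  methylation_mask <- as.integer(methylation_mask)
  if (length(methylation_mask)) {
    if (any(methylation_mask < 1L | methylation_mask > length(s))) {
      stop("methylation mask positions outside the reference")
    }
    if (any(s[methylation_mask] != "C")) {
      stop("every masked position must hold a C in the reference")
    }
  }
  cs <- setdiff(which(s == "C"), methylation_mask)
  with_seed(seed, {
    convert <- cs[runif(length(cs)) < conversion_efficiency]
    s[convert] <- "T"
    paste(s, collapse = "")
  })
}

#' Write or read sequences as FASTA
#'
#' Thin wrappers around Biostrings for the character-vector sequence sets
#' used by the simulators.
#'
#' @param x named character vector of sequences.
#' @param file path to a FASTA file.
#' @return `read_fasta` returns a named character vector; `write_fasta`
#'   returns `file` invisibly.
#' @export
write_fasta <- function(x, file) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), file)
  invisible(file)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(as.character(x), names(x))
}
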