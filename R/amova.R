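#' Pairwise squared Euclidean distances between binary marker rows
#'
#' The distance used by the AMOVA-based Phi estimators for dominant
#' (binary) markers: the squared Euclidean distance between two
#' individuals' marker rows. Missing entries are handled
#' pairwise-complete, with the sum rescaled by `L / L_complete` so that
#' distances stay comparable across pairs with different missingness.
#'
#' @param markers 0/1/NA matrix, individuals in rows.
#' @return a symmetric `n x n` matrix of squared distances.
#' @export
marker_sqdist <- function(markers) {
  x <- unclass(as.matrix(markers))
  storage.mode(x) <- "double"
  n <- nrow(x); L <- ncol(x)
  if (!L) stop("no markers")
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  if (!anyNA(x)) {
    # ||xi - xj||^2 = ||xi||^2 + ||xj||^2 - 2 xi.xj
    cp <- tcrossprod(x)
    sq <- diag(cp)
    d <- outer(sq, sq, "+") - 2 * cp
    diag(d) <- 0
    return(d)
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(x[i, ]) & !is.na(x[j, ])
      m <- sum(ok)
      if (m == 0L) stop("individuals ", i, " and ", j,
                        " share no non-missing markers")
      d[i, j] <- d[j, i] <- sum((x[i, ok] - x[j, ok])^2) * L / m
    }
  }
  d
}

phi_from_distances <- function(d, grp) {
  n <- length(grp)
  k <- nlevels(grp)
  sizes <- tabulate(grp, nbins = k)
  ss_total <- sum(d) / (2 * n)
  ss_within <- 0
  for (g in seq_len(k)) {
    idx <- which(as.integer(grp) == g)
    ss_within <- ss_within + sum(d[idx, idx]) / (2 * length(idx))
  }
  ss_among <- ss_total - ss_within
  df_among <- k - 1L
  df_within <- n - k
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (n - sum(sizes^2) / n) / df_among
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n0
  phi <- sigma_among / (sigma_among + sigma_within)
  list(phi = phi,
       ss = c(among = ss_among, within = ss_within, total = ss_total),
       df = c(among = df_among, within = df_within),
       sigma = c(among = sigma_among, within = sigma_within),
       n0 = n0)
}

#' AMOVA-based differentiation (Phi-ST / PhiPT) with permutation test
#'
#' Analysis of molecular variance on binary epilocus profiles: squared
#' Euclidean distances between individuals are partitioned into among- and
#' within-group sums of squares, variance components are estimated by the
#' standard unbalanced-design estimators, and the fixation-index analogue
#' `Phi = sigma2_among / (sigma2_among + sigma2_within)` is tested by
#' permuting individuals among groups with group sizes fixed. The same
#' estimator is conventionally labelled Phi-ST on MSL-scheme markers and
#' PhiPT on Mixed Scoring 2 markers. Negative estimates (possible under
#' no differentiation) are reported as computed, never truncated at zero.
#' The permutation p-value uses the add-one rule
#' `p = (1 + #{Phi_perm >= Phi_obs}) / (n_permutations + 1)` so it is
#' never 0 and never below `1/(n_permutations + 1)`.
#'
#' @param markers an `epilocus_matrix` or 0/1/NA matrix.
#' @param groups group factor (defaults to the matrix attribute); every
#'   group needs at least 2 individuals.
#' @param n_permutations number of label permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @return an `amova_result` list: `phi`, `p_value`, `n_permutations`,
#'   `ss`, `df`, `sigma` (variance components), `n0`, `label`
#'   (`"Phi_ST"` or `"PhiPT"` by scheme), `group_sizes`.
#' @export
amova_phi <- function(markers, groups = NULL, n_permutations = 10000,
                      seed = NULL) {
  g <- resolve_groups(markers, groups)
  if (nlevels(g) < 2L) stop("AMOVA needs at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 individuals")
  d <- marker_sqdist(markers)
  obs <- phi_from_distances(d, g)
  if (obs$ss[["total"]] <= 0) stop("zero total variance: Phi undefined")
  n <- length(g)
  perm_phi <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      phi_from_distances(d, g[sample.int(n)])$phi
    }, numeric(1))
  })
  # count ties as exceedances: permuted relabelings can reproduce the
  # observed Phi exactly in exact arithmetic, differing only by float
  # summation order, so compare with a tolerance far below any real
  # difference between distinct partitions
  exceed <- sum(perm_phi >= obs$phi - 1e-12, na.rm = TRUE)
  scheme <- attr(markers, "scheme")
  structure(
    c(obs,
      list(p_value = (1 + exceed) / (n_permutations + 1),
           n_permutations = n_permutations,
           perm_phi = perm_phi,
           label = if (identical(scheme, "MIXED2")) "PhiPT" else "Phi_ST",
           group_sizes = table(g))),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("%s = %.3f  (permutation P = %s, %d permutations)\n",
              x$label, x$phi, format.pval(x$p_value, digits = 3),
              x$n_permutations))
  cat(sprintf("  SS among = %.3f (df %d), SS within = %.3f (df %d)\n",
              x$ss[["among"]], x$df[["among"]],
              x$ss[["within"]], x$df[["within"]]))
  cat(sprintf("  variance components: among = %.4f, within = %.4f\n",
              x$sigma[["among"]], x$sigma[["within"]]))
  invisible(x)
}

#' Pairwise differentiation between all group pairs
#'
#' Applies [amova_phi()] to every pair of groups and assembles the
#' conventional square report: statistics below the diagonal, permutation
#' p-values above (see [render_pairwise_table()]).
#'
#' @inheritParams amova_phi
#' @return a `pairwise_phi` object: data frame of `group1`, `group2`,
#'   `phi`, `p_value` plus attributes `groups` and `label`.
#' @export
pairwise_differentiation <- function(markers, groups = NULL,
                                     n_permutations = 10000, seed = NULL) {
  g <- resolve_groups(markers, groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  pairs <- combn(levels(g), 2L)
  seeds <- if (is.null(seed)) vector("list", ncol(pairs)) else
    as.list(seed + seq_len(ncol(pairs)) - 1L)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    keep <- g %in% pairs[, p]
    sub <- unclass(as.matrix(markers))[keep, , drop = FALSE]
    attr(sub, "scheme") <- attr(markers, "scheme")
    attr(sub, "meta") <- attr(markers, "meta")
    res <- amova_phi(sub, groups = droplevels(g[keep]),
                     n_permutations = n_permutations, seed = seeds[[p]])
    data.frame(group1 = pairs[1, p], group2 = pairs[2, p],
               phi = res$phi, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, groups = levels(g),
            label = if (identical(attr(markers, "scheme"), "MIXED2"))
              "PhiPT" else "Phi_ST",
            class = c("pairwise_phi", "data.frame"))
}
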