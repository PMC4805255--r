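#' Run the full MS-AFLP scoring and statistics pipeline
#'
#' Chains the scoring stages in dependency order: combine the two digest
#' band matrices into four-state patterns, classify
#' methylation-susceptible loci, build both epilocus matrices (MSL binary
#' and Mixed Scoring 2), then compute state frequencies, the diversity
#' report (Mixed Scoring 2 markers), the global AMOVA on MSL markers, and
#' pairwise differentiation on MSL markers (Phi-ST) and on the
#' methylated (`m`) Mixed Scoring 2 epiloci (PhiPT). Given identical
#' inputs and `seed`, the result is reproducible.
#'
#' @param mspI,hpaII the [band_matrix()] pair.
#' @param threshold MSL classification threshold (see [classify_msl()]).
#' @param n_permutations permutations per AMOVA test.
#' @param seed integer seed for all permutation streams.
#' @return an `msap_analysis` list: `states`, `partition`, `msl_markers`,
#'   `mixed_markers`, `state_freqs`, `diversity`, `amova_global`,
#'   `pairwise_msl`, `pairwise_m`, and the `settings` used.
#' @export
run_msap_pipeline <- function(mspI, hpaII, threshold = 0.05,
                              n_permutations = 10000, seed = NULL) {
  states <- combine_digests(mspI, hpaII)
  partition <- classify_msl(states, threshold = threshold)
  msl <- msl_binary(states, partition)
  mixed <- mixed_scoring2(states)
  meta <- attr(mixed, "meta")
  m_only <- mixed[, meta$type == "m", drop = FALSE]
  m_only <- new_epilocus_matrix(m_only, meta[meta$type == "m", , drop = FALSE],
                                "MIXED2", attr(mixed, "groups"))
  structure(list(
    states = states,
    partition = partition,
    msl_markers = msl,
    mixed_markers = mixed,
    state_freqs = state_frequencies(states, partition),
    diversity = diversity_report(mixed),
    amova_global = amova_phi(msl, n_permutations = n_permutations, seed = seed),
    pairwise_msl = pairwise_differentiation(msl, n_permutations = n_permutations,
                                            seed = if (is.null(seed)) NULL else seed + 1000L),
    pairwise_m = pairwise_differentiation(m_only, n_permutations = n_permutations,
                                          seed = if (is.null(seed)) NULL else seed + 2000L),
    settings = list(threshold = threshold, n_permutations = n_permutations,
                    seed = seed)),
    class = "msap_analysis")
}

#' @export
print.msap_analysis <- function(x, ...) {
  cat("MS-AFLP analysis\n")
  cat(sprintf("  %d individuals, %d loci; %d MSL / %d NML (threshold %.2f)\n",
              nrow(x$states), ncol(x$states),
              sum(x$partition$class == "MSL"), sum(x$partition$class == "NML"),
              x$settings$threshold))
  cat(sprintf("  Mixed Scoring 2: %d epiloci\n", ncol(x$mixed_markers)))
  cat(sprintf("  global %s = %.3f (P = %s)\n", x$amova_global$label,
              x$amova_global$phi, format.pval(x$amova_global$p_value, digits = 3)))
  invisible(x)
}

#' Render the square pairwise differentiation table
#'
#' Conventional layout: statistics (3 decimals) below the diagonal,
#' permutation p-values (3 decimals) above, empty diagonal. When two
#' `pairwise_phi` objects are given (e.g. Phi-ST on MSL markers and PhiPT
#' on methylated epiloci), cells show `first/second`.
#'
#' @param x a `pairwise_phi` object from [pairwise_differentiation()].
#' @param y optional second `pairwise_phi` over the same groups.
#' @param digits decimals for both statistics and p-values.
#' @return a character matrix with group names as dimnames.
#' @export
render_pairwise_table <- function(x, y = NULL, digits = 3) {
  gl <- attr(x, "groups")
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  cell <- function(df, g1, g2, col) {
    hit <- (df$group1 == g1 & df$group2 == g2) |
      (df$group1 == g2 & df$group2 == g1)
    fmt(df[[col]][hit])
  }
  out <- matrix("", length(gl), length(gl), dimnames = list(gl, gl))
  for (i in seq_along(gl)) {
    for (j in seq_along(gl)) {
      if (i == j) next
      col <- if (i > j) "phi" else "p_value"
      v <- cell(x, gl[i], gl[j], col)
      if (!is.null(y)) v <- paste0(v, "/", cell(y, gl[i], gl[j], col))
      out[i, j] <- v
    }
  }
  out
}

#' Render the per-group state frequency table
#'
#' Rows are the four band patterns with their conventional labels
#' (unmethylated, internal-cytosine methylated, unspecific,
#' uninformative); columns are the groups with sample sizes appended.
#'
#' @param freqs matrix from [state_frequencies()].
#' @param group_sizes optional named sizes to append as `(N = n)`.
#' @param digits decimals (default 3).
#' @return a data frame ready for printing.
#' @export
render_state_frequencies <- function(freqs, group_sizes = NULL, digits = 3) {
  out <- as.data.frame(t(round(freqs, digits)))
  rownames(out) <- STATE_LABELS[rownames(out)]
  if (!is.null(group_sizes)) {
    colnames(out) <- sprintf("%s (N = %d)", colnames(out),
                             as.integer(group_sizes[colnames(out)]))
  }
  out
}

#' Render the diversity report at table precision
#'
#' Percentages to 1 decimal (private markers to 2), Shannon index to 3 --
#' rounding happens only here, at render time; the underlying report
#' keeps full precision.
#'
#' @param report data frame from [diversity_report()].
#' @return a data frame of formatted character columns.
#' @export
render_diversity_table <- function(report) {
  data.frame(
    type = report$type,
    group = report$group,
    n_markers = report$n_markers,
    pct_polymorphic = sprintf("%.1f (%d)", report$pct_polymorphic,
                              report$n_polymorphic),
    pct_private = sprintf("%.2f", report$pct_private),
    shannon = sprintf("%.3f", report$shannon),
    stringsAsFactors = FALSE)
}

#' Write the pipeline's report bundle to a directory
#'
#' Emits TSVs for the state frequency table, diversity report, pairwise
#' differentiation table, MSL partition and the epilocus matrices, plus a
#' JSON with the full-precision AMOVA components. Every file starts with
#' a provenance comment (package version, seed, settings).
#'
#' @param analysis an `msap_analysis` from [run_msap_pipeline()].
#' @param dir output directory (created if needed).
#' @return the written paths, invisibly.
#' @export
write_msap_reports <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# epimark %s | seed=%s threshold=%s permutations=%d | 1-based coordinates",
                   as.character(utils::packageVersion("epimark")),
                   analysis$settings$seed %||% "NULL",
                   analysis$settings$threshold,
                   analysis$settings$n_permutations)
  emit <- function(obj, name, row_names = FALSE) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(stamp, con)
    write.table(obj, con, sep = "\t", quote = FALSE,
                row.names = row_names,
                col.names = if (row_names) NA else TRUE)
    close(con)
    path
  }
  paths <- c(
    emit(render_state_frequencies(analysis$state_freqs),
         "state_frequencies.tsv", row_names = TRUE),
    emit(render_diversity_table(analysis$diversity), "diversity.tsv"),
    emit(render_pairwise_table(analysis$pairwise_msl, analysis$pairwise_m),
         "pairwise_differentiation.tsv", row_names = TRUE),
    emit(as.data.frame(analysis$partition), "msl_partition.tsv"))
  json <- file.path(dir, "amova.json")
  g <- analysis$amova_global
  jsonlite::write_json(
    list(label = g$label, phi = g$phi, p_value = g$p_value,
         n_permutations = g$n_permutations,
         ss = as.list(g$ss), sigma = as.list(g$sigma),
         pairwise_msl = as.data.frame(analysis$pairwise_msl),
         pairwise_m = as.data.frame(analysis$pairwise_m),
         settings = analysis$settings),
    json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, json))
}
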