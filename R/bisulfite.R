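as_base_vector <- function(x, what) {
  s <- strsplit(toupper(as.character(x)), "")[[1]]
  if (!length(s)) stop("'", what, "' must be a non-empty sequence")
  if (!all(s %in% c("A", "C", "G", "T", "N"))) {
    stop("'", what, "' may contain only A/C/G/T/N")
  }
  s
}

#' Place a bisulfite-converted read on its untreated reference
#'
#' Gap-free placement by exhaustive offset scan under bisulfite-aware
#' equality: a reference C may pair with a converted C (methylated,
#' protected) or T (unmethylated, converted); every other base must match
#' exactly; N on either side matches anything. Bisulfite conversion is
#' substitution-only, so no indel handling is attempted. Exactly one
#' qualifying offset must exist; zero offsets is an alignment failure
#' (e.g. a reverse-strand read, which is rejected rather than silently
#' reverse-complemented) and more than one is an ambiguity failure.
#'
#' @param reference untreated reference sequence (character scalar).
#' @param converted bisulfite-converted, sequenced fragment.
#' @return a `bisulfite_alignment` list: `reference`, `converted`,
#'   `offset` (1-based start of the fragment on the reference).
#' @examples
#' align_converted("ACGTACGT", "ATGT")$offset  # 1
#' @export
align_converted <- function(reference, converted) {
  r <- as_base_vector(reference, "reference")
  v <- as_base_vector(converted, "converted")
  if (length(v) > length(r)) stop("converted fragment longer than the reference")
  hits <- integer(0)
  for (off in seq_len(length(r) - length(v) + 1L)) {
    rs <- r[off:(off + length(v) - 1L)]
    ok <- rs == v | rs == "N" | v == "N" | (rs == "C" & v == "T")
    if (all(ok)) hits <- c(hits, off)
  }
  if (length(hits) == 0L) {
    stop("no valid placement of the converted fragment on the reference")
  }
  if (length(hits) > 1L) {
    stop("ambiguous placement: offsets ", paste(hits, collapse = ", "))
  }
  structure(list(reference = paste(r, collapse = ""),
                 converted = paste(v, collapse = ""),
                 offset = hits),
            class = "bisulfite_alignment")
}

#' Call per-cytosine methylation from a bisulfite alignment
#'
#' For every reference cytosine inside the aligned span: a converted-read
#' C means the cytosine was protected (methylated), T means it was
#' converted (unmethylated), N is uncallable; any other base is a
#' data-integrity error. CpG context is taken from the untreated reference
#' (the next reference base is G), never from the converted read, since
#' conversion destroys context; a C at the last reference position is
#' non-CpG. Coordinates are 1-based reference positions.
#'
#' @param alignment a `bisulfite_alignment` from [align_converted()], or a
#'   reference sequence (then `converted` must be given and is aligned
#'   first).
#' @param converted optional converted sequence when `alignment` is a
#'   plain reference.
#' @return a `methylation_calls` object: `calls` data frame (`position`,
#'   `context` `"CpG"`/`"non-CpG"`, `status`
#'   `"methylated"`/`"unmethylated"`/`"uncallable"`) and a `summary` list
#'   with counts, per-context counts, `percent_methylated` at full
#'   precision and `percent_methylated_rounded` to the nearest integer.
#' @examples
#' call_methylation("ACCGA", "ATCGA")$summary$percent_methylated  # 50
#' @export
call_methylation <- function(alignment, converted = NULL) {
  if (!inherits(alignment, "bisulfite_alignment")) {
    alignment <- align_converted(alignment, converted)
  }
  r <- strsplit(alignment$reference, "")[[1]]
  v <- strsplit(alignment$converted, "")[[1]]
  off <- alignment$offset
  span <- off:(off + length(v) - 1L)
  cpos <- span[r[span] == "C"]
  status <- character(length(cpos))
  for (i in seq_along(cpos)) {
    b <- v[cpos[i] - off + 1L]
    status[i] <- switch(b,
                        C = "methylated",
                        T = "unmethylated",
                        N = "uncallable",
                        stop("base '", b, "' at reference C position ", cpos[i],
                             " is neither C, T nor N"))
  }
  context <- ifelse(cpos < length(r) & r[pmin(cpos + 1L, length(r))] == "G",
                    "CpG", "non-CpG")
  calls <- data.frame(position = cpos, context = context, status = status,
                      stringsAsFactors = FALSE)
  n <- nrow(calls)
  n_meth <- sum(status == "methylated")
  pct <- if (n > 0) 100 * n_meth / n else NA_real_
  summary <- list(
    n_cytosines = n,
    n_methylated = n_meth,
    n_unmethylated = sum(status == "unmethylated"),
    n_uncallable = sum(status == "uncallable"),
    by_context = table(context = factor(context, c("CpG", "non-CpG")),
                       status = factor(status, c("methylated", "unmethylated",
                                                 "uncallable"))),
    percent_methylated = pct,
    percent_methylated_rounded = if (is.na(pct)) NA_integer_ else
      as.integer(round(pct)))
  structure(list(calls = calls, summary = summary,
                 offset = off, span = range(span)),
            class = "methylation_calls")
}

#' @export
print.methylation_calls <- function(x, ...) {
  s <- x$summary
  cat("Per-cytosine methylation calls",
      sprintf("(1-based reference coordinates %d-%d)\n", x$span[1], x$span[2]))
  cat(sprintf("  %d cytosines: %d methylated (%d%%), %d unmethylated, %d uncallable\n",
              s$n_cytosines, s$n_methylated, s$percent_methylated_rounded,
              s$n_unmethylated, s$n_uncallable))
  cpg <- x$calls$context == "CpG" & x$calls$status == "methylated"
  if (any(cpg)) {
    cat("  methylated CpG positions:",
        paste(x$calls$position[cpg], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bisulfite conversion efficiency proxy
#'
#' Fraction of non-CpG cytosines called unmethylated. Genuine methylation
#' outside CpG context is rare in most animal genomes, so unconverted
#' non-CpG cytosines indicate incomplete conversion; this rate is the
#' standard quality-control proxy for conversion efficiency. Uncallable
#' positions are excluded.
#'
#' @param callset a `methylation_calls` object.
#' @return a fraction in \[0, 1\].
#' @export
conversion_rate <- function(callset) {
  calls <- callset$calls
  keep <- calls$context == "non-CpG" & calls$status != "uncallable"
  if (!any(keep)) stop("no non-CpG cytosines in span: conversion rate undefined")
  mean(calls$status[keep] == "unmethylated")
}

#' Write methylation calls as TSV plus a JSON summary
#'
#' The TSV has one row per reference cytosine (position, context, status);
#' the JSON carries the summary counts and percentages. Both state the
#' 1-based reference coordinate convention in a header comment.
#'
#' @param callset a `methylation_calls` object.
#' @param out_prefix path prefix; writes `<prefix>_calls.tsv` and
#'   `<prefix>_summary.json`.
#' @return the two paths, invisibly.
#' @export
write_methylation_calls <- function(callset, out_prefix) {
  tsv <- paste0(out_prefix, "_calls.tsv")
  js <- paste0(out_prefix, "_summary.json")
  con <- file(tsv, "w")
  writeLines("# per-cytosine methylation calls; positions are 1-based on the reference",
             con)
  write.table(callset$calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  s <- callset$summary
  s$by_context <- as.data.frame(s$by_context)
  jsonlite::write_json(s, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
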