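DINUC_MAP <- c(CpG = "CG", GpC = "GC", TpG = "TG")

as_dna_set <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) return(sequences)
  x <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  if (is.null(names(x))) names(x) <- sprintf("seq_%04d", seq_along(x))
  x
}

#' Dinucleotide observed/expected ratio
#'
#' For a dinucleotide XpY on sequence(s) of effective length `l`
#' (ambiguous N bases are excluded from all counts and subtracted from
#' `l`), the ratio is
#' `o/e = (n_XY / (n_X * n_Y)) * l^2 / (l - 1)`,
#' where `n_XY` counts overlapping dinucleotides. The `l^2/(l-1)` factor
#' corrects for the sequence having `l - 1` dinucleotide positions;
#' `length_correction = "simple"` uses the plain factor `l` common in the
#' CpG-depletion literature. CpG o/e near 1 is the neutral baseline;
#' persistent germline methylation depletes CpG (deamination of
#' 5-methylcytosine to thymine) and drives the ratio below 1, while GpC
#' o/e -- same base composition, no methylation target -- stays near 1.
#'
#' @param sequences character vector or `DNAStringSet`.
#' @param dinucleotide `"CpG"`, `"GpC"` or `"TpG"`.
#' @param length_correction `"paper"` (`l^2/(l-1)`, default) or
#'   `"simple"` (`l`).
#' @return numeric vector of ratios; `NA` where a required mononucleotide
#'   count is zero (undefined ratio).
#' @examples
#' dinucleotide_oe("ACGCGT", "CpG")  # 3.6
#' dinucleotide_oe("ACGCGT", "GpC")  # 1.8
#' @export
dinucleotide_oe <- function(sequences, dinucleotide = c("CpG", "GpC", "TpG"),
                            length_correction = c("paper", "simple")) {
  dinucleotide <- match.arg(dinucleotide)
  length_correction <- match.arg(length_correction)
  stats <- contig_oe(sequences, length_correction = length_correction)
  stats[[c(CpG = "cpg_oe", GpC = "gpc_oe", TpG = "tpg_oe")[[dinucleotide]]]]
}

#' Per-contig dinucleotide composition statistics
#'
#' Counts mononucleotides and overlapping CpG, GpC and TpG dinucleotides
#' per sequence and computes the three observed/expected ratios (see
#' [dinucleotide_oe()] for the formula and N handling).
#'
#' @inheritParams dinucleotide_oe
#' @return data frame: `id`, `l` (effective length, N excluded), `n_C`,
#'   `n_G`, `n_T`, `n_CpG`, `n_GpC`, `n_TpG`, `cpg_oe`, `gpc_oe`,
#'   `tpg_oe` (NA where undefined).
#' @export
contig_oe <- function(sequences, length_correction = c("paper", "simple")) {
  length_correction <- match.arg(length_correction)
  x <- as_dna_set(sequences)
  if (any(Biostrings::width(x) < 2L)) {
    stop("sequences must be at least 2 nucleotides long")
  }
  mono <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  di <- Biostrings::dinucleotideFrequency(x)
  l <- rowSums(mono)   # width minus ambiguous bases
  factor_l <- if (length_correction == "paper") l^2 / (l - 1) else l
  oe <- function(nxy, nx, ny) ifelse(nx * ny > 0, nxy / (nx * ny) * factor_l,
                                     NA_real_)
  data.frame(
    id = names(x),
    l = as.integer(l),
    n_C = mono[, "C"], n_G = mono[, "G"], n_T = mono[, "T"],
    n_CpG = di[, "CG"], n_GpC = di[, "GC"], n_TpG = di[, "TG"],
    cpg_oe = oe(di[, "CG"], mono[, "C"], mono[, "G"]),
    gpc_oe = oe(di[, "GC"], mono[, "G"], mono[, "C"]),
    tpg_oe = oe(di[, "TG"], mono[, "T"], mono[, "G"]),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter transcriptome contigs for composition analysis
#'
#' Keeps contigs that (a) contain a predicted ORF, (b) carry at least one
#' biological-process GO term, and (c) reach a minimum mean expression
#' (FPKM) in at least one condition. Non-coding contigs and barely
#' expressed contigs would otherwise dilute the methylation signature of
#' expressed coding sequence.
#'
#' @param annotation data frame with columns `id`, `has_orf` (logical or
#'   0/1), one or more `fpkm_*` columns (mean FPKM per condition), and
#'   `go_bp` (semicolon-separated biological-process GO ids, empty string
#'   when none).
#' @param min_fpkm threshold that the maximum over conditions must reach.
#' @param require_orf,require_bp_go toggle the ORF and GO criteria.
#' @return the retained rows, with attribute `removed` giving counts
#'   removed per criterion (applied in sequence).
#' @export
filter_contigs <- function(annotation, min_fpkm = 10, require_orf = TRUE,
                           require_bp_go = TRUE) {
  stopifnot(is.data.frame(annotation), "id" %in% names(annotation))
  fpkm_cols <- grep("^fpkm_", names(annotation), value = TRUE)
  if (!length(fpkm_cols)) stop("no fpkm_* columns in annotation")
  keep <- rep(TRUE, nrow(annotation))
  removed <- c(no_orf = 0L, no_bp_go = 0L, low_fpkm = 0L)
  if (require_orf) {
    ok <- as.logical(annotation$has_orf)
    removed["no_orf"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (require_bp_go) {
    ok <- !is.na(annotation$go_bp) & nzchar(trimws(annotation$go_bp))
    removed["no_bp_go"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  fpkm_max <- do.call(pmax, c(annotation[fpkm_cols], na.rm = TRUE))
  ok <- fpkm_max >= min_fpkm
  removed["low_fpkm"] <- sum(keep & !ok)
  keep <- keep & ok
  structure(annotation[keep, , drop = FALSE], removed = removed)
}

#' Assign contigs to GO Slim bins
#'
#' A contig belongs to the union of the GO Slim bins its GO terms map to;
#' multiple terms mapping to the same bin count once (a contig enters a
#' given bin at most once), while terms mapping to different bins place
#' the contig in all of them. GO terms absent from the mapping are
#' skipped and recorded; contigs whose terms map to no bin land in the
#' `unbinned` attribute and are excluded from category statistics.
#'
#' @param annotation data frame with `id` and `go_bp` (semicolon-separated
#'   GO ids).
#' @param slim_map data frame with columns `go_term`, `slim_bin` (a term
#'   may map to several bins over several rows).
#' @return long data frame (`id`, `bin`), one row per contig x bin, with
#'   attributes `unbinned` (contig ids) and `unmapped_terms`.
#' @export
assign_goslim <- function(annotation, slim_map) {
  stopifnot(all(c("go_term", "slim_bin") %in% names(slim_map)))
  terms <- strsplit(ifelse(is.na(annotation$go_bp), "", annotation$go_bp), ";")
  terms <- lapply(terms, trimws)
  all_terms <- unique(unlist(terms))
  all_terms <- all_terms[nzchar(all_terms)]
  unmapped <- setdiff(all_terms, slim_map$go_term)
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    tt <- terms[[i]][nzchar(terms[[i]])]
    bins <- sort(unique(slim_map$slim_bin[slim_map$go_term %in% tt]))
    if (!length(bins)) return(NULL)
    data.frame(id = annotation$id[i], bin = bins, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(id = character(0), bin = character(0),
                                      stringsAsFactors = FALSE)
  structure(out,
            unbinned = setdiff(annotation$id, out$id),
            unmapped_terms = unmapped)
}

#' Per-bin CpG o/e summary with ANOVA and pooled-SD pairwise t-tests
#'
#' For each GO Slim bin: number of contigs, mean CpG o/e and standard
#' error of the mean (sample SD / sqrt(n)). Differences among bin means
#' are tested by one-way ANOVA, followed by all pairwise t-tests using the
#' pooled standard deviation across all bins ([stats::pairwise.t.test()]
#' with `pool.sd = TRUE`). P-values are raw by default;
#' `p_adjust = "holm"` applies a Holm correction.
#'
#' @param values data frame with columns `bin` and `cpg_oe` (one row per
#'   contig x bin membership; NA ratios are dropped).
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return list: `summary` (per-bin n/mean/sem; bins with < 2 contigs
#'   carry `sem = NA` and are excluded from tests), `anova` (`F`, `p`,
#'   dfs), `pairwise` (lower-triangular p-value matrix).
#' @export
category_stats <- function(values, p_adjust = "none") {
  stopifnot(all(c("bin", "cpg_oe") %in% names(values)))
  values <- values[!is.na(values$cpg_oe), , drop = FALSE]
  n_by <- table(values$bin)
  summ <- do.call(rbind, lapply(names(n_by), function(b) {
    v <- values$cpg_oe[values$bin == b]
    data.frame(bin = b, n = length(v), mean = mean(v),
               sem = if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  testable <- names(n_by)[n_by >= 2L]
  if (length(testable) < 2L) {
    stop("ANOVA needs at least 2 bins with at least 2 contigs each")
  }
  sub <- values[values$bin %in% testable, , drop = FALSE]
  sub$bin <- factor(sub$bin)
  fit <- aov(cpg_oe ~ bin, data = sub)
  at <- anova(fit)
  pw <- pairwise.t.test(sub$cpg_oe, sub$bin, pool.sd = TRUE,
                        p.adjust.method = p_adjust)
  list(summary = summ,
       anova = c(F = at$`F value`[1], p = at$`Pr(>F)`[1],
                 df_between = at$Df[1], df_within = at$Df[2]),
       pairwise = pw$p.value)
}

#' Between-group CpG o/e contrasts per GO Slim bin
#'
#' Compares contig-level CpG o/e between two expression-defined contig
#' sets (e.g. contigs expressed in females carrying benthic vs planktonic
#' broods), bin by bin, with a two-sample t-test, and reports which
#' group's mean is higher. Bins present in only one group are skipped and
#' listed in the `skipped` attribute.
#'
#' @param values data frame with columns `bin`, `cpg_oe`, `group` (exactly
#'   two group labels).
#' @param var_equal passed to [stats::t.test()] (default `FALSE`, Welch).
#' @return data frame per shared bin: `bin`, `n_<group>`, `mean_<group>`
#'   columns, `t`, `p_value`, `higher` (group with larger mean).
#' @export
group_contrasts <- function(values, var_equal = FALSE) {
  stopifnot(all(c("bin", "cpg_oe", "group") %in% names(values)))
  values <- values[!is.na(values$cpg_oe), , drop = FALSE]
  gl <- unique(as.character(values$group))
  if (length(gl) != 2L) stop("exactly two groups are required")
  bins <- unique(values$bin)
  shared <- bins[vapply(bins, function(b) {
    all(gl %in% values$group[values$bin == b])
  }, logical(1))]
  rows <- lapply(shared, function(b) {
    a <- values$cpg_oe[values$bin == b & values$group == gl[1]]
    z <- values$cpg_oe[values$bin == b & values$group == gl[2]]
    tt <- t.test(a, z, var.equal = var_equal)
    out <- data.frame(bin = b, n1 = length(a), n2 = length(z),
                      mean1 = mean(a), mean2 = mean(z),
                      t = unname(tt$statistic), p_value = tt$p.value,
                      higher = gl[which.max(c(mean(a), mean(z)))],
                      stringsAsFactors = FALSE)
    names(out)[2:5] <- c(paste0("n_", gl), paste0("mean_", gl))
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no bin is represented in both groups")
  structure(out, skipped = setdiff(bins, shared), groups = gl)
}

#' CpG depletion signature: TpG vs CpG o/e correlation
#'
#' Deamination of methylated CpG produces TpG, so historically methylated
#' sequence shows depleted CpG and enriched TpG: a negative Pearson
#' correlation between the two ratios across contigs is the expected
#' footprint. Also returns distribution summaries (mean and a kernel
#' density table) for all three ratios.
#'
#' @param stats a [contig_oe()] data frame (columns `cpg_oe`, `gpc_oe`,
#'   `tpg_oe`).
#' @return list: `r`, `p_value`, `n` (complete pairs), `means` (named,
#'   over defined values), `density` (long data frame `ratio`, `x`, `y`).
#'   When one variable is constant the correlation is undefined and `r`
#'   and `p_value` are NA.
#' @export
depletion_correlation <- function(stats) {
  ok <- is.finite(stats$cpg_oe) & is.finite(stats$tpg_oe)
  if (sum(ok) < 3L) stop("need at least 3 contigs with defined CpG and TpG o/e")
  x <- stats$tpg_oe[ok]; y <- stats$cpg_oe[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  dens <- do.call(rbind, lapply(c("cpg_oe", "gpc_oe", "tpg_oe"), function(v) {
    vals <- stats[[v]][is.finite(stats[[v]])]
    if (length(vals) < 3L) return(NULL)
    d <- density(vals)
    data.frame(ratio = v, x = d$x, y = d$y, stringsAsFactors = FALSE)
  }))
  list(r = r, p_value = p, n = sum(ok),
       means = c(cpg_oe = mean(stats$cpg_oe[is.finite(stats$cpg_oe)]),
                 gpc_oe = mean(stats$gpc_oe[is.finite(stats$gpc_oe)]),
                 tpg_oe = mean(stats$tpg_oe[is.finite(stats$tpg_oe)])),
       density = dens)
}

#' Read the contig annotation and GO Slim mapping tables
#'
#' `read_contig_annotation` expects a TSV with columns `id`, `has_orf`,
#' `fpkm_benthic`, `fpkm_planktonic`, `fpkm_nonrepro`, `go_bp`
#' (semicolon-separated biological-process GO ids). `read_slim_map`
#' expects columns `go_term`, `slim_bin`.
#'
#' @param file path to a TSV file.
#' @return a data frame.
#' @export
read_contig_annotation <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  needed <- c("id", "has_orf", "go_bp")
  if (!all(needed %in% names(df))) {
    stop("annotation must contain columns: ", paste(needed, collapse = ", "),
         " and fpkm_* columns")
  }
  df$go_bp[is.na(df$go_bp)] <- ""
  df
}

#' @rdname read_contig_annotation
#' @export
read_slim_map <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("go_term", "slim_bin") %in% names(df))) {
    stop("slim map must contain columns go_term, slim_bin")
  }
  df
}
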