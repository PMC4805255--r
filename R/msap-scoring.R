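new_methylation_states <- function(states, groups) {
  structure(states,
            groups = factor(groups, levels = unique(as.character(groups))),
            class = c("methylation_states", "matrix", "array"))
}

#' @export
print.methylation_states <- function(x, ...) {
  cat(sprintf("methylation_states: %d individuals x %d loci\n", nrow(x), ncol(x)))
  tab <- table(factor(x, levels = STATES))
  print(round(tab / sum(tab), 3))
  invisible(x)
}

#' Combine the two digest band matrices into four methylation states
#'
#' Pairs the MspI and HpaII presence calls cellwise into the four band
#' patterns: `1/1` unmethylated, `1/0` internal-cytosine methylation
#' (HpaII blocked), `0/1` unspecific product, `0/0` uninformative (no
#' digestion: hypermethylation or absence of the restriction site). The
#' pairing is lossless; [split_digests()] recovers the original matrices.
#'
#' @param mspI,hpaII a conformable pair of [band_matrix()] objects (same
#'   individuals, same loci, same groups).
#' @return a `methylation_states` character matrix (entries among
#'   `"1/1","1/0","0/1","0/0"`) with a `groups` attribute.
#' @examples
#' sim <- simulate_msap(c(A = 4, B = 4), 6, c(0.25, 0.25, 0.25, 0.25), 0, seed = 2)
#' st <- combine_digests(sim$mspI, sim$hpaII)
#' identical(unclass(st), unclass(sim$true_states))
#' @export
combine_digests <- function(mspI, hpaII) {
  if (!identical(dim(mspI), dim(hpaII)) ||
      !identical(rownames(mspI), rownames(hpaII)) ||
      !identical(colnames(mspI), colnames(hpaII))) {
    stop("the two band matrices must share individuals and loci, in order")
  }
  if (!identical(as.character(attr(mspI, "groups")),
                 as.character(attr(hpaII, "groups")))) {
    stop("the two band matrices must share group labels")
  }
  states <- matrix(paste(mspI, hpaII, sep = "/"), nrow(mspI), ncol(mspI),
                   dimnames = dimnames(mspI))
  new_methylation_states(states, attr(mspI, "groups"))
}

#' @rdname combine_digests
#' @param states a `methylation_states` matrix.
#' @return `split_digests` returns a list with the `mspI` and `hpaII`
#'   [band_matrix()] pair.
#' @export
split_digests <- function(states) {
  msp <- substr(states, 1L, 1L) == "1"
  hpa <- substr(states, 3L, 3L) == "1"
  dim(msp) <- dim(hpa) <- dim(states)
  dimnames(msp) <- dimnames(hpa) <- dimnames(states)
  g <- attr(states, "groups")
  list(mspI = band_matrix(msp + 0L, groups = g, enzyme = "MspI"),
       hpaII = band_matrix(hpa + 0L, groups = g, enzyme = "HpaII"))
}

#' Classify loci as methylation-susceptible (MSL) or nonmethylated (NML)
#'
#' A locus is methylation-susceptible when the proportion of individuals
#' showing a methylated band pattern (`1/0` or `0/1`) exceeds the
#' error-rate threshold (default 5%, strict inequality). The default
#' denominator is the informative individuals (those not `0/0`) at the
#' locus; `denominator = "all"` uses all individuals instead, since
#' scoring tools differ on this convention.
#'
#' @param states a `methylation_states` matrix from [combine_digests()].
#' @param threshold fraction that the methylated proportion must exceed.
#' @param denominator `"informative"` (default) or `"all"`.
#' @return an `msl_partition` data frame with one row per locus: `locus`,
#'   `n_informative`, `prop_methylated`, `class` (`"MSL"`/`"NML"`), plus
#'   the threshold and denominator convention as attributes.
#' @export
classify_msl <- function(states, threshold = 0.05,
                         denominator = c("informative", "all")) {
  denominator <- match.arg(denominator)
  if (!nrow(states) || !ncol(states)) stop("empty state matrix")
  if (nrow(states) < 2L) stop("at least 2 individuals are required")
  meth <- colSums(states == "1/0" | states == "0/1")
  info <- colSums(states != "0/0")
  denom <- if (denominator == "informative") info else rep(nrow(states), ncol(states))
  prop <- ifelse(denom > 0, meth / denom, 0)
  out <- data.frame(locus = colnames(states),
                    n_informative = as.integer(info),
                    prop_methylated = as.numeric(prop),
                    class = ifelse(prop > threshold, "MSL", "NML"),
                    stringsAsFactors = FALSE)
  structure(out, threshold = threshold, denominator = denominator,
            class = c("msl_partition", "data.frame"))
}

new_epilocus_matrix <- function(markers, meta, scheme, groups) {
  structure(markers,
            meta = meta, scheme = scheme,
            groups = factor(groups, levels = unique(as.character(groups))),
            class = c("epilocus_matrix", "matrix", "array"))
}

#' @export
print.epilocus_matrix <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("epilocus_matrix (%s): %d individuals x %d epiloci\n",
              attr(x, "scheme"), nrow(x), ncol(x)))
  if (nrow(meta)) print(table(type = meta$type))
  invisible(x)
}

#' Binary MSL markers (msap-style scoring)
#'
#' One binary epilocus per methylation-susceptible locus: 1 when the
#' individual shows a methylated pattern (`1/0` or `0/1`), 0 when
#' unmethylated (`1/1`). Uninformative cells (`0/0`) become missing by
#' default; `uninformative = "methylated"` scores them 1 instead, the
#' convention of part of the MS-AFLP literature that reads no-digestion as
#' hypermethylation. Nonmethylated loci are excluded.
#'
#' @param states a `methylation_states` matrix.
#' @param partition the [classify_msl()] result for the same states.
#' @param uninformative `"missing"` (default) or `"methylated"`.
#' @return an `epilocus_matrix` (scheme `"MSL"`) of 0/1/NA markers with a
#'   `meta` attribute (epilocus, source locus, type).
#' @export
msl_binary <- function(states, partition,
                       uninformative = c("missing", "methylated")) {
  uninformative <- match.arg(uninformative)
  if (!identical(partition$locus, colnames(states))) {
    stop("'partition' does not match the loci of 'states'")
  }
  keep <- partition$locus[partition$class == "MSL"]
  sub <- states[, keep, drop = FALSE]
  m <- matrix(NA_integer_, nrow(sub), ncol(sub), dimnames = dimnames(sub))
  m[sub == "1/0" | sub == "0/1"] <- 1L
  m[sub == "1/1"] <- 0L
  if (uninformative == "methylated") m[sub == "0/0"] <- 1L
  meta <- data.frame(epilocus = colnames(sub) %||% character(0),
                     locus = colnames(sub) %||% character(0),
                     type = rep("msl-binary", ncol(sub)),
                     stringsAsFactors = FALSE)
  new_epilocus_matrix(m, meta, "MSL", attr(states, "groups"))
}

#' Mixed Scoring 2 epilocus transformation
#'
#' Expands each source locus into up to three binary epiloci, one per
#' observed condition: `u` unmethylated (`1/1`), `m` internal-cytosine
#' methylation (`1/0`), `h` hemimethylation of the external cytosine or
#' unspecific product (`0/1`). An epilocus of a given type is created only
#' when at least one individual anywhere shows that condition. An
#' individual scores 1 at the epilocus matching its state and 0 at the
#' locus's other epiloci; uninformative (`0/0`) individuals score 0 at all
#' of them, so rows stay complete for downstream diversity scripts.
#'
#' @param states a `methylation_states` matrix.
#' @return an `epilocus_matrix` (scheme `"MIXED2"`); `meta` maps each
#'   epilocus to its source locus and type (`u`/`m`/`h`).
#' @export
mixed_scoring2 <- function(states) {
  if (!nrow(states) || !ncol(states)) stop("empty state matrix")
  cond <- c(u = "1/1", m = "1/0", h = "0/1")
  cols <- list(); meta <- list()
  for (j in seq_len(ncol(states))) {
    for (t in names(cond)) {
      hit <- states[, j] == cond[[t]]
      if (any(hit)) {
        nm <- paste0(colnames(states)[j], "_", t)
        cols[[nm]] <- hit + 0L
        meta[[nm]] <- data.frame(epilocus = nm, locus = colnames(states)[j],
                                 type = t, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cols)) {
    m <- matrix(integer(0), nrow(states), 0, dimnames = list(rownames(states), NULL))
    meta_df <- data.frame(epilocus = character(0), locus = character(0),
                          type = character(0), stringsAsFactors = FALSE)
  } else {
    m <- do.call(cbind, cols)
    rownames(m) <- rownames(states)
    meta_df <- do.call(rbind, meta)
    rownames(meta_df) <- NULL
  }
  new_epilocus_matrix(m, meta_df, "MIXED2", attr(states, "groups"))
}

#' Per-group frequencies of the four methylation states at MSL loci
#'
#' For each group, the frequency of each band pattern over all
#' (individual x MSL-locus) cells, in the order `1/1`, `1/0`, `0/1`,
#' `0/0`. Rows sum to 1.
#'
#' @param states a `methylation_states` matrix.
#' @param partition the [classify_msl()] result; only MSL loci enter.
#' @return a groups x 4 numeric matrix of frequencies, columns named by
#'   the state codes.
#' @export
state_frequencies <- function(states, partition) {
  keep <- partition$locus[partition$class == "MSL"]
  if (!length(keep)) stop("no MSL loci: state frequencies undefined")
  sub <- states[, keep, drop = FALSE]
  g <- attr(states, "groups")
  out <- t(vapply(levels(g), function(gl) {
    cells <- sub[g == gl, , drop = FALSE]
    tab <- table(factor(cells, levels = STATES))
    as.numeric(tab / sum(tab))
  }, numeric(4)))
  colnames(out) <- STATES
  out
}

#' Write an epilocus matrix with its metadata as TSV
#'
#' Columns: epilocus id, source locus, type, then one 0/1/NA column per
#' individual (transposed layout keeps the metadata adjacent).
#' @param x an `epilocus_matrix`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_epilocus_matrix <- function(x, file) {
  meta <- attr(x, "meta")
  df <- cbind(meta, as.data.frame(t(unclass(x)), check.names = FALSE))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
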