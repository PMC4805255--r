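#' Construct a band (presence/absence) matrix for one enzyme digest
#'
#' MS-AFLP runs each sample through two parallel restriction digests
#' (EcoRI+MspI and EcoRI+HpaII). Each digest yields, per individual, a
#' presence (1) / absence (0) call for every scored fragment (locus). A
#' `band_matrix` holds one digest: a binary individuals x loci matrix with a
#' group label per individual and the enzyme name.
#'
#' @param presence numeric or integer matrix of 0/1 entries; rows are
#'   individuals, columns are loci. Dimnames are used as individual and
#'   locus ids (defaults are generated when absent).
#' @param groups character or factor of group labels, one per row.
#' @param enzyme `"MspI"` or `"HpaII"`.
#' @return an object of class `band_matrix`: the binary matrix with
#'   attributes `groups` (factor) and `enzyme`.
#' @examples
#' m <- band_matrix(matrix(c(1, 0, 1, 1), 2, 2), groups = c("A", "B"), enzyme = "MspI")
#' @export
band_matrix <- function(presence, groups, enzyme = c("MspI", "HpaII")) {
  enzyme <- match.arg(enzyme)
  presence <- as.matrix(presence)
  if (!all(presence %in% c(0, 1))) {
    stop("band matrix entries must be 0 or 1")
  }
  storage.mode(presence) <- "integer"
  if (length(groups) != nrow(presence)) {
    stop("'groups' must supply one label per individual (row)")
  }
  if (is.null(rownames(presence))) {
    rownames(presence) <- sprintf("ind_%03d", seq_len(nrow(presence)))
  }
  if (is.null(colnames(presence))) {
    colnames(presence) <- sprintf("L%03d", seq_len(ncol(presence)))
  }
  structure(presence,
            groups = factor(groups, levels = unique(as.character(groups))),
            enzyme = enzyme,
            class = c("band_matrix", "matrix", "array"))
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix: %d individuals x %d loci (%s digest)\n",
              nrow(x), ncol(x), attr(x, "enzyme")))
  cat("groups:", paste(sprintf("%s (n=%d)", levels(attr(x, "groups")),
                               table(attr(x, "groups"))), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a band matrix as TSV
#'
#' Layout: one header row of locus ids after the `individual` and `group`
#' columns; one row per individual with 0/1 entries.
#'
#' @param x a [band_matrix()].
#' @param file path of the TSV file.
#' @param enzyme enzyme label to attach when reading.
#' @return `read_band_matrix` returns a [band_matrix()];
#'   `write_band_matrix` returns `file` invisibly.
#' @export
write_band_matrix <- function(x, file) {
  df <- data.frame(individual = rownames(x),
                   group = as.character(attr(x, "groups")),
                   unclass(x), check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_band_matrix
#' @export
read_band_matrix <- function(file, enzyme = c("MspI", "HpaII")) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("individual", "group"))) {
    stop("expected columns: individual, group, then locus ids")
  }
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$individual
  band_matrix(m, groups = df$group, enzyme = match.arg(enzyme))
}

#' @export
groups.band_matrix <- function(x) attr(x, "groups")

#' Group labels of a marker or band container
#' @param x an epimark container carrying per-individual group labels.
#' @return a factor of group labels.
#' @export
groups <- function(x) UseMethod("groups")

#' @export
groups.default <- function(x) attr(x, "groups")
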