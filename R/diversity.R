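marker_types <- function(markers) {
  meta <- attr(markers, "meta")
  if (is.null(meta)) rep("marker", ncol(markers)) else meta$type
}

resolve_groups <- function(markers, groups) {
  g <- groups %||% attr(markers, "groups")
  if (is.null(g)) g <- rep("all", nrow(markers))
  factor(g, levels = unique(as.character(g)))
}

#' Within-group marker polymorphism
#'
#' A marker is polymorphic within a group when both presence (1) and
#' absence (0) occur among the group's non-missing entries. Percentages
#' are over the total markers of the same type.
#'
#' @param markers an `epilocus_matrix` (or 0/1/NA matrix).
#' @param groups optional group factor; defaults to the matrix's `groups`
#'   attribute, or a single pooled group when absent.
#' @return data frame with one row per type x group: `type`, `group`,
#'   `n_markers`, `n_polymorphic`, `pct_polymorphic` (0-100, full
#'   precision; round at render time).
#' @export
polymorphism_summary <- function(markers, groups = NULL) {
  if (!ncol(markers)) stop("at least one marker is required")
  g <- resolve_groups(markers, groups)
  if (any(table(g) == 0)) stop("empty group")
  types <- marker_types(markers)
  out <- list()
  for (ty in unique(types)) {
    m <- markers[, types == ty, drop = FALSE]
    for (gl in levels(g)) {
      sub <- m[g == gl, , drop = FALSE]
      poly <- vapply(seq_len(ncol(sub)), function(j) {
        v <- sub[, j]; v <- v[!is.na(v)]
        length(v) > 0 && any(v == 1) && any(v == 0)
      }, logical(1))
      out[[length(out) + 1L]] <- data.frame(
        type = ty, group = gl, n_markers = ncol(sub),
        n_polymorphic = sum(poly),
        pct_polymorphic = 100 * sum(poly) / ncol(sub),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Private markers per group
#'
#' Under the default per-group reading, a marker is private to a group
#' when presence (1) occurs in that group and in no other group. The
#' per-individual reading (`per = "individual"`) instead calls a marker
#' private when exactly one individual in the whole data set carries the
#' presence allele, attributing it to that individual's group.
#'
#' @inheritParams polymorphism_summary
#' @param per `"group"` (default) or `"individual"`.
#' @return data frame per type x group: `n_private`, `pct_private` over
#'   the type's total marker count.
#' @export
private_markers <- function(markers, groups = NULL, per = c("group", "individual")) {
  per <- match.arg(per)
  g <- resolve_groups(markers, groups)
  if (nlevels(g) < 2L) stop("private markers need at least 2 groups")
  types <- marker_types(markers)
  out <- list()
  for (ty in unique(types)) {
    m <- markers[, types == ty, drop = FALSE]
    pres <- vapply(levels(g), function(gl) {
      colSums(m[g == gl, , drop = FALSE] == 1, na.rm = TRUE)
    }, numeric(ncol(m)))
    if (ncol(m) == 1L) pres <- matrix(pres, nrow = 1L,
                                      dimnames = list(NULL, levels(g)))
    for (gl in levels(g)) {
      here <- pres[, gl]
      elsewhere <- rowSums(pres[, colnames(pres) != gl, drop = FALSE])
      priv <- if (per == "group") {
        here > 0 & elsewhere == 0
      } else {
        here == 1 & elsewhere == 0
      }
      out[[length(out) + 1L]] <- data.frame(
        type = ty, group = gl, n_private = sum(priv),
        pct_private = 100 * sum(priv) / ncol(m),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Mean Shannon information index per group
#'
#' For each marker, with `p` the within-group frequency of presence among
#' non-missing entries, the Shannon information index is
#' `I = -(p log p + (1 - p) log(1 - p))` (natural log, `0 log 0 = 0`),
#' bounded by `log(2) ~ 0.693` for binary markers. The per-group value is
#' the mean of `I` over markers of each type; markers with all entries
#' missing in a group are skipped.
#'
#' @inheritParams polymorphism_summary
#' @return data frame per type x group with column `shannon`.
#' @export
shannon_mean <- function(markers, groups = NULL) {
  g <- resolve_groups(markers, groups)
  types <- marker_types(markers)
  ent <- function(p) {
    q <- 1 - p
    -(ifelse(p > 0, p * log(p), 0) + ifelse(q > 0, q * log(q), 0))
  }
  out <- list()
  for (ty in unique(types)) {
    m <- markers[, types == ty, drop = FALSE]
    for (gl in levels(g)) {
      sub <- m[g == gl, , drop = FALSE]
      p <- colMeans(sub == 1, na.rm = TRUE)   # NaN when all missing
      I <- ent(p[is.finite(p)])
      if (!length(I)) stop("all markers missing for group ", gl)
      out[[length(out) + 1L]] <- data.frame(
        type = ty, group = gl, shannon = mean(I), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Epigenetic diversity report
#'
#' Combines [polymorphism_summary()], [private_markers()] and
#' [shannon_mean()] into one table per marker type and group, the layout
#' used to compare epigenetic diversity among sample groups.
#'
#' @inheritParams private_markers
#' @return data frame: `type`, `group`, `n_markers`,
#'   `pct_polymorphic`, `n_polymorphic`, `pct_private`, `shannon`.
#' @export
diversity_report <- function(markers, groups = NULL, per = c("group", "individual")) {
  a <- polymorphism_summary(markers, groups)
  b <- private_markers(markers, groups, per = per)
  d <- shannon_mean(markers, groups)
  out <- merge(merge(a, b[, c("type", "group", "n_private", "pct_private")],
                     by = c("type", "group"), sort = FALSE),
               d, by = c("type", "group"), sort = FALSE)
  out[order(match(out$type, unique(marker_types(markers))),
            match(out$group, levels(resolve_groups(markers, groups)))), ,
      drop = FALSE]
}
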