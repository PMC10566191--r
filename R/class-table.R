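#' Per-marker genotype class inventory of the entire collection
#'
#' Tabulates, for every marker, the distinct genotype classes observed in the
#' entire collection, their counts and proportions among non-missing calls,
#' the class number `e_i`, and the coverage weight `w_i = 1/(m * e_i)` — the
#' CV increment earned by newly covering one class of marker `i`. Markers
#' with zero non-missing calls carry no class information and are excluded
#' (and reported in `$excluded_markers`); `m` counts included markers only.
#'
#' The table also carries an integer coding of the call grid (`$codes`):
#' cell (i, a) holds the index of accession a's class within marker i's
#' lexicographically sorted class labels, `NA` for missing. All downstream
#' metrics and the selection algorithm work on this coding.
#'
#' @param x A [genotype_matrix()].
#' @return A `class_table` with fields `marker_ids`, `accession_ids`,
#'   `classes` (list of sorted label vectors), `counts`, `props`, `e`, `w`,
#'   `m`, `n_calls`, `codes`, `excluded_markers`.
#' @examples
#' gm <- make_worked_toy()
#' ct <- build_class_table(gm)
#' ct$e[["M_focal"]]          # 3 classes
#' ct$props[["M_focal"]]      # 0.05 0.45 0.50
#' @export
build_class_table <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  keep <- rowSums(!is.na(x)) > 0L
  if (!any(keep)) {
    stop("every marker is entirely missing; no class table can be built",
         call. = FALSE)
  }
  excluded <- rownames(x)[!keep]
  sub <- unclass(x)[keep, , drop = FALSE]
  m <- nrow(sub)
  classes <- counts <- props <- vector("list", m)
  e <- integer(m)
  n_calls <- integer(m)
  codes <- matrix(NA_integer_, m, ncol(sub), dimnames = dimnames(sub))
  for (i in seq_len(m)) {
    row <- sub[i, ]
    obs <- row[!is.na(row)]
    tab <- table(obs)
    labs <- sort(names(tab))
    cnt <- as.integer(tab[labs])
    classes[[i]] <- labs
    counts[[i]] <- stats::setNames(cnt, labs)
    n_calls[i] <- length(obs)
    props[[i]] <- stats::setNames(cnt / length(obs), labs)
    e[i] <- length(labs)
    codes[i, ] <- match(row, labs)
  }
  names(classes) <- names(counts) <- names(props) <- rownames(sub)
  names(e) <- names(n_calls) <- rownames(sub)
  structure(list(
    marker_ids = rownames(sub),
    accession_ids = colnames(sub),
    classes = classes,
    counts = counts,
    props = props,
    e = e,
    w = stats::setNames(1 / (m * e), rownames(sub)),
    m = m,
    n_calls = n_calls,
    codes = codes,
    excluded_markers = excluded
  ), class = "class_table")
}

#' @export
print.class_table <- function(x, ...) {
  cat(sprintf("class_table: %d markers x %d accessions\n", x$m,
              length(x$accession_ids)))
  cat(sprintf("  classes per marker: min %d / median %s / max %d\n",
              min(x$e), format(stats::median(x$e)), max(x$e)))
  if (length(x$excluded_markers)) {
    cat(sprintf("  %d marker(s) excluded (all calls missing)\n",
                length(x$excluded_markers)))
  }
  invisible(x)
}

# Check a class_table was built from (a matrix identical in ids to) `mat`.
check_table_matches <- function(table, mat) {
  if (!identical(table$accession_ids, colnames(mat))) {
    stop("class table does not match the genotype matrix (accession ids differ)",
         call. = FALSE)
  }
  invisible(table)
}
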