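#' Coverage (CV) of a core collection
#'
#' CV is the mean over markers of the fraction of the entire collection's
#' genotype classes that the core retains: `CV = (1/m) * sum_i c_i / e_i`,
#' where `e_i` is the number of classes of marker `i` in the entire
#' collection and `c_i` the number of those classes observed among the
#' core's non-missing calls. Adding an entry never lowers CV.
#'
#' @param core Accession ids or column indices of the core entries; an empty
#'   core has coverage 0.
#' @param x The entire collection, a [genotype_matrix()].
#' @param table Its [build_class_table()] (built on demand when `NULL`).
#' @return CV in `[0, 1]`.
#' @export
coverage <- function(core, x, table = NULL) {
  if (is.null(table)) table <- build_class_table(x)
  check_table_matches(table, x)
  idx <- resolve_core(core, x)
  if (!length(idx)) return(0)
  sub <- table$codes[, idx, drop = FALSE]
  ci <- vapply(seq_len(nrow(sub)), function(i) {
    r <- sub[i, ]
    length(unique(r[!is.na(r)]))
  }, integer(1))
  mean(ci / table$e)
}

#' Base-c Shannon diversity of a core
#'
#' For each marker the Shannon index of the core's class proportions is
#' computed with the logarithm base equal to the marker's entire-collection
#' class number `e_i`, which maps it to `[0, 1]` with 1 meaning perfectly
#' even proportions over all `e_i` classes. Conventions: `0*log(0) = 0`;
#' a monomorphic marker (`e_i = 1`) scores 1 (its single class is trivially
#' even) unless `monomorphic = "exclude"` drops such markers from the mean;
#' a polymorphic marker at which the core has no non-missing call scores 0.
#'
#' @inheritParams coverage
#' @param monomorphic How to treat markers with one class in the entire
#'   collection: score them `"one"` (default) or `"exclude"` them.
#' @return List with `sh` (mean over markers) and `per_marker` (named vector).
#' @export
shannon_index <- function(core, x, table = NULL,
                          monomorphic = c("one", "exclude")) {
  monomorphic <- match.arg(monomorphic)
  if (is.null(table)) table <- build_class_table(x)
  check_table_matches(table, x)
  idx <- resolve_core(core, x)
  if (!length(idx)) stop("core is empty", call. = FALSE)
  sub <- table$codes[, idx, drop = FALSE]
  if (all(is.na(sub))) {
    stop("core has no non-missing calls at any marker", call. = FALSE)
  }
  per <- vapply(seq_len(nrow(sub)), function(i) {
    ei <- table$e[i]
    if (ei == 1L) return(1)
    r <- sub[i, ]
    r <- r[!is.na(r)]
    if (!length(r)) return(0)
    q <- tabulate(r, nbins = ei) / length(r)
    q <- q[q > 0]
    -sum(q * log(q)) / log(ei)
  }, numeric(1))
  names(per) <- table$marker_ids
  use <- if (monomorphic == "exclude") table$e > 1L else rep(TRUE, table$m)
  if (!any(use)) stop("no polymorphic markers to average over", call. = FALSE)
  list(sh = mean(per[use]), per_marker = per)
}

#' Modified Rogers distance between two accessions
#'
#' Each call label is decomposed into allele tokens (a two-character label or
#' an `a/b` label gives two tokens; anything else counts as a single opaque
#' token). Per marker, an accession's dosage vector puts 1 on the allele of
#' a homozygote and 0.5 on each allele of a heterozygote. The distance is
#' `sqrt( sum_i sum_alleles (d_a - d_b)^2 / (2 * m_used) )` over the
#' `m_used` markers where both accessions have calls, which lies in `[0, 1]`.
#'
#' @param a,b Accession ids or column indices (one each).
#' @param x A [genotype_matrix()].
#' @return Distance in `[0, 1]`.
#' @export
modified_rogers_pair <- function(a, b, x) {
  ia <- resolve_core(a, x); ib <- resolve_core(b, x)
  stopifnot(length(ia) == 1L, length(ib) == 1L)
  if (ia == ib) stop("a and b must be distinct accessions", call. = FALSE)
  ca <- unclass(x)[, ia]; cb <- unclass(x)[, ib]
  ok <- !is.na(ca) & !is.na(cb)
  if (!any(ok)) {
    stop("accessions share no marker with calls in both; distance undefined",
         call. = FALSE)
  }
  ca <- ca[ok]; cb <- cb[ok]
  ss <- 0
  for (i in seq_along(ca)) {
    da <- allele_dosage(ca[i]); db <- allele_dosage(cb[i])
    al <- union(names(da), names(db))
    va <- ifelse(al %in% names(da), da[al], 0)
    vb <- ifelse(al %in% names(db), db[al], 0)
    ss <- ss + sum((va - vb)^2)
  }
  sqrt(ss / (2 * sum(ok)))
}

allele_dosage <- function(label) {
  toks <- split_allele_tokens(label)
  if (length(toks) == 2L) {
    if (toks[1] == toks[2]) stats::setNames(1, toks[1])
    else stats::setNames(c(0.5, 0.5), toks)
  } else {
    stats::setNames(1, label)
  }
}

#' Mean modified Rogers distance of a core
#'
#' Arithmetic mean of [modified_rogers_pair()] over all unordered pairs of
#' core entries, computed with a vectorized cross-product formulation
#' (identical to the pairwise definition; asserted in the test suite).
#'
#' @inheritParams coverage
#' @return Mean pairwise distance in `[0, 1]`.
#' @export
mean_modified_rogers <- function(core, x) {
  idx <- resolve_core(core, x)
  if (length(idx) < 2L) {
    stop("mean modified Rogers distance needs at least two entries",
         call. = FALSE)
  }
  D <- mr_pairwise_matrix(x, idx)
  mean(D[lower.tri(D)])
}

# All-pairs MR via crossprods on the (marker, allele) dosage design matrix.
# Missing markers handled pairwise-complete through a validity indicator.
mr_pairwise_matrix <- function(x, idx) {
  sub <- unclass(x)[, idx, drop = FALSE]
  m <- nrow(sub); k <- ncol(sub)
  Vm <- !is.na(sub)             # m x k marker validity
  feat_of_marker <- integer(0)
  Xi <- list()
  for (i in seq_len(m)) {
    labs <- unique(sub[i, !is.na(sub[i, ])])
    if (!length(labs)) next
    dos <- lapply(labs, allele_dosage)
    alleles <- unique(unlist(lapply(dos, names)))
    nf <- length(alleles)
    block <- matrix(0, nf, k)
    for (a in seq_len(k)) {
      lab <- sub[i, a]
      if (is.na(lab)) next
      d <- dos[[match(lab, labs)]]
      block[match(names(d), alleles), a] <- block[match(names(d), alleles), a] + d
    }
    Xi[[length(Xi) + 1L]] <- block
    feat_of_marker <- c(feat_of_marker, rep.int(i, nf))
  }
  if (!length(Xi)) {
    stop("core has no non-missing calls at any marker", call. = FALSE)
  }
  X <- do.call(rbind, Xi)                       # features x k, zeros where missing
  Vf <- Vm[feat_of_marker, , drop = FALSE] * 1  # validity expanded to features
  P <- crossprod(X * X, Vf)                     # sum_f x_af^2 v_bf
  S <- P + t(P) - 2 * crossprod(X)
  Mused <- crossprod(Vm * 1)
  if (any(Mused[lower.tri(Mused)] == 0)) {
    stop("some entry pair shares no marker with calls in both; distance undefined",
         call. = FALSE)
  }
  D <- sqrt(pmax(S, 0) / (2 * Mused))
  diag(D) <- 0
  D
}

#' Rarity score of an accession
#'
#' Quantifies how much an accession contributes rare alleles. With `p_ij`
#' the entire-collection proportion of class `j` at marker `i`, the odds of
#' drawing that class are `eta_ij = p_ij / (1 - p_ij)`; the accession's
#' score is `RS = sum_i 1 / eta_ij* = sum_i (1 - p_ij*) / p_ij*` over its
#' non-missing markers, `j*` being its own class at marker `i`. Markers where
#' the accession is missing contribute 0; a fully common profile (every call
#' in a class of proportion 1) scores 0.
#'
#' @param accession Accession id or column index (scalar or vector; vector
#'   input returns one score per accession).
#' @inheritParams coverage
#' @return Numeric score(s) `>= 0`.
#' @export
rarity_score <- function(accession, x, table = NULL) {
  if (is.null(table)) table <- build_class_table(x)
  check_table_matches(table, x)
  idx <- resolve_core(accession, x)
  prop_list <- table$props
  vapply(idx, function(a) {
    codes <- table$codes[, a]
    s <- 0
    for (i in which(!is.na(codes))) {
      p <- prop_list[[i]][[codes[i]]]
      s <- s + (1 - p) / p
    }
    s
  }, numeric(1))
}

#' Rarest-class proportions per marker
#'
#' For each marker, finds the entire collection's rarest genotype class
#' (minimum proportion, ties broken by lexicographically first label) and
#' reports its proportion in the entire collection and among the core's
#' non-missing calls at that marker (0 when the core lacks the class or has
#' no calls there). This is the diagnostic behind rare-allele enrichment
#' scatter plots.
#'
#' @inheritParams coverage
#' @return A data.frame with columns `marker_id`, `prop_entire`, `prop_core`.
#' @export
rarest_allele_props <- function(core, x, table = NULL) {
  if (is.null(table)) table <- build_class_table(x)
  check_table_matches(table, x)
  idx <- resolve_core(core, x)
  if (!length(idx)) stop("core is empty", call. = FALSE)
  sub <- table$codes[, idx, drop = FALSE]
  res <- vapply(seq_len(table$m), function(i) {
    p <- table$props[[i]]
    j <- which.min(p)       # classes sorted lexicographically, so first tie wins
    r <- sub[i, ]
    r <- r[!is.na(r)]
    core_p <- if (length(r)) sum(r == j) / length(r) else 0
    c(p[[j]], core_p)
  }, numeric(2))
  data.frame(marker_id = table$marker_ids,
             prop_entire = res[1, ],
             prop_core = res[2, ],
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Evaluate a core collection
#'
#' Assembles the standard evaluation report for a core against its entire
#' collection: coverage CV, mean base-c Shannon diversity SH, mean pairwise
#' modified Rogers distance MR (flagged unavailable for singleton cores),
#' the mean per-entry rarity score and its natural logarithm, and the
#' per-marker diagnostics (per-marker SH; rarest-class proportions).
#'
#' @inheritParams coverage
#' @param monomorphic Passed to [shannon_index()].
#' @return An `evaluation_report` list.
#' @export
evaluate_core <- function(core, x, table = NULL,
                          monomorphic = c("one", "exclude")) {
  monomorphic <- match.arg(monomorphic)
  if (is.null(table)) table <- build_class_table(x)
  check_table_matches(table, x)
  idx <- resolve_core(core, x)
  if (!length(idx)) stop("core is empty", call. = FALSE)
  cv <- coverage(idx, x, table)
  sh <- shannon_index(idx, x, table, monomorphic = monomorphic)
  mr_available <- length(idx) >= 2L
  mr <- if (mr_available) mean_modified_rogers(idx, x) else NA_real_
  rs <- rarity_score(idx, x, table)
  rs_mean <- mean(rs)
  structure(list(
    core = colnames(x)[idx],
    core_size = length(idx),
    cv = cv,
    sh = sh$sh,
    mr = mr,
    mr_available = mr_available,
    rs_mean = rs_mean,
    rs_log = log(rs_mean),
    per_entry_rs = stats::setNames(rs, colnames(x)[idx]),
    per_marker_sh = sh$per_marker,
    per_marker_rarest_prop = rarest_allele_props(idx, x, table)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat(sprintf("core evaluation: %d entries\n", x$core_size))
  cat(sprintf("  CV  = %.*f\n", digits, x$cv))
  cat(sprintf("  SH  = %.*f  (base-c Shannon, mean over markers)\n",
              digits, x$sh))
  if (x$mr_available) {
    cat(sprintf("  MR  = %.*f  (mean pairwise modified Rogers)\n",
                digits, x$mr))
  } else {
    cat("  MR  = unavailable (singleton core)\n")
  }
  cat(sprintf("  RS  = %.*f  (mean per-entry rarity), log(RS) = %.*f\n",
              digits, x$rs_mean, digits, x$rs_log))
  invisible(x)
}
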