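# Two-phase core selection: greedy CV covering + rarity-score thickening.
#
# The covering phase is a deterministic greedy: at each iteration the
# accession with the maximal CV gain joins the core. Two operations keep the
# per-iteration cost low without changing the selected sequence:
#   1. once a (marker, class) pair is covered by the core, every cell holding
#      that class is voided (set NA) in the working grid, so a candidate's
#      gain is just a weighted count of its non-NA cells;
#   2. markers whose classes are all covered are dropped from the working
#      grid altogether.
# Equivalence with a naive greedy that re-scores every candidate by full CV
# recomputation is asserted property-style in the test suite.

CV_TOL <- 1e-12

#' Covering phase: greedy coverage maximization
#'
#' Builds a core by repeatedly adding the accession whose inclusion raises CV
#' the most, until `max_cv` is reached (or every accession is selected, or no
#' positive gain remains — only possible at CV = 1). Gains are exact weighted
#' CV increments by default; `gain = "unweighted"` scores candidates by the
#' raw count of their still-uncovered (marker, class) cells instead, which
#' coincides with the weighted rule only when all markers have equal class
#' numbers. Ties (gains equal within 1e-12) go to the accession with fewer
#' missing calls in the input, then to input column order, so identical
#' inputs always give identical cores. The trace records CV after every
#' addition and the `n_p` map records, for every integer coverage percent
#' crossed and for `min_cv`/`max_cv`, the smallest core size attaining it.
#'
#' @param x The entire collection, a [genotype_matrix()].
#' @param table Its [build_class_table()] (built on demand when `NULL`).
#' @param max_cv Target coverage in (0, 1]; selection stops once CV reaches it.
#' @param min_cv Lower coverage threshold in (0, `max_cv`]; recorded in the
#'   `n_p` map for the thickening phase.
#' @param gain `"weighted"` (exact CV gain) or `"unweighted"` (uncovered-cell
#'   count).
#' @param first `"greedy"` picks the first entry by the same maximal-gain rule
#'   as every other iteration; `"min-missing"` picks the accession with the
#'   fewest missing calls.
#' @return A `core_result` with `entries`, `phase`, `trace`, `n_p`,
#'   `reached_max` and the run parameters.
#' @export
select_covering <- function(x, table = NULL, max_cv = 0.99, min_cv = max_cv,
                            gain = c("weighted", "unweighted"),
                            first = c("greedy", "min-missing")) {
  gain <- match.arg(gain)
  first <- match.arg(first)
  check_cv_thresholds(min_cv, max_cv)
  if (is.null(table)) table <- build_class_table(x)
  check_table_matches(table, x)

  n <- ncol(x)
  work <- table$codes                 # active-marker working grid
  w <- table$w                        # CV weight per active marker
  e_left <- table$e                   # classes still uncovered per active marker
  miss_count <- colSums(is.na(unclass(x)))
  selected <- logical(n)
  cv <- 0
  entries <- integer(0)
  trace_cv <- numeric(0)
  trace_gain <- numeric(0)
  n_p <- numeric(0)                   # names = percent thresholds, values = size
  want_pct <- sort(unique(c(1:100, min_cv * 100, max_cv * 100)))
  next_pct <- 1L                      # index into want_pct not yet attained

  repeat {
    if (cv >= max_cv - CV_TOL) break
    if (all(selected)) break
    nonmiss <- !is.na(work)
    gains_cv <- if (nrow(work)) as.numeric(crossprod(nonmiss, w)) else numeric(n)
    score <- if (gain == "weighted") gains_cv else colSums(nonmiss)
    score[selected] <- -Inf
    if (first == "min-missing" && length(entries) == 0L) {
      pick <- order(miss_count, seq_len(n))[1L]
      if (gains_cv[pick] <= 0) {
        # degenerate: that accession covers nothing new; fall back to greedy
        pick <- pick_best(score, miss_count)
      }
    } else {
      pick <- pick_best(score, miss_count)
    }
    if (is.na(pick) || gains_cv[pick] <= 0) break
    step_gain <- gains_cv[pick]
    selected[pick] <- TRUE
    entries <- c(entries, pick)
    cv <- cv + step_gain

    # acceleration 1: void every cell whose (marker, class) is now covered
    sel_codes <- work[, pick]
    newly <- !is.na(sel_codes)
    if (any(newly)) {
      hit <- which(work == sel_codes)  # column-major recycling; NAs drop out
      work[hit] <- NA_integer_
      e_left[newly] <- e_left[newly] - 1L
      # acceleration 2: drop fully covered markers
      done <- e_left == 0L
      if (any(done)) {
        work <- work[!done, , drop = FALSE]
        w <- w[!done]
        e_left <- e_left[!done]
      }
    }
    trace_cv <- c(trace_cv, cv)
    trace_gain <- c(trace_gain, step_gain)
    while (next_pct <= length(want_pct) &&
           cv >= want_pct[next_pct] / 100 - CV_TOL) {
      n_p <- c(n_p, stats::setNames(length(entries),
                                    format_pct(want_pct[next_pct])))
      next_pct <- next_pct + 1L
    }
  }

  reached_max <- cv >= max_cv - CV_TOL
  if (!reached_max) {
    warning("maximum coverage ", max_cv, " not attained (final CV = ",
            signif(cv, 6), "); all useful accessions exhausted", call. = FALSE)
  }
  new_core_result(
    entries = colnames(x)[entries],
    phase = rep("covering", length(entries)),
    trace = data.frame(step = seq_along(entries),
                       accession_id = colnames(x)[entries],
                       cv = trace_cv, gain = trace_gain,
                       phase = "covering", stringsAsFactors = FALSE),
    n_p = n_p,
    reached_max = reached_max,
    params = list(min_cv = min_cv, max_cv = max_cv, gain = gain, first = first)
  )
}

# Argmax with the deterministic tie rule: among scores within 1e-12 of the
# maximum, fewest missing calls first, then lowest input column index.
pick_best <- function(score, miss_count) {
  best <- max(score)
  if (!is.finite(best)) return(NA_integer_)
  tied <- which(score >= best - CV_TOL)
  tied[order(miss_count[tied], tied)][1L]
}

format_pct <- function(p) {
  format(p, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

check_cv_thresholds <- function(min_cv, max_cv) {
  if (!is.numeric(min_cv) || !is.numeric(max_cv) ||
      length(min_cv) != 1L || length(max_cv) != 1L ||
      is.na(min_cv) || is.na(max_cv) ||
      min_cv <= 0 || max_cv > 1 || min_cv > max_cv) {
    stop("coverage thresholds must satisfy 0 < min_cv <= max_cv <= 1",
         call. = FALSE)
  }
  invisible(TRUE)
}

new_core_result <- function(entries, phase, trace, n_p, reached_max, params,
                            report = NULL) {
  structure(list(entries = entries, phase = phase, trace = trace, n_p = n_p,
                 reached_max = reached_max, params = params, report = report),
            class = "core_result")
}

#' @export
print.core_result <- function(x, ...) {
  k <- length(x$entries)
  cat(sprintf("core_result: %d entries (%d covering, %d thickening)\n", k,
              sum(x$phase == "covering"), sum(x$phase == "thickening")))
  if (k) cat(sprintf("  final CV = %.4f\n", x$trace$cv[nrow(x$trace)]))
  if (length(x$n_p)) {
    shown <- utils::tail(x$n_p, 4)
    cat("  n_p:", paste(sprintf("%s%% -> %d", names(shown), shown),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Naive greedy reference selector
#'
#' The same greedy rule as [select_covering()] implemented the slow way: at
#' every iteration each remaining candidate is scored by recomputing the full
#' CV of the augmented core from scratch. Exists as an independent oracle for
#' the accelerated implementation (the two must produce identical entry
#' sequences); intended for small, test-scale inputs only.
#'
#' @inheritParams select_covering
#' @return A `core_result` (covering only).
#' @export
naive_greedy_reference <- function(x, table = NULL, max_cv = 1) {
  check_cv_thresholds(max_cv, max_cv)
  if (is.null(table)) table <- build_class_table(x)
  check_table_matches(table, x)
  n <- ncol(x)
  miss_count <- colSums(is.na(unclass(x)))
  selected <- logical(n)
  entries <- integer(0)
  cv <- 0
  trace_cv <- numeric(0)
  trace_gain <- numeric(0)
  repeat {
    if (cv >= max_cv - CV_TOL || all(selected)) break
    score <- rep(-Inf, n)
    for (a in which(!selected)) {
      score[a] <- coverage(c(entries, a), x, table)
    }
    pick <- pick_best(score, miss_count)
    if (is.na(pick) || score[pick] - cv <= 0) break
    gain_step <- score[pick] - cv
    cv <- score[pick]
    selected[pick] <- TRUE
    entries <- c(entries, pick)
    trace_cv <- c(trace_cv, cv)
    trace_gain <- c(trace_gain, gain_step)
  }
  new_core_result(
    entries = colnames(x)[entries],
    phase = rep("covering", length(entries)),
    trace = data.frame(step = seq_along(entries),
                       accession_id = colnames(x)[entries],
                       cv = trace_cv, gain = trace_gain,
                       phase = "covering", stringsAsFactors = FALSE),
    n_p = numeric(0),
    reached_max = cv >= max_cv - CV_TOL,
    params = list(min_cv = max_cv, max_cv = max_cv, gain = "weighted",
                  first = "greedy")
  )
}

#' Thickening phase: rare-allele enrichment at fixed core size
#'
#' Starting from a covering run that reached `max_cv` with `n_max` entries and
#' attained `min_cv` at `n_min` entries, the thickened core keeps the first
#' `n_min` covering entries and appends the `n_max - n_min` accessions with
#' the highest rarity scores among all accessions outside that truncated core
#' (covering entries beyond `n_min` are eligible again; rarity ties go to
#' input order). The result has the same size as the covering core and its
#' coverage stays at or above `min_cv`.
#'
#' @param covering A `core_result` from [select_covering()].
#' @param x,table The entire collection and its class table.
#' @param min_cv Coverage threshold at which the covering core is truncated;
#'   must have been attained by the covering run.
#' @return A `core_result` with mixed covering/thickening phases.
#' @export
thicken <- function(covering, x, table = NULL, min_cv) {
  stopifnot(inherits(covering, "core_result"))
  if (is.null(table)) table <- build_class_table(x)
  check_table_matches(table, x)
  check_cv_thresholds(min_cv, 1)
  if (min_cv > covering$params$max_cv + CV_TOL) {
    stop("min_cv exceeds the covering run's max_cv", call. = FALSE)
  }
  trace <- covering$trace
  attained <- which(trace$cv >= min_cv - CV_TOL)
  if (!length(attained)) {
    stop("covering run never attained min_cv = ", min_cv,
         "; cannot thicken", call. = FALSE)
  }
  n_min <- attained[1L]
  n_max <- length(covering$entries)
  kept <- covering$entries[seq_len(n_min)]
  n_add <- n_max - n_min
  if (n_add == 0L) {
    out <- covering
    out$params$min_cv <- min_cv
    return(out)
  }
  pool <- setdiff(colnames(x), kept)
  rs <- rarity_score(pool, x, table)
  add <- pool[order(-rs, match(pool, colnames(x)))][seq_len(n_add)]
  entries <- c(kept, add)
  add_cv <- vapply(seq_along(add), function(k) {
    coverage(c(kept, add[seq_len(k)]), x, table)
  }, numeric(1))
  base_cv <- trace$cv[n_min]
  new_rows <- data.frame(step = n_min + seq_len(n_add),
                         accession_id = add,
                         cv = add_cv,
                         gain = diff(c(base_cv, add_cv)),
                         phase = "thickening", stringsAsFactors = FALSE)
  new_core_result(
    entries = entries,
    phase = c(rep("covering", n_min), rep("thickening", n_add)),
    trace = rbind(trace[seq_len(n_min), ], new_rows),
    n_p = covering$n_p,
    reached_max = covering$reached_max,
    params = utils::modifyList(covering$params, list(min_cv = min_cv))
  )
}

#' Two-phase core selection
#'
#' Runs the covering phase up to `max_cv`, then the thickening phase back
#' from `min_cv`, and evaluates both cores. The two cores have the same size
#' `n_max`; the covering core maximizes CV at that size, while the thickened
#' core trades the CV earned between `min_cv` and `max_cv` for the accessions
#' richest in rare alleles, raising Shannon diversity and rarity at a slight
#' coverage cost. Fully deterministic: identical inputs give identical cores.
#'
#' @inheritParams select_covering
#' @param evaluate Compute [evaluate_core()] reports for both cores.
#' @return A `two_phase_result` list with elements `covering` and `thickened`
#'   (each a `core_result` carrying its `evaluation_report` in `$report`).
#' @examples
#' gm <- simulate_panel(simulation_config(n_markers = 60, n_accessions = 40,
#'                                        seed = 7))
#' res <- select_two_phase(gm, min_cv = 0.90, max_cv = 0.95)
#' res$thickened$report$cv
#' @export
select_two_phase <- function(x, min_cv = 0.98, max_cv = 0.99, table = NULL,
                             gain = c("weighted", "unweighted"),
                             first = c("greedy", "min-missing"),
                             evaluate = TRUE) {
  gain <- match.arg(gain)
  first <- match.arg(first)
  check_cv_thresholds(min_cv, max_cv)
  if (is.null(table)) table <- build_class_table(x)
  covering <- select_covering(x, table, max_cv = max_cv, min_cv = min_cv,
                              gain = gain, first = first)
  thickened <- thicken(covering, x, table, min_cv = min_cv)
  if (evaluate) {
    covering$report <- evaluate_core(covering$entries, x, table)
    thickened$report <- evaluate_core(thickened$entries, x, table)
  }
  structure(list(covering = covering, thickened = thickened),
            class = "two_phase_result")
}

#' @export
print.two_phase_result <- function(x, ...) {
  cat("two-phase core selection\n")
  cat(sprintf("  covering core : %d entries", length(x$covering$entries)))
  if (!is.null(x$covering$report)) {
    cat(sprintf("  (CV %.4f, SH %.4f)", x$covering$report$cv,
                x$covering$report$sh))
  }
  cat("\n")
  cat(sprintf("  thickened core: %d entries", length(x$thickened$entries)))
  if (!is.null(x$thickened$report)) {
    cat(sprintf("  (CV %.4f, SH %.4f)", x$thickened$report$cv,
                x$thickened$report$sh))
  }
  cat("\n")
  invisible(x)
}
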