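#' Simulation recipe for a biallelic SNP panel
#'
#' Describes a seeded synthetic genotype panel: marker and accession counts,
#' the minor-allele-frequency spectrum, an inbreeding coefficient controlling
#' heterozygote deficit, a per-cell missingness rate, and optional planted
#' rare-class carriers. Genotypes are drawn per marker under Hardy–Weinberg
#' proportions adjusted for inbreeding F: with minor-allele frequency q and
#' p = 1 - q, P(AA) = p^2 + Fpq, P(AB) = 2pq(1 - F), P(BB) = q^2 + Fpq.
#' The default F = 0.9 mimics the heterozygote-poor panels of selfing crops
#' such as wheat, giving the 2-to-3-classes-per-marker structure that core
#' selection typically operates on.
#'
#' @param n_markers,n_accessions Panel dimensions (both >= 1).
#' @param maf_spectrum Minor-allele-frequency distribution: one of
#'   `list(type = "uniform", lo =, hi =)` (default `uniform(0.05, 0.5)`),
#'   `list(type = "beta", a =, b =)` (scaled to (0, 0.5]), or
#'   `list(type = "fixed", values =)` (recycled over markers).
#' @param inbreeding Inbreeding coefficient F in `[0, 1]`; default 0.9.
#' @param missing_rate Per-cell missingness probability in `[0, 1)`;
#'   default 0.02.
#' @param planted_rares `NULL`, or a data.frame with columns `marker`
#'   (marker index), `carriers` (how many accessions carry the planted class)
#'   and optionally `label` (planted class label, default `"BB"`). At a
#'   planted marker exactly `carriers` accessions carry the class and no
#'   other accession does, so the class frequency is `carriers` divided by
#'   the marker's non-missing calls.
#' @param seed Integer seed; all draws derive from it.
#' @return A validated `simulation_config`.
#' @export
simulation_config <- function(n_markers, n_accessions,
                              maf_spectrum = list(type = "uniform",
                                                  lo = 0.05, hi = 0.5),
                              inbreeding = 0.9,
                              missing_rate = 0.02,
                              planted_rares = NULL,
                              seed = 1L) {
  if (!is.numeric(n_markers) || !is.numeric(n_accessions) ||
      n_markers < 1 || n_accessions < 1) {
    stop("n_markers and n_accessions must be >= 1", call. = FALSE)
  }
  if (!is.list(maf_spectrum) || is.null(maf_spectrum$type) ||
      !maf_spectrum$type %in% c("uniform", "beta", "fixed")) {
    stop("maf_spectrum must be a list of type uniform, beta or fixed",
         call. = FALSE)
  }
  if (maf_spectrum$type == "uniform" &&
      !(maf_spectrum$lo > 0 && maf_spectrum$hi <= 0.5 &&
        maf_spectrum$lo <= maf_spectrum$hi)) {
    stop("uniform MAF bounds must satisfy 0 < lo <= hi <= 0.5", call. = FALSE)
  }
  if (maf_spectrum$type == "fixed" &&
      !(length(maf_spectrum$values) >= 1 && all(maf_spectrum$values > 0) &&
        all(maf_spectrum$values <= 0.5))) {
    stop("fixed MAF values must lie in (0, 0.5]", call. = FALSE)
  }
  if (!is.numeric(inbreeding) || inbreeding < 0 || inbreeding > 1) {
    stop("inbreeding F must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(planted_rares)) {
    planted_rares <- as.data.frame(planted_rares)
    if (!all(c("marker", "carriers") %in% names(planted_rares))) {
      stop("planted_rares needs columns marker and carriers", call. = FALSE)
    }
    if (is.null(planted_rares$label)) planted_rares$label <- "BB"
    if (any(planted_rares$marker < 1) ||
        any(planted_rares$marker > n_markers) ||
        anyDuplicated(planted_rares$marker)) {
      stop("planted_rares marker indices must be unique and within range",
           call. = FALSE)
    }
    if (any(planted_rares$carriers < 1) ||
        any(planted_rares$carriers > n_accessions)) {
      stop("planted carrier counts must lie in [1, n_accessions]",
           call. = FALSE)
    }
  }
  structure(list(n_markers = as.integer(n_markers),
                 n_accessions = as.integer(n_accessions),
                 maf_spectrum = maf_spectrum,
                 inbreeding = inbreeding,
                 missing_rate = missing_rate,
                 planted_rares = planted_rares,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a biallelic SNP genotype panel
#'
#' Draws a markers-by-accessions panel of `"AA"`/`"AB"`/`"BB"` calls under
#' the recipe in `config`. Each marker gets its own sub-stream derived from
#' the global seed, so enlarging `n_markers` never perturbs earlier markers.
#' Missingness is applied per cell; planted rare carriers are written after
#' missingness so they are always present, and the planted class is removed
#' from every non-carrier (replaced by a draw from the remaining classes), so
#' planted class frequencies are exact.
#'
#' @param config A [simulation_config()].
#' @return A [genotype_matrix()] with markers `M0001, ...` and accessions
#'   `ACC0001, ...`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_m <- config$n_markers
  n_a <- config$n_accessions
  set.seed(config$seed)
  marker_seeds <- sample.int(.Machine$integer.max - 1L, n_m)
  planted <- config$planted_rares
  calls <- matrix(NA_character_, n_m, n_a)
  labels <- c("AA", "AB", "BB")
  for (i in seq_len(n_m)) {
    set.seed(marker_seeds[i])
    q <- draw_maf(config$maf_spectrum, i)
    p <- 1 - q
    f <- config$inbreeding
    probs <- c(p * p + f * p * q, 2 * p * q * (1 - f), q * q + f * p * q)
    row <- sample(labels, n_a, replace = TRUE, prob = probs)
    if (config$missing_rate > 0) {
      row[stats::runif(n_a) < config$missing_rate] <- NA_character_
    }
    if (!is.null(planted) && i %in% planted$marker) {
      spec <- planted[planted$marker == i, ]
      carriers <- sample.int(n_a, spec$carriers)
      clash <- which(!is.na(row) & row == spec$label)
      clash <- setdiff(clash, carriers)
      if (length(clash)) {
        repl <- setdiff(labels, spec$label)
        row[clash] <- sample(repl, length(clash), replace = TRUE,
                             prob = probs[match(repl, labels)])
      }
      row[carriers] <- spec$label
    }
    calls[i, ] <- row
  }
  genotype_matrix(calls,
                  marker_ids = sprintf("M%04d", seq_len(n_m)),
                  accession_ids = sprintf("ACC%04d", seq_len(n_a)))
}

draw_maf <- function(spec, i) {
  switch(spec$type,
         uniform = stats::runif(1, spec$lo, spec$hi),
         beta = 0.5 * stats::rbeta(1, spec$a, spec$b),
         fixed = spec$values[(i - 1L) %% length(spec$values) + 1L])
}

#' Worked toy collection
#'
#' A deterministic 100-accession collection whose first marker (`M_focal`)
#' has three genotype classes A, B and C with counts 5, 45 and 50 — the
#' textbook configuration for reasoning about rarity: an A-carrier's rarity
#' term at that marker is (1 - 0.05)/0.05 = 19, and a core of 10 entries
#' holding 1 A, 1 B and 8 C fully covers the marker with a rarest-class core
#' proportion of 0.10. Nine seeded biallelic filler markers complete the
#' panel. [worked_toy_core()] returns such a size-10 core.
#'
#' @return A [genotype_matrix()] of 10 markers x 100 accessions.
#' @export
make_worked_toy <- function() {
  n <- 100L
  focal <- c(rep("A", 5), rep("B", 45), rep("C", 50))
  filler <- simulate_panel(simulation_config(
    n_markers = 9, n_accessions = n, inbreeding = 0.9,
    missing_rate = 0, seed = 20101L))
  calls <- rbind(matrix(focal, nrow = 1), unclass(filler))
  genotype_matrix(calls,
                  marker_ids = c("M_focal", rownames(filler)),
                  accession_ids = colnames(filler))
}

#' @rdname make_worked_toy
#' @return For `worked_toy_core()`: the ids of a 10-entry core carrying 1 A,
#'   1 B and 8 C at the focal marker.
#' @export
worked_toy_core <- function() {
  sprintf("ACC%04d", c(1L, 6L, 51:58))
}
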