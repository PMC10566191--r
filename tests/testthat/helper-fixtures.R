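# Shared fixtures built in code.

# Small genotype matrix with hand-set classes.
toy_matrix <- function() {
  calls <- matrix(c(
    # s1    s2    s3    s4
    "AA",  "AB", "BB", "AA",   # m1: 3 classes
    "AA",  "AA", "AB", NA,     # m2: 2 classes
    "CC",  "CC", "CC", "CC"    # m3: 1 class
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("m1", "m2", "m3"), c("s1", "s2", "s3", "s4")))
  genotype_matrix(calls)
}

# Random categorical panel: no biological structure, 2-4 classes per marker,
# optional missingness. Used for property campaigns.
random_panel <- function(n_markers, n_accessions, missing_rate = 0.1,
                         seed = 1) {
  set.seed(seed)
  calls <- matrix(NA_character_, n_markers, n_accessions)
  for (i in seq_len(n_markers)) {
    k <- sample(2:4, 1)
    labs <- c("AA", "AB", "BB", "CC")[seq_len(k)]
    calls[i, ] <- sample(labs, n_accessions, replace = TRUE)
  }
  calls[matrix(stats::runif(length(calls)) < missing_rate,
               n_markers, n_accessions)] <- NA_character_
  # guarantee no marker all-missing
  for (i in which(rowSums(!is.na(calls)) == 0)) calls[i, 1] <- "AA"
  genotype_matrix(calls,
                  marker_ids = paste0("m", seq_len(n_markers)),
                  accession_ids = paste0("s", seq_len(n_accessions)))
}

# Panel design for the planted-rare-carrier campaigns. Fixed MAF 0.3 and
# moderate inbreeding keep every background class count well above 1, so the
# planted singleton (frequency 1/100) is the unique rarest class and its
# rarity term (99) dominates the spread of baseline rarity scores.
planted_panel_config <- function(seed) {
  simulation_config(
    n_markers = 60, n_accessions = 100, missing_rate = 0,
    maf_spectrum = list(type = "fixed", values = 0.3),
    inbreeding = 0.5,
    planted_rares = data.frame(marker = 5, carriers = 1),
    seed = seed)
}

# Per-definition reference implementations, kept deliberately naive and
# independent of the package internals (they read labels, not codes).
coverage_by_definition <- function(core_idx, gm) {
  calls <- unclass(gm)
  ratios <- apply(calls, 1, function(row) {
    entire <- unique(row[!is.na(row)])
    if (!length(entire)) return(NA_real_)
    core <- row[core_idx]
    core <- unique(core[!is.na(core)])
    length(intersect(core, entire)) / length(entire)
  })
  mean(ratios[!is.na(ratios)])
}

shannon_by_definition <- function(core_idx, gm) {
  calls <- unclass(gm)
  per <- apply(calls, 1, function(row) {
    entire <- unique(row[!is.na(row)])
    e <- length(entire)
    if (e == 0) return(NA_real_)
    if (e == 1) return(1)
    core <- row[core_idx]
    core <- core[!is.na(core)]
    if (!length(core)) return(0)
    q <- table(core) / length(core)
    -sum(q * log(q, base = e))
  })
  mean(per[!is.na(per)])
}

rarity_by_definition <- function(a_idx, gm) {
  calls <- unclass(gm)
  total <- 0
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    obs <- row[!is.na(row)]
    if (!length(obs) || is.na(row[a_idx])) next
    p <- sum(obs == row[a_idx]) / length(obs)
    total <- total + (1 - p) / p
  }
  total
}

# Minimal VCF writer for fixtures.
write_test_vcf <- function(path, records, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
}

vcf_record <- function(chrom, pos, id, gts, ref = "A", alt = "T") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
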