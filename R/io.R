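#' Genotype table dialect
#'
#' Describes the delimited text layout of a genotype table: the field
#' separator, the strings to treat as missing calls, and whether markers are
#' laid out as rows (the native layout: header = accession ids, first column
#' = marker ids) or as columns.
#'
#' @param delimiter Single-character field separator (default tab).
#' @param missing_codes Character vector of cell values read as missing; the
#'   first element is the code written out for missing calls.
#' @param orientation `"markers-as-rows"` (default) or `"markers-as-columns"`.
#' @return A `genotype_dialect` list.
#' @export
genotype_dialect <- function(delimiter = "\t",
                             missing_codes = c("NA", "", "--", "NN", "./.", "."),
                             orientation = c("markers-as-rows",
                                             "markers-as-columns")) {
  if (!is.character(delimiter) || length(delimiter) != 1L ||
      nchar(delimiter) != 1L) {
    stop("delimiter must be a single character", call. = FALSE)
  }
  missing_codes <- as.character(missing_codes)
  if (!length(missing_codes)) {
    stop("missing_codes must be non-empty", call. = FALSE)
  }
  orientation <- match.arg(orientation)
  structure(list(delimiter = delimiter, missing_codes = missing_codes,
                 orientation = orientation), class = "genotype_dialect")
}

#' Read a delimited genotype table
#'
#' Reads a genotype-call table in the delimited layout used by core-selection
#' tools: one header line of identifiers, one identifier column, and
#' categorical genotype calls in the body. All dialect missing codes are
#' normalized to `NA` and the result is oriented markers-by-accessions
#' regardless of the file's orientation.
#'
#' @param path Path to the text file.
#' @param dialect A [genotype_dialect()].
#' @return A [genotype_matrix()].
#' @export
read_genotype_table <- function(path, dialect = genotype_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < 2L) {
    stop("genotype table is empty or has no data rows: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, dialect$delimiter, fixed = TRUE)
  widths <- lengths(fields)
  # strsplit drops a trailing empty field ("a,b," -> 2 fields); pad rows that
  # end in the delimiter so missing last cells survive.
  ends_delim <- endsWith(lines, dialect$delimiter)
  fields[ends_delim] <- lapply(fields[ends_delim], function(f) c(f, ""))
  widths <- lengths(fields)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row %d: %d fields where header has %d",
                 bad, widths[bad], widths[1L]), call. = FALSE)
  }
  if (widths[1L] < 2L) {
    stop("genotype table has no call columns", call. = FALSE)
  }
  header <- fields[[1L]][-1L]
  row_ids <- vapply(fields[-1L], `[[`, character(1), 1L)
  body <- t(vapply(fields[-1L], function(f) f[-1L], character(widths[1L] - 1L)))
  if (widths[1L] == 2L) body <- matrix(body, ncol = 1L)
  body[body %in% dialect$missing_codes] <- NA_character_
  if (dialect$orientation == "markers-as-columns") {
    body <- t(body)
    tmp <- header; header <- row_ids; row_ids <- tmp
  }
  check_unique_ids(row_ids, "marker")
  check_unique_ids(header, "accession")
  genotype_matrix(body, marker_ids = row_ids, accession_ids = header)
}

#' Write a delimited genotype table
#'
#' Inverse of [read_genotype_table()]: the written file reads back to an
#' identical `genotype_matrix` under the same dialect. Missing calls are
#' written as the dialect's first missing code.
#'
#' @param x A [genotype_matrix()].
#' @param path Output path.
#' @param dialect A [genotype_dialect()].
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path, dialect = genotype_dialect()) {
  stopifnot(inherits(x, "genotype_matrix"))
  cells <- unclass(x)
  cells[is.na(cells)] <- dialect$missing_codes[1L]
  if (any(grepl(dialect$delimiter, cells, fixed = TRUE)) ||
      any(grepl(dialect$delimiter, unlist(dimnames(x)), fixed = TRUE))) {
    stop("calls or identifiers contain the delimiter; choose another delimiter",
         call. = FALSE)
  }
  if (dialect$orientation == "markers-as-columns") {
    cells <- t(cells)
    row_ids <- colnames(x); col_ids <- rownames(x)
  } else {
    row_ids <- rownames(x); col_ids <- colnames(x)
  }
  d <- dialect$delimiter
  lines <- c(paste(c("ID", col_ids), collapse = d),
             paste(row_ids, apply(cells, 1L, paste, collapse = d), sep = d))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read genotype classes from a VCF
#'
#' Collapses each sample's GT call at each variant to one categorical
#' genotype class. Phase separators and allele order are ignored: `0/1`,
#' `0|1` and `1|0` all map to the class `"0/1"`. Missing GTs (any `.` allele)
#' become `NA`. Marker identifiers come from the ID column, falling back to
#' `CHROM:POS` where ID is missing.
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @return A [genotype_matrix()] of dimension variants x samples.
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcf@fix
  gt <- vcf@gt
  if (is.null(fix) || nrow(fix) == 0L) {
    stop("VCF contains zero variant records: ", path, call. = FALSE)
  }
  if (is.null(gt) || ncol(gt) < 2L) {
    stop("VCF has no sample genotype columns: ", path, call. = FALSE)
  }
  format <- gt[, 1L]
  gt_pos <- vapply(strsplit(format, ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1))
  if (anyNA(gt_pos)) {
    stop("VCF record without GT in FORMAT (record ",
         which(is.na(gt_pos))[1L], ")", call. = FALSE)
  }
  samples <- colnames(gt)[-1L]
  calls <- matrix(NA_character_, nrow = nrow(gt), ncol = length(samples))
  for (i in seq_len(nrow(gt))) {
    raw <- gt[i, -1L]
    gtf <- vapply(strsplit(raw, ":", fixed = TRUE), function(f) {
      if (length(f) >= gt_pos[i]) f[[gt_pos[i]]] else NA_character_
    }, character(1))
    calls[i, ] <- normalize_gt(gtf)
  }
  ids <- fix[, "ID"]
  fallback <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  ids[is.na(ids) | ids == "." | ids == ""] <- fallback[is.na(ids) | ids == "." | ids == ""]
  check_unique_ids(ids, "marker")
  genotype_matrix(calls, marker_ids = ids, accession_ids = samples)
}

# "0|1" / "1/0" / "0/1" -> "0/1"; any missing allele -> NA.
normalize_gt <- function(gtf) {
  vapply(gtf, function(g) {
    if (is.na(g) || g == "." || g == "") return(NA_character_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (!length(alleles) || any(alleles == ".") || any(!nzchar(alleles))) {
      return(NA_character_)
    }
    paste(sort(alleles), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}
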