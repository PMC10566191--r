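#' Genotype matrix container
#'
#' A genotype matrix is the in-memory representation of an entire germplasm
#' collection: a markers-by-accessions character matrix of categorical
#' genotype calls ("genotype classes", e.g. `"AA"`, `"AB"`, `"BB"` for a
#' biallelic SNP). Row names are marker identifiers, column names are
#' accession identifiers; missing calls are `NA`. Calls are opaque labels:
#' none of the coverage, Shannon or rarity computations interpret them
#' biologically. Heterozygous labels made of exactly two allele tokens are
#' canonicalized by sorting the tokens (`"BA"` becomes `"AB"`, `"1/0"`
#' becomes `"0/1"`) so that equivalent calls always fall into one class.
#'
#' @param calls Character matrix of genotype calls, `NA` for missing.
#' @param marker_ids Marker identifiers (default: `rownames(calls)`).
#' @param accession_ids Accession identifiers (default: `colnames(calls)`).
#' @return An object of class `genotype_matrix`: a character matrix with
#'   unique dimnames and canonicalized call labels.
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c("AA", "AB", "BB", "AA", NA, "BB"), nrow = 3,
#'          dimnames = list(c("m1", "m2", "m3"), c("s1", "s2"))))
#' n_missing(gm)
#' @export
genotype_matrix <- function(calls, marker_ids = rownames(calls),
                            accession_ids = colnames(calls)) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (nrow(calls) < 1L || ncol(calls) < 1L) {
    stop("a genotype matrix needs at least one marker and one accession",
         call. = FALSE)
  }
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(nrow(calls)))
  if (is.null(accession_ids)) accession_ids <- paste0("S", seq_len(ncol(calls)))
  marker_ids <- as.character(marker_ids)
  accession_ids <- as.character(accession_ids)
  if (length(marker_ids) != nrow(calls)) {
    stop("length of marker_ids does not match the number of rows", call. = FALSE)
  }
  if (length(accession_ids) != ncol(calls)) {
    stop("length of accession_ids does not match the number of columns",
         call. = FALSE)
  }
  check_unique_ids(marker_ids, "marker")
  check_unique_ids(accession_ids, "accession")
  calls[!is.na(calls) & calls == ""] <- NA_character_
  calls[] <- canonicalize_calls(calls)
  dimnames(calls) <- list(marker_ids, accession_ids)
  structure(calls, class = c("genotype_matrix", "matrix", "array"))
}

check_unique_ids <- function(ids, what) {
  if (anyNA(ids) || any(ids == "")) {
    stop(sprintf("empty or NA %s identifier", what), call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

#' Canonicalize genotype call labels
#'
#' Labels that decompose into exactly two allele tokens — either two single
#' characters (`"AB"`) or two tokens separated by `/` (`"0/1"`) — are
#' rewritten with the tokens sorted, so allele order and phase never split
#' one genotype class into two. Any other label is kept verbatim.
#'
#' @param x Character vector (or matrix) of call labels.
#' @return `x` with canonical labels.
#' @keywords internal
canonicalize_calls <- function(x) {
  ux <- unique(x[!is.na(x)])
  if (!length(ux)) return(x)
  canon <- vapply(ux, canonicalize_one, character(1), USE.NAMES = FALSE)
  if (all(canon == ux)) return(x)
  out <- canon[match(x, ux)]
  out[is.na(x)] <- NA_character_
  out
}

canonicalize_one <- function(label) {
  toks <- split_allele_tokens(label)
  if (length(toks) != 2L) return(label)
  toks <- sort(toks)
  if (grepl("/", label, fixed = TRUE)) paste(toks, collapse = "/")
  else paste(toks, collapse = "")
}

# Decompose a call label into allele tokens: "a/b" -> two tokens; a
# two-character label -> its characters; anything else is one opaque token.
split_allele_tokens <- function(label) {
  if (grepl("/", label, fixed = TRUE)) {
    toks <- strsplit(label, "/", fixed = TRUE)[[1]]
    if (length(toks) == 2L && all(nzchar(toks))) return(toks)
    return(label)
  }
  if (nchar(label) == 2L) return(strsplit(label, "", fixed = TRUE)[[1]])
  label
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("genotype_matrix", "matrix", "array")
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d accessions (%d missing calls)\n",
              nrow(x), ncol(x), n_missing(x)))
  m <- min(nrow(x), 6L)
  n <- min(ncol(x), 8L)
  print(unclass(x)[seq_len(m), seq_len(n), drop = FALSE], quote = FALSE, ...)
  if (nrow(x) > m || ncol(x) > n) {
    cat(sprintf("... [%d more markers, %d more accessions]\n",
                nrow(x) - m, ncol(x) - n))
  }
  invisible(x)
}

#' Count missing calls
#' @param x A `genotype_matrix`.
#' @return Integer count of missing cells.
#' @export
n_missing <- function(x) sum(is.na(x))

#' Marker and accession identifiers
#' @param x A `genotype_matrix`.
#' @return Character vector of identifiers.
#' @export
marker_ids <- function(x) rownames(x)

#' @rdname marker_ids
#' @export
accession_ids <- function(x) colnames(x)

# Resolve a core given as accession ids or indices into validated column
# indices of `mat`.
resolve_core <- function(core, mat) {
  if (is.character(core)) {
    idx <- match(core, colnames(mat))
    if (anyNA(idx)) {
      stop("unknown accession id(s): ",
           paste(core[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  } else {
    idx <- as.integer(core)
    if (length(idx) && (anyNA(idx) || any(idx < 1L) || any(idx > ncol(mat)))) {
      stop("accession index out of range", call. = FALSE)
    }
  }
  if (anyDuplicated(idx)) stop("duplicate accessions in core", call. = FALSE)
  idx
}
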