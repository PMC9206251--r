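#' Haplotype / nucleotide dataset
#'
#' A rectangular record matrix `D` of `n` sequences by `m` symbols over a
#' small alphabet: bi-allelic haplotypes (`{0,1}`, one SNP value per column)
#' or nucleotides (`{A,C,G,T}`). Rows are the study participants' sequences;
#' columns are aligned positions, so every record has exactly `m` symbols.
#'
#' @param records character vector of sequences, all the same length.
#' @param ids optional unique record labels; defaults to 1-based row numbers.
#' @param alphabet `"binary"`, `"nucleotide"`, or `NULL` to infer from the
#'   symbols present.
#' @return an object of class `haplotype_dataset` with fields `records`,
#'   `ids`, `n`, `m`, `alphabet` (character vector of allowed symbols).
#' @export
haplotype_dataset <- function(records, ids = NULL, alphabet = NULL) {
  if (length(records) < 1L) stop("dataset must contain at least one record (n >= 1)")
  records <- as.character(records)
  m <- nchar(records[1L])
  bad <- which(nchar(records) != m)
  if (length(bad) > 0L) {
    stop(sprintf("length mismatch: record %d has %d symbols, expected %d",
                 bad[1L], nchar(records[bad[1L]]), m))
  }
  if (m < 1L) stop("records must have at least one symbol (m >= 1)")
  syms <- unique(strsplit(paste(records, collapse = ""), "")[[1L]])
  ab <- resolve_alphabet(alphabet, syms)
  if (!all(syms %in% ab)) {
    stop(sprintf("alphabet error: symbol '%s' not in alphabet {%s}",
                 setdiff(syms, ab)[1L], paste(ab, collapse = ",")))
  }
  if (is.null(ids)) ids <- seq_along(records)
  if (anyDuplicated(ids)) stop("record ids must be unique")
  structure(
    list(records = records, ids = ids, n = length(records), m = m, alphabet = ab),
    class = "haplotype_dataset"
  )
}

ALPHABETS <- list(binary = c("0", "1"), nucleotide = c("A", "C", "G", "T"))

resolve_alphabet <- function(alphabet, syms) {
  if (is.null(alphabet)) {
    if (all(syms %in% ALPHABETS$binary)) return(ALPHABETS$binary)
    if (all(syms %in% ALPHABETS$nucleotide)) return(ALPHABETS$nucleotide)
    stop(sprintf("alphabet error: symbols {%s} fit neither {0,1} nor {A,C,G,T}; mixed alphabets are rejected",
                 paste(syms, collapse = ",")))
  }
  if (is.character(alphabet) && length(alphabet) == 1L && alphabet %in% names(ALPHABETS)) {
    return(ALPHABETS[[alphabet]])
  }
  if (is.character(alphabet) && all(alphabet %in% c("0", "1", "A", "C", "G", "T"))) {
    return(sort(alphabet))
  }
  stop("alphabet must be 'binary', 'nucleotide', or NULL")
}

#' @export
print.haplotype_dataset <- function(x, ...) {
  cat(sprintf("haplotype_dataset: n=%d records x m=%d symbols, alphabet {%s}\n",
              x$n, x$m, paste(x$alphabet, collapse = ",")))
  show <- utils::head(seq_len(x$n), 10L)
  for (i in show) cat(sprintf("  [%s] %s\n", x$ids[i], x$records[i]))
  if (x$n > 10L) cat(sprintf("  ... and %d more\n", x$n - 10L))
  invisible(x)
}

#' @export
format.haplotype_dataset <- function(x, ...) {
  sprintf("<haplotype_dataset %dx%d>", x$n, x$m)
}

#' Read a dataset from disk
#'
#' Matrix format: one sequence per line, optional single-character delimiter
#' between symbols, `#`-prefixed comment lines skipped. FASTA: standard
#' headers, sequences may wrap over lines (nucleotide mode).
#'
#' @param path file path.
#' @param format `"matrix"` or `"fasta"`.
#' @param delim optional single-character delimiter stripped from matrix rows.
#' @return a [haplotype_dataset()].
#' @export
load_dataset <- function(path, format = c("matrix", "fasta"), delim = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  if (format == "matrix") {
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    rows <- trimws(lines)
    if (!is.null(delim) && nzchar(delim)) rows <- gsub(delim, "", rows, fixed = TRUE)
    if (length(rows) == 0L) stop(sprintf("no records in %s", path))
    haplotype_dataset(rows)
  } else {
    hdr <- grepl("^>", lines)
    if (!any(hdr)) stop(sprintf("no FASTA headers in %s", path))
    grp <- cumsum(hdr)
    ids <- sub("^>\\s*", "", lines[hdr])
    seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                   function(x) toupper(paste(x, collapse = "")), character(1))
    haplotype_dataset(unname(seqs), ids = ids)
  }
}

#' Write a dataset to disk
#'
#' `load_dataset(write_dataset(d))` round-trips exactly (matrix format keeps
#' 1..n row ids; FASTA keeps the stored ids as headers).
#'
#' @param dataset a [haplotype_dataset()].
#' @param path output file path.
#' @param format `"matrix"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("matrix", "fasta")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "haplotype_dataset"))
  if (dataset$n < 1L) stop("refusing to write an empty dataset (n >= 1)")
  ok <- try(
    if (format == "matrix") {
      writeLines(dataset$records, path)
    } else {
      writeLines(as.vector(rbind(paste0(">", dataset$ids), dataset$records)), path)
    },
    silent = TRUE
  )
  if (inherits(ok, "try-error")) stop(sprintf("failed to write %s: %s", path, attr(ok, "condition")$message))
  invisible(path)
}

#' Generate a synthetic dataset
#'
#' Draws uniform i.i.d. symbols over the alphabet, deterministically for a
#' given seed; optional substrings can be planted verbatim at stated
#' (record, position) to guarantee query hits.
#'
#' @param n,m dataset dimensions (both >= 1).
#' @param alphabet `"binary"` (default) or `"nucleotide"`.
#' @param seed integer seed; the generator is a pure function of its arguments.
#' @param planted optional list of `list(substring, record, position)` entries
#'   (1-based record row and 1-based start column).
#' @return a [haplotype_dataset()].
#' @export
generate_synthetic <- function(n, m, alphabet = "binary", seed = 1L, planted = NULL) {
  stopifnot(n >= 1L, m >= 1L)
  ab <- resolve_alphabet(alphabet, character(0))
  mat <- withr_seed(seed, function() {
    matrix(sample(ab, n * m, replace = TRUE), nrow = n, ncol = m)
  })
  for (p in planted) {
    s <- strsplit(as.character(p[[1L]]), "")[[1L]]
    r <- as.integer(p[[2L]]); pos <- as.integer(p[[3L]])
    if (r < 1L || r > n) stop(sprintf("planted record %d outside 1..%d", r, n))
    if (pos < 1L || pos + length(s) - 1L > m) {
      stop(sprintf("planted span [%d,%d] exceeds m=%d", pos, pos + length(s) - 1L, m))
    }
    if (!all(s %in% ab)) stop("planted substring uses symbols outside the alphabet")
    mat[r, pos:(pos + length(s) - 1L)] <- s
  }
  haplotype_dataset(apply(mat, 1L, paste, collapse = ""))
}

# run fn under a local RNG state so callers' streams are untouched
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# the worked example printed throughout the docs: 5x6 binary matrix
#' The 5x6 example haplotype matrix
#'
#' Five binary records of six SNPs each, used in all worked examples:
#' 100010, 111010, 110001, 010110, 010101.
#'
#' @return a [haplotype_dataset()] with n=5, m=6.
#' @export
example_dataset <- function() {
  haplotype_dataset(c("100010", "111010", "110001", "010110", "010101"))
}
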