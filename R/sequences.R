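#' Sequence roles understood by the pipeline
#' @export
SEQUENCE_ROLES <- c("lncRNA", "mature_miRNA", "utr3")

# internal RNA alphabet: U and T are unified as U on input
.RNA_ALPHABET <- c("A", "C", "G", "U", "N")

#' Construct a sequence set
#'
#' A named collection of nucleotide sequences with a shared role. Sequences
#' are upper-cased and T is normalized to U, so DNA- and RNA-alphabet inputs
#' (arrays, FASTA downloads) coexist. Mature miRNAs must be 18-26 nt long.
#'
#' @param sequences Named character vector of sequences over A/C/G/U/T/N
#'   (case-insensitive).
#' @param role One of `"lncRNA"`, `"mature_miRNA"`, `"utr3"`.
#' @return A named character vector of class `SequenceSet` with a `role`
#'   attribute; sequences are upper-case RNA alphabet.
#' @export
sequence_set <- function(sequences, role) {
  role <- match.arg(role, SEQUENCE_ROLES)
  ids <- names(sequences)
  if (is.null(ids) || any(ids == ""))
    stop("all sequences must be named", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- chartr("T", "U", toupper(as.character(sequences)))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L)
      stop("empty sequence for id '", ids[i], "'", call. = FALSE)
    bad <- regexpr("[^ACGUN]", seqs[i])
    if (bad > 0L)
      stop(sprintf("illegal character '%s' at position %d of sequence '%s'",
                   substr(seqs[i], bad, bad), bad, ids[i]), call. = FALSE)
  }
  if (role == "mature_miRNA") {
    len <- nchar(seqs)
    off <- which(len < 18L | len > 26L)
    if (length(off))
      stop("mature miRNA length outside [18, 26] for id(s): ",
           paste(ids[off], collapse = ", "), call. = FALSE)
  }
  names(seqs) <- ids
  structure(seqs, role = role, class = "SequenceSet")
}

#' @export
print.SequenceSet <- function(x, ...) {
  cat(sprintf("SequenceSet (%s): %d sequence(s), lengths %d-%d\n",
              attr(x, "role"), length(x),
              min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' @export
`[.SequenceSet` <- function(x, i) {
  structure(NextMethod(), role = attr(x, "role"), class = "SequenceSet")
}

#' Read sequences from FASTA
#'
#' Standard (possibly multi-line) FASTA. The record id is the first
#' whitespace-delimited token of the header line.
#'
#' @param path FASTA file path.
#' @param role Sequence role; see [sequence_set()].
#' @return A `SequenceSet`.
#' @export
read_fasta <- function(path, role) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  sequence_set(seqs, role)
}

#' Write a sequence set to FASTA
#' @param x A `SequenceSet` (or named character vector).
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  ids <- names(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", ids[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of an RNA sequence
#'
#' Watson-Crick complement (A-U, C-G) applied base-wise and reversed;
#' N maps to N. Operates on the internal RNA alphabet.
#'
#' @param seq A single sequence string (A/C/G/U/N; T accepted and read as U).
#' @return The reverse complement, 5' to 3'.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("T", "U", toupper(seq))
  if (nchar(s) == 0L) return("")
  bad <- regexpr("[^ACGUN]", s)
  if (bad > 0L)
    stop(sprintf("illegal character '%s' at position %d",
                 substr(s, bad, bad), bad), call. = FALSE)
  comp <- chartr("ACGUN", "UGCAN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# complement without reversal, used for single flanking bases
complement_base <- function(b) chartr("ACGUN", "UGCAN", b)
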