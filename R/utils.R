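#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rpois runif setNames sd
#' @importFrom utils combn head tail write.table read.delim
NULL

# package-level cache (codon tables, pathway memo)
.mhcf_cache <- new.env(parent = emptyenv())

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that deterministic internals (the
#' packaged mock reference, sub-stage seeds) never perturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a global seed
#'
#' Deterministic fan-out of one user-facing seed into independent per-stage
#' seeds. Result always fits in a 32-bit integer.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629 + 1)
}

# IUPAC two-base ambiguity codes (diploid direct-sequencing superposition)
IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
IUPAC2_REV <- local({
  x <- strsplit(names(IUPAC2), "")
  setNames(x, unname(IUPAC2))
})

# full IUPAC base sets, used for primer motifs with degenerate positions
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Reverse complement of a DNA string
#'
#' Handles the IUPAC ambiguity alphabet.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  y <- chartr("ACGTRYKMBVDHacgtrykmbvdh",
              "TGCAYRMKVBHDtgcayrmkvbhd", x)
  vapply(strsplit(y, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' Hamming distance between two equal-length strings
#' @param a,b character scalars of equal length.
#' @return integer number of differing positions.
#' @keywords internal
hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# character matrix from equal-length sequences (rows = sequences)
seq_matrix <- function(seqs) {
  n <- nchar(seqs)
  stopifnot(length(unique(n)) == 1L)
  matrix(unlist(strsplit(seqs, "")), nrow = length(seqs),
         ncol = n[1], byrow = TRUE)
}

# split a CDS string into codon vector
codon_split <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(gsub("-", "-", seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write amplicon reads to FASTQ
#'
#' Quality is constant (the calling model is not quality-aware beyond
#' tie-breaking).
#'
#' @param reads data frame with columns `read_id` and `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads$sequence),
                 function(n) strrep("I", n), "")
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual),
             con)
  invisible(path)
}

# stop unless all names present in a data frame
need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}
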