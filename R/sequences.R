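#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] enforcing the
#' package's sequence contract: ids must be unique and non-empty, records
#' non-empty, and sequences are upper-cased over the alphabet `{A,C,G,T,N}`.
#'
#' @param path file path (plain text FASTA, wrapped or unwrapped).
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(ss))  # id = first token of header
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  check_records(seqs)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  check_records(seqs)
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

check_records <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every sequence record needs a non-empty id")
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    stop("duplicate sequence ids: ", paste(dup, collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty record body for id(s): ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  invisible(seqs)
}

#' Reverse complement
#'
#' Complement mapping A<->T, C<->G, N<->N; `revcomp(revcomp(s)) == s`.
#'
#' @param seq character vector of sequences over `{A,C,G,T,N}`.
#' @return reverse-complemented sequences.
#' @examples
#' revcomp("AAAC")  # "GTTT"
#' @export
revcomp <- function(seq) {
  if (any(grepl("[^ACGTN]", seq)))
    stop("revcomp: sequence contains characters outside {A,C,G,T,N}")
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  out
}

#' Read a primer table
#'
#' TSV with header columns `name`, `fwd`, `rev`. Forward primers are written
#' 5'->3' on the sense strand; reverse primers 5'->3' on the antisense
#' strand (so a reverse primer anneals where its reverse complement occurs
#' on the sense strand).
#'
#' @param path TSV path.
#' @return data.frame with columns `name`, `fwd`, `rev`.
#' @export
read_primer_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "fwd", "rev")
  if (!all(need %in% names(df)))
    stop("primer TSV needs columns: ", paste(need, collapse = ", "))
  df$fwd <- toupper(df$fwd); df$rev <- toupper(df$rev)
  short <- nchar(df$fwd) < 15L | nchar(df$rev) < 15L
  if (any(short))
    stop("primers shorter than 15 nt: ", paste(df$name[short], collapse = ", "))
  df[need]
}

# Seeded uniform random DNA (generator internals share this).
random_dna <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Apply substitution mutations at the given per-base rate; never introduces
# indels, never mutates to the same base.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# substring by 0-based half-open coordinates
substr0 <- function(seq, start, end) substr(seq, start + 1L, end)
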