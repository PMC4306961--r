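# Sequence I/O and small DNA utilities. File parsing goes through Biostrings;
# these wrappers add the strict IUPAC validation the downstream filters rely on.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

is_iupac <- function(x) {
  !grepl(sprintf("[^%s]", paste(names(IUPAC_CODES), collapse = "")),
         toupper(x))
}

#' Read amplicon sequences from FASTA or FASTQ
#'
#' Reads all records of a FASTA or FASTQ file in file order. Qualities are
#' discarded; sequences are upper-cased. Any record containing a character
#' outside the IUPAC nucleotide alphabet is a parse error that names the
#' offending record.
#'
#' @param path Path to the sequence file.
#' @param format Either \code{"fasta"} or \code{"fastq"}.
#' @return A data.frame with columns \code{read_id} (first whitespace-separated
#'   token of the header) and \code{sequence}, one row per record, in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGT", ">r2", "GGCC"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read sequence file: '", path, "' does not exist")
  }
  bad <- NULL
  res <- tryCatch(
    withCallingHandlers(
      Biostrings::readDNAStringSet(path, format = format),
      warning = function(w) {
        # Biostrings drops invalid letters with a warning; we treat them as a
        # parse error and locate the record ourselves.
        if (grepl("invalid one-letter sequence", conditionMessage(w))) {
          bad <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    ),
    error = function(e) {
      stop("malformed ", format, " file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (isTRUE(bad)) {
    idx <- find_invalid_record(path, format)
    stop("parse error in '", path, "': record ", idx,
         " contains non-IUPAC characters", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(res))
  out <- data.frame(
    read_id = if (length(res)) ids else character(0),
    sequence = toupper(as.character(res)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  bad_chr <- which(!is_iupac(out$sequence))
  if (length(bad_chr)) {
    stop("parse error in '", path, "': record ", bad_chr[1],
         " contains non-IUPAC characters", call. = FALSE)
  }
  out
}

# locate first record with a non-IUPAC character (1-based record index)
find_invalid_record <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  if (format == "fasta") {
    rec <- cumsum(startsWith(lines, ">"))
    seq_lines <- !startsWith(lines, ">")
    bad <- !is_iupac(lines) & seq_lines & nzchar(lines)
    if (any(bad)) return(rec[which(bad)[1]])
  } else {
    seq_idx <- seq(2, length(lines), by = 4)
    bad <- which(!is_iupac(lines[seq_idx]))
    if (length(bad)) return(bad[1])
  }
  NA_integer_
}

#' Write sequences to FASTA
#'
#' @param ids Character vector of record ids.
#' @param sequences Character vector of sequences (same length as \code{ids}).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' IUPAC-aware reverse complement (e.g. the complement of Y is R). Applying it
#' twice returns the input.
#'
#' @param seq A DNA string (IUPAC codes allowed). Vectorised.
#' @return The reverse complement, upper-cased.
#' @examples
#' reverse_complement("AAC") # "GTT"
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  ok <- is_iupac(seq)
  if (!all(ok)) {
    stop("non-IUPAC character in sequence: '", seq[which(!ok)[1]], "'")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# translate an IUPAC primer into a regular expression where degenerate codes
# match any base of their set (Y -> [CT], ...)
iupac_regex <- function(primer) {
  chars <- strsplit(toupper(primer), "")[[1]]
  sets <- IUPAC_CODES[chars]
  if (anyNA(sets)) stop("non-IUPAC character in primer: '", primer, "'")
  paste(ifelse(nchar(sets) == 1, sets, paste0("[", sets, "]")), collapse = "")
}

# draw n concrete realisations of a degenerate primer (for read simulation);
# degenerate positions are sampled independently per read
realize_iupac_many <- function(primer, n) {
  primer <- toupper(primer)
  chars <- strsplit(primer, "")[[1]]
  sets <- IUPAC_CODES[chars]
  deg <- which(nchar(sets) > 1)
  if (!length(deg) || n == 0L) return(rep(primer, n))
  cols <- matrix(rep(chars, each = n), nrow = n)
  for (j in deg) {
    cols[, j] <- sample(strsplit(sets[[j]], "")[[1]], n, replace = TRUE)
  }
  do.call(paste0, split(cols, col(cols)))
}
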