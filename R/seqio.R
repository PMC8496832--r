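# Sequence I/O, one-hot encoding and trimming/padding conventions.
#
# Channel order is fixed as A, C, G, T everywhere in the package; coordinates
# are 0-based half-open internally and 1-based inclusive only in user-facing
# messages and files.

# IUPAC ambiguity codes -> compatible base sets (uniform fractional encoding).
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.base_channels <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# 16 x 4 row-lookup table, rows named by IUPAC code.
.iupac_matrix <- local({
  m <- matrix(0, nrow = length(.iupac_sets), ncol = 4,
              dimnames = list(names(.iupac_sets), names(.base_channels)))
  for (code in names(.iupac_sets)) {
    bases <- .iupac_sets[[code]]
    m[code, .base_channels[bases]] <- 1 / length(bases)
  }
  m
})

#' One-hot encode a nucleotide sequence
#'
#' Encodes a read as a \code{target_length x 4} numeric matrix on the fixed
#' channel order A, C, G, T. Unambiguous bases map to unit vectors; IUPAC
#' ambiguity codes map to the uniform distribution over their compatible
#' bases (so \code{N} becomes \code{(0.25, 0.25, 0.25, 0.25)}). Positions
#' beyond the end of the sequence are zero vectors (right-padding), the
#' convention used to bring variable-length reads to a common length.
#' Lowercase input is uppercased and \code{U} is treated as \code{T}.
#'
#' @param sequence Nucleotide string over the IUPAC alphabet.
#' @param target_length Number of rows of the returned matrix; must be at
#'   least 1 and at least \code{nchar(sequence)}.
#' @return A \code{target_length x 4} matrix with columns named A, C, G, T.
#'   Every row sums to exactly 1 (a real base) or exactly 0 (padding).
#' @examples
#' one_hot_encode("ACGT", 4)
#' one_hot_encode("AC", 4)    # two encoded rows, two zero rows
#' one_hot_encode("R", 1)     # 0.5 on A and G
#' @export
one_hot_encode <- function(sequence, target_length) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  target_length <- as.integer(target_length)
  if (is.na(target_length) || target_length < 1L)
    stop("`target_length` must be a positive integer")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) stop("`sequence` must be non-empty")
  if (n > target_length)
    stop(sprintf("sequence length %d exceeds target_length %d", n, target_length))
  bad <- which(!chars %in% rownames(.iupac_matrix))
  if (length(bad))
    stop(sprintf("non-IUPAC character '%s' at position %d", chars[bad[1]], bad[1]))
  out <- matrix(0, nrow = target_length, ncol = 4,
                dimnames = list(NULL, names(.base_channels)))
  out[seq_len(n), ] <- .iupac_matrix[chars, , drop = FALSE]
  out
}

#' Trim a read to a fixed window
#'
#' Removes the first \code{offset} bases and keeps the next \code{length}
#' bases (e.g. \code{offset = 10, length = 160} drops the first 10 bases and
#' keeps the following 160). If fewer than \code{length} bases remain the
#' shorter remainder is returned as-is; zero-padding to a common length is
#' deferred to \code{\link{one_hot_encode}}.
#'
#' @param sequence Nucleotide string.
#' @param offset Number of leading bases to discard (non-negative).
#' @param length Number of bases to keep after the offset (positive).
#' @return The trimmed nucleotide string.
#' @examples
#' trim_read("AACCGGTT", offset = 2, length = 4)  # "CCGG"
#' @export
trim_read <- function(sequence, offset = 0L, length) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  offset <- as.integer(offset); len <- as.integer(length)
  if (is.na(offset) || offset < 0L) stop("`offset` must be non-negative")
  if (is.na(len) || len < 1L) stop("`length` must be a positive integer")
  n <- nchar(sequence)
  if (offset + 1L > n)
    stop(sprintf("offset %d is beyond the sequence end (length %d)", offset, n))
  substr(sequence, offset + 1L, min(offset + len, n))
}

#' Read a sample metadata table
#'
#' Expects a tab-separated file with header columns \code{sample_id},
#' \code{label} and (optionally) \code{split} with values \code{train} or
#' \code{test}; a missing split column defaults every sample to
#' \code{train}.
#'
#' @param path Path to the metadata TSV.
#' @return A data.frame with columns \code{sample_id}, \code{label},
#'   \code{split}.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "label")
  if (!all(need %in% names(md)))
    stop("metadata must have columns `sample_id` and `label` (tab-separated)")
  if (!"split" %in% names(md)) md$split <- "train"
  if (anyDuplicated(md$sample_id))
    stop(sprintf("duplicate sample_id in metadata: %s",
                 md$sample_id[duplicated(md$sample_id)][1]))
  bad <- !md$split %in% c("train", "test")
  if (any(bad))
    stop(sprintf("split must be 'train' or 'test' (sample %s has '%s')",
                 md$sample_id[bad][1], md$split[bad][1]))
  md[, c("sample_id", "label", "split")]
}

# Read one FASTA/FASTQ file into a named character vector of sequences.
.read_seq_file <- function(path) {
  first <- readLines(path, n = 1L)
  set <- if (startsWith(first, "@")) {
    Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    Biostrings::readDNAStringSet(path, format = "fasta")
  }
  seqs <- as.character(set)
  # keep only the id token of the header line
  names(seqs) <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  seqs
}

#' Load an amplicon dataset
#'
#' Reads demultiplexed FASTA or FASTQ files (one file per sample, or any
#' partition of reads across files) together with a sample metadata TSV.
#' Sample membership is taken from the file-to-sample map; FASTQ qualities
#' are ignored (the pipeline expects already-filtered reads). Record order is
#' deterministic: files in the given order, reads in file order.
#'
#' @param read_files Character vector of FASTA/FASTQ paths.
#' @param metadata Path to a metadata TSV (see \code{\link{read_metadata}})
#'   or an already-loaded metadata data.frame.
#' @param sample_map Optional character vector mapping each file to a
#'   sample_id (same length as \code{read_files}). Defaults to the file base
#'   name without extension.
#' @return A list with \code{reads} (data.frame: \code{read_id},
#'   \code{sequence}, \code{sample_id}) and \code{metadata}. Per-sample read
#'   counts are reported via \code{message()}.
#' @export
load_dataset <- function(read_files, metadata, sample_map = NULL) {
  md <- if (is.character(metadata)) read_metadata(metadata) else metadata
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample ids in metadata")
  if (is.null(sample_map)) {
    sample_map <- sub("\\.(fasta|fa|fna|fastq|fq)$", "",
                      basename(read_files), ignore.case = TRUE)
  }
  stopifnot(length(sample_map) == length(read_files))
  unknown <- setdiff(sample_map, md$sample_id)
  if (length(unknown))
    stop(sprintf("reads map to sample '%s' which is absent from the metadata",
                 unknown[1]))
  parts <- lapply(seq_along(read_files), function(i) {
    seqs <- .read_seq_file(read_files[i])
    data.frame(read_id = names(seqs), sequence = unname(seqs),
               sample_id = sample_map[i], stringsAsFactors = FALSE)
  })
  reads <- do.call(rbind, parts)
  counts <- table(factor(reads$sample_id, levels = unique(sample_map)))
  message(paste(sprintf("%s: %d reads", names(counts), as.integer(counts)),
                collapse = "; "))
  list(reads = reads, metadata = md)
}

#' Group sequences into padded-length buckets
#'
#' Assigns each sequence to the smallest multiple of \code{bucket_size} that
#' is at least its length, then one-hot encodes each bucket to that common
#' length (shorter sequences are right-padded with zero vectors). A sequence
#' of length 1001 with the default bucket size therefore lands in the
#' 1100-base bucket. Used to train variable-length sequence sets bucket by
#' bucket.
#'
#' @param sequences Character vector of nucleotide strings.
#' @param bucket_size Bucket granularity in bases (default 100).
#' @return A named list; element \code{"L"} holds \code{list(length = L,
#'   indices = <positions in `sequences`>, encoded = <n x L x 4 array>)}.
#'   Empty input gives an empty list.
#' @export
bucket_by_length <- function(sequences, bucket_size = 100L) {
  bucket_size <- as.integer(bucket_size)
  if (is.na(bucket_size) || bucket_size < 1L)
    stop("`bucket_size` must be a positive integer")
  if (length(sequences) == 0L) return(list())
  lens <- nchar(sequences)
  bucket <- as.integer(ceiling(lens / bucket_size) * bucket_size)
  out <- list()
  for (L in sort(unique(bucket))) {
    idx <- which(bucket == L)
    enc <- array(0, dim = c(length(idx), L, 4L))
    for (j in seq_along(idx))
      enc[j, , ] <- one_hot_encode(sequences[idx[j]], L)
    out[[as.character(L)]] <- list(length = L, indices = idx, encoded = enc)
  }
  out
}

#' Encode a set of equal-bucket reads as a 3-D array
#'
#' Convenience wrapper stacking \code{\link{one_hot_encode}} over a vector of
#' sequences into an \code{n x T x 4} array.
#'
#' @param sequences Character vector.
#' @param target_length Common encoded length \code{T}.
#' @return An \code{n x T x 4} numeric array.
#' @export
encode_reads <- function(sequences, target_length) {
  n <- length(sequences)
  out <- array(0, dim = c(n, as.integer(target_length), 4L))
  for (i in seq_len(n)) out[i, , ] <- one_hot_encode(sequences[i], target_length)
  out
}
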