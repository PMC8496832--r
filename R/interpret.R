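# Interpretation suite: per-position Shannon entropy, entropy-scaled class
# sequence logos, class-wise mean attention with moving-average smoothing,
# attention mapped onto multiple-sequence-alignment coordinates, and
# per-variable-region attention budgets.

.BASES <- c("A", "C", "G", "T")

# Per-position base-count matrix (L x 4) over equal-length sequences.
# Positions are normalized over the observed A/C/G/T only: gaps and
# ambiguity codes at a position are excluded from that position's counts.
.base_counts <- function(sequences) {
  L <- unique(nchar(sequences))
  if (length(L) != 1L)
    stop("sequences must all have the same length")
  m <- matrix(unlist(strsplit(toupper(sequences), "", fixed = TRUE)),
              ncol = L, byrow = TRUE)
  counts <- sapply(.BASES, function(b) colSums(m == b))
  if (L == 1L) counts <- rbind(counts)
  dimnames(counts) <- list(NULL, .BASES)
  counts
}

#' Per-position Shannon entropy profile
#'
#' For a group of equal-length reads, estimates the base distribution
#' p(b, l) at every position l by the normalized nucleotide frequency
#' f(b, l), and computes the Shannon entropy in bits,
#' H(l) = -sum_b f(b,l) log2 f(b,l), with 0*log2(0) = 0. H is 0 at a
#' perfectly conserved position and 2 bits when the four bases are
#' equifrequent. Characters outside A/C/G/T are excluded from the counts at
#' their position.
#'
#' @param sequences Character vector of equal-length reads.
#' @return A list of class \code{ampatt_entropy}: \code{H} (length-L vector,
#'   bits), \code{freqs} (L x 4 matrix, rows summing to 1 wherever any base
#'   was observed), \code{n_reads} (observations per position).
#' @export
entropy_profile <- function(sequences) {
  if (length(sequences) < 1L) stop("need at least one sequence")
  counts <- .base_counts(sequences)
  n <- rowSums(counts)
  freqs <- counts / ifelse(n > 0, n, NA_real_)
  plogp <- ifelse(is.na(freqs) | freqs == 0, 0, freqs * log2(freqs))
  H <- -rowSums(plogp)
  structure(list(H = H, freqs = freqs, n_reads = n),
            class = "ampatt_entropy")
}

#' Entropy-scaled class sequence logo
#'
#' Letter heights for phenotype class c are S_c(b, l) = f_c(b, l) * H(l):
#' the class-conditional base frequency scaled by the pooled (all-class)
#' entropy at that position. Heights therefore stack to the overall H(l) in
#' every class, and vanish wherever the pooled column is conserved — the
#' logo highlights variable positions and shows which base each class
#' prefers there.
#'
#' @param sequences Character vector of equal-length reads (the pooled set).
#' @param class_labels Class label per read.
#' @param H Optional precomputed \code{\link{entropy_profile}} of the pooled
#'   set; computed if omitted.
#' @param classes Which classes to include (default: all observed, sorted).
#' @return A list of class \code{ampatt_logo}: \code{S} and
#'   \code{class_freqs} (both class x L x 4 arrays), \code{classes},
#'   \code{H}.
#' @export
class_logo <- function(sequences, class_labels, H = NULL, classes = NULL) {
  class_labels <- as.character(class_labels)
  stopifnot(length(sequences) == length(class_labels))
  if (is.null(classes)) classes <- sort(unique(class_labels))
  missing_cls <- setdiff(classes, class_labels)
  if (length(missing_cls))
    stop(sprintf("class '%s' has no reads", missing_cls[1]))
  if (is.null(H)) H <- entropy_profile(sequences)
  L <- length(H$H)
  S <- array(0, dim = c(length(classes), L, 4L),
             dimnames = list(classes, NULL, .BASES))
  cf <- S
  for (ci in seq_along(classes)) {
    ep <- entropy_profile(sequences[class_labels == classes[ci]])
    f <- ep$freqs
    f[is.na(f)] <- 0
    cf[ci, , ] <- f
    S[ci, , ] <- f * H$H
  }
  structure(list(S = S, class_freqs = cf, classes = classes, H = H),
            class = "ampatt_logo")
}

#' Class-wise mean attention
#'
#' Averages per-read attention vectors within each class, either by the
#' model's predicted label (the usual choice for phenotype models, where a
#' read's true habitat is ambiguous) or by the true label (natural for
#' taxonomic models where each sequence has one genus). Since every
#' attention vector sums to 1, each class row also sums to 1.
#'
#' @param attention_vectors A reads x L matrix (or list of length-L
#'   vectors).
#' @param labels Per-read class labels under the chosen grouping.
#' @param grouping Either \code{"predicted_label"} or \code{"true_label"};
#'   purely descriptive metadata recording which labels were passed.
#' @param window Smoothing window for the \code{smoothed} rows (odd,
#'   default 9, the convolution window).
#' @return A list of class \code{ampatt_attention_summary}: \code{A}
#'   (class x L mean attention), \code{smoothed} (same, after
#'   \code{\link{smooth_attention}}), \code{classes}, \code{n_reads},
#'   \code{grouping}, \code{window}. Classes with zero reads are omitted
#'   with a warning.
#' @export
mean_attention <- function(attention_vectors, labels,
                           grouping = c("predicted_label", "true_label"),
                           window = 9L) {
  grouping <- match.arg(grouping)
  if (is.list(attention_vectors))
    attention_vectors <- do.call(rbind, attention_vectors)
  labels <- as.character(labels)
  stopifnot(nrow(attention_vectors) == length(labels))
  classes <- sort(unique(labels))
  A <- t(sapply(classes, function(cl)
    colMeans(attention_vectors[labels == cl, , drop = FALSE])))
  n_reads <- as.integer(table(factor(labels, levels = classes)))
  sm <- t(apply(A, 1L, smooth_attention, window = window))
  rownames(A) <- rownames(sm) <- classes
  structure(list(A = A, smoothed = sm, classes = classes, n_reads = n_reads,
                 grouping = grouping, window = as.integer(window)),
            class = "ampatt_attention_summary")
}

#' Moving-average smoothing of an attention vector
#'
#' Centered moving average of odd window size (default 9, matching the
#' convolutional window, so the smoothed profile reflects what a filter can
#' see). At the edges the window truncates to the available positions, so
#' the output has the same length as the input.
#'
#' @param vector Numeric vector (length L).
#' @param window Odd window size, at most L.
#' @return Smoothed numeric vector of length L.
#' @export
smooth_attention <- function(vector, window = 9L) {
  window <- as.integer(window)
  L <- length(vector)
  if (window %% 2L == 0L) stop("`window` must be odd")
  if (window > L) stop("`window` must not exceed the vector length")
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, vector))
  lo <- pmax(seq_len(L) - half, 1L)
  hi <- pmin(seq_len(L) + half, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Map attention vectors onto alignment coordinates
#'
#' Given an externally produced multiple sequence alignment of the same
#' reads (gap character \code{-}), places the attention value of each
#' original (ungapped) position at the alignment column holding that
#' residue. A sequence's gap columns are undefined (NA) for that sequence,
#' and the per-column mean averages the defined entries only — so insertions
#' and deletions no longer blur attention peaks across sequences.
#'
#' @param aligned An aligned FASTA path, or a named character vector of
#'   aligned (gapped) sequences.
#' @param attention_by_id Named list: sequence id -> attention vector whose
#'   length equals that sequence's ungapped length.
#' @return A list of class \code{ampatt_aligned_attention}:
#'   \code{per_sequence} (n x L_aln matrix with NA at gaps),
#'   \code{column_mean} (length L_aln), \code{n_defined} (sequences defined
#'   per column), \code{alignment_length}.
#' @export
align_attention <- function(aligned, attention_by_id) {
  if (is.character(aligned) && length(aligned) == 1L && file.exists(aligned)) {
    ss <- Biostrings::readBStringSet(aligned)
    seqs <- as.character(ss)
    names(seqs) <- vapply(strsplit(names(ss), "[ \t]"), `[[`, "", 1L)
    aligned <- seqs
  }
  ids <- names(attention_by_id)
  missing_ids <- setdiff(ids, names(aligned))
  if (length(missing_ids))
    stop(sprintf("sequence '%s' not found in the alignment", missing_ids[1]))
  L_aln <- unique(nchar(aligned[ids]))
  if (length(L_aln) != 1L) stop("aligned sequences must share one length")
  per_seq <- matrix(NA_real_, length(ids), L_aln, dimnames = list(ids, NULL))
  for (id in ids) {
    chars <- strsplit(aligned[[id]], "", fixed = TRUE)[[1]]
    res_cols <- which(chars != "-")
    att <- attention_by_id[[id]]
    if (length(res_cols) != length(att))
      stop(sprintf(
        "sequence '%s': ungapped length %d does not match attention length %d",
        id, length(res_cols), length(att)))
    per_seq[id, res_cols] <- att
  }
  n_def <- colSums(!is.na(per_seq))
  col_mean <- colMeans(per_seq, na.rm = TRUE)
  col_mean[n_def == 0L] <- NA_real_
  structure(list(per_sequence = per_seq, column_mean = col_mean,
                 n_defined = n_def, alignment_length = L_aln),
            class = "ampatt_aligned_attention")
}

#' Read a variable-region breakpoint table
#'
#' Tab-separated file with header \code{name<TAB>start<TAB>end}, coordinates
#' 1-based inclusive (the convention of published 16S variable-region
#' tables, V1..V9).
#'
#' @param path TSV path.
#' @return A data.frame with columns \code{name}, \code{start}, \code{end}.
#' @export
read_regions <- function(path) {
  rg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "start", "end")
  if (!all(need %in% names(rg)))
    stop("region table must have columns name, start, end")
  rg$start <- as.integer(rg$start); rg$end <- as.integer(rg$end)
  if (any(rg$end < rg$start)) stop("region end before start")
  rg[order(rg$start), need]
}

#' Sum attention per variable region
#'
#' Sums mean attention weights within each named region (e.g. the 16S
#' hypervariable regions V1..V9), per class/genus row. Regions are 1-based
#' inclusive and must not overlap; over a full partition of the positions
#' the row sums recover the total attention (1 for an unsmoothed mean of
#' unit-sum vectors).
#'
#' @param attention A class x L matrix (e.g. \code{mean_attention()$A}), a
#'   single length-L vector, or an \code{ampatt_aligned_attention} (its
#'   column mean is used, NA columns contributing 0).
#' @param regions A data.frame \code{name,start,end} (see
#'   \code{\link{read_regions}}) or a path to one.
#' @return A groups x regions matrix of class \code{ampatt_region_table}.
#' @export
region_attention <- function(attention, regions) {
  if (is.character(regions)) regions <- read_regions(regions)
  if (inherits(attention, "ampatt_aligned_attention")) {
    v <- attention$column_mean
    v[is.na(v)] <- 0
    attention <- rbind(column_mean = v)
  }
  if (is.null(dim(attention))) attention <- rbind(attention = attention)
  L <- ncol(attention)
  if (any(regions$start < 1L) || any(regions$end > L))
    stop(sprintf("regions must lie within [1, %d]", L))
  o <- order(regions$start)
  rs <- regions$start[o]; re <- regions$end[o]
  if (any(rs[-1] <= re[-length(re)]))
    stop("regions overlap")
  sums <- sapply(seq_len(nrow(regions)), function(i)
    rowSums(attention[, regions$start[i]:regions$end[i], drop = FALSE]))
  if (is.null(dim(sums))) sums <- rbind(sums)
  dimnames(sums) <- list(rownames(attention), regions$name)
  structure(sums, class = c("ampatt_region_table", "matrix", "array"))
}

#' Plot an entropy-scaled sequence logo
#'
#' Stacked-letter logo for one class: letters at each position are stacked
#' in increasing height order so the tallest (most frequent) base tops the
#' stack; total stack height is the pooled entropy H(l). Mean attention, if
#' supplied, is drawn as background shading.
#'
#' @param logo An \code{ampatt_logo}.
#' @param class Which class to draw (default first).
#' @param attention Optional length-L attention vector for shading.
#' @param xlim Positions to draw (default all).
#' @param ... Passed to \code{plot}.
#' @export
plot_logo <- function(logo, class = logo$classes[1], attention = NULL,
                      xlim = NULL, ...) {
  stopifnot(inherits(logo, "ampatt_logo"))
  ci <- match(class, logo$classes)
  if (is.na(ci)) stop(sprintf("class '%s' not in the logo", class))
  S <- logo$S[ci, , , drop = TRUE]
  L <- nrow(S)
  if (is.null(xlim)) xlim <- c(1L, L)
  pos <- seq(xlim[1], xlim[2])
  cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  plot(NULL, xlim = xlim + c(-0.5, 0.5), ylim = c(0, 2.05),
       xlab = "position (base)", ylab = "bits",
       main = sprintf("class %s", class), ...)
  if (!is.null(attention)) {
    a <- attention[pos]
    shade <- grDevices::gray(1 - 0.8 * a / max(a, na.rm = TRUE))
    graphics::rect(pos - 0.5, 0, pos + 0.5, 2.05, col = shade, border = NA)
  }
  for (l in pos) {
    h <- S[l, ]
    ord <- order(h)  # draw small letters first so the tallest sits on top
    y0 <- 0
    for (b in ord) {
      if (h[b] <= 0) next
      graphics::text(l, y0 + h[b] / 2, .BASES[b], col = cols[.BASES[b]],
                     cex = max(0.3, min(1.4, 2 * h[b])), font = 2)
      y0 <- y0 + h[b]
    }
  }
  invisible(logo)
}
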