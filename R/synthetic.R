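# Synthetic amplicon generator: labelled multi-sample datasets with known
# class-discriminative loci, so the whole pipeline is testable end to end
# with exact ground truth.

#' Describe a synthetic amplicon dataset
#'
#' The generator emulates the statistical structure the read-level
#' classifier assumes: several phenotype classes, genus-like reference
#' clusters shared by all classes, class-discriminative bases planted at
#' known loci, and per-base substitution (and optional single-base indel)
#' noise. Every genus has one random backbone of length \code{read_length};
#' the class-specific references differ from it only inside the planted
#' windows, so any class signal a model finds must come from those windows.
#'
#' @param n_classes Number of phenotype classes (>= 2, default 3).
#' @param n_genera Number of genus-like reference clusters (default 5).
#' @param read_length Read length T in bases (default 100).
#' @param planted_windows List of windows, each
#'   \code{list(start, end, assignments = <character vector, one string of
#'   length end-start+1 per class>)}; \code{assignments = NULL} draws
#'   distinct random per-class strings from the seed. Coordinates 1-based
#'   inclusive. Default: one 10-base window at positions 46-55.
#' @param substitution_rate Per-base substitution probability (default
#'   0.01; substitutions draw uniformly from the 3 alternative bases).
#' @param indel_rate Per-base single-indel probability (default 0; reads
#'   are re-trimmed/padded back to \code{read_length}).
#' @param reads_per_sample Reads drawn per sample (default 500).
#' @param samples_per_class Samples per class (default 10).
#' @param class_genus_mixture Optional \code{n_classes x n_genera} row-
#'   stochastic matrix of genus composition per class; default uniform, so
#'   genus composition carries no class signal.
#' @param seed Integer seed (default 1).
#' @return A validated list of class \code{ampatt_synth_spec}.
#' @export
synthetic_spec <- function(n_classes = 3L, n_genera = 5L, read_length = 100L,
                           planted_windows = NULL,
                           substitution_rate = 0.01, indel_rate = 0,
                           reads_per_sample = 500L, samples_per_class = 10L,
                           class_genus_mixture = NULL, seed = 1L) {
  n_classes <- as.integer(n_classes); n_genera <- as.integer(n_genera)
  read_length <- as.integer(read_length)
  if (n_classes < 2L) stop("`n_classes` must be >= 2")
  if (n_genera < 1L) stop("`n_genera` must be >= 1")
  if (read_length < 1L) stop("`read_length` must be positive")
  if (substitution_rate < 0 || substitution_rate > 0.5)
    stop("`substitution_rate` must be in [0, 0.5]")
  if (indel_rate < 0 || indel_rate > 0.5)
    stop("`indel_rate` must be in [0, 0.5]")
  if (is.null(planted_windows))
    planted_windows <- list(list(start = 46L, end = 55L, assignments = NULL))
  for (w in planted_windows) {
    if (w$start < 1L || w$end > read_length || w$end < w$start)
      stop(sprintf("planted window [%d, %d] outside [1, %d]",
                   w$start, w$end, read_length))
    if (!is.null(w$assignments)) {
      if (length(w$assignments) != n_classes)
        stop("window assignments must give one string per class")
      if (any(nchar(w$assignments) != w$end - w$start + 1L))
        stop("window assignment length must equal the window width")
    }
  }
  planted_windows <- lapply(planted_windows, function(w) {
    w$start <- as.integer(w$start); w$end <- as.integer(w$end); w
  })
  if (length(planted_windows) > 1L) {
    st <- vapply(planted_windows, `[[`, 0L, "start")
    en <- vapply(planted_windows, `[[`, 0L, "end")
    o <- order(st)
    if (any(st[o][-1] <= en[o][-length(en)]))
      stop("planted windows conflict (overlap)")
  }
  if (is.null(class_genus_mixture))
    class_genus_mixture <- matrix(1 / n_genera, n_classes, n_genera)
  class_genus_mixture <- as.matrix(class_genus_mixture)
  if (!all(dim(class_genus_mixture) == c(n_classes, n_genera)))
    stop("`class_genus_mixture` must be n_classes x n_genera")
  if (any(abs(rowSums(class_genus_mixture) - 1) > 1e-8))
    stop("`class_genus_mixture` rows must sum to 1")
  structure(list(
    n_classes = n_classes, n_genera = n_genera, read_length = read_length,
    planted_windows = planted_windows,
    substitution_rate = substitution_rate, indel_rate = indel_rate,
    reads_per_sample = as.integer(reads_per_sample),
    samples_per_class = as.integer(samples_per_class),
    class_genus_mixture = class_genus_mixture, seed = as.integer(seed)
  ), class = "ampatt_synth_spec")
}

.rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

#' Generate genus/class reference sequences
#'
#' Draws one random backbone per genus; class references share the backbone
#' except inside planted windows, where each class receives its assigned
#' bases. Auto-generated assignments are guaranteed distinct across classes,
#' so classes are separable exactly at the planted loci.
#'
#' @param spec An \code{\link{synthetic_spec}}.
#' @return A list: \code{references[[genus]][[class]]} nucleotide string,
#'   \code{windows} (the windows with assignments resolved), plus the genus
#'   and class names used (\code{genus1..}, \code{classA..}).
#' @export
generate_references <- function(spec) {
  stopifnot(inherits(spec, "ampatt_synth_spec"))
  set.seed(spec$seed)
  classes <- paste0("class", LETTERS[seq_len(spec$n_classes)])
  genera <- paste0("genus", seq_len(spec$n_genera))
  windows <- lapply(spec$planted_windows, function(w) {
    if (is.null(w$assignments)) {
      width <- w$end - w$start + 1L
      repeat {
        w$assignments <- vapply(seq_len(spec$n_classes),
                                function(i) .rand_bases(width), "")
        if (!anyDuplicated(w$assignments)) break
      }
    }
    names(w$assignments) <- classes
    w
  })
  refs <- stats::setNames(vector("list", spec$n_genera), genera)
  for (g in genera) {
    backbone <- .rand_bases(spec$read_length)
    per_class <- stats::setNames(vector("list", spec$n_classes), classes)
    for (cl in classes) {
      s <- backbone
      for (w in windows)
        substr(s, w$start, w$end) <- w$assignments[[cl]]
      per_class[[cl]] <- s
    }
    refs[[g]] <- per_class
  }
  list(references = refs, windows = windows, classes = classes,
       genera = genera)
}

# Mutate one read: i.i.d. substitutions, then optional single-base indels
# with re-trim/pad back to length T. Returns the read and mutation counts.
.mutate_read <- function(ref, sub_rate, indel_rate) {
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  T <- length(chars)
  n_sub <- 0L
  if (sub_rate > 0) {
    hit <- which(stats::runif(T) < sub_rate)
    n_sub <- length(hit)
    for (i in hit)
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  n_indel <- 0L
  if (indel_rate > 0) {
    hit <- which(stats::runif(T) < indel_rate)
    n_indel <- length(hit)
    for (i in sort(hit, decreasing = TRUE)) {
      if (stats::runif(1) < 0.5) {  # insertion before position i
        chars <- append(chars, sample(c("A", "C", "G", "T"), 1L), after = i - 1L)
      } else {
        chars <- chars[-i]
      }
    }
    if (length(chars) > T) chars <- chars[seq_len(T)]
    while (length(chars) < T)
      chars <- c(chars, sample(c("A", "C", "G", "T"), 1L))
  }
  list(seq = paste(chars, collapse = ""), n_sub = n_sub, n_indel = n_indel)
}

#' Generate a labelled synthetic dataset
#'
#' Draws \code{samples_per_class} samples per class; each sample draws
#' \code{reads_per_sample} reads by picking a genus from the class's
#' mixture row, taking the class-specific reference, and applying i.i.d.
#' substitution (and optional indel) noise. With both rates at 0 every read
#' equals its reference exactly.
#'
#' @param spec An \code{\link{synthetic_spec}}.
#' @param dir Optional output directory: writes one FASTA per sample, a
#'   \code{metadata.tsv} matching the loader's schema, and
#'   \code{ground_truth.tsv} (read_id, sample_id, class, genus, n_sub,
#'   n_indel).
#' @param split Value of the metadata \code{split} column (default
#'   \code{"train"}).
#' @param seed Seed for the draw (default \code{spec$seed}); references are
#'   always derived from \code{spec$seed} so train/test sets generated with
#'   different draw seeds share the same ground-truth references.
#' @return A list: \code{reads} (data.frame read_id, sequence, sample_id),
#'   \code{metadata}, \code{ground_truth}, \code{references},
#'   \code{windows}, \code{classes}, \code{genera}, and \code{files} when
#'   \code{dir} was given.
#' @export
generate_samples <- function(spec, dir = NULL, split = "train",
                             seed = spec$seed) {
  stopifnot(inherits(spec, "ampatt_synth_spec"))
  refset <- generate_references(spec)
  set.seed(seed)
  classes <- refset$classes; genera <- refset$genera
  reads <- list(); gt <- list(); meta <- list()
  for (ci in seq_along(classes)) {
    for (s in seq_len(spec$samples_per_class)) {
      sid <- sprintf("%s_%s_s%02d", split, classes[ci], s)
      gidx <- sample.int(spec$n_genera, spec$reads_per_sample, replace = TRUE,
                         prob = spec$class_genus_mixture[ci, ])
      seqs <- character(spec$reads_per_sample)
      nsub <- integer(spec$reads_per_sample)
      nind <- integer(spec$reads_per_sample)
      for (r in seq_len(spec$reads_per_sample)) {
        mut <- .mutate_read(refset$references[[gidx[r]]][[ci]],
                            spec$substitution_rate, spec$indel_rate)
        seqs[r] <- mut$seq; nsub[r] <- mut$n_sub; nind[r] <- mut$n_indel
      }
      rid <- sprintf("%s_r%04d", sid, seq_len(spec$reads_per_sample))
      reads[[sid]] <- data.frame(read_id = rid, sequence = seqs,
                                 sample_id = sid, stringsAsFactors = FALSE)
      gt[[sid]] <- data.frame(read_id = rid, sample_id = sid,
                              class = classes[ci], genus = genera[gidx],
                              n_sub = nsub, n_indel = nind,
                              stringsAsFactors = FALSE)
      meta[[sid]] <- data.frame(sample_id = sid, label = classes[ci],
                                split = split, stringsAsFactors = FALSE)
    }
  }
  out <- list(reads = do.call(rbind, reads),
              metadata = do.call(rbind, meta),
              ground_truth = do.call(rbind, gt),
              references = refset$references, windows = refset$windows,
              classes = classes, genera = genera)
  rownames(out$reads) <- rownames(out$metadata) <- rownames(out$ground_truth) <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(0)
    for (sid in out$metadata$sample_id) {
      rr <- out$reads[out$reads$sample_id == sid, ]
      path <- file.path(dir, paste0(sid, ".fasta"))
      writeLines(paste0(">", rr$read_id, "\n", rr$sequence), path)
      files <- c(files, path)
    }
    utils::write.table(out$metadata, file.path(dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$ground_truth, file.path(dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$files <- files
  }
  out
}
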