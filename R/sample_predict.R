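# Sample-level phenotype prediction from read-level classifier outputs:
# majority vote with a 1/N read caller, averaged sample embeddings, k-means
# "Pseudo OTU" tables, and the k-mer frequency-table baseline.

#' Majority vote over read-level class scores
#'
#' Each read votes for every class whose likelihood score strictly exceeds
#' chance, 1/N (N = number of classes), so a read split between two habitats
#' can vote for both. If no class strictly exceeds 1/N (e.g. exactly uniform
#' scores) the read casts a single vote for its argmax class. The sample
#' prediction is the argmax of the vote counts; tied maxima are broken by
#' class-name order.
#'
#' @param score_vectors A reads x N matrix of class scores (rows sum to 1),
#'   or a list of length-N score vectors.
#' @param class_names Character vector of the N class names (defaults to the
#'   matrix column names).
#' @param sample_id Optional sample identifier carried into the result.
#' @return A list of class \code{ampatt_vote}: \code{votes} (named integer
#'   vector), \code{threshold} (= 1/N), \code{predicted_label},
#'   \code{sample_id}.
#' @examples
#' majority_vote(rbind(c(0.51, 0.43, 0.06)), c("gut", "skin", "oral"))
#' @export
majority_vote <- function(score_vectors, class_names = NULL, sample_id = NA) {
  if (is.list(score_vectors)) score_vectors <- do.call(rbind, score_vectors)
  if (is.null(dim(score_vectors))) score_vectors <- rbind(score_vectors)
  if (nrow(score_vectors) == 0L) stop("no reads to vote with")
  if (is.null(class_names)) class_names <- colnames(score_vectors)
  N <- ncol(score_vectors)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(N))
  if (N < 2L) stop("need at least 2 classes")
  threshold <- 1 / N
  above <- score_vectors > threshold
  none <- rowSums(above) == 0L
  if (any(none)) {
    fallback <- max.col(score_vectors[none, , drop = FALSE],
                        ties.method = "first")
    above[cbind(which(none), fallback)] <- TRUE
  }
  votes <- colSums(above)
  names(votes) <- class_names
  # argmax with ties broken by class-name order
  winner <- class_names[order(-votes, class_names)][1]
  structure(list(sample_id = sample_id, votes = as.integer(votes),
                 class_names = class_names, threshold = threshold,
                 predicted_label = winner),
            class = "ampatt_vote")
}

#' @export
print.ampatt_vote <- function(x, ...) {
  cat(sprintf("vote tally (threshold %.4g): %s -> %s\n", x$threshold,
              paste(x$class_names, x$votes, sep = "=", collapse = ", "),
              x$predicted_label))
  invisible(x)
}

#' Average read embeddings into a sample embedding
#'
#' @param read_embeddings A reads x N_h matrix (or list of equal-length
#'   vectors) of read embeddings from one sample.
#' @param sample_id Optional identifier.
#' @return A list with \code{sample_id} and \code{vector}, the elementwise
#'   arithmetic mean of the read embeddings.
#' @export
average_embedding <- function(read_embeddings, sample_id = NA) {
  if (is.list(read_embeddings)) read_embeddings <- do.call(rbind, read_embeddings)
  if (is.null(dim(read_embeddings))) read_embeddings <- rbind(read_embeddings)
  if (nrow(read_embeddings) == 0L) stop("no read embeddings to average")
  list(sample_id = sample_id, vector = colMeans(read_embeddings))
}

# k-means++ seeding: spread initial centres proportionally to squared
# distance from the nearest centre already chosen.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2L, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    tot <- sum(d2)
    centers[j, ] <- if (tot > 0) {
      # fewer distinct points than k leaves all-zero distances; fall back
      # to uniform draws (duplicates are separated below)
      x[sample.int(n, 1L, prob = d2 / tot), ]
    } else x[sample.int(n, 1L), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  dup <- duplicated(centers)
  if (any(dup)) {
    eps <- 1e-8 * max(1, mean(abs(x)))
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(stats::rnorm(sum(dup) * ncol(x), sd = eps), sum(dup))
  }
  centers
}

#' Cluster read embeddings into Pseudo OTUs
#'
#' Runs Euclidean k-means (k-means++ seeding, \code{restarts} independent
#' starts, best total within-cluster sum of squares kept) on the training
#' reads' embedding vectors. The fitted centroids define "Pseudo OTUs":
#' clusters of related reads that play the role of sequence-similarity OTUs
#' in downstream abundance tables.
#'
#' @param train_embeddings A reads x N_h numeric matrix.
#' @param k Number of clusters (default 1000).
#' @param seed Integer seed fixing the initialization.
#' @param restarts Number of k-means++ starts (default 10).
#' @param iter_max Lloyd iteration cap per start.
#' @return A k x N_h centroid matrix of class \code{ampatt_centroids}.
#' @export
pseudo_otu_fit <- function(train_embeddings, k = 1000L, seed = 1L,
                           restarts = 10L, iter_max = 50L) {
  x <- as.matrix(train_embeddings)
  k <- as.integer(k)
  if (nrow(x) < k)
    stop(sprintf(paste0("%d embeddings cannot support k = %d clusters; ",
                        "lower k to at most the number of reads"),
                 nrow(x), k))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    ctrs <- .kmeanspp_centers(x, k)
    km <- suppressWarnings(
      stats::kmeans(x, centers = ctrs, iter.max = iter_max,
                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  structure(best$centers, class = c("ampatt_centroids", "matrix", "array"))
}

# Nearest centroid (Euclidean) for each row of x; ties to the lowest index.
# Centroids of empty clusters are NaN (k-means never filled them); they can
# never be nearest, keeping them as zero-usage Pseudo OTUs.
.assign_clusters <- function(x, centroids) {
  ok <- is.finite(rowSums(centroids))
  if (!any(ok)) stop("no finite centroids to assign to")
  c_ok <- centroids[ok, , drop = FALSE]
  cn2 <- rowSums(c_ok^2)
  # squared distance = |x|^2 - 2 x.c + |c|^2; |x|^2 constant per row
  cross <- x %*% t(c_ok)
  d2 <- sweep(-2 * cross, 2L, cn2, "+")
  which(ok)[max.col(-d2, ties.method = "first")]
}

#' Build a Pseudo OTU table
#'
#' Assigns every read embedding to its nearest centroid (Euclidean distance,
#' ties to the lowest cluster index) and tabulates per-sample cluster
#' counts; rows are row-normalized into relative abundances. Empty clusters
#' are retained as zero columns so the table always has k columns.
#'
#' @param embeddings_by_sample Named list: sample_id -> reads x N_h matrix.
#' @param centroids Centroid matrix from \code{\link{pseudo_otu_fit}}.
#' @return A list of class \code{ampatt_pseudo_otu}: \code{counts}
#'   (samples x k integer matrix), \code{relabund} (row-normalized; rows of
#'   empty samples are NA and flagged in \code{empty_samples}),
#'   \code{centroids}.
#' @export
pseudo_otu_table <- function(embeddings_by_sample, centroids) {
  k <- nrow(centroids)
  samples <- names(embeddings_by_sample)
  if (is.null(samples)) samples <- paste0("sample", seq_along(embeddings_by_sample))
  counts <- matrix(0L, length(samples), k,
                   dimnames = list(samples, paste0("potu", seq_len(k))))
  for (i in seq_along(embeddings_by_sample)) {
    e <- embeddings_by_sample[[i]]
    if (is.null(e) || NROW(e) == 0L) next
    e <- if (is.null(dim(e))) rbind(e) else as.matrix(e)
    asg <- .assign_clusters(e, centroids)
    tab <- tabulate(asg, nbins = k)
    counts[i, ] <- tab
  }
  rs <- rowSums(counts)
  relabund <- counts / ifelse(rs > 0, rs, NA_real_)
  empty <- samples[rs == 0]
  if (length(empty))
    warning(sprintf("sample(s) with zero reads: %s (relabund rows are NA)",
                    paste(empty, collapse = ", ")))
  structure(list(counts = counts, relabund = relabund, centroids = centroids,
                 empty_samples = empty),
            class = "ampatt_pseudo_otu")
}

#' Random Forest sample-level classifier
#'
#' Trains a Random Forest (100 trees, the library default) on sample-level
#' feature rows — averaged embeddings, Pseudo OTU relative abundances, or
#' k-mer tables interchangeably.
#'
#' @param features A samples x d numeric matrix.
#' @param labels Phenotype label per sample.
#' @param seed Integer seed.
#' @param ntree Number of trees (default 100).
#' @return An object of class \code{ampatt_rf} wrapping the forest.
#' @export
fit_sample_classifier <- function(features, labels, seed = 1L, ntree = 100L) {
  features <- as.matrix(features)
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 classes to train")
  keep <- stats::complete.cases(features)
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) with undefined features (no reads)",
                    sum(!keep)))
    features <- features[keep, , drop = FALSE]
    labels <- droplevels(labels[keep])
  }
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  set.seed(seed)
  rf <- randomForest::randomForest(x = features, y = labels, ntree = ntree)
  structure(list(forest = rf, d = ncol(features),
                 class_names = levels(labels)), class = "ampatt_rf")
}

#' @rdname fit_sample_classifier
#' @param classifier A fitted \code{ampatt_rf}.
#' @return \code{predict_samples} returns a character vector of predicted
#'   labels, one per feature row.
#' @export
predict_samples <- function(classifier, features) {
  stopifnot(inherits(classifier, "ampatt_rf"))
  features <- as.matrix(features)
  if (ncol(features) != classifier$d)
    stop(sprintf("feature dimension %d does not match training dimension %d",
                 ncol(features), classifier$d))
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  as.character(predict(classifier$forest, features))
}

#' k-mer frequency table
#'
#' Counts all overlapping k-mers over each sample's reads and row-normalizes
#' into relative frequencies. The default k = 9 matches the convolution
#' window, so this table is the natural hand-crafted counterpart of what the
#' first conv layer can see. Columns are all 4^k k-mers in lexicographic
#' (A < C < G < T) order; windows containing a non-ACGT character are
#' skipped.
#'
#' @param reads_by_sample Named list: sample_id -> character vector of reads.
#' @param k k-mer size (default 9).
#' @return A samples x 4^k relative-frequency matrix; a sample all of whose
#'   reads are shorter than k gets a zero row (flagged with a warning).
#' @export
kmer_table <- function(reads_by_sample, k = 9L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  samples <- names(reads_by_sample)
  if (is.null(samples)) samples <- paste0("sample", seq_along(reads_by_sample))
  out <- NULL
  for (i in seq_along(reads_by_sample)) {
    seqs <- reads_by_sample[[i]]
    keep <- nchar(seqs) >= k
    if (any(keep)) {
      ss <- Biostrings::DNAStringSet(seqs[keep])
      cnt <- colSums(Biostrings::oligonucleotideFrequency(ss, width = k))
    } else {
      cnt <- stats::setNames(numeric(4^k),
                             Biostrings::mkAllStrings(c("A", "C", "G", "T"), k))
    }
    if (is.null(out))
      out <- matrix(0, length(reads_by_sample), length(cnt),
                    dimnames = list(samples, names(cnt)))
    tot <- sum(cnt)
    if (tot == 0) {
      warning(sprintf("sample '%s' has no reads of length >= %d; zero row",
                      samples[i], k))
      out[i, ] <- 0
    } else out[i, ] <- cnt / tot
  }
  out
}

#' Write a samples-by-features table as TSV
#'
#' @param mat A matrix with sample row names and feature column names.
#' @param path Output path.
#' @export
write_feature_table <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
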