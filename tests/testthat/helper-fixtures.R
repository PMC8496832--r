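# Shared fixtures. The full-scale trained model used by the end-to-end
# planted-signal checks is expensive (minutes), so it is computed once per
# test run and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

random_reads <- function(n, len, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

tiny_hp <- function(...) {
  defaults <- list(T = 20L, N_y = 3L, W = 3L, n_conv_blocks = 2L, N_c = 6L,
                   N_h = 8L, N_a = 4L, batch_size = 8L, epochs = 2L,
                   seed = 7L)
  args <- utils::modifyList(defaults, list(...))
  do.call(hyperparams, args)
}

# A small but learnable planted-signal problem for fast training checks:
# 2 classes differing in a 4-base window of 30-base reads, no noise.
tiny_planted <- function(n_per_class = 150L, seed = 5L) {
  spec <- synthetic_spec(
    n_classes = 2L, n_genera = 2L, read_length = 30L,
    planted_windows = list(list(start = 14L, end = 17L, assignments = NULL)),
    substitution_rate = 0, indel_rate = 0,
    reads_per_sample = n_per_class, samples_per_class = 1L, seed = seed)
  generate_samples(spec, seed = seed)
}

# Study-scale fixture: default generator conditions (3 classes x 10 samples
# x 500 reads of 100 bases, one 10-base planted window, 1% substitution),
# the small model (N_c = 64, N_h = 32) trained for 5 epochs, plus
# predictions on an independent test draw of the same conditions.
acceptance_fixture <- function() {
  if (!is.null(.fixture_env$acc)) return(.fixture_env$acc)
  spec <- synthetic_spec(seed = 11L)
  train <- generate_samples(spec, split = "train", seed = 11L)
  test <- generate_samples(spec, split = "test", seed = 12L)
  hp <- hyperparams(T = spec$read_length, N_y = spec$n_classes,
                    N_c = 64L, N_h = 32L, epochs = 5L, batch_size = 128L,
                    seed = 11L)
  x_train <- encode_reads(train$reads$sequence, hp$T)
  labels <- train$ground_truth$class
  model <- train_model(build_model(hp), x_train, labels)
  x_test <- encode_reads(test$reads$sequence, hp$T)
  pred_test <- predict_reads(model, x_test)
  pred_train <- predict_reads(model, x_train)
  .fixture_env$acc <- list(spec = spec, train = train, test = test, hp = hp,
                           model = model, pred_test = pred_test,
                           pred_train = pred_train)
  .fixture_env$acc
}

# Control: same conditions, read labels permuted before training so the
# read-label association is destroyed outright. (Permuting labels at the
# sample level is too weak a control at 30 samples: the permutation can
# leave each true class's plurality label unchanged, and a model that
# learns the empirical per-archetype label imbalance then still scores far
# above chance.)
shuffled_fixture <- function() {
  if (!is.null(.fixture_env$shuf)) return(.fixture_env$shuf)
  acc <- acceptance_fixture()
  set.seed(100L)
  labels <- sample(acc$train$ground_truth$class)
  x_train <- encode_reads(acc$train$reads$sequence, acc$hp$T)
  model <- train_model(build_model(acc$hp), x_train, labels)
  pred_test <- predict_reads(model, encode_reads(acc$test$reads$sequence,
                                                 acc$hp$T))
  .fixture_env$shuf <- list(model = model, pred_test = pred_test,
                            labels = labels)
  .fixture_env$shuf
}
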