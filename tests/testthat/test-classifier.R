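# deterministic, linearly separable toy data over the toy taxonomy
toy_data <- function(n_per_leaf = 6L, seed = 5L) {
  tax <- toy_taxonomy()
  leaves <- tax_leaves(tax)
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(leaves), function(i) {
    centre <- rep(0, length(leaves))
    centre[i] <- 5
    m <- matrix(rep(centre, n_per_leaf), nrow = n_per_leaf, byrow = TRUE)
    m + matrix(stats::rnorm(n_per_leaf * length(leaves), sd = 0.1),
               nrow = n_per_leaf)
  }))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  list(x = x, labels = rep(leaves, each = n_per_leaf), tax = tax)
}

test_that("separable toy data is classified perfectly by RFSB", {
  d <- toy_data()
  fit <- te_classifier(d$x, d$labels, d$tax, seed = 1)
  expect_equal(predict(fit, d$x, type = "code"), d$labels)
})

test_that("selective training pools are the parent-activated subsets", {
  d <- toy_data()
  memb <- transposcope:::membership_matrix(d$labels, d$tax)
  pools <- transposcope:::training_pools(d$labels, d$tax, "selective", memb)
  # pool of node "1/1" (children trained from it) = samples under "1"
  expect_setequal(pools[["1"]], which(startsWith(d$labels, "1")))
  expect_setequal(pools[["1/1"]],
                  which(startsWith(d$labels, "1/1")))
  expect_setequal(pools[[".root"]], seq_along(d$labels))
  # nesting along the root-to-leaf chain
  expect_true(all(pools[["1/1"]] %in% pools[["1"]]))
  expect_true(all(pools[["1"]] %in% pools[[".root"]]))
})

test_that("the all strategy trains every node on the full set", {
  d <- toy_data()
  memb <- transposcope:::membership_matrix(d$labels, d$tax)
  pools <- transposcope:::training_pools(d$labels, d$tax, "all", memb)
  for (p in names(pools)) {
    expect_setequal(pools[[p]], seq_along(d$labels))
  }
})

test_that("binary decoding follows the argmax chain with ascending tie-break", {
  tax <- parse_taxonomy(c("1\ta", "1/1\taa", "1/2\tab", "2\tb"))
  dec <- transposcope:::decode_binary(
    c("1" = 0.9, "2" = 0.1, "1/1" = 0.2, "1/2" = 0.8), tax)
  expect_equal(dec$path, c("1", "1/2"))
  tie <- transposcope:::decode_binary(
    c("1" = 0.5, "2" = 0.5, "1/1" = 0.5, "1/2" = 0.5), tax)
  expect_equal(tie$path, c("1", "1/1"))  # ascending code order on ties
})

test_that("multilabel decoding backtracks on the return label", {
  tax <- parse_taxonomy(c("1\ta", "1/1\taa", "1/2\tab", "2\tb"))
  # root prefers "1"; at "1" the return label wins -> fall back to "2"
  step <- list(".root" = c("1" = 0.6, "2" = 0.3, "-1" = 0.1),
               "1" = c("1/1" = 0.1, "1/2" = 0.3, "-1" = 0.6))
  dec <- transposcope:::decode_multilabel(step, tax)
  expect_equal(dec$path, "2")
  # root emits return with no alternatives -> unclassified
  step2 <- list(".root" = c("1" = 0.1, "2" = 0.2, "-1" = 0.7))
  dec2 <- transposcope:::decode_multilabel(step2, tax)
  expect_equal(dec2$path, character(0))
})

test_that("predicted paths are connected root-to-node chains", {
  sim <- simulate_te_sequences(n_per_class = 12, seed = 3)
  fv <- build_feature_matrix(sim$sequences, sim$hits, ks = c(2L, 3L),
                             domains = sim$domain_pool)
  for (structure in c("binary", "multilabel")) {
    fit <- te_classifier(fv, sim$labels, sim$taxonomy,
                         structure = structure, seed = 1)
    paths <- predict(fit, fv[1:20, , drop = FALSE])
    for (p in paths$path) {
      if (length(p) == 0L) next
      expect_equal(p, augmented_labels(sim$taxonomy, p[length(p)]))
    }
  }
})

test_that("base learners share decoding behaviour", {
  d <- toy_data(n_per_leaf = 8L)
  for (learner in c("random_forest", "logistic_regression", "naive_bayes",
                    "adaboost", "svm")) {
    fit <- te_classifier(d$x, d$labels, d$tax, learner = learner, seed = 1)
    codes <- predict(fit, d$x, type = "code")
    # separable data: every learner recovers at least the top level
    top <- substr(codes, 1, 1)
    expect_gt(mean(top == substr(d$labels, 1, 1)), 0.9)
  }
})

test_that("model save/load round-trips predictions and checks integrity", {
  d <- toy_data()
  fit <- te_classifier(d$x, d$labels, d$tax, seed = 1)
  path <- tempfile(fileext = ".rds")
  save_te_model(fit, path)
  back <- load_te_model(path)
  expect_identical(predict(back, d$x, type = "code"),
                   predict(fit, d$x, type = "code"))
  # not-a-model payload is refused
  bogus <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bogus)
  expect_error(load_te_model(bogus), "integrity")
  # corrupted bytes are refused
  writeLines("not an rds", bogus)
  expect_error(load_te_model(bogus), "corrupted|integrity")
})

test_that("predicting on a different feature layout is refused", {
  d <- toy_data()
  fit <- te_classifier(d$x, d$labels, d$tax, seed = 1)
  x2 <- d$x
  colnames(x2) <- paste0("g", seq_len(ncol(x2)))
  expect_error(predict(fit, x2), "layout")
})

test_that("training is deterministic given the seed", {
  d <- toy_data()
  f1 <- te_classifier(d$x, d$labels, d$tax, seed = 9)
  f2 <- te_classifier(d$x, d$labels, d$tax, seed = 9)
  expect_identical(predict(f1, d$x, type = "code"),
                   predict(f2, d$x, type = "code"))
})

test_that("empty datasets and unknown labels are rejected", {
  tax <- toy_taxonomy()
  expect_error(te_classifier(matrix(numeric(0), 0, 3), character(0), tax),
               "empty")
  expect_error(te_classifier(matrix(1, 2, 2), c("1", "7/7"), tax),
               "not in taxonomy")
})
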