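#' Fit a hierarchical transposon classifier
#'
#' Trains a hierarchical classification model over a transposon taxonomy.
#' Two model structures are supported:
#' \describe{
#'   \item{binary}{one yes/no scorer per taxonomy node; decoding starts at
#'     the (virtual) root and repeatedly descends to the child whose node
#'     scorer assigns the highest probability, down to a leaf.}
#'   \item{multilabel}{one multiclass scorer per internal node over its
#'     children plus a reserved return label \code{"-1"}; decoding descends
#'     by most-probable child and backtracks one level whenever \code{"-1"}
#'     outranks the remaining children.}
#' }
#' Two training strategies control each node's training pool: \code{"all"}
#' trains every node on the whole training set, while \code{"selective"}
#' trains each node only on the samples activated by its parent (samples
#' whose true lineage passes through the parent node).  The recommended
#' configuration — random forest base learner, selective strategy, binary
#' structure — is the package default (RFSB).
#'
#' For the binary structure, node \code{c}'s positives are the samples whose
#' ancestor-augmented label set contains \code{c}; negatives are the rest of
#' the strategy-determined pool.  For the multilabel structure, a pool
#' sample's class at parent \code{p} is the child of \code{p} on its lineage,
#' or \code{"-1"} when its lineage does not continue below \code{p};
#' out-of-subtree \code{"-1"} examples are subsampled to the mean child-class
#' size to avoid degenerate priors.  Nodes with fewer than
#' \code{min_node_examples} positives fall back to a constant-prior scorer
#' and are recorded in the fitted model.
#'
#' @param x Numeric feature matrix, one row per sequence (see
#'   [build_feature_matrix()]).  Column names define the feature layout,
#'   which is stored in the model and verified at prediction time.
#' @param labels Character vector of true class codes, one per row of
#'   \code{x}; every label must be a node of \code{taxonomy}.
#' @param taxonomy A \code{"te_taxonomy"} object (default
#'   [default_taxonomy()]).
#' @param structure \code{"binary"} or \code{"multilabel"}.
#' @param strategy \code{"selective"} or \code{"all"}.
#' @param learner Base learner: \code{"random_forest"} (default),
#'   \code{"adaboost"}, \code{"logistic_regression"}, \code{"svm"} or
#'   \code{"naive_bayes"}.
#' @param learner_params Named list of learner hyper-parameters (e.g.
#'   \code{list(ntree = 200)} for the random forest; default 100 trees).
#' @param seed Integer RNG seed; fitting is deterministic given the seed.
#' @param min_node_examples Minimum positive examples to fit a node scorer
#'   (default 2).
#' @return An object of class \code{"te_classifier"} with components
#'   \code{scorers}, \code{taxonomy}, \code{layout}, \code{fallback_nodes}
#'   and the echoed configuration.
#' @examples
#' sim <- simulate_te_sequences(n_per_class = 15, seed = 1)
#' fv <- build_feature_matrix(sim$sequences, sim$hits, ks = 2,
#'                            domains = sim$domain_pool)
#' fit <- te_classifier(fv, sim$labels, sim$taxonomy, seed = 1)
#' predict(fit, fv[1:3, , drop = FALSE], type = "code")
#' @seealso [predict.te_classifier()], [cross_validate()]
#' @export
te_classifier <- function(x, labels, taxonomy = default_taxonomy(),
                          structure = c("binary", "multilabel"),
                          strategy = c("selective", "all"),
                          learner = "random_forest",
                          learner_params = list(),
                          seed = 1L, min_node_examples = 2L) {
  structure <- match.arg(structure)
  strategy <- match.arg(strategy)
  learner <- match.arg(learner, LEARNERS)
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty training set")
  stopifnot(length(labels) == nrow(x), min_node_examples >= 2L)
  unknown <- setdiff(unique(labels), taxonomy$codes)
  if (length(unknown)) {
    stop("label(s) not in taxonomy: ", paste(unknown, collapse = ", "))
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))

  set.seed(seed)
  memb <- membership_matrix(labels, taxonomy)
  pools <- training_pools(labels, taxonomy, strategy, memb)

  fallback <- character(0)
  if (structure == "binary") {
    scorers <- lapply(taxonomy$codes, function(node) {
      pool <- pools[[parent_key(taxonomy, node)]]
      y <- ifelse(memb[pool, node], "pos", "neg")
      if (sum(y == "pos") < min_node_examples || sum(y == "neg") < 1L) {
        fallback <<- c(fallback, node)
        return(constant_scorer(factor(y, levels = c("neg", "pos"))))
      }
      fit_scorer(x[pool, , drop = FALSE], factor(y, levels = c("neg", "pos")),
                 learner, learner_params)
    })
    names(scorers) <- taxonomy$codes
  } else {
    parents <- c(".root", tax_internal(taxonomy))
    scorers <- lapply(parents, function(p) {
      node <- if (p == ".root") NULL else p
      kids <- tax_children(taxonomy, node)
      pool <- pools[[p]]
      y <- multilabel_targets(pool, kids, memb)
      ## out-of-subtree return examples, subsampled to mean child size
      if (!is.null(node)) {
        outside <- setdiff(seq_along(labels), which(memb[, node]))
        n_ret <- ceiling(mean(table(y[y != "-1"])))
        if (length(outside) && is.finite(n_ret) && n_ret >= 1L) {
          extra <- outside[sample.int(length(outside),
                                      min(n_ret, length(outside)))]
          pool <- c(pool, extra)
          y <- c(y, rep("-1", length(extra)))
        }
      }
      present <- names(which(table(y) >= 1L))
      if (sum(table(y) >= min_node_examples) < 2L) {
        fallback <<- c(fallback, p)
        return(constant_scorer(factor(y, levels = c(kids, "-1"))))
      }
      fit_scorer(x[pool, , drop = FALSE], factor(y, levels = present),
                 learner, learner_params)
    })
    names(scorers) <- parents
  }

  obj <- list(structure = structure, strategy = strategy, learner = learner,
              learner_params = learner_params, seed = seed,
              min_node_examples = min_node_examples,
              taxonomy = taxonomy, layout = colnames(x),
              scorers = scorers, fallback_nodes = fallback,
              n_train = nrow(x),
              version = TE_MODEL_VERSION)
  class(obj) <- "te_classifier"
  obj
}

TE_MODEL_VERSION <- "te_classifier/1"

## logical matrix: sample i belongs to node c's augmented label set
membership_matrix <- function(labels, taxonomy) {
  aug <- lapply(labels, function(l) augmented_labels(taxonomy, l))
  memb <- matrix(FALSE, nrow = length(labels), ncol = length(taxonomy$codes),
                 dimnames = list(NULL, taxonomy$codes))
  for (i in seq_along(aug)) memb[i, aug[[i]]] <- TRUE
  memb
}

parent_key <- function(taxonomy, node) {
  p <- tax_parent(taxonomy, node)
  if (is.na(p)) ".root" else p
}

## training pool (row indices) per parent node under the given strategy
training_pools <- function(labels, taxonomy, strategy, memb) {
  keys <- c(".root", tax_internal(taxonomy))
  pools <- lapply(keys, function(p) {
    if (strategy == "all" || p == ".root") {
      seq_along(labels)
    } else {
      which(memb[, p])
    }
  })
  names(pools) <- keys
  pools
}

## class targets for a multilabel node: the child on each sample's lineage,
## or "-1" when the lineage stops at or outside the parent
multilabel_targets <- function(pool, kids, memb) {
  y <- rep("-1", length(pool))
  for (k in kids) y[memb[pool, k]] <- k
  y
}

#' Predict transposon classes from a fitted hierarchical model
#'
#' Decodes a root-to-node path for each row of \code{newdata} using the
#' fitted model's structure.  Binary structure: descend from the root,
#' choosing at each step the child whose node scorer assigns the highest
#' probability (ties broken by ascending code order), until a leaf.
#' Multilabel structure: at each internal node take the candidates (children
#' plus \code{"-1"}) in decreasing probability; descending into a child that
#' later returns \code{"-1"} resumes with the next-most-probable unvisited
#' child; if the root returns \code{"-1"} with no alternatives the sample is
#' left unclassified.
#'
#' @param object A fitted \code{"te_classifier"}.
#' @param newdata Feature matrix whose column names match the model's stored
#'   feature layout exactly (predicting on a different layout is refused).
#' @param type \code{"path"} (default) returns a \code{"te_paths"} object
#'   carrying full paths and per-step candidate probabilities;
#'   \code{"code"} returns just the deepest predicted code per sample
#'   (\code{NA} when unclassified).
#' @param ... Unused.
#' @return See \code{type}.
#' @export
predict.te_classifier <- function(object, newdata,
                                  type = c("path", "code"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), object$layout)) {
    stop("feature layout mismatch: newdata columns do not match the ",
         "layout this model was trained on")
  }
  tax <- object$taxonomy
  n <- nrow(newdata)
  if (object$structure == "binary") {
    prob <- vapply(tax$codes,
                   function(node) scorer_prob(object$scorers[[node]],
                                              newdata)[, "pos"],
                   numeric(n))
    if (n == 1L) prob <- matrix(prob, nrow = 1L,
                                dimnames = list(NULL, tax$codes))
    res <- lapply(seq_len(n), function(i) decode_binary(prob[i, ], tax))
  } else {
    probs <- lapply(object$scorers, function(sc) scorer_prob(sc, newdata))
    res <- lapply(seq_len(n), function(i) {
      step <- lapply(probs, function(p) p[i, ])
      decode_multilabel(step, tax)
    })
  }
  paths <- structure(list(
    code = vapply(res, function(r) {
      if (length(r$path)) r$path[length(r$path)] else NA_character_
    }, character(1)),
    path = lapply(res, `[[`, "path"),
    steps = lapply(res, `[[`, "steps"),
    ids = rownames(newdata)
  ), class = "te_paths")
  if (type == "code") paths$code else paths
}

decode_binary <- function(nodeprob, tax) {
  path <- character(0)
  steps <- list()
  node <- NULL
  repeat {
    kids <- tax_children(tax, node)
    if (length(kids) == 0L) break
    pv <- nodeprob[kids]
    steps[[length(steps) + 1L]] <- pv
    node <- kids[which.max(pv)]  # first max = ascending-code tie-break
    path <- c(path, node)
  }
  list(path = path, steps = steps)
}

decode_multilabel <- function(stepprob, tax) {
  steps <- list()
  descend <- function(node) {
    key <- if (is.null(node)) ".root" else node
    pv <- stepprob[[key]]
    if (is.null(pv)) return(list(path = node, ok = TRUE))  # leaf reached
    steps[[key]] <<- pv
    cand <- names(pv)
    ## rank: decreasing probability; ties ascending code order, "-1" last
    tiekey <- ifelse(cand == "-1", "~", cand)
    ord <- order(-pv, tiekey, method = "radix")
    for (c in cand[ord]) {
      if (c == "-1") return(list(path = character(0), ok = FALSE))
      if (is.null(stepprob[[c]]) || !(c %in% tax_internal(tax))) {
        return(list(path = c(node, c), ok = TRUE))
      }
      sub <- descend(c)
      if (sub$ok) return(list(path = c(node, sub$path), ok = TRUE))
    }
    list(path = character(0), ok = FALSE)
  }
  out <- descend(NULL)
  list(path = if (out$ok) out$path else character(0), steps = steps)
}

#' @export
print.te_classifier <- function(x, ...) {
  cat("Hierarchical transposon classifier\n")
  cat("  structure:", x$structure, "  strategy:", x$strategy,
      "  learner:", x$learner, "\n")
  cat("  taxonomy: ", length(x$taxonomy$codes), " classes (",
      length(tax_leaves(x$taxonomy)), " leaves)\n", sep = "")
  cat("  features:", length(x$layout), "  training samples:", x$n_train,
      "  seed:", x$seed, "\n")
  if (length(x$fallback_nodes)) {
    cat("  constant-prior fallback at:",
        paste(x$fallback_nodes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.te_classifier <- function(object, ...) {
  print(object)
  cat("  scorers:", length(object$scorers), "\n")
  invisible(object)
}

#' @export
print.te_paths <- function(x, ...) {
  cat("Predicted taxonomy paths for", length(x$code), "sequence(s)\n")
  shown <- utils::head(seq_along(x$code), 10L)
  for (i in shown) {
    id <- if (!is.null(x$ids)) x$ids[i] else i
    p <- if (length(x$path[[i]])) paste(x$path[[i]], collapse = " > ")
         else "<unclassified>"
    cat(" ", id, ": ", p, "\n", sep = "")
  }
  if (length(x$code) > 10L) cat("  ...\n")
  invisible(x)
}

#' Save or load a fitted classifier
#'
#' Models are stored as a single serialized file embedding a format-version
#' tag, the taxonomy snapshot and the feature layout.  \code{load_te_model()}
#' verifies the tag and structural integrity and refuses payloads that are
#' not transposcope models.
#'
#' @param model A \code{"te_classifier"}.
#' @param path File path.
#' @return \code{load_te_model()} returns the \code{"te_classifier"};
#'   \code{save_te_model()} returns \code{path} invisibly.
#' @export
save_te_model <- function(model, path) {
  stopifnot(inherits(model, "te_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_te_model
#' @export
load_te_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupted or unreadable model file: ", conditionMessage(e))
  })
  if (!inherits(obj, "te_classifier") ||
      !identical(obj$version, TE_MODEL_VERSION) ||
      !inherits(obj$taxonomy, "te_taxonomy") ||
      is.null(obj$layout) || is.null(obj$scorers)) {
    stop("integrity error: file is not a valid te_classifier model")
  }
  obj
}
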