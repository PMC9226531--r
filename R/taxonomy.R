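#' Transposon taxonomy trees
#'
#' A transposon taxonomy is a rooted tree of class codes.  Each code is a
#' slash-separated path of integers (e.g. \code{"2/1/6"}), so the code itself
#' encodes the full lineage: \code{"2/1/6"} is the sixth child of \code{"2/1"},
#' which is the first child of the top-level class \code{"2"}.  A virtual root
#' sits above the top-level codes but is never emitted as a label.
#'
#' @name te_taxonomy
#' @keywords internal
NULL

## split a code into its integer components; "2/1/6" -> c(2L, 1L, 6L)
code_components <- function(code) {
  lapply(strsplit(code, "/", fixed = TRUE), as.integer)
}

## order codes by numeric path components (ascending, siblings numeric)
code_order <- function(codes) {
  if (length(codes) == 0L) return(integer(0))
  comp <- code_components(codes)
  maxd <- max(lengths(comp))
  keys <- vapply(comp, function(x) {
    paste(sprintf("%06d", c(x, rep(0L, maxd - length(x)))), collapse = "/")
  }, character(1))
  order(keys)
}

#' Parse a taxonomy configuration
#'
#' Reads a plain-text taxonomy configuration mapping class codes to
#' human-readable names and returns a validated taxonomy tree.  The format is
#' one \code{code<TAB>name} pair per line; blank lines and lines starting with
#' \code{#} are ignored.  Codes are slash-separated integer paths such as
#' \code{"1/1/3"}.
#'
#' The code set must be prefix-closed: every non-top-level code's parent
#' prefix must itself be listed.  Codes must be unique.
#'
#' @param config Either a path to a configuration file or a character vector
#'   of configuration lines.
#' @return An object of class \code{"te_taxonomy"}: a list with elements
#'   \code{codes} (character vector in deterministic numeric order),
#'   \code{names} (named character vector, code -> name) and \code{parent}
#'   (named character vector, code -> parent code, \code{NA} for top-level
#'   codes).
#' @examples
#' tax <- parse_taxonomy(c("1\tRetrotransposon", "1/1\tLTR", "1/1/3\tERV"))
#' tax_depth(tax, "1/1/3")
#' @seealso [default_taxonomy()], [tax_children()], [tax_ancestors()]
#' @export
parse_taxonomy <- function(config) {
  if (length(config) == 1L && !grepl("[\t\n]", config) && file.exists(config)) {
    lines <- readLines(config, warn = FALSE)
  } else {
    lines <- unlist(strsplit(config, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(new_taxonomy(character(0), character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 1L
  codes <- vapply(parts, `[[`, character(1), 1L)
  nms <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "", character(1))
  if (anyDuplicated(codes)) {
    stop("duplicate taxonomy code(s): ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  if (!all(grepl("^[0-9]+(/[0-9]+)*$", codes))) {
    stop("malformed taxonomy code(s): ",
         paste(codes[!grepl("^[0-9]+(/[0-9]+)*$", codes)], collapse = ", "))
  }
  new_taxonomy(codes, nms)
}

new_taxonomy <- function(codes, nms) {
  parent <- tax_parent_code(codes)
  missing <- !is.na(parent) & !(parent %in% codes)
  if (any(missing)) {
    stop("taxonomy is not prefix-closed: parent of ",
         paste(codes[missing], collapse = ", "), " is missing")
  }
  ord <- code_order(codes)
  codes <- codes[ord]
  nms <- nms[ord]
  names(nms) <- codes
  parent <- parent[ord]
  names(parent) <- codes
  structure(list(codes = codes, names = nms, parent = parent),
            class = "te_taxonomy")
}

## parent code string(s); NA for top-level codes
tax_parent_code <- function(codes) {
  ifelse(grepl("/", codes, fixed = TRUE),
         sub("/[0-9]+$", "", codes),
         NA_character_)
}

#' Default transposon taxonomy
#'
#' The taxonomy shipped with the package.  Class 1 (retrotransposons) splits
#' into LTR elements (Copia, Gypsy, ERV, BelPao) and non-LTR elements (LINE,
#' SINE); class 2 (DNA transposons) covers TIR superfamilies (Tc1-Mariner,
#' hAT, CMC, Sola, Zator, Novosib), Helitrons and MITEs.  The configuration
#' file lives at \code{system.file("extdata", "taxonomy_default.txt",
#' package = "transposcope")} and can be copied and edited.
#'
#' @return A \code{"te_taxonomy"} object.
#' @export
default_taxonomy <- function() {
  parse_taxonomy(system.file("extdata", "taxonomy_default.txt",
                             package = "transposcope", mustWork = TRUE))
}

stopifnot_code <- function(tax, code) {
  if (!code %in% tax$codes) stop("unknown taxonomy code: ", code)
}

#' Query a taxonomy tree
#'
#' \code{tax_ancestors()} returns all proper ancestors of a code (excluding
#' the virtual root), ordered shallow to deep.  \code{tax_children()} returns
#' the immediate children of a code (or of the virtual root when
#' \code{code = NULL}) in ascending numeric order.  \code{tax_depth()} is the
#' number of path components.  \code{tax_leaves()} lists the codes with no
#' children.  \code{augmented_labels()} returns the ancestor-augmented label
#' set \code{c(ancestors, code)} used throughout hierarchical evaluation.
#'
#' @param tax A \code{"te_taxonomy"} object.
#' @param code A class code present in \code{tax}; \code{NULL} means the
#'   virtual root for \code{tax_children()}.
#' @return Character vectors of class codes (\code{tax_depth()}: an integer).
#' @examples
#' tax <- default_taxonomy()
#' tax_ancestors(tax, "2/1/6")   # "2", "2/1"
#' tax_children(tax, NULL)       # "1", "2"
#' @export
tax_ancestors <- function(tax, code) {
  stopifnot_code(tax, code)
  comps <- strsplit(code, "/", fixed = TRUE)[[1L]]
  n <- length(comps)
  if (n <= 1L) return(character(0))
  vapply(seq_len(n - 1L), function(i) paste(comps[seq_len(i)], collapse = "/"),
         character(1))
}

#' @rdname tax_ancestors
#' @export
tax_children <- function(tax, code = NULL) {
  if (is.null(code)) {
    kids <- tax$codes[is.na(tax$parent)]
  } else {
    stopifnot_code(tax, code)
    kids <- tax$codes[!is.na(tax$parent) & tax$parent == code]
  }
  kids[code_order(kids)]
}

#' @rdname tax_ancestors
#' @export
tax_depth <- function(tax, code) {
  stopifnot_code(tax, code)
  length(strsplit(code, "/", fixed = TRUE)[[1L]])
}

#' @rdname tax_ancestors
#' @export
tax_leaves <- function(tax) {
  tax$codes[!(tax$codes %in% tax$parent[!is.na(tax$parent)])]
}

#' @rdname tax_ancestors
#' @export
tax_parent <- function(tax, code) {
  stopifnot_code(tax, code)
  unname(tax$parent[code])
}

#' @rdname tax_ancestors
#' @export
augmented_labels <- function(tax, code) {
  c(tax_ancestors(tax, code), code)
}

## internal nodes = codes with at least one child (root handled separately)
tax_internal <- function(tax) {
  intersect(tax$codes, unique(tax$parent[!is.na(tax$parent)]))
}

## is `code` equal to or a descendant of `anc`?
is_under <- function(code, anc) {
  code == anc | startsWith(code, paste0(anc, "/"))
}

#' @export
print.te_taxonomy <- function(x, ...) {
  cat("Transposon taxonomy:", length(x$codes), "classes\n")
  for (code in x$codes) {
    depth <- length(strsplit(code, "/", fixed = TRUE)[[1L]])
    cat(strrep("  ", depth - 1L), code, "  ", unname(x$names[code]), "\n",
        sep = "")
  }
  invisible(x)
}

#' Restrict a taxonomy to selected codes and their ancestors
#'
#' Useful for training on a subset of classes: keeps every listed code plus
#' all ancestors, so the result is again prefix-closed.
#'
#' @param tax A \code{"te_taxonomy"} object.
#' @param codes Class codes to keep (with their lineages).
#' @return A pruned \code{"te_taxonomy"}.
#' @export
tax_prune <- function(tax, codes) {
  for (code in codes) stopifnot_code(tax, code)
  keep <- unique(unlist(lapply(codes, function(c) augmented_labels(tax, c))))
  new_taxonomy(keep, unname(tax$names[keep]))
}
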