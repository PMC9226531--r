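#' Curation rules for assembling a transposon sequence database
#'
#' Raw transposon databases are heterogeneous: they mix labelled elements
#' with fragments, contigs, satellites and RNA entries, use database-specific
#' label vocabularies and contain duplicates.  [curate_sequences()] applies
#' the standard filter cascade and unifies labels onto a taxonomy;
#' [merge_curated()] combines several curated sets with exact-sequence
#' deduplication and per-source provenance.
#'
#' @param min_length_bp Exclusive minimum sequence length: sequences of this
#'   length or shorter are dropped (default 100, i.e. only > 100 bp kept).
#' @param required_letters Letters each kept sequence must contain at least
#'   once (default A, C, G, T).
#' @param excluded_keywords Case-insensitive keywords that mark an excluded
#'   category when found in a record's category tags (default fragment,
#'   contig, satellite, RNA).
#' @param synonym_map Named character vector mapping raw database labels to
#'   taxonomy class codes.  Labels that already are taxonomy codes pass
#'   through unchanged.
#' @return A list of class \code{"curation_rules"}.
#' @export
curation_rules <- function(min_length_bp = 100L,
                           required_letters = c("A", "C", "G", "T"),
                           excluded_keywords = c("fragment", "contig",
                                                 "satellite", "rna"),
                           synonym_map = default_synonym_map()) {
  stopifnot(min_length_bp > 0)
  structure(list(min_length_bp = min_length_bp,
                 required_letters = toupper(required_letters),
                 excluded_keywords = tolower(excluded_keywords),
                 synonym_map = synonym_map),
            class = "curation_rules")
}

#' Default raw-label synonym map
#'
#' Maps common RepBase/Wicker-style superfamily names onto the default
#' taxonomy's class codes.  User-extensible: supply your own named vector to
#' [curation_rules()].
#'
#' @return Named character vector, raw label -> class code.
#' @export
default_synonym_map <- function() {
  c("Copia" = "1/1/1", "Ty1" = "1/1/1",
    "Gypsy" = "1/1/2", "Ty3" = "1/1/2",
    "ERV" = "1/1/3", "Endogenous Retrovirus" = "1/1/3",
    "BelPao" = "1/1/4", "Bel-Pao" = "1/1/4", "Pao" = "1/1/4",
    "LTR" = "1/1", "LINE" = "1/2/1", "SINE" = "1/2/2",
    "non-LTR" = "1/2", "Retrotransposon" = "1",
    "Tc1-Mariner" = "2/1/1", "Tc1/Mariner" = "2/1/1", "Mariner" = "2/1/1",
    "hAT" = "2/1/2", "CMC" = "2/1/3", "CACTA" = "2/1/3", "EnSpm" = "2/1/3",
    "Sola" = "2/1/4", "Zator" = "2/1/5", "Novosib" = "2/1/6",
    "TIR" = "2/1", "Helitron" = "2/2", "MITE" = "2/3",
    "DNA transposon" = "2", "DNA" = "2")
}

#' Curate raw transposon records
#'
#' Applies the database-assembly filter cascade, in this fixed order of
#' drop reasons:
#' \enumerate{
#'   \item excluded category (fragment, contig, satellite, RNA, ...);
#'   \item no label, or a label the synonym map cannot unify;
#'   \item length at or below the minimum (strictly more than 100 bp kept);
#'   \item missing any of the letters A, C, G and T;
#'   \item exact duplicate of an earlier kept sequence (case-insensitive
#'     full-sequence identity; first occurrence kept).
#' }
#' Survivors carry unified taxonomy codes.  The operation is idempotent:
#' curating an already-curated set changes nothing.
#'
#' @param records Data frame with columns \code{id}, \code{seq},
#'   \code{label} and optionally \code{category} (free-text category tags,
#'   \code{""}/\code{NA} for none).
#' @param rules A \code{"curation_rules"} object.
#' @param taxonomy Taxonomy the unified codes must belong to.
#' @return A list with \code{kept} (data frame \code{id}, \code{seq},
#'   \code{code}, plus pass-through columns) and \code{report} (class
#'   \code{"curation_report"}: counts per drop reason, duplicates and kept;
#'   these always reconcile exactly with the input count).
#' @export
curate_sequences <- function(records, rules = curation_rules(),
                             taxonomy = default_taxonomy()) {
  stopifnot(is.data.frame(records),
            all(c("id", "seq", "label") %in% names(records)))
  bad_target <- setdiff(unname(rules$synonym_map), taxonomy$codes)
  if (length(bad_target)) {
    stop("synonym map targets not in taxonomy: ",
         paste(bad_target, collapse = ", "))
  }
  n <- nrow(records)
  category <- if ("category" %in% names(records)) {
    tolower(ifelse(is.na(records$category), "", records$category))
  } else rep("", n)
  seqs <- toupper(records$seq)
  label <- ifelse(is.na(records$label), "", records$label)

  excl_pat <- paste(rules$excluded_keywords, collapse = "|")
  drop_cat <- nzchar(category) & grepl(excl_pat, category)

  code <- ifelse(label %in% taxonomy$codes, label,
                 unname(rules$synonym_map[label]))
  drop_lab <- !drop_cat & (!nzchar(label) | is.na(code))

  drop_len <- !drop_cat & !drop_lab & nchar(seqs) <= rules$min_length_bp

  has_all <- Reduce(`&`, lapply(rules$required_letters,
                                function(l) grepl(l, seqs, fixed = TRUE)))
  drop_let <- !drop_cat & !drop_lab & !drop_len & !has_all

  surv <- !(drop_cat | drop_lab | drop_len | drop_let)
  ## duplicates only count among surviving sequences; first occurrence kept
  dup <- surv & duplicated(replace(seqs, !surv, NA_character_),
                           incomparables = NA)

  kept <- records[surv & !dup, , drop = FALSE]
  kept$code <- code[surv & !dup]
  rownames(kept) <- NULL
  report <- structure(list(
    input = n,
    dropped = c(excluded_category = sum(drop_cat),
                unmappable_label = sum(drop_lab),
                too_short = sum(drop_len),
                missing_letters = sum(drop_let)),
    duplicates = sum(dup),
    kept = nrow(kept)), class = "curation_report")
  list(kept = kept, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report:", x$input, "input records\n")
  for (r in names(x$dropped)) {
    cat(sprintf("  dropped (%s): %d\n", r, x$dropped[[r]]))
  }
  cat("  duplicates:", x$duplicates, "\n")
  cat("  kept:", x$kept, "\n")
  invisible(x)
}

#' Merge curated transposon sets
#'
#' Combines curated sets from several source databases into a single
#' deduplicated collection.  Duplicates are exact full-sequence matches
#' (case-insensitive); the first occurrence is kept and the provenance
#' column lists every source that contributed the sequence.  Self-merge is
#' idempotent.
#'
#' @param sets Named list of curated data frames (the \code{kept} component
#'   of [curate_sequences()] output); names are the source database names.
#' @return Data frame with columns \code{id}, \code{seq}, \code{code},
#'   \code{sources} (comma-separated provenance).
#' @export
merge_curated <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("source", seq_along(sets))
  }
  all <- do.call(rbind, lapply(names(sets), function(src) {
    s <- sets[[src]]
    data.frame(id = s$id, seq = s$seq, code = s$code, source = src,
               stringsAsFactors = FALSE)
  }))
  key <- toupper(all$seq)
  first <- !duplicated(key)
  prov <- vapply(key[first], function(k) {
    paste(unique(all$source[key == k]), collapse = ",")
  }, character(1))
  out <- all[first, c("id", "seq", "code")]
  out$sources <- unname(prov)
  rownames(out) <- NULL
  out
}
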