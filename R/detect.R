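#' Transposition-event detection from structural variants
#'
#' Identifies candidate transposition events by matching filtered,
#' deduplicated structural-variant (SV) calls against transposon
#' annotations.  The pipeline is
#' \code{[filter_svs()]} (length filters) \code{->}
#' \code{[merge_sv_duplicates()]} (same-type duplicate merging) \code{->}
#' \code{[match_te_events()]} (intersection + length-similarity matching),
#' followed by [event_stats()] for summary statistics and
#' [phylo_event_regression()] for the relationship between phylogenetic
#' distance and event counts.
#'
#' Structural variants are data frames with columns \code{seqid},
#' \code{pos} (1-based), \code{end}, \code{svtype} (\code{DEL}, \code{INS},
#' \code{DUP} or \code{INV}), \code{svlen} (positive bp length), and
#' optionally \code{caller} and \code{id}.  Insertions have no reference
#' span (\code{end} may equal \code{pos}).
#'
#' @name te_detect
#' @keywords internal
NULL

SV_TYPES <- c("DEL", "INS", "DUP", "INV")

#' Detection configuration
#'
#' @param min_sv_len_bp Minimum SV length; shorter variants are excluded
#'   (strictly shorter: the default 50 keeps a 50 bp variant).
#' @param max_sv_fraction_of_genome Maximum SV length as a fraction of the
#'   genome length (default 0.01; longer variants are excluded).
#' @param min_intersection_fraction Minimum intersection, as a fraction of
#'   the shorter of SV and annotation (default 0.10).
#' @param length_similarity_threshold Minimum min/max length ratio between
#'   SV and annotation (default 0.50).
#' @param duplicate_overlap_fraction Reciprocal-overlap fraction above which
#'   same-type SVs are considered duplicates (default 0.8).
#' @param ins_window_bp Breakpoint window for insertions, used both for
#'   duplicate merging and annotation matching (default 100).
#' @return A list of class \code{"detect_config"}.
#' @export
detect_config <- function(min_sv_len_bp = 50L,
                          max_sv_fraction_of_genome = 0.01,
                          min_intersection_fraction = 0.10,
                          length_similarity_threshold = 0.50,
                          duplicate_overlap_fraction = 0.8,
                          ins_window_bp = 100L) {
  stopifnot(min_sv_len_bp >= 1L,
            max_sv_fraction_of_genome > 0, max_sv_fraction_of_genome <= 1,
            min_intersection_fraction > 0, min_intersection_fraction <= 1,
            length_similarity_threshold > 0,
            length_similarity_threshold <= 1,
            duplicate_overlap_fraction > 0, duplicate_overlap_fraction <= 1)
  structure(list(min_sv_len_bp = min_sv_len_bp,
                 max_sv_fraction_of_genome = max_sv_fraction_of_genome,
                 min_intersection_fraction = min_intersection_fraction,
                 length_similarity_threshold = length_similarity_threshold,
                 duplicate_overlap_fraction = duplicate_overlap_fraction,
                 ins_window_bp = ins_window_bp),
            class = "detect_config")
}

as_svs <- function(svs) {
  stopifnot(is.data.frame(svs),
            all(c("seqid", "pos", "svtype", "svlen") %in% names(svs)))
  if (any(!svs$svtype %in% SV_TYPES)) {
    stop("unsupported svtype(s): ",
         paste(setdiff(unique(svs$svtype), SV_TYPES), collapse = ", "))
  }
  if (any(svs$svlen <= 0)) stop("non-positive svlen in SV table")
  if (is.null(svs$end)) {
    svs$end <- ifelse(svs$svtype == "INS", svs$pos,
                      svs$pos + svs$svlen - 1L)
  }
  if (is.null(svs$caller)) svs$caller <- "unknown"
  if (is.null(svs$id)) svs$id <- paste0("sv", seq_len(nrow(svs)))
  svs
}

#' Read structural variants from a VCF file
#'
#' Extracts \code{SVTYPE}, \code{SVLEN} and \code{END} from the INFO field
#' of a VCF of structural-variant calls (symbolic ALT alleles accepted).
#' Records without a supported \code{SVTYPE} are skipped.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param caller Caller name recorded in the \code{caller} column.
#' @return An SV data frame (see [te_detect]).
#' @export
read_sv_vcf <- function(path, caller = "unknown") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("vcfR is required for VCF input")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  svtype <- vcfR::extract.info(v, "SVTYPE")
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(v, "SVLEN")))
  end <- suppressWarnings(as.numeric(vcfR::extract.info(v, "END")))
  keep <- !is.na(svtype) & svtype %in% SV_TYPES
  pos <- as.integer(fix[keep, "POS"])
  svtype <- svtype[keep]
  svlen <- abs(svlen[keep])
  end <- end[keep]
  end <- ifelse(is.na(end),
                ifelse(svtype == "INS", pos, pos + svlen - 1),
                end)
  id <- fix[keep, "ID"]
  id[is.na(id) | id == "."] <- paste0("sv", which(is.na(id) | id == "."))
  as_svs(data.frame(seqid = fix[keep, "CHROM"], pos = pos, end = end,
                    svtype = svtype, svlen = svlen, caller = caller,
                    id = id, stringsAsFactors = FALSE))
}

#' Filter structural variants by length
#'
#' Excludes variants shorter than the minimum length (strictly shorter than
#' 50 bp by default, so a 50 bp variant is kept) or longer than the stated
#' fraction of the genome (1\% by default).
#'
#' @param svs SV data frame.
#' @param genome_length_bp Total genome length in bp.
#' @param cfg A [detect_config()].
#' @return List with \code{kept} (SV data frame) and \code{report} (counts
#'   \code{input}, \code{too_short}, \code{too_long}, \code{kept}).
#' @export
filter_svs <- function(svs, genome_length_bp, cfg = detect_config()) {
  stopifnot(genome_length_bp > 0)
  svs <- as_svs(svs)
  max_len <- cfg$max_sv_fraction_of_genome * genome_length_bp
  too_short <- svs$svlen < cfg$min_sv_len_bp
  too_long <- !too_short & svs$svlen > max_len
  kept <- svs[!too_short & !too_long, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       report = c(input = nrow(svs), too_short = sum(too_short),
                  too_long = sum(too_long), kept = nrow(kept)))
}

#' Merge duplicate structural variants
#'
#' Two variants are duplicates when they share chromosome and SV type and
#' (spanned types) overlap reciprocally by at least the configured fraction
#' of each variant's span, or (insertions) have breakpoints within the
#' insertion window and a min/max length ratio of at least 0.5.  Duplicate
#' relations are closed transitively; each group collapses to the variant
#' with the longest span (ties: smallest position).  The operation is
#' idempotent.
#'
#' @inheritParams filter_svs
#' @return Deduplicated SV data frame with a \code{merged_ids} column
#'   listing the ids absorbed into each survivor.
#' @export
merge_sv_duplicates <- function(svs, cfg = detect_config()) {
  svs <- as_svs(svs)
  n <- nrow(svs)
  if (n <= 1L) {
    svs$merged_ids <- svs$id
    return(svs)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  groups <- split(seq_len(n), paste(svs$seqid, svs$svtype))
  for (g in groups) {
    if (length(g) < 2L) next
    for (a in seq_along(g)) {
      for (b in seq_len(a - 1L)) {
        i <- g[a]; j <- g[b]
        if (sv_duplicate(svs[i, ], svs[j, ], cfg)) union2(i, j)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- vapply(split(seq_len(n), root), function(idx) {
    span <- svs$svlen[idx]
    cand <- idx[span == max(span)]
    cand[which.min(svs$pos[cand])]
  }, integer(1))
  merged <- vapply(split(seq_len(n), root), function(idx) {
    paste(svs$id[idx], collapse = ",")
  }, character(1))
  out <- svs[keep, , drop = FALSE]
  out$merged_ids <- merged
  out <- out[order(out$seqid, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sv_duplicate <- function(a, b, cfg) {
  if (a$svtype == "INS") {
    abs(a$pos - b$pos) <= cfg$ins_window_bp &&
      min(a$svlen, b$svlen) / max(a$svlen, b$svlen) >= 0.5
  } else {
    inter <- min(a$end, b$end) - max(a$pos, b$pos) + 1
    if (inter <= 0) return(FALSE)
    la <- a$end - a$pos + 1
    lb <- b$end - b$pos + 1
    inter / la >= cfg$duplicate_overlap_fraction &&
      inter / lb >= cfg$duplicate_overlap_fraction
  }
}

#' Match structural variants to transposon annotations
#'
#' A spanned SV (DEL, DUP, INV) matches an annotation on the same
#' chromosome when their intersection covers at least the configured
#' fraction (default 10\%) of the shorter of the two intervals and their
#' min/max length ratio reaches the similarity threshold (default 0.5).
#' Insertions, which have no reference span, match when their breakpoint
#' falls within the annotation extended by the insertion window and the
#' same length-similarity test holds between the inserted length and the
#' annotation length.  One event is emitted per qualifying (SV, annotation)
#' pair; per SV, the pair with the largest intersection (ties: longest
#' annotation) is flagged as the best match.
#'
#' @param svs Filtered, merged SV data frame.
#' @param ann Annotation data frame (see [annotation_stats]).
#' @param cfg A [detect_config()].
#' @return Data frame of transposition events: \code{sv_id}, \code{ann_id},
#'   \code{seqid}, \code{svtype}, \code{class}, \code{sv_len},
#'   \code{ann_len}, \code{intersection_bp}, \code{length_ratio},
#'   \code{best}.
#' @export
match_te_events <- function(svs, ann, cfg = detect_config()) {
  svs <- as_svs(svs)
  ann <- as_annotations(ann)
  events <- list()
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, ]
    cand <- ann[ann$seqid == sv$seqid, , drop = FALSE]
    if (nrow(cand) == 0L) next
    alen <- cand$end - cand$start + 1L
    ratio <- pmin(sv$svlen, alen) / pmax(sv$svlen, alen)
    if (sv$svtype == "INS") {
      hit <- sv$pos >= cand$start - cfg$ins_window_bp &
        sv$pos <= cand$end + cfg$ins_window_bp &
        ratio >= cfg$length_similarity_threshold
      inter <- rep(0, nrow(cand))
    } else {
      inter <- pmin(sv$end, cand$end) - pmax(sv$pos, cand$start) + 1
      inter[inter < 0] <- 0
      sv_span <- sv$end - sv$pos + 1
      need <- cfg$min_intersection_fraction * pmin(sv_span, alen)
      hit <- inter >= need & inter > 0 &
        ratio >= cfg$length_similarity_threshold
    }
    if (!any(hit)) next
    ev <- data.frame(sv_id = sv$id, ann_id = cand$id[hit],
                     seqid = sv$seqid, svtype = sv$svtype,
                     class = cand$class[hit], sv_len = sv$svlen,
                     ann_len = alen[hit], intersection_bp = inter[hit],
                     length_ratio = ratio[hit], stringsAsFactors = FALSE)
    best <- order(-ev$intersection_bp, -ev$ann_len)[1L]
    ev$best <- seq_len(nrow(ev)) == best
    events[[length(events) + 1L]] <- ev
  }
  if (length(events) == 0L) {
    return(data.frame(sv_id = character(0), ann_id = character(0),
                      seqid = character(0), svtype = character(0),
                      class = character(0), sv_len = numeric(0),
                      ann_len = numeric(0), intersection_bp = numeric(0),
                      length_ratio = numeric(0), best = logical(0)))
  }
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Run the full detection pipeline
#'
#' Convenience wrapper: [filter_svs()] then [merge_sv_duplicates()] then
#' [match_te_events()].
#'
#' @inheritParams match_te_events
#' @inheritParams filter_svs
#' @return List with \code{events}, \code{svs} (post filter+merge) and
#'   \code{filter_report}.
#' @export
detect_events <- function(svs, ann, genome_length_bp,
                          cfg = detect_config()) {
  flt <- filter_svs(svs, genome_length_bp, cfg)
  merged <- merge_sv_duplicates(flt$kept, cfg)
  events <- match_te_events(merged, ann, cfg)
  list(events = events, svs = merged, filter_report = flt$report)
}

#' Transposition-event summary statistics
#'
#' From the best-match events (one per SV): the share of each SV type among
#' events, and the relative activity of each transposon class.  Relative
#' activity is the class's share of base pairs among transposition events
#' divided by its share of base pairs in the annotation set; a value above
#' 1 marks a class that is over-represented among events relative to its
#' genomic abundance.  A class with events but no annotated base pairs gets
#' \code{Inf}.
#'
#' @param events Event data frame from [match_te_events()].
#' @param ann Annotation data frame the events were matched against.
#' @return List with \code{n_events}, \code{svtype_share} (named vector over
#'   DEL/INS/DUP/INV) and \code{relative_activity} (data frame
#'   \code{class}, \code{event_bp_share}, \code{annotation_bp_share},
#'   \code{relative_activity}).
#' @export
event_stats <- function(events, ann) {
  ann <- as_annotations(ann)
  best <- if (!is.null(events$best)) {
    events[events$best, , drop = FALSE]
  } else events
  n <- nrow(best)
  share <- if (n > 0) {
    prop.table(table(factor(best$svtype, levels = SV_TYPES)))
  } else {
    table(factor(character(0), levels = SV_TYPES))
  }
  ev_cls <- ifelse(is.na(best$class) | !nzchar(best$class), "unknown",
                   best$class)
  ev_bp <- tapply(as.numeric(best$sv_len), ev_cls, sum)
  ann_cls <- ifelse(is.na(ann$class) | !nzchar(ann$class), "unknown",
                    ann$class)
  ann_bp <- tapply(as.numeric(ann$end - ann$start + 1L), ann_cls, sum)
  classes <- sort(unique(c(names(ev_bp), names(ann_bp))))
  evs <- ifelse(classes %in% names(ev_bp), ev_bp[classes], 0)
  ans <- ifelse(classes %in% names(ann_bp), ann_bp[classes], 0)
  ev_share <- if (sum(evs) > 0) evs / sum(evs) else evs
  an_share <- if (sum(ans) > 0) ans / sum(ans) else ans
  ra <- ifelse(an_share > 0, ev_share / an_share,
               ifelse(ev_share > 0, Inf, NA_real_))
  list(n_events = n,
       svtype_share = stats::setNames(as.numeric(share), SV_TYPES),
       relative_activity = data.frame(
         class = classes,
         event_bp_share = as.numeric(ev_share),
         annotation_bp_share = as.numeric(an_share),
         relative_activity = as.numeric(ra),
         stringsAsFactors = FALSE))
}

#' Regression of event counts on phylogenetic distance
#'
#' Ordinary least-squares fit of observed transposition-event counts
#' against pairwise phylogenetic distances, with the Pearson correlation.
#'
#' @param distance Numeric vector of phylogenetic distances.
#' @param events Numeric vector of event counts (same length, >= 3 pairs).
#' @return List with \code{slope}, \code{intercept}, \code{r} and the
#'   underlying \code{lm} fit.
#' @export
phylo_event_regression <- function(distance, events) {
  stopifnot(length(distance) == length(events))
  if (length(distance) < 3L) stop("at least 3 pairs are required")
  fit <- stats::lm(events ~ distance)
  r <- if (stats::sd(distance) > 0 && stats::sd(events) > 0) {
    stats::cor(distance, events)
  } else 0
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = r, fit = fit)
}

#' Patristic distance between two leaves of a phylogeny
#'
#' The sum of branch lengths from each leaf to their last common ancestor.
#'
#' @param tree An \pkg{ape} \code{"phylo"} tree (or a newick string / file
#'   path, parsed with [ape::read.tree()]).
#' @param a,b Tip labels.
#' @return Numeric distance.
#' @export
patristic_distance <- function(tree, a, b) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  d <- ape::cophenetic.phylo(tree)
  if (!a %in% rownames(d) || !b %in% rownames(d)) {
    stop("unknown tip label(s)")
  }
  d[a, b]
}
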