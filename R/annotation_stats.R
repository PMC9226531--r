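#' Genome-wide transposon annotation statistics
#'
#' Aggregation layer over per-tool transposon annotations: build the
#' transposon region mask (union of all annotated base pairs), compute the
#' genome's TE content, per-class composition, length distributions,
#' density tracks along chromosomes and the pairwise overlap between
#' annotation tools.
#'
#' Annotations are plain data frames with columns \code{seqid},
#' \code{start}, \code{end} (1-based inclusive, as in GFF3), and optionally
#' \code{strand}, \code{class} (taxonomy code or \code{NA}), \code{tool}
#' and \code{id}.  [read_te_gff3()] / [write_te_gff3()] convert to and from
#' GFF3 files.
#'
#' @name annotation_stats
#' @keywords internal
NULL

## validate and coerce an annotation data frame; fill optional columns
as_annotations <- function(ann) {
  stopifnot(is.data.frame(ann),
            all(c("seqid", "start", "end") %in% names(ann)))
  bad <- which(ann$start > ann$end)
  if (length(bad)) {
    stop("annotation with start > end at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  n <- nrow(ann)
  if (is.null(ann$strand)) ann$strand <- rep("*", n)
  if (is.null(ann$class)) ann$class <- rep(NA_character_, n)
  if (is.null(ann$tool)) ann$tool <- rep("unknown", n)
  if (is.null(ann$id)) {
    ann$id <- if (n) paste0("te", seq_len(n)) else character(0)
  }
  ann
}

ann_granges <- function(ann) {
  GenomicRanges::GRanges(ann$seqid,
                         IRanges::IRanges(ann$start, ann$end),
                         strand = "*")
}

#' Read / write transposon annotations as GFF3
#'
#' Thin wrappers around \pkg{rtracklayer}'s GFF3 import/export.  The GFF3
#' \code{source} column holds the annotation tool, and the attributes
#' \code{ID} and \code{classification} hold the annotation id and taxonomy
#' class code.
#'
#' @param path GFF3 file path.
#' @param ann Annotation data frame (see [as_annotations()] columns).
#' @return \code{read_te_gff3()}: an annotation data frame;
#'   \code{write_te_gff3()}: \code{path}, invisibly.
#' @export
read_te_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GFF3 I/O")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  cls <- if ("classification" %in% names(md)) {
    as.character(md$classification)
  } else NA_character_
  tool <- if ("source" %in% names(md)) as.character(md$source) else "unknown"
  id <- if ("ID" %in% names(md)) as.character(md$ID) else
    paste0("te", seq_along(gr))
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             class = cls, tool = tool, id = id,
             stringsAsFactors = FALSE)
}

#' @rdname read_te_gff3
#' @export
write_te_gff3 <- function(ann, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GFF3 I/O")
  }
  ann <- as_annotations(ann)
  gr <- GenomicRanges::GRanges(
    ann$seqid, IRanges::IRanges(ann$start, ann$end),
    strand = ifelse(ann$strand %in% c("+", "-"), ann$strand, "*"))
  S4Vectors::mcols(gr)$source <- ann$tool
  S4Vectors::mcols(gr)$type <- "transposable_element"
  S4Vectors::mcols(gr)$ID <- ann$id
  S4Vectors::mcols(gr)$classification <- ann$class
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Build the transposon region mask
#'
#' The mask is the per-chromosome union of all annotated intervals:
#' overlapping and book-ended annotations coalesce into single segments.
#'
#' @param ann Annotation data frame.
#' @return Data frame with columns \code{seqid}, \code{start}, \code{end}:
#'   sorted, pairwise disjoint segments.
#' @examples
#' build_mask(data.frame(seqid = "chr1", start = c(100, 150),
#'                       end = c(200, 250)))  # one segment 100-250
#' @export
build_mask <- function(ann) {
  ann <- as_annotations(ann)
  if (nrow(ann) == 0L) {
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0)))
  }
  red <- GenomicRanges::reduce(ann_granges(ann))
  red <- GenomicRanges::sort(red)
  data.frame(seqid = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red),
             end = GenomicRanges::end(red),
             stringsAsFactors = FALSE)
}

mask_bp <- function(mask) {
  if (nrow(mask) == 0L) return(0)
  sum(as.numeric(mask$end - mask$start + 1L))
}

#' Genome TE content
#'
#' The TE content is the ratio of the number of base pairs in the transposon
#' region mask to the total genome size, as a percentage.
#'
#' @param mask Mask data frame from [build_mask()] (an annotation data frame
#'   is accepted and reduced first).
#' @param genome_length_bp Total genome length in bp (scalar, or named
#'   vector of per-sequence lengths which is summed).
#' @return Percentage in \code{[0, 100]}.
#' @export
te_content <- function(mask, genome_length_bp) {
  total <- sum(as.numeric(genome_length_bp))
  stopifnot(total > 0)
  mask <- build_mask(mask)
  bp <- mask_bp(mask)
  if (bp > total) stop("mask covers more base pairs than the genome")
  100 * bp / total
}

#' Per-class annotation statistics
#'
#' Computes, per taxonomy class (annotations without a class pooled under
#' \code{"unknown"}):
#' \itemize{
#'   \item content percent: summed annotation lengths over genome length
#'     (raw lengths, not the union mask — overlapping copies count twice);
#'   \item element count and count share;
#'   \item length distribution: 25/50/75 percentiles (linear interpolation,
#'     quantile type 7) and 1.5 x IQR whisker positions.
#' }
#'
#' @param ann Annotation data frame.
#' @param genome_length_bp Total genome length in bp.
#' @return Data frame, one row per class, columns \code{class}, \code{n},
#'   \code{count_share}, \code{content_percent}, \code{len_q25},
#'   \code{len_median}, \code{len_q75}, \code{whisker_low},
#'   \code{whisker_high}.
#' @export
class_stats <- function(ann, genome_length_bp) {
  ann <- as_annotations(ann)
  total <- sum(as.numeric(genome_length_bp))
  stopifnot(total > 0)
  cls <- ifelse(is.na(ann$class) | !nzchar(ann$class), "unknown", ann$class)
  len <- ann$end - ann$start + 1L
  out <- do.call(rbind, lapply(sort(unique(cls)), function(cl) {
    l <- len[cls == cl]
    q <- stats::quantile(l, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(class = cl, n = length(l),
               count_share = length(l) / nrow(ann),
               content_percent = 100 * sum(as.numeric(l)) / total,
               len_q25 = q[1], len_median = q[2], len_q75 = q[3],
               whisker_low = q[1] - 1.5 * iqr,
               whisker_high = q[3] + 1.5 * iqr,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Annotation density along chromosomes
#'
#' Tiles each chromosome with fixed windows starting at position 1 and
#' reports, per window, the number of annotations starting in it and the
#' number of annotated base pairs covering it (an annotation spanning a
#' window boundary is counted in its start window but its covered base
#' pairs are split across windows).
#'
#' @param ann Annotation data frame.
#' @param window_bp Window size in bp.
#' @param seqlens Named vector of sequence lengths; defaults to the largest
#'   annotated coordinate per chromosome.
#' @return Data frame with columns \code{seqid}, \code{window_start},
#'   \code{window_end}, \code{count}, \code{covered_bp}.
#' @export
density_track <- function(ann, window_bp, seqlens = NULL) {
  stopifnot(window_bp > 0)
  ann <- as_annotations(ann)
  if (is.null(seqlens)) {
    seqlens <- tapply(ann$end, ann$seqid, max)
  }
  out <- lapply(names(seqlens), function(chr) {
    L <- as.numeric(seqlens[[chr]])
    starts <- seq(1, L, by = window_bp)
    ends <- pmin(starts + window_bp - 1, L)
    a <- ann[ann$seqid == chr, , drop = FALSE]
    cnt <- integer(length(starts))
    cov <- numeric(length(starts))
    if (nrow(a) > 0L) {
      widx <- ((a$start - 1L) %/% window_bp) + 1L
      tab <- table(widx)
      cnt[as.integer(names(tab))] <- as.integer(tab)
      win <- IRanges::IRanges(starts, ends)
      annr <- IRanges::reduce(IRanges::IRanges(a$start, a$end))
      hits <- IRanges::findOverlaps(win, annr)
      if (length(hits) > 0L) {
        inter <- IRanges::pintersect(
          win[S4Vectors::queryHits(hits)], annr[S4Vectors::subjectHits(hits)])
        cov_by <- tapply(IRanges::width(inter), S4Vectors::queryHits(hits),
                         sum)
        cov[as.integer(names(cov_by))] <- as.numeric(cov_by)
      }
    }
    data.frame(seqid = chr, window_start = starts, window_end = ends,
               count = cnt, covered_bp = cov, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pairwise overlap between annotation tools
#'
#' For every ordered pair of tools (i, j), the share of tool i's mask base
#' pairs that are also covered by tool j's mask.  The matrix is asymmetric:
#' if A's annotations are a subset of B's covering half the base pairs,
#' entry (A, B) is 1 and (B, A) is 0.5.  Tools with an empty mask get 0 in
#' their row.
#'
#' @param ann Annotation data frame with a \code{tool} column, or a named
#'   list of per-tool annotation data frames.
#' @return Square numeric matrix, rows/columns named by tool.
#' @export
tool_overlap <- function(ann) {
  if (is.data.frame(ann)) {
    ann <- as_annotations(ann)
    sets <- split(ann, ann$tool)
  } else {
    sets <- lapply(ann, as_annotations)
  }
  if (length(sets) < 2L) stop("at least two tools are required")
  masks <- lapply(sets, function(a) ann_granges(as_annotations(build_mask_df(a))))
  tools <- names(sets)
  m <- matrix(0, length(tools), length(tools),
              dimnames = list(tools, tools))
  bp <- vapply(masks, function(g) sum(as.numeric(GenomicRanges::width(g))),
               numeric(1))
  for (i in seq_along(tools)) {
    if (bp[i] == 0) next
    for (j in seq_along(tools)) {
      inter <- suppressWarnings(
        GenomicRanges::intersect(masks[[i]], masks[[j]]))
      m[i, j] <- sum(as.numeric(GenomicRanges::width(inter))) / bp[i]
    }
  }
  m
}

## build_mask() returning a frame usable as annotations again
build_mask_df <- function(ann) {
  mk <- build_mask(ann)
  if (nrow(mk) == 0L) {
    mk <- data.frame(seqid = character(0), start = integer(0),
                     end = integer(0))
  }
  mk
}
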