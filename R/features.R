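#' Feature extraction for transposon classification
#'
#' The classifier's feature vector concatenates two blocks:
#' \itemize{
#'   \item relative k-mer frequencies for k = 2, 3, 4 (16 + 64 + 256 = 336
#'     values), each in \code{[0, 1]};
#'   \item 169 binary protein-domain indicators, one per conserved-domain
#'     accession, set when a domain hit at or below the e-value threshold is
#'     present for the sequence.
#' }
#' The relative frequency of a k-mer is its overlapping occurrence count in
#' the sequence divided by the number of times it would occur if the sequence
#' consisted of that k-mer alone, i.e. in the k-mer's own periodic tiling
#' truncated to the sequence length.  This normalisation bounds every k-mer
#' feature by 1 regardless of the k-mer's internal periodicity.
#'
#' @name te_features
#' @keywords internal
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

## all k-mers over ACGT in lexicographic order
all_kmers <- function(k) {
  grid <- do.call(expand.grid,
                  c(rep(list(DNA_ALPHABET), k), stringsAsFactors = FALSE))
  ## expand.grid varies the first factor fastest; reverse for lexicographic
  do.call(paste0, rev(grid))
}

## rotation shifts s in 0..k-1 under which the k-mer maps to itself.
## Occurrences of a k-mer in its own tiling of length L happen exactly at
## positions i with (i - 1) mod k in this set (and i + k - 1 <= L).
kmer_self_shifts <- function(kmer) {
  k <- nchar(kmer)
  chars <- strsplit(kmer, "")[[1L]]
  shifts <- integer(0)
  for (s in 0:(k - 1L)) {
    rot <- paste(chars[((seq_len(k) - 1L + s) %% k) + 1L], collapse = "")
    if (rot == kmer) shifts <- c(shifts, s)
  }
  shifts
}

## occurrences of `kmer` in tile(kmer, L): closed form from the self-shifts
tiling_count <- function(kmer, L) {
  k <- nchar(kmer)
  if (L < k) return(0L)
  shifts <- kmer_self_shifts(kmer)
  shifts <- shifts[shifts <= L - k]
  if (length(shifts) == 0L) return(0L)
  sum(((L - k - shifts) %/% k) + 1L)
}

#' Relative k-mer frequency of a single k-mer
#'
#' Counts overlapping occurrences of \code{kmer} in \code{seq} (case
#' insensitive; windows containing non-ACGT characters never match) and
#' divides by the occurrence count of \code{kmer} in its own periodic tiling
#' of the same length.  Sequences shorter than the k-mer yield 0 with a
#' warning.
#'
#' @param seq A nucleotide sequence (single character string).
#' @param kmer The k-mer (single character string over ACGT).
#' @return A numeric scalar in \code{[0, 1]}.
#' @examples
#' relative_kmer_frequency("ACACAC", "AC")  # 1
#' relative_kmer_frequency("ACGT", "CG")    # 0.5
#' @export
relative_kmer_frequency <- function(seq, kmer) {
  stopifnot(length(seq) == 1L, length(kmer) == 1L)
  kmer <- toupper(kmer)
  if (!grepl("^[ACGT]+$", kmer)) stop("k-mer must be over the ACGT alphabet")
  L <- nchar(seq)
  k <- nchar(kmer)
  if (L < k) {
    warning("sequence shorter than k-mer; returning 0")
    return(0)
  }
  denom <- tiling_count(kmer, L)
  if (denom == 0L) return(0)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(toupper(chartr("U", "T", seq))), width = k)
  unname(counts[kmer]) / denom
}

## denominator matrix for a vector of sequence lengths: n x 4^k
tiling_denominators <- function(kmers, lengths) {
  k <- nchar(kmers[1L])
  shift_sets <- lapply(kmers, kmer_self_shifts)
  out <- matrix(0, nrow = length(lengths), ncol = length(kmers),
                dimnames = list(NULL, kmers))
  for (j in seq_along(kmers)) {
    cnt <- numeric(length(lengths))
    for (s in shift_sets[[j]]) {
      ok <- lengths >= k + s
      cnt[ok] <- cnt[ok] + ((lengths[ok] - k - s) %/% k) + 1
    }
    out[, j] <- cnt
  }
  out
}

#' Relative k-mer frequency block
#'
#' Computes the full k-mer feature block for one or more sequences: for every
#' k in \code{ks} and every k-mer over ACGT in lexicographic order, the
#' relative k-mer frequency as defined in [relative_kmer_frequency()].
#'
#' @param seqs A character vector of nucleotide sequences (optionally named),
#'   or a [Biostrings::DNAStringSet].
#' @param ks Integer vector of k values; the default \code{c(2, 3, 4)} gives
#'   a 336-dimensional block.
#' @return A numeric matrix with one row per sequence and columns named
#'   \code{"k<k>_<kmer>"}; all entries in \code{[0, 1]}.
#' @examples
#' kmer_block(c(s1 = "ACGTACGT"))[, c("k2_AC", "k2_CG")]
#' @export
kmer_block <- function(seqs, ks = c(2L, 3L, 4L)) {
  stopifnot(all(ks >= 1L))
  if (methods::is(seqs, "DNAStringSet")) {
    set <- seqs
  } else {
    set <- Biostrings::DNAStringSet(toupper(chartr("Uu", "Tt", seqs)))
  }
  lens <- Biostrings::width(set)
  blocks <- lapply(ks, function(k) {
    kmers <- all_kmers(k)
    counts <- Biostrings::oligonucleotideFrequency(set, width = k)
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                               dimnames = list(NULL, kmers))
    if (any(lens < k)) {
      warning(sum(lens < k), " sequence(s) shorter than k = ", k,
              "; their k-mer features are 0")
    }
    denom <- tiling_denominators(kmers, lens)
    freq <- counts / denom
    freq[!is.finite(freq)] <- 0
    colnames(freq) <- paste0("k", k, "_", kmers)
    freq
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- names(seqs) %||% names(set)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default conserved-domain accession list
#'
#' The 169 protein-domain accessions used for the binary domain block.  The
#' shipped list (\code{extdata/domains_synthetic.txt}) is a synthetic
#' stand-in assembled from conserved-domain families commonly associated
#' with transposons (reverse transcriptases, integrases, transposases,
#' helicases, ...); replace it with a curated list for production use.  Any
#' list of unique accessions works: the feature layout follows the file
#' order.
#'
#' @return Character vector of 169 domain accessions.
#' @export
default_domains <- function() {
  path <- system.file("extdata", "domains_synthetic.txt",
                      package = "transposcope", mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read a protein-domain hit table
#'
#' Reads the tab-separated tabular output of an RPSTBLASTN-style search.
#' The default column map expects at least \code{qseqid}, \code{sseqid} and
#' \code{evalue} in columns 1, 2 and 3; other layouts can be declared via
#' \code{col_map}.
#'
#' @param path Path to the tab-separated hit table (no header).
#' @param col_map Named integer vector giving the column positions of
#'   \code{seq_id}, \code{domain_id} and \code{evalue}.
#' @return A data frame with columns \code{seq_id}, \code{domain_id},
#'   \code{evalue}.
#' @export
read_domain_hits <- function(path,
                             col_map = c(seq_id = 1L, domain_id = 2L,
                                         evalue = 3L)) {
  stopifnot(all(c("seq_id", "domain_id", "evalue") %in% names(col_map)))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  data.frame(seq_id = as.character(raw[[col_map[["seq_id"]]]]),
             domain_id = as.character(raw[[col_map[["domain_id"]]]]),
             evalue = as.numeric(raw[[col_map[["evalue"]]]]),
             stringsAsFactors = FALSE)
}

#' Binary protein-domain block
#'
#' Builds the binary domain-presence indicators for one or more sequence
#' ids from a domain hit table.  Entry (i, j) is 1 when the table contains a
#' hit of sequence i against domain j with e-value at or below the
#' threshold (the boundary is inclusive: e = 5.0 passes the default
#' threshold 5.0).  Hits referencing domains outside \code{domains} are
#' ignored and counted in the \code{"skipped"} attribute.
#'
#' @param seq_ids Character vector of sequence ids (rows of the result).
#' @param hits Data frame with columns \code{seq_id}, \code{domain_id},
#'   \code{evalue} (see [read_domain_hits()]).
#' @param domains Ordered character vector of domain accessions defining the
#'   feature layout; defaults to [default_domains()].
#' @param evalue_threshold Numeric e-value cutoff, default 5.0.
#' @return A 0/1 integer matrix, rows \code{seq_ids}, columns
#'   \code{domains}, with an integer attribute \code{"skipped"} counting
#'   ignored unknown-domain hits.
#' @export
domain_block <- function(seq_ids, hits, domains = default_domains(),
                         evalue_threshold = 5.0) {
  stopifnot(evalue_threshold > 0, !anyDuplicated(domains))
  out <- matrix(0L, nrow = length(seq_ids), ncol = length(domains),
                dimnames = list(seq_ids, domains))
  skipped <- 0L
  if (NROW(hits) > 0L) {
    stopifnot(all(c("seq_id", "domain_id", "evalue") %in% names(hits)))
    if (any(hits$evalue < 0)) stop("negative e-value in hit table")
    unknown <- !(hits$domain_id %in% domains)
    skipped <- sum(unknown)
    keep <- !unknown & hits$evalue <= evalue_threshold &
      hits$seq_id %in% seq_ids
    if (any(keep)) {
      out[cbind(match(hits$seq_id[keep], seq_ids),
                match(hits$domain_id[keep], domains))] <- 1L
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' Build the full feature matrix
#'
#' Concatenates the k-mer block and the domain block into the feature matrix
#' used by [te_classifier()].  With the default configuration the layout is
#' 336 k-mer features followed by 169 domain indicators (505 columns).  The
#' column-name vector is the feature layout; trained models store it and
#' refuse to predict on a different layout.
#'
#' @param seqs Named character vector of nucleotide sequences (names are the
#'   sequence ids) or a named [Biostrings::DNAStringSet].
#' @param hits Domain hit table (see [read_domain_hits()]); \code{NULL} for
#'   an all-zero domain block.
#' @param ks Integer vector of k values (default \code{c(2, 3, 4)}).
#' @param domains Ordered domain accession list (default
#'   [default_domains()]).
#' @param evalue_threshold E-value cutoff for domain presence, default 5.0.
#' @return Numeric matrix, one row per sequence.
#' @examples
#' fv <- build_feature_matrix(c(s1 = "ACGTACGTAA"), hits = NULL,
#'                            domains = c("d1", "d2"))
#' dim(fv)  # 1 x 338
#' @export
build_feature_matrix <- function(seqs, hits = NULL, ks = c(2L, 3L, 4L),
                                 domains = default_domains(),
                                 evalue_threshold = 5.0) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  km <- kmer_block(seqs, ks)
  if (is.null(hits)) {
    hits <- data.frame(seq_id = character(0), domain_id = character(0),
                       evalue = numeric(0))
  }
  dm <- domain_block(ids, hits, domains, evalue_threshold)
  out <- cbind(km, dm)
  rownames(out) <- ids
  out
}
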