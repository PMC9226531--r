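#' Deterministic synthetic data for transposon analysis
#'
#' Three generators make every pipeline stage testable without external
#' downloads: [simulate_te_sequences()] emits labelled transposon-like
#' sequences whose classes differ by k-mer composition and pseudo protein
#' domains (mirroring the two real feature families);
#' [simulate_te_genome()] plants labelled TE copies into a random genome
#' at recorded coordinates; [simulate_te_svs()] turns planted TEs into
#' structural-variant calls with optional breakpoint jitter, sub-threshold
#' decoys and duplicate caller copies.  All generators are pure functions
#' of their arguments and seed: the same call produces identical output.
#'
#' @name te_simulate
#' @keywords internal
NULL

## Markov order-1 transition matrix for one class: uniform 0.25 plus a
## class-specific perturbation of the given strength, rows renormalized.
class_transition <- function(class_idx, bias_strength) {
  P <- matrix(0.25, 4, 4, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  if (bias_strength > 0) {
    ## deterministic per-class perturbation pattern
    set <- ((class_idx - 1L + seq_len(4L)) %% 4L) + 1L
    for (r in 1:4) {
      P[r, set[r]] <- P[r, set[r]] + 0.5 * bias_strength
    }
    P <- P / rowSums(P)
  }
  P
}

markov_seq <- function(len, P) {
  out <- character(len)
  out[1L] <- sample(DNA_ALPHABET, 1L)
  for (i in seq_len(len - 1L)) {
    out[i + 1L] <- sample(DNA_ALPHABET, 1L, prob = P[out[i], ])
  }
  paste(out, collapse = "")
}

#' Simulate labelled transposon sequences
#'
#' Draws sequences for a set of leaf classes from class-specific order-1
#' Markov chains and emits class-specific pseudo-domain hits with e-values
#' below the detection threshold, so both feature families carry class
#' signal.  With \code{bias_strength = 0} all classes share one composition
#' and no informative domains are emitted (negative control); a warning is
#' raised in that case.
#'
#' @param classes Leaf class codes to simulate; default four classes
#'   spanning retrotransposons and DNA transposons.
#' @param n_per_class Sequences per class (default 200).
#' @param length_range Sequence length range in bp (default 300-800).
#' @param bias_strength Strength of the per-class compositional bias in
#'   \code{[0, 1]} (default 0.6); 0 = identical classes.
#' @param domains_per_class Class-specific pseudo-domains per class
#'   (default 2); ignored when \code{bias_strength} is 0.
#' @param domain_hit_prob Probability that a sequence receives each of its
#'   class's domain hits (default 0.9).
#' @param evalue_threshold Hits are drawn uniformly below this e-value
#'   (default 5.0).
#' @param taxonomy Taxonomy to prune to the simulated classes (default
#'   [default_taxonomy()]).
#' @param seed Integer seed.
#' @return List with \code{sequences} (named character vector),
#'   \code{labels} (named character vector of class codes), \code{hits}
#'   (domain hit table), \code{domain_pool} (the ordered pseudo-domain
#'   layout), \code{taxonomy} (pruned) and \code{classes}.
#' @export
simulate_te_sequences <- function(classes = c("1/1/1", "1/1/2", "2/1/1",
                                              "2/2"),
                                  n_per_class = 200L,
                                  length_range = c(300L, 800L),
                                  bias_strength = 0.6,
                                  domains_per_class = 2L,
                                  domain_hit_prob = 0.9,
                                  evalue_threshold = 5.0,
                                  taxonomy = default_taxonomy(),
                                  seed = 1L) {
  stopifnot(length(classes) >= 2L, n_per_class >= 1L)
  if (bias_strength == 0) {
    warning("bias_strength = 0: all classes share one composition ",
            "(negative control)")
  }
  tax <- tax_prune(taxonomy, classes)
  set.seed(seed)
  n_dom <- if (bias_strength > 0) domains_per_class else 0L
  domain_pool <- paste0("simdom", sprintf("%03d",
                                          seq_len(max(1L, n_dom * length(classes)))))
  seqs <- character(0)
  labels <- character(0)
  hit_rows <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    P <- class_transition(ci, bias_strength)
    cl_doms <- if (n_dom > 0) {
      domain_pool[((ci - 1L) * n_dom + 1L):(ci * n_dom)]
    } else character(0)
    for (j in seq_len(n_per_class)) {
      id <- sprintf("%s_seq%03d", gsub("/", ".", cl), j)
      len <- sample(length_range[1L]:length_range[2L], 1L)
      seqs[id] <- markov_seq(len, P)
      labels[id] <- cl
      for (d in cl_doms) {
        if (stats::runif(1) < domain_hit_prob) {
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            seq_id = id, domain_id = d,
            evalue = stats::runif(1, 0, evalue_threshold),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(hit_rows)) {
    do.call(rbind, hit_rows)
  } else {
    data.frame(seq_id = character(0), domain_id = character(0),
               evalue = numeric(0))
  }
  list(sequences = seqs, labels = labels, hits = hits,
       domain_pool = domain_pool, taxonomy = tax, classes = classes)
}

#' Simulate a genome with planted transposon copies
#'
#' Builds a random background genome and plants labelled TE copies at
#' recorded coordinates.  In non-overlapping mode (the default), copies are
#' placed left to right with random gaps, so the planted base-pair total is
#' exact: planting 21\% of the genome yields a mask of exactly 21\%.
#'
#' @param genome_length_bp Genome length (single chromosome; default
#'   100000).
#' @param te_lengths Integer vector of TE copy lengths.  Alternatively give
#'   \code{te_fraction} and \code{n_tes} to derive equal lengths summing to
#'   an exact fraction of the genome.
#' @param te_fraction Fraction of the genome to cover with TEs (used when
#'   \code{te_lengths} is \code{NULL}).
#' @param n_tes Number of planted copies (with \code{te_fraction}).
#' @param classes Class codes cycled over the planted copies.
#' @param overlap Allow planted copies to overlap (default \code{FALSE};
#'   when \code{TRUE}, positions are drawn independently).
#' @param seqid Chromosome name (default \code{"chr1"}).
#' @param seed Integer seed.
#' @return List with \code{genome} (named character vector of length 1),
#'   \code{annotations} (annotation data frame with \code{class} and
#'   \code{tool = "simulated"}) and \code{genome_length_bp}.
#' @export
simulate_te_genome <- function(genome_length_bp = 100000L,
                               te_lengths = NULL, te_fraction = 0.1,
                               n_tes = 20L,
                               classes = c("1/1/1", "2/1/1"),
                               overlap = FALSE, seqid = "chr1",
                               seed = 1L) {
  set.seed(seed)
  if (is.null(te_lengths)) {
    total <- round(te_fraction * genome_length_bp)
    base <- total %/% n_tes
    te_lengths <- rep(base, n_tes)
    te_lengths[seq_len(total - base * n_tes)] <-
      te_lengths[seq_len(total - base * n_tes)] + 1L
  }
  n <- length(te_lengths)
  if (!overlap && sum(te_lengths) > genome_length_bp) {
    stop("planted TE base pairs exceed the genome length")
  }
  if (n > 0L && !overlap) {
    slack <- genome_length_bp - sum(te_lengths)
    ## random composition of the slack into n+1 non-negative gaps
    cuts <- sort(sample.int(slack + n, n, replace = FALSE))
    gaps <- diff(c(0L, cuts, slack + n + 1L)) - 1L
    starts <- cumsum(c(gaps[seq_len(n)])) +
      cumsum(c(0L, te_lengths[-n])) + 1L
  } else if (n > 0L) {
    starts <- sample.int(genome_length_bp - max(te_lengths) + 1L, n,
                         replace = TRUE)
  } else {
    starts <- integer(0)
  }
  genome <- paste(sample(DNA_ALPHABET, genome_length_bp, replace = TRUE),
                  collapse = "")
  ann <- if (n > 0L) {
    data.frame(seqid = seqid, start = starts,
               end = starts + te_lengths - 1L, strand = "+",
               class = rep_len(classes, n), tool = "simulated",
               id = sprintf("planted%03d", seq_len(n)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(seqid = character(0), start = integer(0), end = integer(0),
               strand = character(0), class = character(0),
               tool = character(0), id = character(0))
  }
  ## overwrite planted regions with class-biased sequence so copies are
  ## compositionally distinct from the background
  if (n > 0L) {
    gch <- strsplit(genome, "")[[1L]]
    for (i in seq_len(n)) {
      ci <- match(ann$class[i], unique(ann$class))
      P <- class_transition(ci, 0.6)
      gch[ann$start[i]:ann$end[i]] <-
        strsplit(markov_seq(te_lengths[i], P), "")[[1L]]
    }
    genome <- paste(gch, collapse = "")
  }
  list(genome = stats::setNames(genome, seqid), annotations = ann,
       genome_length_bp = genome_length_bp)
}

#' Simulate structural-variant calls from planted transposons
#'
#' Emits a chosen subset of planted TE annotations as structural-variant
#' calls (types cycled from \code{svtypes}), optionally with breakpoint
#' jitter, duplicate copies attributed to a second caller, and sub-minimum
#' decoy variants that the length filter must remove.  The ground-truth
#' event list (which SV corresponds to which planted TE) is returned
#' alongside.
#'
#' @param annotations Planted annotation data frame (from
#'   [simulate_te_genome()]).
#' @param n_events Number of annotations to emit as true events (default:
#'   all).
#' @param svtypes SV types cycled over the events (default
#'   \code{c("DEL", "INS", "DUP", "INV")}).
#' @param jitter_bp Maximum absolute breakpoint jitter (default 0).
#' @param n_decoys Number of sub-50 bp decoy variants (default 0).
#' @param duplicate_copies Number of extra near-identical copies per true
#'   event, attributed to \code{"caller2"} (default 0).
#' @param seed Integer seed.
#' @return List with \code{svs} (SV data frame) and \code{truth} (data
#'   frame \code{sv_id}, \code{ann_id}).
#' @export
simulate_te_svs <- function(annotations, n_events = nrow(annotations),
                            svtypes = SV_TYPES, jitter_bp = 0L,
                            n_decoys = 0L, duplicate_copies = 0L,
                            seed = 1L) {
  stopifnot(n_events <= nrow(annotations))
  set.seed(seed)
  picked <- sort(sample.int(nrow(annotations), n_events))
  rows <- list()
  truth <- list()
  for (k in seq_along(picked)) {
    a <- annotations[picked[k], ]
    type <- svtypes[((k - 1L) %% length(svtypes)) + 1L]
    jit <- if (jitter_bp > 0) sample(-jitter_bp:jitter_bp, 2L, replace = TRUE)
           else c(0L, 0L)
    alen <- a$end - a$start + 1L
    if (type == "INS") {
      pos <- max(1L, a$start + jit[1L])
      row <- data.frame(seqid = a$seqid, pos = pos, end = pos,
                        svtype = type, svlen = max(1L, alen + jit[2L]),
                        caller = "caller1",
                        id = sprintf("ev%03d", k), stringsAsFactors = FALSE)
    } else {
      s <- max(1L, a$start + jit[1L])
      e <- max(s, a$end + jit[2L])
      row <- data.frame(seqid = a$seqid, pos = s, end = e, svtype = type,
                        svlen = e - s + 1L, caller = "caller1",
                        id = sprintf("ev%03d", k), stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- row
    truth[[length(truth) + 1L]] <- data.frame(sv_id = row$id,
                                              ann_id = a$id,
                                              stringsAsFactors = FALSE)
    for (d in seq_len(duplicate_copies)) {
      dup <- row
      dup$caller <- "caller2"
      dup$id <- sprintf("%s_dup%d", row$id, d)
      if (type != "INS") {
        ## small shift that stays far above the reciprocal-overlap bound
        shift <- min(5L, max(0L, (dup$end - dup$pos) %/% 20L))
        dup$pos <- dup$pos + shift
        dup$end <- dup$end + shift
        dup$svlen <- dup$end - dup$pos + 1L
      } else {
        dup$pos <- dup$pos + sample(0:5, 1L)
        dup$end <- dup$pos
      }
      rows[[length(rows) + 1L]] <- dup
    }
  }
  for (d in seq_len(n_decoys)) {
    chr <- annotations$seqid[1L] %||% "chr1"
    pos <- sample.int(max(annotations$end %||% 1000L), 1L)
    len <- sample(10:49, 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = chr, pos = pos, end = pos + len - 1L,
      svtype = "DEL", svlen = len, caller = "caller1",
      id = sprintf("decoy%03d", d), stringsAsFactors = FALSE)
  }
  svs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seqid = character(0), pos = integer(0), end = integer(0),
               svtype = character(0), svlen = integer(0),
               caller = character(0), id = character(0))
  rownames(svs) <- NULL
  list(svs = svs, truth = do.call(rbind, truth))
}
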