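# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: plain string
# scanning, explicit set arithmetic and all-pairs loops.

# overlapping occurrences of `kmer` among the windows of `s`
oracle_count <- function(s, kmer) {
  k <- nchar(kmer)
  L <- nchar(s)
  if (L < k) return(0L)
  wins <- substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  sum(wins == kmer)
}

oracle_kmer_freq <- function(s, kmer) {
  s <- toupper(s)
  L <- nchar(s)
  k <- nchar(kmer)
  if (L < k) return(0)
  tile <- substr(strrep(kmer, ceiling(L / k)), 1L, L)
  den <- oracle_count(tile, kmer)
  if (den == 0L) return(0)
  oracle_count(s, kmer) / den
}

oracle_kmer_block <- function(s, ks = c(2L, 3L, 4L)) {
  unlist(lapply(ks, function(k) {
    kmers <- apply(do.call(expand.grid, rev(rep(list(c("A", "C", "G", "T")),
                                                k))), 1L,
                   function(r) paste(rev(r), collapse = ""))
    kmers <- sort(kmers)
    vapply(kmers, function(km) oracle_kmer_freq(s, km), numeric(1))
  }))
}

# same oracle, organised for speed over many sequences: numerators from a
# table of the sequence's windows, denominators from explicit tile strings
# (cached per kmer/length).  Still shares no code with the implementation.
oracle_denominator_cache <- new.env(parent = emptyenv())

oracle_denominator <- function(kmer, L) {
  key <- paste0(kmer, ":", L)
  hit <- oracle_denominator_cache[[key]]
  if (!is.null(hit)) return(hit)
  tile <- substr(strrep(kmer, ceiling(L / nchar(kmer))), 1L, L)
  val <- oracle_count(tile, kmer)
  oracle_denominator_cache[[key]] <- val
  val
}

oracle_kmer_block_fast <- function(s, ks = c(2L, 3L, 4L)) {
  s <- toupper(s)
  L <- nchar(s)
  unlist(lapply(ks, function(k) {
    kmers <- sort(apply(do.call(expand.grid,
                                rep(list(c("A", "C", "G", "T")), k)), 1L,
                        paste, collapse = ""))
    if (L < k) return(stats::setNames(rep(0, length(kmers)), kmers))
    wins <- substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    tab <- table(wins)
    num <- ifelse(kmers %in% names(tab), as.numeric(tab[kmers]), 0)
    den <- vapply(kmers, oracle_denominator, numeric(1), L = L)
    stats::setNames(ifelse(den > 0, num / den, 0), kmers)
  }))
}

# ancestor set by plain prefix decomposition (no taxonomy object involved)
oracle_aug <- function(code) {
  parts <- strsplit(code, "/", fixed = TRUE)[[1L]]
  vapply(seq_along(parts),
         function(i) paste(parts[seq_len(i)], collapse = "/"), character(1))
}

oracle_hier_prf <- function(truths, pred_codes) {
  P <- lapply(pred_codes, function(p) if (is.na(p)) character(0)
                                      else oracle_aug(p))
  T <- lapply(truths, oracle_aug)
  inter <- sum(mapply(function(p, t) length(intersect(p, t)), P, T))
  hp <- if (sum(lengths(P)) > 0) inter / sum(lengths(P)) else 0
  hr <- if (sum(lengths(T)) > 0) inter / sum(lengths(T)) else 0
  f1 <- if (hp + hr > 0) 2 * hp * hr / (hp + hr) else 0
  c(hP = hp, hR = hr, hF1 = f1)
}

# random prefix-closed taxonomy: each top-level class gets random subtrees
random_taxonomy <- function(max_depth = 3L, max_children = 3L) {
  codes <- character(0)
  grow <- function(prefix, depth) {
    n <- sample.int(max_children, 1L)
    for (i in seq_len(n)) {
      code <- if (nzchar(prefix)) paste0(prefix, "/", i) else as.character(i)
      codes <<- c(codes, code)
      if (depth < max_depth && stats::runif(1) < 0.6) grow(code, depth + 1L)
    }
  }
  grow("", 1L)
  parse_taxonomy(paste0(codes, "\tnode", seq_along(codes)))
}

# all-pairs brute-force application of the three detection rules
oracle_detect <- function(svs, ann, genome_len,
                          min_len = 50, max_frac = 0.01,
                          min_int = 0.10, len_sim = 0.50,
                          dup_frac = 0.8, ins_win = 100) {
  keep <- svs$svlen >= min_len & svs$svlen <= max_frac * genome_len
  svs <- svs[keep, , drop = FALSE]
  n <- nrow(svs)
  # duplicate closure via boolean reachability
  adj <- diag(n) == 1
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- svs[i, ]; b <- svs[j, ]
        if (a$seqid != b$seqid || a$svtype != b$svtype) next
        dup <- if (a$svtype == "INS") {
          abs(a$pos - b$pos) <= ins_win &&
            min(a$svlen, b$svlen) / max(a$svlen, b$svlen) >= 0.5
        } else {
          ov <- min(a$end, b$end) - max(a$pos, b$pos) + 1
          ov > 0 && ov / (a$end - a$pos + 1) >= dup_frac &&
            ov / (b$end - b$pos + 1) >= dup_frac
        }
        if (dup) adj[i, j] <- adj[j, i] <- TRUE
      }
    }
    repeat {
      nxt <- (adj %*% adj) > 0
      if (identical(nxt, adj)) break
      adj <- nxt
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[which(adj[i, ])] <- cid
    }
  }
  survivors <- vapply(split(seq_len(n), comp), function(idx) {
    best <- idx[svs$svlen[idx] == max(svs$svlen[idx])]
    best[which.min(svs$pos[best])]
  }, integer(1))
  svs <- svs[sort(survivors), , drop = FALSE]
  # all-pairs matching
  out <- list()
  for (i in seq_len(nrow(svs))) {
    for (j in seq_len(nrow(ann))) {
      a <- svs[i, ]; t <- ann[j, ]
      if (a$seqid != t$seqid) next
      alen <- t$end - t$start + 1
      ratio <- min(a$svlen, alen) / max(a$svlen, alen)
      ok <- if (a$svtype == "INS") {
        a$pos >= t$start - ins_win && a$pos <= t$end + ins_win &&
          ratio >= len_sim
      } else {
        ov <- min(a$end, t$end) - max(a$pos, t$start) + 1
        span <- a$end - a$pos + 1
        ov > 0 && ov >= min_int * min(span, alen) && ratio >= len_sim
      }
      if (ok) out[[length(out) + 1L]] <- data.frame(sv_id = a$id,
                                                    ann_id = t$id)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sv_id = character(0), ann_id = character(0)))
  }
  do.call(rbind, out)
}

# small 3-level taxonomy used across classifier tests
toy_taxonomy <- function() {
  parse_taxonomy(c("1\tR", "1/1\tR-a", "1/1/1\tR-a-1", "1/1/2\tR-a-2",
                   "1/2\tR-b", "2\tD", "2/1\tD-a", "2/1/1\tD-a-1",
                   "2/2\tD-b"))
}

# random SV / annotation fixture for the detection oracle comparison
random_sv_fixture <- function(genome_len = 100000L) {
  n_ann <- sample(5:15, 1L)
  astart <- sample.int(genome_len - 2000L, n_ann)
  alen <- sample(c(30:80, 100:1500), n_ann, replace = TRUE)
  ann <- data.frame(seqid = "chr1", start = astart,
                    end = pmin(astart + alen - 1L, genome_len),
                    class = sample(c("1/1/1", "2/1/1"), n_ann,
                                   replace = TRUE),
                    id = paste0("t", seq_len(n_ann)),
                    stringsAsFactors = FALSE)
  n_sv <- sample(10:30, 1L)
  near <- sample(c(TRUE, FALSE), n_sv, replace = TRUE, prob = c(0.6, 0.4))
  base <- ifelse(near, ann$start[sample.int(n_ann, n_sv, replace = TRUE)],
                 sample.int(genome_len - 2000L, n_sv, replace = TRUE))
  pos <- pmax(1L, as.integer(base + sample(-200:200, n_sv, replace = TRUE)))
  svlen <- sample(c(20:60, 100:1800, 5000), n_sv, replace = TRUE)
  svtype <- sample(c("DEL", "INS", "DUP", "INV"), n_sv, replace = TRUE)
  svs <- data.frame(seqid = "chr1", pos = pos,
                    end = ifelse(svtype == "INS", pos, pos + svlen - 1L),
                    svtype = svtype, svlen = svlen,
                    caller = "c1", id = paste0("s", seq_len(n_sv)),
                    stringsAsFactors = FALSE)
  list(svs = svs, ann = ann, genome_len = genome_len)
}
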