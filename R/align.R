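# Pairwise local-alignment substrate: Smith-Waterman with affine gaps,
# bit scores via Karlin-Altschul statistics, identity and coverage. This is
# the score scale every other module (search, clustering, neighborhood
# grouping, co-occurrence ratios) is expressed in.

#' Alignment scoring parameters
#'
#' Scoring defaults follow the de-facto protein-search standard the package's
#' identity and coverage thresholds are calibrated against: BLOSUM62 with gap
#' open 11 / gap extend 1, and the gapped Karlin-Altschul pair
#' (lambda = 0.267, K = 0.041) for the bit conversion. X residues score 0
#' against everything, so unknown residues neither reward nor penalize an
#' alignment.
#'
#' @param gap_open Gap opening penalty (non-negative integer).
#' @param gap_extend Gap extension penalty per residue (non-negative integer).
#' @param lambda,K Karlin-Altschul constants for the scoring system.
#' @param db_len Effective database length in residues, used by [evalue()].
#' @return An object of class `align_params`.
#' @export
align_params <- function(gap_open = 11L, gap_extend = 1L,
                         lambda = 0.267, K = 0.041, db_len = 1e6) {
  stopifnot(gap_open >= 0, gap_extend >= 0, lambda > 0, K > 0, db_len > 0)
  structure(list(matrix = "BLOSUM62", gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), lambda = lambda, K = K,
                 db_len = db_len),
            class = "align_params")
}

# BLOSUM62 restricted to the package alphabet, with the X row/column zeroed.
substitution_matrix <- function() {
  if (!is.null(.pkg_env$submat)) return(.pkg_env$submat)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  ab <- aa_alphabet()
  m <- e$BLOSUM62[ab, ab]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  .pkg_env$submat <- m
  m
}

bit_score <- function(raw, params) {
  (params$lambda * raw - log(params$K)) / log(2)
}

#' Expectation value from a bit score
#'
#' `E = m * n * 2^(-bit_score)` with `m` the query length and `n` the
#' effective database residue count; the bit-score closed form is equivalent
#' by definition of bits to `K * m * n * exp(-lambda * S)`.
#'
#' @param bit_score Alignment bit score(s).
#' @param query_len Query length in residues.
#' @param db_len Effective database length in residues.
#' @return Numeric E-value(s), monotone decreasing in the bit score.
#' @export
evalue <- function(bit_score, query_len, db_len) {
  stopifnot(query_len > 0, db_len > 0)
  query_len * db_len * 2^(-bit_score)
}

#' Self-alignment score of a protein, in bits
#'
#' For identical sequences under a BLOSUM-type matrix the optimal local
#' alignment is the full diagonal, so the raw self score is the sum of the
#' matrix diagonal over the sequence.
#'
#' @param seq Amino-acid sequence (string over the 20 residues plus X).
#' @param params [align_params()] object.
#' @return Self score in bits.
#' @export
self_score <- function(seq, params = align_params()) {
  res <- strsplit(toupper(seq), "")[[1]]
  m <- substitution_matrix()
  bad <- setdiff(res, rownames(m))
  if (length(bad))
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  raw <- sum(m[cbind(res, res)])
  if (raw <= 0) stop("zero self score for sequence")
  bit_score(raw, params)
}

#' Bit-score ratio of a hit relative to the query's self score
#'
#' The alignment score of a homolog divided by the alignment score of the
#' query against itself; the quantity the presence/absence plots and the
#' "good homolog" filter consume.
#'
#' @param hit_bits Bit score(s) of hits.
#' @param query_self_bits Query self score in bits (from [self_score()]).
#' @return Ratio in (0, 1] for hits under the same scoring.
#' @export
score_ratio <- function(hit_bits, query_self_bits) {
  if (any(query_self_bits <= 0)) stop("self score must be positive")
  hit_bits / query_self_bits
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman with affine gaps under the package scoring scheme.
#' Identity is computed over alignment columns including gap columns (the
#' protein-BLAST convention, which the 30%/50%/70% thresholds elsewhere in
#' the package assume); coverages are aligned span over sequence length.
#'
#' @param a,b Amino-acid sequences (query and subject).
#' @param params [align_params()] object.
#' @param query_id,subject_id Optional identifiers carried into the result.
#' @return One-row `data.table` with raw/bit score, E-value, identity,
#'   coverages and 1-based endpoints, or `NULL` when no positive-scoring
#'   local alignment exists.
#' @export
local_align <- function(a, b, params = align_params(),
                        query_id = "query", subject_id = "subject") {
  a <- toupper(a); b <- toupper(b)
  res <- .sw_batch(a, b, substitution_matrix(), params$gap_open,
                   params$gap_extend)
  if (res$raw_score[1] <= 0) return(NULL)
  hit_table(query_id, subject_id, res, nchar(a), nchar(b), params)[]
}

# Assemble the standard hit table from kernel output.
hit_table <- function(query_id, subject_ids, res, qlen, slens, params) {
  dt <- as.data.table(res)
  dt[, `:=`(
    query_id = query_id,
    subject_id = subject_ids,
    bit_score = bit_score(raw_score, params),
    pct_identity = 100 * matches / align_cols,
    query_cov = 100 * (qend - qstart + 1) / qlen,
    subject_cov = 100 * (send - sstart + 1) / slens
  )]
  dt[, e_value := evalue(bit_score, qlen, params$db_len)]
  dt[, c("query_id", "subject_id", "raw_score", "bit_score", "e_value",
         "pct_identity", "query_cov", "subject_cov",
         "qstart", "qend", "sstart", "send", "matches", "align_cols"),
     with = FALSE]
}

# ---- k-mer prefilter -------------------------------------------------------

#' Build a k-mer prefilter index over a protein set
#'
#' Inverted index from k-mer code to protein row, used to shortlist
#' candidate subjects before full alignment. A candidate must share at least
#' `min_words` words with the query (default one shared word, favouring
#' recall over speed at desk scale).
#'
#' @param sequences Character vector of protein sequences.
#' @param k Word size (default 4).
#' @return A keyed `data.table` index with attributes `k` and `n_seqs`.
#' @export
kmer_index <- function(sequences, k = 4L) {
  codes <- .kmer_codes(as.character(sequences), as.integer(k))
  idx <- data.table(
    kmer = unlist(codes, use.names = FALSE),
    pidx = rep.int(seq_along(codes), lengths(codes))
  )
  setkey(idx, kmer)
  setattr(idx, "k", as.integer(k))
  setattr(idx, "n_seqs", length(codes))
  idx
}

# Candidate subject rows sharing >= min_words k-mers with the query sequence.
prefilter_candidates <- function(query_seq, index, min_words = 1L) {
  k <- attr(index, "k")
  if (nchar(query_seq) < k) return(seq_len(attr(index, "n_seqs")))
  qcodes <- .kmer_codes(query_seq, k)[[1]]
  m <- index[.(qcodes), nomatch = NULL]
  if (nrow(m) == 0L) return(integer())
  counts <- m[, .N, by = pidx]
  sort(counts[N >= min_words, pidx])
}

#' Search a protein set for local-alignment hits of one query
#'
#' k-mer prefilter followed by full Smith-Waterman of the query against every
#' candidate; hits sorted by bit score (desc), then E-value (asc), then
#' subject id (lexicographic), with ranks 1..N assigned after sorting.
#' Queries shorter than the prefilter word size fall back to exhaustive
#' alignment against all subjects.
#'
#' @param query_seq Query sequence.
#' @param subject_ids,subject_seqs Parallel vectors defining the target set.
#' @param params [align_params()] (its `db_len` should reflect the target set).
#' @param index Optional prebuilt [kmer_index()] over `subject_seqs`.
#' @param min_words Minimum shared words for the prefilter.
#' @param query_id Identifier carried into the hit table.
#' @return Hit `data.table` (possibly empty) with a `rank` column.
#' @export
batch_search <- function(query_seq, subject_ids, subject_seqs,
                         params = align_params(), index = NULL,
                         min_words = 1L, query_id = "query") {
  if (is.null(index)) index <- kmer_index(subject_seqs)
  cand <- prefilter_candidates(query_seq, index, min_words)
  if (length(cand) == 0L) return(empty_hits())
  res <- .sw_batch(toupper(query_seq), toupper(subject_seqs[cand]),
                   substitution_matrix(), params$gap_open, params$gap_extend)
  keep <- res$raw_score > 0
  if (!any(keep)) return(empty_hits())
  hits <- hit_table(query_id, subject_ids[cand][keep],
                    lapply(res, `[`, keep), nchar(query_seq),
                    nchar(subject_seqs[cand])[keep], params)
  sort_and_rank_hits(hits)
}

sort_and_rank_hits <- function(hits) {
  setorder(hits, -bit_score, e_value, subject_id)
  hits[, rank := seq_len(.N)]
  hits[]
}

empty_hits <- function() {
  data.table(query_id = character(), subject_id = character(),
             raw_score = integer(), bit_score = numeric(),
             e_value = numeric(), pct_identity = numeric(),
             query_cov = numeric(), subject_cov = numeric(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), matches = integer(), align_cols = integer(),
             rank = integer())
}

#' @importFrom data.table setattr
NULL
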