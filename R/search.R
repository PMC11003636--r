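# Homolog search against a database: direct search, the two-stage clustered
# search for redundant order-level databases, hit classification, the
# length -> engine-sensitivity schedule and the split-align-merge workflow
# contract for an optional external engine.

#' Search configuration
#'
#' Thresholds used throughout the search and analysis modules: homologs are
#' hits with E <= 1e-3; evaluation uses the stricter E <= 1e-5; at most one
#' hit per genome is kept (`max_hits = n_genomes`); the clustered-search
#' candidate list is capped at `max(n_genomes, 200)`; potential orthologs
#' require >= 30% identity and >= 50% query coverage; "good" homologs a bit
#' score ratio >= 0.3; high-coverage orthologs additionally >= 90% coverage
#' of both sequences.
#'
#' @param db A `gxdb` database (supplies `n_genomes` and the effective
#'   database length), or `NULL` if both are given explicitly.
#' @param n_genomes,db_len Explicit overrides.
#' @return A `search_config` list.
#' @export
search_config <- function(db = NULL, n_genomes = NULL, db_len = NULL) {
  if (!is.null(db)) {
    n_genomes <- n_genomes %||% nrow(db$genomes)
    db_len <- db_len %||% db_residues(db)
  }
  stopifnot(n_genomes >= 1, db_len > 0)
  structure(list(
    e_max = 1e-3, e_strict = 1e-5,
    max_hits = as.integer(n_genomes),
    candidate_cap = max(as.integer(n_genomes), 200L),
    ortho_min_identity = 30, ortho_min_query_cov = 50,
    good_ratio_min = 0.30, high_cov_both = 90,
    n_genomes = as.integer(n_genomes), db_len = db_len),
    class = "search_config")
}

resolve_query <- function(query, db) {
  if (query %in% db$proteins$protein_id)
    list(id = query, seq = db$proteins[protein_id == query, sequence])
  else list(id = "query", seq = toupper(query))
}

db_search_index <- function(db) {
  if (is.null(db$cache$index)) db$cache$index <- kmer_index(db$proteins$sequence)
  db$cache$index
}

attach_genome <- function(hits, db) {
  pg <- db$genes[is_protein_coding == TRUE,
                 .(subject_genome_id = min(genome_id)), by = protein_id]
  hits[, subject_genome_id :=
         pg[match(hits$subject_id, protein_id), subject_genome_id]]
  hits[]
}

#' Classify hits as homolog / potential ortholog / good homolog
#'
#' Adds the bit-score ratio and label columns to a hit table. Every hit that
#' passed the E-value gate is a homolog; a potential (functional) ortholog
#' additionally has >= 30% identity and covers >= 50% of the query
#' (boundaries inclusive); a good homolog has a score ratio >= 0.3; a
#' high-coverage ortholog is a potential ortholog whose alignment also
#' covers >= 90% of both sequences.
#'
#' @param hits Hit table.
#' @param query_self_bits Query self score in bits.
#' @param cfg [search_config()] object.
#' @return The hit table with `score_ratio` and label columns added.
#' @export
classify_hits <- function(hits, query_self_bits, cfg) {
  hits <- as.data.table(hits)
  hits[, score_ratio := score_ratio(bit_score, query_self_bits)]
  hits[, is_homolog := TRUE]
  hits[, is_potential_ortholog :=
         pct_identity >= cfg$ortho_min_identity &
         query_cov >= cfg$ortho_min_query_cov]
  hits[, is_good_homolog := score_ratio >= cfg$good_ratio_min]
  hits[, is_high_coverage_ortholog :=
         is_potential_ortholog & query_cov >= cfg$high_cov_both &
         subject_cov >= cfg$high_cov_both]
  hits[]
}

#' Direct homolog search of a database
#'
#' k-mer-prefiltered Smith-Waterman of the query against every distinct
#' protein, filtered to E <= `cfg$e_max`, truncated to the top
#' `cfg$max_hits` hits, with ranks reassigned 1..N. Queries shorter than
#' the prefilter word size are aligned exhaustively.
#'
#' @param query A protein id present in `db` or a raw amino-acid sequence.
#' @param db A `gxdb` object.
#' @param cfg [search_config()]; defaults to `search_config(db)`.
#' @param params [align_params()]; its `db_len` is set from `cfg`.
#' @return Classified hit `data.table` (includes `score_ratio` and labels).
#' @export
search_direct <- function(query, db, cfg = search_config(db),
                          params = align_params(db_len = cfg$db_len)) {
  q <- resolve_query(query, db)
  hits <- batch_search(q$seq, db$proteins$protein_id, db$proteins$sequence,
                       params = params, index = db_search_index(db),
                       query_id = q$id)
  finish_hits(hits, q, db, cfg, params)
}

finish_hits <- function(hits, q, db, cfg, params) {
  hits <- hits[e_value <= cfg$e_max]
  hits <- head(hits, cfg$max_hits)
  if (nrow(hits)) hits[, rank := seq_len(.N)]
  hits <- attach_genome(hits, db)
  classify_hits(hits, self_score(q$seq, params), cfg)
}

#' Two-stage clustered homolog search
#'
#' Stage 1 searches the cluster representatives only; stage 2 expands each
#' representative hit to its full cluster membership, ordered by stage-1
#' representative score (descending) with members in cluster order, and
#' truncates the candidate list to `cfg$candidate_cap`; stage 3 re-aligns
#' the query to every candidate with the same kernel and score scale as the
#' direct search, then filters, sorts and ranks exactly as
#' [search_direct()] does.
#'
#' @inheritParams search_direct
#' @return Classified hit `data.table`.
#' @export
search_clustered <- function(query, db, cfg = search_config(db),
                             params = align_params(db_len = cfg$db_len)) {
  if (is.null(db$clusters))
    stop("database has no cluster table; run cluster_database() ",
         "(CLI: `cluster`) first")
  q <- resolve_query(query, db)
  reps <- unique(db$clusters$rep_id)
  repdt <- db$proteins[protein_id %in% reps]
  if (is.null(db$cache$rep_index))
    db$cache$rep_index <- kmer_index(repdt$sequence)
  rep_params <- align_params(gap_open = params$gap_open,
                             gap_extend = params$gap_extend,
                             lambda = params$lambda, K = params$K,
                             db_len = sum(repdt$length))
  stage1 <- batch_search(q$seq, repdt$protein_id, repdt$sequence,
                         params = rep_params, index = db$cache$rep_index,
                         query_id = q$id)
  stage1 <- stage1[e_value <= cfg$e_max]
  if (nrow(stage1) == 0L)
    return(classify_hits(attach_genome(empty_hits(), db),
                         self_score(q$seq, params), cfg))
  # stage 2: expand representatives to members, cap the candidate list
  members <- db$clusters[, .(rep_id, member_id,
                             member_ord = seq_len(.N)), by = cluster_id]
  expanded <- merge(stage1[, .(subject_id, s1_rank = rank)],
                    members, by.x = "subject_id", by.y = "rep_id",
                    sort = FALSE, allow.cartesian = TRUE)
  setorder(expanded, s1_rank, member_ord)
  cand_ids <- unique(expanded$member_id)
  cand_ids <- head(cand_ids, cfg$candidate_cap)
  cand <- db$proteins[match(cand_ids, protein_id)]
  # stage 3: re-align against every candidate on the full-database scale
  res <- .sw_batch(q$seq, cand$sequence, substitution_matrix(),
                   params$gap_open, params$gap_extend)
  keep <- res$raw_score > 0
  hits <- if (!any(keep)) empty_hits()
  else sort_and_rank_hits(hit_table(q$id, cand$protein_id[keep],
                                    lapply(res, `[`, keep), nchar(q$seq),
                                    cand$length[keep], params))
  finish_hits(hits, q, db, cfg, params)
}

#' Engine sensitivity as a function of query length
#'
#' The piecewise schedule used for external-engine searches: maximum
#' sensitivity 7.5 for queries up to 150 residues, then 7.0 (<= 250), 6.25
#' (<= 350), 6.0 (<= 650), and the engine default 5.7 beyond that; short
#' queries need higher sensitivity because their miss rate is otherwise
#' much higher.
#'
#' @param query_len Query length(s) in residues (>= 1).
#' @return Numeric sensitivity value(s).
#' @export
sensitivity_for_length <- function(query_len) {
  stopifnot(all(query_len >= 1))
  ifelse(query_len <= 150, 7.5,
         ifelse(query_len <= 250, 7.0,
                ifelse(query_len <= 350, 6.25,
                       ifelse(query_len <= 650, 6.0, 5.7))))
}

#' Split a prefilter candidate table into contiguous parts
#'
#' The split-align-merge workflow contract: the candidate list is cut into
#' `n_parts` contiguous, near-equal slices whose concatenation preserves
#' the original row multiset and order.
#'
#' @param candidates `data.frame` (or vector) of prefilter candidates.
#' @param n_parts Number of parts.
#' @return List of `n_parts` slices (some possibly empty).
#' @export
split_candidates <- function(candidates, n_parts = 10L) {
  stopifnot(n_parts >= 1)
  n <- if (is.data.frame(candidates)) nrow(candidates) else length(candidates)
  sizes <- diff(floor(seq(0, n, length.out = n_parts + 1)))
  grp <- rep(seq_len(n_parts), times = sizes)
  if (is.data.frame(candidates))
    lapply(split(seq_len(n), grp), function(ix) candidates[ix, , drop = FALSE])
  else split(candidates, grp)
}

#' Merge per-part hit tables into one globally ordered result
#'
#' @param parts List of hit tables, each internally sorted or not.
#' @param n_keep Truncate the merged table to the top `n_keep` rows
#'   (typically the number of genomes in the target database).
#' @return Merged, globally sorted and re-ranked hit table.
#' @export
merge_hit_parts <- function(parts, n_keep = NULL) {
  merged <- rbindlist(parts, use.names = TRUE, fill = TRUE)
  if (nrow(merged) == 0L) return(merged)
  merged <- sort_and_rank_hits(merged)
  if (!is.null(n_keep)) merged <- head(merged, n_keep)
  merged[, rank := seq_len(.N)]
  merged[]
}

#' Search through an optional external prefilter+align engine
#'
#' Adapter for an mmseqs-style external engine following the
#' split-align-merge workflow: prefilter, split the candidates into
#' `n_parts` contiguous parts, align the parts concurrently, merge, and
#' keep the top `n_genomes` entries, invoking the engine with
#' `max_candidates = 8 * n_genomes` and the sensitivity from
#' [sensitivity_for_length()]. No engine is bundled: when the configured
#' executable is absent this errors rather than silently falling back.
#'
#' @param query Query sequence.
#' @param db A `gxdb` object.
#' @param engine Path to the engine executable (`NULL` = unconfigured).
#' @param n_parts Number of alignment parts.
#' @param cfg [search_config()].
#' @return Hit table (when an engine is available).
#' @export
parallel_engine_search <- function(query, db, engine = NULL, n_parts = 10L,
                                   cfg = search_config(db)) {
  if (is.null(engine) || !nzchar(engine) ||
      (!file.exists(engine) && !nzchar(Sys.which(engine))))
    stop("no external search engine is configured/installed; ",
         "parallel_engine_search requires one (capability error)")
  stop("external engine adapters are not implemented for engine: ", engine)
}
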