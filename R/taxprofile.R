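# Taxonomic prevalence of a protein's homologs at a chosen rank, with
# per-taxon genome counts and the maximum bit-score ratio.

# per-genome expansion of a (classified) hit table: one row per genome
# carrying a hit protein, keeping the best (lowest-rank) hit per genome
hits_per_genome <- function(hits, db) {
  hits <- as.data.table(hits)
  if (nrow(hits) == 0L)
    return(data.table(genome_id = character(), protein_id = character(),
                      rank = integer(), bit_score = numeric(),
                      score_ratio = numeric()))
  pg <- db$genes[is_protein_coding == TRUE & protein_id %in% hits$subject_id,
                 .(genome_id = unique(genome_id)), by = protein_id]
  x <- merge(pg, hits, by.x = "protein_id", by.y = "subject_id",
             allow.cartesian = TRUE)
  setorder(x, genome_id, rank, protein_id)
  best <- x[, .SD[1], by = genome_id]
  cols <- intersect(c("genome_id", "protein_id", "rank", "bit_score",
                      "e_value", "score_ratio", "pct_identity", "query_cov",
                      "subject_cov", "is_potential_ortholog",
                      "is_good_homolog"), names(best))
  best[, cols, with = FALSE]
}

filter_hits_by_label <- function(hits, filter) {
  switch(filter,
         all = hits,
         potential_ortholog = hits[hits$is_potential_ortholog == TRUE, ],
         good_homolog = hits[hits$is_good_homolog == TRUE, ],
         stop("unknown filter: ", filter))
}

#' Taxonomic prevalence profile of a hit list
#'
#' Aggregates homologs at a chosen taxonomic level: for each taxon with at
#' least one genome in the database, the number of genomes, the number with
#' a hit (a genome counts once regardless of hit multiplicity), the
#' fraction, and the maximum bit-score ratio among the taxon's hits. Taxa
#' without hits are included with zero counts by default, since prevalence
#' includes absence.
#'
#' @param hits Classified hit table (from [search_direct()] /
#'   [search_clustered()]).
#' @param db A `gxdb` object.
#' @param level One of domain, phylum, class, order, family, genus, species.
#' @param filter `"all"`, `"potential_ortholog"` or `"good_homolog"`.
#' @param include_empty Keep taxa with zero hit genomes.
#' @return `data.table` with `level`, `taxon`, `n_genomes_in_db`,
#'   `n_genomes_with_hit`, `fraction`, `max_ratio` (NA when no hits),
#'   sorted by hit count (descending) then taxon label.
#' @export
tax_profile <- function(hits, db, level = "phylum",
                    filter = c("all", "potential_ortholog", "good_homolog"),
                    include_empty = TRUE) {
  filter <- match.arg(filter)
  if (!level %in% TAX_LEVELS) stop("unknown taxonomic level: ", level)
  hits <- filter_hits_by_label(as.data.table(hits), filter)
  per_g <- hits_per_genome(hits, db)
  tax <- db$genomes[, .(genome_id = assembly_id, taxon = get(level))]
  per_g <- merge(per_g, tax, by = "genome_id")
  out <- tax[, .(n_genomes_in_db = .N), by = taxon]
  withhit <- if (nrow(per_g))
    per_g[, .(n_genomes_with_hit = .N, max_ratio = max(score_ratio)),
          by = taxon]
  else data.table(taxon = character(), n_genomes_with_hit = integer(),
                  max_ratio = numeric())
  out <- merge(out, withhit, by = "taxon", all.x = TRUE)
  out[is.na(n_genomes_with_hit), n_genomes_with_hit := 0L]
  out[, fraction := n_genomes_with_hit / n_genomes_in_db]
  if (!include_empty) out <- out[n_genomes_with_hit > 0L]
  out[, level := level]
  setorder(out, -n_genomes_with_hit, taxon)
  out[, .(level, taxon, n_genomes_in_db, n_genomes_with_hit, fraction,
          max_ratio)]
}

#' Export the full homolog table with lineages
#'
#' One row per hit, in hit-rank order, with the subject genome's full
#' 7-rank lineage, bit score, E-value, identity, coverages and score ratio.
#'
#' @param hits Classified hit table.
#' @param db A `gxdb` object.
#' @return `data.table` ready to write as TSV.
#' @export
export_homolog_table <- function(hits, db) {
  hits <- as.data.table(hits)
  lin <- db$genomes[, c("assembly_id", TAX_LEVELS), with = FALSE]
  out <- merge(hits, lin, by.x = "subject_genome_id", by.y = "assembly_id",
               all.x = TRUE, sort = FALSE)
  setorder(out, rank)
  cols <- c("rank", "query_id", "subject_id", "subject_genome_id",
            TAX_LEVELS, "bit_score", "e_value", "pct_identity", "query_cov",
            "subject_cov", "score_ratio")
  out[, intersect(cols, names(out)), with = FALSE]
}
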