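# Genome quality gate and representative selection: one genome per genus for
# a main database, up to 10 per species for order-level databases.

#' Genome quality gate
#'
#' A genome passes iff completeness >= 90, contamination <= 5, it is not
#' chimeric, it is an isolate or meets the MIMAG high-quality-draft
#' criteria, it has at least one gene, and at least half of its genes are
#' protein coding. The first failing rule (in that order) is reported as
#' the reason.
#'
#' @param genomes Genome metadata `data.frame` (one row per assembly, with
#'   the documented metadata columns plus `n_genes`/`n_protein_coding`).
#' @return `data.table` with `assembly_id`, `pass`, `reason` (`NA` on pass).
#' @export
passes_quality <- function(genomes) {
  g <- as.data.table(genomes)
  need <- c("assembly_id", "completeness", "contamination", "is_chimeric",
            "is_isolate", "mimag_high_quality", "n_genes",
            "n_protein_coding")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop("missing metadata field(s): ", paste(miss, collapse = ", "))
  for (cc in need)
    if (any(is.na(g[[cc]])))
      stop("missing value in metadata field '", cc, "'")
  reason <- rep(NA_character_, nrow(g))
  rule <- function(cond, label) ifelse(is.na(reason) & cond, label, reason)
  reason <- rule(g$completeness < 90, "completeness")
  reason <- rule(g$contamination > 5, "contamination")
  reason <- rule(g$is_chimeric, "chimeric")
  reason <- rule(!g$is_isolate & !g$mimag_high_quality, "mimag")
  reason <- rule(g$n_genes <= 0, "no_genes")
  reason <- rule(g$n_genes > 0 & g$n_protein_coding / pmax(g$n_genes, 1) <
                   0.5, "coding_fraction")
  data.table(assembly_id = g$assembly_id, pass = is.na(reason),
             reason = reason)
}

#' Selection key for representative-genome preference
#'
#' Ordered criteria, most important first: presence in RefSeq; type species
#' of the genus; species representative; lower quality score
#' `2 * contamination - completeness`; presence in the important-strains
#' list; longer largest scaffold; and finally the assembly id
#' (lexicographic) to make the order total and deterministic.
#'
#' @param genomes Genome metadata `data.frame`.
#' @return `data.table` of key columns, oriented so that ascending
#'   lexicographic order on all columns is preference order.
#' @export
selection_key <- function(genomes) {
  g <- as.data.table(genomes)
  data.table(assembly_id = g$assembly_id,
             k_refseq = -as.integer(g$in_refseq),
             k_type_species = -as.integer(g$is_type_species),
             k_species_rep = -as.integer(g$is_species_representative),
             k_quality = 2 * g$contamination - g$completeness,
             k_important = -as.integer(g$in_important_strains),
             k_scaffold = -as.numeric(g$largest_scaffold_bp))
}

#' Pick representative genomes per taxonomic group
#'
#' Within each group (genus or species), genomes are ordered by
#' [selection_key()] and the top `min(max_per_group, group size)` are
#' returned in preference order. Selection is a pure function of the
#' metadata: permuting the input rows never changes the outcome.
#'
#' @param genomes Genome metadata; all rows are assumed to have passed the
#'   quality gate.
#' @param group_rank `"genus"` or `"species"`.
#' @param max_per_group Maximum representatives per group (>= 1).
#' @return Named list mapping group label to an ordered character vector of
#'   chosen assembly ids.
#' @export
pick_representatives <- function(genomes, group_rank = c("genus", "species"),
                                 max_per_group = 1L) {
  group_rank <- match.arg(group_rank)
  if (max_per_group < 1L) stop("max_per_group must be >= 1")
  g <- as.data.table(genomes)
  if (nrow(g) == 0L) return(setNames(list(), character()))
  key <- selection_key(g)
  g <- cbind(g[, .(grp = get(group_rank))], key)
  setorder(g, grp, k_refseq, k_type_species, k_species_rep, k_quality,
           k_important, k_scaffold, assembly_id)
  picked <- g[, .(assembly_id = head(assembly_id, max_per_group)), by = grp]
  split(picked$assembly_id, picked$grp)[unique(g$grp)]
}
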