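# Seeded generator of synthetic taxonomies, protein families, genomes and
# metadata with known ground truth. Emulates the shape of a representative-
# genome collection: a small GTDB-style 7-rank taxonomy, protein families
# evolved by substitution down the taxonomy, operons, an implanted
# co-occurring gene pair, and assembly metadata with controllable quality
# failures. Substitution-only evolution keeps identity/coverage ground truth
# exact.

#' Configuration for the synthetic-genome generator
#'
#' The defaults describe a small but realistic study condition: two phyla,
#' a handful of genera with a few species each, per-rank divergence rising
#' from 2% between genomes of a species to 35% between phyla (so
#' within-species copies sit far inside the 70%-identity cluster contract
#' while cross-phylum homologs stay detectable), lognormal protein lengths
#' around 180 residues, operons with sub-kilobase spacings, and one implanted
#' co-occurring family pair that is jointly present in half the genomes and
#' jointly absent in the other half.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_phyla,genera_per_phylum,species_per_genus,genomes_per_species
#'   Taxonomy shape (one class/order/family per phylum lineage).
#' @param n_families Number of ordinary protein families.
#' @param presence_prob Probability a family is present in a genus.
#' @param retention_prob Probability a genus-present family is retained in
#'   each genome of that genus.
#' @param divergence Named fractions of substituted residues introduced on
#'   the branch to each taxonomic level (`phylum`, `genus`, `species`,
#'   `genome`); must increase with taxonomic distance.
#' @param length_meanlog,length_sdlog,min_len,max_len Protein length model.
#' @param n_contigs Contigs per genome (genes are split evenly).
#' @param intergenic_gap Range (bp) of gaps between adjacent genes.
#' @param n_operons,operon_size,operon_gap Operon spec: the first
#'   `n_operons * operon_size` families form same-strand adjacent blocks
#'   with gaps drawn from `operon_gap` (all well under 5 kb).
#' @param n_trna Non-coding (tRNA) genes per genome.
#' @param implant Implanted co-occurring pair spec: `both_frac` of genomes
#'   carry both families, the complement neither (plus optional
#'   `only_a_frac`/`only_b_frac`); `nearby_frac` of joint-presence genomes
#'   encode the pair within 5 kb on the same strand.
#' @param fail_fracs Fraction of genomes made to fail each metadata quality
#'   rule (`completeness`, `contamination`, `chimeric`, `mimag`, `coding`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_phyla = 2L, genera_per_phylum = 2L,
                       species_per_genus = 2L, genomes_per_species = 2L,
                       n_families = 30L,
                       presence_prob = 0.85, retention_prob = 0.95,
                       divergence = c(phylum = 0.35, genus = 0.16,
                                      species = 0.05, genome = 0.02),
                       length_meanlog = log(180), length_sdlog = 0.30,
                       min_len = 60L, max_len = 600L,
                       n_contigs = 2L, intergenic_gap = c(40L, 400L),
                       n_operons = 3L, operon_size = 3L,
                       operon_gap = c(10L, 150L),
                       n_trna = 2L,
                       implant = list(enabled = TRUE, both_frac = 0.5,
                                      only_a_frac = 0, only_b_frac = 0,
                                      nearby_frac = 0.8),
                       fail_fracs = c(completeness = 0, contamination = 0,
                                      chimeric = 0, mimag = 0, coding = 0)) {
  stopifnot(n_phyla >= 1, genera_per_phylum >= 1, species_per_genus >= 1,
            genomes_per_species >= 1, n_families >= 1,
            presence_prob >= 0, presence_prob <= 1,
            all(divergence >= 0), all(divergence < 1),
            all(c("phylum", "genus", "species", "genome") %in%
                  names(divergence)))
  if (is.unsorted(rev(divergence[c("phylum", "genus", "species", "genome")])))
    stop("divergence must increase with taxonomic distance")
  structure(as.list(environment()), class = "sim_config")
}

#' Evolve copies of a protein family root by exact-fraction substitution
#'
#' Each copy substitutes a seeded random subset of positions (of size
#' `round(divergence * length)`) with a uniformly drawn *different* residue,
#' so the realized identity to the root is exactly `1 - divergence`.
#'
#' @param root_sequence Root amino-acid sequence.
#' @param n_copies Number of copies.
#' @param divergence_fractions Divergence per copy, recycled to `n_copies`;
#'   each in `[0, 1)`.
#' @param seed Optional seed; if `NULL`, uses the current RNG stream.
#' @return Character vector of `n_copies` sequences.
#' @export
evolve_family <- function(root_sequence, n_copies, divergence_fractions,
                          seed = NULL) {
  if (any(divergence_fractions >= 1) || any(divergence_fractions < 0))
    stop("divergence must be in [0, 1)")
  run <- function() {
    aa <- aa_alphabet()[1:20]
    root <- strsplit(root_sequence, "")[[1]]
    L <- length(root)
    divs <- rep_len(divergence_fractions, n_copies)
    vapply(seq_len(n_copies), function(i) {
      nsub <- round(divs[i] * L)
      s <- root
      if (nsub > 0) {
        pos <- sample.int(L, nsub)
        for (p in pos) s[p] <- sample(setdiff(aa, s[p]), 1L)
      }
      paste(s, collapse = "")
    }, character(1))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

random_protein <- function(len) {
  paste(sample(aa_alphabet()[1:20], len, replace = TRUE), collapse = "")
}

# GTDB-style 7-rank labels for the synthetic taxonomy.
synth_taxonomy <- function(cfg) {
  rows <- list()
  g_id <- 0L
  for (p in seq_len(cfg$n_phyla)) {
    for (ge in seq_len(cfg$genera_per_phylum)) {
      g_id <- g_id + 1L
      for (sp in seq_len(cfg$species_per_genus)) {
        for (gn in seq_len(cfg$genomes_per_species)) {
          rows[[length(rows) + 1L]] <- data.table(
            assembly_id = "", phylum_i = p, genus_i = g_id, species_i = sp,
            domain = "d__Bacteria",
            phylum = sprintf("p__Phylum%02d", p),
            class = sprintf("c__Class%02d", p),
            order = sprintf("o__Order%02d", p),
            family = sprintf("f__Family%03d", g_id),
            genus = sprintf("g__Genus%03d", g_id),
            species = sprintf("s__Genus%03d sp%03d", g_id, sp))
        }
      }
    }
  }
  tax <- rbindlist(rows)
  tax[, assembly_id := sprintf("GCSYN%04d", .I)]
  tax
}

#' Simulate an annotated genome collection with ground truth
#'
#' Generates protein FASTA, GFF3 coordinates, an assembly metadata table and
#' a ground-truth object for a taxonomy of the shape given in `cfg`.
#' Families evolve root -> phylum -> genus -> species -> genome with the
#' per-rank divergences; operon families are placed adjacently on the same
#' strand; the implanted co-occurring pair follows its joint-presence
#' fractions and is placed within 5 kb (same strand) in `nearby_frac` of the
#' joint-presence genomes and made non-nearby (different contig or > 5 kb)
#' otherwise. Output files are byte-identical across runs with the same
#' config.
#'
#' @param cfg A [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the ground-truth list (also written as
#'   `ground_truth.json`): per-genome family presence, gene-to-family map,
#'   within-species cluster truth, implanted-pair locations and quality-rule
#'   failures.
#' @export
simulate_genomes <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(cfg$seed, .simulate_impl(cfg, out_dir))
}

.simulate_impl <- function(cfg, out_dir) {
  tax <- synth_taxonomy(cfg)
  n_genomes <- nrow(tax)
  fam_ids <- sprintf("FAM%04d", seq_len(cfg$n_families))
  implant_on <- isTRUE(cfg$implant$enabled)
  implant_ids <- if (implant_on) c("PAIRA", "PAIRB") else character()
  all_fams <- c(fam_ids, implant_ids)

  # family roots and lengths
  fam_len <- pmin(pmax(round(stats::rlnorm(length(all_fams),
                                           cfg$length_meanlog,
                                           cfg$length_sdlog)),
                       cfg$min_len), cfg$max_len)
  names(fam_len) <- all_fams
  roots <- setNames(vapply(fam_len, random_protein, character(1)), all_fams)

  # presence: per-genus Bernoulli, then per-genome retention
  genus_keys <- unique(tax$genus)
  presence <- matrix(FALSE, n_genomes, length(all_fams),
                     dimnames = list(tax$assembly_id, all_fams))
  for (f in fam_ids) {
    gen_present <- setNames(runif(length(genus_keys)) < cfg$presence_prob,
                            genus_keys)
    keep <- gen_present[tax$genus] & (runif(n_genomes) < cfg$retention_prob)
    presence[, f] <- keep
  }

  # implanted pair: joint presence by configured fractions
  implant_truth <- NULL
  if (implant_on) {
    ord <- sample.int(n_genomes)
    nb <- round(cfg$implant$both_frac * n_genomes)
    na_ <- round(cfg$implant$only_a_frac * n_genomes)
    nbb <- round(cfg$implant$only_b_frac * n_genomes)
    both <- tax$assembly_id[ord[seq_len(nb)]]
    onlya <- tax$assembly_id[ord[nb + seq_len(na_)]]
    onlyb <- tax$assembly_id[ord[nb + na_ + seq_len(nbb)]]
    presence[c(both, onlya), "PAIRA"] <- TRUE
    presence[c(both, onlyb), "PAIRB"] <- TRUE
    nearby_genomes <- both[seq_len(round(cfg$implant$nearby_frac *
                                           length(both)))]
    implant_truth <- list(family_a = "PAIRA", family_b = "PAIRB",
                          both = sort(both), only_a = sort(onlya),
                          only_b = sort(onlyb),
                          neither = sort(setdiff(tax$assembly_id,
                                                 c(both, onlya, onlyb))),
                          nearby = sort(nearby_genomes))
  }

  # evolve sequences down the taxonomy; caches per (family, level)
  div <- cfg$divergence
  phy_seq <- list(); gen_seq <- list(); spe_seq <- list()
  seq_for_genome <- function(fam, prow) {
    kp <- paste(fam, prow$phylum_i)
    if (is.null(phy_seq[[kp]]))
      phy_seq[[kp]] <<- evolve_family(roots[[fam]], 1L, div[["phylum"]])
    kg <- paste(fam, prow$genus_i)
    if (is.null(gen_seq[[kg]]))
      gen_seq[[kg]] <<- evolve_family(phy_seq[[kp]], 1L, div[["genus"]])
    ks <- paste(fam, prow$genus_i, prow$species_i)
    if (is.null(spe_seq[[ks]]))
      spe_seq[[ks]] <<- evolve_family(gen_seq[[kg]], 1L, div[["species"]])
    evolve_family(spe_seq[[ks]], 1L, div[["genome"]])
  }

  operon_fams <- fam_ids[seq_len(min(cfg$n_operons * cfg$operon_size,
                                     length(fam_ids)))]
  operon_of <- setNames(rep(seq_len(cfg$n_operons),
                            each = cfg$operon_size)[seq_along(operon_fams)],
                        operon_fams)

  gene_rows <- list(); prot_seqs <- list(); truth_genes <- list()
  meta_rows <- list()
  fail_sets <- lapply(cfg$fail_fracs, function(fr)
    if (fr > 0) sample(tax$assembly_id, round(fr * n_genomes)) else character())

  for (gi in seq_len(n_genomes)) {
    prow <- tax[gi]
    gid <- prow$assembly_id
    fams_here <- all_fams[presence[gid, ]]
    seqs <- setNames(vapply(fams_here, function(f) seq_for_genome(f, prow),
                            character(1)), fams_here)

    # layout units: operon blocks stay adjacent; everything else shuffles
    ordinary <- setdiff(fams_here, c(names(operon_of), implant_ids))
    blocks <- lapply(split(intersect(fams_here, names(operon_of)),
                           operon_of[intersect(fams_here,
                                               names(operon_of))]),
                     identity)
    blocks <- blocks[lengths(blocks) > 0]
    units <- c(lapply(ordinary, identity), unname(blocks))
    units <- if (length(units)) units[sample.int(length(units))] else units

    pair_nearby <- implant_on && gid %in% implant_truth$nearby
    pair_here <- intersect(implant_ids, fams_here)
    # non-nearby joint carriers: keep the pair apart (opposite ends / strands)
    n_ctg <- max(1L, cfg$n_contigs)
    per_ctg <- split(units, rep(seq_len(n_ctg),
                                length.out = max(length(units), 1L)))
    gserial <- 0L
    new_gene <- function(contig, start, end, strand, fam, coding = TRUE) {
      gserial <<- gserial + 1L
      data.table(gene_id = sprintf("%s_g%04d", gid, gserial),
                 genome_id = gid, contig_id = contig,
                 start = start, end = end, strand = strand,
                 is_protein_coding = coding,
                 annotation = if (coding) paste0(fam, " protein")
                              else "tRNA-Xxx",
                 locus_tag = sprintf("%s_%04d", gid, gserial),
                 family = fam)
    }
    place_fam <- function(contig, pos, fam, strand) {
      glen <- 3L * nchar(seqs[[fam]]) + 3L
      g <- new_gene(contig, pos, pos + glen - 1L, strand, fam)
      prot_seqs[[g$gene_id]] <<- seqs[[fam]]
      gene_rows[[length(gene_rows) + 1L]] <<- g
      pos + glen
    }
    contig_ends <- integer(n_ctg)
    for (ci in seq_len(n_ctg)) {
      pos <- 1L + sample(cfg$intergenic_gap[1]:cfg$intergenic_gap[2], 1L)
      for (unit in per_ctg[[as.character(ci)]] %||% list()) {
        if (length(unit) > 1L) {  # operon: same strand, small gaps
          strand <- sample(c("+", "-"), 1L)
          for (f in unit) {
            pos <- place_fam(ci_name(ci), pos, f, strand)
            pos <- pos + sample(cfg$operon_gap[1]:cfg$operon_gap[2], 1L)
          }
        } else {
          pos <- place_fam(ci_name(ci), pos, unit[[1]],
                           sample(c("+", "-"), 1L))
          pos <- pos + sample(cfg$intergenic_gap[1]:cfg$intergenic_gap[2], 1L)
        }
      }
      contig_ends[ci] <- pos
    }
    # implanted pair placement
    if (length(pair_here)) {
      if (setequal(pair_here, implant_ids) && pair_nearby) {
        strand <- sample(c("+", "-"), 1L)
        pos <- contig_ends[1] + sample(50:2000, 1L)
        pos <- place_fam(ci_name(1L), pos, "PAIRA", strand)
        pos <- pos + sample(50:2000, 1L)
        pos <- place_fam(ci_name(1L), pos, "PAIRB", strand)
        contig_ends[1] <- pos
      } else {
        # apart: different contigs when possible, else far apart
        ctgs <- if (n_ctg >= 2) c(1L, 2L) else c(1L, 1L)
        strands <- c("+", "-")
        for (k in seq_along(pair_here)) {
          ci <- ctgs[k]
          pos <- contig_ends[ci] + if (ci == ctgs[1] && k == 2) 8000L
                                   else sample(200:2000, 1L)
          contig_ends[ci] <- place_fam(ci_name(ci), pos, pair_here[k],
                                       strands[k])
        }
      }
    }
    # non-coding genes
    for (tt in seq_len(cfg$n_trna)) {
      pos <- contig_ends[1] + sample(cfg$intergenic_gap[1]:
                                       cfg$intergenic_gap[2], 1L)
      g <- new_gene(ci_name(1L), pos, pos + 75L, sample(c("+", "-"), 1L),
                    NA_character_, coding = FALSE)
      gene_rows[[length(gene_rows) + 1L]] <- g
      contig_ends[1] <- pos + 76L
    }

    # metadata with controlled quality failures
    fails <- vapply(fail_sets, function(s) gid %in% s, logical(1))
    if (fails[["coding"]]) {
      # add pseudogene rows so the protein-coding fraction drops below half
      extra <- length(fams_here) + cfg$n_trna + 1L
      for (e in seq_len(extra)) {
        pos <- contig_ends[1] + 50L
        g <- new_gene(ci_name(1L), pos, pos + 200L, "+", NA_character_,
                      coding = FALSE)
        gene_rows[[length(gene_rows) + 1L]] <- g
        contig_ends[1] <- pos + 251L
      }
    }
    meta_rows[[gi]] <- data.table(
      assembly_id = gid,
      domain = prow$domain, phylum = prow$phylum, class = prow$class,
      order = prow$order, family = prow$family, genus = prow$genus,
      species = prow$species,
      is_isolate = if (fails[["mimag"]]) FALSE else runif(1) < 0.7,
      completeness = if (fails[["completeness"]])
        round(runif(1, 60, 89.9), 1) else round(runif(1, 95, 100), 1),
      contamination = if (fails[["contamination"]])
        round(runif(1, 5.1, 20), 1) else round(runif(1, 0, 2), 1),
      is_chimeric = fails[["chimeric"]],
      mimag_high_quality = !fails[["mimag"]],
      in_refseq = runif(1) < 0.7,
      is_type_species = runif(1) < 0.2,
      is_species_representative = runif(1) < 0.5,
      in_important_strains = runif(1) < 0.1,
      largest_scaffold_bp = max(contig_ends))
  }

  genes <- rbindlist(gene_rows)
  meta <- rbindlist(meta_rows)

  # emit FASTA + GFF3 per genome, metadata TSV, ground truth JSON
  for (gid in tax$assembly_id) {
    gsub <- genes[genome_id == gid]
    coding <- gsub[is_protein_coding == TRUE]
    aaset <- Biostrings::AAStringSet(
      setNames(unlist(prot_seqs[coding$gene_id]), coding$gene_id))
    Biostrings::writeXStringSet(aaset, file.path(out_dir,
                                                 paste0(gid, ".faa")))
    write_gff3(gsub, file.path(out_dir, paste0(gid, ".gff")))
  }
  write_tsv(meta, file.path(out_dir, "metadata.tsv"))

  truth <- list(
    config = list(seed = cfg$seed, n_genomes = n_genomes,
                  n_families = length(all_fams)),
    presence = lapply(seq_len(n_genomes), function(i)
      as.list(setNames(as.logical(presence[i, ]), colnames(presence)))),
    genomes = tax$assembly_id,
    gene_family = setNames(as.list(genes[is_protein_coding == TRUE, family]),
                           genes[is_protein_coding == TRUE, gene_id]),
    species_clusters = split(tax$assembly_id, tax$species),
    implant = implant_truth,
    quality_failures = fail_sets)
  names(truth$presence) <- tax$assembly_id
  write_json_file(truth, file.path(out_dir, "ground_truth.json"))
  invisible(truth)
}

ci_name <- function(i) sprintf("ctg%d", i)

# GFF3 writer for generated gene tables (via rtracklayer).
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$source <- "synthgen"
  S4Vectors::mcols(gr)$type <- ifelse(genes$is_protein_coding, "CDS", "tRNA")
  S4Vectors::mcols(gr)$phase <- ifelse(genes$is_protein_coding, 0L,
                                       NA_integer_)
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$locus_tag <- genes$locus_tag
  S4Vectors::mcols(gr)$product <- genes$annotation
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
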