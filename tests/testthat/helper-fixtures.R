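# Shared fixtures and independent oracles, all built in code.

suppressPackageStartupMessages({
  library(data.table)
  library(Biostrings)
})

AA20 <- aa_alphabet()[1:20]

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                  collapse = "")

# substitute exactly k positions of a sequence (always to a different residue)
mutate_seq <- function(seq, k) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample(length(s), k)
  for (p in pos) s[p] <- sample(setdiff(AA20, s[p]), 1)
  paste(s, collapse = "")
}

# the package-standard scoring matrix, built independently from Biostrings
oracle_submat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  ab <- aa_alphabet()
  m <- e$BLOSUM62[ab, ab]
  m["X", ] <- 0L; m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  m
}

# independent local-alignment oracle (Biostrings dynamic programming)
oracle_align <- function(a, b, score_only = TRUE) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = oracle_submat(), gapOpening = 11, gapExtension = 1,
    scoreOnly = score_only)
  if (score_only) max(0, pa) else pa
}

# write a tiny hand-built genome collection (FASTA + GFF3 + metadata) to dir
write_toy_genomes <- function(dir, genomes) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  for (g in genomes) {
    coding <- vapply(g$genes, function(x) isTRUE(x$coding), logical(1))
    aa <- Biostrings::AAStringSet(setNames(
      vapply(g$genes[coding], function(x) x$seq, character(1)),
      names(g$genes)[coding]))
    Biostrings::writeXStringSet(aa, file.path(dir, paste0(g$id, ".faa")))
    lines <- c("##gff-version 3")
    for (nm in names(g$genes)) {
      gene <- g$genes[[nm]]
      type <- if (isTRUE(gene$coding %||% TRUE)) "CDS" else "tRNA"
      lines <- c(lines, paste(
        gene$contig %||% "ctg1", "toy", type, gene$start, gene$end, ".",
        gene$strand %||% "+", "0",
        sprintf("ID=%s;locus_tag=%s;product=%s", nm, nm,
                gene$product %||% "hypothetical protein"), sep = "\t"))
    }
    writeLines(lines, file.path(dir, paste0(g$id, ".gff")))
    meta[[g$id]] <- toy_meta_row(g$id, g$tax %||% list())
  }
  mdt <- rbindlist(meta)
  prokbrowse:::write_tsv(mdt, file.path(dir, "metadata.tsv"))
  dir
}

toy_meta_row <- function(id, tax = list()) {
  data.table(
    assembly_id = id,
    domain = tax$domain %||% "d__Bacteria",
    phylum = tax$phylum %||% "p__P1", class = tax$class %||% "c__C1",
    order = tax$order %||% "o__O1", family = tax$family %||% "f__F1",
    genus = tax$genus %||% "g__G1",
    species = tax$species %||% "s__G1 sp1",
    is_isolate = TRUE, completeness = 99, contamination = 0.5,
    is_chimeric = FALSE, mimag_high_quality = TRUE, in_refseq = TRUE,
    is_type_species = FALSE, is_species_representative = TRUE,
    in_important_strains = FALSE, largest_scaffold_bp = 100000L)
}

# helper: a gene spec row for write_toy_genomes
toy_gene <- function(seq = NULL, start, end = NULL, strand = "+",
                     contig = "ctg1", coding = !is.null(seq),
                     product = "hypothetical protein") {
  if (is.null(end)) end <- start + 3 * nchar(seq) + 2
  list(seq = seq, start = start, end = end, strand = strand,
       contig = contig, coding = coding, product = product)
}

# metadata generator for selection tests
random_metadata <- function(n, seed) {
  withr::with_seed(seed, {
    data.table(
      assembly_id = sprintf("GC%05d", sample(1e5, n)),
      domain = "d__Bacteria", phylum = "p__P1", class = "c__C1",
      order = "o__O1", family = "f__F1",
      genus = sprintf("g__G%02d", sample(1:8, n, TRUE)),
      species = sprintf("s__S%02d", sample(1:12, n, TRUE)),
      is_isolate = sample(c(TRUE, FALSE), n, TRUE, c(.8, .2)),
      completeness = round(runif(n, 90, 100), 1),
      contamination = round(runif(n, 0, 5), 1),
      is_chimeric = FALSE, mimag_high_quality = TRUE,
      in_refseq = sample(c(TRUE, FALSE), n, TRUE),
      is_type_species = sample(c(TRUE, FALSE), n, TRUE, c(.2, .8)),
      is_species_representative = sample(c(TRUE, FALSE), n, TRUE),
      in_important_strains = sample(c(TRUE, FALSE), n, TRUE, c(.1, .9)),
      largest_scaffold_bp = sample(c(5e5, 1e6, 2e6, 2e6), n, TRUE),
      n_genes = 1000L, n_protein_coding = 900L)
  })
}

# brute-force preference comparator for representative selection: returns
# TRUE if genome a is strictly preferred over b (literal rule-by-rule walk)
oracle_prefer <- function(a, b) {
  cmp_flag <- function(x, y) if (x != y) return(x) else NA
  for (f in c("in_refseq", "is_type_species", "is_species_representative")) {
    r <- cmp_flag(a[[f]], b[[f]])
    if (!is.na(r)) return(r)
  }
  qa <- 2 * a$contamination - a$completeness
  qb <- 2 * b$contamination - b$completeness
  if (qa != qb) return(qa < qb)
  r <- cmp_flag(a$in_important_strains, b$in_important_strains)
  if (!is.na(r)) return(r)
  if (a$largest_scaffold_bp != b$largest_scaffold_bp)
    return(a$largest_scaffold_bp > b$largest_scaffold_bp)
  a$assembly_id < b$assembly_id
}

# O(n^2) selection sort by oracle_prefer
oracle_sort <- function(dt) {
  rows <- split(dt, seq_len(nrow(dt)))
  n <- length(rows)
  for (i in seq_len(max(0, n - 1))) {
    best <- i
    for (j in (i + 1):n)
      if (oracle_prefer(rows[[j]], rows[[best]])) best <- j
    tmp <- rows[[i]]; rows[[i]] <- rows[[best]]; rows[[best]] <- tmp
  }
  unname(vapply(rows, function(r) r$assembly_id, character(1)))
}

# Exhaustive oracle for midpoint rooting: over every possible root placement
# on any edge, the smallest achievable maximum root-to-leaf distance equals
# half the tree diameter (the longest leaf-to-leaf path).
min_possible_root_height <- function(tr) {
  max(stats::cophenetic(tr)) / 2
}

# small simulated database, shared across tests (built once per run)
shared_small_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "prokbrowse-shared-sim")
      cfg <- sim_config(seed = 77, n_phyla = 2, genera_per_phylum = 2,
                        species_per_genus = 2, genomes_per_species = 2,
                        n_families = 25)
      truth <- simulate_genomes(cfg, dir)
      db <- build_database(dir, quality_filter = FALSE)
      db <- cluster_database(db)
      cache <<- list(db = db, truth = truth, dir = dir)
    }
    cache
  }
})
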