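---
title: "Methods: accelerated comparative browsing of prokaryotic genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accelerated comparative browsing of prokaryotic genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

prokbrowse is an offline engine for comparative analysis of bacterial and
archaeal genomes. Its pieces mirror how a comparative genome browser works
internally: build a database of representative genomes, find homologs of a
query protein quickly, then summarize those homologs three ways — gene
neighborhoods, taxonomic prevalence, and two-protein co-occurrence. This
vignette explains the models and procedures, the parameters that matter,
the numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Database model

A database holds genomes, genes and *distinct* protein sequences. Genes
carry 1-based inclusive coordinates on stranded contigs (the GFF3
convention; all internal arithmetic keeps it). Identical amino-acid
sequences are collapsed to one protein record whose id is a 64-bit content
hash of the sequence, so deduplication is deterministic across runs and
machines. Contig ids are scoped per genome — the global key is
(genome id, contig id) — because assemblies routinely reuse names like
`contig1`. Non-coding genes (tRNA/rRNA/pseudogene rows) are kept for
neighborhood display but excluded from all searches.

Persistence uses a versioned single-file text container (a header line
plus one TSV section per table). A relational single-file store would do
equally well; the text container keeps round trips byte-reproducible and
diffable, and the loader refuses files written under a different schema
version rather than guessing.

### Genome quality gate and representative selection

Only high-quality assemblies make presence/absence analyses trustworthy,
so the gate requires: completeness ≥ 90% and contamination ≤ 5% (CheckM
scores, consumed as metadata), not flagged chimeric (GUNC assessment,
likewise consumed), MIMAG high-quality-draft status for anything that is
not an isolate, and at least half of the genes protein-coding (screens out
pseudogene-riddled assemblies). The first failing rule, in that order, is
reported as the rejection reason; a missing metadata field is an error,
never a silent pass.

Representatives — one per genus for a main database, up to 10 per species
for order-level databases — are chosen by a fixed preference list: in
RefSeq; type species of the genus; the species representative; lower
`2 * contamination − completeness`; on an important-strains list; longer
largest scaffold. The published preference list ends there, which leaves
ties possible, so the assembly id (lexicographic) is appended as a final
tiebreak: selection becomes a total order and a pure function of the
metadata, and permuting input rows cannot change the outcome. Boolean
criteria compare preferred-first; the quality score and scaffold length
compare numerically with no rounding.

## Alignment substrate

Every similarity in the package — search hits, cluster membership,
neighborhood color groups, tree distances — comes from one Smith–Waterman
local-alignment kernel with affine gaps, implemented in C++ with full
traceback. Scoring is BLOSUM62 with gap open 11 / gap extend 1, the
de-facto protein-search standard that the 30%/50%/70%/90% thresholds used
elsewhere were calibrated against. Raw scores convert to bits via the
gapped Karlin–Altschul pair λ = 0.267, K = 0.041, and
`E = m · n · 2^(−bits)` with `m` the query length and `n` the total
residue count of the target set (equivalent to the `K·m·n·e^(−λS)` form by
the definition of bits). X residues score 0 against everything, so unknown
residues neither help nor hurt.

Two conventions matter and are applied uniformly:

* **Identity denominator** = alignment columns *including gap columns*
  (the protein-BLAST convention). Tools in the CD-HIT family divide by the
  shorter sequence instead; for the high-coverage alignments the cluster
  contract admits the difference is small, but it is a real divergence and
  the package uses its own convention everywhere.
* **Coverage** = aligned span over sequence length, per side.

When two alignments are co-optimal the kernel reports one optimal path;
tests therefore assert score equality exactly but endpoints/identity only
where the optimum is unique.

The search prefilter is a shared-k-mer shortlist (k = 4, minimum one
shared word), chosen for recall over speed at desk scale: a pair at ≥ 70%
identity over 100+ columns shares a 4-mer with probability
indistinguishable from 1. Queries shorter than the word size are aligned
exhaustively rather than silently returning nothing. There is no
composition-based score adjustment and no iterated/profile search; both
omissions are deliberate scope limits, and the synthetic data is generated
with uniform residue frequencies so compositional bias does not arise in
the tests.

## Homolog search

`search_direct` aligns the query against every distinct protein passing
the prefilter, keeps hits with E ≤ 10⁻³, truncates to the number of
genomes, and ranks by bit score (then E-value, then subject id, making the
order total and deterministic). Hit labels:

* **homolog** — any hit passing the E-value gate;
* **potential ortholog** — identity ≥ 30% and query coverage ≥ 50%
  (boundaries inclusive);
* **good homolog** — bit score ≥ 30% of the query's self score (the
  *score ratio*, which is also the axis quantity of the presence/absence
  plot);
* **high-coverage ortholog** — a potential ortholog covering ≥ 90% of
  both sequences.

`search_clustered` is the accelerated path for redundant order-level
databases: search the cluster representatives, expand each representative
hit to its full cluster membership (candidates ordered by representative
score, members in cluster order, truncated to `max(n_genomes, 200)`),
re-align the query to every candidate, then filter/sort/rank exactly as
the direct search. The re-alignment uses the same kernel and score scale
as stage 1 — a deliberate unification; production browsers mix engines
with incompatible bit scores, which complicates downstream ratio
thresholds for no benefit at this scale. The candidate-truncation ordering
(strongest representatives first) keeps the strongest families when the
cap binds.

`sensitivity_for_length` records the piecewise schedule an external
engine would be driven with (7.5 up to 150 aa, 7.0 to 250, 6.25 to 350,
6.0 to 650, 5.7 beyond): short queries need the highest sensitivity. The
split–align–merge workflow contract for such an engine (contiguous
candidate splits whose concatenation preserves the original list; merged
results sorted identically to a single run; truncation to the genome
count) is implemented and tested as pure functions; invoking an actual
engine requires one to be configured and errors otherwise rather than
silently falling back.

## Greedy clustering

Order-level databases are redundant (up to 10 genomes per species), so
proteins are clustered once and searches run against representatives.
The algorithm is greedy and incremental: process proteins longest-first
(ties by id); each joins the first existing cluster — in creation order —
whose representative aligns at ≥ 70% identity with ≥ 90% coverage of
*both* sequences, else founds a new cluster. First-fit rather than
best-fit matches the behavior of the standard greedy clustering tools and
is deterministic.

Candidates are prescreened by shared k-mers plus a length bound that
follows from the contract itself: matches ≥ 0.7 · columns ≥ 0.63 ·
rep-length while matches ≤ member-length, so representatives longer than
member/0.63 cannot qualify and are skipped without aligning. The
clustering prescreen requires two shared 4-mers (the search prefilter
keeps its one-word minimum): contract-satisfying pairs share ~35 words in
expectation, and `verify_clusters` independently re-aligns every member to
its representative, so a zero-violation report certifies the emitted
contract regardless of prescreen choices.

## Gene neighborhoods

For each displayed homolog the view extracts all genes overlapping a
window around the anchor (±10 kb by default; the window size is this
package's choice — browsers rarely state theirs — and is configurable),
mirrored so the anchor always points rightward. Visible proteins are
aligned all-vs-all; pairs whose alignment covers ≥ 50% of both sequences
are linked and groups are the connected components (single linkage, pairs
processed in bit-score order for determinism). Whether production
browsers use single linkage or representative-based greedy grouping here
is not generally documented; single linkage was chosen because it cannot
split a family whose members all match a common core.

Styling: the query's group is white (effectively an extra color);
remaining multi-member groups take styles from 11 colors × 3 hatch states
(none/two hatches) = 33 distinct styles, allocated by group size and
reused cyclically afterwards; singleton groups are neutral gray and do not
consume a style — this keeps the 33 informative styles for groups that
actually show conservation.

Same-species rows whose proteins share a cluster collapse into one row
(the highest-scoring member represents it; all merged genomes are
recorded), which keeps 10-per-species databases readable. Gene spacing is
`start₂ − end₁ − 1`: zero means abutting, negative means overlap — small
spacings are strong operon evidence, which is why the number is surfaced.

The guide tree orders rows: pairwise distances are `1 − fractional
identity` of alignments between the query-matched regions only (flanking
domains absent from the query should not distort the tree), neighbor
joining builds the topology (negative NJ branch lengths are clamped to
zero), the root is the midpoint (minimizing the maximum root-to-leaf
distance, which equals half the tree diameter), and children at every node
are ordered by best descendant bit score so the strongest homolog is the
top leaf. A full MSA + approximate-ML tree would be marginally better and
much heavier; NJ on kernel distances removes the external-binary
dependency, and adapters for external MSA/tree tools remain out of scope.
Up to 200 homologs are shown; they can be the top hits or a seeded uniform
sample of all (or only "good") homologs, which reveals the breadth of a
large family instead of its dense top.

## Taxonomic profiles and co-occurrence

The prevalence profile counts, per taxon at a chosen rank, the genomes in
the database and the genomes with a hit (each genome once, however many
hits it has), plus the maximum score ratio in the taxon. Taxa without hits
are included by default — prevalence includes absence. The profile can be
restricted to potential orthologs or good homologs; distant homologs
below 30% identity usually differ in function, so the unrestricted view
is the most permissive, not the most meaningful.

Co-occurrence compares two proteins' hit lists. Per genome, the best hit
of each protein gives a score-ratio pair; genomes carrying only one side
are marked absent on the other axis (drawn in a gray band below zero).
Two flags annotate each genome: *nearby* (best homolog genes within 5 kb,
inclusive, on the same strand and contig; overlap counts as distance 0)
and *fused* (the same subject protein is the best hit for both queries).

The association statistic optimizes one shared rank threshold k: a genome
is "present" for a protein iff its best hit has rank ≤ k. Candidate
thresholds are the ranks at which either list gains a genome (the P-value
is a step function of k, constant between those points, so nothing is
lost by skipping the plateaus); for each candidate a one-sided Fisher
exact P — the hypergeometric tail, computed in closed form — is taken over
the 2×2 table of *all* database genomes, including genomes with neither
protein (the universe must be fixed a priori, not conditioned on having a
hit). The minimal P is reported with its threshold (ties to the smallest
k) after Bonferroni correction by the number of candidates considered;
both the factor and the full scan are returned so alternative corrections
can be audited. One-sided is the right test here: the statistic exists to
detect co-occurrence, not avoidance. The two-threshold variant of partial
phylogenetic profiling is out of scope by design.

## Evaluation harness

Search variants are compared by rank-binned miss rates: the reference
universe is the reference method's hits with E ≤ 10⁻⁵ and rank ≤ half the
genome count (few proteins have orthologs in most prokaryotes, so deeper
hits are rarely orthologs), optionally restricted to potential orthologs
or to score ratio ≥ 0.3. A reference hit is missed iff its
(query, subject) pair is absent from the test results — scores are never
compared, because different engines score differently. Hits are binned by
reference rank (50 ranks per bin by default) and per-bin plus overall
rates reported.

## Synthetic data and what the tests show

The generator emits a small GTDB-style taxonomy (7 ranks; one
class/order/family lineage per phylum), protein families evolved root →
phylum → genus → species → genome by substitution-only mutation with
per-rank divergences, genomes laid out on 1–3 contigs with operon blocks
(same strand, sub-kilobase gaps), one implanted co-occurring family pair,
and metadata with controllable per-rule quality failures. Defaults: 2%
divergence per genome, 5% per species, 16% per genus, 35% per phylum —
within-species copies sit far inside the 70/90 cluster contract while
cross-clade homologs stay findable; lognormal lengths around 180
residues; family presence drawn per genus at 0.85 with 0.95 per-genome
retention; the implanted pair jointly present in half the genomes and
jointly absent in the rest, adjacent within 5 kb on the same strand in
80% of the joint carriers. Substitution of exactly `round(d·L)` positions
(always to a different residue) makes identity ground truth exact; an
indel-free model also makes coverage ground truth exact. Uniform residue
frequencies avoid compositional bias, which the kernel does not correct
for.

The clustered-search fidelity condition is a synthetic *order*: one
order of 8 genera × 3 species × 8 genomes with ~150 families (about
23,000 distinct proteins), mirroring the setting where clustered search
is the intended tool — order-level databases hold genomes of a single
order. Fifty random queries are searched both ways and potential-ortholog
recall of the clustered path is required to be ≥ 99%.

What passing does **not** show about real data: no indels or domain
rearrangements (an indel mode exists for stress-testing coverage logic,
with ground truth then defined by realized alignments), no horizontal
transfer, no paralogs within a genome, no compositional bias, uniform
family sizes, and far smaller databases than production scale. The tests
certify the algorithms' contracts and internal consistency, not
field-scale sensitivity figures.

## Problem sizes and numerical choices

Deliberate sizes used by the test suite and the acceptance script: the
order-scale fixture above (~23k proteins, 192 genomes, 50 queries); 20
seeded clustering fixtures of 4–8 families; 100 brute-force threshold
instances on 40 genomes; 500 independent pairs (marginal presence 0.3) on
200 genomes for type-I control; 50 random trees for the midpoint oracle;
1,000 metadata rows for the selection comparator. Numerical choices worth
knowing: E-values use the bit-score closed form; NJ branch lengths are
floored at zero; Fisher tails come from `phyper` (exact, not simulated);
rank ties are impossible by construction of the three-key sort; the
Bonferroni factor is the number of candidate thresholds actually scanned.

## Known limitations

Single-threaded reference kernels (the parallel split–align–merge is a
tested contract, not a performance feature here); no iterative search; no
composition-adjusted scores; substitution-only ground truth by default;
the text-container store is not meant for concurrent access. Wall-clock
performance claims of production systems are explicitly out of scope.
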