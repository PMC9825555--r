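---
title: "Methods: CGC detection and glycan substrate prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CGC detection and glycan substrate prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgckit)
```

# The problem

Bacteria that degrade complex glycans organize the required machinery in
gene clusters: glycoside hydrolases and other CAZymes sit next to the
transporter that imports the substrate, the regulator that senses it, and
often a signal transduction protein. `cgckit` detects such CAZyme gene
clusters (CGCs) in annotated genomes or MAGs and predicts each cluster's
glycan substrate by two independent routes, so that agreement between the
routes can serve as a confidence signal. The package consumes annotation
*tables* (per-tool CAZyme calls, TC/TF/STP calls, pairwise protein hits in
tabular alignment format); it never runs the search engines itself, which
keeps it fast, deterministic and ecosystem-neutral.

# Signature classification

A gene's class is one of CAZyme, TC, TF, STP or Other. CAZyme status is
decided by a consensus over up to three calling tools (`hmm`, `alignment`,
`kmer`): a protein is kept iff at least `min_tools` (default 2) *distinct*
tools report any CAZyme family. Distinct-tool counting — rather than hit
counting — is the literal reading of a "called by at least two tools"
rule; two hits from one tool are one vote. The retained family set is the
union over reporting tools. Tools can disagree on the family label; we
union rather than intersect because the family set is descriptive metadata
here (clustering only needs the CAZyme/not-CAZyme decision, and voting
uses the k-mer subfamily, not the family set).

When a protein carries both a CAZyme call and a TC/TF/STP call, the
precedence CAZyme > TC > TF > STP applies. No convention is universal
here; we put CAZyme first because CAZymes anchor the cluster definition —
masking one could delete a true cluster, whereas masking a second TC in a
cluster that already has one is harmless. The precedence is an argument of
`classify_genes()` for users who disagree.

# Cluster detection

Detection operates on gene *ordinals* (rank along the contig), never on
base-pair distances: the defining rule speaks of "inserted genes", and
rank is robust to the wildly variable intergenic distances of draft MAGs.
The scan chains signature genes while at most `max_insert` (default 2)
consecutive non-signature genes separate them; chains are trimmed to their
first and last signature gene, then kept iff they contain ≥ 1 CAZyme and
≥ 1 gene of a class in `required_other` (default any of TC/TF/STP).

Design points that were genuinely open:

* **Composition rule.** Run configurations of cluster finders are often
  described loosely as "CAZyme + TC + TF". We implement the precise
  definition — one CAZyme plus at least one *of* the other signature
  classes — as the default, and expose `require_all = TRUE` for the
  strict conjunctive reading, plus `required_other` to restrict which
  classes qualify.
* **STP as a chain extender.** STP genes count as signature during the
  scan by default (`active_signature_set`), because the class is part of
  the cluster definition; removing it from the active set demotes STPs to
  inserted genes.
* **Trimming.** Candidates are trimmed to signature boundaries rather
  than retaining flanking inserted genes; `keep_flanks = TRUE` reverses
  this. Trimming makes spans reproducible and never changes the
  composition test.
* **Contigs are independent.** Chains terminate at contig ends; no
  attempt is made to join clusters across a fragmented assembly.

The scan is checked against an independent brute-force oracle (enumerate
all contiguous windows, keep chain-valid maximal ones, filter by
composition) on thousands of random contigs in the test suite; the two
formulations are equivalent because every chain-valid window is contained
in exactly one maximal chain of signature genes.

# Substrate by PUL homology

Query CGC proteins are compared against the proteins of characterized
PULs; the package consumes precomputed 12-column tabular hits. Scoring a
(CGC, PUL) pair:

1. discard hits with e-value above `min_evalue` (default `1e-4`, the
   conventional protein-homology cutoff; results are insensitive to the
   exact value because true cluster-to-PUL hits are far below it);
2. reduce the remaining hits to a one-to-one matching, greedily by
   descending bit score with deterministic tie-breaks (query id, then
   subject id). One-to-one matching prevents a single promiscuous protein
   (for example a SusC-like transporter hitting every PUL member) from
   inflating the score. Greedy rather than optimal matching is a
   deliberate simplification: on the homolog-dominant instances this
   problem produces (each protein has one strong true partner and only
   weak spurious alternatives) greedy is provably optimal, which the test
   suite asserts against an exhaustive maximum-weight matcher;
3. sum the matched bit scores; the match is *eligible* only with ≥ 1
   CAZyme↔CAZyme pair and ≥ 1 pair agreeing on a class in {TC, TF, STP}.
   Requiring class agreement on both sides of a pair is the natural
   reading of "a CAZyme match"; it stops a cluster from qualifying via a
   CAZyme that happens to align to a PUL transporter.

The best eligible PUL (highest summed bits; ties by more pairs, then
lexicographically smaller PUL id — both purely for determinism) donates
its substrate. No minimum score floor is applied: an eligible match
already requires two class-consistent significant alignments, and a floor
would add a second arbitrary threshold.

# Substrate by subfamily voting

K-mer subfamilies (`FAMILY_e<digits>`) subdivide poly-specific CAZyme
families into groups with few (often one) EC numbers, which makes a
subfamily → EC → substrate table feasible. Each CAZyme in a cluster looks
its subfamily up and casts one vote; subfamilies absent from the table or
without a curated substrate abstain. "Majority" is implemented as
*plurality* (strictly highest count), because clusters frequently have
only a minority of their CAZymes annotated and a >50% rule would silence
most of them; `strict_majority = TRUE` switches to the >50%-of-annotated
rule. Ties yield no call — downstream agreement statistics need a single
label per approach, and an arbitrary tie-break would manufacture spurious
agreement or disagreement. `min_votes` (default 1) exists because a
single-vote call is weak evidence; raising it can only retract winners,
never change one, which the suite verifies.

# Consensus and summary statistics

Two assignments agree when both exist and the substrate strings match
after case-folding and trimming. No glycan-synonym merging is applied:
glycan nomenclature overlaps (pectin side chains are arabinogalactans;
beta-galactan occurs in carrageenans), so any merging scheme would be a
curation decision, not a computation, and agreement rates should be read
as conservative. Percentages are rounded half-up at the printed precision
(2 decimals for table rows, 1 for the agreement rate) — half-up, not
banker's rounding, is what reproduces printed tables exactly.

# What the synthetic generator emulates

`make_fixture()` writes a complete, internally consistent input bundle:
a mock PUL database (20 PULs by default, each with a substrate from a
20-term vocabulary and a gene layout drawn from five compositions that
all begin and end with a signature gene), genomes whose contigs carry
mostly `Other` genes, and 60 implanted clusters (default) that are copies
of randomly chosen PULs. Implants are separated by background runs of at
least three genes so they can never merge under the default insertion
allowance. Consistency rules:

* implant CAZymes are reported by two tools (so the consensus keeps
  them) and their k-mer subfamily maps to the source PUL's substrate;
  background decoys are reported by a single tool (so the consensus
  removes them) or are lone transporters deep inside background runs;
* every implant protein receives a fabricated alignment hit to its PUL
  counterpart (bit score 180 ± jitter, e-value 10⁻⁵⁰) plus one weak
  cross-PUL decoy hit (40 bits) that can never make a wrong PUL eligible
  on its own;
* noise knobs: `drop_hit_prob` removes hits, `bitscore_jitter_sd`
  perturbs scores, `mislabel_prob` silently drops a gene's annotation.

With all noise at zero, both prediction routes recover 100% of implanted
substrates, and recovery under hit dropout is what the acceptance script
measures. The generator does **not** emulate sequence evolution, family
label noise, assembly fragmentation inside a cluster, overlapping or
nested clusters, or biased substrate composition — so passing tests show
the *machinery* is correct under the stated rules, not that prediction
accuracy on real MAGs reaches any particular level. Bit scores are
fabricated, not computed from the synthetic sequences; the sequences
exist only so the bundle is format-complete.

Coordinates are laid on a fixed 1500-bp grid (gene length 1200 bp)
because all logic is ordinal-based; coordinate realism would add nothing
the tests could detect.

# Degenerate inputs and numerical conventions

* Empty GFF3 files, contigs without signature genes, clusters without
  mapped CAZymes, and empty hit tables all produce empty (not missing)
  results.
* Gene ordering ties at equal start coordinate break by end coordinate,
  then gene id.
* All orderings that affect output (cluster numbering, vote
  serialization, candidate PUL ranking) have total, deterministic sort
  keys, so identical inputs give byte-identical output files.
* Percentage denominators of zero are an error, not `NaN`.

# Problem sizes in the shipped checks

The test suite checks detection against the brute-force oracle on 1000
random contigs of up to 12 genes, monotonicity over 300 contigs × 4 gap
settings, and recovery on the default 60-implant/20-PUL study plus its
30%-dropout variant; the acceptance script repeats the recovery and
oracle-agreement measurements end to end. These sizes exercise every rule
boundary (window sizes up to 12 cover all gap/boundary interactions at
`max_insert` ≤ 3) while keeping a full run in well under two minutes.

# Known limitations

* Substrate vocabulary is treated as flat strings; hierarchical glycan
  ontologies are out of scope.
* The homology route depends entirely on the supplied hit table; the
  package does not validate that the alignment tool's e-value model
  matches the default `min_evalue`.
* Strand is read and preserved but ignored by clustering — operonic
  directionality is not modelled.
* Cross-contig cluster joining is not attempted, so fragmented assemblies
  undercount clusters.
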