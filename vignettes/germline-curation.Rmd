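---
title: "Curating germline sets with germlinekit: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating germline sets with germlinekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germlinekit)
```

# The curation problem this package models

Immunoglobulin and T-cell receptor germline sets are collections of the
known V, D and J alleles of one locus (IGH, IGK, IGL, TRA, TRB, TRG or
TRD) of one species, possibly restricted to a subgroup such as an inbred
strain. Two features of current allele discovery shape the whole design:

1. **Alleles may be unmapped.** A sequence inferred from repertoire data
   can be known with confidence while the gene it belongs to is not. The
   data model therefore treats the *allele* (a sequence-level entity with
   a label) as primary, and the *gene* assignment (`gene_label`) as an
   optional annotation. No operation in the package parses information out
   of a name: locus, type, functionality and coordinates are explicit
   fields.
2. **Names change; history must not be lost.** When an unmapped allele is
   later assigned to a gene, or reconciled with another database, its
   label changes. Every record carries an ordered alias list, oldest
   first; renaming appends the outgoing label, and `resolve_label()`
   searches current labels and then aliases, so any name the allele ever
   carried keeps resolving to the same record.

# Temporary labels and the identifier space

A temporary label has the shape
`<locus><type><subgroup>-<identifier>*<allele>`, e.g. `IGHV0-A5B2*00`.
Subgroup and allele designator hold null values (`"0"`, `"00"`) until a
curator assigns real ones. The identifier is a uniformly drawn 20-bit
value encoded in 4 symbols of the RFC 4648 §6 base32 alphabet — `A`–`Z`
followed by `2`–`7` — so the digits 0, 1, 8 and 9 never occur and the
space holds exactly $32^4 = 2^{20} = 1{,}048{,}576$ values.

Conventions the encoding needed that the label template alone does not
fix:

* **Bit order.** Values are split into four 5-bit groups most-significant
  first, matching the stream order of the RFC itself. `encode_identifier()`
  and `decode_identifier()` are exact inverses over the whole space (the
  test suite enumerates all $2^{20}$ values).
* **Temporary vs legacy classification.** `parse_label()` treats a label
  as temporary only when its identifier matches `[A-Z2-7]{4}` *and*
  either contains a letter or the subgroup and allele designators are both
  null. An all-digit identifier such as `2345` under a non-null subgroup is
  visually indistinguishable from a ratified gene number (e.g.
  `IGHV3-2345*01`), so it is classified legacy. This leaves a small,
  documented ambiguity for all-digit identifiers; labels freshly
  allocated by this package always carry their null designators while
  temporary, so round-tripping is unaffected.
* **Case.** Labels are uppercase; lowercase input is uppercased with a
  warning rather than rejected.

# The naming-domain registry

A naming domain is the uniqueness scope of identifiers — a whole species,
or one subgroup, chosen by the curators when the domain is created.
Because the registry CSV is fixed to a minimal, diff-friendly column set
(`identifier,current_label,sequence,status,allocated,aliases,notes`),
domain identity (`domain_id`, locus) is a property supplied at creation or
load time, not a column; `load_registry()` defaults the locus from the
first record's label.

Allocation draws uniformly over the *never-issued* values. Withdrawn
records keep their identifiers forever (`status = "withdrawn"`, never
deletion), so an identifier can never acquire a second meaning within its
domain. The sampler uses rejection sampling while less than half the
space is issued and an explicit set-difference draw beyond that, so the
distribution stays uniform and the near-exhausted case (a single
remaining value) is exact; requesting more identifiers than remain is a
capacity error. All draws honour a caller-supplied seed, and
`apply_proposals()` records the seed in its report, so an allocation run
is bit-reproducible: same registry bytes in, same registry bytes out.

## Two-phase allocation

`propose()` compares each candidate (uppercased, gap characters and
whitespace stripped) against the registry by **exact string containment**
— equality, strict substring, strict superstring — with no
reverse-complement matching and no similarity threshold. Germline
submissions are conventionally sense-strand, and fuzzy matching would
quietly merge distinct alleles; both are documented limitations rather
than options. Batch-internal duplicates collapse onto their first
occurrence.

Defaults encode the review policy:

* exact duplicates of an active record default to
  `assign_existing:<identifier>`;
* new sequences default to `allocate_new`;
* sub-/super-sequence calls get **no default**. Whether two nested
  sequences represent the same allele depends on haplotype or usage
  evidence only a curator can weigh, so `apply_proposals()` rejects a
  batch containing unresolved calls without touching the registry;
* duplicates whose only matches are withdrawn records are flagged in the
  proposal's `note` column and likewise left to the curator.

Ties among multiple containment matches are ordered by allocation date,
then identifier — a deterministic order that also fixes the bytes of the
saved proposal file.

`merge_registries()` supports registries maintained under version control
by several groups: records agreeing on identifier and sequence union
their aliases (first registry's order wins, novel names appended); an
identifier with two sequences, or one sequence under two identifiers, is
a clash, and any clash aborts the merge with a full report — a merge is
all-or-nothing so no partially merged registry can be saved.

# Serialisation choices

JSON output is canonical: fixed key order, 2-space indent, LF endings,
UTF-8, allele descriptions sorted by label (the `germline_set()`
constructor itself keeps alleles in label order, so equality after a
read/write round trip is exact object identity). Optional scalars are
emitted as `null` rather than omitted, which keeps diffs between releases
positional. The `schema_version` string (`germline-kit-1.0`) is checked
on read and unknown versions are rejected outright — a best-effort parse
of a future schema could silently drop fields.

FASTA export writes the label as the entire header and wraps sequence at
60 columns; all metadata lives in JSON, so FASTA consumers are never
tempted to parse data out of names. Gapped export requires a gapped
alignment on every V allele and errors with the offending labels
otherwise; the gap character is `.` (`-` is normalised on input). The
package stores gapped alignments; it never computes them.

`diff_sets()` matches alleles by record identifier first and then by
resolving new labels through old labels *and aliases*, so a pure rename
is reported as a modification of `label`, not as removal plus addition.
Per-record `version` and `release_date` are bookkeeping and excluded from
comparison — hence `bump_version()` followed by a diff reports no allele
changes, which is the property release tooling needs.

# Genotypes and personalised sets

`classify_allele()` mirrors the registry's containment logic against
published sets: exact equality is `documented`; a strict substring of a
reference is a `partial_match` whose truncation side comes from the match
offset (suffix missing → `3p`, prefix missing → `5p`, interior →
`both`) — reflecting that repertoire-inferred sequences are often
inconclusive at their 3' ends; a strict superstring partial-matches only
references explicitly flagged incomplete. Partial matches are never
auto-promoted to documented, mirroring the registry's curator-decides
rule.

`personalize()` builds a subject's set: one allele per documented call
(copied from the referenced set, aliases resolved), one per undocumented
allele, none from genes confirmed deleted, phasing propagated into
evidence notes. With a registry supplied, undocumented alleles get fresh
null-valued temporary labels; because the function returns a
`germline_set`, the updated registry rides along as the `naming_domain`
attribute. Deletions are *confirmed* deletions only: a gene merely not
observed in a repertoire is not represented, since absence of evidence is
analysis-dependent.

# Synthetic data: what it does and does not emulate

`generate_set()` emulates the *variation structure* the tooling must
handle — several alleles per gene differing by point substitutions, and a
minority of 5'- or 3'-truncated sequences flagged incomplete — with
sequences drawn uniformly over ACGT. Defaults: base length 280–320 nt
(typical V exon scale), 2 alleles per gene, per-site substitution rate
0.02 (a handful of differences per allele pair), truncation probability
0.1 with 1–15 nt trimmed. The generator deliberately carries **no
biological signal**: no recombination signal sequences, leaders, codon
structure or hotspot bias. Passing tests therefore demonstrate correct
data handling — containment logic, validation, serialisation, allocation
— not biological fidelity; real sequences are more self-similar than
uniform random ones, so real curation will see sub-/super-sequence calls
more often than the synthetic mix does. Generation is bit-reproducible
under a fixed seed, and generated dates are constants so that generated
JSON is byte-stable across sessions.

The packaged mouse table transcribes the published community-curated set
sizes for 20 inbred strains; `table1_germline_sets()` materialises one
synthetic set per row at exactly the published allele count. The counts
are faithful, the nucleotides are synthetic, and the sets exist to
exercise set handling at realistic scale without shipping third-party
sequence data.

Test problem sizes were chosen to probe each property at the smallest
scale that exercises it fully: the identifier round-trip enumerates the
entire $2^{20}$ space; proposal correctness is checked against a
brute-force, substring-enumeration containment oracle over 1,000
randomised batches (domains up to 100 records, sequences 4–400 nt);
no-reuse is checked over 10,000 allocations interleaved with
withdrawals.

# Known limitations

* Constant (C) genes are out of scope; the model covers V, D and J.
* Sequence matching is literal: IUPAC ambiguity codes are accepted in
  sequences (with a warning-level violation) but never expanded during
  registry or genotype matching.
* No reverse-complement or similarity matching (see above).
* Haplotype phasing is carried as an integer chromosome index per call;
  the package stores phasing, it does not reconstruct haplotypes.
* Gapped alignments and region delineations are stored and validated
  (coordinates 1-based inclusive on the ungapped sequence, regions
  non-overlapping and ascending) but never computed from sequence.
* The command-line wrapper is a thin layer over the exported functions;
  anything it can do, the functions do in-process.
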