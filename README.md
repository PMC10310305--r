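# germlinekit

Curation, temporary nomenclature and publication of immunoglobulin (IG) and
T-cell receptor (TR) germline reference sets.

## The problem

Accurate analysis of adaptive immune receptor repertoire sequencing
(AIRR-seq) data depends on complete germline sets — curated collections of
the V, D and J alleles of a locus. Many newly discovered alleles, inferred
from repertoires or from long-read assemblies, cannot yet be mapped to a
gene, so they cannot receive a formally ratified name. Curators still need
to publish them, refer to them unambiguously, track them through renames,
and merge contributions from multiple groups. `germlinekit` provides the
machinery for that workflow:

* **A data model with validation** — `allele_description()`,
  `germline_set()`, `genotype()` / `genotype_set()`, with `validate_*`
  functions that return violations as data, not exceptions.
* **Temporary nomenclature** — labels of the form
  `<locus><type><subgroup>-<identifier>*<allele>`, e.g. `IGHV0-A5B2*00`.
  The identifier is a random 20-bit value rendered in 4 characters of the
  RFC 4648 §6 base32 alphabet (A–Z then 2–7; the digits 0, 1, 8 and 9 never
  occur), giving 32⁴ = 1,048,576 memorable, collision-checked identifiers
  per naming domain. Subgroup and allele designators hold null values
  (`0`, `00`) until real values are assigned.
* **A two-phase allocation registry** — `propose()` classifies candidate
  sequences against a CSV-backed naming-domain registry (duplicate /
  subsequence / supersequence / new, by exact string containment);
  a curator reviews the proposals; `apply_proposals()` executes them,
  allocating identifiers that are unique forever — withdrawn identifiers
  are never re-used. Renames keep every previous label as an alias
  (`rename_record()`, `add_alias()`, `resolve_label()`), and registries
  maintained by different groups can be merged with clash detection
  (`merge_registries()`).
* **Interoperable publication** — canonical, byte-stable JSON and
  60-column FASTA (`write_germline_set()`, `export_fasta()`), release
  bumping and release-to-release diffs (`bump_version()`, `diff_sets()`).
* **Genotype application** — classify observed sequences against reference
  sets (`classify_allele()`: documented / partial match with 5'/3'
  truncation side / undocumented) and build personalised germline sets for
  a subject (`personalize()`).
* **Synthetic data** — deterministic generators (`generate_set()`,
  `generate_genotype()`) plus a packaged transcription of the
  community-curated mouse germline-set sizes (`table1_fixture()`,
  `table1_germline_sets()`), so every workflow can be exercised without
  downloads.

A thin command-line wrapper, `exec/germline-kit`, exposes the same
operations (`label propose|apply|rename|resolve|merge`,
`set validate|diff|export-fasta|import-fasta|bump`,
`genotype validate|personalize`, `fixtures synth|genotype|table1`).

## Worked example

Two novel heavy-chain V sequences are submitted to an empty naming domain,
labels are allocated, and a fragment of one of them is later recognised as
a subsequence (which the curator, not the tool, must resolve):

```r
library(germlinekit)

dom <- naming_domain("macaque-IGH", "IGH")
pr <- propose(c(seq1 = "CAGGTGCAGCTGGTGGAGTCTGGGGGAGGC",
                seq2 = "GAGGTGCAGCTGTTGGAGTCTGGGGGAGGC"), dom)
pr[, c("input_id", "proposed_action", "final_action")]
#>   input_id proposed_action final_action
#> 1     seq1             new allocate_new
#> 2     seq2             new allocate_new

res <- apply_proposals(pr, dom, seed = 42, date = "2026-01-15")
res$report
#>   input_id       action identifier         label
#> 1     seq1 allocate_new       B37E IGHV0-B37E*00
#> 2     seq2 allocate_new       BVEY IGHV0-BVEY*00
```

Both sequences received null-valued temporary labels: subgroup `0` and
allele designator `00` say "not yet assigned", and `B37E` / `BVEY` are the
random base32 identifiers. A later submission containing a fragment is
flagged, with no default action:

```r
pr2 <- propose(c(frag = "CTGGTGGAGTCTGGG"), res$domain)
pr2[, c("input_id", "proposed_action", "matched_identifiers", "final_action")]
#>   input_id proposed_action matched_identifiers final_action
#> 1     frag     subsequence                B37E
```

When the allele is eventually characterised, renaming preserves
traceability — the old label resolves to the same record forever:

```r
dom2 <- rename_record(res$domain, "B37E", "IGHV4-QSPG*01")
resolve_label(dom2, "IGHV0-B37E*00")$current_label
#> [1] "IGHV4-QSPG*01"
```

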