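# Builders and independent oracles shared across the test files.

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

tiny_allele <- function(label = "IGHV0-AAAA*00", seqnc = "ACGTACGT",
                        locus = "IGH", sequence_type = "V", ...) {
  allele_description(
    allele_description_id = paste0("ad-", label),
    label = label, sequence_type = sequence_type, locus = locus,
    coding_sequence = seqnc, release_date = "2026-01-01", ...)
}

tiny_set <- function(alleles, locus = "IGH", id = "set-1", version = 1L,
                     species = "Mus musculus") {
  germline_set(
    germline_set_id = id, name = paste("tiny", id), species = species,
    locus = locus, release_version = version, release_date = "2026-01-01",
    allele_descriptions = alleles)
}

# Registry with n synthetic records, distinct identifiers, varied dates.
random_domain <- function(n, locus = "IGH", p_withdrawn = 0) {
  ids <- encode_identifier(sample.int(1048576L, n) - 1L)
  recs <- lapply(seq_len(n), function(i) {
    germlinekit:::registry_record(
      ids[i],
      format_label(null_label_for(locus, "V", ids[i])),
      random_nt(sample(10:60, 1)),
      status = if (stats::runif(1) < p_withdrawn) "withdrawn" else "active",
      allocated = sprintf("2025-%02d-%02d", sample(12, 1), sample(28, 1)),
      aliases = character(), notes = "")
  })
  naming_domain("test-domain", locus, recs)
}

# Independent containment check: enumerate every substring of b of a's
# length and compare, rather than delegating to regex matching.
oracle_contains <- function(b, a) {
  na <- nchar(a); nb <- nchar(b)
  if (na > nb) return(FALSE)
  any(substring(b, 1:(nb - na + 1), na:nb) == a)
}

# Brute-force all-pairs re-derivation of propose()'s verdicts.
oracle_propose <- function(sequences, domain) {
  recs <- domain$records
  ord <- order(vapply(recs, `[[`, "", "allocated"),
               vapply(recs, `[[`, "", "identifier"), method = "radix")
  recs <- recs[ord]
  rs <- vapply(recs, `[[`, "", "sequence")
  rid <- vapply(recs, `[[`, "", "identifier")
  active <- vapply(recs, `[[`, "", "status") == "active"
  lapply(sequences, function(q) {
    eq <- rs == q
    if (any(eq)) return(list(action = "duplicate", matched = rid[eq]))
    sub <- active & nchar(rs) > nchar(q) &
      vapply(rs, function(r) oracle_contains(r, q), NA)
    if (any(sub)) return(list(action = "subsequence", matched = rid[sub]))
    sup <- active & nchar(rs) < nchar(q) &
      vapply(rs, function(r) oracle_contains(q, r), NA)
    if (any(sup)) return(list(action = "supersequence", matched = rid[sup]))
    list(action = "new", matched = character())
  })
}

degap <- function(x) gsub("[.-]", "", x)
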