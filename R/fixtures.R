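#' Synthetic germline data
#'
#' Deterministic generators that emulate the variation structure of real
#' germline sets — allelic point variation on a per-gene base sequence and
#' 5'/3'-truncated (incomplete) variants — without any biological motif
#' content. They exist so that every workflow in the package can be
#' exercised end to end, at any scale, without external downloads. A
#' packaged transcription of the community-curated mouse germline sets
#' (strain, locus type, sequence count) is included, with a companion
#' builder that materialises one synthetic set per table row at the
#' published allele counts.
#'
#' @name fixtures
NULL

#' Specification for a synthetic germline set
#'
#' @param locus Locus of the generated set.
#' @param n_base_alleles Number of genes (base sequences).
#' @param alleles_per_gene Alleles per gene; the first allele of each gene
#'   is the base sequence, the rest are point-mutated variants.
#' @param point_mutation_rate Per-site substitution probability for
#'   variant alleles. The default 0.02 gives a handful of substitutions on
#'   a typical 300 nt V sequence, matching the scale of allelic point
#'   variation.
#' @param length_range Integer (min, max) of base-sequence lengths in
#'   nucleotides; the default 280-320 nt brackets typical V exon lengths.
#' @param truncation_prob Probability that an allele is 5'- or 3'-shortened
#'   and flagged incomplete. The default 0.1 reflects that current sets
#'   contain a minority of incomplete sequences, most often at the 3' end.
#' @param sequence_type Sequence type of the generated alleles.
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(locus = "IGH", n_base_alleles = 10L,
                       alleles_per_gene = 2L, point_mutation_rate = 0.02,
                       length_range = c(280L, 320L), truncation_prob = 0.1,
                       sequence_type = "V", seed = NULL) {
  locus <- match.arg(locus, GK_LOCI)
  sequence_type <- match.arg(sequence_type, GK_SEQUENCE_TYPES)
  stopifnot(n_base_alleles >= 1, alleles_per_gene >= 1,
            point_mutation_rate >= 0, point_mutation_rate <= 1,
            truncation_prob >= 0, truncation_prob <= 1,
            length(length_range) == 2, length_range[1] <= length_range[2],
            length_range[1] >= 1)
  structure(list(locus = locus, n_base_alleles = as.integer(n_base_alleles),
                 alleles_per_gene = as.integer(alleles_per_gene),
                 point_mutation_rate = point_mutation_rate,
                 length_range = as.integer(length_range),
                 truncation_prob = truncation_prob,
                 sequence_type = sequence_type, seed = seed),
            class = "synth_spec")
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_sequence <- function(s, rate, min_changes = 0L) {
  chars <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) < min_changes) {
    hit <- unique(c(hit, sample(length(chars), min_changes)))
  }
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic germline set
#'
#' Base sequences are drawn uniformly over ACGT; variant alleles apply
#' independent per-site substitutions at the specified rate; a fraction of
#' alleles is truncated at a randomly chosen end and flagged
#' `incomplete_5p` / `incomplete_3p`. Generation is bit-reproducible under
#' a fixed seed. Variants that collapse onto an identical sequence (e.g.
#' at mutation rate zero) are deduplicated with a warning.
#'
#' @param spec A [synth_spec()].
#' @param species Species label recorded on the set.
#' @param species_subgroup,species_subgroup_type Optional subgroup fields.
#' @param date ISO 8601 date stamped on the set and its alleles; fixed by
#'   default so generated JSON is byte-stable.
#' @return A [germline_set()] that passes [validate_germline_set()].
#' @export
generate_set <- function(spec, species = "synthetic organism",
                         species_subgroup = NA_character_,
                         species_subgroup_type = "none",
                         date = "2026-01-01") {
  build <- function() {
    ids <- encode_identifier(draw_identifiers(integer(), spec$n_base_alleles))
    ads <- list()
    collapsed <- 0L
    for (gi in seq_len(spec$n_base_alleles)) {
      len <- sample(seq(spec$length_range[1], spec$length_range[2]), 1)
      base <- random_sequence(len)
      gene <- sprintf("SYNG%03d", gi)
      seen <- character()
      for (ai in seq_len(spec$alleles_per_gene)) {
        s <- if (ai == 1) base else {
          mutate_sequence(base, spec$point_mutation_rate)
        }
        inc5 <- FALSE; inc3 <- FALSE
        if (stats::runif(1) < spec$truncation_prob && nchar(s) > 30) {
          k <- sample(1:15, 1)
          if (stats::runif(1) < 0.5) {
            s <- substr(s, k + 1, nchar(s)); inc5 <- TRUE
          } else {
            s <- substr(s, 1, nchar(s) - k); inc3 <- TRUE
          }
        }
        if (s %in% seen) {
          collapsed <- collapsed + 1L
          next
        }
        seen <- c(seen, s)
        ads <- c(ads, list(allele_description(
          allele_description_id = sprintf("synth-%s-%03d-%02d",
                                          spec$locus, gi, ai),
          label = paste0(spec$locus, spec$sequence_type, "0-", ids[gi], "*",
                         sprintf("%02d", ai)),
          sequence_type = spec$sequence_type, locus = spec$locus,
          coding_sequence = s, gene_label = gene,
          incomplete_5p = inc5, incomplete_3p = inc3,
          functionality = "unknown", version = 1L, release_date = date)))
      }
    }
    if (collapsed > 0) {
      warning(sprintf(
        "%d variant(s) identical to another allele of their gene were collapsed",
        collapsed), call. = FALSE)
    }
    germline_set(
      germline_set_id = sprintf("synth-%s-%d", spec$locus,
                                spec$n_base_alleles),
      name = sprintf("Synthetic %s%s set (%d genes)", spec$locus,
                     spec$sequence_type, spec$n_base_alleles),
      species = species, locus = spec$locus,
      species_subgroup = species_subgroup,
      species_subgroup_type = species_subgroup_type,
      release_version = 1L, release_date = date,
      release_description = "Synthetic set for workflow testing",
      allele_descriptions = ads)
  }
  if (is.null(spec$seed)) build() else with_seed(spec$seed, build())
}

#' Sample a synthetic genotype from a germline set
#'
#' Documented calls are sampled without replacement from the set's alleles
#' (avoiding deleted genes); undocumented alleles are point-mutated copies
#' of set alleles, re-drawn until absent from the set; deleted genes are
#' sampled from the set's gene labels. The result validates against the
#' source set.
#'
#' @param set A [germline_set()] with gene labels on its alleles.
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @param n_documented Number of documented calls; default half the
#'   eligible alleles (at least 1).
#' @param n_undocumented Number of undocumented alleles to inject.
#' @param n_deleted Number of genes to record as deleted.
#' @param subject_id Subject identifier.
#' @return A [genotype_set()] with one [genotype()] for the set's locus.
#' @export
generate_genotype <- function(set, seed = NULL, n_documented = NULL,
                              n_undocumented = 0L, n_deleted = 0L,
                              subject_id = "SYN-SUBJ-1") {
  build <- function() {
    ads <- set$allele_descriptions
    genes <- unique(stats::na.omit(vapply(ads, `[[`, "", "gene_label")))
    if (n_deleted > length(genes)) {
      stop(sprintf("cannot delete %d gene(s): the set has %d distinct gene label(s)",
                   n_deleted, length(genes)), call. = FALSE)
    }
    deleted <- if (n_deleted > 0) sample(genes, n_deleted) else character()
    eligible <- which(vapply(ads, function(a) {
      is.na(a$gene_label) || !a$gene_label %in% deleted
    }, NA))
    nd <- if (is.null(n_documented)) max(1L, length(eligible) %/% 2L) else n_documented
    if (nd > length(eligible)) {
      stop(sprintf("cannot document %d allele(s): only %d are eligible",
                   nd, length(eligible)), call. = FALSE)
    }
    picked <- if (length(eligible) == 1) eligible else sample(eligible, nd)
    documented <- data.frame(
      label = vapply(ads[picked], `[[`, "", "label"),
      ref = rep(1L, nd),
      phasing = sample(c(1L, 2L, NA_integer_), nd, replace = TRUE),
      stringsAsFactors = FALSE)
    known <- vapply(ads, `[[`, "", "coding_sequence")
    undoc <- character(n_undocumented)
    i <- 0L
    while (i < n_undocumented) {
      cand <- mutate_sequence(sample(known, 1), 0.02, min_changes = 1L)
      if (!cand %in% known && !cand %in% undoc) {
        i <- i + 1L
        undoc[i] <- cand
      }
    }
    undocumented <- data.frame(
      sequence = undoc,
      phasing = if (n_undocumented) sample(c(1L, 2L, NA_integer_),
                                           n_undocumented, replace = TRUE) else integer(),
      notes = rep("synthetic undocumented allele", n_undocumented),
      stringsAsFactors = FALSE)
    g <- genotype(
      locus = set$locus,
      germline_set_refs = list(list(germline_set_id = set$germline_set_id,
                                    release_version = set$release_version)),
      documented_calls = documented,
      undocumented_alleles = undocumented,
      deleted_genes = deleted)
    genotype_set(paste0("synth-genotype-", subject_id), subject_id, list(g))
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Community-curated mouse germline sets: packaged table
#'
#' A packaged transcription of the published per-strain sequence counts of
#' the community-curated mouse germline sets (20 inbred strains; IGHV,
#' IGKV and IGLV set sizes).
#'
#' @return Data frame with columns `strain`, `type` (e.g. `IGKV`) and
#'   `count`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_mouse_germline_sets.tsv",
                      package = "germlinekit", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer"))
  names(df) <- c("strain", "type", "count")
  df
}

#' Materialise synthetic germline sets at the published mouse counts
#'
#' Builds one synthetic germline set per (strain, locus type) row of
#' [table1_fixture()], each containing exactly the published number of
#' alleles. Sequences are synthetic — the counts are faithful, the
#' nucleotides are not — so the sets exercise set-handling code at
#' realistic scale without shipping third-party sequence data.
#'
#' @param seed Integer seed for sequence generation.
#' @return Named list of [germline_set()] objects, names `"<strain> <type>"`.
#' @export
table1_germline_sets <- function(seed = 1L) {
  tab <- table1_fixture()
  with_seed(seed, {
    sets <- lapply(seq_len(nrow(tab)), function(i) {
      locus <- substr(tab$type[i], 1, 3)
      stype <- substr(tab$type[i], 4, 4)
      spec <- synth_spec(locus = locus, n_base_alleles = tab$count[i],
                         alleles_per_gene = 1L, point_mutation_rate = 0,
                         truncation_prob = 0, sequence_type = stype,
                         seed = NULL)
      s <- generate_set(spec, species = "Mus musculus",
                        species_subgroup = tab$strain[i],
                        species_subgroup_type = "inbred_strain")
      s$germline_set_id <- sprintf("mouse-%s-%s",
                                   gsub("[^A-Za-z0-9]+", "_", tab$strain[i]),
                                   tab$type[i])
      s$name <- sprintf("%s %s germline set (synthetic sequences)",
                        tab$strain[i], tab$type[i])
      s
    })
    names(sets) <- paste(tab$strain, tab$type)
    sets
  })
}
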