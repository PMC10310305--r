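#' Domain model for germline sets and genotypes
#'
#' The data model centres on three objects. An [allele_description()] records
#' a single germline V, D or J allele: its label, core (and, for V alleles,
#' gapped) sequence, framework/CDR delineations, J splice information,
#' supporting evidence, aliases and completeness flags. A [germline_set()]
#' is a versioned, attributed collection of allele descriptions for one
#' locus of one species or species subgroup. A [genotype()] records, with
#' reference to one or more germline sets, the alleles carried by a single
#' subject at one locus, including previously undocumented alleles and
#' confirmed gene deletions; a [genotype_set()] groups the genotypes of one
#' subject across loci.
#'
#' Validation never throws on bad data: the `validate_*` functions return a
#' data frame of violations (field path, severity, message), empty when all
#' invariants hold. Severity `"error"` marks an invariant failure;
#' `"warning"` and `"info"` rows are advisory.
#'
#' @name germline-model
NULL

GK_IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")
GK_FUNCTIONALITY <- c("functional", "ORF", "pseudogene", "unknown")
GK_SUBGROUP_TYPES <- c("locational", "breed", "inbred_strain",
                       "outbred_strain", "none")
GK_SCHEMES <- c("IMGT", "Kabat", "Chothia", "custom")
GK_REGIONS <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
GK_EVIDENCE_TYPES <- c("genomic", "inferred", "rearranged")

violation <- function(field, message, severity = "error") {
  data.frame(field = field, severity = severity, message = message,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(field = character(), severity = character(),
             message = character(), stringsAsFactors = FALSE)
}

bind_violations <- function(...) {
  out <- do.call(rbind, Filter(Negate(is.null), list(...)))
  if (is.null(out)) no_violations() else out
}

#' Does a violation table contain errors?
#'
#' @param v A violation data frame from one of the `validate_*` functions.
#' @return `TRUE` when no `"error"`-severity row is present (warnings and
#'   informational notes are allowed).
#' @export
is_clean <- function(v) {
  !any(v$severity == "error")
}

normalise_sequence <- function(x) {
  gsub("[-.[:space:]]", "", toupper(x))
}

#' Supporting evidence for an allele
#'
#' @param evidence_type One of `genomic`, `inferred`, `rearranged`.
#' @param repository Repository name, e.g. a sequence archive.
#' @param accession Accession within the repository.
#' @param notes Free-form notes, including any coding or non-coding
#'   elements observed alongside the core sequence.
#' @return An object of class `supporting_evidence`.
#' @export
supporting_evidence <- function(evidence_type, repository = "",
                                accession = "", notes = "") {
  evidence_type <- match.arg(evidence_type, GK_EVIDENCE_TYPES)
  structure(list(evidence_type = evidence_type, repository = repository,
                 accession = accession, notes = notes),
            class = "supporting_evidence")
}

#' Framework / CDR delineation of a V sequence
#'
#' Region coordinates are 1-based inclusive positions on the ungapped
#' coding sequence.
#'
#' @param scheme Delineation scheme: `IMGT`, `Kabat`, `Chothia` or `custom`.
#' @param regions Data frame with columns `region_name` (one of FR1, CDR1,
#'   FR2, CDR2, FR3, CDR3, FR4), `start`, `end`.
#' @return An object of class `delineation`.
#' @export
delineation <- function(scheme, regions) {
  scheme <- match.arg(scheme, GK_SCHEMES)
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  stopifnot(all(c("region_name", "start", "end") %in% names(regions)))
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  structure(list(scheme = scheme,
                 regions = regions[, c("region_name", "start", "end")]),
            class = "delineation")
}

#' Describe a single germline V, D or J allele
#'
#' @param allele_description_id Opaque unique identifier for this record.
#' @param label The allele's label (temporary or legacy).
#' @param sequence_type `V`, `D` or `J`.
#' @param locus One of `IGH`, `IGK`, `IGL`, `TRA`, `TRB`, `TRG`, `TRD`.
#' @param coding_sequence Ungapped nucleotide sequence (upper-cased on
#'   construction).
#' @param gapped_sequence Optional gap-aligned sequence (V alleles only);
#'   gap characters are `"."`, with `"-"` accepted and normalised on input.
#'   Removing gaps must yield `coding_sequence` exactly.
#' @param aliases Previous or synonym labels, oldest first.
#' @param delineations List of [delineation()] objects.
#' @param j_codon_frame Codon frame orientation of a J allele (1, 2 or 3).
#' @param j_donor_splice 1-based position of the donor splice site on the
#'   coding sequence (J alleles only).
#' @param gene_label Label of the gene this allele maps to; `NA` while the
#'   allele is unmapped.
#' @param functionality `functional`, `ORF`, `pseudogene` or `unknown`.
#' @param incomplete_5p,incomplete_3p Is the sequence known to be truncated
#'   at the 5' or 3' end?
#' @param evidence List of [supporting_evidence()] objects.
#' @param version Record version, starting at 1.
#' @param release_date ISO 8601 date string.
#' @return An object of class `allele_description`.
#' @export
allele_description <- function(allele_description_id, label, sequence_type,
                               locus, coding_sequence,
                               gapped_sequence = NA_character_,
                               aliases = character(),
                               delineations = list(),
                               j_codon_frame = NA_integer_,
                               j_donor_splice = NA_integer_,
                               gene_label = NA_character_,
                               functionality = "unknown",
                               incomplete_5p = FALSE, incomplete_3p = FALSE,
                               evidence = list(),
                               version = 1L,
                               release_date = format(Sys.Date())) {
  coding_sequence <- toupper(coding_sequence)
  if (!is.na(gapped_sequence)) {
    gapped_sequence <- chartr("-", ".", toupper(gapped_sequence))
  }
  structure(
    list(allele_description_id = as.character(allele_description_id),
         label = as.character(label),
         sequence_type = as.character(sequence_type),
         locus = as.character(locus),
         coding_sequence = coding_sequence,
         gapped_sequence = gapped_sequence,
         aliases = as.character(aliases),
         delineations = delineations,
         j_codon_frame = as.integer(j_codon_frame),
         j_donor_splice = as.integer(j_donor_splice),
         gene_label = as.character(gene_label),
         functionality = as.character(functionality),
         incomplete_5p = isTRUE(incomplete_5p),
         incomplete_3p = isTRUE(incomplete_3p),
         evidence = evidence,
         version = as.integer(version),
         release_date = as.character(release_date)),
    class = "allele_description")
}

#' @export
print.allele_description <- function(x, ...) {
  cat(sprintf("<allele_description> %s (%s%s, %d nt%s)\n",
              x$label, x$locus, x$sequence_type, nchar(x$coding_sequence),
              if (x$incomplete_5p || x$incomplete_3p) ", incomplete" else ""))
  invisible(x)
}

#' A versioned germline set for one locus
#'
#' @param germline_set_id Opaque unique identifier.
#' @param name Human-readable set name.
#' @param species Species label, or a list `list(label=, taxon_id=)`.
#' @param locus One of `IGH`, `IGK`, `IGL`, `TRA`, `TRB`, `TRG`, `TRD`.
#' @param species_subgroup Optional subgroup (e.g. a strain) the set is
#'   restricted to.
#' @param species_subgroup_type Controlled vocabulary: `locational`,
#'   `breed`, `inbred_strain`, `outbred_strain` or `none`.
#' @param release_version Release number, starting at 1.
#' @param release_date ISO 8601 date string.
#' @param release_description Free-text description of the release.
#' @param license Data licence; defaults to `"CC0 1.0"`.
#' @param acknowledgements List of contributors, each a list with `name`,
#'   `institution` and `orcid_id`.
#' @param allele_descriptions List of [allele_description()] objects, all of
#'   the set's locus.
#' @return An object of class `germline_set`.
#' @export
germline_set <- function(germline_set_id, name, species, locus,
                         species_subgroup = NA_character_,
                         species_subgroup_type = "none",
                         release_version = 1L,
                         release_date = format(Sys.Date()),
                         release_description = "",
                         license = "CC0 1.0",
                         acknowledgements = list(),
                         allele_descriptions = list()) {
  if (is.character(species)) species <- list(label = species, taxon_id = NA_integer_)
  if (length(allele_descriptions) > 1) {
    # kept in label order so serialisation is canonical by construction
    labs <- vapply(allele_descriptions, `[[`, "", "label")
    allele_descriptions <- allele_descriptions[order(labs, method = "radix")]
  }
  structure(
    list(germline_set_id = as.character(germline_set_id),
         name = as.character(name),
         species = species,
         species_subgroup = as.character(species_subgroup),
         species_subgroup_type = as.character(species_subgroup_type),
         locus = as.character(locus),
         release_version = as.integer(release_version),
         release_date = as.character(release_date),
         release_description = as.character(release_description),
         license = as.character(license),
         acknowledgements = acknowledgements,
         allele_descriptions = allele_descriptions),
    class = "germline_set")
}

#' @export
print.germline_set <- function(x, ...) {
  cat(sprintf("<germline_set> %s: %s %s, release %d (%s)\n",
              x$germline_set_id, x$species$label, x$locus,
              x$release_version, x$release_date))
  cat(sprintf("  %d allele description(s)\n", length(x$allele_descriptions)))
  invisible(x)
}

set_labels <- function(set) {
  vapply(set$allele_descriptions, `[[`, "", "label")
}

#' Find an allele in a germline set by label or alias
#'
#' Current labels are searched before aliases.
#'
#' @param set A [germline_set()].
#' @param label Label or alias to look up.
#' @return The matching [allele_description()], or `NULL` when absent.
#' @export
find_allele <- function(set, label) {
  for (ad in set$allele_descriptions) if (ad$label == label) return(ad)
  for (ad in set$allele_descriptions) if (label %in% ad$aliases) return(ad)
  NULL
}

#' Per-subject allele calls at one locus
#'
#' @param locus One of `IGH`, `IGK`, `IGL`, `TRA`, `TRB`, `TRG`, `TRD`.
#' @param germline_set_refs List of `list(germline_set_id=, release_version=)`
#'   identifying the sets the calls refer to.
#' @param documented_calls Data frame with columns `label` (resolvable in a
#'   referenced set, directly or via alias), `ref` (1-based index into
#'   `germline_set_refs`) and `phasing` (chromosome index, `NA` when
#'   unphased).
#' @param undocumented_alleles Data frame with columns `sequence`, `phasing`,
#'   `notes` for alleles observed in this subject that cannot be found in
#'   the referenced sets.
#' @param deleted_genes Gene labels confirmed deleted in this subject.
#' @return An object of class `genotype`.
#' @export
genotype <- function(locus, germline_set_refs,
                     documented_calls = data.frame(label = character(),
                                                   ref = integer(),
                                                   phasing = integer()),
                     undocumented_alleles = data.frame(sequence = character(),
                                                       phasing = integer(),
                                                       notes = character()),
                     deleted_genes = character()) {
  documented_calls <- as.data.frame(documented_calls, stringsAsFactors = FALSE)
  undocumented_alleles <- as.data.frame(undocumented_alleles,
                                        stringsAsFactors = FALSE)
  if (nrow(undocumented_alleles)) {
    undocumented_alleles$sequence <- normalise_sequence(undocumented_alleles$sequence)
  }
  structure(
    list(locus = as.character(locus),
         germline_set_refs = germline_set_refs,
         documented_calls = documented_calls,
         undocumented_alleles = undocumented_alleles,
         deleted_genes = as.character(deleted_genes)),
    class = "genotype")
}

#' A subject's genotypes across loci
#'
#' @param genotype_set_id Opaque identifier.
#' @param subject_id Identifier of the subject.
#' @param genotypes List of [genotype()] objects, at most one per locus.
#' @return An object of class `genotype_set`.
#' @export
genotype_set <- function(genotype_set_id, subject_id, genotypes = list()) {
  structure(
    list(genotype_set_id = as.character(genotype_set_id),
         subject_id = as.character(subject_id),
         genotypes = genotypes),
    class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("<genotype_set> %s, subject %s: %d locus genotype(s)\n",
              x$genotype_set_id, x$subject_id, length(x$genotypes)))
  invisible(x)
}

validate_delineation <- function(d, seq_len, path) {
  v <- no_violations()
  r <- d$regions
  if (!nrow(r)) return(v)
  bad_name <- !r$region_name %in% GK_REGIONS
  if (any(bad_name)) {
    v <- bind_violations(v, violation(
      paste0(path, ".regions"),
      sprintf("unknown region name(s): %s",
              paste(r$region_name[bad_name], collapse = ", "))))
  }
  if (any(r$start > r$end)) {
    v <- bind_violations(v, violation(
      paste0(path, ".regions"), "region start exceeds end"))
  }
  if (any(r$start < 1 | r$end > seq_len)) {
    v <- bind_violations(v, violation(
      paste0(path, ".regions"),
      sprintf("region coordinates outside [1, %d]", seq_len)))
  }
  if (nrow(r) > 1) {
    if (is.unsorted(r$start, strictly = TRUE)) {
      v <- bind_violations(v, violation(
        paste0(path, ".regions"), "region starts must be strictly ascending"))
    } else if (any(r$start[-1] <= r$end[-nrow(r)])) {
      v <- bind_violations(v, violation(
        paste0(path, ".regions"), "regions must not overlap"))
    }
  }
  v
}

#' Validate an allele description
#'
#' Checks every structural invariant of the record: sequence alphabet,
#' gapped/ungapped consistency, J-specific fields, alias uniqueness,
#' delineation coordinates and enum membership. Non-ACGT IUPAC ambiguity
#' codes are accepted but flagged at warning severity, since registry
#' matching is literal.
#'
#' @param desc An [allele_description()].
#' @return A violation data frame; empty when all invariants hold.
#' @export
validate_allele_description <- function(desc) {
  v <- no_violations()
  n <- nchar(desc$coding_sequence)
  if (is.na(desc$coding_sequence) || n == 0) {
    v <- bind_violations(v, violation("coding_sequence",
                                      "coding_sequence must be non-empty"))
    return(v)
  }
  chars <- unique(strsplit(desc$coding_sequence, "")[[1]])
  if (!all(chars %in% GK_IUPAC)) {
    v <- bind_violations(v, violation(
      "coding_sequence",
      sprintf("characters outside the IUPAC nucleotide alphabet: %s",
              paste(setdiff(chars, GK_IUPAC), collapse = ""))))
  } else if (!all(chars %in% c("A", "C", "G", "T"))) {
    v <- bind_violations(v, violation(
      "coding_sequence",
      "IUPAC ambiguity codes present; registry sequence matching is literal",
      severity = "warning"))
  }
  if (!desc$sequence_type %in% GK_SEQUENCE_TYPES) {
    v <- bind_violations(v, violation(
      "sequence_type", sprintf("unknown sequence_type '%s'", desc$sequence_type)))
  }
  if (!desc$locus %in% GK_LOCI) {
    v <- bind_violations(v, violation(
      "locus", sprintf("unknown locus '%s'", desc$locus)))
  }
  if (!desc$functionality %in% GK_FUNCTIONALITY) {
    v <- bind_violations(v, violation(
      "functionality", sprintf("unknown functionality '%s'", desc$functionality)))
  }
  if (!is.na(desc$gapped_sequence)) {
    if (desc$sequence_type != "V") {
      v <- bind_violations(v, violation(
        "gapped_sequence", "gapped_sequence is only defined for V alleles"))
    }
    if (normalise_sequence(desc$gapped_sequence) != desc$coding_sequence) {
      v <- bind_violations(v, violation(
        "gapped_sequence",
        "removing gap characters from gapped_sequence must yield coding_sequence"))
    }
  }
  if (!is.na(desc$j_codon_frame) || !is.na(desc$j_donor_splice)) {
    if (desc$sequence_type != "J") {
      v <- bind_violations(v, violation(
        if (is.na(desc$j_codon_frame)) "j_donor_splice" else "j_codon_frame",
        "J splice fields are only defined for J alleles"))
    }
    if (!is.na(desc$j_codon_frame) && !desc$j_codon_frame %in% 1:3) {
      v <- bind_violations(v, violation(
        "j_codon_frame", "j_codon_frame must be 1, 2 or 3"))
    }
    if (!is.na(desc$j_donor_splice) &&
        (desc$j_donor_splice < 1 || desc$j_donor_splice > n)) {
      v <- bind_violations(v, violation(
        "j_donor_splice",
        sprintf("j_donor_splice %d outside [1, %d]", desc$j_donor_splice, n)))
    }
  }
  if (anyDuplicated(desc$aliases)) {
    v <- bind_violations(v, violation("aliases", "aliases must be pairwise distinct"))
  }
  if (desc$label %in% desc$aliases) {
    v <- bind_violations(v, violation("aliases",
                                      "an alias must not equal the current label"))
  }
  if (length(desc$delineations)) {
    for (i in seq_along(desc$delineations)) {
      v <- bind_violations(v, validate_delineation(
        desc$delineations[[i]], n, sprintf("delineations[%d]", i)))
    }
  }
  if (is.na(desc$version) || desc$version < 1) {
    v <- bind_violations(v, violation("version", "version must be >= 1"))
  }
  v[order(v$field), , drop = FALSE]
}

#' Validate a germline set
#'
#' Aggregates per-allele violations (field paths prefixed with the allele's
#' label) and adds set-level checks: all alleles share the set's locus;
#' labels and record identifiers are unique; no alias of one allele collides
#' with the label of another. An empty set is valid but flagged with an
#' informational note. Output ordering is deterministic: set-level rows
#' first, then per-allele rows by allele label and field path.
#'
#' @param set A [germline_set()].
#' @return A violation data frame; empty (or info-only) when valid.
#' @export
validate_germline_set <- function(set) {
  v <- no_violations()
  if (!set$locus %in% GK_LOCI) {
    v <- bind_violations(v, violation("locus",
                                      sprintf("unknown locus '%s'", set$locus)))
  }
  if (!set$species_subgroup_type %in% GK_SUBGROUP_TYPES) {
    v <- bind_violations(v, violation(
      "species_subgroup_type",
      sprintf("unknown species_subgroup_type '%s'", set$species_subgroup_type)))
  }
  if (is.na(set$release_version) || set$release_version < 1) {
    v <- bind_violations(v, violation("release_version",
                                      "release_version must be >= 1"))
  }
  ads <- set$allele_descriptions
  if (!length(ads)) {
    v <- bind_violations(v, violation(
      "allele_descriptions", "set contains no allele descriptions",
      severity = "info"))
    return(v)
  }
  labels <- vapply(ads, `[[`, "", "label")
  ids <- vapply(ads, `[[`, "", "allele_description_id")
  loci <- vapply(ads, `[[`, "", "locus")
  dup <- unique(labels[duplicated(labels)])
  for (d in dup) {
    v <- bind_violations(v, violation(
      "allele_descriptions",
      sprintf("duplicate label '%s' (%d records)", d, sum(labels == d))))
  }
  dup_id <- unique(ids[duplicated(ids)])
  for (d in dup_id) {
    v <- bind_violations(v, violation(
      "allele_descriptions",
      sprintf("duplicate allele_description_id '%s'", d)))
  }
  mism <- which(loci != set$locus)
  for (i in mism) {
    v <- bind_violations(v, violation(
      sprintf("allele_descriptions[%s].locus", labels[i]),
      sprintf("allele locus '%s' does not match set locus '%s'",
              loci[i], set$locus)))
  }
  all_aliases <- lapply(ads, `[[`, "aliases")
  for (i in seq_along(ads)) {
    clash <- intersect(all_aliases[[i]], labels[-i])
    for (cl in clash) {
      v <- bind_violations(v, violation(
        sprintf("allele_descriptions[%s].aliases", labels[i]),
        sprintf("alias '%s' collides with the label of another allele", cl)))
    }
  }
  per <- lapply(order(labels), function(i) {
    vi <- validate_allele_description(ads[[i]])
    if (nrow(vi)) {
      vi$field <- sprintf("allele_descriptions[%s].%s", labels[i], vi$field)
    }
    vi
  })
  bind_violations(v, do.call(bind_violations, per))
}

match_set_ref <- function(sets, ref) {
  for (s in sets) {
    if (s$germline_set_id == ref$germline_set_id &&
        s$release_version == ref$release_version) {
      return(s)
    }
  }
  NULL
}

#' Validate a subject's genotypes against their referenced germline sets
#'
#' Every documented call must resolve (directly or via alias) in its
#' referenced set; a sequence recorded as undocumented must not equal any
#' coding sequence in the referenced sets; no documented call may sit on a
#' gene recorded as deleted; each locus appears at most once.
#'
#' @param gset A [genotype_set()].
#' @param sets List of [germline_set()] objects covering every
#'   `germline_set_ref`; a missing referenced set is an error (the check
#'   cannot proceed without it).
#' @return A violation data frame; empty when the genotypes are consistent.
#' @export
validate_genotype <- function(gset, sets) {
  if (inherits(sets, "germline_set")) sets <- list(sets)
  v <- no_violations()
  loci <- vapply(gset$genotypes, `[[`, "", "locus")
  dup <- unique(loci[duplicated(loci)])
  for (d in dup) {
    v <- bind_violations(v, violation(
      "genotypes", sprintf("more than one genotype for locus %s", d)))
  }
  for (g in gset$genotypes) {
    path <- sprintf("genotypes[%s]", g$locus)
    refsets <- vector("list", length(g$germline_set_refs))
    for (i in seq_along(g$germline_set_refs)) {
      ref <- g$germline_set_refs[[i]]
      s <- match_set_ref(sets, ref)
      if (is.null(s)) {
        stop(sprintf(
          "referenced germline set (%s, release %s) was not supplied",
          ref$germline_set_id, ref$release_version), call. = FALSE)
      }
      refsets[[i]] <- s
    }
    dc <- g$documented_calls
    if (nrow(dc)) {
      for (i in seq_len(nrow(dc))) {
        ref_idx <- dc$ref[i]
        if (is.na(ref_idx) || ref_idx < 1 || ref_idx > length(refsets)) {
          v <- bind_violations(v, violation(
            sprintf("%s.documented_calls[%s]", path, dc$label[i]),
            sprintf("ref index %s does not identify a referenced set", ref_idx)))
          next
        }
        ad <- find_allele(refsets[[ref_idx]], dc$label[i])
        if (is.null(ad)) {
          v <- bind_violations(v, violation(
            sprintf("%s.documented_calls[%s]", path, dc$label[i]),
            sprintf("label '%s' cannot be found (directly or via alias) in set %s",
                    dc$label[i], refsets[[ref_idx]]$germline_set_id)))
        } else if (!is.na(ad$gene_label) && ad$gene_label %in% g$deleted_genes) {
          v <- bind_violations(v, violation(
            sprintf("%s.documented_calls[%s]", path, dc$label[i]),
            sprintf("documented call on gene '%s' which is recorded as deleted",
                    ad$gene_label)))
        }
      }
    }
    known <- unlist(lapply(refsets, function(s) {
      vapply(s$allele_descriptions, `[[`, "", "coding_sequence")
    }))
    ua <- g$undocumented_alleles
    if (nrow(ua)) {
      hit <- ua$sequence %in% known
      for (i in which(hit)) {
        v <- bind_violations(v, violation(
          sprintf("%s.undocumented_alleles[%d]", path, i),
          "sequence recorded as undocumented is identical to a documented allele in a referenced set"))
      }
    }
  }
  v
}
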