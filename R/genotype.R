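#' Genotype application: classification and personalised germline sets
#'
#' A subject's genotype lists the alleles inferred at one locus with
#' reference to published germline sets. Observed sequences are classified
#' against those sets — exact match (documented), partial containment
#' (which often reflects 5'/3' incompleteness of either the observation or
#' the reference, since AIRR-seq inference is frequently inconclusive for
#' the terminal nucleotides), or undocumented. A personalised germline set
#' containing exactly the alleles carried by the subject can then be built
#' for downstream annotation.
#'
#' @name genotype-application
NULL

GK_GS_KEYS <- c("schema_version", "genotype_set_id", "subject_id", "genotypes")

#' Classify an observed allele sequence against germline sets
#'
#' Exact equality with a set allele's coding sequence gives verdict
#' `documented`. A strict substring of one or more set alleles — or a
#' strict superstring of a set allele flagged incomplete — gives
#' `partial_match`, with the truncation side derived from the match offset:
#' a query matching a suffix of the reference is missing its 5' end, a
#' query matching a prefix is missing its 3' end. Anything else is
#' `undocumented`. Partial matches are never auto-promoted to documented;
#' whether a nested sequence represents the same allele is a curatorial
#' decision.
#'
#' @param sequence Observed nucleotide sequence (normalised internally).
#' @param sets A [germline_set()] or list of them.
#' @return An object of class `allele_classification`: list with `sequence`,
#'   `verdict`, `matches` (data frame of `germline_set_id`, `label`) and
#'   `truncation` (`"5p"`, `"3p"`, `"both"` or `NA`).
#' @export
classify_allele <- function(sequence, sets) {
  if (inherits(sets, "germline_set")) sets <- list(sets)
  if (!length(sets)) stop("at least one germline set must be supplied",
                          call. = FALSE)
  q <- normalise_sequence(sequence)
  if (!nzchar(q)) stop("empty query sequence", call. = FALSE)
  empty_matches <- data.frame(germline_set_id = character(),
                              label = character(), stringsAsFactors = FALSE)
  result <- function(verdict, matches = empty_matches,
                     truncation = NA_character_) {
    structure(list(sequence = q, verdict = verdict, matches = matches,
                   truncation = truncation),
              class = "allele_classification")
  }
  exact <- empty_matches
  partial <- empty_matches
  sides <- character()
  for (s in sets) {
    for (ad in s$allele_descriptions) {
      ref <- ad$coding_sequence
      if (q == ref) {
        exact <- rbind(exact, data.frame(
          germline_set_id = s$germline_set_id, label = ad$label,
          stringsAsFactors = FALSE))
      } else if (nchar(q) < nchar(ref)) {
        pos <- regexpr(q, ref, fixed = TRUE)
        if (pos > 0) {
          partial <- rbind(partial, data.frame(
            germline_set_id = s$germline_set_id, label = ad$label,
            stringsAsFactors = FALSE))
          at_start <- pos == 1
          at_end <- (pos + nchar(q) - 1L) == nchar(ref)
          sides <- c(sides,
                     if (at_start && !at_end) "3p"
                     else if (at_end && !at_start) "5p"
                     else "both")
        }
      } else if ((ad$incomplete_5p || ad$incomplete_3p) &&
                 grepl(ref, q, fixed = TRUE)) {
        partial <- rbind(partial, data.frame(
          germline_set_id = s$germline_set_id, label = ad$label,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(exact)) return(result("documented", exact))
  if (nrow(partial)) {
    trunc <- if (!length(sides)) NA_character_
      else if (all(sides == "3p")) "3p"
      else if (all(sides == "5p")) "5p"
      else "both"
    return(result("partial_match", partial, trunc))
  }
  result("undocumented")
}

#' @export
print.allele_classification <- function(x, ...) {
  cat(sprintf("<allele_classification> %s (%d nt)%s\n", x$verdict,
              nchar(x$sequence),
              if (!is.na(x$truncation)) paste0(", truncation ", x$truncation) else ""))
  if (nrow(x$matches)) {
    for (i in seq_len(nrow(x$matches))) {
      cat(sprintf("  %s :: %s\n", x$matches$germline_set_id[i], x$matches$label[i]))
    }
  }
  invisible(x)
}

#' Build a personalised germline set for one subject
#'
#' The output set contains exactly one allele description per documented
#' call (copied from the referenced set, resolving aliases) and one per
#' undocumented allele. Undocumented alleles receive a fresh null-valued
#' temporary label when a naming-domain registry is supplied (the updated
#' registry is attached as the `naming_domain` attribute of the result);
#' without a registry they carry placeholder labels `UND-<n>`. No allele of
#' a gene recorded as deleted appears, and phasing values are propagated
#' into evidence notes.
#'
#' @param sets A [germline_set()] or list of them, covering the genotype's
#'   `germline_set_refs`.
#' @param g A [genotype()].
#' @param subject_id Subject identifier, recorded in the set's name.
#' @param registry Optional [naming_domain()] used to allocate temporary
#'   labels for undocumented alleles.
#' @param sequence_type Sequence type assumed for undocumented alleles when
#'   deriving temporary labels.
#' @param seed Optional allocation seed.
#' @param release_date ISO 8601 date stamped on the personalised set.
#' @return A [germline_set()] (release 1) named for the subject.
#' @export
personalize <- function(sets, g, subject_id = "subject", registry = NULL,
                        sequence_type = "V", seed = NULL,
                        release_date = format(Sys.Date())) {
  if (inherits(sets, "germline_set")) sets <- list(sets)
  gs <- genotype_set("tmp", subject_id, list(g))
  v <- validate_genotype(gs, sets)
  if (!is_clean(v)) {
    stop(paste0("genotype does not validate against the referenced sets:\n  ",
                paste(v$message[v$severity == "error"], collapse = "\n  ")),
         call. = FALSE)
  }
  refsets <- lapply(g$germline_set_refs, function(ref) match_set_ref(sets, ref))
  ads <- list()
  dc <- g$documented_calls
  if (nrow(dc)) {
    for (i in seq_len(nrow(dc))) {
      ad <- find_allele(refsets[[dc$ref[i]]], dc$label[i])
      if (!is.na(ad$gene_label) && ad$gene_label %in% g$deleted_genes) next
      if (!is.null(dc$phasing) && !is.na(dc$phasing[i])) {
        ad$evidence <- c(ad$evidence, list(supporting_evidence(
          "inferred",
          notes = sprintf("phasing: chromosome %d in subject %s",
                          dc$phasing[i], subject_id))))
      }
      ads <- c(ads, list(ad))
    }
  }
  ua <- g$undocumented_alleles
  if (nrow(ua)) {
    labels <- if (!is.null(registry)) {
      ids <- allocate_identifier(registry, n = nrow(ua), seed = seed)
      for (i in seq_len(nrow(ua))) {
        registry$records <- c(registry$records, list(registry_record(
          ids[i],
          format_label(null_label_for(g$locus, sequence_type, ids[i])),
          ua$sequence[i], allocated = release_date,
          notes = sprintf("undocumented allele of subject %s", subject_id))))
      }
      vapply(registry$records[seq(length(registry$records) - nrow(ua) + 1,
                                  length(registry$records))],
             `[[`, "", "current_label")
    } else {
      sprintf("UND-%d", seq_len(nrow(ua)))
    }
    for (i in seq_len(nrow(ua))) {
      notes <- character()
      if (!is.null(ua$phasing) && !is.na(ua$phasing[i])) {
        notes <- c(notes, sprintf("phasing: chromosome %d", ua$phasing[i]))
      }
      if (!is.null(ua$notes) && nzchar(ua$notes[i])) {
        notes <- c(notes, ua$notes[i])
      }
      ads <- c(ads, list(allele_description(
        allele_description_id = sprintf("personal-%s-undoc-%d", subject_id, i),
        label = labels[i], sequence_type = sequence_type, locus = g$locus,
        coding_sequence = ua$sequence[i],
        evidence = list(supporting_evidence(
          "inferred",
          notes = paste(c(sprintf("undocumented in subject %s", subject_id),
                          notes), collapse = "; "))),
        version = 1L, release_date = release_date)))
    }
  }
  first_ref <- refsets[[1]]
  out <- germline_set(
    germline_set_id = sprintf("personal-%s-%s", subject_id, g$locus),
    name = sprintf("Personalised %s germline set for subject %s",
                   g$locus, subject_id),
    species = first_ref$species,
    locus = g$locus,
    species_subgroup = first_ref$species_subgroup,
    species_subgroup_type = first_ref$species_subgroup_type,
    release_version = 1L,
    release_date = release_date,
    release_description = sprintf("Personalised set derived from genotype of subject %s",
                                  subject_id),
    allele_descriptions = ads)
  if (!is.null(registry)) attr(out, "naming_domain") <- registry
  out
}

genotype_to_json_list <- function(g) {
  list(
    locus = g$locus,
    germline_set_refs = lapply(g$germline_set_refs, function(r) {
      list(germline_set_id = r$germline_set_id,
           release_version = as.integer(r$release_version))
    }),
    documented_calls = lapply(seq_len(nrow(g$documented_calls)), function(i) {
      list(label = g$documented_calls$label[i],
           ref = as.integer(g$documented_calls$ref[i]),
           phasing = as.integer(g$documented_calls$phasing[i]))
    }),
    undocumented_alleles = lapply(seq_len(nrow(g$undocumented_alleles)), function(i) {
      list(sequence = g$undocumented_alleles$sequence[i],
           phasing = as.integer(g$undocumented_alleles$phasing[i]),
           notes = g$undocumented_alleles$notes[i])
    }),
    deleted_genes = g$deleted_genes)
}

#' Write a genotype set as canonical JSON
#'
#' Same canonical contract as [write_germline_set()]: fixed key order,
#' 2-space indent, LF, byte-stable on repeated writes.
#'
#' @param gset A [genotype_set()].
#' @return A single JSON string.
#' @export
write_genotype_set <- function(gset) {
  obj <- list(
    schema_version = GK_SCHEMA_VERSION,
    genotype_set_id = gset$genotype_set_id,
    subject_id = gset$subject_id,
    genotypes = lapply(gset$genotypes, genotype_to_json_list))
  txt <- jsonlite::toJSON(obj, pretty = 2, auto_unbox = TRUE, na = "null",
                          digits = NA)
  paste0(as.character(txt), "\n")
}

#' Read a genotype set from JSON
#'
#' @param json JSON text, or the path of a JSON file.
#' @return A [genotype_set()].
#' @export
read_genotype_set <- function(json) {
  txt <- slurp_text(json)
  x <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (is.null(x$schema_version)) {
    stop("validation error at $.schema_version: required field missing",
         call. = FALSE)
  }
  if (!identical(x$schema_version, GK_SCHEMA_VERSION)) {
    stop(sprintf("unknown schema_version '%s'", x$schema_version), call. = FALSE)
  }
  for (f in c("genotype_set_id", "subject_id")) require_field(x, f, "$")
  genotypes <- lapply(seq_along(x$genotypes), function(i) {
    gx <- x$genotypes[[i]]
    path <- sprintf("$.genotypes[%d]", i)
    require_field(gx, "locus", path)
    dc <- gx$documented_calls
    documented <- data.frame(
      label = vapply(dc, function(d) as.character(d$label), ""),
      ref = vapply(dc, function(d) as.integer(d$ref), 1L),
      phasing = vapply(dc, function(d) json_scalar(d$phasing, NA_integer_), 1L),
      stringsAsFactors = FALSE)
    ua <- gx$undocumented_alleles
    undocumented <- data.frame(
      sequence = vapply(ua, function(u) as.character(u$sequence), ""),
      phasing = vapply(ua, function(u) json_scalar(u$phasing, NA_integer_), 1L),
      notes = vapply(ua, function(u) json_scalar(u$notes, ""), ""),
      stringsAsFactors = FALSE)
    genotype(
      locus = gx$locus,
      germline_set_refs = lapply(gx$germline_set_refs, function(r) {
        list(germline_set_id = as.character(r$germline_set_id),
             release_version = as.integer(r$release_version))
      }),
      documented_calls = documented,
      undocumented_alleles = undocumented,
      deleted_genes = as.character(unlist(gx$deleted_genes)))
  })
  genotype_set(x$genotype_set_id, x$subject_id, genotypes)
}
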