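#' Germline-set serialisation, versioning and release diffing
#'
#' Germline sets are published in a schema-compliant JSON form and in FASTA.
#' The JSON writer is canonical — fixed key order, 2-space indent, LF line
#' endings, allele descriptions sorted by label — so that two releases of a
#' set can be compared byte-for-byte under version control, and
#' `write(read(text))` is canonical even when `text` was not. Releases are
#' identified by `(germline_set_id, release_version)`; [diff_sets()]
#' identifies the additions, removals and modifications between two
#' releases, following labels through renames via aliases.
#'
#' @name setio
NULL

GK_SCHEMA_VERSION <- "germline-kit-1.0"

GK_SET_KEYS <- c("schema_version", "germline_set_id", "name", "species",
                 "species_subgroup", "species_subgroup_type", "locus",
                 "release_version", "release_date", "release_description",
                 "license", "acknowledgements", "allele_descriptions")
GK_AD_KEYS <- c("allele_description_id", "label", "sequence_type",
                "gene_label", "functionality", "coding_sequence",
                "gapped_sequence", "incomplete_5p", "incomplete_3p",
                "j_codon_frame", "j_donor_splice", "delineations", "aliases",
                "evidence", "version", "release_date")

ad_to_json_list <- function(ad) {
  list(
    allele_description_id = ad$allele_description_id,
    label = ad$label,
    sequence_type = ad$sequence_type,
    gene_label = ad$gene_label,
    functionality = ad$functionality,
    coding_sequence = ad$coding_sequence,
    gapped_sequence = ad$gapped_sequence,
    incomplete_5p = ad$incomplete_5p,
    incomplete_3p = ad$incomplete_3p,
    j_codon_frame = ad$j_codon_frame,
    j_donor_splice = ad$j_donor_splice,
    delineations = lapply(ad$delineations, function(d) {
      list(scheme = d$scheme, regions = d$regions)
    }),
    aliases = ad$aliases,
    evidence = lapply(ad$evidence, function(e) {
      list(evidence_type = e$evidence_type, repository = e$repository,
           accession = e$accession, notes = e$notes)
    }),
    version = ad$version,
    release_date = ad$release_date)
}

#' Write a germline set as canonical JSON
#'
#' @param set A [germline_set()].
#' @return A single JSON string (UTF-8, LF, 2-space indent, terminated by a
#'   newline). Writing the same set twice yields byte-identical output.
#' @export
write_germline_set <- function(set) {
  ads <- set$allele_descriptions
  if (length(ads)) {
    ads <- ads[order(vapply(ads, `[[`, "", "label"), method = "radix")]
  }
  obj <- list(
    schema_version = GK_SCHEMA_VERSION,
    germline_set_id = set$germline_set_id,
    name = set$name,
    species = list(label = set$species$label, taxon_id = set$species$taxon_id),
    species_subgroup = set$species_subgroup,
    species_subgroup_type = set$species_subgroup_type,
    locus = set$locus,
    release_version = set$release_version,
    release_date = set$release_date,
    release_description = set$release_description,
    license = set$license,
    acknowledgements = lapply(set$acknowledgements, function(a) {
      list(name = a$name, institution = a$institution, orcid_id = a$orcid_id)
    }),
    allele_descriptions = lapply(ads, ad_to_json_list))
  txt <- jsonlite::toJSON(obj, pretty = 2, auto_unbox = TRUE, na = "null",
                          digits = NA)
  paste0(as.character(txt), "\n")
}

json_scalar <- function(x, default) {
  if (is.null(x) || (length(x) == 1 && is.na(x))) return(default)
  cast <- switch(class(default)[1],
                 character = as.character, integer = as.integer,
                 numeric = as.numeric, logical = as.logical, identity)
  cast(x)
}

require_field <- function(obj, field, path) {
  if (is.null(obj[[field]])) {
    stop(sprintf("validation error at %s.%s: required field missing",
                 path, field), call. = FALSE)
  }
  obj[[field]]
}

ad_from_json_list <- function(x, path) {
  for (f in c("allele_description_id", "label", "sequence_type", "locus",
              "coding_sequence")) {
    if (f != "locus") require_field(x, f, path)
  }
  delins <- lapply(x$delineations, function(d) {
    regions <- do.call(rbind, lapply(d$regions, function(r) {
      data.frame(region_name = as.character(r$region_name),
                 start = as.integer(r$start), end = as.integer(r$end),
                 stringsAsFactors = FALSE)
    }))
    delineation(d$scheme, regions)
  })
  ev <- lapply(x$evidence, function(e) {
    supporting_evidence(e$evidence_type,
                        repository = json_scalar(e$repository, ""),
                        accession = json_scalar(e$accession, ""),
                        notes = json_scalar(e$notes, ""))
  })
  allele_description(
    allele_description_id = x$allele_description_id,
    label = x$label,
    sequence_type = x$sequence_type,
    locus = x$locus,
    coding_sequence = x$coding_sequence,
    gapped_sequence = json_scalar(x$gapped_sequence, NA_character_),
    aliases = as.character(unlist(x$aliases)),
    delineations = delins,
    j_codon_frame = json_scalar(x$j_codon_frame, NA_integer_),
    j_donor_splice = json_scalar(x$j_donor_splice, NA_integer_),
    gene_label = json_scalar(x$gene_label, NA_character_),
    functionality = json_scalar(x$functionality, "unknown"),
    incomplete_5p = isTRUE(x$incomplete_5p),
    incomplete_3p = isTRUE(x$incomplete_3p),
    evidence = ev,
    version = json_scalar(x$version, 1L),
    release_date = json_scalar(x$release_date, NA_character_))
}

#' Read a germline set from schema-compliant JSON
#'
#' @param json JSON text, or the path of a JSON file.
#' @return A [germline_set()].
#' @export
read_germline_set <- function(json) {
  txt <- slurp_text(json)
  x <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  sv <- x$schema_version
  if (is.null(sv)) {
    stop("validation error at $.schema_version: required field missing",
         call. = FALSE)
  }
  if (!identical(sv, GK_SCHEMA_VERSION)) {
    stop(sprintf("unknown schema_version '%s' (this reader understands '%s')",
                 sv, GK_SCHEMA_VERSION), call. = FALSE)
  }
  for (f in c("germline_set_id", "name", "species", "locus",
              "release_version", "release_date")) {
    require_field(x, f, "$")
  }
  ads <- lapply(seq_along(x$allele_descriptions), function(i) {
    a <- x$allele_descriptions[[i]]
    a$locus <- json_scalar(a$locus, x$locus)
    ad_from_json_list(a, sprintf("$.allele_descriptions[%d]", i))
  })
  germline_set(
    germline_set_id = x$germline_set_id,
    name = x$name,
    species = list(label = require_field(x$species, "label", "$.species"),
                   taxon_id = json_scalar(x$species$taxon_id, NA_integer_)),
    locus = x$locus,
    species_subgroup = json_scalar(x$species_subgroup, NA_character_),
    species_subgroup_type = json_scalar(x$species_subgroup_type, "none"),
    release_version = as.integer(x$release_version),
    release_date = x$release_date,
    release_description = json_scalar(x$release_description, ""),
    license = json_scalar(x$license, "CC0 1.0"),
    acknowledgements = lapply(x$acknowledgements, function(a) {
      list(name = json_scalar(a$name, ""),
           institution = json_scalar(a$institution, ""),
           orcid_id = json_scalar(a$orcid_id, ""))
    }),
    allele_descriptions = ads)
}

slurp_text <- function(x) {
  if (length(x) == 1 && !grepl("[{\n]", x) && file.exists(x)) {
    return(paste(readLines(x, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n"))
  }
  paste(x, collapse = "\n")
}

wrap60 <- function(s) {
  n <- nchar(s)
  starts <- seq(1L, n, by = 60L)
  substring(s, starts, pmin(starts + 59L, n))
}

#' Export a germline set as FASTA
#'
#' One record per allele, header `>` + label (metadata stays in the JSON
#' form: names are identifiers, not data), sequence wrapped at 60 columns,
#' records in label order. With `gapped = TRUE`, V alleles are emitted as
#' their gap-aligned sequences (every V allele must carry one); other
#' alleles are always emitted ungapped.
#'
#' @param set A [germline_set()].
#' @param gapped Emit gapped V sequences?
#' @return FASTA text as a single string.
#' @export
export_fasta <- function(set, gapped = FALSE) {
  ads <- set$allele_descriptions
  if (length(ads)) {
    ads <- ads[order(vapply(ads, `[[`, "", "label"), method = "radix")]
  }
  if (gapped) {
    is_v <- vapply(ads, `[[`, "", "sequence_type") == "V"
    missing <- vapply(ads, function(a) is.na(a$gapped_sequence), NA) & is_v
    if (any(missing)) {
      stop(sprintf("gapped export requested but gapped_sequence is absent for: %s",
                   paste(vapply(ads[missing], `[[`, "", "label"),
                         collapse = ", ")), call. = FALSE)
    }
  }
  chunks <- vapply(ads, function(a) {
    s <- if (gapped && a$sequence_type == "V") a$gapped_sequence else a$coding_sequence
    paste0(">", a$label, "\n", paste(wrap60(s), collapse = "\n"), "\n")
  }, "")
  paste(chunks, collapse = "")
}

#' Import a legacy FASTA file as a skeleton germline set
#'
#' A migration path for sets published as bare FASTA: one allele description
#' per record, the label taken as the first whitespace-delimited header
#' token and the sequence type inferred from the label. The result carries
#' no delineations, evidence or gapped alignments — those are curated later.
#'
#' @param text FASTA text or the path of a FASTA file.
#' @param locus Locus of the imported set.
#' @param species Species label.
#' @return A [germline_set()] (release 1).
#' @export
import_fasta <- function(text, locus, species) {
  path <- if (length(text) == 1 && !grepl("[>\n]", text) && file.exists(text)) {
    text
  } else {
    tf <- tempfile(fileext = ".fasta")
    writeLines(sub("\n$", "", paste(text, collapse = "\n")), tf)
    tf
  }
  recs <- Biostrings::readBStringSet(path)
  headers <- names(recs)
  labels <- vapply(strsplit(headers, "[[:space:]]+"), `[[`, "", 1)
  dup <- unique(labels[duplicated(labels)])
  if (length(dup)) {
    stop(sprintf("duplicate FASTA header(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  ads <- lapply(seq_along(recs), function(i) {
    pl <- try(suppressWarnings(parse_label(labels[i])), silent = TRUE)
    stype <- if (!inherits(pl, "try-error") && !is.na(pl$sequence_type)) {
      pl$sequence_type
    } else {
      "V"
    }
    allele_description(
      allele_description_id = sprintf("%s-import-%03d", locus, i),
      label = labels[i], sequence_type = stype, locus = locus,
      coding_sequence = normalise_sequence(as.character(recs[[i]])),
      version = 1L, release_date = format(Sys.Date()))
  })
  germline_set(
    germline_set_id = sprintf("%s-%s-imported", gsub("[^A-Za-z0-9]+", "_", species), locus),
    name = sprintf("Imported %s %s set", species, locus),
    species = species, locus = locus,
    release_version = 1L,
    release_description = "Imported from FASTA",
    allele_descriptions = ads)
}

AD_DIFF_FIELDS <- c("label", "sequence_type", "gene_label", "functionality",
                    "coding_sequence", "gapped_sequence", "incomplete_5p",
                    "incomplete_3p", "j_codon_frame", "j_donor_splice",
                    "delineations", "aliases", "evidence")

changed_fields <- function(a, b) {
  AD_DIFF_FIELDS[!vapply(AD_DIFF_FIELDS, function(f) {
    identical(a[[f]], b[[f]])
  }, NA)]
}

#' Identify changes between two releases of a germline set
#'
#' Alleles are matched by `allele_description_id` first, then by resolving
#' the new release's labels against the old release's labels and aliases
#' (so a renamed allele is reported as modified on `label`, not as a
#' removal plus an addition). Per-record `version` and `release_date` are
#' bookkeeping and not compared.
#'
#' @param old,new [germline_set()] objects for the same locus and species.
#' @return An object of class `set_diff`: list with `added` and `removed`
#'   label vectors and `modified`, a named list mapping each modified
#'   allele's label (in `new`) to the changed field paths.
#' @export
diff_sets <- function(old, new) {
  if (old$locus != new$locus || old$species$label != new$species$label) {
    stop(sprintf(
      "sets are not comparable: (%s, %s) vs (%s, %s)",
      old$species$label, old$locus, new$species$label, new$locus),
      call. = FALSE)
  }
  old_ads <- old$allele_descriptions
  new_ads <- new$allele_descriptions
  old_ids <- vapply(old_ads, `[[`, "", "allele_description_id")
  matched_old <- logical(length(old_ads))
  added <- character()
  modified <- list()
  for (na in new_ads) {
    j <- which(old_ids == na$allele_description_id & !matched_old)[1]
    if (is.na(j)) {
      j <- which(!matched_old & vapply(old_ads, function(oa) {
        na$label == oa$label || na$label %in% oa$aliases
      }, NA))[1]
    }
    if (!is.na(j)) {
      matched_old[j] <- TRUE
      ch <- changed_fields(old_ads[[j]], na)
      if (length(ch)) modified[[na$label]] <- ch
    } else {
      added <- c(added, na$label)
    }
  }
  removed <- vapply(old_ads[!matched_old], `[[`, "", "label")
  if (length(modified)) {
    modified <- modified[order(names(modified), method = "radix")]
  }
  structure(list(added = sort(added, method = "radix"),
                 removed = sort(removed, method = "radix"),
                 modified = modified),
            class = "set_diff")
}

#' @export
print.set_diff <- function(x, ...) {
  cat(sprintf("<set_diff> +%d added, -%d removed, ~%d modified\n",
              length(x$added), length(x$removed), length(x$modified)))
  for (a in x$added) cat("  + ", a, "\n", sep = "")
  for (r in x$removed) cat("  - ", r, "\n", sep = "")
  for (m in names(x$modified)) {
    cat("  ~ ", m, " [", paste(x$modified[[m]], collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}

#' Is a release diff empty?
#'
#' @param diff A `set_diff` from [diff_sets()].
#' @return `TRUE` when no allele was added, removed or modified.
#' @export
is_empty_diff <- function(diff) {
  !length(diff$added) && !length(diff$removed) && !length(diff$modified)
}

#' Open a new release of a germline set
#'
#' Increments `release_version`, stamps the supplied date and replaces the
#' release description; allele contents are untouched.
#'
#' @param set A [germline_set()].
#' @param description Release description for the new version.
#' @param release_date ISO 8601 date of the new release.
#' @return The bumped [germline_set()].
#' @export
bump_version <- function(set, description = "",
                         release_date = format(Sys.Date())) {
  set$release_version <- set$release_version + 1L
  set$release_date <- as.character(release_date)
  set$release_description <- as.character(description)
  set
}
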