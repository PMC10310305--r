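#' Naming-domain registry and the two-phase label-allocation workflow
#'
#' A naming domain is the scope — a species, or a subgroup such as an
#' inbred strain — within which 4-character temporary identifiers are
#' guaranteed unique and are never re-used, even after a record is
#' withdrawn. The registry backing a domain is a flat CSV database of
#' records, one per allocated identifier, designed to live under version
#' control so that changes from multiple curation groups can be merged.
#'
#' Label allocation is two-phase. [propose()] compares a batch of candidate
#' sequences against the registry and returns a proposed action for each:
#' exact duplicates of an existing record, sub- or super-sequences of
#' existing records (which a curator must resolve, since whether two nested
#' sequences represent the same allele is a curatorial judgement), or new
#' sequences. [apply_proposals()] then executes the reviewed actions,
#' allocating fresh identifiers and null-valued temporary labels for the
#' accepted new sequences.
#'
#' @name registry
NULL

REGISTRY_HEADER <- "identifier,current_label,sequence,status,allocated,aliases,notes"
REGISTRY_COLS <- strsplit(REGISTRY_HEADER, ",")[[1]]
GK_ID_SPACE <- 1048576L  # 32^4

registry_record <- function(identifier, current_label, sequence,
                            status = "active",
                            allocated = format(Sys.Date()),
                            aliases = character(), notes = "") {
  structure(
    list(identifier = as.character(identifier),
         current_label = as.character(current_label),
         sequence = normalise_sequence(sequence),
         status = match.arg(status, c("active", "withdrawn")),
         allocated = as.character(allocated),
         aliases = as.character(aliases),
         notes = as.character(notes)),
    class = "registry_record")
}

#' Create a naming domain
#'
#' @param domain_id Scope of the domain (a species, or species + subgroup).
#' @param locus The locus whose alleles this domain names (labels allocated
#'   by [apply_proposals()] carry this locus). Domain identity is supplied at
#'   creation or load time; the registry CSV itself holds only records.
#' @param records List of registry records (normally empty at creation).
#' @return An object of class `naming_domain`.
#' @export
naming_domain <- function(domain_id, locus = "IGH", records = list()) {
  locus <- match.arg(locus, GK_LOCI)
  structure(list(domain_id = as.character(domain_id), locus = locus,
                 records = records),
            class = "naming_domain")
}

#' @export
print.naming_domain <- function(x, ...) {
  st <- vapply(x$records, `[[`, "", "status")
  cat(sprintf("<naming_domain> %s (%s): %d record(s), %d withdrawn\n",
              x$domain_id, x$locus, length(x$records), sum(st == "withdrawn")))
  invisible(x)
}

domain_identifiers <- function(domain) {
  vapply(domain$records, `[[`, "", "identifier")
}

domain_find <- function(domain, identifier) {
  idx <- which(domain_identifiers(domain) == identifier)
  if (!length(idx)) NULL else idx[1]
}

#' Audit a naming domain's structural invariants
#'
#' Checks identifier uniqueness and validity, non-empty sequences, label
#' parseability, and that no label or alias is claimed by two records.
#'
#' @param domain A [naming_domain()].
#' @return A violation data frame; empty when the registry is consistent.
#' @export
audit_registry <- function(domain) {
  v <- no_violations()
  recs <- domain$records
  if (!length(recs)) return(v)
  ids <- domain_identifiers(domain)
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) {
    v <- bind_violations(v, violation(
      "records", sprintf("identifier '%s' appears in more than one record", d)))
  }
  bad <- ids[!is_valid_identifier(ids)]
  for (b in bad) {
    v <- bind_violations(v, violation(
      sprintf("records[%s].identifier", b),
      "identifier must match [A-Z2-7]{4}"))
  }
  for (r in recs) {
    if (!nzchar(r$sequence)) {
      v <- bind_violations(v, violation(
        sprintf("records[%s].sequence", r$identifier), "sequence is empty"))
    }
    if (!is_parseable_label(r$current_label)) {
      v <- bind_violations(v, violation(
        sprintf("records[%s].current_label", r$identifier),
        sprintf("label '%s' is not parseable", r$current_label)))
    }
  }
  active <- vapply(recs, `[[`, "", "status") == "active"
  lab <- vapply(recs, `[[`, "", "current_label")
  dup_lab <- unique(lab[active][duplicated(lab[active])])
  for (d in dup_lab) {
    v <- bind_violations(v, violation(
      "records", sprintf("label '%s' is current in two active records", d)))
  }
  all_aliases <- unlist(lapply(recs, `[[`, "aliases"))
  dup_al <- unique(all_aliases[duplicated(all_aliases)])
  for (d in dup_al) {
    v <- bind_violations(v, violation(
      "records", sprintf("alias '%s' appears in more than one record", d)))
  }
  v
}

csv_escape <- function(x) {
  needs <- grepl('[,;"]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

record_to_row <- function(r) {
  paste(csv_escape(c(r$identifier, r$current_label, r$sequence, r$status,
                     r$allocated, paste(r$aliases, collapse = ";"),
                     r$notes)),
        collapse = ",")
}

#' Save a naming-domain registry as CSV
#'
#' The file format is bit-exact and diff-friendly: UTF-8, LF line endings,
#' a fixed header line, records sorted by allocation date then identifier,
#' aliases `";"`-joined, and fields quoted only when they contain a comma,
#' semicolon or quote (internal quotes doubled).
#'
#' @param domain A [naming_domain()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_registry <- function(domain, path) {
  recs <- domain$records
  if (length(recs)) {
    ord <- order(vapply(recs, `[[`, "", "allocated"),
                 vapply(recs, `[[`, "", "identifier"))
    recs <- recs[ord]
  }
  rows <- vapply(recs, record_to_row, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(REGISTRY_HEADER, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Load a naming-domain registry from CSV
#'
#' @param path Registry CSV path (format as written by [save_registry()]).
#' @param domain_id Domain identity; defaults to the file name without
#'   extension (the CSV carries records only).
#' @param locus Locus of the domain; defaults to the locus of the first
#'   record's label, or `IGH` for an empty registry.
#' @return A [naming_domain()].
#' @export
load_registry <- function(path, domain_id = NULL, locus = NULL) {
  if (!file.exists(path)) stop(sprintf("registry file '%s' not found", path),
                               call. = FALSE)
  if (is.null(domain_id)) {
    domain_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || lines[1] != REGISTRY_HEADER) {
    stop(sprintf("line 1: expected header '%s'", REGISTRY_HEADER), call. = FALSE)
  }
  nf <- utils::count.fields(path, sep = ",", quote = '"', blank.lines.skip = FALSE)
  bad <- which(nf != length(REGISTRY_COLS))
  if (length(bad)) {
    stop(sprintf("line %d: expected %d fields, found %d",
                 bad[1], length(REGISTRY_COLS), nf[bad[1]]), call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), REGISTRY_COLS)) {
    stop("registry header does not match the required column set", call. = FALSE)
  }
  if (anyDuplicated(df$identifier)) {
    d <- df$identifier[duplicated(df$identifier)][1]
    stop(sprintf("integrity error: identifier '%s' appears in more than one row", d),
         call. = FALSE)
  }
  records <- lapply(seq_len(nrow(df)), function(i) {
    aliases <- df$aliases[i]
    aliases <- if (nzchar(aliases)) strsplit(aliases, ";", fixed = TRUE)[[1]] else character()
    registry_record(df$identifier[i], df$current_label[i], df$sequence[i],
                    status = df$status[i], allocated = df$allocated[i],
                    aliases = aliases, notes = df$notes[i])
  })
  if (is.null(locus)) {
    locus <- "IGH"
    if (length(records)) {
      pl <- try(suppressWarnings(parse_label(records[[1]]$current_label)),
                silent = TRUE)
      if (!inherits(pl, "try-error")) locus <- pl$locus
    }
  }
  naming_domain(domain_id, locus, records)
}

order_by_allocation <- function(records) {
  if (!length(records)) return(records)
  ord <- order(vapply(records, `[[`, "", "allocated"),
               vapply(records, `[[`, "", "identifier"))
  records[ord]
}

as_input_table <- function(new_sequences) {
  if (is.character(new_sequences)) {
    ids <- names(new_sequences)
    if (is.null(ids)) ids <- paste0("seq", seq_along(new_sequences))
    new_sequences <- data.frame(input_id = ids, sequence = unname(new_sequences),
                                stringsAsFactors = FALSE)
  }
  new_sequences <- as.data.frame(new_sequences, stringsAsFactors = FALSE)
  stopifnot(all(c("input_id", "sequence") %in% names(new_sequences)))
  new_sequences
}

#' Phase one: propose an action for each candidate sequence
#'
#' Each input sequence (normalised to upper case with gap characters and
#' whitespace stripped) is compared against the registry by exact string
#' containment. A sequence equal to an existing record's sequence is a
#' `duplicate`; a strict substring of one or more active records is a
#' `subsequence`; a strict superstring is a `supersequence`; anything else
#' is `new`. Multiple containment matches are listed ordered by allocation
#' date then identifier. Inputs identical to an earlier input in the same
#' batch are collapsed onto the first occurrence. Withdrawn records still
#' participate in duplicate detection; such matches are flagged in the
#' `note` column and left for the curator.
#'
#' Duplicate proposals default to assigning the matched record and `new`
#' proposals to allocating a fresh label; sub-/super-sequence proposals have
#' no default `final_action` — whether nested sequences represent the same
#' allele is a curatorial decision, and [apply_proposals()] refuses
#' unresolved proposals.
#'
#' @param new_sequences Data frame with columns `input_id`, `sequence`, or a
#'   (optionally named) character vector of sequences.
#' @param domain A [naming_domain()].
#' @return A data frame of class `action_proposals` with columns `input_id`,
#'   `sequence`, `proposed_action`, `matched_identifiers` (`";"`-joined),
#'   `final_action` and `note`; collapsed batch duplicates are recorded in
#'   the `collapsed` attribute.
#' @export
propose <- function(new_sequences, domain) {
  inputs <- as_input_table(new_sequences)
  if (!nrow(inputs)) stop("no input sequences supplied", call. = FALSE)
  inputs$sequence <- normalise_sequence(inputs$sequence)
  if (any(!nzchar(inputs$sequence))) {
    stop(sprintf("empty sequence for input '%s'",
                 inputs$input_id[!nzchar(inputs$sequence)][1]), call. = FALSE)
  }
  first <- !duplicated(inputs$sequence)
  collapsed <- inputs[!first, , drop = FALSE]
  inputs <- inputs[first, , drop = FALSE]

  recs <- order_by_allocation(domain$records)
  rec_seq <- vapply(recs, `[[`, "", "sequence")
  rec_id <- vapply(recs, `[[`, "", "identifier")
  rec_active <- vapply(recs, `[[`, "", "status") == "active"

  n <- nrow(inputs)
  action <- character(n); matched <- character(n)
  final <- character(n); note <- character(n)
  for (i in seq_len(n)) {
    s <- inputs$sequence[i]
    eq <- rec_seq == s
    if (any(eq)) {
      action[i] <- "duplicate"
      matched[i] <- paste(rec_id[eq], collapse = ";")
      if (any(eq & rec_active)) {
        final[i] <- paste0("assign_existing:", rec_id[eq & rec_active][1])
      } else {
        note[i] <- "matches withdrawn record(s) only"
      }
      next
    }
    is_sub <- rec_active & nchar(rec_seq) > nchar(s) &
      vapply(rec_seq, function(r) grepl(s, r, fixed = TRUE), NA)
    if (any(is_sub)) {
      action[i] <- "subsequence"
      matched[i] <- paste(rec_id[is_sub], collapse = ";")
      next
    }
    is_super <- rec_active & nchar(rec_seq) < nchar(s) &
      vapply(rec_seq, function(r) grepl(r, s, fixed = TRUE), NA)
    if (any(is_super)) {
      action[i] <- "supersequence"
      matched[i] <- paste(rec_id[is_super], collapse = ";")
      next
    }
    action[i] <- "new"
    final[i] <- "allocate_new"
  }
  out <- data.frame(input_id = inputs$input_id, sequence = inputs$sequence,
                    proposed_action = action, matched_identifiers = matched,
                    final_action = final, note = note,
                    stringsAsFactors = FALSE)
  class(out) <- c("action_proposals", "data.frame")
  attr(out, "collapsed") <- collapsed
  out
}

#' Write / read a proposal file
#'
#' Proposal CSVs carry the columns `input_id,sequence,proposed_action,`
#' `matched_identifiers,final_action`; `matched_identifiers` is
#' `";"`-joined. The curator edits `final_action` between the two phases.
#'
#' @param proposals An `action_proposals` data frame.
#' @param path File path.
#' @return `path` (write) or an `action_proposals` data frame (read).
#' @export
write_proposals <- function(proposals, path) {
  cols <- c("input_id", "sequence", "proposed_action", "matched_identifiers",
            "final_action")
  rows <- vapply(seq_len(nrow(proposals)), function(i) {
    paste(csv_escape(as.character(unlist(proposals[i, cols]))), collapse = ",")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = ","), rows), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' @rdname write_proposals
#' @export
read_proposals <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("input_id", "sequence", "proposed_action", "matched_identifiers",
            "final_action")
  if (!identical(names(df), need)) {
    stop("proposal file header does not match the required column set",
         call. = FALSE)
  }
  df$note <- ""
  class(df) <- c("action_proposals", "data.frame")
  df
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

draw_identifiers <- function(issued_values, n) {
  remaining <- GK_ID_SPACE - length(issued_values)
  if (n > remaining) {
    stop(sprintf(
      "naming domain exhausted: %d identifier(s) requested but only %d of %d remain unissued",
      n, remaining, GK_ID_SPACE), call. = FALSE)
  }
  if (length(issued_values) > GK_ID_SPACE / 2) {
    pool <- setdiff(0:(GK_ID_SPACE - 1L), issued_values)
    return(if (length(pool) == 1L) pool else sample(pool, n))
  }
  out <- integer(0)
  taken <- issued_values
  while (length(out) < n) {
    k <- max(2L * (n - length(out)), 16L)
    cand <- sample.int(GK_ID_SPACE, k, replace = TRUE) - 1L
    cand <- cand[!cand %in% taken]
    cand <- cand[!duplicated(cand)]
    out <- c(out, cand)
    taken <- c(taken, cand)
  }
  out[seq_len(n)]
}

#' Allocate fresh identifiers in a naming domain
#'
#' Draws uniformly over the 20-bit values never issued in the domain
#' (withdrawn records still count as issued: identifiers are never
#' re-used). Deterministic under a fixed seed.
#'
#' @param domain A [naming_domain()].
#' @param n Number of identifiers to allocate.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return Character vector of `n` fresh 4-character identifiers.
#' @export
allocate_identifier <- function(domain, n = 1L, seed = NULL) {
  issued <- decode_identifier_safe(domain_identifiers(domain))
  vals <- with_seed(seed, draw_identifiers(issued, n))
  encode_identifier(vals)
}

decode_identifier_safe <- function(ids) {
  if (!length(ids)) return(integer())
  decode_identifier(ids)
}

#' Phase two: apply reviewed proposals to the registry
#'
#' Every proposal must carry a resolved `final_action`
#' (`assign_existing:<identifier>`, `allocate_new` or `skip`); sub-/super-
#' sequence proposals left unresolved cause the whole batch to be rejected
#' without mutating the registry. `allocate_new` creates a record with a
#' fresh identifier and a null-valued temporary label; `assign_existing`
#' appends a provenance note to the matched record.
#'
#' @param proposals An `action_proposals` data frame (from [propose()] or
#'   [read_proposals()]), reviewed by the curator.
#' @param domain A [naming_domain()].
#' @param seed Integer seed for identifier allocation (recorded in the
#'   report for provenance).
#' @param sequence_type Sequence type (`V`, `D` or `J`) for labels allocated
#'   in this batch.
#' @param date Allocation date recorded on new records (ISO 8601).
#' @return A list with elements `domain` (the updated [naming_domain()]) and
#'   `report` (a data frame mapping `input_id` to `action`, `identifier`,
#'   `label`, with the seed stored in its `seed` attribute).
#' @export
apply_proposals <- function(proposals, domain, seed = NULL,
                            sequence_type = "V",
                            date = format(Sys.Date())) {
  sequence_type <- match.arg(sequence_type, GK_SEQUENCE_TYPES)
  unresolved <- !proposals$final_action %in% c("allocate_new", "skip") &
    !grepl("^assign_existing:[A-Z2-7]{4}$", proposals$final_action)
  if (any(unresolved)) {
    stop(sprintf(
      "unresolved final_action for input(s): %s (sub-/super-sequence calls must be decided by the curator)",
      paste(proposals$input_id[unresolved], collapse = ", ")), call. = FALSE)
  }
  assign_to <- sub("^assign_existing:", "", proposals$final_action)
  assign_idx <- grepl("^assign_existing:", proposals$final_action)
  known <- domain_identifiers(domain)
  missing <- setdiff(assign_to[assign_idx], known)
  if (length(missing)) {
    stop(sprintf("integrity error: unknown matched identifier(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  n_new <- sum(proposals$final_action == "allocate_new")
  fresh <- if (n_new) allocate_identifier(domain, n = n_new, seed = seed) else character()

  report <- data.frame(input_id = proposals$input_id,
                       action = proposals$final_action,
                       identifier = NA_character_, label = NA_character_,
                       stringsAsFactors = FALSE)
  k <- 0L
  for (i in seq_len(nrow(proposals))) {
    fa <- proposals$final_action[i]
    if (fa == "skip") next
    if (fa == "allocate_new") {
      k <- k + 1L
      id <- fresh[k]
      lab <- format_label(null_label_for(domain$locus, sequence_type, id))
      domain$records <- c(domain$records, list(registry_record(
        id, lab, proposals$sequence[i], status = "active", allocated = date,
        notes = sprintf("allocated for input %s", proposals$input_id[i]))))
      report$identifier[i] <- id
      report$label[i] <- lab
    } else {
      id <- assign_to[i]
      j <- domain_find(domain, id)
      rec <- domain$records[[j]]
      prov <- sprintf("assigned input %s", proposals$input_id[i])
      rec$notes <- if (nzchar(rec$notes)) paste(rec$notes, prov, sep = "; ") else prov
      domain$records[[j]] <- rec
      report$identifier[i] <- id
      report$label[i] <- rec$current_label
    }
  }
  attr(report, "seed") <- seed
  list(domain = domain, report = report)
}

#' Register a single sequence directly
#'
#' Convenience wrapper allocating one record. By default the record gets a
#' null-valued temporary label; an explicit `label` (for example a legacy
#' designation already in use in the literature) may be supplied instead —
#' the registry identifier is allocated regardless, since identifiers, not
#' labels, guarantee uniqueness.
#'
#' @param domain A [naming_domain()].
#' @param sequence Nucleotide sequence.
#' @param label Optional explicit label; must be parseable and not in use.
#' @param sequence_type `V`, `D` or `J` (used when deriving a temporary
#'   label).
#' @param seed Optional allocation seed.
#' @param date Allocation date (ISO 8601).
#' @return The updated [naming_domain()].
#' @export
register_sequence <- function(domain, sequence, label = NULL,
                              sequence_type = "V", seed = NULL,
                              date = format(Sys.Date())) {
  id <- allocate_identifier(domain, 1L, seed = seed)
  if (is.null(label)) {
    label <- format_label(null_label_for(domain$locus, sequence_type, id))
  } else {
    if (!is_parseable_label(label)) {
      stop(sprintf("label '%s' is not parseable", label), call. = FALSE)
    }
    check_label_free(domain, label)
  }
  domain$records <- c(domain$records, list(registry_record(
    id, label, sequence, allocated = date)))
  domain
}

all_domain_names <- function(domain, except_identifier = NULL) {
  recs <- domain$records
  if (!is.null(except_identifier)) {
    recs <- recs[vapply(recs, `[[`, "", "identifier") != except_identifier]
  }
  unlist(lapply(recs, function(r) c(r$current_label, r$aliases)))
}

check_label_free <- function(domain, label, except_identifier = NULL) {
  taken <- all_domain_names(domain, except_identifier)
  if (label %in% taken) {
    holder <- Find(function(r) label %in% c(r$current_label, r$aliases),
                   domain$records)
    stop(sprintf("label '%s' is already in use by record %s (%s)",
                 label, holder$identifier, holder$current_label), call. = FALSE)
  }
  invisible(TRUE)
}

#' Rename a registry record, preserving traceability
#'
#' The previous current label is appended to the record's aliases (oldest
#' first), so every name the allele has ever carried remains resolvable.
#' The identifier never changes. No renaming policy is enforced beyond
#' uniqueness: when and why to rename is left to the curators.
#'
#' @param domain A [naming_domain()].
#' @param identifier Identifier of the record to rename.
#' @param new_label The new current label (must be parseable and not in use
#'   by another record).
#' @return The updated [naming_domain()].
#' @export
rename_record <- function(domain, identifier, new_label) {
  i <- domain_find(domain, identifier)
  if (is.null(i)) stop(sprintf("no record with identifier '%s'", identifier),
                       call. = FALSE)
  if (!is_parseable_label(new_label)) {
    stop(sprintf("label '%s' is not parseable", new_label), call. = FALSE)
  }
  check_label_free(domain, new_label, except_identifier = identifier)
  rec <- domain$records[[i]]
  if (new_label != rec$current_label) {
    if (!rec$current_label %in% rec$aliases) {
      rec$aliases <- c(rec$aliases, rec$current_label)
    }
    rec$aliases <- setdiff(rec$aliases, new_label)
    rec$current_label <- new_label
  }
  domain$records[[i]] <- rec
  domain
}

#' Record a synonym on a registry record
#'
#' Aliases capture legacy designations and alternative nomenclatures of an
#' allele (for example its name in another germline database), providing
#' traceability across time and across databases.
#'
#' @inheritParams rename_record
#' @param alias The synonym to record (must not be in use anywhere in the
#'   domain).
#' @return The updated [naming_domain()].
#' @export
add_alias <- function(domain, identifier, alias) {
  i <- domain_find(domain, identifier)
  if (is.null(i)) stop(sprintf("no record with identifier '%s'", identifier),
                       call. = FALSE)
  check_label_free(domain, alias)
  rec <- domain$records[[i]]
  rec$aliases <- c(rec$aliases, alias)
  domain$records[[i]] <- rec
  domain
}

#' Withdraw a registry record
#'
#' The record's status becomes `withdrawn`; its identifier remains issued
#' forever and is never re-allocated.
#'
#' @inheritParams rename_record
#' @return The updated [naming_domain()].
#' @export
withdraw_record <- function(domain, identifier) {
  i <- domain_find(domain, identifier)
  if (is.null(i)) stop(sprintf("no record with identifier '%s'", identifier),
                       call. = FALSE)
  domain$records[[i]]$status <- "withdrawn"
  domain
}

#' Resolve a label or alias to its registry record
#'
#' Current labels are searched before aliases; a label must resolve to
#' exactly one record (two hits indicate a corrupt registry).
#'
#' @param domain A [naming_domain()].
#' @param label Label or alias to resolve.
#' @return The matching registry record.
#' @export
resolve_label <- function(domain, label) {
  cur <- vapply(domain$records, `[[`, "", "current_label")
  hits <- which(cur == label)
  if (!length(hits)) {
    hits <- which(vapply(domain$records, function(r) label %in% r$aliases, NA))
  }
  if (!length(hits)) {
    stop(sprintf("label '%s' not found in domain %s", label, domain$domain_id),
         call. = FALSE)
  }
  if (length(hits) > 1) {
    stop(sprintf(
      "integrity error: label '%s' resolves to %d records (%s)",
      label, length(hits),
      paste(vapply(domain$records[hits], `[[`, "", "identifier"),
            collapse = ", ")), call. = FALSE)
  }
  domain$records[[hits]]
}

#' Merge two registries of the same naming domain
#'
#' Registries published under version control may be extended by multiple
#' curation groups and merged. Records agreeing on both identifier and
#' sequence are unioned (aliases: `a`'s, then `b`'s novel ones; `b`'s
#' current label becomes an alias if it differs). An identifier carried by
#' both with different sequences, or one sequence carried under two
#' identifiers, is a clash: no merge is performed and a full clash report
#' is returned instead.
#'
#' @param a,b [naming_domain()] objects with equal `domain_id`.
#' @return The merged [naming_domain()], or a data frame of class
#'   `clash_report` (columns `kind`, `identifier_a`, `identifier_b`,
#'   `detail`) when any clash exists.
#' @export
merge_registries <- function(a, b) {
  if (a$domain_id != b$domain_id) {
    stop(sprintf("cannot merge registries of different naming domains ('%s' vs '%s')",
                 a$domain_id, b$domain_id), call. = FALSE)
  }
  clashes <- data.frame(kind = character(), identifier_a = character(),
                        identifier_b = character(), detail = character(),
                        stringsAsFactors = FALSE)
  ids_a <- domain_identifiers(a)
  ids_b <- domain_identifiers(b)
  seq_a <- vapply(a$records, `[[`, "", "sequence")
  seq_b <- vapply(b$records, `[[`, "", "sequence")
  for (id in intersect(ids_a, ids_b)) {
    sa <- seq_a[ids_a == id]; sb <- seq_b[ids_b == id]
    if (sa != sb) {
      clashes <- rbind(clashes, data.frame(
        kind = "identifier_sequence_mismatch", identifier_a = id,
        identifier_b = id,
        detail = sprintf("identifier %s has different sequences", id),
        stringsAsFactors = FALSE))
    }
  }
  for (i in seq_along(seq_b)) {
    j <- which(seq_a == seq_b[i] & ids_a != ids_b[i])
    for (jj in j) {
      clashes <- rbind(clashes, data.frame(
        kind = "sequence_identifier_mismatch", identifier_a = ids_a[jj],
        identifier_b = ids_b[i],
        detail = "same sequence recorded under different identifiers",
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(clashes)) {
    class(clashes) <- c("clash_report", "data.frame")
    return(clashes)
  }
  merged <- a
  for (i in seq_along(b$records)) {
    rb <- b$records[[i]]
    j <- domain_find(merged, rb$identifier)
    if (is.null(j)) {
      merged$records <- c(merged$records, list(rb))
    } else {
      ra <- merged$records[[j]]
      extra <- setdiff(c(if (rb$current_label != ra$current_label) rb$current_label,
                         rb$aliases),
                       c(ra$current_label, ra$aliases))
      ra$aliases <- c(ra$aliases, extra)
      if (rb$status == "withdrawn") ra$status <- "withdrawn"
      if (nzchar(rb$notes) && !identical(rb$notes, ra$notes)) {
        ra$notes <- if (nzchar(ra$notes)) paste(ra$notes, rb$notes, sep = "; ") else rb$notes
      }
      merged$records[[j]] <- ra
    }
  }
  aud <- audit_registry(merged)
  aud <- aud[aud$severity == "error", , drop = FALSE]
  if (nrow(aud)) {
    clashes <- data.frame(kind = "audit_failure", identifier_a = NA_character_,
                          identifier_b = NA_character_, detail = aud$message,
                          stringsAsFactors = FALSE)
    class(clashes) <- c("clash_report", "data.frame")
    return(clashes)
  }
  merged
}
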