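test_that("JSON serialisation round-trips and is canonical", {
  s <- generate_set(synth_spec(seed = 21, n_base_alleles = 3,
                               alleles_per_gene = 2, truncation_prob = 0.3))
  s$allele_descriptions[[1]]$gapped_sequence <- chartr(
    "x", ".", s$allele_descriptions[[1]]$coding_sequence)  # no-op gap form
  s$allele_descriptions[[2]]$aliases <- "IGHV1-OLD*01"
  s$allele_descriptions[[2]]$delineations <- list(delineation(
    "IMGT", data.frame(region_name = c("FR1", "CDR1"),
                       start = c(1L, 40L), end = c(30L, 55L))))
  s$allele_descriptions[[3]]$evidence <- list(supporting_evidence(
    "inferred", repository = "ENA", accession = "X999", notes = "n"))
  txt <- write_germline_set(s)
  expect_identical(read_germline_set(txt), s)
  expect_identical(write_germline_set(read_germline_set(txt)), txt)
  expect_identical(write_germline_set(s), txt)  # write twice: same bytes
  expect_true(endsWith(txt, "\n"))
  expect_false(grepl("\r", txt))
})

test_that("JSON reader rejects bad schema versions and missing fields", {
  s <- generate_set(synth_spec(seed = 22, n_base_alleles = 2))
  txt <- write_germline_set(s)
  expect_error(read_germline_set(sub("germline-kit-1.0", "germline-kit-9.9", txt)),
               "schema_version")
  x <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  x$locus <- NULL
  broken <- jsonlite::toJSON(x, auto_unbox = TRUE, na = "null")
  expect_error(read_germline_set(as.character(broken)), "\\$\\.locus")
})

test_that("canonical form is stable on randomised sets", {
  set.seed(300)
  for (seed in c(31, 32, 33)) {
    s <- generate_set(synth_spec(seed = seed,
                                 n_base_alleles = sample(2:8, 1),
                                 truncation_prob = 0.2))
    w1 <- write_germline_set(s)
    w2 <- write_germline_set(read_germline_set(w1))
    expect_identical(w2, w1)
  }
})

test_that("FASTA export wraps at 60 columns and keeps labels as headers", {
  a <- tiny_allele("IGHV0-A5B2*00", "ACGT")
  s1 <- tiny_set(list(a))
  expect_identical(export_fasta(s1), ">IGHV0-A5B2*00\nACGT\n")

  long <- tiny_allele("IGHV0-AAAB*00", strrep("ACGTA", 13))  # 65 nt
  lines <- strsplit(export_fasta(tiny_set(list(long))), "\n")[[1]]
  expect_identical(nchar(lines), c(14L, 60L, 5L))  # header, then 60 + 5 nt

  exact <- tiny_allele("IGHV0-AAAC*00", random_nt(61))
  lines61 <- strsplit(export_fasta(tiny_set(list(exact))), "\n")[[1]]
  expect_identical(nchar(lines61[-1]), c(60L, 1L))
})

test_that("gapped FASTA export degaps back to the coding sequences", {
  set.seed(41)
  ads <- lapply(1:4, function(i) {
    core <- random_nt(90)
    # scatter gap characters through the core to form the aligned view
    pieces <- strsplit(core, "")[[1]]
    gaps <- sort(sample(90, 6))
    gapped <- paste(unlist(Map(function(ch, j) {
      if (j %in% gaps) paste0(ch, ".") else ch
    }, pieces, seq_along(pieces))), collapse = "")
    tiny_allele(sprintf("IGHV0-AAA%s*00", LETTERS[i]), core,
                gapped_sequence = gapped)
  })
  s <- tiny_set(ads)
  txt <- export_fasta(s, gapped = TRUE)
  recs <- strsplit(txt, ">")[[1]][-1]
  for (r in recs) {
    ln <- strsplit(r, "\n")[[1]]
    lab <- ln[1]
    seqs <- paste(ln[-1], collapse = "")
    expect_identical(degap(seqs), find_allele(s, lab)$coding_sequence)
  }
  # J/D alleles have no gapped form and are emitted ungapped
  j <- tiny_allele("IGHJ0-AAAJ*00", "ACGTACGT", sequence_type = "J")
  expect_identical(export_fasta(tiny_set(list(j)), gapped = TRUE),
                   ">IGHJ0-AAAJ*00\nACGTACGT\n")
  # a V allele without a gapped sequence blocks gapped export by name
  bare <- tiny_allele("IGHV0-BARE*00", "ACGT")
  expect_error(export_fasta(tiny_set(list(bare, j)), gapped = TRUE),
               "IGHV0-BARE\\*00")
})

test_that("FASTA import builds a skeleton set and rejects duplicate headers", {
  txt <- ">IGHV0-AAAA*00 first\nACGTACGT\n>IGHJ0-AAAA*00\nTTTTCCCC\n"
  s <- import_fasta(txt, locus = "IGH", species = "Mus musculus")
  expect_length(s$allele_descriptions, 2)
  labs <- vapply(s$allele_descriptions, `[[`, "", "label")
  expect_setequal(labs, c("IGHV0-AAAA*00", "IGHJ0-AAAA*00"))
  expect_identical(find_allele(s, "IGHJ0-AAAA*00")$sequence_type, "J")
  expect_identical(find_allele(s, "IGHV0-AAAA*00")$sequence_type, "V")
  expect_identical(s$release_version, 1L)
  expect_error(import_fasta(">A*1\nACGT\n>A*1\nACGT\n", "IGH", "m"),
               "duplicate")
})

test_that("FASTA export then import recovers every label/sequence pair", {
  s <- generate_set(synth_spec(seed = 61, n_base_alleles = 10,
                               truncation_prob = 0.2))
  imp <- import_fasta(export_fasta(s), locus = "IGH",
                      species = s$species$label)
  pair <- function(x) vapply(x$allele_descriptions, function(a) {
    paste(a$label, a$coding_sequence)
  }, "")
  expect_identical(sort(pair(imp)), sort(pair(s)))
})

test_that("release diffs identify additions, removals and modifications", {
  s <- suppressWarnings(generate_set(synth_spec(seed = 71, n_base_alleles = 5)))
  expect_true(is_empty_diff(diff_sets(s, s)))

  removed <- s
  gone <- removed$allele_descriptions[[3]]$label
  removed$allele_descriptions <- removed$allele_descriptions[-3]
  d <- diff_sets(s, removed)
  expect_identical(d$removed, gone)
  expect_length(d$added, 0)
  expect_length(d$modified, 0)

  mut <- s
  cs <- mut$allele_descriptions[[2]]$coding_sequence
  substr(cs, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(cs, 5, 5))[1]
  mut$allele_descriptions[[2]]$coding_sequence <- cs
  d2 <- diff_sets(s, mut)
  expect_identical(names(d2$modified), mut$allele_descriptions[[2]]$label)
  expect_identical(d2$modified[[1]], "coding_sequence")

  # a pure rename (alias retained) is a modification on "label"
  ren <- s
  old_lab <- ren$allele_descriptions[[1]]$label
  ren$allele_descriptions[[1]]$label <- "IGHV4-A5B2*01"
  ren$allele_descriptions[[1]]$aliases <- old_lab
  d3 <- diff_sets(s, ren)
  expect_length(d3$added, 0)
  expect_length(d3$removed, 0)
  expect_setequal(d3$modified[["IGHV4-A5B2*01"]], c("label", "aliases"))

  other <- suppressWarnings(generate_set(synth_spec(locus = "TRB", seed = 72,
                                                    n_base_alleles = 2)))
  expect_error(diff_sets(s, other), "not comparable")
})

test_that("diff is anti-symmetric on randomised set pairs", {
  for (seed in c(81, 82, 83)) {
    a <- generate_set(synth_spec(seed = seed, n_base_alleles = 6))
    b <- a
    drop <- sample(length(b$allele_descriptions), 2)
    b$allele_descriptions <- b$allele_descriptions[-drop]
    extra <- generate_set(synth_spec(seed = seed + 1000, n_base_alleles = 2))
    b$allele_descriptions <- c(b$allele_descriptions,
                               extra$allele_descriptions[1])
    b <- tiny_set(b$allele_descriptions, id = a$germline_set_id,
                  species = a$species$label)
    ab <- diff_sets(a, b)
    ba <- diff_sets(b, a)
    expect_identical(ab$added, ba$removed)
    expect_identical(ab$removed, ba$added)
  }
})

test_that("version bumps touch bookkeeping only", {
  s <- generate_set(synth_spec(seed = 91, n_base_alleles = 3))
  s2 <- bump_version(s, "second release", release_date = "2026-06-01")
  expect_identical(s2$release_version, 2L)
  expect_identical(s2$release_date, "2026-06-01")
  expect_identical(s2$release_description, "second release")
  expect_true(is_empty_diff(diff_sets(s, s2)))
  s3 <- bump_version(s2, "third", release_date = "2026-07-01")
  expect_identical(s3$release_version, 3L)
  expect_identical(s3$release_date, "2026-07-01")
})
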