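test_that("similarity table rows map field-for-field", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# a comment line",
    "g1\tg2\t92.5\t300\t20\t1\t1\t300\t1\t300\t1e-50\t500",
    "g2\tg3\t88.0\t250\t30\t2\t1\t250\t1\t250\t2e-30\t410.5"
  ), tf)
  hits <- read_similarity_table(tf)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$query_id, c("g1", "g2"))
  expect_equal(hits$percent_identity, c(92.5, 88.0))
  expect_equal(hits$e_value, c(1e-50, 2e-30))
  expect_equal(hits$bit_score, c(500, 410.5))
})

test_that("empty similarity file yields an empty table with a warning", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), tf)
  expect_warning(hits <- read_similarity_table(tf), "empty")
  expect_equal(nrow(hits), 0L)
  expect_named(hits, c("query_id", "subject_id", "percent_identity",
                       "alignment_length", "mismatches", "gap_opens",
                       "query_start", "query_end", "subject_start",
                       "subject_end", "e_value", "bit_score"))
})

test_that("malformed similarity lines are rejected with the line number", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "g1\tg2\t92.5\t300\t20\t1\t1\t300\t1\t300\t1e-50\t500",
    "g1\tg2\t92.5\t300"
  ), tf)
  expect_error(read_similarity_table(tf), "line 2.*12")
  writeLines("g1\tg2\tnot_a_number\t300\t20\t1\t1\t300\t1\t300\t1e-50\t500", tf)
  expect_error(read_similarity_table(tf), "line 1")
  writeLines("g1\tg2\t101\t300\t20\t1\t1\t300\t1\t300\t1e-50\t500", tf)
  expect_error(read_similarity_table(tf), "identity")
})

test_that("similarity write -> read round-trips a generated table", {
  set.seed(11)
  hits <- make_hits(
    query = sprintf("q%02d", 1:10), subject = sprintf("s%02d", 1:10),
    identity = round(runif(10, 60, 100), 1),
    evalue = 10^-sample(6:60, 10), bit = round(runif(10, 50, 900), 1)
  )
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_table(hits, tf)
  back <- read_similarity_table(tf)
  expect_equal(back, hits)
})

test_that("signature table parses one row per match and tolerates extras", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("p1", "abc", "300", "Pfam", "PF00504",
          "Chlorophyll A-B binding protein", "10", "120", "1.2E-30",
          "T", "2021-01-01", "IPR001344", "Chlorophyll A-B", sep = "\t"),
    paste("p1", "abc", "300", "Pfam", "PF00078", "Reverse transcriptase",
          "130", "290", "5.0E-20", "T", "2021-01-01", "-", "-",
          "GO:0003964", "extra_pathway_col", sep = "\t")
  ), tf)
  sig <- read_signature_table(tf)
  expect_equal(nrow(sig), 2L)
  expect_equal(unique(sig$protein_id), "p1")
  expect_equal(unique(sig$sequence_length), 300L)
  # 15-column row parsed, columns 14+ dropped, "-" mapped to empty
  expect_equal(sig$interpro_accession, c("IPR001344", ""))
  expect_equal(ncol(sig), 13L)
})

test_that("signature validation catches bad lengths and coordinates", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  row <- function(len, start, end)
    paste("p1", "x", len, "Pfam", "PF00504", "d", start, end,
          "1e-5", "T", "2021-01-01", "-", "-", sep = "\t")
  writeLines(row("0", "1", "10"), tf)
  expect_error(read_signature_table(tf), "sequence_length")
  writeLines(row("100", "50", "120"), tf)
  expect_error(read_signature_table(tf), "coordinates")
})

test_that("signature write -> read round-trips", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("p1", "abc", "300", "Pfam", "PF00504", "desc", "10",
                   "120", "1.5", "T", "2021-01-01", "IPR001344", "idesc",
                   sep = "\t"), tf)
  sig <- read_signature_table(tf)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_signature_table(sig, tf2)
  expect_equal(read_signature_table(tf2), sig)
})

test_that("KO assignments parse, collapse duplicates, and flag bad tokens", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("geneA\tK02639", "geneB\t", "geneC\tK00001",
               "geneC\tK00002"), tf)
  ko <- read_ko_file(tf)
  expect_equal(ko$ko_accession[ko$gene_id == "geneA"], "K02639")
  expect_equal(ko$ko_accession[ko$gene_id == "geneB"], "")
  # duplicate gene rows: first KO kept
  expect_equal(ko$ko_accession[ko$gene_id == "geneC"], "K00001")
  expect_equal(nrow(ko), 3L)

  writeLines(c("geneA\tnot_a_ko", "geneB\tK12345"), tf)
  expect_warning(ko2 <- read_ko_file(tf), "K#####")
  expect_equal(ko2$ko_accession, c("", "K12345"))
})

test_that("duplicate gene with empty-then-real KO keeps the real one", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("geneA\t", "geneA\tK02639"), tf)
  ko <- read_ko_file(tf)
  expect_equal(ko$ko_accession, "K02639")
})

test_that("FASTA lengths handle LF, CRLF and reject duplicates", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 some description", "MKV", ">g2", "MKVLTT"), tf)
  expect_equal(read_fasta_lengths(tf), c(g1 = 3L, g2 = 6L))

  crlf <- withr::local_tempfile(fileext = ".fasta")
  writeBin(charToRaw(">g1\r\nMKV\r\n>g2\r\nMKVLTT\r\n"), crlf)
  expect_equal(read_fasta_lengths(crlf), c(g1 = 3L, g2 = 6L))

  writeLines(c(">g1", "MKV", ">g1", "MK"), tf)
  expect_error(read_fasta_lengths(tf), "duplicate")
})

test_that("generated FASTA lengths match the generator's ground truth", {
  fams <- lapply(1:20, function(i)
    planted_family(sprintf("f%02d", i), copy_count = 5,
                   length_base = 100 + 17 * i, length_jitter = 3))
  bundle <- generate_hsd_dataset(fams, seed = 3,
                                 dir = withr::local_tempdir())
  lens <- read_fasta_lengths(bundle$paths$fasta)
  expect_equal(lens[bundle$genes$gene_id],
               stats::setNames(bundle$genes$length, bundle$genes$gene_id))
  expect_equal(length(lens), 100L)
})

test_that("HSD table writes 8 columns and round-trips group membership", {
  fams <- mixed_family_spec()
  bundle <- generate_hsd_dataset(fams, seed = 5, dir = withr::local_tempdir())
  groups <- suppressMessages(find_hsds(
    bundle$paths$similarity, bundle$paths$signatures, bundle$paths$fasta))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_hsd_table(groups, tf, provenance = "test run")
  raw <- readLines(tf)
  body <- raw[!grepl("^#", raw)]
  expect_true(all(lengths(strsplit(body, "\t")) == 8L))
  back <- read_hsd_table(tf)
  expect_equal(partition_of(back$members), partition_of(groups$members))
  expect_equal(back$classification, groups$classification)
  expect_equal(back$space_flag, groups$space_flag)
  expect_equal(back$member_lengths, groups$member_lengths)
})

test_that("an empty group list writes a header-only file", {
  empty <- cluster_groups(make_hits(character(0), character(0),
                                    numeric(0))[0, ] |>
                            filter_edges(make_genes(character(0), integer(0))))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_hsd_table(empty, tf)
  raw <- readLines(tf)
  expect_true(all(grepl("^#", raw)))
  expect_equal(nrow(read_hsd_table(tf)), 0L)
})

test_that("category map reads 3 or 4 columns and deduplicates", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("K02639\t09102\tEnergy metabolism\tferredoxin",
               "K02639\t09102\tEnergy metabolism\tferredoxin",
               "K13979\t09101\tCarbohydrate metabolism"), tf)
  cm <- read_category_map(tf)
  expect_equal(nrow(cm), 2L)
  expect_equal(cm$ko_description, c("ferredoxin", ""))
})
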