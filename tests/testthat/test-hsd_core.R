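test_that("gene records collect Pfam and InterPro profiles per protein", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("p1", "x", "300", "Pfam", "PF00504", "Chlorophyll A-B", "10",
          "120", "1e-30", "T", "d", "IPR001344", "Chl", sep = "\t"),
    paste("p1", "x", "300", "Pfam", "PF00078", "RT", "130", "290",
          "1e-20", "T", "d", "IPR000477", "RT", sep = "\t"),
    paste("p1", "x", "300", "MobiDBLite", "mobidb-lite", "disorder",
          "1", "30", "-", "T", "d", "-", "-", sep = "\t"),
    paste("p2", "x", "280", "Pfam", "PF00504", "Chlorophyll A-B", "5",
          "110", "1e-25", "T", "d", "IPR001344", "Chl", sep = "\t")
  ), tf)
  genes <- build_gene_records(read_signature_table(tf),
                              fasta_lengths = c(p3 = 99L))
  expect_setequal(genes$gene_id, c("p1", "p2", "p3"))
  p1 <- genes[genes$gene_id == "p1", ]
  expect_equal(p1$pfam_profile[[1]], c("PF00078", "PF00504"))
  expect_equal(p1$interpro_profile[[1]], c("IPR000477", "IPR001344"))
  expect_equal(p1$length, 300L)
  # non-Pfam analyses never enter the Pfam profile
  expect_false("mobidb-lite" %in% p1$pfam_profile[[1]])
  # FASTA-only protein: length from FASTA, empty profiles
  p3 <- genes[genes$gene_id == "p3", ]
  expect_equal(p3$length, 99L)
  expect_length(p3$pfam_profile[[1]], 0L)
})

test_that("conflicting annotated lengths for one protein raise an error", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("p1", "x", "300", "Pfam", "PF00504", "d", "1", "100", "1e-5",
          "T", "d", "-", "-", sep = "\t"),
    paste("p1", "x", "310", "Pfam", "PF00078", "d", "1", "100", "1e-5",
          "T", "d", "-", "-", sep = "\t")
  ), tf)
  expect_error(build_gene_records(read_signature_table(tf)), "p1")
})

test_that("edge filtering applies identity, length and E-value thresholds", {
  genes <- make_genes(c("a", "b", "c", "d"), c(300, 305, 300, 400))
  hits <- rbind(
    make_hits("a", "b", 92.0),               # qualifies
    make_hits("a", "a", 100),                # self-hit, dropped
    make_hits("a", "c", 89.9),               # identity below default
    make_hits("a", "d", 95.0),               # length differs by 100
    make_hits("b", "c", 95.0, evalue = 1e-3) # E-value above cutoff
  )
  edges <- filter_edges(hits, genes)
  expect_equal(nrow(edges), 1L)
  expect_equal(c(edges$gene_a, edges$gene_b), c("a", "b"))
  # the 89.9% pair appears at the relaxed 80% setting
  edges80 <- filter_edges(hits, genes, threshold_config(identity_min = 80))
  expect_true(any(edges80$gene_a == "a" & edges80$gene_b == "c"))
})

test_that("thresholds are inclusive at their boundaries", {
  genes <- make_genes(c("a", "b"), c(300, 310))  # |diff| exactly 10
  hits <- make_hits("a", "b", 90.0, evalue = 1e-5)  # both at the boundary
  expect_equal(nrow(filter_edges(hits, genes)), 1L)
  genes11 <- make_genes(c("a", "b"), c(300, 311))
  expect_equal(nrow(filter_edges(hits, genes11)), 0L)
})

test_that("best hit per pair is chosen by bit score, first seen on ties", {
  genes <- make_genes(c("a", "b"), c(300, 302))
  hits <- rbind(
    make_hits("a", "b", 95.0, bit = 400),
    make_hits("b", "a", 85.0, bit = 600)  # higher bit score governs
  )
  edges <- filter_edges(hits, genes, threshold_config(identity_min = 90))
  expect_equal(nrow(edges), 0L)  # best hit (85%) fails the 90% cutoff
  edges80 <- filter_edges(hits, genes, threshold_config(identity_min = 80))
  expect_equal(edges80$best_identity, 85.0)
  expect_equal(edges80$best_bit_score, 600)
  # tie on bit score: first encountered wins
  tie <- rbind(make_hits("a", "b", 95.0, bit = 500),
               make_hits("a", "b", 91.0, bit = 500))
  expect_equal(filter_edges(tie, genes)$best_identity, 95.0)
})

test_that("pairs with unknown lengths are excluded and counted", {
  genes <- make_genes(c("a", "b", "c"), c(300, NA, 302))
  hits <- rbind(make_hits("a", "b", 95.0), make_hits("a", "c", 95.0))
  edges <- filter_edges(hits, genes)
  expect_equal(nrow(edges), 1L)
  expect_equal(attr(edges, "skipped_no_length"), 1L)
})

test_that("filtering is invariant under query/subject swap", {
  set.seed(42)
  ids <- sprintf("g%03d", 1:40)
  genes <- make_genes(ids, sample(280:320, 40, replace = TRUE))
  n <- 200
  hits <- make_hits(sample(ids, n, TRUE), sample(ids, n, TRUE),
                    identity = round(runif(n, 70, 100), 1),
                    evalue = 10^-sample(3:60, n, TRUE),
                    bit = round(runif(n, 100, 900), 1))
  swapped <- hits
  swapped$query_id <- hits$subject_id
  swapped$subject_id <- hits$query_id
  e1 <- filter_edges(hits, genes)
  e2 <- filter_edges(swapped, genes)
  key <- function(e) sort(paste(e$gene_a, e$gene_b))
  expect_equal(key(e1), key(e2))
})

test_that("qualifying pairs equal an independent brute-force re-scan", {
  for (seed in 1:5) {
    set.seed(seed)
    ids <- sprintf("g%03d", 1:30)
    genes <- make_genes(ids, sample(250:350, 30, replace = TRUE))
    n <- 200
    hits <- make_hits(sample(ids, n, TRUE), sample(ids, n, TRUE),
                      identity = round(runif(n, 60, 100), 1),
                      evalue = 10^-sample(0:60, n, TRUE),
                      bit = round(runif(n, 100, 900), 1))
    cfg <- threshold_config(identity_min = 85, length_diff_max = 20)
    edges <- filter_edges(hits, genes, cfg)
    # naive oracle: scan every row, track best per unordered pair
    len <- stats::setNames(genes$length, genes$gene_id)
    best <- list()
    for (r in seq_len(nrow(hits))) {
      q <- hits$query_id[r]; s <- hits$subject_id[r]
      if (q == s) next
      k <- paste(min(q, s), max(q, s))
      if (is.null(best[[k]]) || hits$bit_score[r] > best[[k]]$bit) {
        best[[k]] <- list(id = hits$percent_identity[r],
                          ev = hits$e_value[r], bit = hits$bit_score[r],
                          a = min(q, s), b = max(q, s))
      }
    }
    want <- sort(vapply(
      Filter(function(h) h$ev <= cfg$evalue_max && h$id >= cfg$identity_min &&
               abs(len[h$a] - len[h$b]) <= cfg$length_diff_max, best),
      function(h) paste(h$a, h$b), character(1)))
    expect_equal(sort(paste(edges$gene_a, edges$gene_b)), unname(want))
  }
})

test_that("edge counts are monotone in the thresholds", {
  set.seed(99)
  ids <- sprintf("g%03d", 1:50)
  genes <- make_genes(ids, sample(250:350, 50, replace = TRUE))
  n <- 400
  hits <- make_hits(sample(ids, n, TRUE), sample(ids, n, TRUE),
                    identity = round(runif(n, 50, 100), 1),
                    evalue = 10^-sample(0:60, n, TRUE),
                    bit = round(runif(n, 100, 900), 1))
  n_edges <- function(id, len) nrow(filter_edges(
    hits, genes, threshold_config(identity_min = id, length_diff_max = len)))
  # raising identity_min never adds edges
  counts_id <- vapply(c(60, 70, 80, 90), n_edges, integer(1), len = 10)
  expect_true(all(diff(counts_id) <= 0))
  # raising length_diff_max never removes edges
  counts_len <- vapply(c(10, 30, 50, 70, 100), n_edges, integer(1), id = 60)
  expect_true(all(diff(counts_len) >= 0))
})

test_that("transitive link groups A, B and C together", {
  genes <- make_genes(c("A", "B", "C"), c(300, 301, 302))
  hits <- rbind(make_hits("A", "B", 95), make_hits("A", "C", 94))
  groups <- cluster_groups(filter_edges(hits, genes))
  expect_equal(nrow(groups), 1L)
  expect_equal(groups$members[[1]], c("A", "B", "C"))
  expect_equal(groups$group_id, "A")
})

test_that("disjoint pairs stay in separate groups", {
  edges <- data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
                      best_identity = 95, best_evalue = 1e-50,
                      best_bit_score = 500, stringsAsFactors = FALSE)
  groups <- cluster_groups(edges)
  expect_equal(groups$group_id, c("A", "C"))
  expect_equal(groups$size, c(2L, 2L))
})

test_that("components match a brute-force transitive closure on random graphs", {
  set.seed(2024)
  for (i in 1:20) {
    edges <- random_edges(n_genes = 300, n_edges = 400)
    groups <- cluster_groups(edges)
    oracle <- brute_force_components(
      lapply(seq_len(nrow(edges)), function(r)
        c(edges$gene_a[r], edges$gene_b[r])))
    expect_equal(partition_of(groups$members), partition_of(oracle))
  }
})

test_that("groups partition the incident genes exactly", {
  set.seed(7)
  edges <- random_edges(n_genes = 120, n_edges = 150)
  groups <- cluster_groups(edges)
  all_members <- unlist(groups$members)
  expect_false(anyDuplicated(all_members) > 0)
  expect_setequal(all_members, unique(c(edges$gene_a, edges$gene_b)))
  expect_true(all(groups$size >= 2L))
  expect_equal(groups$group_id,
               vapply(groups$members, `[`, character(1), 1L))
  expect_false(is.unsorted(groups$group_id))
})

test_that("copy-number histogram bins 2 / 3 / >=4 and sums correctly", {
  g <- data.frame(group_id = c("a", "c", "e", "h"),
                  stringsAsFactors = FALSE)
  g$members <- list(c("a", "b"), c("c", "d"), c("e", "f", "g"),
                    c("h", "i", "j", "k", "l"))
  g$size <- lengths(g$members)
  h <- copy_number_histogram(g)
  expect_equal(h[c("groups_2", "groups_3", "groups_4plus")],
               list(groups_2 = 2L, groups_3 = 1L, groups_4plus = 1L))
  expect_equal(h[c("copies_2", "copies_3", "copies_4plus")],
               list(copies_2 = 4L, copies_3 = 3L, copies_4plus = 5L))
  empty <- g[0, ]
  expect_equal(unlist(copy_number_histogram(empty)), c(
    groups_2 = 0L, groups_3 = 0L, groups_4plus = 0L,
    copies_2 = 0L, copies_3 = 0L, copies_4plus = 0L))
})
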