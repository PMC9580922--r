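# Candidate HSD detection: threshold configuration, per-gene records,
# qualifying-pair filtering and transitive-link clustering.

#' Threshold configuration for HSD detection
#'
#' The defaults encode the conservative setting recommended for
#' well-assembled genomes: copies must share at least 90% pairwise amino-acid
#' identity and have protein lengths within 10 amino acids of each other,
#' with alignment E-value at most 1e-5. A common relaxed setting keeps the
#' length bound and lowers identity to 80%.
#'
#' @param identity_min Minimum pairwise amino-acid identity in percent,
#'   inclusive; in (0, 100]. Default 90.
#' @param length_diff_max Maximum absolute protein length difference in
#'   amino acids, inclusive; >= 0. Default 10.
#' @param evalue_max Maximum alignment E-value, inclusive; > 0. Default 1e-5.
#' @return A list of class `hsd_thresholds`.
#' @export
#' @examples
#' threshold_config()               # strict default
#' threshold_config(identity_min = 80)  # relaxed identity
threshold_config <- function(identity_min = 90, length_diff_max = 10,
                             evalue_max = 1e-5) {
  stopifnot(
    is.numeric(identity_min), length(identity_min) == 1L,
    identity_min > 0, identity_min <= 100,
    is.numeric(length_diff_max), length(length_diff_max) == 1L,
    length_diff_max >= 0,
    is.numeric(evalue_max), length(evalue_max) == 1L, evalue_max > 0
  )
  structure(
    list(identity_min = identity_min, length_diff_max = length_diff_max,
         evalue_max = evalue_max),
    class = "hsd_thresholds"
  )
}

#' @export
print.hsd_thresholds <- function(x, ...) {
  cat(sprintf(
    "HSD thresholds: identity >= %g%%, |length difference| <= %g aa, E-value <= %g\n",
    x$identity_min, x$length_diff_max, x$evalue_max))
  invisible(x)
}

#' Assemble per-gene records from signature annotations
#'
#' Builds one record per protein: its length in residues and its
#' domain-signature profiles. The Pfam profile collects the distinct
#' signature accessions whose analysis field equals `pfam_analysis`; the
#' InterPro profile collects the distinct non-empty integrated accessions
#' over all of the protein's rows. Protein lengths are taken from the
#' signature table's sequence-length column; proteins present only in
#' `fasta_lengths` get their length from there with empty profiles. A
#' protein annotated with contradictory lengths is an error.
#'
#' @param signatures Signature table from [read_signature_table()].
#' @param fasta_lengths Optional named integer vector from
#'   [read_fasta_lengths()], used as a fallback length source and to register
#'   unannotated proteins.
#' @param pfam_analysis Name of the member-database analysis treated as Pfam
#'   (default `"Pfam"`).
#' @return A data frame keyed by `gene_id` with columns `length` (integer,
#'   `NA` when unknown) and list-columns `pfam_profile`, `interpro_profile`
#'   (character vectors of distinct accessions, sorted) and `descriptions`
#'   (named character vector, accession -> description).
#' @export
build_gene_records <- function(signatures, fasta_lengths = NULL,
                               pfam_analysis = "Pfam") {
  ids <- unique(c(signatures$protein_id, names(fasta_lengths)))
  by_prot <- split(seq_len(nrow(signatures)), signatures$protein_id)

  len <- rep(NA_integer_, length(ids))
  names(len) <- ids
  for (p in names(by_prot)) {
    l <- unique(signatures$sequence_length[by_prot[[p]]])
    if (length(l) > 1L) {
      stop("conflicting sequence lengths for protein ", p, ": ",
           paste(l, collapse = ", "), call. = FALSE)
    }
    len[p] <- l
  }
  if (!is.null(fasta_lengths)) {
    missing_len <- is.na(len) & ids %in% names(fasta_lengths)
    len[missing_len] <- fasta_lengths[ids[missing_len]]
  }

  pfam <- vector("list", length(ids)); names(pfam) <- ids
  ipr <- vector("list", length(ids)); names(ipr) <- ids
  desc <- vector("list", length(ids)); names(desc) <- ids
  pfam[] <- list(character(0)); ipr[] <- list(character(0))
  desc[] <- list(stats::setNames(character(0), character(0)))
  for (p in names(by_prot)) {
    rows <- signatures[by_prot[[p]], , drop = FALSE]
    is_pf <- rows$analysis == pfam_analysis
    pfam[[p]] <- sort(unique(rows$signature_accession[is_pf]))
    ipr_acc <- rows$interpro_accession[nzchar(rows$interpro_accession)]
    ipr[[p]] <- sort(unique(ipr_acc))
    d <- c(
      stats::setNames(rows$signature_description[is_pf],
                      rows$signature_accession[is_pf]),
      stats::setNames(rows$interpro_description[nzchar(rows$interpro_accession)],
                      ipr_acc)
    )
    desc[[p]] <- d[!duplicated(names(d))]
  }

  out <- data.frame(gene_id = ids, length = unname(len),
                    stringsAsFactors = FALSE)
  out$pfam_profile <- unname(pfam)
  out$interpro_profile <- unname(ipr)
  out$descriptions <- unname(desc)
  out
}

#' Filter qualifying gene pairs from similarity hits
#'
#' Self-hits are removed. For each unordered gene pair the best hit over both
#' directions is selected (maximum bit score, first encountered on ties). The
#' pair qualifies when that best hit has E-value <= `evalue_max`, percent
#' identity >= `identity_min`, both protein lengths are known, and the
#' absolute length difference is <= `length_diff_max`. Pairs whose genes lack
#' a length source are excluded and counted in the `skipped_no_length`
#' attribute rather than silently dropped.
#'
#' @param hits Similarity table from [read_similarity_table()].
#' @param genes Gene records from [build_gene_records()].
#' @param cfg Thresholds from [threshold_config()].
#' @return Data frame of qualifying edges with columns `gene_a`, `gene_b`
#'   (with `gene_a` < `gene_b`), `best_identity`, `best_evalue`,
#'   `best_bit_score`; attribute `skipped_no_length` counts pairs excluded
#'   for missing lengths.
#' @export
filter_edges <- function(hits, genes, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "hsd_thresholds"))
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      best_identity = numeric(0), best_evalue = numeric(0),
                      best_bit_score = numeric(0), stringsAsFactors = FALSE)
  attr(empty, "skipped_no_length") <- 0L
  if (nrow(hits) == 0L) return(empty)

  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)

  a <- pmin(h$query_id, h$subject_id)
  b <- pmax(h$query_id, h$subject_id)
  key <- paste(a, b, sep = "\r")
  # best hit per unordered pair: max bit score, first seen wins ties
  ord <- order(match(key, unique(key)), -h$bit_score,
               seq_len(nrow(h)))
  first <- !duplicated(key[ord])
  sel <- ord[first]
  best <- data.frame(gene_a = a[sel], gene_b = b[sel],
                     best_identity = h$percent_identity[sel],
                     best_evalue = h$e_value[sel],
                     best_bit_score = h$bit_score[sel],
                     stringsAsFactors = FALSE)

  len <- stats::setNames(genes$length, genes$gene_id)
  la <- len[best$gene_a]
  lb <- len[best$gene_b]
  pass_thresh <- best$best_evalue <= cfg$evalue_max &
    best$best_identity >= cfg$identity_min
  no_len <- is.na(la) | is.na(lb)
  skipped <- sum(pass_thresh & no_len)
  qual <- pass_thresh & !no_len & abs(la - lb) <= cfg$length_diff_max
  out <- best[qual, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_no_length") <- as.integer(skipped)
  out
}

#' Cluster qualifying pairs into HSD groups by transitive linkage
#'
#' Groups are the connected components of the undirected graph whose
#' vertices are genes and whose edges are the qualifying pairs: if copy A is
#' highly similar to copies B and C, then A, B and C fall in one group even
#' when B and C themselves miss the thresholds. Singletons are never
#' emitted. The group identifier is the lexicographically smallest member
#' gene id; members are sorted and groups ordered by identifier.
#'
#' @param edges Edge table from [filter_edges()].
#' @param genes Optional gene records; when supplied, member protein lengths
#'   and domain annotations are attached to each group.
#' @return Data frame with columns `group_id`, `size` and list-column
#'   `members`; with `genes`, also list-columns `member_lengths`,
#'   `pfam_accessions`, `pfam_descriptions`, `interpro_accessions`,
#'   `interpro_descriptions`.
#' @export
cluster_groups <- function(edges, genes = NULL) {
  out <- data.frame(group_id = character(0), size = integer(0),
                    stringsAsFactors = FALSE)
  out$members <- list()
  if (nrow(edges) == 0L) {
    if (!is.null(genes)) out <- .annotate_groups(out, genes)
    return(out)
  }
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, function(m) sort(unname(m)))
  gid <- vapply(members, `[`, character(1L), 1L)
  ord <- order(gid)
  out <- data.frame(group_id = gid[ord], stringsAsFactors = FALSE)
  out$members <- unname(members[ord])
  out$size <- lengths(out$members)
  rownames(out) <- NULL
  if (!is.null(genes)) out <- .annotate_groups(out, genes)
  out
}

.annotate_groups <- function(groups, genes) {
  idx <- stats::setNames(seq_len(nrow(genes)), genes$gene_id)
  groups$member_lengths <- lapply(groups$members, function(m)
    unname(genes$length[idx[m]]))
  groups$pfam_accessions <- lapply(groups$members, function(m)
    sort(unique(unlist(genes$pfam_profile[idx[m]]))))
  groups$interpro_accessions <- lapply(groups$members, function(m)
    sort(unique(unlist(genes$interpro_profile[idx[m]]))))
  all_desc <- function(m, acc) {
    d <- unlist(genes$descriptions[idx[m]])
    d <- d[!duplicated(names(d))]
    unname(d[acc])
  }
  groups$pfam_descriptions <- mapply(
    function(m, acc) all_desc(m, acc),
    groups$members, groups$pfam_accessions, SIMPLIFY = FALSE)
  groups$interpro_descriptions <- mapply(
    function(m, acc) all_desc(m, acc),
    groups$members, groups$interpro_accessions, SIMPLIFY = FALSE)
  groups
}

#' Copy-number histogram of HSD groups
#'
#' Tallies groups with exactly 2, exactly 3, and at least 4 gene copies,
#' along with the total gene copies falling in each bin.
#'
#' @param groups Group table from [cluster_groups()].
#' @return A list with integer fields `groups_2`, `groups_3`,
#'   `groups_4plus`, `copies_2`, `copies_3`, `copies_4plus`.
#' @export
#' @examples
#' g <- data.frame(group_id = c("a", "c", "e", "h"))
#' g$members <- list(c("a","b"), c("c","d"), c("e","f","g"),
#'                   c("h","i","j","k","l"))
#' g$size <- lengths(g$members)
#' copy_number_histogram(g)
copy_number_histogram <- function(groups) {
  s <- groups$size
  list(
    groups_2 = sum(s == 2L), groups_3 = sum(s == 3L),
    groups_4plus = sum(s >= 4L),
    copies_2 = sum(s[s == 2L]), copies_3 = sum(s[s == 3L]),
    copies_4plus = sum(s[s >= 4L])
  )
}
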