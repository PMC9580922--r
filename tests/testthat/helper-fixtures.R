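# Shared fixture builders: similarity rows, gene-record tables and random
# edge lists, all constructed in code.

make_hits <- function(query, subject, identity, evalue = 1e-50,
                      bit = 500, aln = 300) {
  n <- length(query)
  data.frame(
    query_id = query, subject_id = subject,
    percent_identity = rep_len(identity, n),
    alignment_length = rep_len(aln, n),
    mismatches = rep_len(5, n), gap_opens = rep_len(0, n),
    query_start = rep_len(1, n), query_end = rep_len(aln, n),
    subject_start = rep_len(1, n), subject_end = rep_len(aln, n),
    e_value = rep_len(evalue, n), bit_score = rep_len(bit, n),
    stringsAsFactors = FALSE
  )
}

make_genes <- function(ids, lengths, pfam = NULL, interpro = NULL) {
  n <- length(ids)
  if (is.null(pfam)) pfam <- rep(list(character(0)), n)
  if (is.null(interpro)) interpro <- rep(list(character(0)), n)
  out <- data.frame(gene_id = ids, length = as.integer(lengths),
                    stringsAsFactors = FALSE)
  out$pfam_profile <- pfam
  out$interpro_profile <- interpro
  out$descriptions <- rep(list(stats::setNames(character(0), character(0))), n)
  out
}

# random undirected edge list over gene ids g001..g<n>
random_edges <- function(n_genes, n_edges) {
  ids <- sprintf("g%03d", seq_len(n_genes))
  a <- sample(ids, n_edges, replace = TRUE)
  b <- sample(ids, n_edges, replace = TRUE)
  keep <- a != b
  data.frame(gene_a = pmin(a[keep], b[keep]), gene_b = pmax(a[keep], b[keep]),
             best_identity = 95, best_evalue = 1e-50, best_bit_score = 500,
             stringsAsFactors = FALSE)
}

# canonical representation of a group partition for comparisons
partition_of <- function(members_list) {
  unname(lapply(members_list, function(m) sort(unname(m))))
}

mixed_family_spec <- function() {
  list(
    planted_family("famA", 3, "true"),
    planted_family("famB", 2, "space"),
    planted_family("famC", 3, "incomplete"),
    planted_family("famD", 2, "near_miss_identity"),
    planted_family("famE", 3, "near_miss_length"),
    planted_family("famF", 5, "true", pfam_profile = c("PF00125", "PF01015"),
                   ko = "K02868"),
    planted_family("famG", 2, "true", ko = "K02639")
  )
}

load_bundle_genes <- function(bundle) {
  build_gene_records(
    read_signature_table(bundle$paths$signatures),
    read_fasta_lengths(bundle$paths$fasta)
  )
}
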