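# High-level one-call pipeline: files in, classified HSD table out.

#' Detect highly similar duplicated genes from input files
#'
#' Runs the full detection pipeline: parse the 12-column similarity table
#' and 13-column signature table, assemble gene records (FASTA lengths as
#' fallback), filter qualifying pairs, cluster by transitive linkage,
#' classify by domain-profile agreement, and optionally write the 8-column
#' HSD table. Stage counts are reported via `message()`.
#'
#' @param similarity_path 12-column all-vs-all similarity TSV.
#' @param signature_path 13-column InterProScan TSV.
#' @param fasta_path Optional protein FASTA (fallback length source).
#' @param cfg Thresholds from [threshold_config()].
#' @param out_path Optional output path for the 8-column HSD table.
#' @param provenance Write provenance comment lines (tool version,
#'   thresholds, input checksums) into `out_path`.
#' @param profile Domain profile used for classification (see
#'   [classify_groups()]).
#' @return The classified, annotated group table (invisibly when
#'   `out_path` is given).
#' @export
find_hsds <- function(similarity_path, signature_path, fasta_path = NULL,
                      cfg = threshold_config(), out_path = NULL,
                      provenance = TRUE, profile = "pfam") {
  hits <- read_similarity_table(similarity_path)
  signatures <- read_signature_table(signature_path)
  fasta_lengths <- if (!is.null(fasta_path)) read_fasta_lengths(fasta_path)
  genes <- build_gene_records(signatures, fasta_lengths)
  message(sprintf("read %d similarity hits, %d signature rows, %d genes",
                  nrow(hits), nrow(signatures), nrow(genes)))
  edges <- filter_edges(hits, genes, cfg)
  message(sprintf("%d qualifying pairs (%d skipped for unknown length)",
                  nrow(edges), attr(edges, "skipped_no_length")))
  groups <- cluster_groups(edges, genes)
  groups <- classify_groups(groups, genes, profile = profile)
  tal <- tally_classifications(groups)
  message(sprintf("%d HSD groups: %d true (%d space), %d incomplete",
                  tal$candidate, tal$true_count, tal$space, tal$incomplete))
  if (!is.null(out_path)) {
    prov <- if (isTRUE(provenance)) .provenance_lines(
      cfg, c(similarity_path, signature_path, fasta_path))
    write_hsd_table(groups, out_path, provenance = prov)
    return(invisible(groups))
  }
  groups
}

.provenance_lines <- function(cfg, inputs) {
  sums <- tools::md5sum(inputs[!vapply(inputs, is.null, logical(1L))])
  c(
    sprintf("hsdetect %s", as.character(utils::packageVersion("hsdetect"))),
    sprintf("thresholds: identity>=%g%% length_diff<=%g evalue<=%g",
            cfg$identity_min, cfg$length_diff_max, cfg$evalue_max),
    sprintf("input md5 %s %s", basename(names(sums)), unname(sums))
  )
}
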