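# Readers and writers for every external tabular format the pipeline touches.
# All readers skip comment lines (leading '#'), preserve row order and never
# reinterpret locale: decimal points only, scientific notation accepted.

SIMILARITY_COLS <- c(
  "query_id", "subject_id", "percent_identity", "alignment_length",
  "mismatches", "gap_opens", "query_start", "query_end",
  "subject_start", "subject_end", "e_value", "bit_score"
)

SIGNATURE_COLS <- c(
  "protein_id", "sequence_md5", "sequence_length", "analysis",
  "signature_accession", "signature_description", "match_start", "match_end",
  "score", "status", "run_date", "interpro_accession", "interpro_description"
)

HSD_TABLE_COLS <- c(
  "hsd_id", "members", "lengths", "pfam_accessions", "pfam_descriptions",
  "interpro_accessions", "interpro_descriptions", "classification"
)

# Read lines of a tab-delimited file, dropping comment ('#') and blank lines
# but remembering the original line number of each retained line.
.read_data_lines <- function(path) {
  if (!file.exists(path)) {
    stop("file does not exist: ", path, call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", raw) & nzchar(trimws(raw))
  list(lines = raw[keep], lineno = which(keep))
}

.split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

.parse_numeric <- function(x, what, lineno) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("line %d: cannot parse %s value '%s'", lineno[i], what, x[i]),
         call. = FALSE)
  }
  out
}

#' Read a 12-column all-vs-all protein similarity table
#'
#' Parses the standard 12-column tab-delimited alignment report (the BLAST
#' `-outfmt 6` dialect: query, subject, percent identity, alignment length,
#' mismatches, gap opens, query/subject start/end, E-value, bit score).
#' Comment lines starting with `#` are skipped; row order is preserved.
#'
#' @param path Path to the tab-delimited file.
#' @return A data frame with one row per alignment and columns
#'   `query_id`, `subject_id`, `percent_identity`, `alignment_length`,
#'   `mismatches`, `gap_opens`, `query_start`, `query_end`, `subject_start`,
#'   `subject_end`, `e_value`, `bit_score`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("g1\tg2\t92.5\t300\t20\t1\t1\t300\t1\t300\t1e-50\t500", tf)
#' read_similarity_table(tf)
read_similarity_table <- function(path) {
  dat <- .read_data_lines(path)
  if (length(dat$lines) == 0L) {
    warning("similarity table is empty: ", path)
    out <- as.data.frame(setNames(rep(list(character(0)), 12), SIMILARITY_COLS))
    num <- SIMILARITY_COLS[3:12]
    out[num] <- lapply(out[num], as.numeric)
    return(out)
  }
  fields <- .split_fields(dat$lines)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1L]
    stop(sprintf("line %d: expected 12 tab-separated fields, found %d",
                 dat$lineno[i], nf[i]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    stringsAsFactors = FALSE
  )
  for (j in 3:12) {
    out[[SIMILARITY_COLS[j]]] <-
      .parse_numeric(m[, j], SIMILARITY_COLS[j], dat$lineno)
  }
  .validate_similarity(out, dat$lineno)
  out
}

.validate_similarity <- function(df, lineno) {
  chk <- function(bad, msg) {
    if (any(bad)) {
      stop(sprintf("line %d: %s", lineno[which(bad)[1L]], msg), call. = FALSE)
    }
  }
  chk(!nzchar(df$query_id) | !nzchar(df$subject_id),
      "empty query or subject id")
  chk(df$percent_identity < 0 | df$percent_identity > 100,
      "percent identity outside [0, 100]")
  chk(df$alignment_length < 1, "alignment length < 1")
  chk(df$e_value < 0, "negative E-value")
  invisible(df)
}

#' Write a similarity table in the 12-column tabular format
#'
#' Inverse of [read_similarity_table()]; used by the synthetic generator.
#'
#' @param hits Data frame as returned by [read_similarity_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_similarity_table <- function(hits, path) {
  stopifnot(identical(names(hits), SIMILARITY_COLS))
  lines <- apply(hits, 1L, function(r) paste(trimws(r), collapse = "\t"))
  writeLines(as.character(lines), path)
  invisible(path)
}

#' Read a 13-column InterProScan protein-signature table
#'
#' Parses the tab-separated InterProScan output (`-f tsv`). Files may carry
#' more than 13 columns when GO terms or pathway annotations were requested;
#' columns beyond the 13th are ignored. The InterProScan missing-value token
#' `-` maps to the empty string in text columns.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `protein_id`, `sequence_md5`,
#'   `sequence_length`, `analysis`, `signature_accession`,
#'   `signature_description`, `match_start`, `match_end`, `score`, `status`,
#'   `run_date`, `interpro_accession`, `interpro_description`. One protein may
#'   span many rows (one per signature match).
#' @export
read_signature_table <- function(path) {
  dat <- .read_data_lines(path)
  empty <- as.data.frame(setNames(rep(list(character(0)), 13), SIGNATURE_COLS))
  empty$sequence_length <- integer(0)
  empty$match_start <- integer(0)
  empty$match_end <- integer(0)
  empty$score <- numeric(0)
  if (length(dat$lines) == 0L) {
    warning("signature table is empty: ", path)
    return(empty)
  }
  fields <- .split_fields(dat$lines)
  nf <- lengths(fields)
  if (any(nf < 13L)) {
    i <- which(nf < 13L)[1L]
    stop(sprintf("line %d: expected at least 13 tab-separated fields, found %d",
                 dat$lineno[i], nf[i]), call. = FALSE)
  }
  m <- t(vapply(fields, function(f) f[1:13], character(13L)))
  m[m == "-"] <- ""
  out <- data.frame(
    protein_id = m[, 1], sequence_md5 = m[, 2],
    sequence_length = NA_integer_, analysis = m[, 4],
    signature_accession = m[, 5], signature_description = m[, 6],
    match_start = NA_integer_, match_end = NA_integer_,
    score = NA_real_, status = m[, 10], run_date = m[, 11],
    interpro_accession = m[, 12], interpro_description = m[, 13],
    stringsAsFactors = FALSE
  )
  out$sequence_length <-
    as.integer(.parse_numeric(m[, 3], "sequence_length", dat$lineno))
  out$match_start <- as.integer(.parse_numeric(m[, 7], "match_start", dat$lineno))
  out$match_end <- as.integer(.parse_numeric(m[, 8], "match_end", dat$lineno))
  sc <- m[, 9]
  sc[!nzchar(sc)] <- NA_character_
  out$score <- suppressWarnings(as.numeric(sc))
  bad <- is.na(out$sequence_length) | out$sequence_length < 1L
  if (any(bad)) {
    stop(sprintf("line %d: sequence_length must be a positive integer",
                 dat$lineno[which(bad)[1L]]), call. = FALSE)
  }
  bad <- !nzchar(out$protein_id)
  if (any(bad)) {
    stop(sprintf("line %d: empty protein id", dat$lineno[which(bad)[1L]]),
         call. = FALSE)
  }
  bad <- out$match_start < 1L | out$match_end < out$match_start |
    out$match_end > out$sequence_length
  if (any(bad)) {
    stop(sprintf("line %d: match coordinates outside [1, sequence_length]",
                 dat$lineno[which(bad)[1L]]), call. = FALSE)
  }
  out
}

#' Write a 13-column protein-signature table
#'
#' Inverse of [read_signature_table()]. Empty text fields are written as the
#' conventional `-` token.
#'
#' @param sig Data frame as returned by [read_signature_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signature_table <- function(sig, path) {
  stopifnot(identical(names(sig), SIGNATURE_COLS))
  m <- vapply(SIGNATURE_COLS, function(col) {
    v <- as.character(sig[[col]])
    v[is.na(v) | !nzchar(v)] <- "-"
    v
  }, character(nrow(sig)))
  if (nrow(sig) == 1L) m <- matrix(m, nrow = 1L)
  writeLines(apply(m, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a two-column gene-to-KO assignment file
#'
#' Reads the tab-separated mapping of gene model identifiers to KEGG
#' Orthology accessions, as produced by BlastKOALA or GhostKOALA. The second
#' column may be empty (no assignment). Duplicate gene rows are collapsed,
#' keeping the first non-empty KO. Tokens not matching `K` + five digits are
#' kept as empty with a warning.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `gene_id` and `ko_accession` (empty
#'   string when unassigned), one row per gene.
#' @export
read_ko_file <- function(path) {
  dat <- .read_data_lines(path)
  if (length(dat$lines) == 0L) {
    return(data.frame(gene_id = character(0), ko_accession = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- .split_fields(dat$lines)
  gene <- vapply(fields, `[`, character(1L), 1L)
  ko <- vapply(fields, function(f) if (length(f) >= 2L) f[2L] else "",
               character(1L))
  ko[is.na(ko)] <- ""
  ko <- trimws(ko)
  bad <- nzchar(ko) & !grepl("^K[0-9]{5}$", ko)
  if (any(bad)) {
    warning(sprintf("%d KO token(s) not matching K##### kept as unassigned (first: '%s')",
                    sum(bad), ko[which(bad)[1L]]))
    ko[bad] <- ""
  }
  # collapse duplicates: first non-empty KO wins, else first row
  ord <- order(match(gene, unique(gene)), !nzchar(ko))
  gene <- gene[ord]; ko <- ko[ord]
  keep <- !duplicated(gene)
  out <- data.frame(gene_id = gene[keep], ko_accession = ko[keep],
                    stringsAsFactors = FALSE)
  out[match(unique(gene), out$gene_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Read a KO-to-pathway-category mapping table
#'
#' Three tab-separated columns: KO accession, category identifier (e.g.
#' `09101`) and category name (e.g. `Carbohydrate metabolism`). An optional
#' fourth column carries a KO description (e.g. `ferredoxin`). A KO may map
#' to several categories.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `ko_accession`, `category_id`,
#'   `category_name`, `ko_description`.
#' @export
read_category_map <- function(path) {
  dat <- .read_data_lines(path)
  if (length(dat$lines) == 0L) {
    return(data.frame(ko_accession = character(0), category_id = character(0),
                      category_name = character(0),
                      ko_description = character(0), stringsAsFactors = FALSE))
  }
  fields <- .split_fields(dat$lines)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1L]
    stop(sprintf("line %d: expected at least 3 tab-separated fields, found %d",
                 dat$lineno[i], nf[i]), call. = FALSE)
  }
  out <- data.frame(
    ko_accession = vapply(fields, `[`, character(1L), 1L),
    category_id = vapply(fields, `[`, character(1L), 2L),
    category_name = vapply(fields, `[`, character(1L), 3L),
    ko_description = vapply(fields, function(f)
      if (length(f) >= 4L) f[4L] else "", character(1L)),
    stringsAsFactors = FALSE
  )
  out[!duplicated(out[c("ko_accession", "category_id")]), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Read protein lengths from a FASTA file
#'
#' @param path Path to a protein FASTA file.
#' @return Named integer vector mapping each record id (first whitespace
#'   token of the header) to its sequence length in residues.
#' @export
read_fasta_lengths <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  len <- Biostrings::width(seqs)
  if (any(len == 0L)) {
    stop("empty sequence for FASTA id: ", ids[which(len == 0L)[1L]],
         call. = FALSE)
  }
  stats::setNames(as.integer(len), ids)
}

.join_semicolon <- function(x) paste(x, collapse = ";")

#' Write HSD groups as an 8-column tab-delimited table
#'
#' Column layout: (1) HSD identifier, (2) semicolon-joined member gene ids,
#' (3) semicolon-joined member protein lengths in amino acids, (4) distinct
#' Pfam accessions, (5) their descriptions, (6) distinct InterPro accessions,
#' (7) their descriptions, (8) classification label: `true`, `true;space`
#' (all copies lack domains) or `incomplete`. A header line (prefixed `#`) is
#' written first; optional provenance lines can precede it.
#'
#' @param groups Classified group table from [classify_groups()] (an
#'   unclassified [cluster_groups()] table is accepted; column 8 is then
#'   empty).
#' @param path Output path.
#' @param provenance Optional character vector of provenance lines, written
#'   as leading `#` comments (suppress for byte-identical reruns).
#' @return Invisibly, `path`.
#' @export
write_hsd_table <- function(groups, path, provenance = NULL) {
  lines <- character(0)
  if (!is.null(provenance)) {
    lines <- paste0("# ", provenance)
  }
  lines <- c(lines, paste0("# ", paste(HSD_TABLE_COLS, collapse = "\t")))
  if (nrow(groups) > 0L) {
    cls <- if ("classification" %in% names(groups)) {
      ifelse(groups$space_flag, paste0(groups$classification, ";space"),
             groups$classification)
    } else {
      rep("", nrow(groups))
    }
    body <- vapply(seq_len(nrow(groups)), function(i) {
      paste(
        groups$group_id[i],
        .join_semicolon(groups$members[[i]]),
        .join_semicolon(groups$member_lengths[[i]]),
        .join_semicolon(groups$pfam_accessions[[i]]),
        .join_semicolon(groups$pfam_descriptions[[i]]),
        .join_semicolon(groups$interpro_accessions[[i]]),
        .join_semicolon(groups$interpro_descriptions[[i]]),
        cls[i],
        sep = "\t"
      )
    }, character(1L))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

.split_semicolon <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1L]]
}

#' Read an 8-column HSD table written by [write_hsd_table()]
#'
#' @param path Path to the TSV file.
#' @return Data frame with list-columns `members`, `member_lengths`,
#'   `pfam_accessions`, `pfam_descriptions`, `interpro_accessions`,
#'   `interpro_descriptions` plus `group_id`, `classification` and
#'   `space_flag`.
#' @export
read_hsd_table <- function(path) {
  dat <- .read_data_lines(path)
  out <- data.frame(group_id = character(0), stringsAsFactors = FALSE)
  out$members <- list(); out$member_lengths <- list()
  out$pfam_accessions <- list(); out$pfam_descriptions <- list()
  out$interpro_accessions <- list(); out$interpro_descriptions <- list()
  out$classification <- character(0); out$space_flag <- logical(0)
  if (length(dat$lines) == 0L) return(out)
  fields <- .split_fields(dat$lines)
  nf <- lengths(fields)
  # a trailing empty classification field is dropped by strsplit
  if (any(nf < 7L | nf > 8L)) {
    i <- which(nf < 7L | nf > 8L)[1L]
    stop(sprintf("line %d: expected 8 tab-separated fields, found %d",
                 dat$lineno[i], nf[i]), call. = FALSE)
  }
  n <- length(fields)
  cls_raw <- vapply(fields, function(f) if (length(f) == 8L) f[8L] else "",
                    character(1L))
  data.frame(group_id = vapply(fields, `[`, character(1L), 1L),
             stringsAsFactors = FALSE) -> out
  out$members <- lapply(fields, function(f) .split_semicolon(f[2L]))
  out$member_lengths <- lapply(fields, function(f)
    as.integer(.split_semicolon(f[3L])))
  out$pfam_accessions <- lapply(fields, function(f) .split_semicolon(f[4L]))
  out$pfam_descriptions <- lapply(fields, function(f) .split_semicolon(f[5L]))
  out$interpro_accessions <- lapply(fields, function(f) .split_semicolon(f[6L]))
  out$interpro_descriptions <- lapply(fields, function(f) .split_semicolon(f[7L]))
  out$classification <- sub(";space$", "", cls_raw)
  out$space_flag <- grepl(";space$", cls_raw)
  out$size <- lengths(out$members)
  out
}
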