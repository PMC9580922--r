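# Domain-profile classification of HSD groups: true / incomplete / space.

#' Classify HSD groups by domain-profile agreement
#'
#' A group is `true` when all member proteins carry an identical set of
#' domain accessions — including the degenerate case where no member has any
#' domain at all (typically hypothetical proteins), which additionally
#' raises the `space` flag. A group is `incomplete` when members carry
#' differing domain sets. Comparison is by set of distinct accessions;
#' domain order and per-domain copy counts are ignored.
#'
#' @param groups Group table from [cluster_groups()].
#' @param genes Gene records from [build_gene_records()]; every member must
#'   have a record.
#' @param profile Which accession profile defines "same domain(s)":
#'   `"pfam"` (default) or `"interpro"`.
#' @return `groups` with added columns `classification` (`"true"` or
#'   `"incomplete"`), `space_flag` (logical) and list-column
#'   `shared_profile` (the common accession set for `true` groups, the
#'   union otherwise).
#' @export
classify_groups <- function(groups, genes, profile = c("pfam", "interpro")) {
  profile <- match.arg(profile)
  col <- if (profile == "pfam") "pfam_profile" else "interpro_profile"
  idx <- stats::setNames(seq_len(nrow(genes)), genes$gene_id)

  n <- nrow(groups)
  label <- character(n)
  space <- logical(n)
  shared <- vector("list", n)
  for (i in seq_len(n)) {
    m <- groups$members[[i]]
    if (anyNA(idx[m])) {
      stop("no gene record for member(s): ",
           paste(m[is.na(idx[m])], collapse = ", "), call. = FALSE)
    }
    profs <- genes[[col]][idx[m]]
    identical_sets <- all(vapply(profs[-1L], function(p)
      identical(p, profs[[1L]]), logical(1L)))
    if (identical_sets) {
      label[i] <- "true"
      space[i] <- length(profs[[1L]]) == 0L
      shared[[i]] <- profs[[1L]]
    } else {
      label[i] <- "incomplete"
      space[i] <- FALSE
      shared[[i]] <- sort(unique(unlist(profs)))
    }
  }
  groups$classification <- label
  groups$space_flag <- space
  groups$shared_profile <- shared
  groups
}

#' Tally group classifications
#'
#' @param groups Classified group table from [classify_groups()].
#' @return A list with integer fields `candidate` (all groups), `true_count`
#'   (identical domain profiles, including all-empty), `space` (no member
#'   has any domain; a subset of `true_count`) and `incomplete` (differing
#'   profiles). Always `candidate == true_count + incomplete` and
#'   `space <= true_count`.
#' @export
#' @examples
#' # 3 domain-consistent groups (1 of them domain-less) + 2 discordant ones
#' cls <- data.frame(classification = c("true","true","true",
#'                                      "incomplete","incomplete"),
#'                   space_flag = c(TRUE, FALSE, FALSE, FALSE, FALSE))
#' tally_classifications(cls)
tally_classifications <- function(groups) {
  stopifnot(all(groups$classification %in% c("true", "incomplete")),
            !any(groups$space_flag & groups$classification == "incomplete"))
  list(
    candidate = nrow(groups),
    true_count = sum(groups$classification == "true"),
    space = sum(groups$space_flag),
    incomplete = sum(groups$classification == "incomplete")
  )
}
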